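#' @title Four-symbol coupling algebra
#'
#' @description
#' Every Jacobian entry of a rational vector field is abstracted to one of
#' four symbols describing how variable \eqn{x_j} enters equation
#' \eqn{f_i}: absent (`0`), linear (`1`), nonlinear polynomial (`1b`,
#' printed \eqn{\bar 1}) or rational with \eqn{x_j} in the denominator
#' (`1bb`, printed \eqn{\bar{\bar 1}}). Observability matrices and their
#' determinant summaries are computed entirely in this algebra, using a
#' product and an addition law under which the more severe (less
#' observable) symbol always dominates.
#'
#' Symbols are stored as integer codes 0:3. The constants [SYM_ZERO],
#' [SYM_ONE], [SYM_BAR] and [SYM_DBL] name the codes.
#'
#' @name semiring
NULL

#' @rdname semiring
#' @export
SYM_ZERO <- 0L

#' @rdname semiring
#' @export
SYM_ONE <- 1L

#' @rdname semiring
#' @export
SYM_BAR <- 2L

#' @rdname semiring
#' @export
SYM_DBL <- 3L

# Text tokens used in model files and printed output, indexed by code + 1.
.sym_tokens <- c("0", "1", "1b", "1bb")

# Product and addition tables, transcribed rule by rule (rows = left
# operand, columns = right operand, both in code order 0, 1, 1b, 1bb).
# The tables are the source of truth; their equivalence with the
# "max severity unless a factor is absent" shortcut is asserted in tests.
#
# product:  0 x a = 0;  1 x a = a;  1b x a = a for a in {1b, 1bb}
#           (and 1b x 1 = 1b by commutativity);  1bb x a = 1bb for a != 0.
.sym_mul_table <- matrix(
  c(0L, 0L, 0L, 0L,
    0L, 1L, 2L, 3L,
    0L, 2L, 2L, 3L,
    0L, 3L, 3L, 3L),
  nrow = 4L, byrow = TRUE
)

# addition: 0 + a = a;  1 + a = a for a != 0;  1b + a = a for a not in
#           {0, 1} (and 1b + 1 = 1b, 1b + 1b = 1b);  1bb + a = 1bb.
.sym_add_table <- matrix(
  c(0L, 1L, 2L, 3L,
    1L, 1L, 2L, 3L,
    2L, 2L, 2L, 3L,
    3L, 3L, 3L, 3L),
  nrow = 4L, byrow = TRUE
)

# Weights used by the non-measured in-strength: 1 -> 1, 1b -> 2, 1bb -> 3.
.sym_weights <- c(0L, 1L, 2L, 3L)

.check_sym <- function(x, arg = deparse(substitute(x))) {
  x <- as.integer(x)
  if (anyNA(x) || any(x < 0L | x > 3L)) {
    stop("`", arg, "` must contain symbol codes in 0:3 (0, 1, 1b, 1bb)",
         call. = FALSE)
  }
  x
}

#' Symbolic product and sum of coupling symbols
#'
#' Vectorised product (`sym_mul`) and sum (`sym_add`) over the four-symbol
#' algebra. The product of anything with an absent coupling is absent;
#' otherwise both operations return the more severe operand, so that a
#' rational coupling anywhere in a chain marks the whole chain rational.
#'
#' @param a,b integer vectors of symbol codes in `0:3`.
#' @return An integer vector of symbol codes, recycled to the common length.
#' @examples
#' sym_mul(SYM_ONE, SYM_DBL)  # rational dominates
#' sym_add(SYM_ONE, SYM_BAR)  # polynomial dominates linear
#' @export
sym_mul <- function(a, b) {
  a <- .check_sym(a)
  b <- .check_sym(b)
  .sym_mul_table[cbind(a + 1L, b + 1L)]
}

#' @rdname sym_mul
#' @export
sym_add <- function(a, b) {
  a <- .check_sym(a)
  b <- .check_sym(b)
  .sym_add_table[cbind(a + 1L, b + 1L)]
}

#' Severity weight of coupling symbols
#'
#' Maps symbols to the integer weights used by the non-measured in-strength
#' criterion: linear couplings weigh 1, polynomial 2, rational 3, absent 0.
#'
#' @param a integer vector of symbol codes in `0:3`.
#' @return An integer vector of weights.
#' @export
sym_weight <- function(a) {
  .sym_weights[.check_sym(a) + 1L]
}

#' Convert between symbol codes and text tokens
#'
#' The serialization tokens are `"0"`, `"1"`, `"1b"` and `"1bb"`.
#'
#' @param a integer vector of symbol codes.
#' @param tok character vector of tokens.
#' @return `sym_to_token()` a character vector; `sym_from_token()` an
#'   integer vector of codes.
#' @export
sym_to_token <- function(a) {
  .sym_tokens[.check_sym(a) + 1L]
}

#' @rdname sym_to_token
#' @export
sym_from_token <- function(tok) {
  idx <- match(trimws(as.character(tok)), .sym_tokens)
  if (anyNA(idx)) {
    bad <- unique(tok[is.na(idx)])
    stop("unknown symbol token(s): ", paste(bad, collapse = ", "),
         " (expected 0, 1, 1b, 1bb)", call. = FALSE)
  }
  as.integer(idx - 1L)
}

#' Construct a symbolic matrix
#'
#' A symbolic matrix is an integer matrix of symbol codes with class
#' `"sym_matrix"`; it is the common currency of Jacobians and
#' observability matrices. Token input (character) is accepted.
#'
#' @param x an integer matrix of codes in `0:3`, or a character matrix of
#'   tokens, or anything coercible to one.
#' @param nrow,ncol optional dimensions when `x` is a vector.
#' @return An integer matrix with class `"sym_matrix"`.
#' @export
sym_matrix <- function(x, nrow = NULL, ncol = NULL) {
  if (is.character(x)) {
    dm <- dim(x)
    x <- sym_from_token(x)
    dim(x) <- dm
  }
  if (!is.matrix(x)) {
    if (is.null(nrow) || is.null(ncol)) {
      stop("`x` must be a matrix, or nrow/ncol must be given", call. = FALSE)
    }
    x <- matrix(as.integer(x), nrow = nrow, ncol = ncol)
  }
  storage.mode(x) <- "integer"
  .check_sym(x, "x")
  structure(x, class = c("sym_matrix", "matrix"))
}

#' @export
print.sym_matrix <- function(x, ...) {
  m <- matrix(sym_to_token(x), nrow = nrow(x))
  dimnames(m) <- dimnames(x)
  cat("symbolic matrix (", nrow(x), " x ", ncol(x), ")\n", sep = "")
  print(m, quote = FALSE)
  invisible(x)
}
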