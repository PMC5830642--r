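#' Measurement configurations
#'
#' A measurement configuration lists which state variables are measured
#' (the sensors) and how many reconstructed coordinates each contributes:
#' a coordinate count of `c` means the variable itself plus its first
#' `c - 1` time derivatives. The counts must total the dimension `d` of
#' the system the configuration is used with. The canonical string form
#' sorts sensors by variable index and writes counts as exponents, e.g.
#' `"x2^2 x3 x5^2"`.
#'
#' @param vars integer vector of sensor variable indices (distinct).
#' @param counts integer vector of coordinate counts (`>= 1`), same length.
#' @return An object of class `"meas_config"` with fields `vars`, `counts`,
#'   `m` (number of sensors) and `total` (sum of counts); entries are
#'   stored sorted by variable index.
#' @export
measurement_config <- function(vars, counts) {
  vars <- as.integer(vars)
  counts <- as.integer(counts)
  if (length(vars) != length(counts) || length(vars) == 0L) {
    stop("`vars` and `counts` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (anyDuplicated(vars)) {
    stop("duplicate sensor variable in configuration", call. = FALSE)
  }
  if (any(counts < 1L)) {
    stop("coordinate counts must be >= 1", call. = FALSE)
  }
  ord <- order(vars)
  structure(
    list(vars = vars[ord], counts = counts[ord],
         m = length(vars), total = sum(counts)),
    class = "meas_config"
  )
}

#' Parse a configuration string
#'
#' Grammar: whitespace-separated tokens `var` or `var^k` with `k >= 1`,
#' where `var` is a variable name of the model (or an `x<i>` index when
#' only a dimension is known).
#'
#' @param s configuration string, e.g. `"x2^2 x3 x5^2"`.
#' @param variables character vector of variable names used to resolve
#'   tokens (a [system_model()] may be given instead).
#' @return A [measurement_config()].
#' @export
parse_config <- function(s, variables) {
  if (inherits(variables, "system_model")) variables <- variables$variables
  toks <- strsplit(trimws(s), "\\s+")[[1L]]
  if (length(toks) == 0L) stop("empty configuration string", call. = FALSE)
  mt <- regmatches(toks, regexec("^([^\\^[:space:]]+)(\\^([0-9]+))?$", toks))
  bad <- vapply(mt, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed configuration token(s): ",
         paste(toks[bad], collapse = ", "),
         " (expected `var` or `var^k`)", call. = FALSE)
  }
  names_ <- vapply(mt, `[`, character(1), 2L)
  counts <- vapply(mt, `[`, character(1), 4L)
  counts <- ifelse(counts == "", "1", counts)
  idx <- match(names_, variables)
  if (anyNA(idx)) {
    stop("unknown variable(s) in configuration: ",
         paste(unique(names_[is.na(idx)]), collapse = ", "),
         "; model variables are ", paste(variables, collapse = ", "),
         call. = FALSE)
  }
  measurement_config(idx, as.integer(counts))
}

#' Canonical string form of a configuration
#'
#' @param config a [measurement_config()].
#' @param variables optional variable names; defaults to `x<i>`.
#' @return A single string, sensors sorted by variable index.
#' @export
format_config <- function(config, variables = NULL) {
  nm <- if (is.null(variables)) paste0("x", config$vars)
        else variables[config$vars]
  paste(ifelse(config$counts > 1L,
               paste0(nm, "^", config$counts), nm),
        collapse = " ")
}

#' @export
print.meas_config <- function(x, ...) {
  cat("measurement configuration: ", format_config(x),
      "  (m = ", x$m, ", total = ", x$total, ")\n", sep = "")
  invisible(x)
}

#' Propagate a symbolic row through the Jacobian
#'
#' One step of symbolic Lie-derivative propagation: given the symbolic
#' gradient row `v` of some Lie derivative, the gradient row of the next
#' Lie derivative has entries \eqn{w_j = \oplus_i (v_i \otimes J_{ij})},
#' the semiring row-by-matrix product.
#'
#' @param v integer vector of symbol codes, length `d`.
#' @param J a `d x d` [sym_matrix()].
#' @return An integer vector of symbol codes, length `d`.
#' @export
lie_row <- function(v, J) {
  J <- sym_matrix(as.matrix(J))
  d <- ncol(J)
  v <- .check_sym(v)
  if (length(v) != d || nrow(J) != d) {
    stop("dimension mismatch: |v| = ", length(v), ", J is ",
         nrow(J), " x ", ncol(J), call. = FALSE)
  }
  w <- rep(SYM_ZERO, d)
  for (i in which(v != SYM_ZERO)) {
    w <- sym_add(w, sym_mul(rep(v[i], d), J[i, ]))
  }
  w
}

#' Build the symbolic observability matrix
#'
#' For each sensor the matrix receives a block of rows: the unit row
#' selecting the sensor itself (gradient of the zeroth Lie derivative),
#' then the sensor's Jacobian row (gradient of the first), then further
#' rows obtained by [lie_row()] propagation, one per extra coordinate.
#' Blocks are stacked in configuration order; the result is square of
#' size `d` because the coordinate counts total `d`.
#'
#' @param J a `d x d` [sym_matrix()] (a symbolic Jacobian).
#' @param config a [measurement_config()] with `total == d`, or a
#'   configuration string (resolved against `x1..xd`).
#' @return A [sym_matrix()] with attribute `block_index`, a data frame
#'   giving for each row the sensor variable and derivative order.
#' @export
build_matrix <- function(J, config) {
  J <- sym_matrix(as.matrix(J))
  d <- nrow(J)
  if (is.character(config)) config <- parse_config(config, paste0("x", 1:d))
  if (!inherits(config, "meas_config")) {
    stop("`config` must be a measurement_config or a string", call. = FALSE)
  }
  if (any(config$vars > d)) {
    stop("configuration refers to variable index beyond d = ", d,
         call. = FALSE)
  }
  if (config$total != d) {
    stop("coordinate counts total ", config$total,
         " but the system dimension is ", d, call. = FALSE)
  }
  rows <- matrix(SYM_ZERO, d, d)
  sensor <- integer(d)
  order_ <- integer(d)
  r <- 0L
  for (k in seq_len(config$m)) {
    i <- config$vars[k]
    ci <- config$counts[k]
    v <- rep(SYM_ZERO, d)
    v[i] <- SYM_ONE
    for (ord in seq_len(ci) - 1L) {
      if (ord == 1L) {
        v <- J[i, ]              # gradient of the first Lie derivative
      } else if (ord > 1L) {
        v <- lie_row(v, J)
      }
      r <- r + 1L
      rows[r, ] <- v
      sensor[r] <- i
      order_[r] <- ord
    }
  }
  out <- sym_matrix(rows)
  attr(out, "block_index") <- data.frame(sensor = sensor, order = order_)
  out
}
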