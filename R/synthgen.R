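# run fn with R's RNG temporarily seeded, restoring the caller's stream
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Random symbolic coupling matrix
#'
#' Seeded generator of synthetic symbol matrices for property testing.
#' The diagonal is always nonzero (every variable relaxes or grows on its
#' own); each off-diagonal coupling is present with probability `density`
#' and its symbol is drawn from the mixture over linear / polynomial /
#' rational. With `ensure_connected`, any variable left fully decoupled
#' off-diagonally is linked to a random earlier variable so the coupling
#' graph has no isolated node.
#'
#' @param d dimension (`>= 2`).
#' @param density probability of an off-diagonal coupling, in (0, 1].
#' @param weights mixture weights over the symbols `(1, 1b, 1bb)`; need
#'   not be normalized.
#' @param seed integer seed; identical seeds give identical matrices.
#' @param ensure_connected logical, see above.
#' @return A `d x d` [sym_matrix()].
#' @export
random_symbol_matrix <- function(d, density = 0.3,
                                 weights = c(0.4, 0.3, 0.3),
                                 seed = 1L, ensure_connected = TRUE) {
  stopifnot(d >= 2L, density > 0, density <= 1, length(weights) == 3L,
            all(weights >= 0), sum(weights) > 0)
  .with_seed(seed, function() {
    syms <- c(SYM_ONE, SYM_BAR, SYM_DBL)
    M <- matrix(SYM_ZERO, d, d)
    diag(M) <- sample(syms, d, replace = TRUE, prob = weights)
    off <- which(row(M) != col(M))
    on <- off[stats::runif(length(off)) < density]
    M[on] <- sample(syms, length(on), replace = TRUE, prob = weights)
    if (ensure_connected) {
      for (j in seq_len(d)) {
        others <- setdiff(seq_len(d), j)
        if (all(M[j, others] == SYM_ZERO) &&
            all(M[others, j] == SYM_ZERO)) {
          k <- if (j > 1L) sample(seq_len(j - 1L), 1L) else 2L
          M[j, k] <- sample(syms, 1L, prob = weights)
        }
      }
    }
    sym_matrix(M)
  })
}

#' Realize a symbol matrix as a rational ODE system
#'
#' Constructs right-hand sides whose classified Jacobian is exactly the
#' given symbol matrix: a linear coupling becomes a term `a*x_j`; a
#' polynomial coupling becomes a product `a*x_j*x_k` with a partner `k`
#' drawn (from the seed) among the other polynomial couplings of the same
#' equation, or `a*x_j^2` when the equation has no such partner; a
#' rational coupling becomes a saturating term `a*x_j/(K + x_j)`. All
#' coefficients are fresh parameter names, so no two terms can cancel.
#' The central round-trip property — [build_symbolic_jacobian()] of the
#' realized model returns the input matrix — holds by construction and is
#' exercised in the test suite.
#'
#' @param J a square [sym_matrix()].
#' @param seed integer seed for partner choices.
#' @param name model name.
#' @return A [system_model()] with `rhs` present.
#' @export
realize_odes <- function(J, seed = 1L, name = "synthetic") {
  J <- sym_matrix(as.matrix(J))
  d <- nrow(J)
  if (d != ncol(J)) stop("matrix must be square", call. = FALSE)
  vars <- paste0("x", seq_len(d))
  rhs <- .with_seed(seed, function() {
    vapply(seq_len(d), function(i) {
      terms <- character(0)
      bars <- which(J[i, ] == SYM_BAR)
      for (j in seq_len(d)) {
        a <- sprintf("a%d_%d", i, j)
        term <- switch(as.character(J[i, j]),
          "0" = NULL,
          "1" = sprintf("%s*x%d", a, j),
          "2" = {
            partners <- setdiff(bars, j)
            if (length(partners)) {
              k <- if (length(partners) == 1L) partners
                   else sample(partners, 1L)
              sprintf("%s*x%d*x%d", a, j, k)
            } else {
              sprintf("%s*x%d^2", a, j)
            }
          },
          "3" = sprintf("%s*x%d/(K%d_%d + x%d)", a, j, i, j, j)
        )
        if (!is.null(term)) terms <- c(terms, term)
      }
      if (length(terms) == 0L) "0" else paste(terms, collapse = " + ")
    }, character(1))
  })
  system_model(vars, rhs = rhs, name = name)
}
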