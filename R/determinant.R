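#' Symbolic determinant summary
#'
#' The symbolic determinant of an observability matrix is expanded over
#' all permutations, with no sign bookkeeping and no cancellation: every
#' permutation whose factors are all nonzero contributes one term, and the
#' symbols of its `d` factors are tallied. The summary keeps only the term
#' count `T` and the total occurrences `N1`, `Nbar`, `Ndbl` of the linear,
#' polynomial and rational symbols over all terms — everything the
#' observability coefficient needs.
#'
#' `det_summary()` computes the tallies by a dynamic program over column
#' subsets (the standard permanent recursion, here aggregating occurrence
#' totals alongside term counts) and handles dimensions up to ~20.
#' `det_summary_bruteforce()` enumerates the permutations explicitly and
#' is kept as an independent oracle for small matrices (`d <= 8`).
#'
#' @param M a square [sym_matrix()].
#' @return An object of class `"det_summary"`: a list with fields `T`,
#'   `n1`, `nbar`, `ndbl` and `d`. Always `n1 + nbar + ndbl = d * T`.
#' @export
det_summary <- function(M) {
  M <- sym_matrix(as.matrix(M))
  d <- nrow(M)
  if (d != ncol(M)) stop("matrix must be square", call. = FALSE)
  if (d > 25L) stop("dimension ", d, " too large for the subset recursion",
                    call. = FALSE)
  nset <- 2L^d
  sets <- 0:(nset - 1L)
  cnt <- numeric(nset); cnt[1L] <- 1
  t1 <- tb <- td <- numeric(nset)
  for (k in seq_len(d)) {
    ncnt <- numeric(nset)
    n1 <- nb <- nd <- numeric(nset)
    for (j in which(M[k, ] != SYM_ZERO)) {
      bit <- 2^(j - 1L)
      src <- which(bitwAnd(sets, bit) == 0 & cnt > 0)
      if (!length(src)) next
      tgt <- src + bit
      w <- M[k, j]
      ncnt[tgt] <- ncnt[tgt] + cnt[src]
      n1[tgt] <- n1[tgt] + t1[src] + (w == SYM_ONE) * cnt[src]
      nb[tgt] <- nb[tgt] + tb[src] + (w == SYM_BAR) * cnt[src]
      nd[tgt] <- nd[tgt] + td[src] + (w == SYM_DBL) * cnt[src]
    }
    cnt <- ncnt; t1 <- n1; tb <- nb; td <- nd
  }
  .det_summary(T = cnt[nset], n1 = t1[nset], nbar = tb[nset],
               ndbl = td[nset], d = d)
}

.det_summary <- function(T, n1, nbar, ndbl, d) {
  structure(list(T = T, n1 = n1, nbar = nbar, ndbl = ndbl, d = d),
            class = "det_summary")
}

#' @export
print.det_summary <- function(x, ...) {
  cat("symbolic determinant: T = ", x$T, " term(s); N1 = ", x$n1,
      ", Nbar = ", x$nbar, ", Ndbl = ", x$ndbl, "\n", sep = "")
  invisible(x)
}

# all permutations of 1:d as a matrix (d! rows); recursion is fine for d <= 8
.perm_matrix <- function(d) {
  if (d == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perm_matrix(d - 1L)
  out <- vector("list", d)
  for (k in seq_len(d)) {
    rest <- seq_len(d)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), d - 1L))
  }
  do.call(rbind, out)
}

#' @rdname det_summary
#' @export
det_summary_bruteforce <- function(M) {
  M <- sym_matrix(as.matrix(M))
  d <- nrow(M)
  if (d != ncol(M)) stop("matrix must be square", call. = FALSE)
  if (d > 8L) {
    stop("brute-force enumeration is limited to d <= 8 (oracle use only)",
         call. = FALSE)
  }
  P <- .perm_matrix(d)
  E <- matrix(0L, nrow(P), d)
  for (k in seq_len(d)) E[, k] <- M[(P[, k] - 1L) * d + k]
  keep <- rowSums(E == SYM_ZERO) == 0L
  E <- E[keep, , drop = FALSE]
  .det_summary(T = sum(keep), n1 = sum(E == SYM_ONE),
               nbar = sum(E == SYM_BAR), ndbl = sum(E == SYM_DBL), d = d)
}

# 2-dp rounding, half away from zero, exact while the integers fit doubles
.round2_exact <- function(num, den) {
  if (den <= 0) stop("invalid denominator")
  if (200 * num + den < 2^53) {
    floor((200 * num + den) / (2 * den)) / 100
  } else {
    round(num / den, 2L)
  }
}

#' Symbolic observability coefficient
#'
#' Converts a determinant summary into the scalar coefficient
#' \deqn{\eta = N_1/D + \bar N/D^2 + \bar{\bar N}/D^3, \quad
#'       D = \max(1, N_1) + \bar N + \bar{\bar N},}
#' with the rational-system condition applied first: if no polynomial
#' symbol occurs but rational ones do (\eqn{\bar N = 0},
#' \eqn{\bar{\bar N} > 0}), set \eqn{\bar N \leftarrow \bar{\bar N}}. An
#' empty determinant (`T == 0`, a structurally rank-deficient matrix)
#' gives \eqn{\eta = 0}; \eqn{\eta = 1} exactly when at least one term
#' exists and all symbols are linear. The value is carried as an exact
#' integer fraction and only rounded (half away from zero) for the
#' two-decimal display field.
#'
#' @param summary a `"det_summary"` object.
#' @return An object of class `"obs_coefficient"`: list with `eta` (double),
#'   `eta_num`/`eta_den` (exact fraction), `eta_2dp`, `D` and `summary`.
#' @export
observability_coefficient <- function(summary) {
  stopifnot(inherits(summary, "det_summary"))
  if (summary$T == 0) {
    out <- list(eta = 0, eta_num = 0, eta_den = 1, eta_2dp = 0,
                D = 0, summary = summary)
    return(structure(out, class = "obs_coefficient"))
  }
  n1 <- summary$n1
  nbar <- summary$nbar
  ndbl <- summary$ndbl
  if (nbar == 0 && ndbl > 0) nbar <- ndbl  # rational-system condition
  D <- max(1, n1) + nbar + ndbl
  num <- n1 * D^2 + nbar * D + ndbl
  den <- D^3
  eta2 <- .round2_exact(num, den)
  structure(
    list(eta = num / den, eta_num = num, eta_den = den, eta_2dp = eta2,
         D = D, summary = summary),
    class = "obs_coefficient"
  )
}

#' @export
print.obs_coefficient <- function(x, ...) {
  cfg <- attr(x, "config_string")
  if (!is.null(cfg)) cat("configuration:", cfg, "\n")
  cat(sprintf("eta = %s = %.2f  (exact %s/%s)\n",
              format(x$eta, digits = 6), x$eta_2dp,
              format(x$eta_num, scientific = FALSE),
              format(x$eta_den, scientific = FALSE)))
  print(x$summary)
  invisible(x)
}

#' Observability coefficient of a measurement configuration
#'
#' End-to-end pipeline: build the symbolic observability matrix for the
#' configuration, summarize its symbolic determinant, and evaluate the
#' observability coefficient.
#'
#' @param model a [system_model()].
#' @param config a [measurement_config()] or a configuration string over
#'   the model's variable names.
#' @return An `"obs_coefficient"` with the configuration attached.
#' @examples
#' gold <- fixture_model("goldbeter5d")
#' coefficient_for(gold, "x2^2 x3 x5^2")  # fully observable
#' coefficient_for(gold, "x5^5")
#' @export
coefficient_for <- function(model, config) {
  stopifnot(inherits(model, "system_model"))
  if (is.character(config)) config <- parse_config(config, model$variables)
  if (config$total != model$d) {
    stop("configuration provides ", config$total,
         " coordinates but the model dimension is ", model$d, call. = FALSE)
  }
  O <- build_matrix(model$jacobian, config)
  res <- observability_coefficient(det_summary(O))
  attr(res, "config") <- config
  attr(res, "config_string") <- format_config(config, model$variables)
  res
}
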