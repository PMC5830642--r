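#' Linear out-strength of each variable
#'
#' Counts, for each variable, in how many *other* equations it appears
#' linearly: \eqn{\sigma^{lin}_{out}(i) = \#\{j \ne i : \tilde J_{ji} = 1\}}.
#' A variable with zero linear out-strength is never seen linearly by the
#' rest of the network and must itself be measured for full observability.
#'
#' @param J a square [sym_matrix()].
#' @return An integer vector, one entry per variable.
#' @export
linear_out_strength <- function(J) {
  J <- sym_matrix(as.matrix(J))
  d <- nrow(J)
  vapply(seq_len(d),
         function(i) sum(J[-i, i] == SYM_ONE),
         integer(1))
}

#' In-strength from the non-measured variables
#'
#' Weighted count of couplings from candidate non-measured variables into
#' each variable's equation: \eqn{\sigma^{nm}_{in}(i) = \sum_{k \in V_{nm},
#' k \ne i} w(\tilde J_{ik})} with weights 1 (linear), 2 (polynomial) and
#' 3 (rational). The more nonlinearly an equation is fed by unmeasured
#' variables, the less the system is observable through it, so among
#' candidates the one with the *larger* in-strength is preferably removed
#' from the sensor set.
#'
#' @param J a square [sym_matrix()].
#' @param Vnm integer vector of candidate non-measured variable indices
#'   (non-empty).
#' @return An integer vector over all variables (named by index).
#' @export
nonmeasured_in_strength <- function(J, Vnm) {
  J <- sym_matrix(as.matrix(J))
  d <- nrow(J)
  Vnm <- as.integer(Vnm)
  if (length(Vnm) == 0L) {
    stop("`Vnm` must be a non-empty set of variable indices", call. = FALSE)
  }
  if (any(Vnm < 1L | Vnm > d)) {
    stop("`Vnm` contains indices outside 1..", d, call. = FALSE)
  }
  out <- vapply(seq_len(d), function(i) {
    ks <- setdiff(Vnm, i)
    if (!length(ks)) return(0L)
    sum(sym_weight(J[i, ks]))
  }, integer(1))
  stats::setNames(out, seq_len(d))
}

#' Exclusive pairs of candidate sensors
#'
#' Two candidate variables form an exclusive pair when they are coupled to
#' each other linearly and each is seen linearly by no other equation
#' (\eqn{\tilde J_{ij} = \tilde J_{ji} = 1} and both linear out-strengths
#' equal 1). Each can then only be reconstructed through the other, so at
#' least one member of every such pair must be measured.
#'
#' @param J a square [sym_matrix()].
#' @param candidates integer vector of candidate variable indices.
#' @param sigma linear out-strengths, as from [linear_out_strength()].
#' @return A two-column integer matrix, one unordered pair per row
#'   (possibly zero rows).
#' @export
exclusive_pairs <- function(J, candidates, sigma = linear_out_strength(J)) {
  J <- sym_matrix(as.matrix(J))
  candidates <- sort(as.integer(candidates))
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (length(candidates) < 2L) return(pairs)
  for (a in seq_along(candidates)[-length(candidates)]) {
    for (b in (a + 1L):length(candidates)) {
      i <- candidates[a]; j <- candidates[b]
      if (J[i, j] == SYM_ONE && J[j, i] == SYM_ONE &&
          sigma[i] == 1L && sigma[j] == 1L) {
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  pairs
}

#' Preselect minimal sensor sets from the symbolic Jacobian
#'
#' Applies the two graph-strength criteria to propose minimal sets of
#' measured variables before any coefficient is computed:
#' \enumerate{
#'   \item variables with zero linear out-strength are essential (must be
#'     measured); the rest are candidates for removal;
#'   \item among the candidates, exclusive pairs are found; in each pair
#'     the member with the larger in-strength from the candidate set is
#'     removed (ties produce one branch per choice); candidates in no
#'     pair are removed outright;
#'   \item a removed variable must appear in at least one measured
#'     equation (reachability), otherwise it is retained after all.
#' }
#'
#' @param model a [system_model()].
#' @return An object of class `"preselection_report"`: list with
#'   `sigma_out_lin`, `essential`, `removable`, `exclusive_pairs`,
#'   `sigma_in_nm` (over `Vnm` = the full removable set) and `branches`,
#'   each branch a list with `removed`, `sensors` and `reachable`
#'   (named logical over the removed variables).
#' @export
preselect <- function(model) {
  stopifnot(inherits(model, "system_model"))
  J <- model$jacobian
  d <- model$d
  sigma <- linear_out_strength(J)
  essential <- which(sigma == 0L)
  removable <- which(sigma > 0L)
  report <- structure(
    list(sigma_out_lin = sigma, essential = essential,
         removable = removable,
         exclusive_pairs = matrix(integer(0), ncol = 2L),
         sigma_in_nm = integer(0), branches = list()),
    class = "preselection_report"
  )
  if (length(removable) == 0L) {
    report$branches <- list(list(removed = integer(0),
                                 sensors = seq_len(d),
                                 reachable = logical(0)))
    return(report)
  }
  sig_in <- nonmeasured_in_strength(J, removable)
  pairs <- exclusive_pairs(J, removable, sigma)
  report$exclusive_pairs <- pairs
  report$sigma_in_nm <- sig_in[removable]
  unpaired <- setdiff(removable, as.integer(pairs))
  # one removal choice per exclusive pair; exact ties branch
  choices <- list(integer(0))
  if (nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      drop_ <- if (sig_in[i] > sig_in[j]) list(i)
               else if (sig_in[j] > sig_in[i]) list(j)
               else list(i, j)
      choices <- unlist(lapply(choices, function(ch)
        lapply(drop_, function(v) c(ch, v))), recursive = FALSE)
    }
  }
  report$branches <- lapply(choices, function(ch) {
    removed0 <- sort(unique(c(unpaired, ch)))
    sensors0 <- setdiff(seq_len(d), removed0)
    # reachability: a removed variable must feed some measured equation
    reach <- vapply(removed0, function(v)
      any(J[sensors0, v] != SYM_ZERO), logical(1))
    names(reach) <- paste0("x", removed0)
    removed <- removed0[reach]  # unreachable candidates are retained
    list(removed = removed, sensors = setdiff(seq_len(d), removed),
         reachable = reach)
  })
  report
}

#' Sensor sets proposed by a preselection report
#'
#' @param report a `"preselection_report"`.
#' @return A list of integer vectors, one minimal sensor set per branch.
#' @export
sensor_sets <- function(report) {
  stopifnot(inherits(report, "preselection_report"))
  lapply(report$branches, `[[`, "sensors")
}

#' @export
print.preselection_report <- function(x, ...) {
  cat("sensor preselection\n")
  cat("  linear out-strength:",
      paste(x$sigma_out_lin, collapse = " "), "\n")
  cat("  essential (must measure): ",
      if (length(x$essential)) paste0("x", x$essential, collapse = ", ")
      else "none", "\n", sep = "")
  if (nrow(x$exclusive_pairs)) {
    cat("  exclusive pairs:",
        paste(apply(x$exclusive_pairs, 1L, function(p)
          paste0("{x", p[1L], ", x", p[2L], "}")), collapse = " "), "\n")
  }
  if (length(x$sigma_in_nm)) {
    cat("  in-strength from candidates:",
        paste0("x", x$removable, "=", x$sigma_in_nm, collapse = " "), "\n")
  }
  for (b in seq_along(x$branches)) {
    br <- x$branches[[b]]
    cat("  branch ", b, ": measure {",
        paste0("x", br$sensors, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}
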