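#' Search specifications
#'
#' Bundles the constraints of a configuration search: the range of the
#' number `m` of measured variables, an optional cap on per-variable
#' coordinate counts, the reporting threshold on the observability
#' coefficient (0.75 by default, the customary bound for "good"
#' observability), and required/forbidden variable sets.
#'
#' @param m_min,m_max inclusive bounds on the number of measured
#'   variables; defaults to `1` and `d - 1` at use (the full-measurement
#'   configuration, which needs no derivatives, is excluded by default).
#' @param max_count optional maximum coordinate count per sensor.
#' @param min_eta report threshold; configurations below it are dropped
#'   unless `retain_all`.
#' @param required,forbidden integer vectors of variable indices that
#'   every / no measured set may contain.
#' @param retain_all keep all evaluated configurations regardless of
#'   `min_eta`.
#' @return An object of class `"search_spec"`.
#' @export
search_spec <- function(m_min = NULL, m_max = NULL, max_count = NULL,
                        min_eta = 0.75, required = integer(),
                        forbidden = integer(), retain_all = FALSE) {
  structure(
    list(m_min = m_min, m_max = m_max, max_count = max_count,
         min_eta = min_eta, required = as.integer(required),
         forbidden = as.integer(forbidden), retain_all = retain_all),
    class = "search_spec"
  )
}

.resolve_m_range <- function(spec, d) {
  m_min <- spec$m_min %||% 1L
  m_max <- spec$m_max %||% (d - 1L)
  if (!(m_min >= 1L && m_min <= m_max && m_max <= d)) {
    stop("invalid sensor-count range [", m_min, ", ", m_max,
         "] for dimension ", d, call. = FALSE)
  }
  c(m_min, m_max)
}

#' Count reconstruction configurations
#'
#' A configuration measures `m` of the `d` variables and distributes the
#' remaining `d - m` coordinates as extra derivatives over the sensors,
#' so there are \eqn{\sum_m \binom{d}{m}\binom{d-1}{m-1}} configurations
#' over an `m` range. The default range `1..d-1` excludes the single
#' derivative-free full measurement.
#'
#' @param d system dimension (`>= 2`).
#' @param m_min,m_max inclusive range of the number of measured variables.
#' @return The configuration count as a double.
#' @examples
#' count_configs(5)   # 125
#' count_configs(9)   # 24309
#' count_configs(13)  # about 5.2e6
#' @export
count_configs <- function(d, m_min = 1L, m_max = d - 1L) {
  if (d < 2L) stop("`d` must be at least 2", call. = FALSE)
  if (!(m_min >= 1L && m_min <= m_max && m_max <= d)) {
    stop("invalid range [", m_min, ", ", m_max, "] for d = ", d,
         call. = FALSE)
  }
  ms <- m_min:m_max
  sum(choose(d, ms) * choose(d - 1L, ms - 1L))
}

# positive compositions of `total` into `parts` parts (rows), lexicographic
.compositions <- function(total, parts) {
  if (parts == 1L) return(matrix(total, 1L, 1L))
  out <- list()
  for (first in seq_len(total - parts + 1L)) {
    rest <- .compositions(total - first, parts - 1L)
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# iterate configurations satisfying `spec`; calls fn(config) for each and
# returns the number visited. Canonical order: m ascending, variable sets
# in combn order, coordinate compositions lexicographic.
.for_each_config <- function(d, spec, fn) {
  rng <- .resolve_m_range(spec, d)
  pool <- setdiff(seq_len(d), spec$forbidden)
  visited <- 0L
  for (m in rng[1L]:rng[2L]) {
    if (m > length(pool)) next
    sets <- utils::combn(pool, m)
    comps <- .compositions(d, m)
    if (!is.null(spec$max_count)) {
      comps <- comps[apply(comps, 1L, max) <= spec$max_count, ,
                     drop = FALSE]
    }
    for (ci in seq_len(ncol(sets))) {
      vars <- sets[, ci]
      if (length(spec$required) && !all(spec$required %in% vars)) next
      for (ri in seq_len(nrow(comps))) {
        fn(measurement_config(vars, comps[ri, ]))
        visited <- visited + 1L
      }
    }
  }
  visited
}

#' Enumerate reconstruction configurations
#'
#' Materializes every configuration consistent with a [search_spec()],
#' each exactly once, in canonical order. The cardinality of the
#' unconstrained enumeration equals [count_configs()]. For very large
#' spaces prefer [evaluate_configs()], which streams instead of
#' materializing.
#'
#' @param d system dimension.
#' @param spec a [search_spec()].
#' @return A list of [measurement_config()] objects.
#' @export
enumerate_configs <- function(d, spec = search_spec()) {
  out <- vector("list", 0L)
  k <- 0L
  .for_each_config(d, spec, function(cfg) {
    k <<- k + 1L
    out[[k]] <<- cfg
  })
  out
}

.results_row <- function(model, config, res) {
  s <- res$summary
  data.frame(
    config = format_config(config, model$variables),
    m = config$m, total = config$total,
    eta = res$eta, eta_2dp = res$eta_2dp,
    eta_num = res$eta_num, eta_den = res$eta_den,
    T = s$T, N1 = s$n1, Nbar = s$nbar, Ndbl = s$ndbl,
    stringsAsFactors = FALSE
  )
}

.rank_results <- function(rows, strategy, model, evaluated) {
  if (length(rows) == 0L) {
    df <- data.frame(config = character(), m = integer(),
                     total = integer(), eta = numeric(),
                     eta_2dp = numeric(), eta_num = numeric(),
                     eta_den = numeric(), T = numeric(), N1 = numeric(),
                     Nbar = numeric(), Ndbl = numeric(),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, rows)
    df <- df[order(-df$eta, df$m, df$config), , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "strategy") <- strategy
  attr(df, "model") <- model$name
  attr(df, "evaluated") <- evaluated
  class(df) <- c("ranked_results", "data.frame")
  df
}

#' @export
print.ranked_results <- function(x, ...) {
  cat("ranked observability results for '", attr(x, "model"),
      "' (strategy: ", attr(x, "strategy"), "; ",
      attr(x, "evaluated"), " configurations evaluated)\n", sep = "")
  print.data.frame(x[, c("config", "m", "eta_2dp", "T", "N1", "Nbar",
                         "Ndbl")], ...)
  invisible(x)
}

#' Evaluate and rank measurement configurations
#'
#' Computes the observability coefficient of every configuration admitted
#' by the search specification and returns the retained ones ranked by
#' decreasing coefficient, then by fewer sensors, then by canonical
#' configuration string. Configurations are streamed, never materialized
#' in bulk, and an optional progress callback reports the running count
#' and best coefficient.
#'
#' @param model a [system_model()].
#' @param spec a [search_spec()].
#' @param progress optional `function(evaluated, best_eta)` called every
#'   `progress_every` configurations.
#' @param progress_every integer interval for the callback.
#' @return A `"ranked_results"` data frame with one row per retained
#'   configuration; attributes record the strategy and the number of
#'   configurations evaluated.
#' @export
evaluate_configs <- function(model, spec = search_spec(), progress = NULL,
                             progress_every = 1000L) {
  stopifnot(inherits(model, "system_model"))
  rows <- list()
  k <- 0L
  best <- 0
  n <- .for_each_config(model$d, spec, function(cfg) {
    res <- coefficient_for(model, cfg)
    best <<- max(best, res$eta)
    if (spec$retain_all || res$eta >= spec$min_eta) {
      k <<- k + 1L
      rows[[k]] <<- .results_row(model, cfg, res)
    }
    if (!is.null(progress) && (k %% progress_every == 0L)) {
      progress(k, best)
    }
  })
  .rank_results(rows, "exhaustive", model, n)
}

#' Leave-one-out observability scan
#'
#' For every excluded variable `j`, measures the remaining `d - 1`
#' variables and places the single extra coordinate (one first
#' derivative) on each measured variable `i` in turn, reporting the
#' observability coefficient per `(j, i)` cell. The scan locates
#' variables whose absence still permits full observability — exactly
#' those seen linearly by some measured equation.
#'
#' @param model a [system_model()].
#' @return A data frame with columns `excluded`, `derivative`, `eta`,
#'   `eta_2dp`.
#' @export
leave_one_out_scan <- function(model) {
  stopifnot(inherits(model, "system_model"))
  d <- model$d
  if (d < 3L) stop("the scan needs d >= 3", call. = FALSE)
  rows <- list()
  k <- 0L
  for (j in seq_len(d)) {
    vars <- setdiff(seq_len(d), j)
    for (i in vars) {
      counts <- rep(1L, d - 1L)
      counts[match(i, vars)] <- 2L
      res <- coefficient_for(model, measurement_config(vars, counts))
      k <- k + 1L
      rows[[k]] <- data.frame(excluded = j, derivative = i,
                              eta = res$eta, eta_2dp = res$eta_2dp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Search restricted to preselected sensor sets
#'
#' Evaluates only configurations whose measured set contains every
#' essential variable and at least one member of each exclusive pair of
#' the preselection report — the reduced space the two network criteria
#' single out. Branches of the report are merged by construction (the
#' pair constraint subsumes them) and no configuration is evaluated
#' twice.
#'
#' @param model a [system_model()].
#' @param report a `"preselection_report"` for the same model; defaults
#'   to `preselect(model)`.
#' @param spec a [search_spec()].
#' @return A `"ranked_results"` data frame.
#' @export
reduced_search <- function(model, report = preselect(model),
                           spec = search_spec()) {
  stopifnot(inherits(model, "system_model"),
            inherits(report, "preselection_report"))
  pairs <- report$exclusive_pairs
  rows <- list()
  k <- 0L
  base <- spec
  base$required <- sort(unique(c(spec$required, report$essential)))
  n_eval <- 0L
  .for_each_config(model$d, base, function(cfg) {
    if (nrow(pairs) > 0L) {
      for (r in seq_len(nrow(pairs))) {
        if (!any(pairs[r, ] %in% cfg$vars)) return(invisible(NULL))
      }
    }
    n_eval <<- n_eval + 1L
    res <- coefficient_for(model, cfg)
    if (spec$retain_all || res$eta >= spec$min_eta) {
      k <<- k + 1L
      rows[[k]] <<- .results_row(model, cfg, res)
    }
  })
  .rank_results(rows, "preselect", model, n_eval)
}
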