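#' Construct a system model
#'
#' A `system_model` bundles an ordered set of state variables, the names
#' treated as constant parameters, optionally the right-hand sides of the
#' ODEs as expressions, and the d x d symbolic Jacobian. When right-hand
#' sides are supplied the Jacobian is derived by classifying every partial
#' derivative; alternatively the Jacobian may be given directly as a token
#' matrix (no expressions attached).
#'
#' @param variables character vector of state-variable names (unique).
#' @param rhs optional list/character vector of d expressions, one per
#'   variable, over variables and parameters using `+ - * / ^`.
#' @param jacobian optional `d x d` symbolic matrix (codes or tokens);
#'   ignored when `rhs` is given.
#' @param parameters optional character vector of parameter names; free
#'   names found in `rhs` are added automatically.
#' @param name model name.
#' @return An object of class `"system_model"` with fields `name`, `d`,
#'   `variables`, `parameters`, `rhs` (list of calls or `NULL`) and
#'   `jacobian` (a [sym_matrix()]).
#' @export
system_model <- function(variables, rhs = NULL, jacobian = NULL,
                         parameters = character(), name = "model") {
  variables <- as.character(variables)
  d <- length(variables)
  if (d < 1L) stop("at least one state variable is required", call. = FALSE)
  if (anyDuplicated(variables)) {
    stop("duplicate state variable name(s): ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(parameters %in% variables)) {
    stop("parameter names must be disjoint from variable names",
         call. = FALSE)
  }
  model <- structure(
    list(name = name, d = d, variables = variables,
         parameters = as.character(parameters), rhs = NULL, jacobian = NULL),
    class = "system_model"
  )
  if (!is.null(rhs)) {
    if (length(rhs) != d) {
      stop("`rhs` must contain exactly one expression per variable (",
           d, "), got ", length(rhs), call. = FALSE)
    }
    model$rhs <- lapply(seq_along(rhs), function(i) {
      e <- rhs[[i]]
      if (is.character(e)) {
        e <- tryCatch(str2lang(e), error = function(err) {
          stop("malformed expression for equation ", i, " (",
               variables[i], "): ", conditionMessage(err), call. = FALSE)
        })
      }
      e
    })
    jac <- build_symbolic_jacobian(model)
    model$parameters <- sort(unique(c(model$parameters,
                                      attr(jac, "free_parameters"))))
    attr(jac, "free_parameters") <- NULL
    model$jacobian <- jac
  } else if (!is.null(jacobian)) {
    jacobian <- sym_matrix(as.matrix(jacobian))
    if (nrow(jacobian) != d || ncol(jacobian) != d) {
      stop("jacobian must be ", d, " x ", d, ", got ",
           nrow(jacobian), " x ", ncol(jacobian), call. = FALSE)
    }
    model$jacobian <- jacobian
  } else {
    stop("either `rhs` or `jacobian` must be supplied", call. = FALSE)
  }
  dimnames(model$jacobian) <- list(variables, variables)
  model
}

#' @export
print.system_model <- function(x, ...) {
  cat("system model '", x$name, "' (d = ", x$d, ")\n", sep = "")
  cat("variables: ", paste(x$variables, collapse = ", "), "\n", sep = "")
  if (length(x$parameters)) {
    cat("parameters:", paste(x$parameters, collapse = ", "), "\n")
  }
  cat("rhs:", if (is.null(x$rhs)) "absent (Jacobian given directly)"
      else "present", "\n")
  print(x$jacobian)
  invisible(x)
}

#' Read a model description file
#'
#' Models are stored as YAML (JSON is a YAML subset and works too) with
#' fields `name`, `variables` (ordered list), optional `parameters`, and
#' either `equations` (list of expression strings, one per variable) or
#' `jacobian` (list of rows of tokens `"0"`, `"1"`, `"1b"`, `"1bb"`).
#' Free names in equations that are not declared variables are registered
#' as parameters.
#'
#' @param path path to a model file, or a literal YAML string containing a
#'   newline.
#' @return A [system_model()].
#' @export
parse_model <- function(path) {
  doc <- if (length(path) == 1L && !grepl("\n", path)) {
    yaml::read_yaml(path)
  } else {
    yaml::yaml.load(paste(path, collapse = "\n"))
  }
  if (is.null(doc$variables)) {
    stop("model document must declare `variables`", call. = FALSE)
  }
  vars <- as.character(unlist(doc$variables))
  if (!is.null(doc$equations)) {
    eqs <- as.character(unlist(doc$equations))
    system_model(vars, rhs = eqs,
                 parameters = as.character(unlist(doc$parameters)),
                 name = doc$name %||% "model")
  } else if (!is.null(doc$jacobian)) {
    rows <- lapply(doc$jacobian, function(r) as.character(unlist(r)))
    if (length(rows) != length(vars) ||
        any(lengths(rows) != length(vars))) {
      stop("jacobian must be ", length(vars), " rows of ", length(vars),
           " tokens each", call. = FALSE)
    }
    tok <- do.call(rbind, rows)
    system_model(vars, jacobian = sym_matrix(tok),
                 parameters = as.character(unlist(doc$parameters)),
                 name = doc$name %||% "model")
  } else {
    stop("model document must contain `equations` or `jacobian`",
         call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a partial derivative into a coupling symbol
#'
#' Given an expression for the partial derivative of one equation with
#' respect to state variable `xj`, returns the coupling symbol: absent if
#' the expression is identically zero, linear if it is constant in every
#' state variable, rational (`1bb`) if after cancelling common polynomial
#' factors its denominator still depends on `xj`, and polynomial
#' nonlinear (`1b`) otherwise. Parameters are treated as nonzero constants,
#' so the class is invariant under rescaling by any parameter.
#'
#' @param derivative_expr an expression (string or language object) rational
#'   in the state variables.
#' @param xj name of the differentiation variable.
#' @param variables character vector of all state-variable names.
#' @return A symbol code in `0:3`.
#' @examples
#' classify_entry("k1", "x4", c("x4", "x5"))             # linear
#' classify_entry("2 * x4 * x5", "x4", c("x4", "x5"))    # polynomial
#' classify_entry("K / (K + x4)^2", "x4", c("x4", "x5")) # rational
#' @export
classify_entry <- function(derivative_expr, xj, variables) {
  if (is.character(derivative_expr)) {
    derivative_expr <- str2lang(derivative_expr)
  }
  variables <- as.character(variables)
  j <- match(xj, variables)
  if (is.na(j)) {
    stop("`xj` (", xj, ") is not among the declared variables", call. = FALSE)
  }
  var_index <- stats::setNames(seq_along(variables), variables)
  out <- SYM_ZERO
  for (salt in c(1L, 2L)) {
    r <- .expr_to_rational(derivative_expr, var_index, salt, NULL)
    out <- max(out, .classify_rational(r, j, length(variables), salt))
  }
  out
}

#' Build the symbolic Jacobian of a model
#'
#' Differentiates every right-hand side with respect to every state
#' variable and classifies each partial derivative with the same rules as
#' [classify_entry()]. The derivative and the cancellation of common
#' polynomial factors are carried out exactly on a ratio-of-polynomials
#' representation, so e.g. a factor shared by numerator and denominator
#' never masquerades as a rational coupling.
#'
#' @param model a [system_model()] with `rhs` present.
#' @return A `d x d` [sym_matrix()].
#' @export
build_symbolic_jacobian <- function(model) {
  if (is.null(model$rhs)) {
    stop("model has no right-hand sides; the Jacobian was supplied directly",
         call. = FALSE)
  }
  d <- model$d
  var_index <- stats::setNames(seq_len(d), model$variables)
  J <- matrix(SYM_ZERO, d, d)
  param_env <- new.env(parent = emptyenv())
  param_env$seen <- character()
  for (salt in c(1L, 2L)) {
    for (i in seq_len(d)) {
      ri <- tryCatch(
        .expr_to_rational(model$rhs[[i]], var_index, salt, param_env),
        error = function(err) {
          stop("equation ", i, " (", model$variables[i], "): ",
               conditionMessage(err), call. = FALSE)
        }
      )
      for (j in seq_len(d)) {
        dij <- .rat_deriv(ri, j)
        sym <- tryCatch(
          .classify_rational(dij, j, d, salt),
          error = function(err) {
            stop("entry (", i, ",", j, "): ", conditionMessage(err),
                 call. = FALSE)
          }
        )
        J[i, j] <- max(J[i, j], sym)
      }
    }
  }
  out <- sym_matrix(J)
  attr(out, "free_parameters") <- setdiff(param_env$seen, model$variables)
  out
}

#' Collapse a symbolic Jacobian to its linear-theory version
#'
#' Replaces every nonzero symbol by the linear symbol, which is how a
#' purely graph-based (linear) observability analysis sees the system:
#' only the sparsity pattern survives, the polynomial/rational character
#' of each coupling is discarded.
#'
#' @param J a [sym_matrix()].
#' @return A [sym_matrix()] of the same sparsity with all nonzero entries
#'   linear.
#' @export
linearize_symbols <- function(J) {
  J <- sym_matrix(as.matrix(J))
  out <- ifelse(unclass(J) != SYM_ZERO, SYM_ONE, SYM_ZERO)
  dimnames(out) <- dimnames(J)
  sym_matrix(out)
}

# cache fixtures: classification of the 13D model is exact but not free
.fixture_cache <- new.env(parent = emptyenv())

#' Bundled benchmark models
#'
#' Three rational reaction-network models widely used to benchmark
#' nonlinear observability methods:
#' \describe{
#'   \item{`goldbeter5d`}{Goldbeter's 5-variable model of circadian PER
#'     protein oscillations in Drosophila (Michaelis-Menten kinetics).}
#'   \item{`rayleigh_benard9d`}{a 9-mode Fourier truncation of
#'     Rayleigh-Benard convection in a square cell.}
#'   \item{`dna13d`}{the Novak-Tyson 13-variable cell-cycle / DNA
#'     replication model for fission yeast; the cell mass is the 13th
#'     state variable `x13`.}
#' }
#'
#' @param name fixture name.
#' @param jacobian for `rayleigh_benard9d` only: `"derived"` (default)
#'   recomputes the symbolic Jacobian from the equations; `"printed"`
#'   returns the historical hand-typed symbol matrix, which disagrees with
#'   the equations in a few entries of columns 5 and 6 (kept for
#'   comparison; it has no equations attached).
#' @return A [system_model()].
#' @export
fixture_model <- function(name = c("goldbeter5d", "rayleigh_benard9d",
                                   "dna13d"),
                          jacobian = c("derived", "printed")) {
  name <- match.arg(name)
  jacobian <- match.arg(jacobian)
  file <- if (name == "rayleigh_benard9d" && jacobian == "printed") {
    "rayleigh_benard9d_printed.yaml"
  } else {
    paste0(name, ".yaml")
  }
  if (!is.null(.fixture_cache[[file]])) return(.fixture_cache[[file]])
  path <- system.file("extdata", file, package = "symobs")
  if (path == "") path <- file.path("inst", "extdata", file)  # dev tree
  model <- parse_model(path)
  .fixture_cache[[file]] <- model
  model
}
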