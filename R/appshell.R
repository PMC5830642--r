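#' Serialize a model to the model-file format
#'
#' Writes the YAML schema read back by [parse_model()]: `name`,
#' `variables`, and `equations` when right-hand sides are present or a
#' token `jacobian` otherwise.
#'
#' @param model a [system_model()].
#' @param path output file; when `NULL` the YAML text is returned.
#' @return Invisibly, the YAML text.
#' @export
write_model_yaml <- function(model, path = NULL) {
  stopifnot(inherits(model, "system_model"))
  doc <- list(name = model$name, variables = as.list(model$variables))
  if (!is.null(model$rhs)) {
    doc$equations <- lapply(model$rhs, function(e) deparse1(e))
  } else {
    tok <- matrix(sym_to_token(model$jacobian), model$d)
    doc$jacobian <- lapply(seq_len(model$d), function(i) as.list(tok[i, ]))
  }
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Export ranked results
#'
#' @param results a `"ranked_results"` data frame from
#'   [evaluate_configs()] or [reduced_search()].
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Serialize a coefficient result
#'
#' @param x an `"obs_coefficient"`.
#' @return A named list suitable for JSON export: `config`, `eta_exact`
#'   (`num`/`den`), `eta_2dp`, `T`, `N1`, `Nbar`, `Ndblbar`, `D`.
#' @export
coefficient_record <- function(x) {
  stopifnot(inherits(x, "obs_coefficient"))
  list(config = attr(x, "config_string") %||% NA_character_,
       eta_exact = list(num = x$eta_num, den = x$eta_den),
       eta_2dp = x$eta_2dp, T = x$summary$T, N1 = x$summary$n1,
       Nbar = x$summary$nbar, Ndblbar = x$summary$ndbl, D = x$D)
}

.cli_load_model <- function(opts) {
  has_fix <- !is.null(opts$fixture)
  has_mod <- !is.null(opts$model)
  if (has_fix == has_mod) {
    stop("exactly one of --fixture or --model is required", call. = FALSE)
  }
  if (has_fix) fixture_model(opts$fixture) else parse_model(opts$model)
}

.cli_option_list <- function(keys) {
  all_opts <- list(
    model = optparse::make_option("--model", type = "character",
      default = NULL, help = "path to a model file (YAML/JSON)"),
    fixture = optparse::make_option("--fixture", type = "character",
      default = NULL,
      help = "bundled model: goldbeter5d, rayleigh_benard9d or dna13d"),
    config = optparse::make_option("--config", type = "character",
      default = NULL, help = "configuration string, e.g. 'x2^2 x3 x5^2'"),
    dim = optparse::make_option("--dim", type = "integer", default = NULL,
      help = "system dimension"),
    out = optparse::make_option("--out", type = "character", default = NULL,
      help = "output file (default: stdout)"),
    format = optparse::make_option("--format", type = "character",
      default = "csv", help = "output format: csv or json [default %default]"),
    seed = optparse::make_option("--seed", type = "integer", default = 1L,
      help = "random seed [default %default]"),
    strategy = optparse::make_option("--strategy", type = "character",
      default = "exhaustive",
      help = "search strategy: exhaustive or preselect [default %default]"),
    m_min = optparse::make_option("--m-min", type = "integer",
      default = NULL, help = "minimum number of measured variables"),
    m_max = optparse::make_option("--m-max", type = "integer",
      default = NULL, help = "maximum number of measured variables"),
    max_count = optparse::make_option("--max-count", type = "integer",
      default = NULL, help = "maximum coordinate count per sensor"),
    min_eta = optparse::make_option("--min-eta", type = "double",
      default = 0.75, help = "report threshold [default %default]"),
    density = optparse::make_option("--density", type = "double",
      default = 0.3, help = "off-diagonal coupling density [default %default]"),
    log_every = optparse::make_option("--log-every", type = "integer",
      default = 1000L, help = "progress interval [default %default]")
  )
  all_opts[keys]
}

.cli_parse <- function(cmd, args, keys) {
  parser <- optparse::OptionParser(
    usage = paste0("symobs ", cmd, " [options]"),
    option_list = .cli_option_list(keys)
  )
  optparse::parse_args(parser, args = args)
}

#' Command-line entry point
#'
#' Dispatches the `symobs` subcommands: `coeff` (observability
#' coefficient of one configuration), `preselect` (sensor preselection
#' report), `search` (evaluate and rank configurations), `scan`
#' (leave-one-out table), `count` (configuration count) and `generate`
#' (seeded synthetic model). Run with no arguments for usage. Installed
#' as the `exec/symobs` script.
#'
#' @param args character vector of command-line arguments; defaults to
#'   the process arguments.
#' @return Invisibly, the command's primary result.
#' @export
symobs_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: symobs <command> [options]",
    "commands:",
    "  coeff      --fixture NAME|--model FILE --config STR",
    "  preselect  --fixture NAME|--model FILE",
    "  search     --fixture NAME|--model FILE [--strategy exhaustive|preselect]",
    "             [--m-min N --m-max N --max-count N --min-eta X --out FILE]",
    "  scan       --fixture NAME|--model FILE [--out FILE]",
    "  count      --dim D [--m-min N --m-max N]",
    "  generate   --dim D --seed S [--density X] [--out FILE]",
    sep = "\n")
  if (length(args) == 0L) {
    cat(usage, "\n")
    return(invisible(NULL))
  }
  cmd <- args[[1L]]
  rest <- args[-1L]
  switch(cmd,
    coeff = {
      opts <- .cli_parse("coeff", rest, c("model", "fixture", "config"))
      if (is.null(opts$config)) {
        stop("--config is required; grammar: whitespace-separated `var` or ",
             "`var^k` tokens, e.g. 'x2^2 x3 x5^2'", call. = FALSE)
      }
      model <- .cli_load_model(opts)
      res <- coefficient_for(model, opts$config)
      print(res)
      invisible(res)
    },
    preselect = {
      opts <- .cli_parse("preselect", rest, c("model", "fixture"))
      model <- .cli_load_model(opts)
      rep_ <- preselect(model)
      print(rep_)
      invisible(rep_)
    },
    search = {
      opts <- .cli_parse("search", rest,
                         c("model", "fixture", "strategy", "m_min", "m_max",
                           "max_count", "min_eta", "out", "format",
                           "log_every"))
      model <- .cli_load_model(opts)
      spec <- search_spec(m_min = opts$`m-min`, m_max = opts$`m-max`,
                          max_count = opts$`max-count`,
                          min_eta = opts$`min-eta`)
      prog <- function(k, best) {
        message(sprintf("evaluated %d configurations; best eta so far %.2f",
                        k, best))
      }
      res <- if (opts$strategy == "preselect") {
        reduced_search(model, spec = spec)
      } else {
        evaluate_configs(model, spec, progress = prog,
                         progress_every = opts$`log-every`)
      }
      if (!is.null(opts$out)) {
        write_results(res, opts$out, opts$format)
        message("wrote ", nrow(res), " rows to ", opts$out)
      } else {
        print(res)
      }
      invisible(res)
    },
    scan = {
      opts <- .cli_parse("scan", rest, c("model", "fixture", "out", "format"))
      model <- .cli_load_model(opts)
      res <- leave_one_out_scan(model)
      if (!is.null(opts$out)) {
        utils::write.csv(res, opts$out, row.names = FALSE)
      } else {
        print(res)
      }
      invisible(res)
    },
    count = {
      opts <- .cli_parse("count", rest, c("dim", "m_min", "m_max"))
      if (is.null(opts$dim)) stop("--dim is required", call. = FALSE)
      n <- count_configs(opts$dim,
                         opts$`m-min` %||% 1L,
                         opts$`m-max` %||% (opts$dim - 1L))
      cat(format(n, scientific = FALSE), "\n")
      invisible(n)
    },
    generate = {
      opts <- .cli_parse("generate", rest, c("dim", "seed", "density", "out"))
      if (is.null(opts$dim)) stop("--dim is required", call. = FALSE)
      M <- random_symbol_matrix(opts$dim, density = opts$density,
                                seed = opts$seed)
      model <- realize_odes(M, seed = opts$seed,
                            name = sprintf("synthetic_d%d_seed%d",
                                           opts$dim, opts$seed))
      txt <- write_model_yaml(model, opts$out)
      if (is.null(opts$out)) cat(txt) else message("wrote ", opts$out)
      invisible(model)
    },
    {
      cat(usage, "\n")
      stop("unknown command: ", cmd, call. = FALSE)
    }
  )
}
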