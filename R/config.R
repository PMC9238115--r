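# YAML configuration round trip. The schema mirrors the printed input tables:
# [model], [transitions] (+ SDs), [utilities] (+ SDs), [costs], [strategies],
# [sa_ranges]. Stay probabilities are never stored; they are derived.

#' Read a model configuration file
#'
#' Parses and validates a YAML model configuration, collecting every schema
#' violation before failing so a broken file is reported in full rather than
#' one field at a time.
#'
#' @param path Path to a YAML configuration.
#' @return A list with elements `params` ([parameter_set()]) and `config`
#'   ([model_config()]).
#' @seealso [write_cua_config()], [replication_params()]
#' @export
read_cua_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  errs <- character()
  need <- function(sec) {
    if (is.null(y[[sec]])) {
      errs <<- c(errs, sprintf("missing section [%s]", sec)); FALSE
    } else TRUE
  }
  ok <- vapply(c("model", "transitions", "utilities", "costs", "strategies"),
               need, TRUE)
  if (!all(ok)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  config <- tryCatch(do.call(model_config, y$model),
                     error = function(e) { errs <<- c(errs, conditionMessage(e))
                                           NULL })
  st <- health_states()
  P <- tryCatch(transition_matrix(y$transitions),
                error = function(e) { errs <<- c(errs, conditionMessage(e))
                                      NULL })
  Psd <- matrix(0, 3, 3, dimnames = list(st, st)); diag(Psd) <- NA
  for (from in names(y$transition_sds %||% list()))
    for (to in names(y$transition_sds[[from]]))
      Psd[from, to] <- y$transition_sds[[from]][[to]]
  u <- unlist(y$utilities)
  if (anyNA(u[health_states()]) || any(u < 0 | u > 1))
    errs <- c(errs, "utilities: one value per state W,S,A required, each in [0,1]")
  strategies <- lapply(y$strategies, function(s)
    tryCatch(do.call(strategy, s),
             error = function(e) { errs <<- c(errs, conditionMessage(e))
                                   NULL }))
  sa <- if (!is.null(y$sa_ranges))
    do.call(rbind, lapply(y$sa_ranges, as.data.frame)) else NULL
  params <- if (!length(errs))
    tryCatch(parameter_set(
      transition = P,
      transition_sds = Psd,
      utilities = unlist(y$utilities),
      utility_sds = unlist(y$utility_sds %||%
                             stats::setNames(as.list(rep(0, 3)), st)),
      state_costs = unlist(y$costs$state_per_cycle),
      state_cost_cv = y$costs$state_per_cycle_cv %||% 0,
      strategies = strategies, sa_ranges = sa),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  if (length(errs))
    stop("invalid configuration '", path, "':\n",
         paste("  -", errs, collapse = "\n"), call. = FALSE)
  list(params = params, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model configuration file
#'
#' Inverse of [read_cua_config()]: `read_cua_config(write_cua_config(x, p))`
#' is value-identical to `x`.
#'
#' @param params A [parameter_set()].
#' @param config A [model_config()].
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_cua_config <- function(params, config, path) {
  st <- health_states()
  offdiag <- function(M) {
    out <- list()
    for (from in st) {
      row <- list()
      for (to in st)
        if (from != to && !is.na(M[from, to]) && M[from, to] != 0)
          row[[to]] <- as.numeric(M[from, to])
      if (length(row)) out[[from]] <- row
    }
    out
  }
  y <- list(
    model = unclass(config),
    transitions = offdiag(params$transition),
    transition_sds = offdiag(params$transition_sds),
    utilities = as.list(params$utilities),
    utility_sds = as.list(params$utility_sds),
    costs = list(state_per_cycle = as.list(params$state_costs),
                 state_per_cycle_cv = params$state_cost_cv),
    strategies = lapply(params$strategies, function(s) unclass(s)))
  names(y$strategies) <- NULL
  if (!is.null(params$sa_ranges)) {
    y$sa_ranges <- lapply(seq_len(nrow(params$sa_ranges)), function(i)
      as.list(params$sa_ranges[i, ]))
    names(y$sa_ranges) <- NULL
  }
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Validate a configuration file and report as JSON
#'
#' @param path Configuration file to check.
#' @param json_out Optional path for a JSON validation report.
#' @return A list with `valid` (logical) and `errors` (character vector),
#'   invisibly when `json_out` is given.
#' @export
validate_cua_config <- function(path, json_out = NULL) {
  res <- tryCatch({ read_cua_config(path); list(valid = TRUE,
                                                errors = character()) },
                  error = function(e)
                    list(valid = FALSE,
                         errors = strsplit(conditionMessage(e), "\n")[[1]]))
  if (!is.null(json_out))
    jsonlite::write_json(res, json_out, auto_unbox = TRUE, pretty = TRUE)
  res
}

#' Frozen replication parameter set
#'
#' Loads the calibrated configuration shipped with the package: the published
#' base-case inputs plus the state costs and testing schedule fitted by
#' [calibrate_cua()] to the published arm-level results.
#'
#' @return As [read_cua_config()]: list with `params` and `config`.
#' @export
replication_params <- function() {
  path <- system.file("extdata", "replication-config.yaml",
                      package = "asthmaCUA", mustWork = TRUE)
  read_cua_config(path)
}
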