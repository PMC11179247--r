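#' Load and validate a study configuration
#'
#' Reads a YAML configuration for the replication study, fills in
#' defaults, and validates it. Unknown keys are rejected, as is any
#' combination that could not run (sample larger than population,
#' unknown scenario, method or strategy, non-positive sizes). The
#' materialized configuration is returned with every default made
#' explicit.
#'
#' Recognized keys (all optional): `scenarios`, `methods`,
#' `strategies`, `N`, `n`, `R`, `seed`, `output_dir`.
#'
#' @param path path to a YAML file.
#' @return validated named list of class `swm_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # keep YAML 1.1 boolean-like scalars (notably the keys `n`, `N`, `y`)
  # as literal strings instead of coercing them to logicals
  keep <- function(x) x
  raw <- yaml::read_yaml(path, handlers = list(`bool#yes` = keep,
                                               `bool#no` = keep))
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

config_defaults <- function() {
  list(scenarios = 1:8, methods = sampling_methods(),
       strategies = weight_strategies(),
       N = 90000L, n = 9000L, R = 1000L, seed = 1L,
       output_dir = ".")
}

validate_config <- function(raw) {
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw)
  cfg$scenarios <- as.integer(cfg$scenarios)
  for (k in c("N", "n", "R", "seed")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || !is.finite(v)) {
      stop(sprintf("config key `%s` must be a positive number", k),
           call. = FALSE)
    }
    cfg[[k]] <- as.integer(v)
  }
  if (!all(cfg$scenarios %in% 1:8)) {
    stop("config key `scenarios` must be a subset of 1:8", call. = FALSE)
  }
  if (!all(cfg$methods %in% sampling_methods())) {
    stop("config key `methods` must be a subset of: ",
         paste(sampling_methods(), collapse = ", "), call. = FALSE)
  }
  if (!all(cfg$strategies %in% weight_strategies())) {
    stop("config key `strategies` must be a subset of: ",
         paste(weight_strategies(), collapse = ", "), call. = FALSE)
  }
  if (cfg$n > cfg$N) {
    stop("config key `n` must not exceed `N`", call. = FALSE)
  }
  structure(cfg, class = c("swm_config", "list"))
}

#' @rdname load_config
#' @param cfg a validated configuration.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a summary table to CSV
#'
#' Deterministic column order and stable 12-significant-digit formatting
#' of floating-point columns, so two runs under the same seed produce
#' byte-identical files.
#'
#' @param rows nonempty data frame (e.g. from [run_grid()]).
#' @param path output path.
#' @export
write_summary <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("refusing to write an empty summary", call. = FALSE)
  }
  rows <- as.data.frame(rows)
  for (j in seq_along(rows)) {
    if (is.double(rows[[j]])) {
      rows[[j]] <- sprintf("%.12g", rows[[j]])
    }
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
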