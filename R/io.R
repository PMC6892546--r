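#' Read a time-series table
#'
#' Delimited text with a `time` column (seconds) and one column per
#' electrode/condition. The sample interval is inferred from the time
#' column and must be uniform.
#'
#' @param path Path to a CSV (`,`) or TSV (tab) file; the delimiter is
#'   chosen from the extension (`.csv` vs anything else).
#' @return A list with `responses` (named list of numeric vectors) and
#'   `grid` (a `time_grid`).
#' @export
load_timeseries_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!"time" %in% names(df)) stop("format error: no 'time' column")
  tt <- df$time
  dts <- diff(tt)
  if (length(dts) < 1 || any(abs(dts - dts[1]) > 1e-9 * max(abs(dts)))) {
    stop("format error: time column is not uniformly spaced")
  }
  grid <- time_grid(dt = dts[1], n = nrow(df), t0 = tt[1])
  cols <- setdiff(names(df), "time")
  if (length(cols) == 0) stop("format error: no response columns")
  list(responses = lapply(df[cols], as.numeric), grid = grid)
}

#' Write a time-series table
#'
#' @param responses Named list of numeric vectors (or a matrix with rows as
#'   series) on a common grid.
#' @param grid A `time_grid`.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_timeseries_table <- function(responses, grid, path) {
  if (is.matrix(responses)) {
    responses <- stats::setNames(
      lapply(seq_len(nrow(responses)), function(i) responses[i, ]),
      rownames(responses) %||% paste0("series", seq_len(nrow(responses))))
  }
  df <- data.frame(time = grid_times(grid), responses, check.names = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a fit result as a flat key/value table
#'
#' @param fit A `dn_fit` from any of the fitting functions.
#' @param path Output path; `.json` writes JSON, anything else a
#'   two-column TSV.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "dn_fit"))
  p <- fit$params
  kv <- c(tau1 = p$tau1, w = p$w, tau2 = p$tau2, n = p$n, sigma = p$sigma,
          shift = p$shift, gain = p$gain, r2 = fit$r2, sse = fit$sse,
          n_iterations = fit$n_iterations,
          converged = as.numeric(fit$converged))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(kv), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(data.frame(key = names(kv), value = unname(kv)),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a fit result written by [write_fit_result()]
#'
#' @param path Path to the JSON or TSV key/value table.
#' @return Named numeric vector.
#' @export
read_fit_result <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    stats::setNames(df$value, df$key)
  }
}

default_config <- function() {
  list(
    dt = 0.001,
    grid_ranges = list(tau1 = c(0.07, 1), tau2 = c(0.07, 1), n = c(1, 6),
                       sigma = c(0.01, 0.5), n_steps = 10),
    fit_bounds = list(lower = c(0.07, 0.07, 1, 0.01, 1e-4),
                      upper = c(1, 1, 6, 0.5, 0.1)),
    band = list(f_lo = 70, f_hi = 210, width = 10, line_freq = 60),
    epoch = list(t0 = -0.2, length = 1.2, baseline = c(-0.2, 0)),
    bold = list(durations_ms = c(0, 17, 33, 67, 134, 267, 533),
                isis_ms = c(17, 33, 67, 134, 267, 533),
                pulse_ms = 134, trial_length = 4.5),
    seed = 1,
    log_level = "info")
}

#' Load a configuration file
#'
#' Reads a JSON or YAML configuration; any field absent from the file takes
#' its default value (sampling interval 1 ms, the standard grid ranges and
#' fit bounds, the 70-210 Hz / 60 Hz-line band design, the 13-condition
#' BOLD set). Supplied fields are validated.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` file, or `NULL` for pure
#'   defaults.
#' @return A named list of class `dn_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
        for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  validate_config(cfg)
  structure(cfg, class = c("dn_config", "list"))
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$dt) || cfg$dt <= 0) stop("config error: dt must be > 0")
  gr <- cfg$grid_ranges
  do.call(grid_ranges, gr)  # range validation
  fb <- cfg$fit_bounds
  fit_bounds(unlist(fb$lower), unlist(fb$upper))
  if (cfg$band$f_lo >= cfg$band$f_hi) stop("config error: band f_lo >= f_hi")
  if (!cfg$log_level %in% c("quiet", "info", "debug")) {
    stop("config error: log_level must be quiet, info or debug")
  }
  invisible(cfg)
}

config_grid_ranges <- function(cfg) do.call(grid_ranges, cfg$grid_ranges)
config_fit_bounds <- function(cfg) {
  fit_bounds(unlist(cfg$fit_bounds$lower), unlist(cfg$fit_bounds$upper))
}
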