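#' Build the 13 one- and two-pulse temporal conditions
#'
#' The fMRI experiment presented a large-field contrast pattern either once
#' per 4.5 s trial (durations from 0, i.e. no stimulus, up to 533 ms) or
#' twice for 134 ms each with a variable inter-stimulus interval. The
#' default duration/ISI values follow the doubling series
#' 17, 33, 67, 134, 267, 533 ms.
#'
#' @param durations One-pulse durations in seconds (default
#'   `c(0, 17, 33, 67, 134, 267, 533) / 1000`).
#' @param isis Two-pulse inter-stimulus intervals in seconds (default
#'   `c(17, 33, 67, 134, 267, 533) / 1000`); each pulse lasts `pulse`
#'   seconds.
#' @param pulse Two-pulse stimulus duration (default 0.134 s).
#' @param trial_length Trial length in seconds (default 4.5).
#' @param dt Sample interval (default 0.001 s).
#' @return A list with `conditions` (data frame: `id`, `kind`,
#'   `duration_ms`, `isi_ms`) and `stims` (list of `stimulus_timecourse`,
#'   one per condition).
#' @export
build_conditions <- function(durations = c(0, 17, 33, 67, 134, 267, 533) / 1000,
                             isis = c(17, 33, 67, 134, 267, 533) / 1000,
                             pulse = 0.134, trial_length = 4.5, dt = 0.001) {
  stopifnot(all(durations >= 0), all(isis >= 0))
  one <- lapply(durations, function(d) stim_step(d, trial_length, dt = dt))
  two <- lapply(isis, function(i) stim_two_pulse(pulse, i, trial_length,
                                                 dt = dt))
  conditions <- data.frame(
    id = seq_len(length(durations) + length(isis)),
    kind = c(rep("one_pulse", length(durations)),
             rep("two_pulse", length(isis))),
    duration_ms = c(durations * 1000, rep(pulse * 1000, length(isis))),
    isi_ms = c(rep(NA_real_, length(durations)), isis * 1000))
  list(conditions = conditions, stims = c(one, two))
}

#' Predict BOLD amplitudes from the normalization model
#'
#' For each temporal condition the model time course is summed over the
#' trial to give the total predicted neuronal response; a single
#' nonnegative gain converts these sums to percent BOLD by least squares
#' across all conditions (the GLM that produced the measured amplitudes
#' already absorbed the hemodynamic response, so a scalar gain is the whole
#' hemodynamic transform).
#'
#' @param params A `dn_params` object (e.g. the median of per-electrode
#'   fits).
#' @param conditions Output of [build_conditions()].
#' @param measured Numeric vector of measured amplitudes (percent BOLD),
#'   one per condition; optional (`NULL` returns unscaled sums with
#'   `gain = 1`).
#' @return A list of class `bold_prediction` with `summed` (per-condition
#'   model sums), `gain`, `predicted`, `r2` (vs `measured`), and the
#'   condition table.
#' @export
predict_bold <- function(params, conditions = build_conditions(),
                         measured = NULL) {
  stopifnot(inherits(params, "dn_params"))
  summed <- vapply(conditions$stims,
                   function(s) sum(dn_response(s, params)$values),
                   numeric(1))
  finish_bold(summed, conditions$conditions, measured, model = "dn")
}

#' Linear baseline prediction of BOLD amplitudes
#'
#' The no-normalization baseline: the predicted amplitude is proportional
#' to the total stimulus-on time, so all two-pulse conditions share one
#' prediction regardless of inter-stimulus interval, and doubling a
#' duration doubles the prediction.
#'
#' @inheritParams predict_bold
#' @return A `bold_prediction` list as in [predict_bold()].
#' @export
linear_bold_prediction <- function(conditions = build_conditions(),
                                   measured = NULL) {
  summed <- vapply(conditions$stims, function(s) sum(s$values), numeric(1))
  finish_bold(summed, conditions$conditions, measured, model = "linear")
}

finish_bold <- function(summed, cond_table, measured, model) {
  if (is.null(measured)) {
    gain <- 1
    r2 <- NA_real_
  } else {
    stopifnot(length(measured) == length(summed))
    ss <- sum(summed ^ 2)
    if (ss == 0) stop("degenerate fit: all summed predictions are zero")
    gain <- max(sum(summed * measured) / ss, 0)
    r2 <- variance_explained(gain * summed, measured)
  }
  structure(list(model = model, summed = summed, gain = gain,
                 predicted = gain * summed, r2 = r2,
                 conditions = cond_table, measured = measured),
            class = "bold_prediction")
}

#' @export
print.bold_prediction <- function(x, ...) {
  cat(sprintf("<bold_prediction> model = %s, gain = %.4g%s\n",
              x$model, x$gain,
              if (is.na(x$r2)) "" else sprintf(", r2 = %.3f", x$r2)))
  invisible(x)
}
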