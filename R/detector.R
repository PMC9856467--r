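#' Detection thresholds (Th = u + 3*sd)
#'
#' Computes the AVG and STD thresholds from a training span of the feature
#' curves: each threshold is the mean of its curve over the span plus three
#' population standard deviations. The training span runs from the start of
#' the features through the offset of the `n_train`-th annotated seizure
#' (default 5), so it mixes interictal background with the training seizures
#' — which is what places the threshold between baseline and ictal levels.
#'
#' @param features a `cc_features` with `avg` and `std` filled
#'   (see [avg_std()]).
#' @param ann a [annotations()] data frame with at least `n_train` rows, or
#'   `NULL` to use the whole feature span.
#' @param n_train number of initial seizures in the training span.
#' @return A list of class `thresholds`: `th_avg`, `th_std`, and the
#'   constituent `u_avg`, `sd_avg`, `u_std`, `sd_std`, plus `fitted_at`.
#' @export
init_thresholds <- function(features, ann = NULL, n_train = 5L) {
  stopifnot(inherits(features, "cc_features"))
  if (is.null(features$avg) || is.null(features$std))
    stop("features must have avg/std curves; run avg_std() first")
  if (!is.null(ann)) {
    if (nrow(ann) < 1L) stop("need at least one training seizure")
    end_s <- ann$offset_s[min(n_train, nrow(ann))]
    keep <- features$times <= end_s
    if (!any(keep)) stop("features do not cover the training span")
  } else {
    keep <- rep(TRUE, length(features$times))
  }
  a <- features$avg[keep]; s <- features$std[keep]
  thresholds(u_avg = mean(a), sd_avg = pop_sd(a),
             u_std = mean(s), sd_std = pop_sd(s), fitted_at = "init")
}

#' Construct a thresholds object
#'
#' @param u_avg,sd_avg,u_std,sd_std means and population SDs of the AVG and
#'   STD curves over the span the thresholds were fitted on.
#' @param fitted_at free-text label of the fitting block.
#' @return A list of class `thresholds` with `th_avg = u_avg + 3*sd_avg` and
#'   `th_std = u_std + 3*sd_std`.
#' @export
thresholds <- function(u_avg, sd_avg, u_std, sd_std, fitted_at = "") {
  structure(list(th_avg = u_avg + 3 * sd_avg, th_std = u_std + 3 * sd_std,
                 u_avg = u_avg, sd_avg = sd_avg, u_std = u_std,
                 sd_std = sd_std, fitted_at = fitted_at),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("<thresholds> AVG %.4f (u=%.4f, sd=%.4f); STD %.4f (u=%.4f, sd=%.4f)%s\n",
              x$th_avg, x$u_avg, x$sd_avg, x$th_std, x$u_std, x$sd_std,
              if (nzchar(x$fitted_at)) paste0(" [", x$fitted_at, "]") else ""))
  invisible(x)
}

#' Save / load thresholds as JSON
#' @param th a `thresholds` object.
#' @param path JSON file path.
#' @return `path` invisibly; `read_thresholds` returns a `thresholds`.
#' @export
write_thresholds <- function(th, path) {
  jsonlite::write_json(unclass(th), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  thresholds(obj$u_avg, obj$sd_avg, obj$u_std, obj$sd_std,
             fitted_at = if (is.null(obj$fitted_at)) "" else obj$fitted_at)
}

#' Detect seizure onsets from feature curves
#'
#' Flags an onset at the first window where **both** `avg > th_avg` and
#' `std > th_std` (the AND of the two criteria). Further qualifying windows
#' within `refractory_s` of a flagged event are absorbed into it, so a
#' sustained seizure produces a single event stamped at its first
#' above-threshold window.
#'
#' @param features a `cc_features` with `avg`/`std` filled.
#' @param th a [thresholds()] object.
#' @param refractory_s absorption window after each event, seconds
#'   (default 30).
#' @return A data frame of class `detection_events` with column `time_s`.
#' @export
detect_events <- function(features, th, refractory_s = 30) {
  stopifnot(inherits(features, "cc_features"), inherits(th, "thresholds"))
  if (is.null(features$avg) || is.null(features$std))
    stop("features must have avg/std curves; run avg_std() first")
  qual <- features$times[features$avg > th$th_avg & features$std > th$th_std]
  ev <- numeric(0)
  last <- -Inf
  for (t in qual) {
    if (t - last > refractory_s) {
      ev <- c(ev, t)
      last <- t
    }
  }
  structure(data.frame(time_s = ev), class = c("detection_events", "data.frame"))
}

#' Evaluate detections against annotations
#'
#' Each event (in time order) is matched to the first still-unmatched
#' annotation whose `[onset, onset + match_window_s]` interval contains it.
#' Detection rate is matched annotations over total annotations (percent);
#' detection delay is event time minus annotated onset over matched events;
#' false alarms are the unmatched events, reported per recorded hour.
#'
#' @param events a `detection_events` data frame (see [detect_events()]).
#' @param ann a [annotations()] data frame.
#' @param duration_s recording duration in seconds (> 0), for the
#'   false-alarm rate.
#' @param match_window_s match tolerance after onset, seconds (default 60).
#' @return A list of class `eval_report`: `detection_rate` (percent),
#'   `mean_delay_s`, `sd_delay_s`, `false_alarm_rate_per_h`, counts
#'   (`n_seizures`, `n_detected`, `n_missed`, `n_false_alarms`), `delays_s`,
#'   and the per-event match table `events`.
#' @export
evaluate_detections <- function(events, ann, duration_s, match_window_s = 60) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive to compute a rate per hour")
  ev_t <- sort(events$time_s)
  matched_ann <- rep(NA_integer_, length(ev_t))
  used <- rep(FALSE, nrow(ann))
  for (k in seq_along(ev_t)) {
    hit <- which(!used & ann$onset_s <= ev_t[k] &
                   ev_t[k] <= ann$onset_s + match_window_s)
    if (length(hit)) {
      matched_ann[k] <- hit[1]
      used[hit[1]] <- TRUE
    }
  }
  delays <- ev_t[!is.na(matched_ann)] - ann$onset_s[matched_ann[!is.na(matched_ann)]]
  n_det <- sum(used)
  n_fa <- sum(is.na(matched_ann))
  structure(list(
    detection_rate = if (nrow(ann)) 100 * n_det / nrow(ann) else NA_real_,
    mean_delay_s = if (length(delays)) mean(delays) else NA_real_,
    sd_delay_s = if (length(delays) > 1) stats::sd(delays) else NA_real_,
    false_alarm_rate_per_h = n_fa / (duration_s / 3600),
    n_seizures = nrow(ann), n_detected = n_det,
    n_missed = nrow(ann) - n_det, n_false_alarms = n_fa,
    delays_s = delays,
    events = data.frame(time_s = ev_t, matched_annotation = matched_ann)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> detection rate %.2f%% (%d/%d), FAR %.2f/h, mean delay %s s\n",
              x$detection_rate, x$n_detected, x$n_seizures,
              x$false_alarm_rate_per_h,
              if (is.na(x$mean_delay_s)) "-" else sprintf("%.2f", x$mean_delay_s)))
  invisible(x)
}

#' Periodic threshold verification and recomputation
#'
#' Walks time-ordered data blocks (e.g. 3-day chunks of monitoring) and, at
#' every `check_every`-th block, verifies the current thresholds by running
#' [detect_events()] + [evaluate_detections()] on the block. Thresholds are
#' kept when every seizure in the block is detected and the false-alarm rate
#' stays below `far_bound`; otherwise they are recomputed from the block's
#' own AVG/STD curves (`Th = u + 3*sd` over the whole block) and re-verified
#' on the same block — adopted only if the re-verification passes, else the
#' previous thresholds are retained and the block is flagged.
#'
#' @param blocks list of blocks, each a list with elements `features` (a
#'   `cc_features` with `avg`/`std`) and `annotations`.
#' @param th0 initial [thresholds()].
#' @param check_every verify at every `check_every`-th block (default 1:
#'   every block is a verification block).
#' @param far_bound false-alarm bound, events per hour (default 10).
#' @param refractory_s,match_window_s passed to the detector/evaluator.
#' @return A list of class `threshold_history`: `history` data frame (one
#'   row per block: rate, FAR, action) and `thresholds` (list, per block the
#'   thresholds in force after the block).
#' @export
iterate_thresholds <- function(blocks, th0, check_every = 1L, far_bound = 10,
                               refractory_s = 30, match_window_s = 60) {
  th <- th0
  hist <- list()
  th_list <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    is_check <- (b %% check_every) == 0L
    action <- "skip"
    rate <- NA_real_; far <- NA_real_
    if (is_check) {
      rep0 <- evaluate_detections(
        detect_events(blk$features, th, refractory_s),
        blk$annotations, blk$features$duration_s, match_window_s)
      rate <- rep0$detection_rate; far <- rep0$false_alarm_rate_per_h
      ok0 <- (is.na(rate) || rate == 100) && far < far_bound
      if (ok0) {
        action <- "keep"
      } else {
        cand <- thresholds(mean(blk$features$avg), pop_sd(blk$features$avg),
                           mean(blk$features$std), pop_sd(blk$features$std),
                           fitted_at = paste0("block", b))
        rep1 <- evaluate_detections(
          detect_events(blk$features, cand, refractory_s),
          blk$annotations, blk$features$duration_s, match_window_s)
        ok1 <- (is.na(rep1$detection_rate) || rep1$detection_rate == 100) &&
          rep1$false_alarm_rate_per_h < far_bound
        if (ok1) {
          th <- cand
          action <- "recomputed"
          rate <- rep1$detection_rate; far <- rep1$false_alarm_rate_per_h
        } else {
          action <- "flagged"
        }
      }
    }
    hist[[b]] <- data.frame(block = b, checked = is_check,
                            detection_rate = rate,
                            false_alarm_rate_per_h = far, action = action,
                            th_avg = th$th_avg, th_std = th$th_std)
    th_list[[b]] <- th
  }
  structure(list(history = do.call(rbind, hist), thresholds = th_list),
            class = "threshold_history")
}
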