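# CPR quality metrics from the chest-compression stream: mean compression
# rate, mean depth, complete-recoil fraction and no-flow fraction, each
# classified against the AHA quality bands (rate 100-120/min, depth 5-6 cm,
# complete recoil in > 50% of compressions, no-flow fraction < 20%).

#' Segment a compression stream into episodes
#'
#' Consecutive compressions whose inter-compression gap does not exceed
#' `pause_threshold_s` merge into one episode; a longer gap starts a new
#' episode. Episode start/end are the first/last compression instants it
#' contains, so a single isolated compression forms a zero-length episode.
#'
#' @param compressions Compression stream (see [as_compressions()]), sorted
#'   by time.
#' @param pause_threshold_s Gap (seconds, > 0) that splits episodes;
#'   default 2.
#' @return data.frame with columns `start_s`, `end_s`, `n_compressions`;
#'   zero rows for an empty stream.
#' @export
compression_episodes <- function(compressions, pause_threshold_s = 2) {
  stopifnot(is.numeric(pause_threshold_s), pause_threshold_s > 0)
  t <- compressions$t
  if (is.unsorted(t)) stop("compression stream must be sorted by time")
  if (!length(t))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_compressions = integer(0)))
  brk <- c(TRUE, diff(t) > pause_threshold_s)
  id <- cumsum(brk)
  data.frame(start_s = tapply(t, id, min),
             end_s = tapply(t, id, max),
             n_compressions = as.integer(tapply(t, id, length)),
             row.names = NULL)
}

# total length of the intersection of episodes with [lo, hi]
.active_within <- function(ep, lo, hi) {
  if (!nrow(ep)) return(0)
  s <- pmax(ep$start_s, lo)
  e <- pmin(ep$end_s, hi)
  sum(pmax(0, e - s))
}

#' Compute CPR quality metrics for one record
#'
#' The resuscitation period runs from the chosen anchor (default:
#' recognition of the pulseless state) to the scenario end. The mean rate is
#' 60 times the number of compressions divided by the total active episode
#' duration, so pauses degrade the no-flow fraction rather than the measured
#' rate. The no-flow fraction is the proportion of the resuscitation period
#' not covered by compression episodes. Complete recoil means a release
#' residual of at most the configured threshold (default 0.5 cm).
#'
#' @param record A [scenario_record()].
#' @param anchor Start of the resuscitation period: `"recognition"`
#'   (default), `"first_compression"` or `"scenario_start"`.
#' @return Object of class `cpr_metrics`: list with `n_compressions`,
#'   `mean_rate_per_min`, `mean_depth_cm`, `recoil_complete_fraction`
#'   (percent), `no_flow_fraction` (0..1), `active_s`, `noflow_s`,
#'   `period_s`, logical `flags` (`rate_in_100_120`, `depth_in_5_6cm`,
#'   `recoil_gt_50pct`, `nff_lt_20pct`) and the `thresholds` used.
#' @export
compute_metrics <- function(record,
                            anchor = c("recognition", "first_compression",
                                       "scenario_start")) {
  stopifnot(inherits(record, "scenario_record"))
  anchor <- match.arg(anchor)
  th <- record$config$thresholds
  cp <- record$compressions
  start <- switch(anchor,
                  recognition = recognition_time(record),
                  first_compression = if (nrow(cp)) cp$t[1] else NA_real_,
                  scenario_start = 0)
  if (is.na(start))
    stop("resuscitation period undefined: anchor '", anchor, "' not found in record")
  end <- record$config$duration_s
  period <- end - start
  if (period <= 0) stop("zero-length resuscitation period")
  ep <- compression_episodes(cp, th$pause_threshold_s)
  active_dur <- sum(ep$end_s - ep$start_s)
  active_in <- .active_within(ep, start, end)
  nff <- 1 - active_in / period
  nff <- min(max(nff, 0), 1)
  rate <- if (active_dur > 0) 60 * nrow(cp) / active_dur else NA_real_
  depth <- if (nrow(cp)) mean(cp$depth_cm) else NA_real_
  recoil <- if (nrow(cp))
    100 * mean(cp$release_residual_cm <= th$recoil_residual_cm) else NA_real_
  flags <- list(rate_in_100_120 = isTRUE(rate >= 100 & rate <= 120),
                depth_in_5_6cm = isTRUE(depth >= 5 & depth <= 6),
                recoil_gt_50pct = isTRUE(recoil > 50),
                nff_lt_20pct = isTRUE(nff < 0.20))
  structure(list(team_id = record$team_id,
                 n_compressions = nrow(cp),
                 mean_rate_per_min = rate,
                 mean_depth_cm = depth,
                 recoil_complete_fraction = recoil,
                 no_flow_fraction = nff,
                 active_s = active_in,
                 noflow_s = period - active_in,
                 period_s = period,
                 anchor = anchor,
                 flags = flags,
                 thresholds = list(pause_threshold_s = th$pause_threshold_s,
                                   recoil_residual_cm = th$recoil_residual_cm)),
            class = "cpr_metrics")
}

#' @export
print.cpr_metrics <- function(x, ...) {
  cat(sprintf(paste0("<cpr_metrics> %s: rate %.1f/min, depth %.2f cm, ",
                     "complete recoil %.1f%%, no-flow fraction %.3f\n"),
              x$team_id, x$mean_rate_per_min, x$mean_depth_cm,
              x$recoil_complete_fraction, x$no_flow_fraction))
  invisible(x)
}
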