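#' Weekly scaling factor from wild-type controls
#'
#' The normalization constant of a testing week: 100 divided by the mean
#' raw fall latency of that week's untrained wild-type controls. Multiplying
#' every raw score of the week by it puts the wild-type mean at exactly 100,
#' making mutant scores comparable across weeks and testers.
#'
#' @param wt_raw numeric vector of wild-type raw scores for the week
#'   (at least 2, positive mean).
#' @return `100 / mean(wt_raw)`.
#' @export
weekly_scaling_factor <- function(wt_raw) {
  wt_raw <- wt_raw[is.finite(wt_raw)]
  if (length(wt_raw) < 2L)
    stop_format("unscorable week: fewer than 2 wild-type controls")
  m <- mean(wt_raw)
  if (m <= 0) stop_format("unscorable week: wild-type mean is not positive")
  100 / m
}

#' Score a screen: normalized scores, Z-scores and T-scores
#'
#' Converts raw fall latencies to weekly normalized scores (raw times the
#' week's wild-type scaling factor) and to T-scores, `50 + 10 * Z`. The
#' Z-reference is by default the week's wild-type controls, per trial, so
#' that wild-type T-scores have mean 50 and SD 10 in every week by
#' construction; `reference = "cohort"` standardizes against all mice
#' tested that week instead. Scaling factors are trial-matched by default;
#' `scaling = "pooled"` applies one factor per week derived from the
#' trial-6 wild-type mean.
#'
#' @param dataset a [screen_dataset()]; every tested week must contain
#'   wild-type controls.
#' @param reference `"wt"` (default) or `"cohort"`.
#' @param scaling `"per_trial"` (default) or `"pooled"`.
#' @return a `score_matrix`: long data.frame with columns `mouse_id`,
#'   `week`, `trial`, `raw`, `normalized`, `z`, `t`, plus a `"weekly"`
#'   attribute (per week x trial: `wt_mean`, `wt_sd`, `scaling_factor`,
#'   `ref_mean`, `ref_sd`).
#' @export
score_screen <- function(dataset, reference = c("wt", "cohort"),
                         scaling = c("per_trial", "pooled")) {
  stopifnot(inherits(dataset, "screen_dataset"))
  reference <- match.arg(reference)
  scaling <- match.arg(scaling)
  tri <- dataset$trials
  if (nrow(tri) == 0L) {
    out <- data.frame(mouse_id = character(0), week = integer(0),
                      trial = integer(0), raw = numeric(0),
                      normalized = numeric(0), z = numeric(0), t = numeric(0))
    return(structure(out, weekly = NULL, reference = reference,
                     scaling = scaling, class = c("score_matrix",
                                                  "data.frame")))
  }
  info <- dataset$mice[match(tri$mouse_id, dataset$mice$mouse_id), ]
  long <- data.frame(
    mouse_id = rep(tri$mouse_id, times = 6L),
    week = rep(info$week, times = 6L),
    generation = rep(info$generation, times = 6L),
    trial = rep(1:6, each = nrow(tri)),
    raw = unlist(tri[paste0("trial_", 1:6)], use.names = FALSE),
    stringsAsFactors = FALSE)

  weekly <- do.call(rbind, lapply(sort(unique(long$week)), function(w) {
    wk <- long[long$week == w, , drop = FALSE]
    wt <- wk[wk$generation == "WT", , drop = FALSE]
    if (nrow(wt) == 0L)
      stop_format("unscorable week %s: no wild-type controls", w)
    per_trial <- lapply(1:6, function(tt) {
      wt_t <- wt$raw[wt$trial == tt]
      sf <- if (scaling == "per_trial") weekly_scaling_factor(wt_t)
            else weekly_scaling_factor(wt$raw[wt$trial == 6L])
      ref <- if (reference == "wt") wt_t else wk$raw[wk$trial == tt]
      data.frame(week = w, trial = tt, wt_mean = mean(wt_t),
                 wt_sd = stats::sd(wt_t), scaling_factor = sf,
                 ref_mean = mean(ref), ref_sd = stats::sd(ref))
    })
    do.call(rbind, per_trial)
  }))
  bad <- weekly[!is.finite(weekly$ref_sd) | weekly$ref_sd <= 0, , drop = FALSE]
  if (nrow(bad))
    stop_format("zero reference SD in week %s, trial %s",
                bad$week[1], bad$trial[1])

  key <- match(paste(long$week, long$trial),
               paste(weekly$week, weekly$trial))
  long$normalized <- long$raw * weekly$scaling_factor[key]
  long$z <- (long$raw - weekly$ref_mean[key]) / weekly$ref_sd[key]
  long$t <- 50 + 10 * long$z
  out <- long[order(long$mouse_id, long$trial),
              c("mouse_id", "week", "trial", "raw", "normalized", "z", "t")]
  rownames(out) <- NULL
  structure(out, weekly = weekly, reference = reference, scaling = scaling,
            class = c("score_matrix", "data.frame"))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d mice x 6 trials, %d weeks (reference: %s, scaling: %s)\n",
              length(unique(x$mouse_id)), length(unique(x$week)),
              attr(x, "reference"), attr(x, "scaling")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Median filter over 2 adjacent trials
#'
#' Smooths a 6-trial curve by replacing each value with the median of
#' itself and its left neighbor (the median of two values being their
#' mean); the first trial has no left neighbor and keeps its own value.
#' Smoothing is for displaying learning trajectories only — group
#' statistics are always computed on unsmoothed scores.
#'
#' @param curve numeric vector of 6 finite values (or a matrix with 6
#'   columns, smoothed row-wise).
#' @param window filter width; only the 2-trial filter is defined.
#' @return same shape as `curve`.
#' @export
median_smooth <- function(curve, window = 2L) {
  if (window != 2L) stop_format("only the 2-trial median filter is defined")
  if (is.matrix(curve)) {
    if (ncol(curve) != 6L) stop_format("curve matrix must have 6 columns")
    return(cbind(curve[, 1L, drop = FALSE],
                 (curve[, -6L, drop = FALSE] + curve[, -1L, drop = FALSE]) / 2))
  }
  if (length(curve) != 6L || any(!is.finite(curve)))
    stop_format("curve must hold 6 finite values")
  c(curve[1L], (curve[-6L] + curve[-1L]) / 2)
}

#' Accelerating-rotarod apparatus geometry
#'
#' Defaults describe the standard apparatus: 3 cm rod diameter, 20 cm fall
#' height, 4 rpm start speed, accelerating by 1 rpm every 8 s.
#'
#' @param rod_diameter rod diameter in meters.
#' @param start_speed starting rotation speed, rpm.
#' @param acceleration rpm gained per second (1/8 by default).
#' @param fall_height fall height in meters.
#' @return a classed list (`rotarod_spec`).
#' @export
rotarod_spec <- function(rod_diameter = 0.03, start_speed = 4,
                         acceleration = 1 / 8, fall_height = 0.20) {
  if (any(c(rod_diameter, start_speed, acceleration, fall_height) <= 0))
    stop_format("all rotarod dimensions must be positive")
  structure(list(rod_diameter = rod_diameter, start_speed = start_speed,
                 acceleration = acceleration, fall_height = fall_height),
            class = "rotarod_spec")
}

#' Rotarod kinematics
#'
#' `rpm_at_time()` gives the rotation speed after `t` seconds on the
#' accelerating rod (`start_speed + acceleration * t`); `linear_speed()`
#' converts rotation speed to the linear surface speed `pi * diameter *
#' rpm` in m/min; `latency_for_speed()` inverts the composition: the fall
#' latency at which the surface reaches a given linear speed.
#'
#' @param t time on the rod, seconds (>= 0).
#' @param rpm rotation speed, revolutions per minute (>= 0).
#' @param v linear surface speed, m/min (at least the start-speed surface
#'   speed).
#' @param spec a [rotarod_spec()].
#' @return numeric: rpm, m/min, or seconds respectively.
#' @export
rpm_at_time <- function(t, spec = rotarod_spec()) {
  if (any(t < 0)) stop_format("time on the rod cannot be negative")
  spec$start_speed + spec$acceleration * t
}

#' @rdname rpm_at_time
#' @export
linear_speed <- function(rpm, spec = rotarod_spec()) {
  if (any(rpm < 0)) stop_format("rpm cannot be negative")
  pi * spec$rod_diameter * rpm
}

#' @rdname rpm_at_time
#' @export
latency_for_speed <- function(v, spec = rotarod_spec()) {
  v0 <- linear_speed(spec$start_speed, spec)
  if (any(v < v0))
    stop_format("speed %.3g m/min is below the start-speed surface speed (%.3g m/min)",
                min(v), v0)
  rpm <- v / (pi * spec$rod_diameter)
  (rpm - spec$start_speed) / spec$acceleration
}
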