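#' Blood input function
#'
#' Container for the tracer concentration in blood, `Ca(t)`, sampled on a
#' strictly increasing time grid starting at 0 and treated as piecewise
#' linear between samples. The curve drives the two-tissue compartment
#' model; `t2` marks the boundary between the baseline and activation
#' sessions (the time of the second bolus), and `pvc` records the scalar
#' partial-volume correction already applied to the curve.
#'
#' @param time Numeric vector, minutes, strictly increasing, first value 0.
#' @param ca Numeric vector of activity concentrations (Bq/mL), same length
#'   as `time`. Small negative values are clipped to zero.
#' @param t2 Session boundary in minutes (default 20); must lie inside the
#'   time range.
#' @param pvc Dimensionless partial-volume correction constant (default 1).
#' @return An object of class `fpet_input` with fields `time`, `ca`, `t2`,
#'   `pvc` and attribute `n_clipped` (number of negative samples clipped).
#' @export
input_function <- function(time, ca, t2 = 20, pvc = 1) {
  time <- as.numeric(time)
  ca <- as.numeric(ca)
  if (length(time) != length(ca)) stop("time and ca must have equal length")
  if (length(time) < 2L) stop("input function needs at least 2 samples")
  if (any(!is.finite(time)) || any(!is.finite(ca)))
    stop("time and ca must be finite")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!is.finite(pvc) || pvc <= 0) stop("pvc must be > 0")
  if (t2 <= time[1L] || t2 >= time[length(time)])
    stop("t2 must lie strictly inside the time range")
  n_clipped <- sum(ca < 0)
  ca[ca < 0] <- 0
  structure(
    list(time = time, ca = ca, t2 = t2, pvc = pvc),
    n_clipped = n_clipped, class = "fpet_input"
  )
}

#' @export
print.fpet_input <- function(x, ...) {
  cat(sprintf(
    "Blood input function: %d samples on [%.3g, %.3g] min, t2 = %g min, peak %.4g Bq/mL, pvc = %g\n",
    length(x$time), x$time[1L], x$time[length(x$time)], x$t2, max(x$ca), x$pvc
  ))
  invisible(x)
}

#' Kinetic rate constants for one session
#'
#' Parameters of the irreversible two-tissue compartment model: `k1` is the
#' unidirectional blood-to-tissue clearance (mL blood per mL tissue per
#' min), `k2` the tissue-to-blood clearance rate (1/min), `k3` the trapping
#' (phosphorylation) rate (1/min), and `v0` the fractional vascular blood
#' volume of the voxel (dimensionless, in `[0, 1]`).
#'
#' @param k1,k2,k3 Non-negative rate constants.
#' @param v0 Blood volume fraction in `[0, 1]` (default 0).
#' @return An object of class `fpet_params`.
#' @export
kinetic_params <- function(k1, k2, k3, v0 = 0) {
  vals <- c(k1 = k1, k2 = k2, k3 = k3, v0 = v0)
  if (any(!is.finite(vals))) stop("kinetic parameters must be finite")
  if (k1 < 0 || k2 < 0 || k3 < 0) stop("k1, k2, k3 must be >= 0")
  if (v0 < 0 || v0 > 1) stop("v0 must lie in [0, 1]")
  structure(list(k1 = k1, k2 = k2, k3 = k3, v0 = v0), class = "fpet_params")
}

#' @export
print.fpet_params <- function(x, ...) {
  cat(sprintf(
    "Kinetic parameters: K1 = %.4g mL/mL/min, k2 = %.4g /min, k3 = %.4g /min, V0 = %.4g (Ki = %.4g)\n",
    x$k1, x$k2, x$k3, x$v0, net_uptake_rate(x)
  ))
  invisible(x)
}

#' Frame schedule
#'
#' The partition of the dynamic acquisition into reconstruction frames.
#'
#' @param start,end Numeric vectors of frame start/end times in minutes;
#'   frames must be strictly increasing and non-overlapping.
#' @return An object of class `fpet_schedule` with fields `start`, `end`.
#' @export
frame_schedule <- function(start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end) || length(start) == 0L)
    stop("start and end must be non-empty vectors of equal length")
  if (any(end <= start)) stop("each frame must have end > start")
  if (any(diff(start) <= 0) || any(start[-1L] < end[-length(end)] - 1e-9))
    stop("frames must be increasing and non-overlapping")
  structure(list(start = start, end = end), class = "fpet_schedule")
}

#' Default two-session acquisition schedule
#'
#' The acquisition framing used throughout: each 20-minute session is framed
#' as 8 frames of 15 s followed by 9 frames of 2 min, and the pattern is
#' repeated from the session boundary `t2`, giving 34 frames over 40 min.
#'
#' @param t2 Session boundary in minutes (default 20).
#' @param n_short,short_s Number and duration (seconds) of the initial short
#'   frames per session (defaults 8 and 15).
#' @param n_long,long_min Number and duration (minutes) of the long frames
#'   per session (defaults 9 and 2).
#' @return An `fpet_schedule` covering `[0, 2 * t2]`.
#' @export
default_frame_schedule <- function(t2 = 20, n_short = 8, short_s = 15,
                                   n_long = 9, long_min = 2) {
  one <- cumsum(c(rep(short_s / 60, n_short), rep(long_min, n_long)))
  start <- c(0, one[-length(one)])
  frames_start <- c(start, t2 + start)
  frames_end <- c(one, t2 + one)
  frame_schedule(frames_start, frames_end)
}

#' @export
print.fpet_schedule <- function(x, ...) {
  cat(sprintf(
    "Frame schedule: %d frames on [%g, %g] min (durations %s min)\n",
    length(x$start), x$start[1L], x$end[length(x$end)],
    paste(signif(sort(unique(x$end - x$start)), 3), collapse = ", ")
  ))
  invisible(x)
}

frame_mid <- function(schedule) (schedule$start + schedule$end) / 2

#' Measured time-activity curve
#'
#' Frame-averaged measured total activity concentration for one voxel or
#' region, aligned to a frame schedule.
#'
#' @param schedule An [frame_schedule()].
#' @param values Numeric vector of activity concentrations (Bq/mL), one per
#'   frame.
#' @return An object of class `fpet_tac`.
#' @export
tac <- function(schedule, values) {
  stopifnot(inherits(schedule, "fpet_schedule"))
  values <- as.numeric(values)
  if (length(values) != length(schedule$start))
    stop("values length must match the number of frames")
  structure(list(schedule = schedule, values = values), class = "fpet_tac")
}

#' @export
print.fpet_tac <- function(x, ...) {
  cat(sprintf(
    "Time-activity curve: %d frames, range [%.4g, %.4g] Bq/mL\n",
    length(x$values), min(x$values), max(x$values)
  ))
  invisible(x)
}

# ---- model evaluation grid ------------------------------------------------

# Union of the input grid, frame boundaries, per-frame refinement points
# (>= `points_per_frame` samples per frame) and t2, with Ca linearly
# interpolated onto it (exact for the piecewise-linear representation).
# Returns the grid, ca, its running integral, the 0-based index of t2 and
# 0-based inclusive index ranges for each frame.
model_grid <- function(input_fn, schedule = NULL, points_per_frame = 21L,
                       t_extra = NULL) {
  tt <- input_fn$time
  pts <- c(tt, input_fn$t2, t_extra)
  if (!is.null(schedule)) {
    for (f in seq_along(schedule$start)) {
      pts <- c(pts, seq(schedule$start[f], schedule$end[f],
                        length.out = points_per_frame))
    }
  }
  pts <- sort(unique(round(pts, 9)))
  pts <- pts[pts >= tt[1L] - 1e-9 & pts <= tt[length(tt)] + 1e-9]
  ca <- stats::approx(tt, input_fn$ca, xout = pts, rule = 2)$y
  i_t2 <- which.min(abs(pts - input_fn$t2)) - 1L
  out <- list(
    time = pts, ca = ca, cumca = cpp_cumtrapz(pts, ca), i_t2 = i_t2
  )
  if (!is.null(schedule)) {
    idx <- function(v) {
      i <- findInterval(v + 1e-9, pts)
      if (any(abs(pts[i] - v) > 1e-6))
        stop("frame boundaries must lie on the model grid")
      i - 1L
    }
    out$i_start <- idx(schedule$start)
    out$i_end <- idx(schedule$end)
  }
  out
}

# ---- operations -----------------------------------------------------------

#' Convolve the input function with a decaying exponential
#'
#' Computes `int_{t_start}^{t} exp(-lam * (t - u)) Ca(u) du` for each `t` in
#' `t_eval`, the kernel of the closed-form compartment solutions. `Ca` is
#' treated as piecewise linear between its samples and each linear segment
#' is integrated against the exponential analytically, so there is no
#' quadrature error beyond the piecewise-linear representation itself.
#'
#' @param input_fn An [input_function()].
#' @param lam Non-negative rate (1/min); `lam = 0` degenerates to the plain
#'   running integral of `Ca`.
#' @param t_start Lower integration limit (minutes, default 0).
#' @param t_eval Evaluation times, all within `[t_start, max(input time)]`.
#' @return Numeric vector, one value per element of `t_eval`.
#' @export
exp_conv <- function(input_fn, lam, t_start = 0, t_eval) {
  stopifnot(inherits(input_fn, "fpet_input"))
  if (!is.finite(lam) || lam < 0) stop("lam must be a finite value >= 0")
  tt <- input_fn$time
  if (any(t_eval < t_start - 1e-9) || any(t_eval > tt[length(tt)] + 1e-9))
    stop("t_eval must lie within [t_start, end of input grid]")
  grid <- sort(unique(round(c(tt[tt >= t_start], t_start, t_eval), 9)))
  ca <- stats::approx(tt, input_fn$ca, xout = grid, rule = 2)$y
  F <- cpp_exp_conv(grid, ca, lam, 0L)
  F[match(round(t_eval, 9), grid)]
}

#' Baseline-session compartment curves
#'
#' Closed-form solution of the irreversible two-tissue model over the
#' baseline session: the free compartment is `K1` times the exponential
#' convolution of `Ca` at rate `k2 + k3`, and the trapped compartment is
#' `K1 k3 / (k2 + k3)` times the difference between the running integral of
#' `Ca` and that convolution. The measured signal adds `v0 * Ca`.
#'
#' @param p An [kinetic_params()] for the baseline session.
#' @param input_fn An [input_function()].
#' @param t_eval Evaluation times within `[0, t2]`.
#' @return An object of class `fpet_curves`: list with `time`, `cf`, `cm`,
#'   `ct` (all Bq/mL; `ct = cf + cm + v0 * ca`).
#' @export
solve_baseline <- function(p, input_fn, t_eval) {
  stopifnot(inherits(p, "fpet_params"), inherits(input_fn, "fpet_input"))
  if (any(t_eval < -1e-9) || any(t_eval > input_fn$t2 + 1e-9))
    stop("t_eval must lie within [0, t2] for the baseline session")
  g <- model_grid(input_fn, t_extra = t_eval)
  sol <- cpp_solve_two_session(
    g$time, g$ca, g$cumca, p$k1, p$k2, p$k3, 0, 0, 0, p$v0,
    g$i_t2, FALSE
  )
  i <- match(round(t_eval, 9), round(g$time, 9))
  structure(
    list(time = t_eval, cf = sol$cf[i], cm = sol$cm[i], ct = sol$ct[i]),
    class = "fpet_curves"
  )
}

#' Activation-session compartment curves
#'
#' Closed-form solution over the activation session (`t > t2`), which
#' carries the baseline terminal state forward: the free compartment gains
#' a decaying boundary term `Cf(t2) exp(-(k2+k3)(t-t2))`, and the trapped
#' compartment the constant `Cm(t2)` plus the continued trapping of that
#' boundary free tracer, `(k3/(k2+k3)) Cf(t2) (1 - exp(-(k2+k3)(t-t2)))`,
#' as required by the model differential equations (without it the
#' piecewise solution would not join the single-session solution).
#'
#' @param p2 An [kinetic_params()] for the activation session.
#' @param input_fn An [input_function()].
#' @param baseline_state Numeric length-2 vector `c(cf, cm)` at `t2`, as
#'   produced by [solve_baseline()] evaluated at `t2`.
#' @param t_eval Evaluation times within `[t2, end]`.
#' @return An `fpet_curves` object (see [solve_baseline()]).
#' @export
solve_activation <- function(p2, input_fn, baseline_state, t_eval) {
  stopifnot(inherits(p2, "fpet_params"), inherits(input_fn, "fpet_input"))
  if (missing(baseline_state) || length(baseline_state) != 2L ||
      any(!is.finite(baseline_state)))
    stop("baseline_state must be the length-2 state c(cf, cm) at t2")
  t2 <- input_fn$t2
  tend <- input_fn$time[length(input_fn$time)]
  if (any(t_eval < t2 - 1e-9) || any(t_eval > tend + 1e-9))
    stop("t_eval must lie within [t2, end] for the activation session")
  g <- model_grid(input_fn, t_extra = t_eval)
  lam <- p2$k2 + p2$k3
  G <- cpp_exp_conv(g$time, g$ca, lam, g$i_t2)
  i <- match(round(t_eval, 9), round(g$time, 9))
  cum0 <- g$cumca[g$i_t2 + 1L]
  E <- exp(-lam * (t_eval - t2))
  cf <- p2$k1 * G[i] + E * baseline_state[1L]
  cm <- if (lam > 0) {
    p2$k1 * p2$k3 / lam * ((g$cumca[i] - cum0) - G[i]) +
      baseline_state[2L] + p2$k3 / lam * baseline_state[1L] * (1 - E)
  } else {
    rep(baseline_state[2L], length(t_eval))
  }
  ca <- g$ca[i]
  structure(
    list(time = t_eval, cf = cf, cm = cm, ct = cf + cm + p2$v0 * ca),
    class = "fpet_curves"
  )
}

#' Predict a frame-averaged time-activity curve
#'
#' Maps the continuous two-session model onto PET frames: the total
#' activity `CT(t)` is evaluated on a fine sub-grid (at least
#' `points_per_frame` points per frame, plus all input samples) and averaged
#' over each frame; a frame crossing the session boundary is split at `t2`
#' internally (the grid always contains `t2`).
#'
#' @param p_base,p_act [kinetic_params()] for the two sessions; `v0` is
#'   taken from `p_base`. With `p_act = NULL` the baseline parameters apply
#'   over the whole acquisition.
#' @param input_fn An [input_function()].
#' @param schedule An [frame_schedule()] covered by the input grid.
#' @param points_per_frame Minimum sub-grid points per frame (default 21).
#' @return An `fpet_tac` of frame-averaged `CT` values.
#' @export
predict_tac <- function(p_base, p_act, input_fn, schedule,
                        points_per_frame = 21L) {
  stopifnot(
    inherits(p_base, "fpet_params"), inherits(input_fn, "fpet_input"),
    inherits(schedule, "fpet_schedule")
  )
  tend <- input_fn$time[length(input_fn$time)]
  if (schedule$end[length(schedule$end)] > tend + 1e-9)
    stop("schedule extends beyond the input grid")
  g <- model_grid(input_fn, schedule, points_per_frame)
  two <- !is.null(p_act)
  if (!two) p_act <- p_base
  vals <- cpp_predict_frames(
    g$time, g$ca, g$cumca, p_base$k1, p_base$k2, p_base$k3,
    p_act$k1, p_act$k2, p_act$k3, p_base$v0, g$i_t2, two,
    g$i_start, g$i_end
  )
  tac(schedule, vals)
}

#' Net uptake rate Ki
#'
#' The net FDG influx (trapping) rate `Ki = K1 k3 / (k2 + k3)` in
#' mL/mL/min, the quantity proportional to the cerebral metabolic rate of
#' glucose. With `k3 = 0` no tracer is trapped and `Ki = 0`.
#'
#' @param p An [kinetic_params()], or `k1` as a numeric if `k2`/`k3` given.
#' @param k2,k3 Optional numeric rates when `p` is numeric `k1`.
#' @return Ki (numeric).
#' @export
net_uptake_rate <- function(p, k2 = NULL, k3 = NULL) {
  if (inherits(p, "fpet_params")) {
    k1 <- p$k1; k2 <- p$k2; k3 <- p$k3
  } else {
    k1 <- p
    if (is.null(k2) || is.null(k3)) stop("supply k2 and k3 with numeric k1")
  }
  if (any(c(k1, k2, k3) < 0)) stop("rate constants must be >= 0")
  ifelse(k3 == 0, 0, k1 * k3 / (k2 + k3))
}

#' Relative change in Ki between sessions
#'
#' Signed percent change of the net uptake rate from baseline to
#' activation. The default expresses the change relative to the baseline
#' (`100 (Ki2 - Ki1) / Ki1`); `denominator = "activation"` selects the
#' alternative normalisation by the activation-session Ki.
#'
#' @param ki_base,ki_act Net uptake rates for the two sessions.
#' @param denominator `"baseline"` (default) or `"activation"`.
#' @return Percent change; `NA` where the chosen denominator is not
#'   positive (never infinite).
#' @export
delta_ki <- function(ki_base, ki_act, denominator = c("baseline", "activation")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "baseline") ki_base else ki_act
  out <- 100 * (ki_act - ki_base) / den
  out[!is.finite(out) | den <= 0] <- NA_real_
  out
}

#' Cerebral metabolic rate of glucose
#'
#' Scales the FDG net uptake rate to a glucose metabolic rate:
#' `CMRglucose = Ki * CPglucose / LC`, where `CPglucose` is the plasma
#' glucose concentration (mmol/L) and `LC` the lumped constant relating FDG
#' to glucose kinetics. A relative change in Ki equals the relative change
#' in glucose metabolism when plasma glucose is constant across sessions.
#'
#' @param ki Net uptake rate(s).
#' @param cp_glucose Plasma glucose concentration, mmol/L (> 0).
#' @param lc Lumped constant (> 0); a pass-through user input.
#' @return CMRglucose in mmol/L * mL/mL/min.
#' @export
cmr_glucose <- function(ki, cp_glucose, lc) {
  if (!is.finite(cp_glucose) || cp_glucose <= 0)
    stop("cp_glucose must be > 0")
  if (!is.finite(lc) || lc <= 0) stop("lc must be > 0")
  ki * cp_glucose / lc
}
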