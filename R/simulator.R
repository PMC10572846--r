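# Synthetic double-bolus data: gamma-variate blood curves, single-voxel
# time-activity curves with count-limited noise, and full 4D phantoms with
# aligned ground truth.

#' Bolus model for the simulated blood curve
#'
#' One bolus contributes a gamma-variate peak
#' `A ((t-t0)/(alpha beta))^alpha exp(alpha - (t-t0)/beta)` (peak value `A`
#' at `t0 + alpha beta`) plus a recirculation tail: the bolus convolved
#' with a normalized slow exponential, weighted by
#' `recirculation_fraction`.
#'
#' @param onset Bolus onset, minutes.
#' @param amplitude Peak concentration, Bq/mL (default 30000, roughly a
#'   150 MBq bolus diluted into the blood pool).
#' @param shape_alpha,shape_beta Gamma-variate shape (defaults 3 and 0.2
#'   min: time-to-peak 0.6 min, consistent with a 24 s injection plus
#'   dispersion).
#' @param recirculation_fraction Tail weight in `[0, 1)` (default 0.15).
#' @param tail_rate Tail exponential rate, 1/min (default 0.08).
#' @return A list of class `fpet_bolus`.
#' @export
bolus_model <- function(onset = 0, amplitude = 30000, shape_alpha = 3,
                        shape_beta = 0.2, recirculation_fraction = 0.15,
                        tail_rate = 0.08) {
  stopifnot(
    amplitude >= 0, shape_alpha > 0, shape_beta > 0,
    recirculation_fraction >= 0, recirculation_fraction < 1, tail_rate > 0
  )
  structure(list(
    onset = onset, amplitude = amplitude, shape_alpha = shape_alpha,
    shape_beta = shape_beta,
    recirculation_fraction = recirculation_fraction, tail_rate = tail_rate
  ), class = "fpet_bolus")
}

# Gamma-variate peak of one bolus on a time grid (no tail).
bolus_peak <- function(b, t) {
  s <- t - b$onset
  out <- numeric(length(t))
  pos <- s > 0
  x <- s[pos] / (b$shape_alpha * b$shape_beta)
  out[pos] <- b$amplitude * x^b$shape_alpha *
    exp(b$shape_alpha - s[pos] / b$shape_beta)
  out
}

#' Simulate a double-bolus blood input function
#'
#' Builds `Ca(t)` as the superposition of two gamma-variate boli (defaults:
#' onsets 0 and 20 min) with recirculation tails, on a fine uniform grid.
#' The tail of each bolus is the bolus shape convolved with a normalized
#' slow exponential, so the curve is non-negative and the two boli
#' superpose exactly.
#'
#' @param bolus1,bolus2 [bolus_model()] objects; defaults are identical
#'   boli at 0 and `t2` min.
#' @param t2 Session boundary, minutes (default 20).
#' @param duration Total length of the grid, minutes (default `2 * t2`).
#' @param grid_step_s Grid spacing, seconds (default 1).
#' @return An [input_function()].
#' @export
simulate_input <- function(bolus1 = bolus_model(onset = 0),
                           bolus2 = bolus_model(onset = 20),
                           t2 = 20, duration = 2 * t2, grid_step_s = 1) {
  stopifnot(inherits(bolus1, "fpet_bolus"), inherits(bolus2, "fpet_bolus"))
  if (bolus2$amplitude > 0 && bolus2$onset < t2 - 1e-6)
    stop("the second bolus must not start before t2")
  t <- seq(0, duration, by = grid_step_s / 60)
  ca <- numeric(length(t))
  for (b in list(bolus1, bolus2)) {
    if (b$amplitude == 0) next
    peak <- bolus_peak(b, t)
    ca <- ca + peak
    if (b$recirculation_fraction > 0) {
      conv <- cpp_exp_conv(t, peak, b$tail_rate, 0L)
      ca <- ca + b$recirculation_fraction * b$tail_rate * conv
    }
  }
  if (bolus1$amplitude > 0 && bolus2$amplitude > 0) {
    pk1 <- bolus1$onset + bolus1$shape_alpha * bolus1$shape_beta
    pk2 <- bolus2$onset + bolus2$shape_alpha * bolus2$shape_beta
    if (pk2 - pk1 < 4 * bolus1$shape_alpha * bolus1$shape_beta)
      warning("boli overlap substantially; the curve may have a single peak")
  }
  input_function(t, ca, t2 = t2)
}

#' Simulate a measured time-activity curve
#'
#' Frame-averages the two-session compartment model ([predict_tac()]) and
#' adds zero-mean Gaussian noise with per-frame standard deviation
#' `noise_scale * sqrt(max(CT, 0) / frame duration)` — a count-limited
#' surrogate in which shorter frames and hotter voxels are noisier, as in
#' reconstructed dynamic PET.
#'
#' @param p_base,p_act [kinetic_params()] for the two sessions (`p_act =
#'   NULL` keeps baseline kinetics throughout); `v0` from `p_base`.
#' @param input_fn An [input_function()].
#' @param schedule An [frame_schedule()].
#' @param noise_scale Noise magnitude (default 4, calibrated so a late
#'   2-min baseline frame of typical grey matter has about 10% relative SD);
#'   0 gives the exact model output.
#' @param seed Optional integer seed for reproducible noise.
#' @return An `fpet_tac`.
#' @export
simulate_tac <- function(p_base, p_act, input_fn, schedule, noise_scale = 4,
                         seed = NULL) {
  clean <- predict_tac(p_base, p_act, input_fn, schedule)
  if (noise_scale == 0) return(clean)
  if (!is.null(seed)) set.seed(seed)
  dt <- schedule$end - schedule$start
  sd <- noise_scale * sqrt(pmax(clean$values, 0) / dt)
  tac(schedule, clean$values + stats::rnorm(length(sd), 0, sd))
}

#' Phantom specification
#'
#' Geometry and kinetics of the digital double-bolus phantom: a tissue
#' ellipsoid containing a spherical "activated" region whose `K1` (hence
#' Ki) rises in session 2, a blood-vessel tube outside the tissue, an air
#' background, and a background reference box in air for the IDIF. All
#' coordinates are physical mm relative to the grid centre.
#'
#' @param shape Grid dimensions (default `c(32, 32, 16)`).
#' @param voxel_size_mm Voxel size (default `c(2.34, 2.34, 2.78)`, the
#'   acquisition voxel size).
#' @param tissue_params Background-tissue [kinetic_params()] (default
#'   `K1 = 0.1, k2 = 0.15, k3 = 0.05, v0 = 0.05`).
#' @param tissue_semiaxes_mm Tissue ellipsoid semi-axes (default
#'   `c(24, 24, 14)`).
#' @param vessel_center_mm,vessel_radius_mm Axis-aligned tube along z
#'   (defaults x,y centre `c(-33, -33)`, in the air corner well clear of
#'   the tissue and the smoothing kernel, radius 3).
#' @param active_center_mm,active_radius_mm Activated sphere (defaults
#'   centre `c(10, 0, 0)`, radius 6).
#' @param bkg_center_mm,bkg_halfwidth_mm Background reference box in air
#'   (defaults centre `c(30, 30, 0)`, half-width 4).
#' @param activation_change Fractional Ki increase in the active region in
#'   session 2 (default 0.5, i.e. a programmed delta Ki of 50%),
#'   implemented as `K1_2 = (1 + change) K1_1` with `k2`, `k3` unchanged.
#' @param noise_scale See [simulate_tac()] (default 4).
#' @param seed Integer seed (default 42).
#' @return A list of class `fpet_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 16),
                         voxel_size_mm = c(2.34, 2.34, 2.78),
                         tissue_params = kinetic_params(0.1, 0.15, 0.05, v0 = 0.05),
                         tissue_semiaxes_mm = c(24, 24, 14),
                         vessel_center_mm = c(-33, -33),
                         vessel_radius_mm = 3,
                         active_center_mm = c(10, 0, 0),
                         active_radius_mm = 6,
                         bkg_center_mm = c(30, 30, 0),
                         bkg_halfwidth_mm = 4,
                         activation_change = 0.5,
                         noise_scale = 4, seed = 42) {
  stopifnot(length(shape) == 3L, activation_change > -1,
            inherits(tissue_params, "fpet_params"))
  structure(as.list(environment()), class = "fpet_phantom_spec")
}

#' Generate a digital double-bolus phantom
#'
#' Builds a 4D dynamic image from the phantom specification: vessel voxels
#' carry the pure blood curve (`CT = Ca`: `v0 = 1`, `K1 = 0`), tissue
#' voxels the compartment model with the spec's parameters, active-region
#' voxels a session-2 `K1` scaled so the true delta Ki equals
#' `activation_change`, and air is zero. Count-limited noise is added per
#' voxel and frame as in [simulate_tac()]. Ground truth (per-region
#' parameters, true input curve, true delta-Ki map and region masks) is
#' returned alongside.
#'
#' @param spec An [phantom_spec()].
#' @param schedule An [frame_schedule()] (default [default_frame_schedule()]).
#' @param input_fn Optional [input_function()]; default
#'   [simulate_input()] with boli at 0 and 20 min.
#' @return A list with `image` ([dynamic_image()]) and `truth`: `ca`
#'   (the true input), `params_base`/`params_act` (per-region
#'   [kinetic_params()]), `delta_ki` (true map, percent), and masks
#'   `vessel`, `active`, `tissue` (background tissue incl. active),
#'   `brain` (tissue only), `bkg` (reference box in air).
#' @export
generate_phantom <- function(spec = phantom_spec(),
                             schedule = default_frame_schedule(),
                             input_fn = NULL) {
  stopifnot(inherits(spec, "fpet_phantom_spec"))
  if (is.null(input_fn)) input_fn <- simulate_input()
  d <- spec$shape
  vs <- spec$voxel_size_mm
  # voxel-centre physical coordinates relative to the grid centre
  cx <- (seq_len(d[1L]) - (d[1L] + 1) / 2) * vs[1L]
  cy <- (seq_len(d[2L]) - (d[2L] + 1) / 2) * vs[2L]
  cz <- (seq_len(d[3L]) - (d[3L] + 1) / 2) * vs[3L]
  X <- array(rep(cx, times = d[2L] * d[3L]), d)
  Y <- array(rep(rep(cy, each = d[1L]), times = d[3L]), d)
  Z <- array(rep(cz, each = d[1L] * d[2L]), d)

  sa <- spec$tissue_semiaxes_mm
  tissue <- (X / sa[1L])^2 + (Y / sa[2L])^2 + (Z / sa[3L])^2 <= 1
  ac <- spec$active_center_mm
  active <- (X - ac[1L])^2 + (Y - ac[2L])^2 + (Z - ac[3L])^2 <=
    spec$active_radius_mm^2
  active <- active & tissue
  vc <- spec$vessel_center_mm
  vessel <- (X - vc[1L])^2 + (Y - vc[2L])^2 <= spec$vessel_radius_mm^2
  # overlaps resolve in favour of the vessel
  tissue <- tissue & !vessel
  active <- active & !vessel
  bc <- spec$bkg_center_mm
  bw <- spec$bkg_halfwidth_mm
  bkg <- abs(X - bc[1L]) <= bw & abs(Y - bc[2L]) <= bw & abs(Z - bc[3L]) <= bw
  bkg <- bkg & !tissue & !vessel

  p <- spec$tissue_params
  p_act <- kinetic_params((1 + spec$activation_change) * p$k1, p$k2, p$k3,
                          v0 = p$v0)
  # one clean TAC per region type; noise is per voxel
  tac_tissue <- predict_tac(p, p, input_fn, schedule)$values
  tac_active <- predict_tac(p, p_act, input_fn, schedule)$values
  tac_vessel <- predict_tac(
    kinetic_params(0, 0, 0, v0 = 1), NULL, input_fn, schedule
  )$values

  nf <- length(schedule$start)
  nvox <- prod(d)
  clean <- matrix(0, nrow = nvox, ncol = nf)
  clean[which(tissue & !active), ] <- rep(tac_tissue, each = sum(tissue & !active))
  clean[which(active), ] <- rep(tac_active, each = sum(active))
  clean[which(vessel), ] <- rep(tac_vessel, each = sum(vessel))
  if (spec$noise_scale > 0) {
    set.seed(spec$seed)
    dt <- rep(schedule$end - schedule$start, each = nvox)
    sd <- spec$noise_scale * sqrt(pmax(clean, 0) / dt)
    clean <- clean + stats::rnorm(length(clean), 0, as.vector(sd))
  }
  img <- dynamic_image(array(clean, c(d, nf)), schedule, vs)

  true_dki <- array(0, d)
  true_dki[tissue] <- 0
  true_dki[active] <- delta_ki(net_uptake_rate(p), net_uptake_rate(p_act))
  true_dki[!tissue] <- NA_real_

  list(
    image = img,
    truth = list(
      ca = input_fn, params_base = p, params_act = p_act,
      delta_ki = true_dki,
      vessel = voi_mask(vessel, "vessel"),
      active = voi_mask(active, "active"),
      tissue = voi_mask(tissue, "tissue"),
      brain = voi_mask(tissue, "brain"),
      bkg = voi_mask(bkg, "background")
    ),
    spec = spec
  )
}
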