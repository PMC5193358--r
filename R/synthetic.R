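#' Generator configuration
#'
#' Settings of the synthetic gait and metabolic data generator. Subjects
#' are drawn from sex-specific truncated normal distributions matching the
#' study population (males: 1.83 ± 0.06 m, 87.9 ± 10.9 kg, 31 ± 6 yr,
#' 212.4 ± 66.2 N·m; females: 1.62 ± 0.07 m, 57.1 ± 10.0 kg, 32 ± 9 yr,
#' 107.6 ± 35.7 N·m). Each subject walks at five conditions (70, 85, 100,
#' 115 and 130% of a preferred speed drawn from 1.29 ± 0.11 m/s, preferred
#' stride length 1.48 ± 0.11 m), and the double-support fraction decreases
#' linearly with speed from 34.9% at the slowest to 22.1% at the fastest
#' condition. Joint trajectories are harmonic (Fourier) series of the
#' stride frequency; torques are harmonic series plus double-support
#' torque bursts at the lower-limb sagittal DOFs. Measured mean MEE per
#' stride is computed from the MEE-rate model under the ground-truth
#' weights and multiplied by lognormal-free Gaussian noise.
#'
#' @param n_subjects Number of estimation-group subjects.
#' @param n_validation Number of validation-group subjects (half unseen,
#'   half shared with the estimation group, as in the study design).
#' @param sex_ratio Proportion of males.
#' @param speeds_pct Condition speeds as percent of preferred speed.
#' @param preferred_speed_mean,preferred_speed_sd Preferred speed
#'   distribution, m/s.
#' @param stride_length_mean,stride_length_sd Preferred-speed stride
#'   length distribution, m.
#' @param ds_anchors Double-support percent of the gait cycle at the
#'   slowest and fastest condition; linear in speed between them.
#' @param harmonics Number of harmonics per DOF trajectory (2-4).
#' @param sample_rate Sampling rate in Hz.
#' @param samples_per_stride If not `NULL`, overrides `sample_rate` with a
#'   fixed number of intervals per stride (reduced-grid studies).
#' @param torque_frac Named amplitude fractions of the subject's scaled
#'   maximum torque per DOF group (`lower_sag`, `lower_other`, `trunk`,
#'   `upper`).
#' @param ds_burst_frac Amplitude of the double-support torque bursts,
#'   as a fraction of the scaled maximum torque (lower-limb sagittal DOFs).
#' @param ds_angle_burst Amplitude (rad) of the angle bumps that make the
#'   lower-limb sagittal angular velocity peak during double support,
#'   emulating push-off.
#' @param angle_amp Base angle amplitude in rad (lower-limb sagittal;
#'   other groups use a third of it).
#' @param speed_exp Exponent scaling torque amplitude with relative speed.
#' @param burst_speed_exp Exponent scaling the double-support bursts with
#'   relative speed (weaker than `speed_exp`: push-off mechanics dominate
#'   relatively more at slow speeds, where double support is longest).
#' @param stride_length_exp Exponent of stride length versus relative
#'   speed.
#' @param speed_ripple Relative amplitude of the periodic centre-of-mass
#'   speed ripple.
#' @param bmr_range Uniform range for the sitting BMR, W.
#' @param noise_sd Relative SD of the multiplicative measurement noise on
#'   mean MEE.
#' @param weights_true Ground-truth [weight_parameters()] (default the
#'   packaged published values).
#' @param with_grf If `TRUE`, attach square-wave vertical GRF channels.
#' @param population Sex-specific subject distributions; see
#'   [default_population()].
#' @param seed Integer seed.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 8L, n_validation = 4L,
                             sex_ratio = 0.5,
                             speeds_pct = c(70, 85, 100, 115, 130),
                             preferred_speed_mean = 1.29,
                             preferred_speed_sd = 0.11,
                             stride_length_mean = 1.48,
                             stride_length_sd = 0.11,
                             ds_anchors = c(34.9, 22.1),
                             harmonics = 3L, sample_rate = 120,
                             samples_per_stride = NULL,
                             torque_frac = c(lower_sag = 0.12,
                                             lower_other = 0.06,
                                             trunk = 0.05, upper = 0.04),
                             ds_burst_frac = 0.45,
                             ds_angle_burst = 0.18,
                             angle_amp = 0.30,
                             speed_exp = 1.4,
                             burst_speed_exp = 0.6,
                             stride_length_exp = 0.5,
                             speed_ripple = 0.05,
                             bmr_range = c(60, 110),
                             noise_sd = 0.03,
                             weights_true = NULL,
                             with_grf = FALSE,
                             population = default_population(),
                             seed = 1L) {
  if (any(ds_anchors <= 0) || any(ds_anchors >= 50)) {
    stop("generator_config: ds_anchors must lie in (0, 50) percent", call. = FALSE)
  }
  if (noise_sd < 0 || preferred_speed_sd < 0 || stride_length_sd < 0) {
    stop("generator_config: standard deviations must be non-negative", call. = FALSE)
  }
  if (is.null(weights_true)) weights_true <- published_weights()
  structure(as.list(environment()), class = "generator_config")
}

# truncated normal draw: +/- 3 SD and a hard floor
rtruncnorm1 <- function(mean, sd, floor) {
  if (sd == 0) return(max(mean, floor))
  lo <- max(floor, mean - 3 * sd); hi <- mean + 3 * sd
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Default subject population (mean, SD) per sex
#'
#' Group statistics of the modelled adult population: height (m), mass
#' (kg), age (yr) and maximum knee extension torque (N·m) for males and
#' females. Used by [generate_subject()]; pass a modified copy through
#' `generator_config(population = ...)` to change the population (set SDs
#' to zero to generate mean subjects).
#'
#' @return A nested list `list(M = ..., F = ...)`, each with `height`,
#'   `mass`, `age`, `knee` as `c(mean, sd)`.
#' @export
default_population <- function() {
  list(
    M = list(height = c(1.83, 0.06), mass = c(87.9, 10.9), age = c(31, 6),
             knee = c(212.4, 66.2)),
    F = list(height = c(1.62, 0.07), mass = c(57.1, 10.0), age = c(32, 9),
             knee = c(107.6, 35.7)))
}

#' Draw a synthetic subject
#'
#' Draws subject parameters from the sex-specific truncated normal
#' distributions of the configured population (truncation at ±3 SD plus
#' physiological floors: 1.2 m, 35 kg, 18 yr, 40 N·m) and the BMR
#' uniformly from `config$bmr_range`. When the configuration carries
#' ground-truth weights, draws are additionally rejected until the
#' subject's heat coefficients under those weights are non-negative, so
#' the synthetic population lies inside the thermodynamic validity region
#' of the generating model (the same region the estimation constraints
#' enforce for estimation subjects). Uses the current RNG state; seed the
#' generator (or call via [generate_dataset()]) for reproducibility.
#'
#' @param config A [generator_config()].
#' @param id Subject label.
#' @param sex `"M"`, `"F"`, or `NULL` to draw from `config$sex_ratio`.
#' @return A [subject_profile()].
#' @export
generate_subject <- function(config, id = "S1", sex = NULL) {
  if (is.null(sex)) sex <- if (stats::runif(1L) < config$sex_ratio) "M" else "F"
  pop <- config$population[[sex]]
  catalog <- if (!is.null(config$weights_true)) default_dof_catalog(sex) else NULL
  for (try in 1:1000) {
    s <- subject_profile(id, sex,
                         mass = rtruncnorm1(pop$mass[1L], pop$mass[2L], 35),
                         height = rtruncnorm1(pop$height[1L], pop$height[2L], 1.2),
                         age = rtruncnorm1(pop$age[1L], pop$age[2L], 18),
                         knee_max_torque = rtruncnorm1(pop$knee[1L], pop$knee[2L], 40),
                         bmr = stats::runif(1L, config$bmr_range[1L], config$bmr_range[2L]),
                         vo2max = NA_real_)
    if (is.null(catalog)) return(s)
    ok <- tryCatch({
      h <- heat_coefficients(config$weights_true, s, catalog, tol = 0)
      # h_sl >= 1 guarantees non-negative net MEE per DOF for arbitrary
      # kinematics (eccentric work cannot outweigh its own heat), so the
      # ground truth stays feasible for the estimator on any trial
      all(h$h_sl >= 1)
    }, error = function(e) FALSE)
    if (ok) return(s)
  }
  stop("generate_subject: could not draw a subject feasible under the ",
       "ground-truth weights", call. = FALSE)
}

dof_group <- function(dof_id) {
  joint <- sub("_.*$", "", dof_id)
  axis <- sub("^.*_", "", dof_id)
  lower <- joint %in% c("ankle", "knee", "hip")
  ifelse(lower & axis == "sag", "lower_sag",
         ifelse(lower, "lower_other",
                ifelse(joint %in% c("neck", "waist"), "trunk", "upper")))
}

# wrapped Gaussian bump, periodic with period T (three nearest images)
periodic_bump <- function(t, center, sigma, T) {
  exp(-((t - center)^2) / (2 * sigma^2)) +
    exp(-((t - center - T)^2) / (2 * sigma^2)) +
    exp(-((t - center + T)^2) / (2 * sigma^2))
}

#' Draw a per-subject gait phase set
#'
#' Draws the random harmonic phases of a subject's gait pattern (one per
#' DOF and harmonic, for angles and torques, plus the speed-ripple
#' phase). Left-side DOFs copy their mirror's phases, so the left leg is
#' the right leg delayed by half a period. Uses the current RNG state.
#'
#' @param catalog A [dof_catalog()].
#' @param config A [generator_config()].
#' @return A list with matrices `q`, `tau` (DOF x harmonic) and scalar
#'   `ripple`.
#' @export
draw_gait_phases <- function(catalog, config) {
  H <- max(2L, min(4L, config$harmonics))
  nd <- nrow(catalog)
  ids <- catalog$dof_id
  right_of <- ifelse(catalog$side == "left", catalog$mirror_of, ids)
  phase_q <- matrix(stats::runif(nd * H, 0, 2 * pi), nd, H,
                    dimnames = list(ids, NULL))
  phase_t <- matrix(stats::runif(nd * H, 0, 2 * pi), nd, H,
                    dimnames = list(ids, NULL))
  phase_q[catalog$side == "left", ] <- phase_q[right_of[catalog$side == "left"], ]
  phase_t[catalog$side == "left", ] <- phase_t[right_of[catalog$side == "left"], ]
  list(q = phase_q, tau = phase_t, ripple = stats::runif(1L, 0, 2 * pi))
}

# exact time-derivative of periodic_bump
periodic_bump_deriv <- function(t, center, sigma, T) {
  -((t - center) * exp(-((t - center)^2) / (2 * sigma^2)) +
      (t - center - T) * exp(-((t - center - T)^2) / (2 * sigma^2)) +
      (t - center + T) * exp(-((t - center + T)^2) / (2 * sigma^2))) / sigma^2
}

#' Generate one synthetic gait stride
#'
#' Builds a single whole-body stride at a given speed: per-DOF joint
#' angles as 2-4 harmonic Fourier series of the stride frequency (left
#' channels are the right channels shifted by half a period), angular
#' velocities as the exact analytic derivatives, torques as phase-shifted
#' harmonic series scaled by the subject's scaled maximum torque (peak
#' |torque| capped at 0.8 of the maximum) plus double-support bursts at
#' the lower-limb sagittal DOFs, a centre-of-mass speed equal to the
#' condition speed plus a zero-mean periodic ripple, and analytically
#' placed gait events realizing the configured double-support fraction.
#'
#' @param subject A [subject_profile()].
#' @param speed Condition speed, m/s.
#' @param config A [generator_config()].
#' @param preferred_speed The subject's preferred speed, m/s (sets the
#'   relative-speed scalings; default `config$preferred_speed_mean`).
#' @param stride_length_pref Stride length at preferred speed, m.
#' @param catalog A [dof_catalog()] (default by subject sex).
#' @param phases Optional phase set from [draw_gait_phases()]; a subject's
#'   gait pattern is consistent across speeds, so [generate_dataset()]
#'   draws one phase set per subject and re-uses it for all conditions.
#'   `NULL` draws a fresh set.
#' @return A [gait_trial()] with events (and GRF if configured); the
#'   realized DS percent is attached as attribute `ds_pct`.
#' @export
generate_gait_trial <- function(subject, speed, config,
                                preferred_speed = config$preferred_speed_mean,
                                stride_length_pref = config$stride_length_mean,
                                catalog = default_dof_catalog(subject$sex),
                                phases = NULL) {
  rel <- speed / preferred_speed
  stride_length <- stride_length_pref * rel^config$stride_length_exp
  T <- stride_length / speed
  n <- if (!is.null(config$samples_per_stride)) config$samples_per_stride else
    max(16L, round(config$sample_rate * T))
  t <- seq(0, T, length.out = n + 1L)
  nd <- nrow(catalog)
  ids <- catalog$dof_id
  grp <- dof_group(ids)
  taumax <- scaled_max_torque(subject, catalog)
  # ds fraction linear in speed between the slowest and fastest condition
  v_lo <- preferred_speed * min(config$speeds_pct) / 100
  v_hi <- preferred_speed * max(config$speeds_pct) / 100
  frac <- if (v_hi > v_lo) (speed - v_lo) / (v_hi - v_lo) else 0.5
  ds_pct <- config$ds_anchors[1L] + frac * (config$ds_anchors[2L] - config$ds_anchors[1L])
  ds_half <- (ds_pct / 100) * T / 2
  events <- data.frame(
    side = c("right", "left", "left", "right", "right"),
    type = c("heel_strike", "toe_off", "heel_strike", "toe_off", "heel_strike"),
    time = c(0, ds_half, T / 2, T / 2 + ds_half, T))
  H <- max(2L, min(4L, config$harmonics))
  w0 <- 2 * pi / T
  q <- qd <- tau <- matrix(0, n + 1L, nd, dimnames = list(NULL, ids))
  amp_angle <- ifelse(grp == "lower_sag", config$angle_amp, config$angle_amp / 3)
  amp_tau <- config$torque_frac[grp] * taumax * rel^config$speed_exp
  if (is.null(phases)) phases <- draw_gait_phases(catalog, config)
  phase_q <- phases$q; phase_t <- phases$tau
  lag <- ifelse(catalog$side == "left", T / 2, 0)
  burst_centers <- c(ds_half / 2, T / 2 + ds_half / 2)
  burst_sigma <- max(ds_half / 2.5, T / 200)
  for (i in seq_len(nd)) {
    ti <- t - lag[i]
    for (k in seq_len(H)) {
      a <- amp_angle[i] / k^2
      q[, i] <- q[, i] + a * cos(k * w0 * ti + phase_q[i, k])
      qd[, i] <- qd[, i] - a * k * w0 * sin(k * w0 * ti + phase_q[i, k])
      tau[, i] <- tau[, i] + (amp_tau[i] / k) * cos(k * w0 * ti + phase_t[i, k])
    }
    if (grp[i] == "lower_sag") {
      # push-off-like bursts: torque and angular velocity peak together
      # during the double-support windows
      ctr <- if (catalog$side[i] == "left") rev(burst_centers) else burst_centers
      tau[, i] <- tau[, i] + config$ds_burst_frac * taumax[i] *
        rel^config$burst_speed_exp *
        (periodic_bump(t, ctr[1L], burst_sigma, T) +
           periodic_bump(t, ctr[2L], burst_sigma, T))
      qb <- config$ds_angle_burst * rel^config$burst_speed_exp
      q[, i] <- q[, i] + qb * (periodic_bump(t, ctr[1L], burst_sigma, T) -
                                 periodic_bump(t, ctr[2L], burst_sigma, T))
      qd[, i] <- qd[, i] + qb * (periodic_bump_deriv(t, ctr[1L], burst_sigma, T) -
                                   periodic_bump_deriv(t, ctr[2L], burst_sigma, T))
    }
    peak <- max(abs(tau[, i]))
    cap <- 0.8 * taumax[i]
    if (peak > cap) tau[, i] <- tau[, i] * cap / peak
  }
  v <- speed * (1 + config$speed_ripple * cos(2 * w0 * t + phases$ripple))
  grf <- NULL
  if (isTRUE(config$with_grf)) {
    Fz <- 1.1 * subject$mass * 9.81
    stance_r <- t <= T / 2 + ds_half | t >= T - 1e-12
    stance_l <- t >= T / 2 | t <= ds_half
    grf <- list(right = ifelse(stance_r, Fz, 0),
                left = ifelse(stance_l, Fz, 0))
  }
  out <- gait_trial(t, q, qd, tau, v, events = events, grf = grf)
  attr(out, "ds_pct") <- ds_pct
  out
}

#' Generate an estimation/validation dataset with ground truth
#'
#' Draws `config$n_subjects` estimation subjects and
#' `config$n_validation` validation subjects (half of them re-used from
#' the estimation group, half unseen, mirroring the study's split), one
#' stride per subject per speed condition. The "measured" mean MEE per
#' stride is the model stride average under the ground-truth weights
#' times `(1 + noise_sd * z)` Gaussian multiplicative noise. All
#' randomness flows from `config$seed`; the same seed reproduces the
#' dataset exactly.
#'
#' @param config A [generator_config()].
#' @return A list with `estimation` and `validation`
#'   ([estimation_dataset()]s) and `truth` (ground-truth weights,
#'   noiseless measurements, per-trial DS percents and subject profiles).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  wv_true <- config$weights_true
  n_shared <- config$n_validation %/% 2L
  n_unseen <- config$n_validation - n_shared
  make_entry <- function(subject) {
    catalog <- default_dof_catalog(subject$sex)
    pref <- rtruncnorm1(config$preferred_speed_mean, config$preferred_speed_sd, 0.6)
    slen <- rtruncnorm1(config$stride_length_mean, config$stride_length_sd, 0.8)
    phases <- draw_gait_phases(catalog, config)
    speeds <- pref * config$speeds_pct / 100
    trials <- lapply(speeds, function(v)
      generate_gait_trial(subject, v, config, preferred_speed = pref,
                          stride_length_pref = slen, catalog = catalog,
                          phases = phases))
    entry <- list(subject = subject, catalog = catalog, trials = trials,
                  measured = rep(NA_real_, length(speeds)), speed = speeds)
    entry
  }
  sexes <- rep(c("M", "F"), length.out = config$n_subjects)
  est_entries <- lapply(seq_len(config$n_subjects), function(i)
    make_entry(generate_subject(config, id = sprintf("E%02d", i), sex = sexes[i])))
  unseen <- lapply(seq_len(n_unseen), function(i)
    make_entry(generate_subject(config, id = sprintf("V%02d", i))))
  shared_idx <- seq_len(min(n_shared, length(est_entries)))
  shared <- lapply(shared_idx, function(i) {
    e <- est_entries[[i]]
    # new strides from the same subject (fresh phases), as in a re-measured trial
    make_entry(e$subject)
  })
  fill_measured <- function(entries) {
    for (j in seq_along(entries)) {
      e <- entries[[j]]
      h <- heat_coefficients(wv_true, e$subject, e$catalog)
      noiseless <- vapply(seq_along(e$trials), function(k) {
        trace <- mee_rate(e$trials[[k]], h, e$subject)
        idx <- seq_along(trace$time)
        wq <- trapz_avg_weights(trace$time)
        sum(trace$e_met[idx] * wq)
      }, numeric(1L))
      noise <- 1 + config$noise_sd * stats::rnorm(length(noiseless))
      entries[[j]]$measured <- noiseless * noise
      entries[[j]]$noiseless <- noiseless
    }
    entries
  }
  est_entries <- fill_measured(est_entries)
  val_entries <- fill_measured(c(unseen, shared))
  truth <- list(weights = wv_true,
                noiseless_estimation = lapply(est_entries, `[[`, "noiseless"),
                noiseless_validation = lapply(val_entries, `[[`, "noiseless"),
                ds_pct = lapply(est_entries, function(e)
                  vapply(e$trials, attr, numeric(1L), "ds_pct")),
                subjects = lapply(est_entries, `[[`, "subject"))
  list(estimation = estimation_dataset(est_entries),
       validation = if (length(val_entries)) estimation_dataset(val_entries),
       truth = truth)
}
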