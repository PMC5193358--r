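#' Detect gait events
#'
#' Detects heel-strike and toe-off events per side. When vertical
#' ground-reaction-force (GRF) traces are available the default is a
#' threshold detector with hysteresis: contact begins when the force rises
#' through `threshold` and ends when it falls below
#' `threshold - hysteresis`; event times are located by linear
#' interpolation between samples. Without force channels a
#' foot-kinematics proxy is used: sign changes of the sagittal ankle
#' angular velocity (negative-going crossing taken as heel strike,
#' positive-going as toe off), which is a coarse fallback meant for
#' data lacking force plates.
#'
#' @param trial A [gait_trial()]; its `grf` element is used when `grf` is
#'   not supplied.
#' @param grf Optional named list with numeric vectors `right` and `left`
#'   (vertical force, N, sampled on the trial grid).
#' @param threshold Contact threshold in N (default 20).
#' @param hysteresis Release hysteresis in N (default 5).
#' @param proxy_dofs Named character vector giving the per-side DOF used by
#'   the kinematic fallback.
#' @return Data frame of ordered events with columns `side`, `type`,
#'   `time`.
#' @export
detect_gait_events <- function(trial, grf = NULL, threshold = 20,
                               hysteresis = 5,
                               proxy_dofs = c(right = "ankle_r_sag",
                                              left = "ankle_l_sag")) {
  stopifnot(inherits(trial, "gait_trial"))
  if (is.null(grf)) grf <- trial$grf
  t <- trial$t
  events <- list()
  if (!is.null(grf)) {
    for (side in c("right", "left")) {
      f <- grf[[side]]
      if (is.null(f)) next
      if (length(f) != length(t)) {
        stop("detect_gait_events: GRF length differs from time grid", call. = FALSE)
      }
      events[[side]] <- grf_threshold_events(t, f, side, threshold, hysteresis)
    }
    if (!length(events)) {
      stop("detect_gait_events: grf given but no right/left channels", call. = FALSE)
    }
  } else {
    for (side in c("right", "left")) {
      dof <- proxy_dofs[[side]]
      if (!dof %in% trial$dof_ids) {
        stop("detect_gait_events: no GRF and proxy DOF '", dof,
             "' absent from trial", call. = FALSE)
      }
      w <- trial$qd[, dof]
      events[[side]] <- velocity_sign_events(t, w, side)
    }
  }
  ev <- do.call(rbind, events)
  if (is.null(ev) || sum(ev$side == "right" & ev$type == "heel_strike") < 2L) {
    stop("detect_gait_events: no complete stride (need two right heel strikes)",
         call. = FALSE)
  }
  validate_events(ev)
}

grf_threshold_events <- function(t, f, side, threshold, hysteresis) {
  on_thr <- threshold
  off_thr <- threshold - hysteresis
  out <- list()
  in_contact <- f[1L] >= on_thr
  for (i in 2L:length(f)) {
    if (!in_contact && f[i - 1L] < on_thr && f[i] >= on_thr) {
      tc <- t[i - 1L] + (on_thr - f[i - 1L]) / (f[i] - f[i - 1L]) * (t[i] - t[i - 1L])
      out[[length(out) + 1L]] <- data.frame(side = side, type = "heel_strike",
                                            time = tc)
      in_contact <- TRUE
    } else if (in_contact && f[i - 1L] >= off_thr && f[i] < off_thr) {
      tc <- t[i - 1L] + (off_thr - f[i - 1L]) / (f[i] - f[i - 1L]) * (t[i] - t[i - 1L])
      out[[length(out) + 1L]] <- data.frame(side = side, type = "toe_off",
                                            time = tc)
      in_contact <- FALSE
    }
  }
  do.call(rbind, out)
}

velocity_sign_events <- function(t, w, side) {
  out <- list()
  for (i in 2L:length(w)) {
    if (w[i - 1L] > 0 && w[i] <= 0) {
      tc <- t[i - 1L] + w[i - 1L] / (w[i - 1L] - w[i]) * (t[i] - t[i - 1L])
      out[[length(out) + 1L]] <- data.frame(side = side, type = "heel_strike",
                                            time = tc)
    } else if (w[i - 1L] < 0 && w[i] >= 0) {
      tc <- t[i - 1L] - w[i - 1L] / (w[i] - w[i - 1L]) * (t[i] - t[i - 1L])
      out[[length(out) + 1L]] <- data.frame(side = side, type = "toe_off",
                                            time = tc)
    }
  }
  do.call(rbind, out)
}

#' Segment strides into single- and double-support phases
#'
#' A stride runs from one right heel strike to the next. Double support
#' (DS) spans from a heel strike of one side to the following toe off of
#' the other side; single support (SS) is the remainder, labelled by the
#' stance side. A complete stride therefore contains, in order: DS1
#' (starting at the right heel strike), SS_right, DS2, SS_left. Phase
#' durations are contiguous and sum exactly to the stride duration.
#'
#' @param events Data frame with columns `side`, `type`, `time` (ordered or
#'   not), e.g. from [detect_gait_events()].
#' @return An object of class `"phase_segmentation"`: a list with
#'   `strides` (data frame `start`, `end`), `phases` (data frame `stride`,
#'   `label`, `start`, `end`, `duration`), and `fractions` (per-stride
#'   `ds_pct`, `ss_pct`, which sum to 100).
#' @export
segment_phases <- function(events) {
  events <- validate_events(events)
  rhs <- events$time[events$side == "right" & events$type == "heel_strike"]
  if (length(rhs) < 2L) {
    stop("segment_phases: no complete stride (need two right heel strikes)",
         call. = FALSE)
  }
  strides <- data.frame(start = utils::head(rhs, -1L), end = utils::tail(rhs, -1L))
  phases <- list(); fracs <- list()
  tol <- 1e-9
  for (k in seq_len(nrow(strides))) {
    s0 <- strides$start[k]; s1 <- strides$end[k]
    # events inside the stride window; the bounding right heel strikes are
    # excluded by type so that a toe off coincident with a heel strike
    # (instantaneous double support) still counts
    within <- events[events$time >= s0 - tol & events$time <= s1 + tol &
                       !(events$side == "right" & events$type == "heel_strike"), ]
    need <- data.frame(side = c("left", "left", "right"),
                       type = c("toe_off", "heel_strike", "toe_off"))
    if (nrow(within) != 3L || !identical(within$side, need$side) ||
        !identical(within$type, need$type)) {
      got <- paste(within$side, within$type, collapse = ", ")
      stop(sprintf(paste0("segment_phases: stride %d events out of order; ",
                          "expected left toe_off, left heel_strike, right toe_off ",
                          "but got: %s"), k, got), call. = FALSE)
    }
    lto <- within$time[1L]; lhs <- within$time[2L]; rto <- within$time[3L]
    ph <- data.frame(stride = k,
                     label = c("DS1", "SS_right", "DS2", "SS_left"),
                     start = c(s0, lto, lhs, rto),
                     end = c(lto, lhs, rto, s1))
    ph$duration <- ph$end - ph$start
    if (any(ph$duration < -tol)) {
      stop("segment_phases: negative phase duration in stride ", k, call. = FALSE)
    }
    phases[[k]] <- ph
    ds <- sum(ph$duration[ph$label %in% c("DS1", "DS2")])
    fracs[[k]] <- data.frame(stride = k,
                             ds_pct = 100 * ds / (s1 - s0),
                             ss_pct = 100 * (1 - ds / (s1 - s0)))
  }
  structure(list(strides = strides,
                 phases = do.call(rbind, phases),
                 fractions = do.call(rbind, fracs)),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("Phase segmentation: %d stride(s), mean DS %.1f%% / SS %.1f%%\n",
              nrow(x$strides), mean(x$fractions$ds_pct),
              mean(x$fractions$ss_pct)))
  invisible(x)
}

#' Synchronize a left stride onto a right-stride time base
#'
#' Builds a whole-body stride from a right-leg stride (which also carries
#' the central and upper-body channels) and a separately captured left-leg
#' stride. The left stride is divided at the right heel strike event it
#' contains and re-ordered so that every sample is synchronous with the
#' right-stride time base; left channels are resampled onto the right grid
#' by periodic linear interpolation.
#'
#' @param right A [gait_trial()] spanning one right stride whose events
#'   include its starting right heel strike.
#' @param left A [gait_trial()] spanning one left stride whose events
#'   include a right heel strike inside its window.
#' @param left_dofs Character vector naming the left-leg channels to take
#'   from `left`; defaults to all DOF ids containing `"_l_"`.
#' @return A [gait_trial()] on the right-stride time grid containing the
#'   union of the right trial's channels and the resampled left channels.
#' @export
synchronize_bilateral <- function(right, left, left_dofs = NULL) {
  stopifnot(inherits(right, "gait_trial"), inherits(left, "gait_trial"))
  if (is.null(left_dofs)) left_dofs <- grep("_l_", left$dof_ids, value = TRUE)
  missing_ch <- setdiff(left_dofs, left$dof_ids)
  if (length(missing_ch)) {
    stop("synchronize_bilateral: left trial missing channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  if (is.null(left$events)) {
    stop("synchronize_bilateral: left trial needs events (a right heel strike)",
         call. = FALSE)
  }
  rhs_in_left <- left$events$time[left$events$side == "right" &
                                    left$events$type == "heel_strike"]
  rhs_in_left <- rhs_in_left[rhs_in_left >= left$t[1L] &
                               rhs_in_left <= left$t[length(left$t)]]
  if (!length(rhs_in_left)) {
    stop("synchronize_bilateral: no right heel strike inside the left stride",
         call. = FALSE)
  }
  split_t <- rhs_in_left[1L]
  TL <- diff(range(left$t))
  # map right-base time to left-stride time, wrapping periodically at the
  # left stride boundaries
  tr <- right$t - right$t[1L]
  tl <- left$t[1L] + (split_t - left$t[1L] + tr) %% TL
  resample <- function(mat) {
    out <- vapply(left_dofs, function(ch)
      stats::approx(left$t, mat[, ch], xout = tl, rule = 2)$y,
      numeric(length(tl)))
    colnames(out) <- left_dofs
    out
  }
  keep <- setdiff(right$dof_ids, left_dofs)
  gait_trial(t = right$t,
             q = cbind(right$q[, keep, drop = FALSE], resample(left$q)),
             qd = cbind(right$qd[, keep, drop = FALSE], resample(left$qd)),
             tau = cbind(right$tau[, keep, drop = FALSE], resample(left$tau)),
             v = right$v, events = right$events, grf = right$grf)
}

#' Froude number of walking
#'
#' Dimensionless walking speed \eqn{Fr = \bar{v} / \sqrt{g\,l}} with leg
#' length estimated from stature as \eqn{l = 0.53 H}.
#'
#' @param v Mean walking speed, m/s (vectorised).
#' @param height Stature in m.
#' @param g Gravitational acceleration, m/s^2.
#' @param leg_length_factor Leg length as a fraction of height.
#' @return Dimensionless Froude number(s).
#' @examples
#' froude_number(1.29, 1.70)  # about 0.434
#' @export
froude_number <- function(v, height, g = 9.81, leg_length_factor = 0.53) {
  if (height <= 0) stop("froude_number: height must be positive", call. = FALSE)
  if (any(v < 0)) stop("froude_number: speed must be non-negative", call. = FALSE)
  v / sqrt(g * leg_length_factor * height)
}

#' Fit a Laurent-form COT versus speed curve
#'
#' Ordinary least squares of cost of transport on the Laurent basis
#' \eqn{\{\bar{v}^{-1}, 1, \bar{v}\}} (powers configurable):
#' \eqn{COT(\bar{v}) = c_{-1}/\bar{v} + c_0 + c_1 \bar{v}}. With
#' \eqn{c_{-1} > 0} the curve is convex on \eqn{\bar v > 0}, and with
#' \eqn{c_1 > 0} as well it has the interior minimum
#' \eqn{\bar{v}^* = \sqrt{c_{-1}/c_1}}.
#'
#' @param v Speeds, m/s (at least 3 distinct, positive).
#' @param cot Observed COT values.
#' @param powers Integer powers of the Laurent basis (default `c(-1,0,1)`).
#' @return An object of class `"cot_curve"` with elements `coefficients`
#'   (named by power), `powers`, `fitted`, `residuals`, `domain`, `argmin`
#'   (NA when not interior) and `convex`.
#' @examples
#' v <- seq(0.8, 1.8, by = 0.25)
#' fit <- fit_cot_curve(v, 0.2 / v + 0.1 + 0.1 * v)
#' fit$argmin  # sqrt(2)
#' @export
fit_cot_curve <- function(v, cot, powers = c(-1L, 0L, 1L)) {
  if (length(v) != length(cot)) stop("fit_cot_curve: length mismatch", call. = FALSE)
  if (length(unique(v)) < 3L) {
    stop("fit_cot_curve: need at least 3 distinct speeds", call. = FALSE)
  }
  if (any(v <= 0)) stop("fit_cot_curve: speeds must be positive", call. = FALSE)
  X <- vapply(powers, function(p) v^p, numeric(length(v)))
  colnames(X) <- paste0("c", powers)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("fit_cot_curve: rank-deficient design (duplicate speeds?)", call. = FALSE)
  }
  beta <- qr.coef(qrX, cot)
  fitted <- drop(X %*% beta)
  cm1 <- if (-1L %in% powers) beta[[paste0("c", -1L)]] else 0
  c1 <- if (1L %in% powers) beta[[paste0("c", 1L)]] else 0
  convex <- cm1 > 0
  argmin <- if (cm1 > 0 && c1 > 0) sqrt(cm1 / c1) else NA_real_
  structure(list(coefficients = beta, powers = powers, fitted = fitted,
                 residuals = cot - fitted, v = v, cot = cot,
                 domain = range(v), argmin = argmin, convex = convex),
            class = "cot_curve")
}

#' @export
print.cot_curve <- function(x, ...) {
  cat("Laurent COT curve: COT(v) =",
      paste(sprintf("%.4g*v^%d", x$coefficients, x$powers), collapse = " + "), "\n")
  if (is.finite(x$argmin)) {
    cat(sprintf("  convex with interior minimum at v* = %.3f m/s (COT %.3f)\n",
                x$argmin, predict(x, x$argmin)))
  }
  invisible(x)
}

#' @export
predict.cot_curve <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$v else as.numeric(newdata)
  X <- vapply(object$powers, function(p) v^p, numeric(length(v)))
  drop(X %*% object$coefficients)
}

#' Phase-specific cost of transport and MEE shares
#'
#' Evaluates the interval COT with \eqn{T} equal to the whole stride, the
#' union of single-support phases and the union of double-support phases,
#' and reports each phase group's share of stride duration and of total
#' metabolic energy. MEE shares sum to 100% across SS and DS.
#'
#' @param trace An `"energetics_trace"` covering the segmented stride.
#' @param segmentation A `"phase_segmentation"`; only strides inside the
#'   trace window are used.
#' @param subject A [subject_profile()] or mass in kg.
#' @param g Gravitational acceleration, m/s^2.
#' @return A list with `cot_total`, `cot_ss`, `cot_ds`, `mee_ss_pct`,
#'   `mee_ds_pct`, `duration_ss_pct`, `duration_ds_pct`.
#' @export
phase_cot <- function(trace, segmentation, subject, g = 9.81) {
  stopifnot(inherits(trace, "energetics_trace"),
            inherits(segmentation, "phase_segmentation"))
  tr_rng <- range(trace$time)
  ph <- segmentation$phases
  ph <- ph[ph$start >= tr_rng[1L] - 1e-9 & ph$end <= tr_rng[2L] + 1e-9, ]
  if (!nrow(ph)) stop("phase_cot: segmentation does not overlap trace", call. = FALSE)
  ph$start <- pmax(ph$start, tr_rng[1L]); ph$end <- pmin(ph$end, tr_rng[2L])
  ss <- as.matrix(ph[ph$label %in% c("SS_left", "SS_right"), c("start", "end")])
  ds <- as.matrix(ph[ph$label %in% c("DS1", "DS2"), c("start", "end")])
  stride <- c(min(ph$start), max(ph$end))
  int_e <- function(iv) sum(apply(iv, 1L, function(r)
    interval_integral(trace$time, trace$e_met, r[1L], r[2L])))
  e_ss <- int_e(ss); e_ds <- int_e(ds)
  e_tot <- interval_integral(trace$time, trace$e_met, stride[1L], stride[2L])
  d_ss <- sum(ss[, 2L] - ss[, 1L]); d_ds <- sum(ds[, 2L] - ds[, 1L])
  list(cot_total = cot(trace, stride, subject, g = g),
       cot_ss = cot(trace, ss, subject, g = g),
       cot_ds = if (d_ds > 0) cot(trace, ds, subject, g = g) else NA_real_,
       mee_ss_pct = 100 * e_ss / e_tot,
       mee_ds_pct = 100 * e_ds / e_tot,
       duration_ss_pct = 100 * d_ss / (d_ss + d_ds),
       duration_ds_pct = 100 * d_ds / (d_ss + d_ds))
}

#' Correlation screen of mean MEE against subject parameters
#'
#' Pearson correlation of measured mean MEE rate (typically at preferred
#' walking speed) against each subject-specific parameter, as used to
#' justify which parameters enter the heat coefficient functions.
#'
#' @param data Data frame with a column `mee` (W) and one column per
#'   candidate parameter (e.g. `mass`, `height`, `age`, `knee_max_torque`,
#'   `vo2max`).
#' @param response Name of the response column (default `"mee"`).
#' @return Data frame with columns `parameter`, `r`, `r_squared`, `p`,
#'   `flag` (`"ok"` or `"undefined-constant"`), one row per parameter.
#' @export
parameter_correlations <- function(data, response = "mee") {
  if (!response %in% names(data)) {
    stop("parameter_correlations: no '", response, "' column", call. = FALSE)
  }
  if (nrow(data) < 3L) {
    stop("parameter_correlations: need at least 3 subjects", call. = FALSE)
  }
  params <- setdiff(names(data), response)
  rows <- lapply(params, function(p) {
    x <- data[[p]]; y <- data[[response]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(parameter = p, r = NA_real_, r_squared = NA_real_,
                        p = NA_real_, flag = "undefined-constant"))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(parameter = p, r = unname(ct$estimate),
               r_squared = unname(ct$estimate)^2, p = ct$p.value, flag = "ok")
  })
  do.call(rbind, rows)
}
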