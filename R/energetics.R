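#' Gait trial container
#'
#' Holds one trial's joint-space time series on a strictly increasing
#' uniform time grid: joint angles `q` (rad), angular velocities `qd`
#' (rad/s) and actuator torques `tau` (N·m), one column per DOF, plus the
#' instantaneous centre-of-mass speed `v` (m/s), optional per-DOF
#' torque-independent cocontraction heat traces `qcc` (W, non-negative) and
#' optional gait events.
#'
#' @param t Time vector in s, strictly increasing, uniform grid.
#' @param q,qd,tau Numeric matrices, samples x DOFs, with column names set
#'   to the DOF ids.
#' @param v Centre-of-mass speed per sample, m/s.
#' @param events Optional data frame with columns `side`
#'   (`"left"`/`"right"`), `type` (`"heel_strike"`/`"toe_off"`), `time`.
#' @param qcc Optional cocontraction heat matrix, samples x DOFs, W,
#'   non-negative.
#' @param grf Optional named list of vertical ground-reaction-force traces
#'   (`right`, `left`), N, same length as `t`.
#' @return An object of class `"gait_trial"`.
#' @export
gait_trial <- function(t, q, qd, tau, v, events = NULL, qcc = NULL, grf = NULL) {
  q <- as.matrix(q); qd <- as.matrix(qd); tau <- as.matrix(tau)
  n <- length(t)
  if (n < 2L) stop("gait_trial: need at least two samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("gait_trial: time must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) {
    stop("gait_trial: time grid must be uniform", call. = FALSE)
  }
  if (nrow(q) != n || nrow(qd) != n || nrow(tau) != n || length(v) != n) {
    stop("gait_trial: channel lengths differ from length(t)", call. = FALSE)
  }
  if (!identical(dim(q), dim(qd)) || !identical(dim(q), dim(tau))) {
    stop("gait_trial: q, qd, tau dimensions differ", call. = FALSE)
  }
  if (is.null(colnames(tau))) {
    stop("gait_trial: matrices must carry DOF ids as column names", call. = FALSE)
  }
  if (!is.null(qcc)) {
    qcc <- as.matrix(qcc)
    if (!identical(dim(qcc), dim(tau))) {
      stop("gait_trial: qcc dimensions differ from tau", call. = FALSE)
    }
    if (any(qcc < 0)) {
      stop("gait_trial: second-law violation, qcc must be non-negative",
           call. = FALSE)
    }
  }
  if (!is.null(events)) events <- validate_events(events)
  structure(list(t = as.numeric(t), q = q, qd = qd, tau = tau,
                 v = as.numeric(v), qcc = qcc, events = events, grf = grf,
                 dof_ids = colnames(tau)),
            class = "gait_trial")
}

validate_events <- function(events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req <- c("side", "type", "time")
  if (!all(req %in% names(events))) {
    stop("events must have columns side, type, time", call. = FALSE)
  }
  if (!all(events$side %in% c("left", "right")) ||
      !all(events$type %in% c("heel_strike", "toe_off"))) {
    stop("events: side must be left/right and type heel_strike/toe_off",
         call. = FALSE)
  }
  events[order(events$time), req, drop = FALSE]
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Gait trial: %d samples, %.3f s, %d DOFs, mean speed %.3f m/s, %d events\n",
              length(x$t), diff(range(x$t)), ncol(x$tau), mean(x$v),
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Instantaneous metabolic energy expenditure rate
#'
#' Evaluates the joint-space MEE-rate model per sample:
#' \deqn{\dot{E}_{met}(t) = \sum_i \tau_i\dot{q}_i
#'   + \sum_i h_i^{am}|\tau_i| + \sum_i h_i^{sl}|\tau_i\dot{q}_i|
#'   + \sum_i \dot{Q}_i^{cc} + \dot{E}_{bmr}}
#' The work term is signed net joint power; both heat terms are
#' non-negative by the second law; `qcc` defaults to zero.
#'
#' @param trial A [gait_trial()].
#' @param h A `"heat_coefficients"` object (or list with `h_am`, `h_sl`
#'   vectors ordered as the trial's DOF columns).
#' @param bmr Basal metabolic rate in W, or a [subject_profile()] (its
#'   `bmr` and `mass` are then attached to the trace).
#' @return An object of classes `"energetics_trace"` and `"data.frame"`
#'   with per-sample columns `time`, `work_rate`, `q_am`, `q_sl`, `q_cc`,
#'   `bmr`, `e_met` (all W) and attributes `per_dof` (samples x DOFs matrix
#'   of per-DOF contributions: work + both heat terms), `v` (m/s), `mass`
#'   (kg, if a subject was given), `events` and metadata.
#' @examples
#' # single-DOF worked example: tau = 10 N.m, qd = 1 rad/s,
#' # h_am = 0.02 1/s, h_sl = 0.1, BMR = 80 W  ->  91.2 W
#' tr <- gait_trial(t = 0:1, q = cbind(j = c(0, 1)), qd = cbind(j = c(1, 1)),
#'                  tau = cbind(j = c(10, 10)), v = c(1.3, 1.3))
#' h <- list(h_am = 0.02, h_sl = 0.1)
#' mee_rate(tr, h, bmr = 80)$e_met
#' @export
mee_rate <- function(trial, h, bmr) {
  stopifnot(inherits(trial, "gait_trial"))
  subject <- NULL
  if (inherits(bmr, "subject_profile")) {
    subject <- bmr
    bmr <- subject$bmr
  }
  h_am <- if (is.list(h) || is.data.frame(h)) h$h_am else stop("invalid h")
  h_sl <- h$h_sl
  if (any(h_am < 0) || any(h_sl < 0)) {
    stop("mee_rate: heat coefficients must be non-negative", call. = FALSE)
  }
  if (inherits(h, "heat_coefficients") &&
      !identical(h$dof_id, trial$dof_ids)) {
    idx <- match(trial$dof_ids, h$dof_id)
    if (anyNA(idx)) {
      stop("mee_rate: trial DOFs missing from heat coefficients: ",
           paste(trial$dof_ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    h_am <- h_am[idx]; h_sl <- h_sl[idx]
  }
  work_dof <- trial$tau * trial$qd
  am_dof <- activation_maintenance_heat(h_am, trial$tau)
  sl_dof <- shortening_lengthening_heat(h_sl, trial$tau, trial$qd)
  qcc_dof <- if (is.null(trial$qcc)) 0 * work_dof else trial$qcc
  per_dof <- work_dof + am_dof + sl_dof
  out <- data.frame(time = trial$t,
                    work_rate = rowSums(work_dof),
                    q_am = rowSums(am_dof),
                    q_sl = rowSums(sl_dof),
                    q_cc = rowSums(qcc_dof),
                    bmr = rep(bmr, length(trial$t)))
  out$e_met <- out$work_rate + out$q_am + out$q_sl + out$q_cc + out$bmr
  colnames(per_dof) <- trial$dof_ids
  structure(out, per_dof = per_dof, v = trial$v, events = trial$events,
            mass = if (is.null(subject)) NA_real_ else subject$mass,
            subject_id = if (is.null(subject)) NA_character_ else subject$id,
            provenance = attr(h, "provenance"),
            class = c("energetics_trace", "data.frame"))
}

#' Instantaneous cost of transport
#'
#' Dimensionless instantaneous cost of transport:
#' \eqn{ICOT(t) = \dot{E}_{met}(t) / (M g v(t))}.
#'
#' @param trace An `"energetics_trace"` from [mee_rate()].
#' @param subject A [subject_profile()], or a body mass in kg.
#' @param v Speed trace in m/s; defaults to the speed stored on the trace.
#' @param g Gravitational acceleration, m/s^2.
#' @return Numeric ICOT vector, one value per sample.
#' @export
icot <- function(trace, subject, v = NULL, g = 9.81) {
  stopifnot(inherits(trace, "energetics_trace"))
  mass <- if (inherits(subject, "subject_profile")) subject$mass else subject
  if (is.null(v)) v <- attr(trace, "v")
  if (length(v) != nrow(trace)) stop("icot: speed length mismatch", call. = FALSE)
  bad <- which(v <= 0)
  if (length(bad)) {
    stop("icot: non-positive speed at sample(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  trace$e_met / (mass * g * v)
}

# trapezoidal integral of y over [t0, t1], linear interpolation at the
# interval endpoints; t must be increasing
interval_integral <- function(t, y, t0, t1) {
  if (t1 < t0) stop("interval_integral: empty interval", call. = FALSE)
  if (t0 < t[1L] - 1e-12 || t1 > t[length(t)] + 1e-12) {
    stop("interval_integral: interval outside trace", call. = FALSE)
  }
  if (t1 == t0) return(0)
  y0 <- stats::approx(t, y, xout = t0)$y
  y1 <- stats::approx(t, y, xout = t1)$y
  inside <- t > t0 & t < t1
  tt <- c(t0, t[inside], t1)
  yy <- c(y0, y[inside], y1)
  sum(diff(tt) * (utils::head(yy, -1L) + utils::tail(yy, -1L)) / 2)
}

#' Cost of transport over a time interval
#'
#' Dimensionless cost of transport over an interval (or union of
#' intervals) \eqn{T}:
#' \deqn{COT = \frac{\frac{1}{T}\int_T \dot{E}_{met}\,dt}
#'                  {M g \left(\frac{1}{T}\int_T v\,dt\right)}}
#' using composite trapezoidal integration on the native sample grid with
#' linear interpolation at interval endpoints. `interval` may be a
#' length-2 vector or a 2-column matrix of disjoint sub-intervals (their
#' integrals are pooled before the ratio, as for phase-specific COT).
#'
#' @param trace An `"energetics_trace"`.
#' @param interval Time interval(s) in s; default full trace.
#' @param subject A [subject_profile()] or body mass in kg.
#' @param g Gravitational acceleration, m/s^2.
#' @return A single dimensionless COT value.
#' @export
cot <- function(trace, interval = NULL, subject, g = 9.81) {
  stopifnot(inherits(trace, "energetics_trace"))
  mass <- if (inherits(subject, "subject_profile")) subject$mass else subject
  t <- trace$time
  v <- attr(trace, "v")
  if (is.null(interval)) interval <- range(t)
  iv <- if (is.matrix(interval)) interval else matrix(interval, ncol = 2L)
  dur <- sum(iv[, 2L] - iv[, 1L])
  if (dur <= 0) stop("cot: empty interval", call. = FALSE)
  int_e <- sum(apply(iv, 1L, function(r) interval_integral(t, trace$e_met, r[1L], r[2L])))
  int_v <- sum(apply(iv, 1L, function(r) interval_integral(t, v, r[1L], r[2L])))
  if (int_v <= 0) stop("cot: non-positive mean speed over interval", call. = FALSE)
  (int_e / dur) / (mass * g * (int_v / dur))
}

#' Energetic component breakdown over an interval
#'
#' Integrates the MEE-rate components (net joint work, activation-
#' maintenance heat, shortening-lengthening heat, cocontraction heat, BMR)
#' over an interval and reports each component's energy and share of the
#' total metabolic energy. Shares sum to 100 by additivity of the model.
#'
#' @param trace An `"energetics_trace"`.
#' @param interval Length-2 time interval in s; default full trace.
#' @return A data frame with columns `component`, `energy_J`, `share_pct`.
#' @export
component_breakdown <- function(trace, interval = NULL) {
  stopifnot(inherits(trace, "energetics_trace"))
  t <- trace$time
  if (is.null(interval)) interval <- range(t)
  comp <- c("work_rate", "q_am", "q_sl", "q_cc", "bmr")
  energy <- vapply(comp, function(cn)
    interval_integral(t, trace[[cn]], interval[1L], interval[2L]), numeric(1L))
  total <- interval_integral(t, trace$e_met, interval[1L], interval[2L])
  data.frame(component = c(comp, "e_met"),
             energy_J = c(energy, total),
             share_pct = 100 * c(energy, total) / total,
             row.names = NULL)
}

#' Write an energetics trace to CSV
#'
#' Columns: `time_s`, `work_rate_W`, `q_am_W`, `q_sl_W`, `q_cc_W`, `bmr_W`,
#' `e_met_W`, `icot` (if `subject` given), then one `emet_<dof>_W` column
#' per DOF.
#'
#' @param trace An `"energetics_trace"`.
#' @param path Output CSV path.
#' @param subject Optional [subject_profile()] to add the ICOT column.
#' @return `path`, invisibly.
#' @export
write_energetics_trace <- function(trace, path, subject = NULL) {
  out <- data.frame(time_s = trace$time, work_rate_W = trace$work_rate,
                    q_am_W = trace$q_am, q_sl_W = trace$q_sl,
                    q_cc_W = trace$q_cc, bmr_W = trace$bmr,
                    e_met_W = trace$e_met)
  if (!is.null(subject)) out$icot <- icot(trace, subject)
  pd <- attr(trace, "per_dof")
  colnames(pd) <- paste0("emet_", colnames(pd), "_W")
  utils::write.csv(cbind(out, pd), path, row.names = FALSE)
  invisible(path)
}
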