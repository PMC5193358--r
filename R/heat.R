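#' Generalized heat coefficients for a subject
#'
#' Evaluates the separable heat coefficient functions at every DOF of the
#' catalog for one subject:
#' \deqn{h_i^{am} = (w_0^{am} + w_1^{am} m_n + w_2^{am} a_n + w_3^{am} h_n)
#'   \left(1 + w_4^{am}\,\frac{\tau_{knee}^{max}}{\tilde{\tau}_{knee}^{max}}
#'   \,\tilde{\tau}_{n,i}\right)}
#' and analogously for \eqn{h_i^{sl}}, where \eqn{m_n, a_n, h_n} and
#' \eqn{\tilde{\tau}_{n,i}} are the normalized subject parameters and
#' per-DOF normalized reference torques (see [normalize_parameters()]).
#' \eqn{h^{am}} has units 1/s (it multiplies a torque to give watts);
#' \eqn{h^{sl}} is dimensionless.
#'
#' The second law of thermodynamics requires \eqn{h_i^{am} \ge 0} and
#' \eqn{h_i^{sl} \ge 0}. Because published weight values are printed to
#' three significant digits, a subject can sit numerically just below zero
#' on a factor that is exactly zero at full precision; `tol` absorbs such
#' round-off: first factors in `(-tol, 0)` are clamped to zero. With
#' `tol = 0` any negative coefficient is an error listing the offending
#' DOFs and factor values.
#'
#' @param w A [weight_parameters()] object.
#' @param subject A [subject_profile()].
#' @param catalog A [dof_catalog()].
#' @param check If `TRUE` (default) enforce non-negativity.
#' @param tol Non-negativity tolerance on the coefficient factors
#'   (default `1e-6`, far below any physiological heat-rate scale).
#' @return An object of classes `"heat_coefficients"` and `"data.frame"`
#'   with columns `dof_id`, `h_am` (1/s), `h_sl` (dimensionless), and the
#'   per-factor values as attributes `first_factor` (length-2, am/sl) and
#'   `second_factor` (2-column matrix).
#' @examples
#' s <- subject_profile("m", "M", 87.9, 1.83, 31, 212.4, bmr = 85)
#' h <- heat_coefficients(published_weights(), s, default_dof_catalog("M"))
#' h[h$dof_id == "hip_r_sag", ]
#' @export
heat_coefficients <- function(w, subject, catalog, check = TRUE, tol = 1e-6) {
  stopifnot(inherits(w, "weight_parameters"))
  np <- normalize_parameters(subject, catalog)
  u <- c(1, np$m_n, np$a_n, np$h_n)
  f1 <- c(am = sum(w$am[1:4] * u), sl = sum(w$sl[1:4] * u))
  f2 <- cbind(am = 1 + w$am[5] * np$knee_ratio * np$tau_n,
              sl = 1 + w$sl[5] * np$knee_ratio * np$tau_n)
  f1c <- f1
  if (check) {
    clampable <- f1 < 0 & f1 > -tol
    f1c[clampable] <- 0
  }
  h_am <- f1c[["am"]] * f2[, "am"]
  h_sl <- f1c[["sl"]] * f2[, "sl"]
  if (check) {
    bad <- which(h_am < 0 | h_sl < 0)
    if (length(bad)) {
      detail <- paste(sprintf(
        "%s (h_am=%.3g = %.3g x %.3g; h_sl=%.3g = %.3g x %.3g)",
        catalog$dof_id[bad], h_am[bad], f1c[["am"]], f2[bad, "am"],
        h_sl[bad], f1c[["sl"]], f2[bad, "sl"]), collapse = "; ")
      stop("heat_coefficients: second-law violation (negative coefficient) at: ",
           detail, call. = FALSE)
    }
  }
  out <- data.frame(dof_id = catalog$dof_id, h_am = unname(h_am),
                    h_sl = unname(h_sl), stringsAsFactors = FALSE)
  structure(out, first_factor = f1, second_factor = f2,
            subject_id = subject$id, provenance = w$provenance,
            class = c("heat_coefficients", "data.frame"))
}

#' Activation-maintenance heat rate
#'
#' Torque-dependent generalized activation-maintenance heat rate at each
#' DOF: \eqn{\dot{Q}_i^{am}(t) = h_i^{am} |\tau_i(t)|}, in watts. The basal
#' torque-dependent cocontraction term is part of the BMR, and the
#' torque-independent cocontraction term is the separate
#' \eqn{\dot{Q}^{cc}} input.
#'
#' @param h_am Per-DOF coefficient vector (1/s), or a
#'   `"heat_coefficients"` object.
#' @param tau Torque matrix, samples x DOFs, in N·m.
#' @return Matrix of non-negative heat rates, samples x DOFs, in W.
#' @export
activation_maintenance_heat <- function(h_am, tau) {
  if (inherits(h_am, "heat_coefficients")) h_am <- h_am$h_am
  tau <- as.matrix(tau)
  if (ncol(tau) != length(h_am)) {
    stop("activation_maintenance_heat: ncol(tau) != length(h_am)", call. = FALSE)
  }
  sweep(abs(tau), 2L, h_am, `*`)
}

#' Shortening-lengthening heat rate
#'
#' Torque- and velocity-dependent generalized shortening-lengthening heat
#' rate at each DOF:
#' \eqn{\dot{Q}_i^{sl}(t) = h_i^{sl} |\tau_i(t)\,\dot{q}_i(t)|}, in watts.
#' Concentric and eccentric phases with equal joint-power magnitude
#' dissipate equally (absolute value).
#'
#' @param h_sl Per-DOF dimensionless coefficient vector, or a
#'   `"heat_coefficients"` object.
#' @param tau Torque matrix, samples x DOFs, N·m.
#' @param qd Angular velocity matrix, samples x DOFs, rad/s.
#' @return Matrix of non-negative heat rates, samples x DOFs, in W.
#' @export
shortening_lengthening_heat <- function(h_sl, tau, qd) {
  if (inherits(h_sl, "heat_coefficients")) h_sl <- h_sl$h_sl
  tau <- as.matrix(tau); qd <- as.matrix(qd)
  if (!identical(dim(tau), dim(qd))) {
    stop("shortening_lengthening_heat: tau and qd dimensions differ", call. = FALSE)
  }
  if (ncol(tau) != length(h_sl)) {
    stop("shortening_lengthening_heat: ncol(tau) != length(h_sl)", call. = FALSE)
  }
  sweep(abs(tau * qd), 2L, h_sl, `*`)
}
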