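# shared fixtures and independent oracles

male_mean_subject <- function(bmr = 85) {
  subject_profile("male-mean", "M", mass = 87.9, height = 1.83, age = 31,
                  knee_max_torque = 212.4, bmr = bmr)
}

female_mean_subject <- function(bmr = 75) {
  subject_profile("female-mean", "F", mass = 57.1, height = 1.62, age = 32,
                  knee_max_torque = 107.6, bmr = 75)
}

# the six subject rows of the study's descriptive table
table1_subjects <- function() {
  list(
    male_mean_subject(),
    female_mean_subject(),
    subject_profile("S6v", "M", mass = 68.5, height = 1.79, age = 21,
                    knee_max_torque = 284.4, bmr = 80),
    subject_profile("S7v", "M", mass = 52.6, height = 1.63, age = 20,
                    knee_max_torque = 208.4, bmr = 80),
    subject_profile("S8v", "F", mass = 75.0, height = 1.75, age = 32,
                    knee_max_torque = 124.1, bmr = 80),
    subject_profile("S9v", "F", mass = 52.2, height = 1.56, age = 23,
                    knee_max_torque = 109.7, bmr = 80))
}

# independent evaluation of the separable coefficient functions, written
# as bare arithmetic (no package code paths)
oracle_heat <- function(w_am, w_sl, mass, age, height, knee, ref_knee, ref_dof) {
  f1a <- w_am[1] + w_am[2] * (mass / 100) + w_am[3] * (age / 100) +
    w_am[4] * (height / 10)
  f2a <- 1 + w_am[5] * (knee / ref_knee) * (ref_dof / 100)
  f1s <- w_sl[1] + w_sl[2] * (mass / 100) + w_sl[3] * (age / 100) +
    w_sl[4] * (height / 10)
  f2s <- 1 + w_sl[5] * (knee / ref_knee) * (ref_dof / 100)
  c(h_am = f1a * f2a, h_sl = f1s * f2s)
}

table2_am <- c(-2.27e-4, -6.40e-5, 1.61e-4, 1.43e-3, 1.82e3)
table2_sl <- c(9.79e-1, 3.45e-2, 1.07, -1.46, -6.97e-3)

# small analytic single/multi-DOF trial on a uniform grid
smooth_trial <- function(n = 200, T = 1.2, ndof = 2, bmr_speed = 1.3) {
  t <- seq(0, T, length.out = n + 1L)
  ids <- paste0("j", seq_len(ndof))
  q <- sapply(seq_len(ndof), function(i) 0.3 * sin(2 * pi * i * t / T))
  qd <- sapply(seq_len(ndof), function(i) 0.3 * (2 * pi * i / T) * cos(2 * pi * i * t / T))
  tau <- sapply(seq_len(ndof), function(i) 30 * cos(2 * pi * t / T + i))
  colnames(q) <- colnames(qd) <- colnames(tau) <- ids
  v <- bmr_speed + 0.1 * sin(2 * pi * t / T)
  gait_trial(t, q, qd, tau, v)
}

# trapezoid integral at k-times finer resolution via linear interpolation
# of the coarse trace would be identical; the oracle instead rebuilds the
# integrand analytically where needed, so tests pass explicit functions
riemann_integral <- function(f, a, b, n = 1e5) {
  x <- seq(a, b, length.out = n + 1L)
  y <- f(x)
  sum((y[-1L] + y[-length(y)]) / 2) * (b - a) / n
}

# events of one ideal stride: RHS 0, LTO, LHS T/2, RTO, RHS T
stride_events <- function(T = 1, ds_pct = 30) {
  dsh <- ds_pct / 100 * T / 2
  data.frame(side = c("right", "left", "left", "right", "right"),
             type = c("heel_strike", "toe_off", "heel_strike", "toe_off",
                      "heel_strike"),
             time = c(0, dsh, T / 2, T / 2 + dsh, T))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
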