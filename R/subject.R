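#' Subject profile
#'
#' Bundles the subject-specific energetic parameters used throughout the
#' package: body mass \eqn{M} (kg), height \eqn{H} (m), age \eqn{A} (years),
#' maximum isometric knee extension torque \eqn{\tau_{knee}^{max}} (N·m,
#' measured at 60 degrees of knee flexion), sitting basal metabolic rate
#' (BMR, W) and optionally the maximum aerobic power \eqn{\dot{V}O_2max}
#' expressed in watts.
#'
#' @param id Subject label.
#' @param sex `"M"` or `"F"`; selects the default reference-torque catalog.
#' @param mass Body mass in kg, positive.
#' @param height Height in m, positive.
#' @param age Age in years, positive.
#' @param knee_max_torque Maximum isometric knee extension torque in N·m,
#'   positive.
#' @param bmr Sitting basal metabolic rate in W, non-negative.
#' @param vo2max Optional maximum aerobic power in W (used only as an upper
#'   bound on average MEE during estimation).
#' @return An object of class `"subject_profile"`.
#' @examples
#' subject_profile("S1", "M", mass = 87.9, height = 1.83, age = 31,
#'                 knee_max_torque = 212.4, bmr = 85)
#' @export
subject_profile <- function(id, sex = c("M", "F"), mass, height, age,
                            knee_max_torque, bmr, vo2max = NA_real_) {
  sex <- match.arg(sex)
  for (fld in c("mass", "height", "age", "knee_max_torque")) {
    val <- get(fld)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop(sprintf("subject_profile: '%s' must be a single positive number", fld),
           call. = FALSE)
    }
  }
  if (!is.numeric(bmr) || length(bmr) != 1L || !is.finite(bmr) || bmr < 0) {
    stop("subject_profile: 'bmr' must be a single non-negative number",
         call. = FALSE)
  }
  structure(list(id = as.character(id), sex = sex, mass = mass,
                 height = height, age = age,
                 knee_max_torque = knee_max_torque, bmr = bmr,
                 vo2max = vo2max),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject '%s' (%s): %.1f kg, %.2f m, %.0f yr, tau_knee^max %.1f N.m, BMR %.1f W\n",
              x$id, x$sex, x$mass, x$height, x$age, x$knee_max_torque, x$bmr))
  if (is.finite(x$vo2max)) cat(sprintf("  VO2max: %.0f W\n", x$vo2max))
  invisible(x)
}

#' Degree-of-freedom catalog
#'
#' A catalog of body degrees of freedom (DOFs) with their reference maximum
#' actuator torques \eqn{\tilde{\tau}_i^{max}} and the reference knee torque
#' \eqn{\tilde{\tau}_{knee}^{max}} used to scale a subject's measured knee
#' strength to every DOF. Mirror (left/right) pairs must carry equal
#' reference torques; the heat coefficients are right-left symmetric.
#'
#' @param dofs A data frame with columns `dof_id`, `name`, `side`
#'   (`"left"`, `"right"` or `"central"`), `reference_max_torque` (N·m) and
#'   `mirror_of` (the paired `dof_id`, or `NA` for central DOFs).
#' @param reference_knee_torque Reference knee extension torque
#'   \eqn{\tilde{\tau}_{knee}^{max}} in N·m.
#' @return An object of classes `"dof_catalog"` and `"data.frame"` with the
#'   reference knee torque stored as attribute `reference_knee_torque`.
#' @seealso [default_dof_catalog()]
#' @export
dof_catalog <- function(dofs, reference_knee_torque) {
  req <- c("dof_id", "name", "side", "reference_max_torque", "mirror_of")
  missing_cols <- setdiff(req, names(dofs))
  if (length(missing_cols)) {
    stop("dof_catalog: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dofs <- as.data.frame(dofs, stringsAsFactors = FALSE)
  if (nrow(dofs) < 1L) stop("dof_catalog: at least one DOF required", call. = FALSE)
  if (anyDuplicated(dofs$dof_id)) stop("dof_catalog: duplicate dof_id", call. = FALSE)
  if (!all(dofs$side %in% c("left", "right", "central"))) {
    stop("dof_catalog: side must be left/right/central", call. = FALSE)
  }
  if (any(!is.finite(dofs$reference_max_torque)) ||
      any(dofs$reference_max_torque <= 0)) {
    stop("dof_catalog: all reference_max_torque must be positive", call. = FALSE)
  }
  if (!is.numeric(reference_knee_torque) || reference_knee_torque <= 0) {
    stop("dof_catalog: reference_knee_torque must be positive", call. = FALSE)
  }
  mirrored <- !is.na(dofs$mirror_of) & nzchar(dofs$mirror_of)
  if (any(mirrored)) {
    idx <- match(dofs$mirror_of[mirrored], dofs$dof_id)
    if (anyNA(idx)) stop("dof_catalog: mirror_of refers to unknown dof_id", call. = FALSE)
    if (any(dofs$reference_max_torque[mirrored] !=
            dofs$reference_max_torque[idx])) {
      stop("dof_catalog: mirror pairs must have equal reference_max_torque",
           call. = FALSE)
    }
  }
  structure(dofs,
            reference_knee_torque = reference_knee_torque,
            class = c("dof_catalog", "data.frame"))
}

#' Default full-body 42-DOF catalog
#'
#' Builds the default three-dimensional 42-DOF catalog: 3 rotational DOFs
#' (sagittal `sag`, frontal `fro`, transverse `tra`) for each of two ankles,
#' knees, hips, wrists, elbows and shoulders, plus 3 for the neck and 3 for
#' the waist. Reference maximum torques for the male sagittal hip
#' (240.1 N·m) and ankle (151.5 N·m) follow published values for adult
#' males; every other entry is a catalog default chosen from typical adult
#' strength tables and flagged `"catalog-default"` in the `source` column.
#' The catalogs ship as editable CSV files under
#' `system.file("extdata", package = "gaitmee")`.
#'
#' The default reference knee torque is the estimation-group mean maximum
#' knee extension torque: 212.4 N·m for males, 107.6 N·m for females. The
#' female catalog scales the male reference torques by the ratio of these
#' two (107.6/212.4).
#'
#' @param sex `"M"` or `"F"`.
#' @return A [dof_catalog()].
#' @examples
#' cat42 <- default_dof_catalog("M")
#' nrow(cat42)  # 42
#' @export
default_dof_catalog <- function(sex = c("M", "F")) {
  sex <- match.arg(sex)
  file <- if (sex == "M") "dof_catalog_male.csv" else "dof_catalog_female.csv"
  path <- system.file("extdata", file, package = "gaitmee")
  if (!nzchar(path)) stop("default catalog file not found: ", file, call. = FALSE)
  read_catalog(path)
}

#' Read a DOF catalog from CSV
#'
#' The CSV must have columns `dof_id`, `name`, `side`,
#' `reference_max_torque_Nm`, `mirror_of` and a comment line (or column
#' `reference_knee_torque_Nm`) carrying the reference knee torque.
#'
#' @param path Path to a catalog CSV file.
#' @return A [dof_catalog()].
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"reference_knee_torque_Nm" %in% names(df)) {
    stop("read_catalog: column reference_knee_torque_Nm required", call. = FALSE)
  }
  ref_knee <- df$reference_knee_torque_Nm[1L]
  names(df)[names(df) == "reference_max_torque_Nm"] <- "reference_max_torque"
  df$reference_knee_torque_Nm <- NULL
  dof_catalog(df, reference_knee_torque = ref_knee)
}

#' @export
print.dof_catalog <- function(x, ...) {
  cat(sprintf("DOF catalog: %d DOFs, reference knee torque %.1f N.m\n",
              nrow(x), attr(x, "reference_knee_torque")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Normalize subject parameters
#'
#' Divides each subject parameter by its maximum order of magnitude so that
#' all regressors in the heat coefficient functions are dimensionless and of
#' comparable scale: 100 for mass (kg), age (years) and maximum joint
#' torques (N·m), and 10 for height (m).
#'
#' @param subject A [subject_profile()].
#' @param catalog A [dof_catalog()].
#' @return A list of class `"normalized_parameters"` with elements `m_n`,
#'   `a_n`, `h_n` (scalars), `tau_n` (named per-DOF vector
#'   \eqn{\tilde{\tau}_i^{max}/100}), `knee_ratio`
#'   (\eqn{\tau_{knee}^{max}/\tilde{\tau}_{knee}^{max}}, already
#'   dimensionless and therefore not rescaled) and `scales`.
#' @examples
#' s <- subject_profile("m", "M", 87.9, 1.83, 31, 212.4, bmr = 85)
#' np <- normalize_parameters(s, default_dof_catalog("M"))
#' np$m_n  # 0.879
#' @export
normalize_parameters <- function(subject, catalog) {
  stopifnot(inherits(subject, "subject_profile"), inherits(catalog, "dof_catalog"))
  scales <- list(mass = 100, age = 100, height = 10, torque = 100)
  tau_n <- catalog$reference_max_torque / scales$torque
  names(tau_n) <- catalog$dof_id
  structure(list(m_n = subject$mass / scales$mass,
                 a_n = subject$age / scales$age,
                 h_n = subject$height / scales$height,
                 tau_n = tau_n,
                 knee_ratio = subject$knee_max_torque /
                   attr(catalog, "reference_knee_torque"),
                 scales = scales),
            class = "normalized_parameters")
}

#' Undo parameter normalization
#'
#' Inverse of [normalize_parameters()]; mainly used to check that the
#' normalization round-trips exactly.
#'
#' @param np A `"normalized_parameters"` object.
#' @return A list with `mass`, `age`, `height` and the per-DOF
#'   `reference_max_torque` on their original scales.
#' @export
denormalize_parameters <- function(np) {
  stopifnot(inherits(np, "normalized_parameters"))
  list(mass = np$m_n * np$scales$mass,
       age = np$a_n * np$scales$age,
       height = np$h_n * np$scales$height,
       reference_max_torque = np$tau_n * np$scales$torque)
}

#' Scale the measured knee strength to other DOFs
#'
#' Estimates a subject's maximum actuator torque at DOF \eqn{i} by linear
#' scaling of the measured maximum knee extension torque:
#' \deqn{\tau_i^{max} = (\tau_{knee}^{max} / \tilde{\tau}_{knee}^{max})
#'       \cdot \tilde{\tau}_i^{max}}
#' so the knee ratio acts as a subject-specific strength factor applied to
#' the DOF-specific catalog reference.
#'
#' @param subject A [subject_profile()].
#' @param catalog A [dof_catalog()].
#' @param dof_id Optional DOF id (or vector of ids); defaults to every DOF
#'   in the catalog.
#' @return Named numeric vector of maximum torques in N·m.
#' @examples
#' s <- subject_profile("S6v", "M", 68.5, 1.79, 21, 284.4, bmr = 80)
#' scaled_max_torque(s, default_dof_catalog("M"), "hip_r_sag")
#' @export
scaled_max_torque <- function(subject, catalog, dof_id = NULL) {
  stopifnot(inherits(subject, "subject_profile"), inherits(catalog, "dof_catalog"))
  if (is.null(dof_id)) dof_id <- catalog$dof_id
  idx <- match(dof_id, catalog$dof_id)
  if (anyNA(idx)) {
    stop("scaled_max_torque: unknown dof_id: ",
         paste(dof_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ratio <- subject$knee_max_torque / attr(catalog, "reference_knee_torque")
  out <- ratio * catalog$reference_max_torque[idx]
  names(out) <- dof_id
  out
}
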