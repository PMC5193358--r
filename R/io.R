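#' Write a gait trial to CSV
#'
#' Columns: `time_s`, `com_speed_mps`, then per DOF `<dof>_angle_rad`,
#' `<dof>_velocity_radps`, `<dof>_torque_Nm` and, when present,
#' `<dof>_qcc_W`. Events, if any, go to a JSON sidecar named
#' `<path minus .csv>.events.json`.
#'
#' @param trial A [gait_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  out <- data.frame(time_s = trial$t, com_speed_mps = trial$v)
  for (d in trial$dof_ids) {
    out[[paste0(d, "_angle_rad")]] <- trial$q[, d]
    out[[paste0(d, "_velocity_radps")]] <- trial$qd[, d]
    out[[paste0(d, "_torque_Nm")]] <- trial$tau[, d]
    if (!is.null(trial$qcc)) out[[paste0(d, "_qcc_W")]] <- trial$qcc[, d]
  }
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(trial$events)) {
    write_events(trial$events, events_sidecar(path))
  }
  invisible(path)
}

events_sidecar <- function(path) paste0(sub("\\.csv$", "", path), ".events.json")

#' Write gait events to JSON
#'
#' @param events Data frame with `side`, `type`, `time`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  jsonlite::write_json(lapply(seq_len(nrow(events)), function(i)
    list(side = events$side[i], type = events$type[i],
         time_s = events$time[i])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read gait events from JSON
#'
#' @param path Events JSON path (list of `{side, type, time_s}`).
#' @return Ordered events data frame.
#' @export
read_events <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_events(data.frame(side = x$side, type = x$type, time = x$time_s))
}

#' Read a gait trial
#'
#' Reads either the package CSV schema (see [write_trial()]) or a
#' tab-delimited motion-file dialect: a free header block terminated by a
#' line `endheader`, then a row of column names, then numeric rows. In
#' the dialect, a header line `inDegrees=yes` marks angle and velocity
#' columns as degrees (converted to radians on read); columns named
#' `<dof>` are taken as angles and `<dof>_moment` as torques. Missing
#' velocity channels are derived by central differences and flagged in
#' the returned trial's `derived_velocity` attribute.
#'
#' @param path Trial file path.
#' @param events Optional events data frame or path to an events JSON; by
#'   default the CSV sidecar is picked up when present.
#' @return A [gait_trial()].
#' @export
read_trial <- function(path, events = NULL) {
  first <- readLines(path, n = 50L, warn = FALSE)
  if (!length(first)) stop("read_trial: empty file: ", path, call. = FALSE)
  is_dialect <- any(trimws(first) == "endheader")
  parsed <- if (is_dialect) read_trial_dialect(path) else read_trial_csv(path)
  ev <- NULL
  if (is.null(events)) {
    side <- events_sidecar(path)
    if (!is_dialect && file.exists(side)) ev <- read_events(side)
  } else if (is.character(events)) {
    ev <- read_events(events)
  } else if (!is.null(events)) {
    ev <- validate_events(events)
  }
  tr <- gait_trial(parsed$t, parsed$q, parsed$qd, parsed$tau, parsed$v,
                   events = ev, qcc = parsed$qcc)
  attr(tr, "derived_velocity") <- parsed$derived_velocity
  tr
}

check_time <- function(t) {
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop("read_trial: non-monotone time at row ", bad[1L] + 1L, call. = FALSE)
  }
}

central_diff <- function(t, y) {
  n <- length(t)
  d <- numeric(n)
  d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  d
}

read_trial_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("read_trial: parse error in ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  if (!all(c("time_s", "com_speed_mps") %in% names(df))) {
    stop("read_trial: missing required columns: ",
         paste(setdiff(c("time_s", "com_speed_mps"), names(df)), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df)) {
    stop("read_trial: parse error at line ",
         which(rowSums(is.na(df)) > 0)[1L] + 1L, " (incomplete row)", call. = FALSE)
  }
  check_time(df$time_s)
  dofs <- unique(sub("_angle_rad$", "", grep("_angle_rad$", names(df), value = TRUE)))
  if (!length(dofs)) stop("read_trial: no <dof>_angle_rad columns", call. = FALSE)
  need_tau <- paste0(dofs, "_torque_Nm")
  miss <- setdiff(need_tau, names(df))
  if (length(miss)) {
    stop("read_trial: missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  q <- as.matrix(df[paste0(dofs, "_angle_rad")])
  tau <- as.matrix(df[need_tau])
  vel_cols <- paste0(dofs, "_velocity_radps")
  derived <- !all(vel_cols %in% names(df))
  qd <- if (!derived) as.matrix(df[vel_cols]) else
    vapply(dofs, function(d) central_diff(df$time_s, df[[paste0(d, "_angle_rad")]]),
           numeric(nrow(df)))
  colnames(q) <- colnames(qd) <- colnames(tau) <- dofs
  qcc_cols <- paste0(dofs, "_qcc_W")
  qcc <- if (all(qcc_cols %in% names(df))) {
    m <- as.matrix(df[qcc_cols]); colnames(m) <- dofs; m
  } else NULL
  list(t = df$time_s, q = q, qd = qd, tau = tau, v = df$com_speed_mps,
       qcc = qcc, derived_velocity = derived)
}

read_trial_dialect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- which(trimws(lines) == "endheader")[1L]
  if (is.na(endh) || endh + 1L > length(lines)) {
    stop("read_trial: truncated dialect file (no data after endheader) in ",
         path, call. = FALSE)
  }
  header <- lines[seq_len(endh - 1L)]
  in_degrees <- any(grepl("inDegrees\\s*=\\s*yes", header, ignore.case = TRUE))
  cols <- strsplit(trimws(lines[endh + 1L]), "[\t ]+")[[1L]]
  body <- lines[-(seq_len(endh + 1L))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("read_trial: dialect file has no data rows", call. = FALSE)
  vals <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[\t ]+")[[1L]]))
    if (length(v) != length(cols) || anyNA(v)) {
      stop("read_trial: parse error at line ", endh + 1L + i, " of ", path,
           call. = FALSE)
    }
    v
  })
  df <- as.data.frame(do.call(rbind, vals))
  names(df) <- cols
  if (!"time" %in% cols) stop("read_trial: dialect file lacks a 'time' column",
                              call. = FALSE)
  check_time(df$time)
  moment_cols <- grep("_moment$", cols, value = TRUE)
  dofs <- sub("_moment$", "", moment_cols)
  if (!length(dofs)) {
    stop("read_trial: dialect file has no <dof>_moment columns", call. = FALSE)
  }
  miss <- setdiff(dofs, cols)
  if (length(miss)) {
    stop("read_trial: missing angle column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  q <- as.matrix(df[dofs])
  if (in_degrees) q <- q * pi / 180
  tau <- as.matrix(df[moment_cols])
  qd <- vapply(dofs, function(d) central_diff(df$time, q[, d]), numeric(nrow(df)))
  colnames(q) <- colnames(qd) <- colnames(tau) <- dofs
  v <- if ("com_speed" %in% cols) df$com_speed else rep(1, nrow(df))
  list(t = df$time, q = q, qd = qd, tau = tau, v = v, qcc = NULL,
       derived_velocity = TRUE)
}

#' Write a subject profile to JSON
#'
#' Keys: `id`, `sex`, `mass_kg`, `height_m`, `age_yr`,
#' `knee_max_torque_Nm`, `bmr_W`, `vo2max_W` (omitted when unknown).
#'
#' @param subject A [subject_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject <- function(subject, path) {
  stopifnot(inherits(subject, "subject_profile"))
  x <- list(id = subject$id, sex = subject$sex, mass_kg = subject$mass,
            height_m = subject$height, age_yr = subject$age,
            knee_max_torque_Nm = subject$knee_max_torque, bmr_W = subject$bmr)
  if (is.finite(subject$vo2max)) x$vo2max_W <- subject$vo2max
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subject profile from JSON
#'
#' @param path Subject JSON path.
#' @return A [subject_profile()].
#' @export
read_subject <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  subject_profile(x$id, x$sex, mass = x$mass_kg, height = x$height_m,
                  age = x$age_yr, knee_max_torque = x$knee_max_torque_Nm,
                  bmr = x$bmr_W,
                  vo2max = if (!is.null(x$vo2max_W)) x$vo2max_W else NA_real_)
}
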