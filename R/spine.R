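#' @useDynLib kinesens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor prcomp qnorm pnorm quantile rnorm runif
#'   rlnorm plnorm qlnorm sd setNames splinefun var
#' @importFrom utils read.csv write.csv head tail
NULL

# Sagittal frame used internally: x anterior-positive (mm), z superior-positive
# (mm). The vehicle frame (x forward, z downward) is applied only when
# reporting kinematics, via z -> -z.

#' Ordered vertebral levels, most inferior first
#'
#' @return Character vector `S1, L5 ... L1, T12 ... T1, C7 ... C2`.
#' @export
vertebra_levels <- function() {
  c("S1",
    paste0("L", 5:1),
    paste0("T", 12:1),
    paste0("C", 7:2))
}

.point_roles <- c("inf_post", "inf_ant", "sup_post", "sup_ant", "meas", "pivot")

#' Joint labels of a spine, most inferior first
#'
#' A joint is named `upper-lower` (e.g. `"L4-L5"` sits between L4 and L5);
#' rotating it moves the upper vertebra and everything above it.
#'
#' @param levels ordered vertebral levels (default [vertebra_levels()]).
#' @return Character vector of joint labels, `"L5-S1"` up to `"C2-C3"`.
#' @export
joint_labels <- function(levels = vertebra_levels()) {
  paste0(levels[-1], "-", levels[-length(levels)])
}

new_spine_model <- function(df, frame = "sagittal_xz") {
  stopifnot(all(c("level", "role", "x", "z") %in% names(df)))
  df$level <- as.character(df$level)
  df$role <- as.character(df$role)
  bad <- setdiff(df$level, vertebra_levels())
  if (length(bad)) stop("unknown vertebral level(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(df$x)) || !all(is.finite(df$z)))
    stop("non-finite landmark coordinates")
  ord <- order(match(df$level, vertebra_levels()), match(df$role, .point_roles))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(landmarks = df, frame = frame), class = "spine_model")
}

#' @export
print.spine_model <- function(x, ...) {
  lv <- unique(x$landmarks$level)
  m <- measure_spine(x)
  cat(sprintf("<spine_model> %d vertebrae (%s..%s), frame %s\n",
              length(lv), lv[1], lv[length(lv)], x$frame))
  cat(sprintf("  lumbar %.2f deg, thoracic %.2f deg, cervical %.2f deg, dx %.1f mm\n",
              m$lumbar_lordosis_deg, m$thoracic_kyphosis_deg,
              m$cervical_lordosis_deg, m$c7_sacrum_dx_mm))
  invisible(x)
}

spine_point <- function(spine, level, role) {
  df <- spine$landmarks
  i <- which(df$level == level & df$role == role)
  if (length(i) != 1L)
    stop("landmark not found: level ", level, " role ", role)
  c(df$x[i], df$z[i])
}

level_index <- function(level) {
  i <- match(level, vertebra_levels())
  if (is.na(i)) stop("unknown vertebral level: ", level)
  i
}

#' Build the default template spine
#'
#' Constructs an idealised sagittal template with four corner landmarks, a
#' measurement node (approximate centre of gravity) and a joint pivot per
#' vertebra. Vertebra orientations follow a piecewise-linear sagittal-lean
#' profile whose segment angles sit near seated-population means
#' (lumbar lordosis ~0.9 deg, thoracic kyphosis ~20.5 deg, cervical lordosis
#' ~1.3 deg). Pivots default to the midpoint of each vertebra's inferior
#' endplate (the instantaneous axis of the joint beneath it); they are data,
#' so alternative axes can be supplied through the template CSV.
#'
#' @return A `spine_model`.
#' @export
template_spine <- function() {
  levels <- vertebra_levels()
  n <- length(levels)
  # body height, anterior-posterior width and disc gap (mm) per region
  region <- substr(levels, 1, 1)
  h <- c(S = 30, L = 28, T = 20, C = 14)[region]
  w <- c(S = 45, L = 35, T = 28, C = 18)[region]
  gap <- c(S = 10, L = 10, T = 6, C = 4)[region]
  # sagittal lean of each vertebra (deg, forward positive), interpolated
  # between anchor levels; differences set the template's segment angles and
  # the overall backward lean a seated, seatback-supported posture shows
  anchors <- c(S1 = -18, L5 = -20, L1 = -20.9, T12 = -24, T5 = -3.5,
               C7 = 2, C2 = 0.7)
  ai <- match(names(anchors), levels)
  psi <- approx(ai, anchors, xout = seq_len(n))$y
  # chain centres upward from S1 at the origin
  cx <- numeric(n); cz <- numeric(n)
  for (i in seq_len(n)[-1]) {
    step <- h[i - 1] / 2 + gap[i - 1] + h[i] / 2
    pm <- (psi[i - 1] + psi[i]) / 2 * pi / 180
    cx[i] <- cx[i - 1] + step * sin(pm)
    cz[i] <- cz[i - 1] + step * cos(pm)
  }
  rows <- lapply(seq_len(n), function(i) {
    p <- psi[i] * pi / 180
    tangent <- c(sin(p), cos(p))        # towards superior
    eplate <- c(cos(p), -sin(p))        # posterior -> anterior
    ctr <- c(cx[i], cz[i])
    half_h <- h[i] / 2; half_w <- w[i] / 2
    pts <- rbind(
      inf_post = ctr - half_h * tangent - half_w * eplate,
      inf_ant  = ctr - half_h * tangent + half_w * eplate,
      sup_post = ctr + half_h * tangent - half_w * eplate,
      sup_ant  = ctr + half_h * tangent + half_w * eplate,
      meas     = ctr,
      pivot    = ctr - half_h * tangent)
    data.frame(level = levels[i], role = rownames(pts),
               x = pts[, 1], z = pts[, 2], row.names = NULL)
  })
  new_spine_model(do.call(rbind, rows))
}

#' Read / write a spine landmark CSV
#'
#' Columns: `level`, `point_role` (one of inf_post, inf_ant, sup_post,
#' sup_ant, meas, pivot), `x_mm`, `z_mm`.
#'
#' @param path file path.
#' @return `read_spine_csv()` a `spine_model`; `write_spine_csv()` the path,
#'   invisibly.
#' @export
read_spine_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "point_role", "x_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("spine CSV must have columns: ", paste(need, collapse = ", "))
  new_spine_model(data.frame(level = df$level, role = df$point_role,
                             x = df$x_mm, z = df$z_mm))
}

#' @rdname read_spine_csv
#' @param spine a `spine_model`.
#' @export
write_spine_csv <- function(spine, path) {
  df <- spine$landmarks
  out <- data.frame(level = df$level, point_role = df$role,
                    x_mm = df$x, z_mm = df$z)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment definitions for the three spinal curvature angles
#'
#' Lumbar lordosis spans L1 superior to L5 inferior endplate (4 joints),
#' thoracic kyphosis T5 superior to T12 inferior (7 joints), cervical lordosis
#' C2 inferior to C7 inferior (5 joints). `sense` maps a counterclockwise
#' joint rotation to the sign of the segment-angle change, so lordotic angles
#' are positive for lumbar/cervical and kyphotic angles positive for thoracic,
#' matching positive population means.
#'
#' @param name one of `"lumbar_lordosis"`, `"thoracic_kyphosis"`,
#'   `"cervical_lordosis"`.
#' @return A `segment_spec` list with fields `name`, `upper_ref`, `lower_ref`,
#'   `joints`, `sense`.
#' @export
segment_spec <- function(name = c("lumbar_lordosis", "thoracic_kyphosis",
                                  "cervical_lordosis")) {
  name <- match.arg(name)
  spec <- switch(name,
    lumbar_lordosis = list(
      upper_ref = c("L1", "superior"), lower_ref = c("L5", "inferior"),
      joints = c("L4-L5", "L3-L4", "L2-L3", "L1-L2"), sense = +1),
    thoracic_kyphosis = list(
      upper_ref = c("T5", "superior"), lower_ref = c("T12", "inferior"),
      joints = paste0("T", 11:5, "-", "T", 12:6), sense = -1),
    cervical_lordosis = list(
      upper_ref = c("C2", "inferior"), lower_ref = c("C7", "inferior"),
      joints = paste0("C", 6:2, "-", "C", 7:3), sense = +1))
  structure(c(list(name = name), spec), class = "segment_spec")
}

endplate_vector <- function(spine, level, endplate) {
  roles <- if (endplate == "superior") c("sup_post", "sup_ant")
           else c("inf_post", "inf_ant")
  spine_point(spine, level, roles[2]) - spine_point(spine, level, roles[1])
}

wrap_deg <- function(a) ((a + 180) %% 360) - 180

#' Signed segment angle between two endplates
#'
#' Angle between the posterior-to-anterior endplate vectors of the segment's
#' reference endplates, about the lateral axis. Lordotic curvature is
#' positive for the lumbar and cervical segments, kyphotic curvature positive
#' for the thoracic segment.
#'
#' @param spine a `spine_model`.
#' @param seg a `segment_spec` (or its name).
#' @return Angle in degrees in (-180, 180].
#' @export
segment_angle <- function(spine, seg) {
  if (is.character(seg)) seg <- segment_spec(seg)
  vu <- endplate_vector(spine, seg$upper_ref[1], seg$upper_ref[2])
  vl <- endplate_vector(spine, seg$lower_ref[1], seg$lower_ref[2])
  au <- atan2(vu[2], vu[1]) * 180 / pi
  al <- atan2(vl[2], vl[1]) * 180 / pi
  wrap_deg(seg$sense * (au - al))
}

#' Rotate all vertebrae above a joint about its pivot
#'
#' Rigidly rotates every landmark of every vertebra superior to the joint
#' (including the joint's upper vertebra) by `angle` counterclockwise in the
#' sagittal plane about the joint's instantaneous axis of rotation (the upper
#' vertebra's `pivot` landmark). Vertebrae at or below the joint's lower
#' vertebra are untouched.
#'
#' @param spine a `spine_model`.
#' @param joint joint label, e.g. `"L1-L2"` or `"C7-T1"`.
#' @param angle rotation in degrees (counterclockwise, +x towards +z is
#'   posterior tilt of the anterior direction).
#' @return The rotated `spine_model`.
#' @export
rotate_about_joint <- function(spine, joint, angle) {
  parts <- strsplit(joint, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !(joint %in% joint_labels()))
    stop("unknown joint label: ", joint)
  upper <- parts[1]
  pivot <- spine_point(spine, upper, "pivot")
  idx <- spine$landmarks$level %in%
    vertebra_levels()[seq(level_index(upper), length(vertebra_levels()))]
  rotate_landmarks(spine, idx, pivot, angle)
}

rotate_landmarks <- function(spine, idx, pivot, angle_deg) {
  if (angle_deg == 0) return(spine)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  df <- spine$landmarks
  dx <- df$x[idx] - pivot[1]
  dz <- df$z[idx] - pivot[2]
  df$x[idx] <- pivot[1] + ca * dx - sa * dz
  df$z[idx] <- pivot[2] + sa * dx + ca * dz
  spine$landmarks <- df
  spine
}

#' Align one spinal segment to a target angle
#'
#' One sweep rotates the segment's joints one at a time from most inferior to
#' most superior, each by `(target - current) / n_joints` (recomputed at the
#' start of every sweep), in the segment's lordotic/kyphotic sense. Sweeps
#' repeat until the residual is within `tol`.
#'
#' @param spine a `spine_model`.
#' @param seg a `segment_spec` or segment name.
#' @param target target segment angle, degrees.
#' @param tol convergence tolerance, degrees (> 0).
#' @param max_iter maximum number of sweeps.
#' @return The aligned `spine_model`, with attribute `"sweeps"`: a data frame
#'   of per-sweep starting angle and per-joint rotation applied.
#' @export
align_segment <- function(spine, seg, target, tol = 0.01, max_iter = 100) {
  if (is.character(seg)) seg <- segment_spec(seg)
  stopifnot(tol > 0, max_iter >= 1)
  log <- data.frame(sweep = integer(), start_angle_deg = numeric(),
                    per_joint_rotation_deg = numeric())
  for (k in seq_len(max_iter)) {
    cur <- segment_angle(spine, seg)
    if (abs(cur - target) <= tol) {
      attr(spine, "sweeps") <- log
      return(spine)
    }
    d <- (target - cur) / length(seg$joints)
    log[nrow(log) + 1L, ] <- list(k, cur, d)
    for (j in seg$joints)
      spine <- rotate_about_joint(spine, j, seg$sense * d)
  }
  res <- segment_angle(spine, seg) - target
  if (abs(res) > tol)
    stop(sprintf("align_segment(%s) did not converge in %d sweeps; residual %.4g deg",
                 seg$name, max_iter, res))
  attr(spine, "sweeps") <- log
  spine
}

#' Rigidly rotate the whole spine about the sacrum to a target C7 offset
#'
#' Rotates every landmark about the S1 measurement node so the horizontal
#' distance x(C7 meas) - x(S1 meas) equals `target_dx`. Of the two candidate
#' rotations the one with the smaller magnitude is applied.
#'
#' @param spine a `spine_model`.
#' @param target_dx target horizontal offset, mm (anterior positive).
#' @return The rotated `spine_model`.
#' @export
rigid_rotate_to_distance <- function(spine, target_dx) {
  s1 <- spine_point(spine, "S1", "meas")
  c7 <- spine_point(spine, "C7", "meas")
  p <- c7 - s1
  r <- sqrt(sum(p^2))
  if (abs(target_dx) > r)
    stop(sprintf("target dx %.1f mm exceeds sacrum-C7 distance %.1f mm",
                 target_dx, r))
  phi0 <- atan2(p[2], p[1])
  base <- acos(target_dx / r)
  cand <- wrap_deg((c(base, -base) - phi0) * 180 / pi)
  a <- cand[which.min(abs(cand))]
  rotate_landmarks(spine, rep(TRUE, nrow(spine$landmarks)), s1, a)
}

#' Construct a set of spinal curvature measurements
#'
#' @param lumbar_lordosis_deg,thoracic_kyphosis_deg,cervical_lordosis_deg
#'   segment angles in degrees, each in (-90, 90).
#' @param c7_sacrum_dx_mm horizontal C7-sacrum offset, mm.
#' @return A `spine_measurements` list.
#' @export
spine_measurements <- function(lumbar_lordosis_deg, thoracic_kyphosis_deg,
                               cervical_lordosis_deg, c7_sacrum_dx_mm) {
  ang <- c(lumbar_lordosis_deg, thoracic_kyphosis_deg, cervical_lordosis_deg)
  if (!all(is.finite(ang)) || any(abs(ang) >= 90))
    stop("segment angles must be finite and within (-90, 90) degrees")
  if (!is.finite(c7_sacrum_dx_mm)) stop("c7_sacrum_dx_mm must be finite")
  structure(list(lumbar_lordosis_deg = lumbar_lordosis_deg,
                 thoracic_kyphosis_deg = thoracic_kyphosis_deg,
                 cervical_lordosis_deg = cervical_lordosis_deg,
                 c7_sacrum_dx_mm = c7_sacrum_dx_mm),
            class = "spine_measurements")
}

#' Measure a spine's three segment angles and C7-sacrum offset
#'
#' @param spine a `spine_model`.
#' @return A `spine_measurements` list.
#' @export
measure_spine <- function(spine) {
  spine_measurements(
    segment_angle(spine, "lumbar_lordosis"),
    segment_angle(spine, "thoracic_kyphosis"),
    segment_angle(spine, "cervical_lordosis"),
    spine_point(spine, "C7", "meas")[1] - spine_point(spine, "S1", "meas")[1])
}

#' Align a spine to a full set of curvature measurements
#'
#' Aligns the lumbar, thoracic and cervical segments (in that inferior-to-
#' superior order, so later stages do not disturb earlier ones), then rotates
#' the whole spine rigidly about the sacrum to the target C7-sacrum offset.
#'
#' @param spine a `spine_model` (typically [template_spine()]).
#' @param m a `spine_measurements` object.
#' @param tol per-segment angle tolerance, degrees.
#' @param max_iter maximum sweeps per segment.
#' @return The aligned `spine_model`.
#' @export
align_spine <- function(spine, m, tol = 0.01, max_iter = 100) {
  spine <- align_segment(spine, "lumbar_lordosis", m$lumbar_lordosis_deg,
                         tol, max_iter)
  spine <- align_segment(spine, "thoracic_kyphosis", m$thoracic_kyphosis_deg,
                         tol, max_iter)
  spine <- align_segment(spine, "cervical_lordosis", m$cervical_lordosis_deg,
                         tol, max_iter)
  rigid_rotate_to_distance(spine, m$c7_sacrum_dx_mm)
}
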