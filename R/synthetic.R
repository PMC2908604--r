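## Seeded synthetic-data generator: smooth periodic stride kinematics with
## published touch-down/lift-off endpoints, gait-parameter variability at
## the published magnitudes, digitization noise at the repeatability
## magnitudes, and calibration scenes for the DLT stage.

#' Stride kinematics template
#'
#' Knot table describing one stride of every DOF of every segment: the
#' touch-down value (contact phase 0), lift-off value (contact phase 1),
#' optional mid-phase extrema, and the return to the touch-down value at
#' the end of swing (periodic closure). Generated traces pass through the
#' knots exactly; between knots the curve is a monotone-segment piecewise
#' cubic (Fritsch-Carlson), so endpoints are controlled exactly and no
#' overshoot is introduced.
#'
#' The default template carries the published endpoint values for all 24
#' DOFs plus mid-phase knots anchored in the qualitative descriptions of
#' the stride: scapular retraction onset at ~30% of contact, the caudal
#' scapular-translation peak of ~-0.8 cm in the second half of contact,
#' humeral full flexion of ~-125 deg shortly after mid contact, and the
#' return to full protraction/extension shortly before the next touch
#' down. Mid-phase shapes beyond these anchors are synthetic conventions.
#'
#' @param endpoints data.frame in the shape of [kinematic_endpoints()].
#' @param extras data.frame of extra knots (`segment`, `dof`, `phase_ref`
#'   in `"contact"`/`"swing"`, `phase` in (0,1), `value`), or `NULL`.
#' @return data.frame of knots, class `kinematics_template`.
#' @export
kinematics_template <- function(endpoints = kinematic_endpoints(),
                                extras = default_template_extras()) {
  base <- do.call(rbind, lapply(seq_len(nrow(endpoints)), function(i) {
    e <- endpoints[i, ]
    data.frame(segment = e$segment, dof = e$dof,
               phase_ref = c("contact", "contact", "swing"),
               phase = c(0, 1, 1), value = c(e$td, e$lo, e$td))
  }))
  knots <- rbind(base, if (!is.null(extras)) extras[, names(base)])
  if (any(!knots$phase_ref %in% c("contact", "swing")))
    stop("phase_ref must be contact or swing", call. = FALSE)
  if (any(knots$phase < 0 | knots$phase > 1))
    stop("knot phase outside [0, 1]", call. = FALSE)
  if (any(!is.finite(knots$value))) stop("knot values must be finite", call. = FALSE)
  class(knots) <- c("kinematics_template", "data.frame")
  knots
}

#' Default mid-phase template knots
#'
#' The text-anchored mid-phase extrema used by the default
#' [kinematics_template()]; see that help page.
#'
#' @return data.frame of knots.
#' @export
default_template_extras <- function() {
  data.frame(
    segment = c("scapula", "scapula", "scapula", "scapula", "scapula",
                "humerus", "humerus"),
    dof = c("ty", "ty", "rx", "rz", "rz", "rz", "rz"),
    phase_ref = c("contact", "contact", "contact", "contact", "swing",
                  "contact", "swing"),
    phase = c(0.5, 0.8, 0.9, 0.3, 0.86, 0.6, 0.86),
    value = c(0, -0.8, -18.3, 71.7, 71.7, -125, -77.4))
}

# one DOF's interpolating function over frame coordinates 0..nc+ns
.template_fun <- function(knots, nc, ns) {
  x <- ifelse(knots$phase_ref == "contact", knots$phase * nc,
              nc + knots$phase * ns)
  o <- order(x)
  x <- x[o]; y <- knots$value[o]
  keep <- !duplicated(x)
  stats::splinefun(x[keep], y[keep], method = "monoH.FC")
}

#' Generate one stride of pose kinematics
#'
#' Evaluates the template on an integer frame grid: contact occupies
#' `round(contact_s * fps)` frames and swing `round(swing_s * fps)`; the
#' touch-down, lift-off and cycle-end frames coincide with template knots,
#' so the generated trace reproduces the template endpoints exactly.
#'
#' @param template a [kinematics_template()].
#' @param contact_s,swing_s sub-phase durations (s).
#' @param fps frame rate (default 300).
#' @param start_frame frame index of touch down (default 0).
#' @return A [pose_series()] spanning touch down to the next touch down,
#'   with attributes `td_frame`, `lo_frame`, `end_frame`.
#' @export
generate_stride_kinematics <- function(template, contact_s = 1.50,
                                       swing_s = 0.84, fps = 300,
                                       start_frame = 0L) {
  stopifnot(inherits(template, "kinematics_template"))
  nc <- round(contact_s * fps); ns <- round(swing_s * fps)
  if (nc < 2L || ns < 2L)
    stop("each sub-phase needs at least 2 frames", call. = FALSE)
  frames <- 0:(nc + ns)
  keys <- unique(template[, c("segment", "dof")])
  segs <- unique(keys$segment)
  mats <- lapply(segs, function(sg) {
    m <- matrix(0, length(frames), 6,
                dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
    for (d in keys$dof[keys$segment == sg]) {
      kn <- template[template$segment == sg & template$dof == d, ]
      m[, d] <- .template_fun(kn, nc, ns)(frames)
    }
    m
  })
  names(mats) <- segs
  out <- .ps_from_matrices(mats, frames + start_frame, fps)
  attr(out, "td_frame") <- start_frame
  attr(out, "lo_frame") <- start_frame + nc
  attr(out, "end_frame") <- start_frame + nc + ns
  out
}

.rtrunc_norm <- function(n, mean, sd, lower = mean - 3 * sd,
                         upper = mean + 3 * sd) {
  lower <- max(lower, 1e-6)
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lower | out > upper
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lower | out > upper
  }
  out
}

#' Generate a synthetic locomotion trial
#'
#' Draws per-stride gait parameters (contact and swing durations, stride
#' length) from truncated normal distributions at the published pooled
#' means and standard deviations, the stride symmetry uniformly inside the
#' inclusion band, evaluates the kinematics template stride by stride, and
#' adds seeded per-frame digitization noise. Fully reproducible under
#' `seed`.
#'
#' @param template a [kinematics_template()].
#' @param n_strides number of stride cycles (default 20, the pooled count).
#' @param fps frame rate (default 300).
#' @param gait named list of gait-parameter distributions with elements
#'   `contact_s`, `swing_s`, `stride_length_cm`, each `c(mean, sd)`;
#'   defaults to the published pooled values.
#' @param symmetry_band band the symmetry draws come from.
#' @param noise_sd named per-DOF noise s.d. (`tx`, `ty`, `tz` in cm; `rx`,
#'   `ry`, `rz` in deg); defaults to [repeatability_reference()]. Use 0 for
#'   noiseless trials.
#' @param seed integer seed fixing all randomness, or `NULL`.
#' @return List with `series` (the concatenated [pose_series()]), `events`
#'   (a [gait_events()] table for limbs `left_fore` and `right_fore`) and
#'   `params` (per-stride data.frame: durations, stride length, speed,
#'   symmetry).
#' @export
generate_trial <- function(template, n_strides = 20L, fps = 300,
                           gait = list(contact_s = c(1.50, 0.2),
                                       swing_s = c(0.84, 0.2),
                                       stride_length_cm = c(58.9, 5.0)),
                           symmetry_band = c(0.4, 0.6),
                           noise_sd = repeatability_reference(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  contact <- .rtrunc_norm(n_strides, gait$contact_s[1], gait$contact_s[2])
  swing <- .rtrunc_norm(n_strides, gait$swing_s[1], gait$swing_s[2])
  slen <- .rtrunc_norm(n_strides, gait$stride_length_cm[1],
                       gait$stride_length_cm[2])
  sym <- stats::runif(n_strides, symmetry_band[1], symmetry_band[2])
  pieces <- vector("list", n_strides)
  start <- 0L
  td <- integer(0); lo <- integer(0); td_c <- integer(0)
  for (k in seq_len(n_strides)) {
    st <- generate_stride_kinematics(template, contact[k], swing[k], fps,
                                     start_frame = start)
    td <- c(td, attr(st, "td_frame"))
    lo <- c(lo, attr(st, "lo_frame"))
    n_k <- attr(st, "end_frame") - attr(st, "td_frame")
    td_c <- c(td_c, start + round(sym[k] * n_k))
    # drop the closing touch-down frame except on the final stride: it is
    # the opening frame of the next stride with identical values
    if (k < n_strides)
      st$data <- st$data[st$data$frame < attr(st, "end_frame"), ]
    pieces[[k]] <- st$data
    start <- start + n_k
  }
  series <- pose_series(do.call(rbind, pieces), fps = fps)
  if (any(noise_sd > 0))
    series <- inject_digitization_noise(series, noise_sd)
  td <- c(td, start)                     # closing touch down
  contact_frames <- round(contact * fps)
  lo_c <- pmin(td_c + contact_frames, c(td_c[-1], start) - 1L)
  ev <- rbind(
    data.frame(limb = "left_fore",
               event = c(rep("touch_down", length(td)),
                         rep("lift_off", length(lo))),
               frame = c(td, lo)),
    data.frame(limb = "right_fore",
               event = c(rep("touch_down", n_strides),
                         rep("lift_off", n_strides)),
               frame = c(td_c, lo_c)))
  events <- gait_events(ev)
  params <- data.frame(stride = seq_len(n_strides), contact_s = contact,
                       swing_s = swing, stride_length_cm = slen,
                       speed_ms = (slen / 100) / (contact + swing),
                       symmetry = sym)
  list(series = series, events = events, params = params)
}

#' Add digitization noise to a pose series
#'
#' Independent Gaussian perturbation per frame and DOF, at the published
#' repeatability magnitudes by default.
#'
#' @param series a [pose_series()].
#' @param sd single value or named per-DOF vector of standard deviations
#'   (`tx`, `ty`, `tz` in cm; `rx`, `ry`, `rz` in degrees).
#' @param seed optional integer seed.
#' @return The perturbed [pose_series()].
#' @export
inject_digitization_noise <- function(series, sd = repeatability_reference(),
                                      seed = NULL) {
  stopifnot(inherits(series, "pose_series"))
  if (!is.null(seed)) set.seed(seed)
  if (length(sd) == 1L) sd <- stats::setNames(rep(sd, 6), .DOF_NAMES)
  if (any(sd < 0) || any(!is.finite(sd)))
    stop("noise sd must be finite and >= 0", call. = FALSE)
  d <- series$data
  for (dof in .DOF_NAMES) {
    s <- sd[[dof]]
    if (s > 0) {
      cl <- paste0(dof, if (substr(dof, 1, 1) == "t") "_cm" else "_deg")
      d[[cl]] <- d[[cl]] + stats::rnorm(nrow(d), 0, s)
    }
  }
  pose_series(d, fps = series$fps)
}

#' Generate a synthetic biplane calibration scene
#'
#' A 20 x 12 x 12 cm bead lattice at 1 cm spacing observed by two
#' synthetic x-ray cameras in the biplane geometry (latero-lateral and
#' dorso-ventral views, 1536 x 1024 px sensors), with optional Gaussian
#' pixel noise on the observations. The ground-truth cameras are returned
#' for oracle tests.
#'
#' @param noise_px s.d. of the observation noise (px).
#' @param seed optional integer seed.
#' @param spacing bead spacing (cm).
#' @return List with `beads` (data.frame `id`, `X_cm`, `Y_cm`, `Z_cm`),
#'   `observations` (data.frame `view`, `id`, `u_px`, `v_px`) and
#'   `cameras` (list of the two ground-truth [dlt_camera()]s).
#' @export
generate_calibration_scene <- function(noise_px = 0, seed = NULL,
                                       spacing = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (noise_px < 0) stop("noise must be >= 0", call. = FALSE)
  g <- expand.grid(X = seq(0, 20, spacing), Y = seq(0, 12, spacing),
                   Z = seq(0, 12, spacing))
  beads <- data.frame(id = seq_len(nrow(g)),
                      X_cm = g$X - 10, Y_cm = g$Y - 6, Z_cm = g$Z - 6)
  f <- 6000; cx <- 768; cy <- 512; d <- 150
  K <- rbind(c(f, 0, cx), c(0, f, cy), c(0, 0, 1))
  mk_cam <- function(R, C, view) {
    P <- K %*% cbind(R, -R %*% C)
    dlt_camera(c(t(P[1:2, ]) / P[3, 4], P[3, 1:3] / P[3, 4]), view = view)
  }
  # latero-lateral: camera on +z axis looking along -z
  R_ll <- rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  # dorso-ventral: camera on +y axis looking along -y
  R_dv <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
  cams <- list(laterolateral = mk_cam(R_ll, c(0, 0, d), "laterolateral"),
               dorsoventral = mk_cam(R_dv, c(0, d, 0), "dorsoventral"))
  world <- as.matrix(beads[, c("X_cm", "Y_cm", "Z_cm")])
  obs <- do.call(rbind, lapply(names(cams), function(v) {
    uv <- dlt_project(cams[[v]], world)
    if (noise_px > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, noise_px), ncol = 2)
    data.frame(view = v, id = beads$id, u_px = uv[, 1], v_px = uv[, 2])
  }))
  list(beads = beads, observations = obs, cameras = cams)
}
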