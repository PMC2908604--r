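## Virtual experiments: hold selected DOFs of selected segments at their
## touch-down state, recompute the elbow trajectory relative to the 1st
## thoracic vertebra, and summarize the displacing effect of the muted
## motion. Muting from touch down guarantees that the initial elbow
## position is identical across all conditions.

.DOF_NAMES <- c("tx", "ty", "tz", "rx", "ry", "rz")

#' Mute degrees of freedom of a pose series
#'
#' From the touch-down frame onward the selected DOFs of the target segment
#' hold their touch-down value; other DOFs, other segments and frames
#' before touch down are untouched. Muting is idempotent, and muting a DOF
#' that is constant at its touch-down value is a no-op.
#'
#' @param series a [pose_series()].
#' @param segment target segment name.
#' @param dofs character vector of DOF names among `tx, ty, tz, rx, ry, rz`,
#'   or `"all"`.
#' @param td_frame touch-down frame (default: first frame of the series).
#' @return The muted [pose_series()].
#' @export
apply_muting <- function(series, segment, dofs = "all", td_frame = NULL) {
  stopifnot(inherits(series, "pose_series"))
  if (!segment %in% unique(series$data$segment))
    stop("series does not contain segment: ", segment, call. = FALSE)
  if (identical(dofs, "all")) dofs <- .DOF_NAMES
  bad <- setdiff(dofs, .DOF_NAMES)
  if (length(bad)) stop("unknown DOF name: ", bad[1], call. = FALSE)
  if (!length(dofs)) stop("empty DOF subset", call. = FALSE)
  if (is.null(td_frame)) td_frame <- min(series$data$frame)
  cols <- paste0(dofs, ifelse(substr(dofs, 1, 1) == "t", "_cm", "_deg"))
  d <- series$data
  sel <- d$segment == segment & d$frame >= td_frame
  at_td <- d$segment == segment & d$frame == td_frame
  if (!any(at_td)) stop("touch-down frame not in series", call. = FALSE)
  for (cl in cols) d[sel, cl] <- d[at_td, cl]
  pose_series(d, fps = series$fps)
}

#' Canonical muting conditions
#'
#' The six experimental conditions of the displacing-effect analysis:
#' unmuted locomotion, total humeral muting, total scapular muting, and
#' single-DOF muting of scapular abduction/adduction (y), scapular
#' long-axis rotation (x) and humeral abduction/adduction (y).
#'
#' @return Named list; each element is a list of mute specs
#'   (`segment`, `dofs`), empty for the `normal` condition.
#' @export
muting_conditions <- function() {
  list(
    normal = list(),
    no_humeral_motion = list(list(segment = "humerus", dofs = "all")),
    no_scapular_motion = list(list(segment = "scapula", dofs = "all")),
    no_scapular_abduction_adduction =
      list(list(segment = "scapula", dofs = "ry")),
    no_scapular_long_axis_rotation =
      list(list(segment = "scapula", dofs = "rx")),
    no_humeral_abduction_adduction =
      list(list(segment = "humerus", dofs = "ry"))
  )
}

# reported anatomical axes of the elbow trajectory in the T1 frame
.AXIS_MAP <- c(medio_lateral = "z", cranio_caudal = "x", dorso_ventral = "y")

#' Run one virtual experiment condition
#'
#' Applies the condition's mute specs from touch down, computes the elbow
#' trajectory relative to the 1st thoracic vertebra, and summarizes the
#' per-axis displacement. Reported axes map onto the T1 frame as
#' cranio-caudal = x, dorso-ventral = y, medio-lateral = z.
#'
#' @param model a `marionette` with an `elbow` landmark.
#' @param series a [pose_series()] (typically the pooled mean stride).
#' @param condition name from [muting_conditions()], or a list of mute
#'   specs of the same shape.
#' @param tfl total forelimb length (cm) normalizing the amplitudes.
#' @param td_frame touch-down frame (default first frame).
#' @param landmark,reference landmark and reference segment names.
#' @return data.frame, class `displacement_summary`: one row per axis with
#'   `axis`, `max_cm`, `min_cm`, `amplitude_cm`, `percent_tfl` (amplitude
#'   as % of `tfl`, computed on unrounded values).
#' @export
run_condition <- function(model, series, condition = "normal", tfl,
                          td_frame = NULL, landmark = "elbow",
                          reference = "thoracic_vertebra_1") {
  stopifnot(inherits(model, "marionette"), inherits(series, "pose_series"))
  if (!is.numeric(tfl) || tfl <= 0) stop("tfl must be positive", call. = FALSE)
  specs <- if (is.character(condition)) {
    conds <- muting_conditions()
    if (!condition %in% names(conds))
      stop("unknown condition: ", condition, call. = FALSE)
    conds[[condition]]
  } else condition
  muted <- series
  for (sp in specs)
    muted <- apply_muting(muted, sp$segment, sp$dofs, td_frame = td_frame)
  traj <- landmark_trajectory(model, muted, landmark, reference)
  out <- data.frame(
    axis = names(.AXIS_MAP),
    max_cm = vapply(.AXIS_MAP, function(ax) max(traj[, ax]), numeric(1)),
    min_cm = vapply(.AXIS_MAP, function(ax) min(traj[, ax]), numeric(1)),
    row.names = NULL)
  out$amplitude_cm <- out$max_cm - out$min_cm
  out$percent_tfl <- 100 * out$amplitude_cm / tfl
  class(out) <- c("displacement_summary", "data.frame")
  attr(out, "trajectory") <- traj
  out
}

#' Run the full virtual-experiment suite
#'
#' Evaluates every canonical condition on the same series; the `normal`
#' row equals the unmuted pipeline's summary exactly.
#'
#' @inheritParams run_condition
#' @return data.frame with columns `condition`, `axis`, `max_cm`, `min_cm`,
#'   `amplitude_cm`, `percent_tfl`.
#' @export
run_experiment_suite <- function(model, series, tfl, td_frame = NULL,
                                 landmark = "elbow",
                                 reference = "thoracic_vertebra_1") {
  conds <- muting_conditions()
  do.call(rbind, lapply(names(conds), function(nm) {
    s <- run_condition(model, series, nm, tfl, td_frame = td_frame,
                       landmark = landmark, reference = reference)
    attr(s, "trajectory") <- NULL
    cbind(condition = nm, as.data.frame(s))
  }))
}
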