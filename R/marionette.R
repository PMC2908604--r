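## The digital marionette: a tree of skeletal elements, each posed relative
## to its parent, with anatomical frames at the centre of rotation of the
## proximally adjacent joint. Forward kinematics walks the unique root path.

#' Segment specification
#'
#' One skeletal element of the marionette. The segment's frame origin sits
#' at the centre of rotation of the proximally adjacent joint, expressed as
#' a constant offset in the parent frame at the zero pose. Landmarks are
#' named points in segment-local coordinates (cm).
#'
#' @param name segment name (e.g. `"scapula"`).
#' @param parent parent segment name, or `NA` for the root.
#' @param origin length-3 offset of the frame origin in the parent frame (cm).
#' @param length segment length along its long axis (cm), or `NA`.
#' @param landmarks named list of length-3 numeric vectors (segment-local cm).
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(name, parent = NA_character_, origin = c(0, 0, 0),
                         length = NA_real_, landmarks = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 vector", call. = FALSE)
  if (!is.na(length) && length <= 0)
    stop("segment length must be positive", call. = FALSE)
  if (length(landmarks) && is.null(names(landmarks)))
    stop("landmarks must be named", call. = FALSE)
  structure(list(name = name, parent = as.character(parent),
                 origin = as.numeric(origin), length = as.numeric(length),
                 landmarks = lapply(landmarks, as.numeric)),
            class = "segment_spec")
}

#' Build a marionette model
#'
#' Validates a collection of [segment_spec()]s into a hierarchy: exactly one
#' root, every parent present, no cycles. Hierarchy ranks (root = 0) are
#' derived from the tree. An isotropic scale factor rescales every origin
#' offset, length and landmark, mirroring the scaling of a template skeleton
#' to the size of a study animal.
#'
#' @param specs list of [segment_spec()] objects.
#' @param scale single positive isotropic scale factor applied to all
#'   lengths, origins and landmarks.
#' @return An object of class `marionette`.
#' @export
build_marionette <- function(specs, scale = 1) {
  if (!length(specs)) stop("no segments supplied", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a single positive number", call. = FALSE)
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate segment name: ", nms[duplicated(nms)][1], call. = FALSE)
  names(specs) <- nms
  parents <- vapply(specs, function(s) s$parent, character(1))
  roots <- nms[is.na(parents)]
  if (length(roots) != 1L)
    stop("model must have exactly one root segment", call. = FALSE)
  missing <- setdiff(parents[!is.na(parents)], nms)
  if (length(missing))
    stop("missing parent segment: ", missing[1], call. = FALSE)
  # rank = depth from root; a segment never reached sits on a cycle
  rank <- stats::setNames(rep(NA_integer_, length(nms)), nms)
  rank[roots] <- 0L
  repeat {
    placed <- !is.na(rank[parents]) & is.na(rank[nms])
    if (!any(placed)) break
    rank[nms[placed]] <- rank[parents[placed]] + 1L
  }
  if (anyNA(rank))
    stop("cycle involving segment: ", nms[is.na(rank)][1], call. = FALSE)
  if (scale != 1) {
    specs <- lapply(specs, function(s) {
      s$origin <- s$origin * scale
      s$length <- s$length * scale
      s$landmarks <- lapply(s$landmarks, `*`, scale)
      s
    })
  }
  structure(list(segments = specs, root = roots, rank = rank, scale = scale),
            class = "marionette")
}

#' @export
print.marionette <- function(x, ...) {
  cat("marionette model:", length(x$segments), "segments, root =", x$root, "\n")
  for (nm in names(x$segments)[order(x$rank)]) {
    s <- x$segments[[nm]]
    cat(sprintf("  %s%s (rank %d%s%s)\n", strrep("  ", x$rank[nm]), nm,
                x$rank[nm],
                if (is.na(s$parent)) "" else paste0(", parent ", s$parent),
                if (is.na(s$length)) "" else sprintf(", length %.1f cm", s$length)))
  }
  invisible(x)
}

#' Default sloth pectoral-girdle marionette
#'
#' The canonical five-segment hierarchy used for the suspensory-locomotion
#' analysis: global -> 1st thoracic vertebra -> \{scapula -> humerus,
#' clavicle\}. Segment lengths default to the female study animal (scapula
#' 8.2, humerus 15.9 cm); in-bone joint-centre and landmark offsets are
#' synthetic fixture conventions (the source anatomy pins only which border
#' of each bone carries the joint, not numeric offsets): the glenoid sits at
#' `scapula_length` along the scapular local +y axis from the scapular
#' centre of rotation at the vertebral border, and the elbow landmark at
#' `humerus_length` along the humeral local +x (long) axis from the
#' gleno-humeral centre.
#'
#' @param scapula_length,humerus_length segment lengths (cm).
#' @param clavicle_length clavicle length (cm).
#' @param scale isotropic scale factor, see [build_marionette()].
#' @return A `marionette` with segments `global`, `thoracic_vertebra_1`,
#'   `scapula` (landmark `glenoid`), `humerus` (landmark `elbow`) and
#'   `clavicle` (landmark `acromial_end`).
#' @export
sloth_marionette <- function(scapula_length = 8.2, humerus_length = 15.9,
                             clavicle_length = 4.6, scale = 1) {
  specs <- list(
    segment_spec("global"),
    segment_spec("thoracic_vertebra_1", "global"),
    segment_spec("scapula", "thoracic_vertebra_1", origin = c(-1, 2, 3),
                 length = scapula_length,
                 landmarks = list(glenoid = c(0, scapula_length, 0))),
    segment_spec("humerus", "scapula", origin = c(0, scapula_length, 0),
                 length = humerus_length,
                 landmarks = list(elbow = c(humerus_length, 0, 0))),
    segment_spec("clavicle", "thoracic_vertebra_1", origin = c(2, -3, 0.5),
                 length = clavicle_length,
                 landmarks = list(acromial_end = c(clavicle_length, 0, 0)))
  )
  build_marionette(specs, scale = scale)
}

.root_path <- function(model, segment) {
  path <- character(0)
  nm <- segment
  while (!is.na(nm)) {
    path <- c(nm, path)
    nm <- model$segments[[nm]]$parent
  }
  path
}

.local_transform <- function(model, segment, pose) {
  s <- model$segments[[segment]]
  T <- pose_transform(pose)
  T$t <- T$t + s$origin
  T
}

#' Forward kinematics at one instant
#'
#' Composes each segment's pose down its unique root path, yielding the
#' world (global-frame) rigid transform of every segment. The root takes the
#' identity; every non-root segment must have a pose.
#'
#' @param model a `marionette`.
#' @param poses named list mapping each non-root segment to a [pose6dof()]
#'   vector (pose relative to its parent frame).
#' @return Named list of `rigid_transform`s, one per segment.
#' @export
forward_kinematics <- function(model, poses) {
  stopifnot(inherits(model, "marionette"))
  nonroot <- setdiff(names(model$segments), model$root)
  absent <- setdiff(nonroot, names(poses))
  if (length(absent))
    stop("missing pose for segment: ", absent[1], call. = FALSE)
  world <- list()
  world[[model$root]] <- rigid_transform()
  for (nm in names(model$segments)[order(model$rank)]) {
    if (nm == model$root) next
    parent <- model$segments[[nm]]$parent
    world[[nm]] <- compose(world[[parent]], .local_transform(model, nm, poses[[nm]]))
  }
  world
}

#' Landmark trajectory relative to a reference segment
#'
#' Evaluates forward kinematics at every frame of a pose series and
#' expresses a landmark's position in the frame of a chosen reference
#' segment: `invert(world(reference)) o world(segment) applied to the
#' landmark`. This is how the elbow displacement relative to the 1st
#' thoracic vertebra is obtained.
#'
#' @param model a `marionette`.
#' @param series a [pose_series()].
#' @param landmark landmark name.
#' @param reference reference segment name.
#' @param segment segment carrying the landmark; if `NULL` it is looked up
#'   by landmark name across all segments.
#' @return n x 3 matrix of positions (cm) in the reference frame, columns
#'   `x`, `y`, `z`, one row per frame.
#' @export
landmark_trajectory <- function(model, series, landmark, reference,
                                segment = NULL) {
  stopifnot(inherits(model, "marionette"), inherits(series, "pose_series"))
  if (is.null(segment)) {
    hits <- names(model$segments)[vapply(model$segments,
      function(s) landmark %in% names(s$landmarks), logical(1))]
    if (!length(hits)) stop("unknown landmark: ", landmark, call. = FALSE)
    segment <- hits[1]
  }
  if (!segment %in% names(model$segments))
    stop("unknown segment: ", segment, call. = FALSE)
  if (!landmark %in% names(model$segments[[segment]]$landmarks))
    stop("landmark ", landmark, " not on segment ", segment, call. = FALSE)
  if (!reference %in% names(model$segments))
    stop("unknown reference segment: ", reference, call. = FALSE)
  p_local <- model$segments[[segment]]$landmarks[[landmark]]
  frames <- sort(unique(series$data$frame))
  mats <- ps_segment_matrices(series)
  # only segments on the two root paths matter
  needed <- union(.root_path(model, segment), .root_path(model, reference))
  needed <- setdiff(needed, model$root)
  out <- matrix(NA_real_, length(frames), 3,
                dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_along(frames)) {
    # segments absent from the series sit at the zero pose
    poses <- lapply(stats::setNames(needed, needed), function(nm)
      if (nm %in% names(mats)) mats[[nm]][i, ] else pose6dof())
    Tseg <- rigid_transform()
    for (nm in .root_path(model, segment)[-1])
      Tseg <- compose(Tseg, .local_transform(model, nm, poses[[nm]]))
    Tref <- rigid_transform()
    for (nm in .root_path(model, reference)[-1])
      Tref <- compose(Tref, .local_transform(model, nm, poses[[nm]]))
    out[i, ] <- transform_points(compose(invert(Tref), Tseg), p_local)
  }
  out
}
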