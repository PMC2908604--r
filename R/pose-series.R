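## Pose series: per-frame six-DOF poses of every segment, the long-format
## table that digitized trials arrive in (one row per frame per segment).

.POSE_COLS <- c("tx_cm", "ty_cm", "tz_cm", "rx_deg", "ry_deg", "rz_deg")
.EULER_CONVENTION <- "intrinsic xyz (Rz*Ry*Rx on column vectors), degrees"

#' Construct a pose series
#'
#' @param data data.frame with columns `frame`, `segment`, `tx_cm`, `ty_cm`,
#'   `tz_cm`, `rx_deg`, `ry_deg`, `rz_deg`. Every segment must be present at
#'   every frame.
#' @param fps frame rate (frames per second, default 300).
#' @return An object of class `pose_series` with elements `data` and `fps`.
#' @export
pose_series <- function(data, fps = 300) {
  need <- c("frame", "segment", .POSE_COLS)
  absent <- setdiff(need, names(data))
  if (length(absent))
    stop("pose series is missing column: ", absent[1], call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  vals <- as.matrix(data[, .POSE_COLS])
  if (any(!is.finite(vals)))
    stop("pose values must be finite", call. = FALSE)
  counts <- table(data$segment)
  if (length(unique(counts)) != 1L)
    stop("all segments must share the same frame index", call. = FALSE)
  data <- data[order(data$segment, data$frame), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, fps = fps), class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  fr <- unique(x$data$frame)
  cat(sprintf("pose series: %d segments x %d frames at %g fps\n",
              length(unique(x$data$segment)), length(fr), x$fps))
  cat("  segments:", paste(unique(x$data$segment), collapse = ", "), "\n")
  invisible(x)
}

#' Per-segment pose matrices
#'
#' @param series a [pose_series()].
#' @return Named list, one n-frame x 6 matrix per segment (columns tx..rz,
#'   cm and degrees), rows ordered by frame.
#' @export
ps_segment_matrices <- function(series) {
  stopifnot(inherits(series, "pose_series"))
  segs <- unique(series$data$segment)
  out <- lapply(segs, function(sg) {
    d <- series$data[series$data$segment == sg, , drop = FALSE]
    m <- as.matrix(d[order(d$frame), .POSE_COLS])
    colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    rownames(m) <- NULL
    m
  })
  stats::setNames(out, segs)
}

#' Frames of a pose series
#'
#' @param series a [pose_series()].
#' @return Sorted unique frame indices.
#' @export
ps_frames <- function(series) sort(unique(series$data$frame))

.ps_from_matrices <- function(mats, frames, fps) {
  data <- do.call(rbind, lapply(names(mats), function(sg) {
    d <- data.frame(frame = frames, segment = sg)
    m <- mats[[sg]]
    colnames(m) <- .POSE_COLS
    cbind(d, as.data.frame(m))
  }))
  pose_series(data, fps = fps)
}

#' Write a pose series to CSV
#'
#' The file carries a header comment recording the Euler convention so data
#' and convention travel together.
#'
#' @param series a [pose_series()].
#' @param path output file path.
#' @export
write_pose_series <- function(series, path) {
  stopifnot(inherits(series, "pose_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# euler_convention: %s", .EULER_CONVENTION), con)
  writeLines(sprintf("# fps: %g", series$fps), con)
  utils::write.csv(series$data, con, row.names = FALSE)
  invisible(path)
}

#' Read a pose series from CSV
#'
#' @param path file written by [write_pose_series()] (header comment lines
#'   starting with `#` are skipped; an `# fps:` line is honoured).
#' @param fps frame rate; overrides any value recorded in the file.
#' @return A [pose_series()].
#' @export
read_pose_series <- function(path, fps = NULL) {
  head <- readLines(path, n = 10)
  fps_line <- grep("^# fps:", head, value = TRUE)
  if (is.null(fps))
    fps <- if (length(fps_line)) as.numeric(sub("^# fps:", "", fps_line[1])) else 300
  data <- utils::read.csv(path, comment.char = "#")
  pose_series(data, fps = fps)
}

#' Write a marionette model to JSON
#'
#' @param model a `marionette`.
#' @param path output file path.
#' @export
write_marionette <- function(model, path) {
  stopifnot(inherits(model, "marionette"))
  segs <- lapply(model$segments, function(s)
    list(parent = if (is.na(s$parent)) NULL else s$parent,
         origin = s$origin, length = if (is.na(s$length)) NULL else s$length,
         landmarks = s$landmarks))
  jsonlite::write_json(list(scale = model$scale, segments = segs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a marionette model from JSON
#'
#' @param path file written by [write_marionette()].
#' @return A `marionette`.
#' @export
read_marionette <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scalar_or <- function(x, default) {  # absent fields arrive as empty lists
    if (is.null(x) || length(x) == 0) default else x
  }
  specs <- lapply(names(j$segments), function(nm) {
    s <- j$segments[[nm]]
    segment_spec(nm,
                 parent = scalar_or(s$parent, NA_character_),
                 origin = as.numeric(s$origin),
                 length = scalar_or(s$length, NA_real_),
                 landmarks = lapply(as.list(s$landmarks), as.numeric))
  })
  # stored geometry is already scaled; record the factor without reapplying
  model <- build_marionette(specs, scale = 1)
  model$scale <- if (is.null(j$scale)) 1 else j$scale
  model
}
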