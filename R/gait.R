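## Stride segmentation, inclusion filters, 50+50-point time normalization,
## pooling into mean +- s.d. curves, endpoint summaries and the
## between-individual comparison used to justify pooling.

#' Gait event table
#'
#' Validated per-limb touch-down / lift-off annotations.
#'
#' @param events data.frame with columns `limb`, `event`
#'   (`"touch_down"` or `"lift_off"`) and `frame`. Within each limb the
#'   events must strictly increase in frame and alternate, starting with a
#'   touch down.
#' @return The validated data.frame, class `gait_events`.
#' @export
gait_events <- function(events) {
  need <- c("limb", "event", "frame")
  absent <- setdiff(need, names(events))
  if (length(absent)) stop("events missing column: ", absent[1], call. = FALSE)
  if (!all(events$event %in% c("touch_down", "lift_off")))
    stop("event must be touch_down or lift_off", call. = FALSE)
  for (lb in unique(events$limb)) {
    e <- events[events$limb == lb, , drop = FALSE]
    e <- e[order(e$frame), , drop = FALSE]
    if (any(diff(e$frame) <= 0))
      stop("events for limb ", lb, " must strictly increase", call. = FALSE)
    expect <- rep(c("touch_down", "lift_off"), length.out = nrow(e))
    if (!identical(e$event, expect))
      stop("events for limb ", lb,
           " must alternate touch_down/lift_off starting with touch_down",
           call. = FALSE)
  }
  events <- events[order(events$limb, events$frame), , drop = FALSE]
  rownames(events) <- NULL
  class(events) <- c("gait_events", "data.frame")
  events
}

#' Segment a pose series into stride cycles
#'
#' Cuts the series at consecutive touch downs of the reference limb. Within
#' each stride every translation DOF of every segment is re-zeroed at the
#' instant of touch down (rotations are untouched). Stride speed is
#' computed as stride length over total cycle duration; symmetry as the
#' elapsed fraction of the cycle at which the contralateral limb touches
#' down.
#'
#' @param series a [pose_series()].
#' @param events a [gait_events()] table.
#' @param limb reference limb (default the first in `events`).
#' @param contralateral name of the contralateral limb for the symmetry
#'   statistic, or `NULL` (symmetry `NA`).
#' @param stride_lengths numeric vector of stride lengths (cm), one per
#'   stride (recycled if length 1), or `NULL` (speed `NA`).
#' @return List of `stride_cycle` objects. Each carries `series` (the
#'   re-zeroed slice), `td_frame`, `lo_frame`, `end_frame`,
#'   `contact_s`, `swing_s`, `stride_length_cm`, `speed_ms`, `symmetry`.
#' @export
segment_strides <- function(series, events, limb = NULL,
                            contralateral = NULL, stride_lengths = NULL) {
  stopifnot(inherits(series, "pose_series"))
  events <- gait_events(as.data.frame(events))
  if (is.null(limb)) limb <- events$limb[1]
  e <- events[events$limb == limb, , drop = FALSE]
  td <- e$frame[e$event == "touch_down"]
  lo <- e$frame[e$event == "lift_off"]
  frames <- ps_frames(series)
  if (any(e$frame < min(frames)) || any(e$frame > max(frames)))
    stop("events outside the series frame range", call. = FALSE)
  n_strides <- length(td) - 1L
  if (n_strides < 1L) stop("need at least two touch downs", call. = FALSE)
  ctd <- if (!is.null(contralateral))
    events$frame[events$limb == contralateral & events$event == "touch_down"]
  else numeric(0)
  if (!is.null(stride_lengths))
    stride_lengths <- rep_len(stride_lengths, n_strides)
  fps <- series$fps
  out <- vector("list", n_strides)
  for (k in seq_len(n_strides)) {
    f0 <- td[k]; f1 <- td[k + 1]
    lok <- lo[lo > f0 & lo < f1]
    if (length(lok) != 1L)
      stop("stride ", k, " must contain exactly one lift off", call. = FALSE)
    keep <- series$data$frame >= f0 & series$data$frame <= f1
    d <- series$data[keep, , drop = FALSE]
    # zero translations at touch down, per segment
    for (sg in unique(d$segment)) {
      at_td <- d$segment == sg & d$frame == f0
      for (cl in c("tx_cm", "ty_cm", "tz_cm"))
        d[d$segment == sg, cl] <- d[d$segment == sg, cl] - d[at_td, cl]
    }
    slice <- pose_series(d, fps = fps)
    contact_s <- (lok - f0) / fps
    swing_s <- (f1 - lok) / fps
    sl <- if (is.null(stride_lengths)) NA_real_ else stride_lengths[k]
    sym <- NA_real_
    if (length(ctd)) {
      hit <- ctd[ctd >= f0 & ctd < f1]
      if (length(hit)) sym <- (hit[1] - f0) / (f1 - f0)
    }
    out[[k]] <- structure(list(
      series = slice, td_frame = f0, lo_frame = lok, end_frame = f1,
      contact_s = contact_s, swing_s = swing_s,
      stride_length_cm = sl,
      speed_ms = if (is.na(sl)) NA_real_ else (sl / 100) / (contact_s + swing_s),
      symmetry = sym), class = "stride_cycle")
  }
  out
}

#' @export
print.stride_cycle <- function(x, ...) {
  cat(sprintf(paste0("stride cycle: frames %d-%d (lift off %d), contact %.3f s,",
                     " swing %.3f s, speed %s m/s, symmetry %s\n"),
              x$td_frame, x$end_frame, x$lo_frame, x$contact_s, x$swing_s,
              format(x$speed_ms, digits = 3), format(x$symmetry, digits = 3)))
  invisible(x)
}

#' Apply the stride inclusion filters
#'
#' A stride is kept iff its speed and its symmetry both lie inside the
#' closed bands; every rejection is logged with its reason.
#'
#' @param cycles list of stride cycles from [segment_strides()].
#' @param speed_band closed speed band in m/s (default `c(0.2, 0.3)`).
#' @param symmetry_band closed symmetry band (default `c(0.4, 0.6)`).
#' @return List with `kept` (stride cycles) and `rejections` (data.frame
#'   `stride`, `reason`, `value`).
#' @export
filter_strides <- function(cycles, speed_band = c(0.2, 0.3),
                           symmetry_band = c(0.4, 0.6)) {
  keep <- logical(length(cycles))
  rej <- list()
  for (k in seq_along(cycles)) {
    cy <- cycles[[k]]
    reasons <- character(0); values <- numeric(0)
    if (!is.na(cy$speed_ms) &&
        (cy$speed_ms < speed_band[1] || cy$speed_ms > speed_band[2])) {
      reasons <- c(reasons, "speed"); values <- c(values, cy$speed_ms)
    }
    if (!is.na(cy$symmetry) &&
        (cy$symmetry < symmetry_band[1] || cy$symmetry > symmetry_band[2])) {
      reasons <- c(reasons, "symmetry"); values <- c(values, cy$symmetry)
    }
    if (length(reasons)) {
      rej[[length(rej) + 1L]] <- data.frame(stride = k, reason = reasons,
                                            value = values)
    } else keep[k] <- TRUE
  }
  rejections <- if (length(rej)) do.call(rbind, rej)
    else data.frame(stride = integer(0), reason = character(0),
                    value = numeric(0))
  list(kept = cycles[keep], rejections = rejections)
}

.stride_variables <- function(cycle) {
  mats <- ps_segment_matrices(cycle$series)
  vars <- list()
  for (sg in names(mats))
    for (cl in colnames(mats[[sg]]))
      vars[[paste(sg, cl, sep = ".")]] <- mats[[sg]][, cl]
  vars
}

#' Time-normalize one stride cycle
#'
#' Interpolates every DOF of every segment onto 50 evenly spaced phase
#' points over the contact phase and 50 over the swing phase (100 samples
#' total). Sample 1 is touch down, sample 50 lift off and sample 100 the
#' next touch down; these endpoint values are preserved exactly. Interior
#' gaps in a sub-phase are bridged by the linear interpolation; each
#' sub-phase needs at least 2 samples.
#'
#' @param cycle a `stride_cycle`.
#' @param n_contact,n_swing samples per sub-phase (defaults 50 + 50).
#' @return 100 x V numeric matrix (V = 6 DOF per segment), columns named
#'   `segment.dof`, with attributes `contact_samples` and `phase`.
#' @export
time_normalize <- function(cycle, n_contact = 50L, n_swing = 50L) {
  stopifnot(inherits(cycle, "stride_cycle"))
  frames <- ps_frames(cycle$series)
  in_contact <- frames >= cycle$td_frame & frames <= cycle$lo_frame
  in_swing <- frames >= cycle$lo_frame & frames <= cycle$end_frame
  if (sum(in_contact) < 2L || sum(in_swing) < 2L)
    stop("each sub-phase needs at least 2 samples", call. = FALSE)
  tc <- seq(cycle$td_frame, cycle$lo_frame, length.out = n_contact)
  tw <- seq(cycle$lo_frame, cycle$end_frame, length.out = n_swing + 1L)[-1]
  vars <- .stride_variables(cycle)
  out <- vapply(vars, function(v) {
    c(stats::approx(frames[in_contact], v[in_contact], xout = tc)$y,
      stats::approx(frames[in_swing], v[in_swing], xout = tw)$y)
  }, numeric(n_contact + n_swing))
  attr(out, "contact_samples") <- n_contact
  attr(out, "phase") <- c(seq(0, 1, length.out = n_contact) * cycle$contact_s /
                            (cycle$contact_s + cycle$swing_s),
                          cycle$contact_s / (cycle$contact_s + cycle$swing_s) +
                            seq_len(n_swing) / n_swing *
                            cycle$swing_s / (cycle$contact_s + cycle$swing_s))
  out
}

#' Pool normalized strides into mean and s.d. curves
#'
#' Pointwise sample mean and (n-1) standard deviation across trials for
#' every variable.
#'
#' @param traces list of matrices from [time_normalize()] (same dimensions
#'   and column names).
#' @return Object of class `curve_set`: `mean` and `sd` (100 x V matrices),
#'   `n`, `trials` (trials x 100 x V array), `contact_samples`.
#' @export
pool_strides <- function(traces) {
  if (length(traces) < 2L) stop("pooling needs at least 2 trials", call. = FALSE)
  dims <- lapply(traces, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("trace dimensions differ across trials", call. = FALSE)
  cols <- colnames(traces[[1]])
  arr <- array(NA_real_, c(length(traces), nrow(traces[[1]]), ncol(traces[[1]])),
               dimnames = list(NULL, NULL, cols))
  for (k in seq_along(traces)) arr[k, , ] <- traces[[k]]
  structure(list(
    mean = apply(arr, c(2, 3), mean),
    sd = apply(arr, c(2, 3), stats::sd),
    n = length(traces), trials = arr,
    contact_samples = attr(traces[[1]], "contact_samples") %||% 50L),
    class = "curve_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("pooled curve set: %d trials, %d samples, %d variables\n",
              x$n, nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' Endpoint summary of pooled curves
#'
#' For every variable: the touch-down and lift-off values (mean +- s.d.
#' across trials read at phase samples 1 and `contact_samples`), the
#' contact amplitude `|lift off - touch down|` of the means, and the
#' maximal amplitude `max - min` of the mean trace over the whole cycle.
#'
#' @param curves a `curve_set` from [pool_strides()].
#' @return data.frame with columns `variable`, `td_mean`, `td_sd`,
#'   `lo_mean`, `lo_sd`, `contact_amplitude`, `max_amplitude`.
#' @export
endpoint_summary <- function(curves) {
  stopifnot(inherits(curves, "curve_set"))
  cs <- curves$contact_samples
  td <- curves$mean[1L, ]; lo <- curves$mean[cs, ]
  data.frame(
    variable = colnames(curves$mean),
    td_mean = unname(td),
    td_sd = unname(apply(curves$trials[, 1L, , drop = FALSE], 3, stats::sd)),
    lo_mean = unname(lo),
    lo_sd = unname(apply(curves$trials[, cs, , drop = FALSE], 3, stats::sd)),
    contact_amplitude = unname(abs(lo - td)),
    max_amplitude = unname(apply(curves$mean, 2, max) -
                             apply(curves$mean, 2, min)),
    row.names = NULL)
}

#' Compare a gait parameter between two individuals
#'
#' Classic equal-variance two-sample Student's t-test, as used to decide
#' whether stride cycles of the two study animals may be pooled. When both
#' groups are constant with equal values the comparison is vacuous and
#' `p = 1` by convention; constant groups with unequal means are rejected.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return List with `t`, `df` and two-tailed `p`.
#' @export
compare_individuals <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    stop("degenerate comparison: zero variance with unequal means",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Repeatability summary of repeated digitizations
#'
#' Per-DOF mean and sample standard deviation of repeated digitizations of
#' one frame (e.g. the scapular lift-off pose re-digitized on ten
#' consecutive days), with values reported rounded to the closest tenth of
#' a centimetre and degree — the reporting precision the repeatability
#' figures justify.
#'
#' @param poses data.frame or matrix with one row per repeat and the six
#'   DOF columns `tx`, `ty`, `tz`, `rx`, `ry`, `rz` (any consistent naming
#'   containing these stems).
#' @param digits rounding applied to the reported values (default 1).
#' @return data.frame `dof`, `mean`, `sd` (rounded), plus unrounded
#'   `mean_raw`, `sd_raw`.
#' @export
repeatability_summary <- function(poses, digits = 1) {
  poses <- as.data.frame(poses)
  if (nrow(poses) < 2L) stop("repeatability needs n >= 2 repeats", call. = FALSE)
  dofs <- c("tx", "ty", "tz", "rx", "ry", "rz")
  cols <- vapply(dofs, function(d) {
    hit <- grep(paste0("^", d), names(poses), value = TRUE)
    if (!length(hit)) NA_character_ else hit[1]
  }, character(1))
  if (anyNA(cols))
    stop("missing DOF column: ", dofs[is.na(cols)][1], call. = FALSE)
  m <- vapply(cols, function(cl) mean(poses[[cl]]), numeric(1))
  s <- vapply(cols, function(cl) stats::sd(poses[[cl]]), numeric(1))
  data.frame(dof = dofs, mean = round(m, digits), sd = round(s, digits),
             mean_raw = unname(m), sd_raw = unname(s), row.names = NULL)
}
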