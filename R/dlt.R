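## 11-parameter direct linear transformation (DLT) for biplane x-ray
## calibration: the rational model
##   u = (L1 X + L2 Y + L3 Z + L4) / (L9 X + L10 Y + L11 Z + 1)
##   v = (L5 X + L6 Y + L7 Z + L8) / (L9 X + L10 Y + L11 Z + 1)
## mapping world coordinates (cm) to image coordinates (pixels).
## Image origin top-left, x right, y down, nominal sensor 1536 x 1024 px.

#' DLT camera object
#'
#' @param L numeric vector of the 11 DLT coefficients (the 12th homogeneous
#'   coefficient is fixed at 1). A length-12 vector is also accepted and
#'   normalized by its last element, so any nonzero rescaling of the full
#'   homogeneous coefficient set yields the identical camera.
#' @param rms RMS reprojection residual of the calibration (px), if known.
#' @param view optional view label (e.g. `"laterolateral"`).
#' @return Object of class `dlt_camera`.
#' @export
dlt_camera <- function(L, rms = NA_real_, view = NA_character_) {
  L <- as.numeric(L)
  if (length(L) == 12L) {
    if (abs(L[12]) < 1e-15)
      stop("homogeneous scale coefficient must be nonzero", call. = FALSE)
    L <- L[1:11] / L[12]
  }
  if (length(L) != 11L || any(!is.finite(L)))
    stop("a DLT camera needs 11 finite coefficients", call. = FALSE)
  structure(list(L = L, rms = rms, view = view), class = "dlt_camera")
}

#' @export
print.dlt_camera <- function(x, ...) {
  cat("DLT camera", if (!is.na(x$view)) paste0("(", x$view, ")"), "\n")
  cat("  L1..L11:", paste(signif(x$L, 6), collapse = " "), "\n")
  if (!is.na(x$rms)) cat(sprintf("  calibration RMS: %.4g px\n", x$rms))
  invisible(x)
}

.as_pts <- function(p, d) {
  if (is.null(dim(p))) p <- matrix(p, ncol = d)
  p <- as.matrix(p)
  if (ncol(p) != d || any(!is.finite(p)))
    stop("expected finite points with ", d, " columns", call. = FALSE)
  p
}

#' Calibrate a DLT camera from point correspondences
#'
#' Linear least-squares solution of the stacked DLT equations, with world
#' and image coordinates centred and scaled before the solve for
#' conditioning (standard DLT practice). Requires at least 6 beads that do
#' not lie on a common plane.
#'
#' @param world n x 3 matrix of bead world coordinates (cm).
#' @param image n x 2 matrix of observed image points (px), same order.
#' @param view optional view label stored on the camera.
#' @return A [dlt_camera()] carrying the RMS reprojection residual.
#' @export
dlt_calibrate <- function(world, image, view = NA_character_) {
  world <- .as_pts(world, 3); image <- .as_pts(image, 2)
  n <- nrow(world)
  if (nrow(image) != n) stop("world/image point counts differ", call. = FALSE)
  if (n < 6L) stop("DLT calibration needs at least 6 points", call. = FALSE)
  ctr <- colMeans(world)
  sv <- svd(sweep(world, 2, ctr))$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    stop("degenerate calibration: beads are coplanar or collinear", call. = FALSE)
  # normalize for conditioning
  ws <- max(sv) / sqrt(n); if (ws == 0) ws <- 1
  W <- sweep(world, 2, ctr) / ws
  ic <- colMeans(image)
  is_ <- mean(sqrt(rowSums(sweep(image, 2, ic)^2))); if (is_ == 0) is_ <- 1
  I <- sweep(image, 2, ic) / is_
  A <- matrix(0, 2 * n, 11)
  b <- numeric(2 * n)
  X <- W[, 1]; Y <- W[, 2]; Z <- W[, 3]; u <- I[, 1]; v <- I[, 2]
  odd <- seq(1, 2 * n, 2); even <- odd + 1
  A[odd, 1:4] <- cbind(X, Y, Z, 1)
  A[odd, 9:11] <- -u * cbind(X, Y, Z)
  A[even, 5:8] <- cbind(X, Y, Z, 1)
  A[even, 9:11] <- -v * cbind(X, Y, Z)
  b[odd] <- u; b[even] <- v
  Ln <- qr.solve(A, b)
  # denormalize: compose pixel <- normalized-image <- normalized-world <- world
  P <- rbind(matrix(Ln[1:8], 2, 4, byrow = TRUE), c(Ln[9:11], 1))
  Tw <- rbind(cbind(diag(3) / ws, -ctr / ws), c(0, 0, 0, 1))
  Ti <- rbind(c(is_, 0, ic[1]), c(0, is_, ic[2]), c(0, 0, 1))
  Pfull <- Ti %*% P %*% Tw
  Pfull <- Pfull / Pfull[3, 4]
  cam <- dlt_camera(c(t(Pfull[1:2, ]), Pfull[3, 1:3]), view = view)
  resid <- dlt_project(cam, world) - image
  cam$rms <- sqrt(mean(resid^2))
  cam
}

#' Project world points through a DLT camera
#'
#' @param camera a [dlt_camera()].
#' @param points length-3 vector or n x 3 matrix of world points (cm).
#' @return n x 2 matrix of image points (px).
#' @export
dlt_project <- function(camera, points) {
  stopifnot(inherits(camera, "dlt_camera"))
  P <- .as_pts(points, 3)
  L <- camera$L
  den <- P %*% L[9:11] + 1
  if (any(abs(den) < 1e-12))
    stop("point on the camera's principal plane (vanishing denominator)",
         call. = FALSE)
  u <- (P %*% L[1:3] + L[4]) / den
  v <- (P %*% L[5:7] + L[8]) / den
  cbind(u = as.numeric(u), v = as.numeric(v))
}

#' Triangulate a 3D point from two calibrated views
#'
#' Linear least-squares solution of the four stacked DLT equations from one
#' observation per view. The conditioning of the stereo geometry is
#' checked: two (near-)identical cameras cannot triangulate.
#'
#' @param cameras list of two [dlt_camera()]s.
#' @param observations 2 x 2 matrix (or list of two length-2 vectors), one
#'   image point (px) per view in camera order.
#' @return List with `point` (length-3 world coordinates, cm), `residuals`
#'   (per-view reprojection residual in px) and `rms`.
#' @export
dlt_reconstruct <- function(cameras, observations) {
  if (length(cameras) != 2L || !all(vapply(cameras, inherits, logical(1), "dlt_camera")))
    stop("need exactly two dlt_camera objects", call. = FALSE)
  if (is.list(observations)) observations <- do.call(rbind, observations)
  observations <- .as_pts(observations, 2)
  if (nrow(observations) != 2L) stop("need one observation per view", call. = FALSE)
  A <- matrix(0, 4, 3); b <- numeric(4)
  for (k in 1:2) {
    L <- cameras[[k]]$L; u <- observations[k, 1]; v <- observations[k, 2]
    A[2 * k - 1, ] <- L[1:3] - u * L[9:11]
    A[2 * k, ] <- L[5:7] - v * L[9:11]
    b[2 * k - 1] <- u - L[4]
    b[2 * k] <- v - L[8]
  }
  qa <- qr(A)
  d <- abs(diag(qr.R(qa)))
  if (qa$rank < 3L || min(d) / max(d) < 1e-10)
    stop("degenerate stereo geometry: viewing rays are (near-)parallel",
         call. = FALSE)
  x <- qr.solve(A, b)
  resid <- vapply(1:2, function(k)
    sqrt(sum((dlt_project(cameras[[k]], x) - observations[k, ])^2)), numeric(1))
  list(point = as.numeric(x), residuals = resid, rms = sqrt(mean(resid^2)))
}

#' Distortion grid
#'
#' A reference grid for image-distortion correction: a regular lattice of
#' true (undistorted) points and their observed (distorted) positions.
#'
#' @param true n x 2 matrix of true lattice points (px), a rectangular grid.
#' @param observed n x 2 matrix of their distorted positions (px).
#' @return Object of class `distortion_grid`.
#' @export
distortion_grid <- function(true, observed) {
  true <- .as_pts(true, 2); observed <- .as_pts(observed, 2)
  if (nrow(true) != nrow(observed))
    stop("true/observed point counts differ", call. = FALSE)
  xs <- sort(unique(true[, 1])); ys <- sort(unique(true[, 2]))
  if (length(xs) < 2L || length(ys) < 2L ||
      nrow(true) != length(xs) * length(ys))
    stop("true points must form a rectangular lattice", call. = FALSE)
  idx <- matrix(NA_integer_, length(xs), length(ys))
  for (i in seq_len(nrow(true)))
    idx[match(true[i, 1], xs), match(true[i, 2], ys)] <- i
  structure(list(xs = xs, ys = ys, true = true, observed = observed,
                 idx = idx), class = "distortion_grid")
}

# invert the bilinear warp of one cell by Newton iteration; returns c(s, t)
# in [0,1]^2 or NULL if the point is not in this cell
.inv_bilinear <- function(q, corners, tol = 1e-10) {
  st <- c(0.5, 0.5)
  for (iter in 1:50) {
    s <- st[1]; t <- st[2]
    f <- (1 - s) * (1 - t) * corners[1, ] + s * (1 - t) * corners[2, ] +
         (1 - s) * t * corners[3, ] + s * t * corners[4, ] - q
    if (sum(abs(f)) < tol) break
    ds <- -(1 - t) * corners[1, ] + (1 - t) * corners[2, ] -
          t * corners[3, ] + t * corners[4, ]
    dt <- -(1 - s) * corners[1, ] - s * corners[2, ] +
          (1 - s) * corners[3, ] + s * corners[4, ]
    J <- cbind(ds, dt)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    st <- st - step
    if (any(!is.finite(st))) return(NULL)
  }
  if (all(st > -1e-9 & st < 1 + 1e-9) && sum(abs(f)) < 1e-6) pmin(pmax(st, 0), 1)
  else NULL
}

#' Undistort image points through a reference grid
#'
#' Maps observed (distorted) points back to true image coordinates by
#' inverting the grid warp cell-by-cell (piecewise-bilinear). Points outside
#' the warped lattice are flagged `NA` with a warning, never extrapolated.
#'
#' @param grid a [distortion_grid()].
#' @param points n x 2 matrix of observed points (px).
#' @return n x 2 matrix of undistorted points; rows outside the grid are
#'   `NA` and marked in the `outside` attribute (logical vector).
#' @export
undistort <- function(grid, points) {
  stopifnot(inherits(grid, "distortion_grid"))
  points <- .as_pts(points, 2)
  nx <- length(grid$xs); ny <- length(grid$ys)
  out <- matrix(NA_real_, nrow(points), 2)
  outside <- rep(TRUE, nrow(points))
  for (p in seq_len(nrow(points))) {
    q <- points[p, ]
    for (i in seq_len(nx - 1)) {
      for (j in seq_len(ny - 1)) {
        ids <- c(grid$idx[i, j], grid$idx[i + 1, j],
                 grid$idx[i, j + 1], grid$idx[i + 1, j + 1])
        corners <- grid$observed[ids, , drop = FALSE]
        rng <- apply(corners, 2, range)
        pad <- 1e-9 + 0.05 * c(diff(rng[, 1]), diff(rng[, 2]))
        if (q[1] < rng[1, 1] - pad[1] || q[1] > rng[2, 1] + pad[1] ||
            q[2] < rng[1, 2] - pad[2] || q[2] > rng[2, 2] + pad[2]) next
        st <- .inv_bilinear(q, corners)
        if (!is.null(st)) {
          tx <- grid$xs[i] + st[1] * (grid$xs[i + 1] - grid$xs[i])
          ty <- grid$ys[j] + st[2] * (grid$ys[j + 1] - grid$ys[j])
          out[p, ] <- c(tx, ty)
          outside[p] <- FALSE
        }
      }
      if (!outside[p]) break
    }
  }
  if (any(outside))
    warning(sum(outside), " point(s) outside the distortion grid; returned NA")
  colnames(out) <- c("u", "v")
  attr(out, "outside") <- outside
  out
}
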