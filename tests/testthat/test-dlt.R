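test_that("a noiseless synthetic scene calibrates to machine precision", {
  sc <- generate_calibration_scene(noise_px = 0)
  for (v in names(sc$cameras)) {
    obs <- sc$observations[sc$observations$view == v, ]
    cam <- dlt_calibrate(sc$beads[, c("X_cm", "Y_cm", "Z_cm")],
                         obs[, c("u_px", "v_px")], view = v)
    expect_lt(cam$rms, 1e-8)
    expect_lt(max(abs(cam$L - sc$cameras[[v]]$L)), 1e-6)
  }
})

test_that("degenerate bead sets are rejected", {
  set.seed(301)
  planar <- cbind(stats::runif(20, -5, 5), stats::runif(20, -5, 5), 0)
  cam <- generate_calibration_scene()$cameras[[1]]
  expect_error(dlt_calibrate(planar, dlt_project(cam, planar)), "coplanar")
  few <- matrix(stats::runif(15, -5, 5), 5, 3)
  expect_error(dlt_calibrate(few, dlt_project(cam, few)), "at least 6")
})

test_that("projection is exact for a constructed camera and homogeneous", {
  sc <- generate_calibration_scene()
  cam <- sc$cameras$laterolateral
  p0 <- c(-10, -6, -6)  # lattice origin bead
  expect_equal(dlt_project(cam, p0),
               sc$observations[sc$observations$view == "laterolateral" &
                                 sc$observations$id == 1, c("u_px", "v_px")] |>
                 as.matrix() |> unname() |> (\(m) {colnames(m) <- c("u","v"); m})(),
               tolerance = 1e-10)
  # rescaling the full homogeneous 12-vector leaves the projection unchanged
  cam2 <- dlt_camera(c(cam$L, 1) * -3.7)
  pts <- matrix(stats::runif(30, -6, 6), 10, 3)
  expect_equal(dlt_project(cam2, pts), dlt_project(cam, pts), tolerance = 1e-9)
  # principal plane: denominator vanishes
  L <- cam$L
  z0 <- -(1 + L[9] * 0 + L[10] * 0) / L[11]
  expect_error(dlt_project(cam, c(0, 0, z0)), "principal plane")
})

test_that("two-view reconstruction round-trips noiselessly", {
  sc <- generate_calibration_scene()
  set.seed(302)
  pts <- matrix(stats::runif(60, -5, 5), 20, 3)
  for (i in seq_len(nrow(pts))) {
    obs <- rbind(dlt_project(sc$cameras[[1]], pts[i, ]),
                 dlt_project(sc$cameras[[2]], pts[i, ]))
    rec <- dlt_reconstruct(sc$cameras, obs)
    expect_lt(max(abs(rec$point - pts[i, ])), 1e-8)
    expect_lt(rec$rms, 1e-6)
  }
  # identical camera twice: degenerate stereo
  obs <- rbind(dlt_project(sc$cameras[[1]], pts[1, ]),
               dlt_project(sc$cameras[[1]], pts[1, ]))
  expect_error(dlt_reconstruct(list(sc$cameras[[1]], sc$cameras[[1]]), obs),
               "degenerate")
})

test_that("calibration residual sits at the noise level", {
  # 0.5 px Gaussian noise: RMS residual concentrates near
  # 0.5 * sqrt(1 - 11/(2n)); check the stated [0.3, 0.7] band across seeds
  for (seed in 1:5) {
    set.seed(seed)
    world <- matrix(stats::runif(300, -8, 8), 100, 3)
    cam <- generate_calibration_scene()$cameras$dorsoventral
    img <- dlt_project(cam, world) + matrix(stats::rnorm(200, 0, 0.5), 100, 2)
    fit <- dlt_calibrate(world, img)
    expect_gt(fit$rms, 0.3); expect_lt(fit$rms, 0.7)
  }
})

test_that("reconstruction error grows with observation noise", {
  sc <- generate_calibration_scene()
  set.seed(303)
  pts <- matrix(stats::runif(150, -5, 5), 50, 3)
  err_at <- function(noise) {
    e <- vapply(seq_len(nrow(pts)), function(i) {
      obs <- rbind(dlt_project(sc$cameras[[1]], pts[i, ]),
                   dlt_project(sc$cameras[[2]], pts[i, ])) +
        matrix(stats::rnorm(4, 0, noise), 2, 2)
      sqrt(sum((dlt_reconstruct(sc$cameras, obs)$point - pts[i, ])^2))
    }, numeric(1))
    mean(e)
  }
  e <- vapply(c(0, 0.5, 2), err_at, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("a known 15 cm separation survives 0.5 px noise within 1 mm", {
  # mirrors the caliper audit: a known 150.00 mm opening re-measured
  sc <- generate_calibration_scene(noise_px = 0.5, seed = 99)
  cams <- lapply(names(sc$cameras), function(v) {
    obs <- sc$observations[sc$observations$view == v, ]
    dlt_calibrate(sc$beads[, c("X_cm", "Y_cm", "Z_cm")],
                  obs[, c("u_px", "v_px")], view = v)
  })
  ends <- rbind(c(-7.5, 0, 0), c(7.5, 0, 0))
  set.seed(100)
  rec <- apply(ends, 1, function(p) {
    obs <- rbind(dlt_project(sc$cameras[[1]], p),
                 dlt_project(sc$cameras[[2]], p)) +
      matrix(stats::rnorm(4, 0, 0.5), 2, 2)
    dlt_reconstruct(cams, obs)$point
  })
  sep <- sqrt(sum((rec[, 1] - rec[, 2])^2))
  expect_lt(abs(sep - 15), 0.1)
})

test_that("undistortion inverts a synthetic warp and flags outside points", {
  lat <- as.matrix(expand.grid(u = seq(0, 1500, 50), v = seq(0, 1000, 50)))
  warp <- function(p) {
    c0 <- c(750, 500)
    r2 <- rowSums(sweep(p, 2, c0)^2)
    sweep(sweep(p, 2, c0) * (1 + 5e-8 * r2), 2, c0, `+`)
  }
  # identity grid: points unchanged
  gid <- distortion_grid(lat, lat)
  set.seed(304)
  probes <- cbind(stats::runif(20, 100, 1400), stats::runif(20, 100, 900))
  u0 <- undistort(gid, probes)
  expect_equal(unname(u0[, ]), unname(probes), tolerance = 1e-8)
  # radial warp: forward-warp oracle, recovered within 0.1 px
  g <- distortion_grid(lat, warp(lat))
  rec <- undistort(g, warp(probes))
  expect_lt(max(abs(rec - probes)), 0.1)
  expect_false(any(attr(rec, "outside")))
  # outside the hull: flagged NA, not extrapolated
  expect_warning(out <- undistort(g, rbind(c(-500, -500))), "outside")
  expect_true(all(is.na(out[1, ])))
  expect_true(attr(out, "outside")[1])
})
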