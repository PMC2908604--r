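# Shared fixtures and independent oracles.

# random Euler triple in degrees, away from the gimbal-lock configuration
rand_angles <- function(n = 1) {
  cbind(rx = stats::runif(n, -179, 179),
        ry = stats::runif(n, -85, 85),
        rz = stats::runif(n, -179, 179))
}

rand_transform <- function() {
  a <- rand_angles(1)
  rigid_transform(euler_matrix(a[1], a[2], a[3]), stats::runif(3, -10, 10))
}

# homogeneous 4x4 oracle, independent of the rigid_transform arithmetic
as_h4 <- function(T) rbind(cbind(T$R, T$t), c(0, 0, 0, 1))
h4_to_rt <- function(H) rigid_transform(H[1:3, 1:3], H[1:3, 4])

# homogeneous-matrix forward-kinematics oracle: multiplies 4x4 matrices
# down the parent chain (poses include the constant origin offset)
fk_oracle <- function(model, poses, segment) {
  H <- diag(4)
  chain <- character(0)
  nm <- segment
  while (!is.na(nm)) { chain <- c(nm, chain); nm <- model$segments[[nm]]$parent }
  for (nm in chain) {
    if (nm == model$root) next
    p <- poses[[nm]]
    R <- euler_matrix(p[4], p[5], p[6])
    t <- p[1:3] + model$segments[[nm]]$origin
    H <- H %*% rbind(cbind(R, t), c(0, 0, 0, 1))
  }
  H
}

# single-segment pose series from a matrix of per-frame values
one_segment_series <- function(values, segment = "seg", fps = 300) {
  n <- nrow(values)
  pose_series(data.frame(frame = seq_len(n) - 1L, segment = segment,
                         tx_cm = values[, 1], ty_cm = values[, 2],
                         tz_cm = values[, 3], rx_deg = values[, 4],
                         ry_deg = values[, 5], rz_deg = values[, 6]),
              fps = fps)
}

# noiseless template series for one representative stride
template_stride <- function(contact_s = 1.50, swing_s = 0.84) {
  generate_stride_kinematics(kinematics_template(), contact_s, swing_s)
}
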