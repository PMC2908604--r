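## Published reference values for Choloepus didactylus suspensory
## locomotion, bundled as plain data.frame constructors. These are the
## inputs the analysis pipeline and the synthetic-data generator are
## parameterized from.

#' Comparative pectoral-girdle measurements
#'
#' Segment lengths (cm) of seven adult *Choloepus didactylus*: three museum
#' specimens, two dissected specimens and the two x-rayed study animals.
#' `NA` marks measurements that could not be taken.
#'
#' @return data.frame with columns `specimen`, `group`, `scapula`,
#'   `spina_scapulae`, `humerus`, `clavicle`, `ulna`, `hand`.
#' @export
girdle_measurements <- function() {
  data.frame(
    specimen = c("MfN_102636", "ZMH_1507", "ZMH_1506",
                 "dissected_1", "dissected_2", "study_male", "study_female"),
    group = c(rep("museum", 3), rep("dissected", 2), rep("study", 2)),
    scapula        = c(8.98, 7.32, 7.25, 8.68, 7.71, 7.7, 8.2),
    spina_scapulae = c(5.74, 5.18, 4.45, 5.73, 5.24, 5.0, 5.8),
    humerus        = c(14.06, 12.94, 11.75, 15.7, 14.58, 13.2, 15.9),
    clavicle       = c(4.64, 3.80, 3.21, 4.52, 4.2, 3.6, 4.6),
    ulna           = c(17.02, 13.91, 14.42, 19.4, 17.38, 15.2, 19.4),
    hand           = c(NA, 8.81, NA, 10.01, 9.2, 9.0, 9.8))
}

#' Reference gait parameters
#'
#' Per-individual and pooled gait-parameter means and standard deviations
#' from the treadpole trials: stride length (cm), forelimb swing and
#' contact phase durations (s), and the 2D scapula touch-down angle (deg).
#'
#' @return data.frame with columns `parameter`, `mean_1`, `sd_1`, `n_1`,
#'   `mean_2`, `sd_2`, `n_2`, `p_value`, `mean_pooled`, `sd_pooled`,
#'   `n_pooled`.
#' @export
gait_reference <- function() {
  data.frame(
    parameter = c("stride_length_cm", "swing_duration_s",
                  "contact_duration_s", "scapula_td_angle_deg"),
    mean_1 = c(57.4, 0.81, 1.47, 43.7), sd_1 = c(4.8, 0.1, 0.2, 5.5),
    n_1 = c(18, 18, 18, 10),
    mean_2 = c(60.4, 0.88, 1.52, 40.4), sd_2 = c(4.9, 0.3, 0.2, 4.9),
    n_2 = c(14, 14, 14, 10),
    p_value = c(0.098, 0.316, 0.541, 0.174),
    mean_pooled = c(58.9, 0.84, 1.50, 42.0),
    sd_pooled = c(5.0, 0.2, 0.2, 5.3),
    n_pooled = c(32, 32, 32, 20))
}

#' Reference six-DOF stride endpoints
#'
#' Touch-down and lift-off means (+- s.d. across the 20 pooled strides)
#' with contact and maximal amplitudes for every DOF of the four elements.
#' Translations in cm (zeroed at touch down), rotations in degrees.
#'
#' @return data.frame with columns `segment`, `dof`, `td`, `td_sd`, `lo`,
#'   `lo_sd`, `contact_amplitude`, `max_amplitude`.
#' @export
kinematic_endpoints <- function() {
  rows <- rbind(
    c("thoracic_vertebra_1", "tx",   0,   NA, -1.0, 2.1,  1.0,  3.2),
    c("thoracic_vertebra_1", "ty",   0,   NA, -0.9, 0.9,  0.9,  1.1),
    c("thoracic_vertebra_1", "tz",   0,   NA,  1.2, 1.7,  1.2,  4.3),
    c("thoracic_vertebra_1", "rx",  -0.4, 3.5,  1.0, 4.0,  1.4,  1.9),
    c("thoracic_vertebra_1", "ry",  -4.6, 6.2, 11.5, 5.7, 16.2, 20.5),
    c("thoracic_vertebra_1", "rz", -10.1, 4.0, -9.8, 2.6,  0.3,  3.0),
    c("scapula", "tx",   0,    NA,  -0.3, 0.2,  0.3,  0.5),
    c("scapula", "ty",   0,    NA,  -0.7, 0.1,  0.7,  0.8),
    c("scapula", "tz",   0,    NA,   0.1, 0.3,  0.1,  0.4),
    c("scapula", "rx", -26.3, 8.1, -18.6, 9.2,  7.7, 10.7),
    c("scapula", "ry", -13.5, 3.2, -13.1, 5.0,  0.4,  7.6),
    c("scapula", "rz",  71.7, 12.9, 39.3, 8.7, 32.4, 35.9),
    c("humerus", "tx",   0,    NA,   0.1, 0.1,  0.1,  0.2),
    c("humerus", "ty",   0,    NA,   0.0, 0.1,  0.0,  0.1),
    c("humerus", "tz",   0,    NA,   0.0, 0.1,  0.0,  0.0),
    c("humerus", "rx",   3.3, 7.2, -20.3, 4.6, 23.6, 23.8),
    c("humerus", "ry",   2.9, 1.2, -10.4, 6.2, 13.3, 18.7),
    c("humerus", "rz", -77.4, 11.4, -117.1, 18.2, 39.7, 57.7),
    c("clavicle", "tx",  0,    NA,  -0.3, 0.2,  0.3,  0.4),
    c("clavicle", "ty",  0,    NA,   0.4, 0.2,  0.4,  0.4),
    c("clavicle", "tz",  0,    NA,  -0.4, 0.2,  0.4,  0.6),
    c("clavicle", "rx", 83.8, 16.4, 20.6, 21.1, 63.2, 68.2),
    c("clavicle", "ry", -22.0, 2.4, -9.0, 1.3, 13.0, 19.6),
    c("clavicle", "rz", -43.7, 8.0, -6.2, 7.7, 37.5, 43.3))
  out <- data.frame(segment = rows[, 1], dof = rows[, 2],
                    apply(rows[, 3:8], 2, as.numeric))
  names(out)[3:8] <- c("td", "td_sd", "lo", "lo_sd",
                       "contact_amplitude", "max_amplitude")
  out
}

#' Reference elbow-displacement summaries
#'
#' Published per-axis maxima, minima, amplitudes and %-of-total-forelimb-
#' length of the elbow trajectory relative to the 1st thoracic vertebra,
#' for normal locomotion and the five muting conditions. The printed
#' `pct_tfl` of 30.1 for cranio-caudal displacement without humeral
#' abduction/adduction is inconsistent with its own amplitude
#' (15.2 / 49.2 = 30.9) and is carried verbatim as a documented misprint.
#'
#' @return data.frame with columns `axis`, `condition`, `max_cm`, `min_cm`,
#'   `amplitude_cm`, `pct_tfl`.
#' @export
elbow_displacement_reference <- function() {
  conds <- c("normal", "no_humeral_motion", "no_scapular_motion",
             "no_scapular_abduction_adduction",
             "no_scapular_long_axis_rotation",
             "no_humeral_abduction_adduction")
  data.frame(
    axis = rep(c("medio_lateral", "cranio_caudal", "dorso_ventral"),
               each = 6),
    condition = rep(conds, 3),
    max_cm = c(8.3, 8.7, 8.9, 8.3, 9.1, 8.7,
               11.7, 6.0, 7.8, 11.6, 11.4, 12.2,
               15.7, 15.9, 15.6, 15.7, 15.8, 15.2),
    min_cm = c(5.9, 7.0, 6.4, 5.9, 6.0, 5.5,
               -2.8, -3.0, -2.8, -2.9, -2.8, -2.9,
               5.4, 14.5, 9.4, 5.3, 5.0, 5.7),
    amplitude_cm = c(2.5, 1.7, 2.5, 2.5, 3.1, 3.1,
                     14.4, 9.0, 10.6, 14.6, 14.2, 15.2,
                     10.3, 1.4, 6.2, 10.4, 10.9, 9.4),
    pct_tfl = c(5.1, 3.5, 5.1, 5.1, 6.3, 6.3,
                29.3, 18.3, 21.5, 29.7, 28.9, 30.1,
                20.9, 2.8, 12.6, 21.1, 22.2, 19.1))
}

#' Digitization repeatability
#'
#' Standard deviations of ten repeated digitizations of one scapular
#' lift-off pose on consecutive days: the magnitude of digitization noise
#' and the justification for reporting kinematics to 0.1 cm / 0.1 deg.
#'
#' @return Named numeric vector of per-DOF s.d.s (`tx`, `ty`, `tz` in cm;
#'   `rx`, `ry`, `rz` in degrees).
#' @export
repeatability_reference <- function() {
  c(tx = 0.13, ty = 0.12, tz = 0.12, rx = 0.76, ry = 0.24, rz = 0.16)
}
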