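## Pectoral-girdle morphometrics: summary statistics of the comparative
## length measurements, the relative scapula length, and the total
## forelimb length (tfl) normalizing elbow-displacement amplitudes.

.MEASURE_COLS <- c("scapula", "spina_scapulae", "humerus", "clavicle",
                   "ulna", "hand")

#' Column-wise summary of girdle measurements
#'
#' Mean and sample (n-1) standard deviation per measurement column,
#' missing entries excluded pairwise. Columns with fewer than two
#' non-missing values are dropped with a warning.
#'
#' @param table data.frame of specimen measurements (cm) with any subset of
#'   columns `scapula`, `spina_scapulae`, `humerus`, `clavicle`, `ulna`,
#'   `hand`; `NA` marks a missing measurement.
#' @param digits rounding applied to the presented mean/sd (default 2).
#' @return data.frame `measure`, `mean`, `sd`, `n`, plus unrounded
#'   `mean_raw`, `sd_raw`.
#' @export
summarize_measurements <- function(table, digits = 2) {
  cols <- intersect(.MEASURE_COLS, names(table))
  if (!length(cols)) stop("no measurement columns found", call. = FALSE)
  rows <- lapply(cols, function(cl) {
    v <- table[[cl]]
    if (any(v[!is.na(v)] <= 0))
      stop("measurements must be positive: ", cl, call. = FALSE)
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      warning("column ", cl, " has fewer than 2 values; excluded")
      return(NULL)
    }
    data.frame(measure = cl, mean = round(mean(v), digits),
               sd = round(stats::sd(v), digits), n = length(v),
               mean_raw = mean(v), sd_raw = stats::sd(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative scapula length
#'
#' The scapula mean length expressed as a percentage of the summed mean
#' scapula + upper-arm (humerus) + lower-arm (ulna) lengths, rounded to
#' integer percent. In *Choloepus* this lands near 21%, far below the
#' roughly 30% typical of pronograde mammals.
#'
#' @param summary output of [summarize_measurements()] (must contain the
#'   `scapula`, `humerus` and `ulna` rows).
#' @return Integer percentage.
#' @export
relative_scapula_length <- function(summary) {
  need <- c("scapula", "humerus", "ulna")
  absent <- setdiff(need, summary$measure)
  if (length(absent))
    stop("summary missing measure: ", absent[1], call. = FALSE)
  m <- stats::setNames(summary$mean_raw, summary$measure)[need]
  round(100 * m["scapula"] / sum(m))[[1]]
}

#' Total forelimb length (tfl)
#'
#' The normalization constant for elbow-displacement amplitudes: the mean
#' over the study animals of scapula + humerus + ulna + hand length. All
#' four components must be present for every supplied animal.
#'
#' @param study_animals data.frame with columns `scapula`, `humerus`,
#'   `ulna`, `hand` (cm), one row per study animal (typically two).
#' @return tfl in cm.
#' @export
total_forelimb_length <- function(study_animals) {
  need <- c("scapula", "humerus", "ulna", "hand")
  absent <- setdiff(need, names(study_animals))
  if (length(absent))
    stop("study animals missing column: ", absent[1], call. = FALSE)
  m <- as.matrix(study_animals[, need])
  if (any(is.na(m)))
    stop("study animal with missing segment length", call. = FALSE)
  mean(rowSums(m))
}

#' Read a girdle measurement CSV
#'
#' Accepts the literal `x` (as printed in comparative tables) or empty
#' cells for missing measurements.
#'
#' @param path CSV with a `specimen` column and measurement columns.
#' @return data.frame with numeric measurement columns, `NA` for missing.
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(.MEASURE_COLS, names(d))) {
    v <- trimws(as.character(d[[cl]]))
    v[v %in% c("", "x", "X")] <- NA
    d[[cl]] <- as.numeric(v)
  }
  d
}
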