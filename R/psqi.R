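#' PSQI component names used throughout the package
#'
#' Internal trait order: the four components analyzed as continuous scores
#' (sleep latency, sleep duration, habitual sleep efficiency, sleep
#' disturbances) followed by the three analyzed as ordinal liability
#' variables (subjective sleep quality, use of sleeping medication, daytime
#' dysfunction).
#'
#' @return Character vector of the seven component names.
#' @export
psqi_components <- function() {
  c("latency", "duration", "efficiency", "disturbances",
    "quality", "medication", "daytime")
}

#' Default measurement specification for the seven PSQI components
#'
#' @return A data frame with columns `trait`, `measure`
#'   (`"continuous"`/`"ordinal"`) and `n_cat` (number of ordinal categories,
#'   `NA` for continuous traits).
#' @export
psqi_specs <- function() {
  data.frame(
    trait   = psqi_components(),
    measure = c(rep("continuous", 4L), rep("ordinal", 3L)),
    n_cat   = c(rep(NA_integer_, 4L), 4L, 4L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Habitual sleep efficiency as a percentage
#'
#' Efficiency is the ratio of hours actually slept to hours spent in bed,
#' expressed as a percentage and capped at 100 (self-reported sleep can
#' exceed reported time in bed through rounding; the downstream 0-3 score
#' is what matters, so such values are capped rather than rejected).
#'
#' @param hours_slept Hours of actual sleep, `>= 0`.
#' @param hours_in_bed Hours spent in bed, `> 0`.
#' @return Efficiency in percent, in `[0, 100]`. Vectorized.
#' @export
sleep_efficiency_percent <- function(hours_slept, hours_in_bed) {
  if (any(!is.finite(hours_in_bed)) || any(hours_in_bed <= 0))
    stop_input("hours_in_bed must be positive")
  if (any(!is.finite(hours_slept)) || any(hours_slept < 0))
    stop_input("hours_slept must be nonnegative")
  pmin(100 * hours_slept / hours_in_bed, 100)
}

#' Default cut-points mapping raw quantities to 0-3 component scores
#'
#' The standard published instrument's mappings. Each entry is a vector of
#' descending lower bounds: a raw value `x` scores `k` where `k` is the
#' first bound it reaches. Exposed so a scoring dialect can be swapped in.
#'
#' @return Named list with elements `efficiency` (percent bounds: `>=85`
#'   scores 0, 75-84 scores 1, 65-74 scores 2, below 65 scores 3),
#'   `latency_minutes` (`<=15` scores 0, 16-30 scores 1, 31-60 scores 2,
#'   over 60 scores 3) and `duration_hours` (`>7` scores 0, 6-7 scores 1,
#'   5-6 scores 2, under 5 scores 3).
#' @export
psqi_cutpoints <- function() {
  list(
    efficiency      = c(85, 75, 65),   # percent, descending
    latency_minutes = c(15, 30, 60),   # ascending upper bounds
    duration_hours  = c(7, 6, 5)       # descending lower bounds
  )
}

#' Score habitual sleep efficiency on the 0-3 component scale
#'
#' @param percent Efficiency percentage (e.g. from
#'   [sleep_efficiency_percent()]).
#' @param bounds Descending vector of three lower bounds, by default the
#'   standard instrument's `c(85, 75, 65)`.
#' @return Integer score 0-3. Vectorized.
#' @export
score_efficiency <- function(percent, bounds = psqi_cutpoints()$efficiency) {
  stopifnot(length(bounds) == 3L, !is.unsorted(rev(bounds)))
  ifelse(percent >= bounds[1L], 0L,
         ifelse(percent >= bounds[2L], 1L,
                ifelse(percent >= bounds[3L], 2L, 3L)))
}

#' Score sleep latency minutes on the 0-3 component scale
#'
#' @param minutes Reported minutes to fall asleep.
#' @param bounds Ascending vector of three upper bounds (defaults
#'   `c(15, 30, 60)`).
#' @return Integer score 0-3. Vectorized.
#' @export
score_latency <- function(minutes, bounds = psqi_cutpoints()$latency_minutes) {
  stopifnot(length(bounds) == 3L, !is.unsorted(bounds))
  ifelse(minutes <= bounds[1L], 0L,
         ifelse(minutes <= bounds[2L], 1L,
                ifelse(minutes <= bounds[3L], 2L, 3L)))
}

#' Score sleep duration hours on the 0-3 component scale
#'
#' @param hours Reported hours of sleep.
#' @param bounds Descending vector of three lower bounds (defaults
#'   `c(7, 6, 5)`).
#' @return Integer score 0-3. Vectorized.
#' @export
score_duration <- function(hours, bounds = psqi_cutpoints()$duration_hours) {
  stopifnot(length(bounds) == 3L, !is.unsorted(rev(bounds)))
  ifelse(hours > bounds[1L], 0L,
         ifelse(hours >= bounds[2L], 1L,
                ifelse(hours >= bounds[3L], 2L, 3L)))
}

#' Global PSQI score and sleep-quality label
#'
#' Sums the seven 0-3 component scores into the 0-21 global index; a global
#' score of 5 or less labels adequate ("good") sleep quality, above 5 poor.
#'
#' @param components Numeric vector (or matrix with 7 columns) of the seven
#'   component scores, each in `{0, 1, 2, 3}`.
#' @return List with `score` (integer, 0-21) and `label` (`"good"`/`"poor"`).
#' @export
global_score <- function(components) {
  x <- if (is.matrix(components)) components else matrix(components, nrow = 1L)
  if (ncol(x) != 7L)
    stop_input("expected 7 component scores, got %d", ncol(x))
  if (any(is.na(x)) || any(!(x %in% 0:3)))
    stop_input("every component score must be in {0, 1, 2, 3}")
  s <- as.integer(rowSums(x))
  res <- list(score = s, label = ifelse(s <= 5L, "good", "poor"))
  if (!is.matrix(components)) {
    res$score <- res$score[1L]
    res$label <- res$label[1L]
  }
  res
}

#' Natural log(x + 1) transform for right-skewed component scores
#'
#' The analysis transform applied to the sleep latency and sleep
#' disturbances scores before treating them as continuous. Natural
#' logarithm; the base only rescales the variance and leaves every
#' standardized quantity unchanged, but one convention is fixed for
#' reproducibility.
#'
#' @param x Nonnegative numeric vector.
#' @return `log(x + 1)`; 0 maps to 0, monotone increasing.
#' @export
log1_transform <- function(x) {
  if (any(!is.na(x) & x < 0)) stop_input("log1_transform requires x >= 0")
  log(x + 1)
}
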