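# Shared helpers and marker vocabulary.

#' Marker identifiers
#'
#' Canonical names of the per-participant numeric markers, in the order used
#' by the flat marker table. `sex` is categorical; everything else numeric.
#'
#' @return Character vector of marker names.
#' @export
marker_names <- function() {
  c(
    "age", "sex", "education_years",
    "physical_activity_level", "physical_activity_variance",
    "distance_traveled_from_home", "distance_traveled_variance",
    "mental_sharpness_mean", "mental_sharpness_variance", "EMA_compliance",
    "shape_learning_rate", "shape_score_mean", "shape_score_sd"
  )
}

# Markers rescaled to the 0-10 integer axis. Age and education stay in
# natural units (rule thresholds such as age <= 79.5 only make sense raw);
# sex is categorical.
scaled_marker_names <- function() {
  setdiff(marker_names(), c("age", "sex", "education_years"))
}

#' Marker-set rule groups
#'
#' The six marker-set families whose rule groups are compared and fused:
#' four numeric groups (rules induced by a decision tree on the group's
#' markers) and two text groups (fixed built-in rules over journals and
#' interview ratings).
#'
#' @return Named list; numeric groups carry `markers`, text groups carry
#'   `text_source`.
#' @export
marker_groups <- function() {
  list(
    demographics = list(markers = c("age", "sex", "education_years")),
    behavior = list(markers = c(
      "physical_activity_level", "physical_activity_variance",
      "distance_traveled_from_home", "distance_traveled_variance"
    )),
    nback = list(markers = c(
      "shape_learning_rate", "shape_score_mean", "shape_score_sd"
    )),
    ema = list(markers = c(
      "mental_sharpness_mean", "mental_sharpness_variance", "EMA_compliance"
    )),
    journal = list(text_source = "speech"),
    test_session = list(text_source = "testing_session")
  )
}

class_labels <- function() c("healthy", "mci")

# Round half away from zero (commercial rounding); base round() is banker's.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Population variance (divisor n), NA-stripping handled by callers.
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

cogdx_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cogdx_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream of sub-seeds from one user seed, all < 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max %/% 2L, n))
}
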