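# Numeric marker extraction: daily behavior aggregates from acceleration and
# location streams, EMA summaries, n-back learning-curve features, and
# min-max rescaling of real-valued markers to the 0-10 integer rule axis.

#' Construct a sensor day
#'
#' @param day_index Non-negative integer day index.
#' @param accel_total Total acceleration summed over the day (arbitrary
#'   units), `NA` when missing.
#' @param locations Two-column matrix or data frame of planar coordinates in
#'   meters (columns `x`, `y`).
#' @param missing Logical; `TRUE` for a missing sensor day.
#' @return A `sensor_day` object.
#' @export
sensor_day <- function(day_index, accel_total = NA_real_, locations = NULL,
                       missing = FALSE) {
  if (missing) {
    accel_total <- NA_real_
    locations <- NULL
  } else {
    locations <- as.data.frame(locations)
    names(locations) <- c("x", "y")
  }
  structure(
    list(
      day_index = as.integer(day_index), accel_total = accel_total,
      locations = locations, missing = isTRUE(missing)
    ),
    class = "sensor_day"
  )
}

# Grid-snapped home cell for one day's coordinate vectors: the most
# populous 10 m cell among the first min(300, n) readings, ties broken by
# the earliest-visited cell. Returns c(x, y) cell center.
home_from_xy <- function(x, y) {
  n <- min(300L, length(x))
  kx <- round(x[seq_len(n)] / 10)
  ky <- round(y[seq_len(n)] / 10)
  # exact numeric cell key (collision-free for |ky| < 2^19 cells ~ 5243 km)
  key <- kx * 2^20 + ky
  uk <- unique(key) # first-occurrence order = earliest visited
  counts <- tabulate(match(key, uk))
  win <- uk[which.max(counts)] # which.max takes the first maximum
  i <- match(win, key)
  c(kx[i] * 10, ky[i] * 10)
}

#' Detect a day's home location
#'
#' Snaps the day's first `min(300, n)` location readings to a 10 m grid and
#' returns the center of the most populous cell; ties are broken in favor of
#' the earliest-visited cell.
#'
#' @param day A [sensor_day()].
#' @return Numeric length-2 vector, the home coordinate in meters.
#' @export
detect_home <- function(day) {
  if (isTRUE(day$missing) || is.null(day$locations) ||
    nrow(day$locations) == 0) {
    cogdx_stop("cannot detect home on a missing sensor day",
      "cogdx_missing_data")
  }
  home_from_xy(day$locations$x, day$locations$y)
}

#' Daily behavior values
#'
#' Activity level is the day's total acceleration; distance from home is the
#' mean Euclidean distance of the day's location readings from `home`.
#'
#' @param day A non-missing [sensor_day()].
#' @param home Length-2 home coordinate (meters).
#' @return Named numeric vector `c(activity, distance)`.
#' @export
daily_behavior <- function(day, home) {
  if (isTRUE(day$missing)) {
    cogdx_stop("daily_behavior on a missing sensor day", "cogdx_missing_data")
  }
  d <- sqrt((day$locations$x - home[1])^2 + (day$locations$y - home[2])^2)
  c(activity = day$accel_total, distance = mean(d))
}

# Modal daily home over a set of per-day homes (rows), ties broken by the
# earliest day. `homes` is a 2-column matrix in day order.
modal_home <- function(homes) {
  key <- paste(homes[, 1], homes[, 2])
  uk <- unique(key)
  counts <- tabulate(match(key, uk))
  win <- uk[which.max(counts)]
  homes[match(win, key), ]
}

#' Aggregate behavior markers over the wear period
#'
#' Detects a home per day, takes the modal daily home as the participant's
#' home, computes daily activity and distance from home over non-missing
#' days, and returns their mean and population variance. Missing days are
#' excluded from all calculations.
#'
#' @param days List of [sensor_day()] objects.
#' @return Named numeric vector with `physical_activity_level`,
#'   `physical_activity_variance`, `distance_traveled_from_home`,
#'   `distance_traveled_variance`.
#' @export
aggregate_behavior <- function(days) {
  present <- Filter(function(d) !isTRUE(d$missing), days)
  if (length(present) < 2) {
    cogdx_stop("need >= 2 non-missing sensor days", "cogdx_insufficient_data")
  }
  homes <- t(vapply(present, detect_home, numeric(2)))
  home <- modal_home(homes)
  daily <- t(vapply(present, daily_behavior, numeric(2), home = home))
  c(
    physical_activity_level = mean(daily[, "activity"]),
    physical_activity_variance = pop_var(daily[, "activity"]),
    distance_traveled_from_home = mean(daily[, "distance"]),
    distance_traveled_variance = pop_var(daily[, "distance"])
  )
}

#' EMA summary markers
#'
#' @param values Numeric vector of answered EMA responses (Likert 1-5).
#' @param scheduled Total number of scheduled prompts (days x prompts/day).
#' @return Named numeric vector `mental_sharpness_mean`,
#'   `mental_sharpness_variance` (population variance) and `EMA_compliance`
#'   (answered / scheduled). Mean and variance are `NA` when nothing was
#'   answered; compliance is then 0.
#' @export
ema_markers <- function(values, scheduled) {
  stopifnot(scheduled >= 1)
  n <- length(values)
  c(
    mental_sharpness_mean = if (n > 0) mean(values) else NA_real_,
    mental_sharpness_variance = if (n > 0) pop_var(values) else NA_real_,
    EMA_compliance = n / scheduled
  )
}

# OLS slope of y against 0..(length(y)-1).
ols_slope <- function(y) {
  x <- seq_along(y) - 1
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' n-back summary markers
#'
#' The learning rate is the ordinary least-squares slope of the first 6
#' daily scores against day indices 0..5; mean and population SD are over
#' all scores.
#'
#' @param accuracies Daily n-back accuracies in chronological order.
#' @return Named numeric vector `shape_learning_rate` (`NA` with < 6
#'   scores), `shape_score_mean`, `shape_score_sd` (`NA` with < 2 scores).
#' @export
nback_markers <- function(accuracies) {
  n <- length(accuracies)
  c(
    shape_learning_rate = if (n >= 6) ols_slope(accuracies[1:6]) else NA_real_,
    shape_score_mean = if (n > 0) mean(accuracies) else NA_real_,
    shape_score_sd = if (n >= 2) pop_sd(accuracies) else NA_real_
  )
}

#' Fit 0-10 scale bounds on a reference cohort
#'
#' @param markers Data frame of raw markers (one row per participant).
#' @param which Marker names to scale; defaults to all real-valued markers
#'   except age and education.
#' @return A `scale_bounds` object (named list of `c(min, max)`).
#' @export
fit_scale <- function(markers, which = intersect(
                        scaled_marker_names(), names(markers))) {
  bounds <- lapply(which, function(m) {
    x <- markers[[m]]
    x <- x[!is.na(x)]
    if (length(unique(x)) < 2) {
      cogdx_stop(
        paste0("marker '", m, "' is constant in the reference cohort; ",
          "scale bounds are degenerate"),
        "cogdx_degenerate_bounds"
      )
    }
    c(min = min(x), max = max(x))
  })
  structure(stats::setNames(bounds, which), class = "scale_bounds")
}

#' Rescale markers to the 0-10 integer axis
#'
#' `scaled = round_half_up(10 * (x - min) / (max - min))`, clamped to
#' `[0, 10]`. Markers without bounds (age, education, sex) pass through
#' unchanged; `NA` stays `NA`.
#'
#' @param raw Data frame or named list/vector of raw marker values.
#' @param bounds A [fit_scale()] result.
#' @return Object of the same shape with scaled integer values.
#' @export
apply_scale <- function(raw, bounds) {
  scale1 <- function(x, b) {
    out <- clamp(round_half_up(10 * (x - b["min"]) / (b["max"] - b["min"])),
      0, 10)
    as.integer(out)
  }
  if (is.data.frame(raw)) {
    for (m in names(bounds)) {
      if (m %in% names(raw)) raw[[m]] <- scale1(raw[[m]], bounds[[m]])
    }
    raw
  } else {
    out <- as.list(raw)
    for (m in names(bounds)) {
      if (m %in% names(out)) out[[m]] <- scale1(out[[m]], bounds[[m]])
    }
    out
  }
}

# Fast per-participant marker computation on the cohort's column-oriented
# streams (equivalent to the sensor_day API; equivalence is tested).
participant_markers <- function(p, ema_per_day) {
  sd_df <- p$sensor_days
  present <- which(!sd_df$missing)
  beh <- c(
    physical_activity_level = NA_real_, physical_activity_variance = NA_real_,
    distance_traveled_from_home = NA_real_,
    distance_traveled_variance = NA_real_
  )
  if (length(present) >= 2 && nrow(p$locations) > 0) {
    loc <- p$locations
    idx <- split(seq_len(nrow(loc)), loc$day_index)
    homes <- t(vapply(idx, function(ii) {
      home_from_xy(loc$x[ii], loc$y[ii])
    }, numeric(2)))
    home <- modal_home(homes)
    dist <- sqrt((loc$x - home[1])^2 + (loc$y - home[2])^2)
    daily_dist <- vapply(idx, function(ii) mean(dist[ii]), numeric(1))
    act <- sd_df$accel_total[present]
    beh <- c(
      physical_activity_level = mean(act),
      physical_activity_variance = pop_var(act),
      distance_traveled_from_home = mean(daily_dist),
      distance_traveled_variance = pop_var(daily_dist)
    )
  }
  scheduled <- nrow(sd_df) * ema_per_day
  ema <- ema_markers(p$ema$value, scheduled)
  nb <- nback_markers(p$nback$accuracy[order(p$nback$day_index)])
  c(
    age = p$age, education_years = as.numeric(p$education_years), beh, ema, nb
  )
}

#' Extract the marker table from a cohort
#'
#' One row per participant with the raw (unscaled) numeric markers plus
#' `id`, `pseudonym`, `label` and `sex`. Markers that cannot be computed
#' (too few non-missing days, no EMA answers, fewer than 6 n-back scores)
#' are `NA`.
#'
#' @param cohort A [generate_cohort()] result (or object read by
#'   [read_cohort()]).
#' @return Data frame of markers.
#' @export
extract_markers <- function(cohort) {
  epd <- cohort$config$ema_per_day %||% 4L
  rows <- lapply(cohort$participants, function(p) {
    m <- participant_markers(p, epd)
    cbind(
      data.frame(
        id = p$id, pseudonym = p$pseudonym, label = p$label, sex = p$sex,
        stringsAsFactors = FALSE
      ),
      as.data.frame(as.list(m))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
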