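# Shared fixtures and independent oracles. Expensive cohorts are built once
# per session and memoized.

small_config <- function(seed = 1L, effects = default_class_effects(), ...) {
  cohort_config(
    n_total = 40L, n_healthy = 20L, n_mci = 20L, n_female = 20L,
    extra_days_mean = 2, seed = seed, class_effects = effects, ...
  )
}

default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_config())
    cache
  }
})

default_markers <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- extract_markers(default_cohort())
    cache
  }
})

big_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(
        n_total = 2000L, n_healthy = 1210L, n_mci = 790L, n_female = 1435L,
        seed = 42L
      ))
    }
    cache
  }
})

# Two-sample permutation test for a difference in means (the location-test
# oracle); two-sided p-value.
perm_pvalue <- function(x, y, n_perm = 1999, seed = 1) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  n <- length(x)
  withr::with_seed(seed, {
    perm <- replicate(n_perm, {
      idx <- sample.int(length(pooled), n)
      mean(pooled[idx]) - mean(pooled[-idx])
    })
  })
  (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
}

# Independent linear-scan oracle for a rule's support and confidence on a
# marker table (kept free of the package's matching code).
oracle_pa_pr <- function(rule, markers, labels) {
  match_row <- vapply(seq_len(nrow(markers)), function(i) {
    all(vapply(rule$conditions, function(cn) {
      v <- markers[[cn$marker]][i]
      if (cn$op == "<=") v <= cn$value
      else if (cn$op == ">") v > cn$value
      else v == cn$value
    }, logical(1)))
  }, logical(1))
  pa <- sum(match_row)
  if (pa == 0) {
    return(c(pa = 0, pr = NA))
  }
  c(pa = pa, pr = 100 * sum(labels[match_row] == rule$consequent) / pa)
}

# Confusion-matrix oracle for the metric suite.
oracle_metrics <- function(pred, lab) {
  tp <- sum(pred == "mci" & lab == "mci")
  fp <- sum(pred == "mci" & lab == "healthy")
  fn <- sum(pred == "healthy" & lab == "mci")
  tn <- sum(pred == "healthy" & lab == "healthy")
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (d == 0) 0 else (tp * tn - fp * fn) / sqrt(d)
  c(accuracy = (tp + tn) / length(lab), mci_precision = prec,
    mci_recall = rec, mcc = mcc)
}

# Marker table with a planted decision stump: label is determined by
# `marker > threshold` up to a fixed flip rate; other markers are noise.
planted_stump_table <- function(n, threshold = 4.5, flip = 0.10, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(
      shape_score_sd = sample(0:10, n, replace = TRUE),
      mental_sharpness_mean = sample(0:10, n, replace = TRUE),
      EMA_compliance = sample(0:10, n, replace = TRUE)
    )
    lab <- ifelse(df$shape_score_sd > threshold, "mci", "healthy")
    flips <- stats::runif(n) < flip
    lab[flips] <- ifelse(lab[flips] == "mci", "healthy", "mci")
    list(markers = df, labels = lab)
  })
}

# Synthetic analysis-set (prep) built directly at the marker level, for
# wrapper tests that do not need raw streams. Journals empty, ratings
# absent, so only numeric groups carry information.
synthetic_prep <- function(markers_raw) {
  ids <- markers_raw$id
  feats <- lapply(ids, function(i) journal_features(character(0)))
  names(feats) <- ids
  ratings <- lapply(ids, function(i) stats::setNames(integer(0), character(0)))
  names(ratings) <- ids
  list(
    markers_raw = markers_raw, features = feats, ratings = ratings,
    ids = ids, labels = stats::setNames(markers_raw$label, ids)
  )
}

# Random complete marker table; `signal_group` (if any) gets separated
# class-conditional values.
random_marker_table <- function(n, seed, signal_group = NULL) {
  withr::with_seed(seed, {
    lab <- rep(c("healthy", "mci"), length.out = n)
    df <- data.frame(
      id = sprintf("S%04d", seq_len(n)), label = lab,
      sex = sample(c("female", "male"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (m in setdiff(marker_names(), "sex")) {
      df[[m]] <- stats::runif(n, 0, 10)
    }
    df$age <- stats::runif(n, 55, 90)
    df$education_years <- sample(10:20, n, replace = TRUE)
    if (!is.null(signal_group)) {
      for (m in marker_groups()[[signal_group]]$markers) {
        if (m == "sex") next
        df[[m]] <- ifelse(lab == "mci", stats::runif(n, 6, 10),
          stats::runif(n, 0, 4))
      }
    }
    df
  })
}
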