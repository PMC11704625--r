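# Reference/training/test split protocol, metric suite, wrapper-based
# greedy fusion over marker-set rule groups, and repeated-run evaluation
# with mean +/- SD reporting.

behavior_complete_markers <- function() {
  c(
    "physical_activity_level", "physical_activity_variance",
    "distance_traveled_from_home", "distance_traveled_variance",
    "mental_sharpness_mean", "mental_sharpness_variance", "EMA_compliance",
    "shape_learning_rate", "shape_score_mean", "shape_score_sd"
  )
}

#' Split a cohort into reference, training and test sets
#'
#' Participants eligible for training/test must have complete behavior, EMA
#' and n-back markers. The test set holds `n_test_per_class` randomly chosen
#' eligible participants per class; the reference set is everyone else; the
#' training set is `n_train_per_class` eligible reference participants per
#' class. Deterministic given `seed`.
#'
#' @param markers Marker table from [extract_markers()].
#' @param seed Integer seed.
#' @param n_test_per_class,n_train_per_class Per-class counts (defaults 24
#'   and 25).
#' @return A `cohort_split`: list of `test`, `reference`, `training` id
#'   vectors plus `seed`.
#' @export
make_split <- function(markers, seed, n_test_per_class = 24L,
                       n_train_per_class = 25L) {
  complete <- stats::complete.cases(
    markers[, behavior_complete_markers(), drop = FALSE]
  )
  withr::with_seed(seed, {
    test <- character(0)
    for (cls in class_labels()) {
      pool <- markers$id[complete & markers$label == cls]
      if (length(pool) < n_test_per_class + n_train_per_class) {
        cogdx_stop(
          sprintf(
            "class '%s' has %d eligible participants; need >= %d",
            cls, length(pool), n_test_per_class + n_train_per_class
          ),
          "cogdx_insufficient_data"
        )
      }
      test <- c(test, sample(pool, n_test_per_class))
    }
    reference <- setdiff(markers$id, test)
    training <- character(0)
    for (cls in class_labels()) {
      pool <- markers$id[complete & markers$label == cls &
        markers$id %in% reference]
      training <- c(training, sample(pool, n_train_per_class))
    }
    structure(
      list(test = test, reference = reference, training = training,
        seed = seed),
      class = "cohort_split"
    )
  })
}

#' Classification metrics
#'
#' Accuracy, precision and recall for the MCI (positive) class, and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' whenever a factor of the denominator is 0 (precision and recall likewise
#' default to 0 on an empty denominator).
#'
#' @param predictions,labels Equal-length character vectors of
#'   `"healthy"`/`"mci"`.
#' @param positive Positive class (default `"mci"`).
#' @return Named numeric vector `accuracy`, `mci_precision`, `mci_recall`,
#'   `mcc`.
#' @export
compute_metrics <- function(predictions, labels, positive = "mci") {
  if (length(predictions) != length(labels) || length(labels) == 0) {
    cogdx_stop("predictions and labels must be equal-length and non-empty",
      "cogdx_config_error")
  }
  tp <- sum(predictions == positive & labels == positive)
  fp <- sum(predictions == positive & labels != positive)
  fn <- sum(predictions != positive & labels == positive)
  tn <- sum(predictions != positive & labels != positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  denom2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0
  c(
    accuracy = (tp + tn) / length(labels),
    mci_precision = prec, mci_recall = rec, mcc = mcc
  )
}

# Precompute everything per-participant the pipeline reuses across runs.
prepare_analysis <- function(cohort) {
  markers_raw <- extract_markers(cohort)
  features <- lapply(cohort$participants, function(p) {
    journal_features(p$journal_texts)
  })
  ratings <- lapply(cohort$participants, `[[`, "interview_ratings")
  ids <- markers_raw$id
  names(features) <- ids
  names(ratings) <- ids
  list(
    markers_raw = markers_raw, features = features, ratings = ratings,
    ids = ids, labels = stats::setNames(markers_raw$label, ids)
  )
}

# Induce the rule set for one marker-set group on given training ids.
group_rules <- function(group_name, prep, scaled, train_ids, opts) {
  g <- marker_groups()[[group_name]]
  if (!is.null(g$text_source)) {
    return(bundled_text_rules(g$text_source))
  }
  rows <- match(train_ids, scaled$id)
  induce_rules(
    scaled[rows, g$markers, drop = FALSE],
    prep$labels[train_ids],
    max_depth = opts$max_depth, min_support_frac = opts$min_support_frac,
    min_confidence_pct = opts$min_confidence_pct, n_trees = opts$n_trees,
    seed = opts$seed
  )
}

default_engine_opts <- function(...) {
  opts <- list(
    max_depth = 2L, min_support_frac = 0.10, min_confidence_pct = 70,
    n_trees = 1L, seed = 1L, policy = "confidence_weighted",
    text_confidence = 75
  )
  utils::modifyList(opts, list(...))
}

# Fit scale/thresholds on the reference set, induce rules per group on the
# training set, classify the given ids with the deterministic engine.
run_pipeline <- function(prep, split, groups, opts, predict_ids = split$test) {
  ref_rows <- match(split$reference, prep$markers_raw$id)
  bounds <- fit_scale(prep$markers_raw[ref_rows, , drop = FALSE])
  scaled <- apply_scale(prep$markers_raw, bounds)
  thresholds <- tryCatch(
    fit_text_thresholds(prep$features[split$reference]),
    error = function(e) NULL
  )
  rules <- list()
  zero_groups <- character(0)
  for (g in groups) {
    gr <- group_rules(g, prep, scaled, split$training, opts)
    if (length(gr) == 0) zero_groups <- c(zero_groups, g)
    rules <- c(rules, gr)
  }
  if (length(zero_groups) > 0) {
    warning(
      "no rules survived filtering for group(s): ",
      paste(zero_groups, collapse = ", "),
      "; affected predictions fall back to the majority class"
    )
  }
  marker_cols <- intersect(marker_names(), names(scaled))
  predictions <- vapply(predict_ids, function(id) {
    row <- scaled[match(id, scaled$id), , drop = FALSE]
    if (length(rules) == 0) {
      return("healthy")
    }
    applied <- apply_rules(
      as.list(row[, marker_cols, drop = FALSE]), rules,
      features = prep$features[[id]], ratings = prep$ratings[[id]],
      thresholds = thresholds, text_confidence = opts$text_confidence
    )
    aggregate_votes(applied, opts$policy)
  }, character(1))
  list(
    predictions = predictions, labels = prep$labels[predict_ids],
    rules = rules, bounds = bounds, thresholds = thresholds
  )
}

#' Wrapper-based greedy group selection
#'
#' Greedy forward selection over the marker-set rule groups: starting from
#' the empty set, each step adds the group that maximizes
#' deterministic-engine accuracy under an internal stratified k-fold
#' cross-validation of the training set, stopping when no addition strictly
#' improves. Ties prefer the candidate set inducing fewer rules, then the
#' fixed group order.
#'
#' @param cohort A cohort (or a prepared analysis from the internal
#'   pipeline).
#' @param split A [make_split()] result.
#' @param groups Candidate group names (default all six).
#' @param seed Seed for fold assignment.
#' @param n_folds Cross-validation folds (default 5).
#' @param opts Engine options.
#' @return List with `selected`, `cv_accuracy` and the greedy `trace`.
#' @export
wrapper_select <- function(cohort, split, groups = names(marker_groups()),
                           seed = 1L, n_folds = 5L,
                           opts = default_engine_opts()) {
  if (length(groups) == 0) {
    cogdx_stop("no candidate groups", "cogdx_config_error")
  }
  prep <- if (inherits(cohort, "cohort")) prepare_analysis(cohort) else cohort
  train <- split$training
  folds <- withr::with_seed(seed, {
    f <- integer(length(train))
    names(f) <- train
    for (cls in class_labels()) {
      ids <- sample(train[prep$labels[train] == cls])
      f[ids] <- rep_len(seq_len(n_folds), length(ids))
    }
    f
  })
  cv_accuracy <- function(gset) {
    accs <- vapply(seq_len(n_folds), function(k) {
      heldout <- train[folds == k]
      sub_split <- split
      sub_split$training <- train[folds != k]
      run <- run_pipeline(prep, sub_split, gset, opts,
        predict_ids = heldout)
      mean(run$predictions == run$labels)
    }, numeric(1))
    mean(accs)
  }
  n_rules_of <- function(gset) {
    sum(vapply(gset, function(g) {
      length(suppressWarnings(
        group_rules(g, prep,
          apply_scale(prep$markers_raw,
            fit_scale(prep$markers_raw[
              match(split$reference, prep$markers_raw$id), , drop = FALSE])),
          split$training, opts)
      ))
    }, numeric(1)))
  }
  selected <- character(0)
  best_acc <- mean(prep$labels[train] == "healthy") # empty set: all healthy
  trace <- list()
  eps <- 1e-9
  repeat {
    remaining <- setdiff(groups, selected)
    if (length(remaining) == 0) break
    step_best <- NULL
    for (g in remaining) {
      acc <- suppressWarnings(cv_accuracy(c(selected, g)))
      nr <- suppressWarnings(n_rules_of(c(selected, g)))
      better <- is.null(step_best) ||
        acc > step_best$acc + eps ||
        (abs(acc - step_best$acc) <= eps && nr < step_best$nr)
      if (better) step_best <- list(group = g, acc = acc, nr = nr)
    }
    trace[[length(trace) + 1]] <- data.frame(
      step = length(selected) + 1, group = step_best$group,
      cv_accuracy = step_best$acc, stringsAsFactors = FALSE
    )
    if (step_best$acc <= best_acc + eps) break
    selected <- c(selected, step_best$group)
    best_acc <- step_best$acc
  }
  if (length(selected) == 0) {
    # all-noise fallback: report the best single group
    selected <- trace[[1]]$group
    best_acc <- trace[[1]]$cv_accuracy
  }
  list(
    selected = selected, cv_accuracy = best_acc,
    trace = do.call(rbind, trace)
  )
}

#' Repeated-run evaluation
#'
#' Runs the pipeline `n_runs` times and reports per-run metrics with their
#' mean and SD. `mode = "resample_split"` re-draws the
#' reference/training/test split each run (the package's configurable
#' analogue of backend nondeterminism); `mode = "fixed_split"` repeats one
#' split, under which the deterministic engine gives SD exactly 0.
#'
#' @param cohort A cohort object.
#' @param groups Group names to include, or `"all"`.
#' @param n_runs Number of repetitions (default 30).
#' @param mode Run-to-run variability source.
#' @param wrapper Run wrapper selection inside each run.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param split Optional fixed split (for `mode = "fixed_split"`).
#' @param opts Engine options from [default_engine_opts()].
#' @return An `evaluation_report`: per-run metric data frame, `mean`, `sd`,
#'   `n_runs`, `mode`, `selected` (per-run wrapper selections), `config`.
#' @export
evaluate_runs <- function(cohort, groups = "all", n_runs = 30L,
                          mode = c("resample_split", "fixed_split"),
                          wrapper = FALSE, seed = 1L, split = NULL,
                          opts = default_engine_opts()) {
  stopifnot(n_runs >= 1)
  mode <- match.arg(mode)
  if (identical(groups, "all")) groups <- names(marker_groups())
  prep <- if (inherits(cohort, "cohort")) prepare_analysis(cohort) else cohort
  run_seeds <- derive_seeds(seed, n_runs)
  base_split <- split %||% make_split(prep$markers_raw, seed)
  runs <- list()
  selected <- list()
  predictions <- list()
  for (r in seq_len(n_runs)) {
    split_r <- if (mode == "resample_split") {
      make_split(prep$markers_raw, run_seeds[r])
    } else {
      base_split
    }
    groups_r <- groups
    if (wrapper) {
      sel <- wrapper_select(prep, split_r, groups,
        seed = run_seeds[r], opts = opts)
      groups_r <- sel$selected
      selected[[r]] <- sel$selected
    }
    run <- suppressWarnings(run_pipeline(prep, split_r, groups_r, opts))
    m <- compute_metrics(run$predictions, run$labels)
    predictions[[r]] <- list(
      predictions = run$predictions, labels = run$labels
    )
    runs[[r]] <- data.frame(
      run = r, seed = run_seeds[r], t(m), stringsAsFactors = FALSE
    )
  }
  runs <- do.call(rbind, runs)
  metric_cols <- c("accuracy", "mci_precision", "mci_recall", "mcc")
  report <- list(
    runs = runs,
    predictions = predictions,
    mean = vapply(runs[metric_cols], mean, numeric(1)),
    sd = vapply(runs[metric_cols], function(x) {
      if (length(x) > 1) stats::sd(x) else 0
    }, numeric(1)),
    n_runs = n_runs, mode = mode,
    selected = if (wrapper) selected else NULL,
    config = list(groups = groups, wrapper = wrapper, seed = seed,
      opts = opts)
  )
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d run(s), mode=%s\n", x$n_runs, x$mode))
  for (m in names(x$mean)) {
    cat(sprintf("  %-14s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Compare single marker-set groups against fused rule sets
#'
#' One evaluation per single group, one with all groups, and one with
#' wrapper selection, in that fixed order (8 rows), all on the same split.
#'
#' @param cohort A cohort object.
#' @param split Optional fixed [make_split()] split (made from `seed`
#'   otherwise).
#' @param seed Seed.
#' @param n_runs Runs per report (default 1; the engine is deterministic on
#'   a fixed split).
#' @param opts Engine options.
#' @return A `comparison_table`: named list of reports plus a `summary`
#'   data frame.
#' @export
compare_single_vs_fused <- function(cohort, split = NULL, seed = 1L,
                                    n_runs = 1L,
                                    opts = default_engine_opts()) {
  prep <- if (inherits(cohort, "cohort")) prepare_analysis(cohort) else cohort
  split <- split %||% make_split(prep$markers_raw, seed)
  rows <- c(names(marker_groups()), "all", "wrapper")
  reports <- list()
  for (row in rows) {
    reports[[row]] <- evaluate_runs(
      prep,
      groups = if (row %in% c("all", "wrapper")) "all" else row,
      n_runs = n_runs, mode = "fixed_split",
      wrapper = row == "wrapper", seed = seed, split = split, opts = opts
    )
  }
  summary <- do.call(rbind, lapply(rows, function(row) {
    data.frame(
      classification = row, t(reports[[row]]$mean),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(reports = reports, summary = summary, split = split),
    class = "comparison_table"
  )
}

#' @export
print.comparison_table <- function(x, ...) {
  print(x$summary, digits = 3)
  invisible(x)
}
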