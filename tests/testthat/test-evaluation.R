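test_that("split sizes, disjointness and balance hold across 1000 seeds", {
  mk <- default_markers()
  ok <- vapply(1:1000, function(seed) {
    s <- make_split(mk, seed)
    length(s$test) == 48 && length(s$reference) == 76 &&
      length(s$training) == 50 &&
      length(intersect(s$test, s$reference)) == 0 &&
      all(s$training %in% s$reference) &&
      sum(mk$label[mk$id %in% s$test] == "mci") == 24 &&
      sum(mk$label[mk$id %in% s$training] == "mci") == 25
  }, logical(1))
  expect_true(all(ok))
  # reference composition is forced by the cohort's class totals
  s <- make_split(mk, 1)
  ref_labs <- mk$label[mk$id %in% s$reference]
  expect_equal(sum(ref_labs == "healthy"), 51)
  expect_equal(sum(ref_labs == "mci"), 25)
  s2 <- make_split(mk, 2)
  expect_false(setequal(s$test, s2$test))
  expect_error(make_split(mk[1:60, ], 1),
    "eligible", class = "cogdx_insufficient_data")
})

test_that("compute_metrics matches hand arithmetic and conventions", {
  perfect <- compute_metrics(c("mci", "healthy"), c("mci", "healthy"))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  # TP=3 FP=1 FN=2 TN=4
  pred <- c(rep("mci", 4), rep("healthy", 6))
  lab <- c(rep("mci", 3), "healthy", rep("mci", 2), rep("healthy", 4))
  m <- compute_metrics(pred, lab)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["mci_precision"]), 0.75)
  expect_equal(unname(m["mci_recall"]), 0.6)
  expect_equal(unname(m["mcc"]), 10 / sqrt(600))
  all_h <- compute_metrics(rep("healthy", 6), rep(c("mci", "healthy"), 3))
  expect_equal(unname(all_h["mcc"]), 0)
  expect_error(compute_metrics("mci", c("mci", "healthy")),
    class = "cogdx_config_error")
})

test_that("compute_metrics equals the confusion oracle on random vectors", {
  withr::with_seed(99, {
    ok <- vapply(1:1000, function(i) {
      n <- sample(2:40, 1)
      pred <- sample(c("healthy", "mci"), n, replace = TRUE)
      lab <- sample(c("healthy", "mci"), n, replace = TRUE)
      isTRUE(all.equal(compute_metrics(pred, lab),
        oracle_metrics(pred, lab)))
    }, logical(1))
  })
  expect_true(all(ok))
})

test_that("wrapper selection finds a planted dominant group", {
  prep <- synthetic_prep(random_marker_table(148, seed = 6,
    signal_group = "nback"))
  split <- make_split(prep$markers_raw, 3)
  sel <- suppressWarnings(wrapper_select(prep, split, seed = 3))
  expect_equal(sel$selected[1], "nback")
  expect_gt(sel$cv_accuracy, 0.9)
  # deterministic given seed and data
  sel2 <- suppressWarnings(wrapper_select(prep, split, seed = 3))
  expect_identical(sel, sel2)
  expect_error(wrapper_select(prep, split, groups = character(0)),
    class = "cogdx_config_error")
})

test_that("all-noise groups leave wrapper accuracy near chance", {
  accs <- vapply(1:10, function(seed) {
    prep <- synthetic_prep(random_marker_table(148, seed = 100 + seed))
    split <- make_split(prep$markers_raw, seed)
    sel <- suppressWarnings(wrapper_select(prep, split, seed = seed))
    run <- suppressWarnings(
      cogdx:::run_pipeline(prep, split, sel$selected,
        cogdx:::default_engine_opts())
    )
    mean(run$predictions == run$labels)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("fixed-split deterministic runs collapse to SD zero", {
  prep <- synthetic_prep(random_marker_table(148, seed = 6,
    signal_group = "nback"))
  split <- make_split(prep$markers_raw, 5)
  rep <- evaluate_runs(prep, groups = "nback", n_runs = 5,
    mode = "fixed_split", split = split, seed = 5)
  expect_equal(rep$n_runs, 5)
  expect_true(all(rep$sd == 0))
  expect_equal(length(unique(rep$runs$accuracy)), 1)
})

test_that("split resampling produces run-to-run variability", {
  rep <- evaluate_runs(default_cohort(), groups = "demographics",
    n_runs = 10, mode = "resample_split", seed = 2)
  expect_true(any(rep$sd > 0))
})

test_that("report metrics recompute from the stored per-run predictions", {
  rep <- evaluate_runs(default_cohort(), groups = c("nback", "ema"),
    n_runs = 3, mode = "resample_split", seed = 8)
  for (r in seq_len(rep$n_runs)) {
    stored <- rep$predictions[[r]]
    m <- compute_metrics(stored$predictions, stored$labels)
    expect_equal(unlist(rep$runs[r, names(m)]), m, ignore_attr = TRUE)
  }
})

test_that("single-group comparison has 8 rows and finds the planted group", {
  eff <- default_class_effects()
  # neutralize everything except the n-back parameters
  for (p in setdiff(names(eff$mci), c("nback_start_mu", "nback_start_sd",
    "nback_plateau_mu", "nback_plateau_sd", "nback_noise_sd"))) {
    eff$mci[[p]] <- eff$healthy[[p]]
  }
  co <- generate_cohort(cohort_config(
    n_total = 148L, n_healthy = 74L, n_mci = 74L, n_female = 74L,
    class_effects = eff, seed = 19L
  ))
  cmp <- suppressWarnings(compare_single_vs_fused(co, seed = 4))
  expect_equal(nrow(cmp$summary), 8)
  expect_equal(cmp$summary$classification,
    c(names(marker_groups()), "all", "wrapper"))
  singles <- cmp$summary[seq_len(6), ]
  expect_equal(singles$classification[which.max(singles$accuracy)], "nback")
  # greedy trace on the selection criterion is non-decreasing
  sel <- cmp$reports$wrapper$selected[[1]]
  expect_true("nback" %in% sel)
})

test_that("a group with no surviving rules warns and predicts majority", {
  # constant demographics admit no split at all, so no candidate rules
  mk <- random_marker_table(148, seed = 55)
  mk$age <- 70
  mk$education_years <- 12
  mk$sex <- "female"
  prep <- synthetic_prep(mk)
  split <- make_split(prep$markers_raw, 2)
  expect_warning(
    run <- cogdx:::run_pipeline(prep, split, "demographics",
      cogdx:::default_engine_opts()),
    "no rules survived"
  )
  expect_true(all(run$predictions == "healthy"))
})
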