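test_that("build_prompt renders the fixed layout deterministically", {
  sl <- sloan_example()
  p <- build_prompt(sl$participant$name, sl$participant$markers, sl$rules,
    sl$participant$journal_texts, sl$participant$ratings)
  expect_match(p, "Rule #3", fixed = TRUE)
  expect_match(p, "shape_score_sd: 6", fixed = TRUE)
  expect_match(p, "Diagnosis Rules:", fixed = TRUE)
  expect_match(p, "Sloan's Information:", fixed = TRUE)
  expect_match(p, "Answer using the format:", fixed = TRUE)
  p2 <- build_prompt(sl$participant$name, sl$participant$markers, sl$rules,
    sl$participant$journal_texts, sl$participant$ratings)
  expect_identical(p, p2)
  expect_error(build_prompt("Ann", sl$participant$markers, list()),
    class = "cogdx_config_error")
  expect_error(
    build_prompt("Ann", list(age = 70), sl$rules),
    "shape_score_sd", class = "cogdx_missing_marker"
  )
})

test_that("parse_response extracts labels case-insensitively", {
  box <- paste0("Diagnosis: Mild cognitive impairment\n",
    "Explanation: Based on the provided information, ...")
  r <- parse_response(box)
  expect_equal(r$label, "mci")
  expect_match(r$explanation, "^Based on the provided information")
  expect_equal(parse_response("diagnosis: HEALTHY")$label, "healthy")
  expect_error(parse_response("I am not sure."),
    class = "cogdx_unparseable_response")
})

test_that("apply_rules honors boundary semantics and missing markers", {
  rules <- parse_rules(c(
    "if shape_score_sd <= 2.5 then more likely healthy # pr=60.00 pa=10",
    "if shape_score_sd > 2.5 then more likely mild cognitive impairment # pr=70.00 pa=10",
    "if EMA_compliance <= 9.5 then more likely mild cognitive impairment # pr=80.00 pa=10"
  ))
  at_boundary <- apply_rules(
    list(shape_score_sd = 2.5, EMA_compliance = NA), rules)
  expect_true(at_boundary$fired[1])
  expect_false(at_boundary$fired[2])
  expect_false(at_boundary$fired[3])
  expect_true(at_boundary$missing[3])
})

test_that("fired sets equal an exhaustive condition oracle", {
  withr::with_seed(31, {
    for (i in 1:20) {
      markers <- list(
        shape_score_sd = sample(0:10, 1), EMA_compliance = sample(0:10, 1),
        mental_sharpness_mean = sample(0:10, 1),
        sex = sample(c("female", "male"), 1)
      )
      rules <- induce_rules(
        planted_stump_table(60, seed = i)$markers,
        planted_stump_table(60, seed = i)$labels
      )
      if (length(rules) == 0) next
      got <- apply_rules(markers, rules)$fired
      want <- vapply(rules, function(r) {
        all(vapply(r$conditions, function(cn) {
          v <- markers[[cn$marker]]
          switch(cn$op, "<=" = v <= cn$value, ">" = v > cn$value,
            "=" = v == cn$value)
        }, logical(1)))
      }, logical(1))
      expect_identical(got, want)
    }
  })
})

test_that("aggregate_votes implements the three policies", {
  df <- function(...) {
    rows <- list(...)
    out <- do.call(rbind, lapply(seq_along(rows), function(i) {
      data.frame(rule = i, text = "t", consequent = rows[[i]][[1]],
        pr = rows[[i]][[2]], fired = rows[[i]][[3]], missing = FALSE)
    }))
    out
  }
  none <- df(list("mci", 90, FALSE))
  expect_equal(aggregate_votes(none), "healthy")
  mixed <- df(list("mci", 80, TRUE), list("mci", 75, TRUE),
    list("healthy", 100, TRUE))
  expect_equal(aggregate_votes(mixed), "mci") # 155 > 100
  expect_equal(aggregate_votes(mixed, "majority"), "mci")
  expect_equal(aggregate_votes(mixed, "first_match"), "mci")
  single <- df(list("healthy", 55, TRUE))
  for (pol in c("confidence_weighted", "majority", "first_match")) {
    expect_equal(aggregate_votes(single, pol), "healthy")
  }
  tie <- df(list("mci", 80, TRUE), list("healthy", 80, TRUE))
  expect_equal(aggregate_votes(tie), "healthy")
  expect_error(aggregate_votes(mixed, "quorum"))
})

test_that("confidence-weighted voting is monotone in added mci rules", {
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(1:6, 1)
      applied <- data.frame(
        rule = seq_len(n), text = "t",
        consequent = sample(c("healthy", "mci"), n, replace = TRUE),
        pr = runif(n, 50, 100), fired = sample(c(TRUE, FALSE), n,
          replace = TRUE), missing = FALSE
      )
      before <- aggregate_votes(applied)
      extra <- rbind(applied, data.frame(rule = n + 1, text = "t",
        consequent = "mci", pr = runif(1, 50, 100), fired = TRUE,
        missing = FALSE))
      if (before == "mci") expect_equal(aggregate_votes(extra), "mci")
    }
  })
})

test_that("the Sloan fixture classifies as MCI with rules 1 and 3 fired", {
  sl <- sloan_example()
  dx <- classify(sl$participant, sl$rules, thresholds = sl$thresholds)
  expect_equal(dx$label, "mci")
  expect_true(all(c(1, 3) %in% dx$fired_rules$rule))
})

test_that("healthy-extreme markers fire only healthy bundled rules", {
  markers <- list(
    age = 80, sex = "female", education_years = 16,
    physical_activity_level = 5, physical_activity_variance = 9,
    distance_traveled_from_home = 10, distance_traveled_variance = 10,
    mental_sharpness_mean = 6, mental_sharpness_variance = 0,
    EMA_compliance = 10, shape_learning_rate = 0, shape_score_mean = 9,
    shape_score_sd = 0
  )
  rules <- bundled_numeric_rules()
  applied <- apply_rules(markers, rules)
  expect_true(all(applied$consequent[applied$fired] == "healthy"))
  dx <- classify(list(name = "Ann", markers = markers), rules)
  expect_equal(dx$label, "healthy")
})

test_that("external backends pass through the prompt contract", {
  sl <- sloan_example()
  fixed <- mock_backend("Diagnosis: healthy\nExplanation: fixed.")
  dx <- classify(sl$participant, sl$rules, backend = fixed)
  expect_equal(dx$label, "healthy")
  expect_equal(dx$backend, "mock")
  boom <- structure(
    list(name = "boom", generate = function(prompt) stop("offline")),
    class = "cogdx_backend"
  )
  expect_error(classify(sl$participant, sl$rules, backend = boom),
    "Sloan", class = "cogdx_backend_error")
})

test_that("prompt -> deterministic backend -> parse round-trips classify", {
  sl <- sloan_example()
  be_sl <- deterministic_backend(thresholds = sl$thresholds)
  sloan_direct <- classify(sl$participant, sl$rules,
    thresholds = sl$thresholds)
  sloan_via <- parse_response(be_sl$generate(build_prompt(
    sl$participant$name, sl$participant$markers, sl$rules,
    sl$participant$journal_texts, sl$participant$ratings
  )))
  expect_identical(sloan_via$label, sloan_direct$label)
  cases <- list()
  withr::with_seed(41, {
    for (i in 1:10) {
      cases[[i]] <- list(
        name = paste0("Case", i),
        markers = c(
          stats::setNames(
            as.list(sample(0:10, length(marker_names()) - 1, replace = TRUE)),
            setdiff(marker_names(), "sex")
          ),
          list(sex = sample(c("female", "male"), 1))
        ),
        journal_texts = if (i %% 2) generate_journal("healthy") else
          character(0),
        ratings = stats::setNames(sample(1:5, 4, replace = TRUE),
          paste0("t", 1:4))
      )
    }
  })
  rules <- c(bundled_numeric_rules(), bundled_text_rules())
  thr <- sl$thresholds
  be <- deterministic_backend(thresholds = thr)
  for (p in cases) {
    direct <- classify(p, rules, thresholds = thr)
    via_prompt <- parse_response(be$generate(
      build_prompt(p$name, p$markers, rules, p$journal_texts, p$ratings)
    ))
    expect_identical(via_prompt$label, direct$label, label = p$name)
  }
})

test_that("cohort_query matches a filter-then-summarize oracle", {
  mk <- default_markers()
  expect_equal(
    cohort_query(mk, "healthy", "shape_score_sd", "mean"),
    mean(mk$shape_score_sd[mk$label == "healthy"], na.rm = TRUE)
  )
  expect_equal(
    cohort_query(mk, "healthy", "age", "count") +
      cohort_query(mk, "mci", "age", "count"),
    nrow(mk)
  )
  const <- data.frame(label = c("mci", "mci"), EMA_compliance = c(4, 4))
  expect_equal(cohort_query(const, "mci", "EMA_compliance", "mean"), 4)
  expect_equal(cohort_query(const, "mci", "EMA_compliance", "sd"), 0)
  expect_error(cohort_query(mk, "well", "age", "mean"),
    class = "cogdx_config_error")
  expect_error(cohort_query(mk, "mci", "nope", "mean"),
    class = "cogdx_config_error")
})
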