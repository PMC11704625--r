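tree_leaves <- function(node) {
  if (node$is_leaf) {
    return(list(node))
  }
  c(tree_leaves(node$left), tree_leaves(node$right))
}

test_that("fit_tree splits separable data at a boundary threshold", {
  markers <- data.frame(shape_score_sd = c(0:4, 6:10))
  labels <- rep(c("healthy", "mci"), each = 5)
  tree <- fit_tree(markers, labels, max_depth = 1, min_leaf = 2)
  expect_false(tree$root$is_leaf)
  expect_gt(tree$root$split$threshold, 4)
  expect_lt(tree$root$split$threshold, 6)
  # training accuracy from the leaves is perfect
  acc <- sum(vapply(tree_leaves(tree$root), function(l) {
    sum(labels[l$ids] == l$class)
  }, numeric(1))) / length(labels)
  expect_equal(acc, 1)
})

test_that("uninformative markers leave accuracy near the majority rate", {
  withr::with_seed(4, {
    markers <- data.frame(m = runif(200))
    names(markers) <- "EMA_compliance"
    labels <- sample(rep(c("healthy", "mci"), c(120, 80)))
  })
  tree <- fit_tree(markers, labels, max_depth = 2)
  acc <- sum(vapply(tree_leaves(tree$root), function(l) {
    sum(labels[l$ids] == l$class)
  }, numeric(1))) / length(labels)
  expect_lt(abs(acc - 0.6), 0.1)
})

test_that("tree fitting is deterministic and rejects NA input", {
  tab <- planted_stump_table(200, seed = 3)
  t1 <- fit_tree(tab$markers, tab$labels)
  t2 <- fit_tree(tab$markers, tab$labels)
  expect_identical(cogdx:::serialize_tree(t1), cogdx:::serialize_tree(t2))
  bad <- tab$markers
  bad[1, 1] <- NA
  expect_error(fit_tree(bad, tab$labels), class = "cogdx_missing_data")
  expect_warning(fit_tree(tab$markers[1:5, ], rep("healthy", 5)),
    "single-class")
})

test_that("extracted rules partition stumps and match the scan oracle", {
  tab <- planted_stump_table(120, seed = 7)
  tree <- fit_tree(tab$markers, tab$labels, max_depth = 1)
  rules <- extract_rules(tree, tab$markers, tab$labels)
  expect_length(rules, 2)
  expect_equal(sum(vapply(rules, `[[`, integer(1), "pa")), 120)
  for (seed in 1:5) {
    tab <- planted_stump_table(150, seed = seed)
    tree <- fit_tree(tab$markers, tab$labels, max_depth = 2)
    rules <- extract_rules(tree, tab$markers, tab$labels)
    for (r in rules) {
      o <- oracle_pa_pr(r, tab$markers, tab$labels)
      expect_equal(r$pa, unname(o["pa"]))
      expect_equal(r$pr, unname(o["pr"]))
    }
  }
})

test_that("children's support sums to the parent's at every node", {
  tab <- planted_stump_table(300, seed = 13)
  tree <- fit_tree(tab$markers, tab$labels, max_depth = 2)
  check <- function(node) {
    if (node$is_leaf) {
      return(invisible())
    }
    expect_equal(node$left$n + node$right$n, node$n)
    check(node$left)
    check(node$right)
  }
  check(tree$root)
})

test_that("a pure 6-participant rule reports pr 100, pa 6", {
  markers <- data.frame(
    distance_traveled_from_home = c(rep(10, 6), rep(0, 44))
  )
  labels <- c(rep("healthy", 6), rep(c("healthy", "mci"), 22))
  rules <- extract_rules(
    fit_tree(markers, labels, max_depth = 1, min_leaf = 5),
    markers, labels
  )
  top <- Filter(function(r) r$conditions[[1]]$op == ">", rules)[[1]]
  expect_equal(top$pr, 100)
  expect_equal(top$pa, 6L)
})

test_that("filter boundaries are exact: pa floor and strict pr", {
  mk <- function(pr, pa) {
    r <- parse_rules("if shape_score_sd > 2.5 then more likely healthy")[[1]]
    r$pr <- pr
    r$pa <- as.integer(pa)
    r
  }
  expect_equal(ceiling(0.10 * 50), 5)
  kept <- filter_rules(list(mk(70, 10), mk(70.01, 10), mk(100, 4),
    mk(100, 5)), n_train = 50)
  expect_length(kept, 2)
  expect_true(all(vapply(kept, `[[`, numeric(1), "pr") > 70))
  expect_true(all(vapply(kept, `[[`, integer(1), "pa") >= 5))
  # sorted by pr then pa, descending
  prs <- vapply(kept, `[[`, numeric(1), "pr")
  expect_true(all(diff(prs) <= 0))
})

test_that("stump inversions are appended with measured complement stats", {
  tab <- planted_stump_table(200, flip = 0.25, seed = 2)
  tree <- fit_tree(tab$markers, tab$labels, max_depth = 1)
  candidates <- extract_rules(tree, tab$markers, tab$labels)
  retained <- filter_rules(candidates, 200)
  out <- add_inversions(retained, candidates, 200)
  if (length(retained) == 1) {
    expect_length(out, 2)
    inv <- out[[2]]
    expect_equal(inv$provenance, "inversion")
    o <- oracle_pa_pr(inv, tab$markers, tab$labels)
    expect_equal(inv$pr, unname(o["pr"]))
    expect_equal(inv$pa, unname(o["pa"]))
  }
  # with both sides retained (or no single-condition rules), nothing is added
  expect_identical(add_inversions(candidates, candidates, 200), candidates)
  two_cond <- parse_rules(paste(
    "if shape_score_sd > 2.5 and EMA_compliance <= 5",
    "then more likely mild cognitive impairment # pr=90.00 pa=30"
  ))
  expect_identical(add_inversions(two_cond, candidates, 200), two_cond)
})

test_that("induce_rules combines tree, filters and inversions end to end", {
  tab <- planted_stump_table(400, flip = 0.2, seed = 5)
  rules <- induce_rules(tab$markers, tab$labels)
  expect_gt(length(rules), 0)
  floor_pa <- ceiling(0.1 * 400)
  for (r in rules) {
    expect_gte(r$pa, floor_pa)
    if (r$provenance != "inversion") expect_gt(r$pr, 70)
    o <- oracle_pa_pr(r, tab$markers, tab$labels)
    expect_equal(r$pa, unname(o["pa"]))
    expect_equal(r$pr, unname(o["pr"]))
  }
})

test_that("the rule DSL parses the bundled inventory and round-trips", {
  rules <- bundled_numeric_rules()
  expect_length(rules, 20)
  first <- parse_rules(
    "if distance_traveled_from_home > 4.5 then more likely healthy")[[1]]
  expect_length(first$conditions, 1)
  expect_equal(first$consequent, "healthy")
  # normalization fixpoint: serialize o parse is the identity on its image
  text <- serialize_rules(rules)
  expect_identical(parse_rules(text), rules)
  expect_identical(serialize_rules(parse_rules(text)), text)
  # unicode comparator and case-insensitive 'if' are accepted
  expect_identical(
    parse_rules("If shape_score_sd ≤ 2.5 then more likely healthy"),
    parse_rules("if shape_score_sd <= 2.5 then more likely healthy")
  )
})

test_that("malformed rules fail with the offending line and token", {
  expect_error(parse_rules("if bogus_marker > 1 then more likely healthy"),
    "line 1.*bogus_marker", class = "cogdx_parse_error")
  expect_error(parse_rules("if age = 70 then more likely healthy"),
    "only valid for sex", class = "cogdx_parse_error")
  expect_error(parse_rules("if sex = banana then more likely healthy"),
    class = "cogdx_parse_error")
  expect_error(
    parse_rules("age > 5 then more likely healthy"),
    class = "cogdx_parse_error"
  )
  expect_error(parse_rules("if age > 5 then more likely fine"),
    class = "cogdx_parse_error")
})
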