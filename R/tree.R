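# CART-style decision tree on the scaled marker table and its conversion
# into the filtered, invertible if-then rule set: one candidate rule per
# path prefix, support/confidence filtering, and complementary-rule
# inversion for retained single-condition (stump) rules.

gini <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

majority_label <- function(labels) {
  # tie broken toward healthy, the majority class of the study population
  n_h <- sum(labels == "healthy")
  if (n_h >= length(labels) - n_h) "healthy" else "mci"
}

# Best split of rows `idx`: lowest weighted child Gini, requiring both
# children >= min_leaf. Deterministic tie-break: first marker in column
# order, then lowest threshold. Numeric markers split at midpoints of
# consecutive distinct values; sex splits on equality.
best_split <- function(markers, labels, idx, min_leaf) {
  best <- NULL
  for (m in names(markers)) {
    x <- markers[[m]][idx]
    y <- labels[idx]
    if (is.numeric(x)) {
      ux <- sort(unique(x))
      if (length(ux) < 2) next
      thresholds <- (ux[-1] + ux[-length(ux)]) / 2
      for (t in thresholds) {
        l <- x <= t
        nl <- sum(l)
        if (nl < min_leaf || length(x) - nl < min_leaf) next
        score <- (nl * gini(y[l]) + (length(x) - nl) * gini(y[!l])) /
          length(x)
        if (is.null(best) || score < best$score - 1e-12) {
          best <- list(
            marker = m, type = "numeric", threshold = t, score = score
          )
        }
      }
    } else {
      l <- x == "female"
      nl <- sum(l)
      if (nl < min_leaf || length(x) - nl < min_leaf) next
      score <- (nl * gini(y[l]) + (length(x) - nl) * gini(y[!l])) / length(x)
      if (is.null(best) || score < best$score - 1e-12) {
        best <- list(marker = m, type = "sex", score = score)
      }
    }
  }
  best
}

grow_node <- function(markers, labels, idx, depth, max_depth, min_leaf) {
  node <- list(
    ids = idx, n = length(idx), class = majority_label(labels[idx]),
    depth = depth, is_leaf = TRUE
  )
  if (depth >= max_depth || length(unique(labels[idx])) < 2 ||
    length(idx) < 2 * min_leaf) {
    return(node)
  }
  sp <- best_split(markers, labels, idx, min_leaf)
  if (is.null(sp)) {
    return(node)
  }
  if (sp$type == "numeric") {
    left_cond <- new_condition(sp$marker, "<=", sp$threshold)
    right_cond <- new_condition(sp$marker, ">", sp$threshold)
    l <- markers[[sp$marker]][idx] <= sp$threshold
  } else {
    left_cond <- new_condition("sex", "=", "female")
    right_cond <- new_condition("sex", "=", "male")
    l <- markers[[sp$marker]][idx] == "female"
  }
  node$is_leaf <- FALSE
  node$split <- sp
  node$left_cond <- left_cond
  node$right_cond <- right_cond
  node$left <- grow_node(markers, labels, idx[l], depth + 1, max_depth,
    min_leaf)
  node$right <- grow_node(markers, labels, idx[!l], depth + 1, max_depth,
    min_leaf)
  node
}

#' Fit a binary decision tree
#'
#' CART-style axis-aligned tree with Gini impurity splits on the (scaled)
#' marker table. Split selection is fully deterministic: ties go to the
#' first marker in column order, then the lowest threshold.
#'
#' @param markers Data frame of feature columns only (numeric markers plus
#'   optionally the categorical `sex`).
#' @param labels Character vector of `"healthy"`/`"mci"` labels.
#' @param max_depth Maximum depth (default 2).
#' @param min_leaf Minimum samples per leaf; defaults to the support floor
#'   `ceiling(0.10 * n)`.
#' @return A `cogdx_tree` object.
#' @export
fit_tree <- function(markers, labels, max_depth = 2L, min_leaf = NULL) {
  stopifnot(is.data.frame(markers), nrow(markers) == length(labels))
  if (anyNA(markers)) {
    cogdx_stop("markers contain NA; restrict to complete participants",
      "cogdx_missing_data")
  }
  if (length(unique(labels)) < 2) {
    warning("single-class input; returning a one-leaf tree")
  }
  if (is.null(min_leaf)) min_leaf <- ceiling(0.10 * length(labels))
  root <- grow_node(markers, labels, seq_along(labels), 0L, max_depth,
    min_leaf)
  structure(
    list(root = root, max_depth = max_depth, min_leaf = min_leaf,
      n = length(labels)),
    class = "cogdx_tree"
  )
}

# Serialize tree structure (for determinism checks).
serialize_tree <- function(tree) {
  walk <- function(node, prefix) {
    if (node$is_leaf) {
      return(sprintf("%s<leaf %s n=%d>", prefix, node$class, node$n))
    }
    cond <- if (node$split$type == "numeric") {
      paste(node$split$marker, "<=", format_value(node$split$threshold))
    } else {
      "sex = female"
    }
    c(
      sprintf("%s<split %s n=%d>", prefix, cond, node$n),
      walk(node$left, paste0(prefix, "  ")),
      walk(node$right, paste0(prefix, "  "))
    )
  }
  paste(walk(tree$root, ""), collapse = "\n")
}

#' @export
print.cogdx_tree <- function(x, ...) {
  cat(serialize_tree(x), "\n")
  invisible(x)
}

# Rows of `markers` matching a rule's antecedent (linear scan).
match_antecedent <- function(rule, markers) {
  ok <- rep(TRUE, nrow(markers))
  for (cn in rule$conditions) {
    x <- markers[[cn$marker]]
    ok <- ok & switch(cn$op,
      "<=" = x <= cn$value,
      ">" = x > cn$value,
      "=" = x == cn$value
    )
  }
  which(ok)
}

# Measure pr/pa of an antecedent on the training set and set the majority
# consequent.
measure_rule <- function(conditions, markers, labels,
                         provenance = "tree") {
  r <- new_rule(conditions, "healthy", provenance = provenance)
  idx <- match_antecedent(r, markers)
  if (length(idx) == 0) {
    return(NULL)
  }
  cons <- majority_label(labels[idx])
  r$consequent <- cons
  r$pa <- length(idx)
  r$pr <- 100 * sum(labels[idx] == cons) / length(idx)
  r
}

#' Extract candidate rules from a fitted tree
#'
#' One candidate rule per path prefix (every non-root node, internal or
#' leaf): the antecedent is the conjunction of edge conditions on the path,
#' the consequent is the majority training label among participants matching
#' the antecedent, `pa` is the number of matching participants and `pr` the
#' percentage of them carrying the consequent label. Empty-match paths are
#' excluded.
#'
#' @param tree A [fit_tree()] result.
#' @param markers,labels The training data the tree was fitted on.
#' @return List of candidate rules.
#' @export
extract_rules <- function(tree, markers, labels) {
  out <- list()
  walk <- function(node, conds) {
    if (length(conds) > 0) {
      r <- measure_rule(conds, markers, labels)
      if (!is.null(r)) out[[length(out) + 1]] <<- r
    }
    if (!node$is_leaf) {
      walk(node$left, c(conds, list(node$left_cond)))
      walk(node$right, c(conds, list(node$right_cond)))
    }
  }
  walk(tree$root, list())
  out
}

#' Filter candidate rules by support and confidence
#'
#' Retains rules with `pa >= ceiling(min_support_frac * n_train)` and
#' `pr > min_confidence_pct` (strict), sorted by confidence then support,
#' both descending.
#'
#' @param candidates Candidate rules with measured `pr`/`pa`.
#' @param n_train Training-set size.
#' @param min_support_frac Support floor fraction (default 0.10).
#' @param min_confidence_pct Confidence threshold in percent (default 70).
#' @return Filtered, sorted list of rules.
#' @export
filter_rules <- function(candidates, n_train, min_support_frac = 0.10,
                         min_confidence_pct = 70) {
  floor_pa <- ceiling(min_support_frac * n_train)
  kept <- Filter(
    function(r) r$pa >= floor_pa && r$pr > min_confidence_pct, candidates
  )
  sort_rules(kept)
}

sort_rules <- function(rules) {
  if (length(rules) == 0) {
    return(rules)
  }
  ord <- order(
    -vapply(rules, `[[`, numeric(1), "pr"),
    -vapply(rules, function(r) as.numeric(r$pa), numeric(1)),
    vapply(rules, rule_key, character(1)),
    method = "radix"
  )
  rules[ord]
}

invert_condition <- function(cn) {
  if (cn$op == "=") {
    new_condition(cn$marker, "=", if (cn$value == "male") "female" else "male")
  } else if (cn$op == "<=") {
    new_condition(cn$marker, ">", cn$value)
  } else {
    new_condition(cn$marker, "<=", cn$value)
  }
}

#' Add stump-rule inversions
#'
#' For each retained single-condition tree rule, appends the
#' complementary-condition rule with its own majority consequent and
#' measured `pr`/`pa` taken from the candidate set. Inversions are exempt
#' from the confidence filter but still require the support floor; rules
#' whose antecedent is already retained are not duplicated.
#'
#' @param retained [filter_rules()] output.
#' @param candidates The full candidate set the tree produced.
#' @param n_train Training-set size.
#' @param min_support_frac Support floor fraction (default 0.10).
#' @return `retained` plus inversion rules (provenance `"inversion"`).
#' @export
add_inversions <- function(retained, candidates, n_train,
                           min_support_frac = 0.10) {
  floor_pa <- ceiling(min_support_frac * n_train)
  have <- vapply(retained, function(r) rule_antecedent_text(r), character(1))
  cand_keys <- vapply(candidates, rule_antecedent_text, character(1))
  out <- retained
  for (r in retained) {
    if (length(r$conditions) != 1 || r$provenance != "tree") next
    inv_ant <- rule_antecedent_text(
      new_rule(list(invert_condition(r$conditions[[1]])), "healthy")
    )
    if (inv_ant %in% have) next
    j <- match(inv_ant, cand_keys)
    if (is.na(j)) next
    inv <- candidates[[j]]
    if (inv$pa < floor_pa) next
    inv$provenance <- "inversion"
    have <- c(have, inv_ant)
    out[[length(out) + 1]] <- inv
  }
  out
}

#' Induce the filtered rule set from training markers
#'
#' Fits the decision tree (or several seed-varied bootstrap trees), extracts
#' candidate rules from every path prefix, measures support/confidence on
#' the full training set, applies the support and confidence filters, and
#' appends stump inversions.
#'
#' @param markers Feature data frame (scaled numeric markers, optionally
#'   `sex`).
#' @param labels Class labels.
#' @param max_depth,min_support_frac,min_confidence_pct See [fit_tree()] and
#'   [filter_rules()].
#' @param n_trees Number of trees; trees beyond the first are fitted on
#'   seeded bootstrap resamples and pooled with de-duplication.
#' @param seed Seed for bootstrap resampling (only used when `n_trees > 1`).
#' @return A ruleset (list of rules).
#' @export
induce_rules <- function(markers, labels, max_depth = 2L,
                         min_support_frac = 0.10, min_confidence_pct = 70,
                         n_trees = 1L, seed = 1L) {
  n <- length(labels)
  min_leaf <- ceiling(min_support_frac * n)
  candidates <- list()
  seen <- character(0)
  boot_seeds <- if (n_trees > 1) derive_seeds(seed, n_trees) else seed
  for (k in seq_len(n_trees)) {
    if (k == 1) {
      idx <- seq_len(n)
    } else {
      idx <- withr::with_seed(boot_seeds[k], sample.int(n, n, replace = TRUE))
    }
    tree <- fit_tree(markers[idx, , drop = FALSE], labels[idx],
      max_depth = max_depth, min_leaf = min_leaf)
    # measure every candidate antecedent on the *full* training set
    for (r in extract_rules(tree, markers[idx, , drop = FALSE], labels[idx])) {
      rm <- measure_rule(r$conditions, markers, labels)
      if (is.null(rm)) next
      key <- rule_key(rm)
      if (key %in% seen) next
      seen <- c(seen, key)
      candidates[[length(candidates) + 1]] <- rm
    }
  }
  retained <- filter_rules(candidates, n, min_support_frac,
    min_confidence_pct)
  add_inversions(retained, candidates, n, min_support_frac)
}
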