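# Deterministic diagnosis engine behind the same prompt/response contract an
# LLM backend would fulfill: build a classification prompt, have a backend
# generate "Diagnosis: ... Explanation: ...", and parse the label back out.
# The bundled deterministic backend recovers the rules and markers from the
# prompt text itself, applies the rules and aggregates votes.

diagnosis_system_message <- function() {
  paste0(
    "You are a knowledgeable health assistant designed to diagnose someone ",
    "as \"healthy\" or \"with mild cognitive impairment\" using diagnosis ",
    "rules and relevant personal information."
  )
}

is_text_rule <- function(r) inherits(r, "text_rule")

rule_line <- function(r) {
  if (is_text_rule(r)) serialize_text_rules(list(r)) else
    serialize_rules(list(r), stats = TRUE)
}

#' Build a classification prompt
#'
#' Renders the fixed prompt layout: system message, diagnosis instruction,
#' numbered `Diagnosis Rules:` block, the participant's information block
#' (only markers referenced by at least one numeric rule, plus the journal
#' text when speech rules are present and the interview ratings when
#' testing-session rules are present), and the answer-format instruction.
#' Numeric rule lines carry their `# pr=.. pa=..` stats so a response is
#' reproducible from the prompt alone. Rendering is deterministic.
#'
#' @param name Participant (pseudonym) name.
#' @param markers Named list of the participant's scaled marker values.
#' @param rules Non-empty list of numeric and/or text rules.
#' @param journal_texts Character vector of journal entries.
#' @param ratings Named integer vector of interview ratings.
#' @return The prompt as a single string (class `prompt_context`).
#' @export
build_prompt <- function(name, markers, rules, journal_texts = NULL,
                         ratings = NULL) {
  if (length(rules) == 0) {
    cogdx_stop("rule block must be non-empty", "cogdx_config_error")
  }
  numeric_rules <- Filter(Negate(is_text_rule), rules)
  text_rules <- Filter(is_text_rule, rules)
  needed <- unique(unlist(lapply(numeric_rules, function(r) {
    vapply(r$conditions, `[[`, character(1), "marker")
  })))
  absent <- setdiff(needed, names(markers))
  if (length(absent) > 0) {
    cogdx_stop(
      paste0("markers referenced by rules but absent: ",
        paste(absent, collapse = ", ")),
      "cogdx_missing_marker"
    )
  }
  rule_lines <- vapply(seq_along(rules), function(i) {
    paste0("Rule #", i, ": ", rule_line(rules[[i]]))
  }, character(1))
  info <- vapply(needed, function(m) {
    paste0(m, ": ", format_value(markers[[m]])) }, character(1))
  if (any(vapply(text_rules, `[[`, character(1), "source") == "speech")) {
    jt <- paste(journal_texts %||% character(0), collapse = " | ")
    info <- c(info, paste0("journal_text: ", jt))
  }
  if (any(vapply(text_rules, `[[`, character(1), "source") ==
    "testing_session")) {
    rt <- if (length(ratings) > 0) {
      paste(paste0(names(ratings), ": ", ratings), collapse = "; ")
    } else {
      ""
    }
    info <- c(info, paste0("interview_assessment: ", rt))
  }
  prompt <- paste(
    c(
      diagnosis_system_message(), "",
      paste0(
        "Diagnose ", name, " as healthy or mild cognitive impairment by ",
        "applying the following rules to ", name, "'s information."
      ),
      "", "Diagnosis Rules:", rule_lines, "",
      paste0(name, "'s Information:"), info, "",
      "Answer using the format:", "Diagnosis: ...", "Explanation: ..."
    ),
    collapse = "\n"
  )
  structure(prompt, class = c("prompt_context", "character"))
}

# Recover name, rules, markers, journal entries and ratings from a rendered
# prompt (the deterministic backend's input contract).
parse_prompt <- function(prompt) {
  lines <- strsplit(unclass(prompt), "\n")[[1]]
  name <- sub(
    "^Diagnose (.*) as healthy or mild cognitive impairment.*$", "\\1",
    grep("^Diagnose ", lines, value = TRUE)[1]
  )
  rl <- grep("^Rule #[0-9]+: ", lines, value = TRUE)
  rules <- lapply(rl, function(line) {
    body <- sub("^Rule #[0-9]+: ", "", line)
    tryCatch(parse_rules(body)[[1]], error = function(e) {
      parse_text_rules(body)[[1]]
    })
  })
  info_start <- grep("'s Information:$", lines)[1]
  info_end <- grep("^Answer using the format:", lines)[1]
  info <- lines[(info_start + 1):(info_end - 1)]
  info <- info[nzchar(info)]
  markers <- list()
  journal_texts <- NULL
  ratings <- NULL
  for (line in info) {
    key <- sub(":.*$", "", line)
    val <- sub("^[^:]+: ?", "", line)
    if (key == "journal_text") {
      journal_texts <- if (nzchar(val)) strsplit(val, " | ", fixed = TRUE)[[1]]
        else character(0)
    } else if (key == "interview_assessment") {
      if (nzchar(val)) {
        parts <- strsplit(val, "; ", fixed = TRUE)[[1]]
        ratings <- stats::setNames(
          as.integer(sub("^.*: ", "", parts)),
          sub(": [0-9NA]+$", "", parts)
        )
      } else {
        ratings <- stats::setNames(integer(0), character(0))
      }
    } else if (key == "sex") {
      markers[[key]] <- val
    } else {
      markers[[key]] <- as.numeric(val)
    }
  }
  list(
    name = name, rules = rules, markers = markers,
    journal_texts = journal_texts, ratings = ratings
  )
}

#' Parse a diagnosis response
#'
#' Case-insensitive regular-expression extraction of
#' `Diagnosis: (healthy|mild cognitive impairment)`; the explanation is
#' whatever follows `Explanation:`, empty if absent.
#'
#' @param text Response text.
#' @return List with `label` (`"healthy"`/`"mci"`) and `explanation`.
#' @export
parse_response <- function(text) {
  m <- regmatches(text, regexpr(
    "diagnosis:\\s*(healthy|mild cognitive impairment)",
    text, ignore.case = TRUE
  ))
  if (length(m) == 0) {
    cond <- errorCondition(
      paste0("unparseable diagnosis response: ", substr(text, 1, 200)),
      class = c("cogdx_unparseable_response", "cogdx_error"),
      response = text
    )
    stop(cond)
  }
  lab <- trimws(sub("^diagnosis:\\s*", "", tolower(m)))
  expl <- ""
  em <- regmatches(text, regexpr("[Ee]xplanation:", text))
  if (length(em) > 0) {
    expl <- trimws(sub("^.*?[Ee]xplanation:", "", text))
  }
  list(
    label = if (lab == "healthy") "healthy" else "mci",
    explanation = expl
  )
}

#' Apply diagnosis rules to one participant
#'
#' A numeric rule fires iff every condition holds on the participant's
#' (scaled) markers, comparisons exactly as written (`<=`, `>`, `=`).
#' Conditions on missing (`NA`) markers make the rule not fire and flag it.
#' Text rules are evaluated as deterministic predicates over the journal
#' features and ratings, and carry the configured pseudo-confidence.
#'
#' @param markers Named list of scaled marker values (plus `sex`).
#' @param rules Mixed list of numeric and text rules.
#' @param features Optional [journal_features()]; computed from
#'   `journal_texts` when omitted.
#' @param journal_texts Journal entries (used if `features` is `NULL`).
#' @param ratings Named integer vector of interview ratings.
#' @param thresholds [fit_text_thresholds()] result for vocabulary/sentence
#'   predicates.
#' @param text_confidence Pseudo-confidence assigned to text rules
#'   (default 75).
#' @return Data frame with one row per rule: `rule`, `text`, `consequent`,
#'   `pr`, `fired`, `missing`.
#' @export
apply_rules <- function(markers, rules, features = NULL,
                        journal_texts = NULL, ratings = NULL,
                        thresholds = NULL, text_confidence = 75) {
  if (length(rules) == 0) {
    return(data.frame(
      rule = integer(0), text = character(0), consequent = character(0),
      pr = numeric(0), fired = logical(0), missing = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(features) && any(vapply(rules, is_text_rule, logical(1)))) {
    features <- journal_features(journal_texts %||% character(0))
  }
  rows <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    if (is_text_rule(r)) {
      res <- eval_text_predicate(r$predicate, features, ratings, thresholds)
      data.frame(
        rule = i, text = serialize_text_rules(list(r)),
        consequent = r$direction, pr = text_confidence,
        fired = res$fired, missing = res$missing, stringsAsFactors = FALSE
      )
    } else {
      fired <- TRUE
      miss <- FALSE
      for (cn in r$conditions) {
        x <- markers[[cn$marker]]
        if (is.null(x) || (!is.character(x) && is.na(x))) {
          fired <- FALSE
          miss <- TRUE
          break
        }
        hold <- switch(cn$op,
          "<=" = x <= cn$value,
          ">" = x > cn$value,
          "=" = x == cn$value
        )
        if (!hold) {
          fired <- FALSE
          break
        }
      }
      data.frame(
        rule = i, text = serialize_rules(list(r), stats = FALSE),
        consequent = r$consequent, pr = if (is.na(r$pr)) text_confidence
          else r$pr,
        fired = fired, missing = miss, stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate fired rules into a label
#'
#' `confidence_weighted` (default): sum rule confidence over fired rules per
#' class; the larger sum wins. `majority`: count fired rules per class.
#' `first_match`: the first fired rule's consequent. No fired rules or an
#' exact tie yield `"healthy"`, the majority class of the study population.
#'
#' @param applied [apply_rules()] output.
#' @param policy Aggregation policy.
#' @return `"healthy"` or `"mci"`.
#' @export
aggregate_votes <- function(applied,
                            policy = c("confidence_weighted", "majority",
                              "first_match")) {
  policy <- match.arg(policy)
  fired <- applied[applied$fired, , drop = FALSE]
  if (nrow(fired) == 0) {
    return("healthy")
  }
  switch(policy,
    confidence_weighted = {
      s_mci <- sum(fired$pr[fired$consequent == "mci"])
      s_h <- sum(fired$pr[fired$consequent == "healthy"])
      if (s_mci > s_h) "mci" else "healthy"
    },
    majority = {
      n_mci <- sum(fired$consequent == "mci")
      n_h <- sum(fired$consequent == "healthy")
      if (n_mci > n_h) "mci" else "healthy"
    },
    first_match = fired$consequent[1]
  )
}

synthesize_explanation <- function(applied, label, detail = FALSE) {
  fired <- applied[applied$fired, , drop = FALSE]
  if (nrow(fired) == 0) {
    return(paste0(
      "No diagnosis rules fired; defaulting to the majority class (healthy)."
    ))
  }
  support <- fired[fired$consequent == label, , drop = FALSE]
  cite <- if (detail) fired else utils::head(support, 3)
  paste0(
    "Based on the provided information, ", nrow(support), " of ",
    nrow(applied), " rules support ", consequent_text(label), ": ",
    paste(paste0("Rule #", cite$rule, " (", cite$text, ")"),
      collapse = "; "), "."
  )
}

#' Deterministic rule-application backend
#'
#' Fulfills the prompt/response contract without any language model: the
#' rules, markers, journal text and ratings are parsed back out of the
#' prompt, the rules are applied, votes aggregated, and a
#' `Diagnosis:/Explanation:` response rendered. Pure and deterministic.
#'
#' @param policy Aggregation policy, see [aggregate_votes()].
#' @param thresholds Text thresholds for vocabulary/sentence predicates.
#' @param text_confidence Pseudo-confidence for text rules.
#' @param detail Cite all fired rules in the explanation instead of the
#'   short form.
#' @return A backend object with `name` and `generate(prompt)`.
#' @export
deterministic_backend <- function(policy = "confidence_weighted",
                                  thresholds = NULL, text_confidence = 75,
                                  detail = FALSE) {
  structure(
    list(
      name = "deterministic",
      generate = function(prompt) {
        ctx <- parse_prompt(prompt)
        applied <- apply_rules(ctx$markers, ctx$rules,
          journal_texts = ctx$journal_texts, ratings = ctx$ratings,
          thresholds = thresholds, text_confidence = text_confidence
        )
        label <- aggregate_votes(applied, policy)
        paste0(
          "Diagnosis: ",
          if (label == "mci") "Mild cognitive impairment" else "Healthy",
          "\nExplanation: ",
          synthesize_explanation(applied, label, detail)
        )
      }
    ),
    class = "cogdx_backend"
  )
}

#' Mock backend returning a fixed response
#'
#' Adapter-shaped stand-in for an external language-model backend; used to
#' exercise the prompt/response contract without network access.
#'
#' @param response The fixed response text to return.
#' @return A backend object.
#' @export
mock_backend <- function(response) {
  structure(
    list(name = "mock", generate = function(prompt) response),
    class = "cogdx_backend"
  )
}

#' Classify one participant
#'
#' With the default deterministic backend this is rule application plus
#' vote aggregation ([apply_rules()] then [aggregate_votes()]), with a
#' synthesized explanation. With any other backend the full prompt contract
#' runs: [build_prompt()], `backend$generate()`, [parse_response()].
#'
#' @param participant List with `name`, `markers` (named list of scaled
#'   values), `journal_texts`, `ratings`.
#' @param rules Mixed list of numeric and text rules.
#' @param backend A backend object; `NULL` (default) uses the direct
#'   deterministic path.
#' @param policy,thresholds,text_confidence,detail See
#'   [deterministic_backend()].
#' @return A `cogdx_diagnosis`: `label`, `explanation`, `fired_rules`,
#'   `policy`, `backend`.
#' @export
classify <- function(participant, rules, backend = NULL,
                     policy = "confidence_weighted", thresholds = NULL,
                     text_confidence = 75, detail = FALSE) {
  if (is.null(backend)) {
    applied <- apply_rules(participant$markers, rules,
      features = participant$features,
      journal_texts = participant$journal_texts,
      ratings = participant$ratings, thresholds = thresholds,
      text_confidence = text_confidence
    )
    label <- aggregate_votes(applied, policy)
    out <- list(
      label = label,
      explanation = synthesize_explanation(applied, label, detail),
      fired_rules = applied[applied$fired, , drop = FALSE],
      policy = policy, backend = "deterministic"
    )
  } else {
    prompt <- build_prompt(participant$name, participant$markers, rules,
      participant$journal_texts, participant$ratings)
    resp <- tryCatch(backend$generate(prompt), error = function(e) {
      cogdx_stop(
        paste0("backend '", backend$name, "' failed for participant '",
          participant$name, "': ", conditionMessage(e)),
        "cogdx_backend_error"
      )
    })
    parsed <- parse_response(resp)
    out <- list(
      label = parsed$label, explanation = parsed$explanation,
      fired_rules = NULL, policy = policy, backend = backend$name
    )
  }
  class(out) <- "cogdx_diagnosis"
  out
}

#' @export
print.cogdx_diagnosis <- function(x, ...) {
  cat("Diagnosis:", consequent_text(x$label), "\n")
  cat("Explanation:", x$explanation, "\n")
  invisible(x)
}

#' Grouped summary statistic of a marker
#'
#' The reference-data calculation contract: a statistic of one marker over
#' the participants carrying a given label.
#'
#' @param markers Marker table ([extract_markers()] output, scaled or raw).
#' @param label `"healthy"` or `"mci"`.
#' @param marker Marker column name.
#' @param statistic One of mean, sd, median, min, max, count (`sd` is the
#'   sample SD).
#' @return A single number.
#' @export
cohort_query <- function(markers, label, marker,
                         statistic = c("mean", "sd", "median", "min", "max",
                           "count")) {
  statistic <- match.arg(statistic)
  if (!label %in% class_labels()) {
    cogdx_stop(paste0("unknown label: ", label), "cogdx_config_error")
  }
  if (!marker %in% names(markers)) {
    cogdx_stop(paste0("unknown marker: ", marker), "cogdx_config_error")
  }
  x <- markers[[marker]][markers$label == label]
  if (statistic == "count") {
    return(length(x))
  }
  x <- x[!is.na(x)]
  switch(statistic,
    mean = mean(x), sd = stats::sd(x), median = stats::median(x),
    min = min(x), max = max(x)
  )
}

#' The Sloan worked example
#'
#' A fixed participant and five-rule subset reproducing the package's
#' worked classification example: Sloan's scaled n-back markers
#' (`shape_learning_rate` 9, `shape_score_sd` 6), a one-sentence journal
#' entry and interview ratings including scores at or below 3. The rule
#' block holds three numeric n-back rules (with their confidences) and two
#' text rules. Text thresholds are synthetic, chosen so the journal does
#' not qualify as rich. Under the deterministic engine Sloan classifies as
#' mild cognitive impairment with rules #1, #3 and #5 fired.
#'
#' @return List with `participant`, `rules`, `thresholds`.
#' @export
sloan_example <- function() {
  rules <- c(
    parse_rules(c(
      "if shape_score_sd > 2.5 then more likely mild cognitive impairment # pr=70.59 pa=17",
      "if shape_score_sd <= 2.5 then more likely healthy # pr=60.61 pa=33",
      "if shape_score_sd > 2.5 and shape_learning_rate > 1.5 then more likely mild cognitive impairment # pr=75.00 pa=16"
    )),
    Filter(
      function(r) r$predicate %in% c("journal_rich", "ratings_some_low"),
      bundled_text_rules()
    )
  )
  participant <- list(
    name = "Sloan",
    markers = list(
      age = 57, sex = "female", education_years = 14,
      shape_learning_rate = 9, shape_score_sd = 6,
      EMA_compliance = 8, physical_activity_level = 4,
      mental_sharpness_mean = 6, mental_sharpness_variance = 5
    ),
    journal_texts = paste0(
      "made a list and went to the store and got everything on it and ",
      "didn't alter from it"
    ),
    ratings = c(
      "Category Fluency (Animals)" = 2L, "Letter Fluency (F)" = 3L,
      "Delayed Recall" = 3L, "Health Literacy" = 4L
    )
  )
  thresholds <- structure(
    list(
      vocabulary_size = 60, mean_sentence_length = 14,
      sentence_complexity = 2, quantile = 0.5
    ),
    class = "text_thresholds"
  )
  list(participant = participant, rules = rules, thresholds = thresholds)
}
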