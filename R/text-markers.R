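# Deterministic text features from journals and interview ratings, and the
# built-in text diagnosis rules as computable predicates. These are the
# reproducible surrogate for qualitative judgments ("large vocabulary",
# "struggled to answer") over the same rule set.

default_lexicons <- function() {
  read_lex <- function(f) {
    readLines(system.file("extdata", f, package = "cogdx"))
  }
  list(
    positive = read_lex("lexicon_positive.txt"),
    negative = read_lex("lexicon_negative.txt")
  )
}

# Subordinating/relative markers used by the clause-count complexity proxy.
subordinators <- function() {
  c(
    "because", "although", "though", "while", "when", "after", "before",
    "since", "which", "that", "who", "where", "until", "unless", "whereas",
    "if", "so"
  )
}

tokenize_words <- function(text) {
  regmatches(tolower(text), gregexpr("[a-z']+", tolower(text)))[[1]]
}

split_sentences <- function(text) {
  s <- strsplit(text, "[.!?]+")[[1]]
  s <- trimws(s)
  s[nzchar(s)]
}

#' Deterministic journal features
#'
#' Tokenization is lowercase word tokens; sentences split on terminal
#' punctuation. `mean_sentence_length` is mean words per sentence.
#' `sentence_complexity` is a clause-count proxy: mean over sentences of
#' 1 + number of commas + number of subordinating/relative markers. Emotion
#' counts use the bundled positive/negative lexicons.
#'
#' @param texts Character vector of journal entries.
#' @param lexicons List with `positive` and `negative` word vectors.
#' @return A `journal_features` object.
#' @export
journal_features <- function(texts, lexicons = default_lexicons()) {
  texts <- texts[!is.na(texts)]
  nonempty <- texts[nzchar(trimws(texts))]
  if (length(nonempty) == 0) {
    out <- list(
      entry_count = 0L, is_empty = TRUE, vocabulary_size = 0L,
      mean_sentence_length = 0, sentence_complexity = 0,
      positive_word_count = 0L, negative_word_count = 0L
    )
    class(out) <- "journal_features"
    return(out)
  }
  all_sent <- unlist(lapply(nonempty, split_sentences))
  toks_by_sent <- lapply(all_sent, tokenize_words)
  all_toks <- unlist(toks_by_sent)
  commas <- vapply(all_sent, function(s) {
    lengths(regmatches(s, gregexpr(",", s)))
  }, numeric(1))
  subs <- vapply(toks_by_sent, function(tk) sum(tk %in% subordinators()),
    numeric(1))
  out <- list(
    entry_count = length(nonempty),
    is_empty = FALSE,
    vocabulary_size = length(unique(all_toks)),
    mean_sentence_length = mean(lengths(toks_by_sent)),
    sentence_complexity = mean(1 + commas + subs),
    positive_word_count = sum(all_toks %in% lexicons$positive),
    negative_word_count = sum(all_toks %in% lexicons$negative)
  )
  class(out) <- "journal_features"
  out
}

#' Fit cohort-relative text thresholds
#'
#' Medians of vocabulary size, mean sentence length and sentence complexity
#' over reference participants with non-empty journals, at a configurable
#' quantile. Used by the "large/small vocabulary" predicates.
#'
#' @param features_list List of [journal_features()] objects.
#' @param quantile Reference quantile (default median).
#' @return A `text_thresholds` object.
#' @export
fit_text_thresholds <- function(features_list, quantile = 0.5) {
  keep <- Filter(function(f) !f$is_empty, features_list)
  if (length(keep) == 0) {
    cogdx_stop("no non-empty journals to fit text thresholds on",
      "cogdx_insufficient_data")
  }
  q <- function(field) {
    stats::quantile(vapply(keep, `[[`, numeric(1), field), quantile,
      names = FALSE, type = 7)
  }
  structure(
    list(
      vocabulary_size = q("vocabulary_size"),
      mean_sentence_length = q("mean_sentence_length"),
      sentence_complexity = q("sentence_complexity"),
      quantile = quantile
    ),
    class = "text_thresholds"
  )
}

# Canonical predicate phrases; parsing matches on the normalized phrase.
text_predicate_table <- function() {
  data.frame(
    predicate = c(
      "journal_empty", "journal_rich", "journal_sparse",
      "journal_positive", "journal_negative",
      "journal_multiple_entries", "journal_single_entry",
      "ratings_some_low", "ratings_most_high",
      "ratings_confident", "ratings_struggled"
    ),
    phrase = c(
      "journal_text is empty",
      "journal_text has a large vocabulary, long sentences, and/or high sentence complexity",
      "journal_text has a small vocabulary, short sentences, and/or low sentence complexity",
      "journal_text uses positive emotion words",
      "journal_text uses negative emotion words",
      "journal_text appears to have more than 1 entry",
      "journal_text appears to only have 1 entry",
      "some interview_assessment ratings are <= 3",
      "most interview_assessment ratings are >= 4",
      "the interview_assessment explanations suggest the participant confidently answered the questions correctly",
      "the interview_assessment explanations suggest the participant struggled to answer the questions correctly"
    ),
    source = c(rep("speech", 7), rep("testing_session", 4)),
    stringsAsFactors = FALSE
  )
}

#' Parse text rules from the if-then DSL
#'
#' Grammar: `if <predicate phrase> then more likely <class>`, one rule per
#' line; `#` comments and blank lines are skipped. The antecedent must be
#' one of the 11 built-in predicate phrases.
#'
#' @param dsl_text DSL text (single string or character vector of lines).
#' @return List of `text_rule` objects.
#' @export
parse_text_rules <- function(dsl_text) {
  lines <- unlist(strsplit(paste(dsl_text, collapse = "\n"), "\n"))
  tab <- text_predicate_table()
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  rules <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    # tolerate the unicode comparators in transcribed rules
    line <- gsub("≤", "<=", gsub("≥", ">=", line))
    m <- regmatches(line, regexec(
      "^[Ii][Ff] (.*) then more likely (healthy|mild cognitive impairment)$",
      line
    ))[[1]]
    if (length(m) == 0) {
      cogdx_stop(sprintf("line %d: not a valid text rule: '%s'", i, line),
        "cogdx_parse_error")
    }
    j <- match(norm(m[2]), norm(tab$phrase))
    if (is.na(j)) {
      cogdx_stop(sprintf("line %d: unknown predicate '%s'", i, m[2]),
        "cogdx_parse_error")
    }
    rules[[length(rules) + 1]] <- structure(
      list(
        id = tab$predicate[j], predicate = tab$predicate[j],
        direction = if (m[3] == "healthy") "healthy" else "mci",
        source = tab$source[j], phrase = tab$phrase[j]
      ),
      class = "text_rule"
    )
  }
  rules
}

#' Serialize text rules to the DSL
#'
#' @param rules List of `text_rule` objects.
#' @return Character vector, one rule per line.
#' @export
serialize_text_rules <- function(rules) {
  vapply(rules, function(r) {
    cls <- if (r$direction == "healthy") "healthy" else
      "mild cognitive impairment"
    paste0("if ", r$phrase, " then more likely ", cls)
  }, character(1))
}

#' The bundled 11 text rules
#'
#' @param source Optionally restrict to `"speech"` or `"testing_session"`.
#' @return List of `text_rule` objects.
#' @export
bundled_text_rules <- function(source = NULL) {
  rules <- parse_text_rules(readLines(
    system.file("extdata", "rules_text.txt", package = "cogdx")
  ))
  if (!is.null(source)) {
    rules <- Filter(function(r) r$source == source, rules)
  }
  rules
}

# Evaluate one predicate. Returns list(fired, missing). "some" = at least
# one; "most" = strictly more than half of the present ratings. Rich/sparse
# fire when at least 2 of the 3 journal features are strictly above/below
# the cohort thresholds. Confident = no present rating below 4; struggled =
# mean present rating below 3.
eval_text_predicate <- function(predicate, features, ratings, thresholds) {
  fired <- FALSE
  miss <- FALSE
  f <- features
  r <- ratings[!is.na(ratings)]
  switch(predicate,
    journal_empty = {
      fired <- isTRUE(f$is_empty)
    },
    journal_rich = ,
    journal_sparse = {
      if (isTRUE(f$is_empty)) {
        fired <- FALSE
      } else if (is.null(thresholds)) {
        miss <- TRUE
      } else {
        above <- c(
          f$vocabulary_size > thresholds$vocabulary_size,
          f$mean_sentence_length > thresholds$mean_sentence_length,
          f$sentence_complexity > thresholds$sentence_complexity
        )
        below <- c(
          f$vocabulary_size < thresholds$vocabulary_size,
          f$mean_sentence_length < thresholds$mean_sentence_length,
          f$sentence_complexity < thresholds$sentence_complexity
        )
        fired <- if (predicate == "journal_rich") sum(above) >= 2 else
          sum(below) >= 2
      }
    },
    journal_positive = {
      fired <- !isTRUE(f$is_empty) && f$positive_word_count >= 1
    },
    journal_negative = {
      fired <- !isTRUE(f$is_empty) && f$negative_word_count >= 1
    },
    journal_multiple_entries = {
      fired <- f$entry_count > 1
    },
    journal_single_entry = {
      fired <- f$entry_count == 1
    },
    ratings_some_low = ,
    ratings_most_high = ,
    ratings_confident = ,
    ratings_struggled = {
      if (length(r) == 0) {
        miss <- TRUE
      } else {
        fired <- switch(predicate,
          ratings_some_low = any(r <= 3),
          ratings_most_high = sum(r >= 4) > length(r) / 2,
          ratings_confident = all(r >= 4),
          ratings_struggled = mean(r) < 3
        )
      }
    },
    cogdx_stop(paste0("unknown text predicate: ", predicate),
      "cogdx_parse_error")
  )
  list(fired = fired, missing = miss)
}

#' Evaluate text rules against one participant
#'
#' @param features A [journal_features()] object.
#' @param ratings Named integer vector of interview ratings (1-5, `NA`
#'   allowed); may be empty.
#' @param thresholds A [fit_text_thresholds()] object (required by the
#'   vocabulary/sentence predicates; without it those report missing).
#' @param rules Text rules, default all 11 bundled ones.
#' @return Data frame with `id`, `predicate`, `direction`, `source`,
#'   `fired`, `missing`. Rules whose inputs are absent report
#'   `fired = FALSE` with `missing = TRUE`.
#' @export
evaluate_text_rules <- function(features, ratings = NULL, thresholds = NULL,
                                rules = bundled_text_rules()) {
  rows <- lapply(rules, function(r) {
    res <- eval_text_predicate(r$predicate, features, ratings, thresholds)
    data.frame(
      id = r$id, predicate = r$predicate, direction = r$direction,
      source = r$source, fired = res$fired, missing = res$missing,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
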