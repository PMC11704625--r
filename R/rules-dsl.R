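# The plain-text if-then rule language for numeric diagnosis rules:
#   if <marker> <cmp> <value> [and ...] then more likely <class>
# with an optional trailing "# pr=<pct> pa=<count>" stats comment.

new_rule <- function(conditions, consequent, pr = NA_real_, pa = NA_integer_,
                     provenance = "tree") {
  stopifnot(length(conditions) >= 1)
  structure(
    list(
      conditions = conditions, consequent = consequent,
      pr = pr, pa = as.integer(pa), provenance = provenance
    ),
    class = "cogdx_rule"
  )
}

new_condition <- function(marker, op, value) {
  list(marker = marker, op = op, value = value)
}

format_value <- function(v) {
  if (is.character(v)) v else
    format(v, digits = 15, trim = TRUE, scientific = FALSE)
}

rule_antecedent_text <- function(rule) {
  paste(vapply(rule$conditions, function(cn) {
    paste(cn$marker, cn$op, format_value(cn$value))
  }, character(1)), collapse = " and ")
}

consequent_text <- function(consequent) {
  if (consequent == "healthy") "healthy" else "mild cognitive impairment"
}

# Identity key used for de-duplication (ignores pr/pa/provenance).
rule_key <- function(rule) {
  paste(rule_antecedent_text(rule), "->", rule$consequent)
}

#' Serialize numeric rules to the DSL
#'
#' @param rules List of rules (a ruleset).
#' @param stats Include the `# pr=.. pa=..` trailing comment where known.
#' @return Character vector, one rule per line.
#' @export
serialize_rules <- function(rules, stats = TRUE) {
  vapply(rules, function(r) {
    line <- paste0(
      "if ", rule_antecedent_text(r), " then more likely ",
      consequent_text(r$consequent)
    )
    if (stats && !is.na(r$pr) && !is.na(r$pa)) {
      line <- paste0(
        line, " # pr=", formatC(r$pr, format = "f", digits = 2),
        " pa=", r$pa
      )
    }
    line
  }, character(1))
}

#' Parse numeric rules from the DSL
#'
#' Accepts `<=`/`>`/`=` comparators (unicode `≤` is normalized), a
#' case-insensitive leading `if`, classes `healthy` or
#' `mild cognitive impairment`, `#` comments and blank lines. `=` is only
#' valid for the categorical marker `sex`.
#'
#' @param dsl_text DSL text (single string or character vector of lines).
#' @return List of rules.
#' @export
parse_rules <- function(dsl_text) {
  lines <- unlist(strsplit(paste(dsl_text, collapse = "\n"), "\n"))
  rules <- list()
  for (i in seq_along(lines)) {
    raw <- trimws(lines[i])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    line <- gsub("≤", "<=", raw)
    pr <- NA_real_
    pa <- NA_integer_
    cm <- regmatches(line, regexec(
      "#\\s*pr=([0-9.]+)\\s+pa=([0-9]+)\\s*$", line
    ))[[1]]
    if (length(cm) > 0) {
      pr <- as.numeric(cm[2])
      pa <- as.integer(cm[3])
      line <- trimws(sub("#.*$", "", line))
    }
    m <- regmatches(line, regexec(
      "^[Ii][Ff]\\s+(.*)\\s+then more likely\\s+(healthy|mild cognitive impairment)$",
      line
    ))[[1]]
    if (length(m) == 0) {
      cogdx_stop(sprintf("line %d: not a valid rule: '%s'", i, raw),
        "cogdx_parse_error")
    }
    conds <- lapply(strsplit(m[2], "\\s+and\\s+")[[1]], function(ctext) {
      cmt <- regmatches(ctext, regexec(
        "^([A-Za-z_][A-Za-z0-9_]*)\\s*(<=|>|=)\\s*(\\S+)$", ctext
      ))[[1]]
      if (length(cmt) == 0) {
        cogdx_stop(
          sprintf("line %d: malformed condition '%s'", i, ctext),
          "cogdx_parse_error"
        )
      }
      marker <- cmt[2]
      op <- cmt[3]
      if (!marker %in% marker_names()) {
        cogdx_stop(
          sprintf("line %d: unknown marker '%s'", i, marker),
          "cogdx_parse_error"
        )
      }
      if (op == "=") {
        if (marker != "sex") {
          cogdx_stop(
            sprintf("line %d: '=' is only valid for sex, got '%s'", i, marker),
            "cogdx_parse_error"
          )
        }
        if (!cmt[4] %in% c("female", "male")) {
          cogdx_stop(
            sprintf("line %d: invalid sex value '%s'", i, cmt[4]),
            "cogdx_parse_error"
          )
        }
        new_condition(marker, "=", cmt[4])
      } else {
        v <- suppressWarnings(as.numeric(cmt[4]))
        if (is.na(v)) {
          cogdx_stop(
            sprintf("line %d: non-numeric threshold '%s'", i, cmt[4]),
            "cogdx_parse_error"
          )
        }
        new_condition(marker, op, v)
      }
    })
    consequent <- if (m[3] == "healthy") "healthy" else "mci"
    rules[[length(rules) + 1]] <- new_rule(conds, consequent, pr, pa)
  }
  rules
}

#' The bundled 20 numeric rules
#'
#' The tree-induced rule inventory shipped with the package, with each
#' rule's confidence (pr) and support (pa).
#'
#' @return List of rules.
#' @export
bundled_numeric_rules <- function() {
  parse_rules(readLines(
    system.file("extdata", "rules_numeric.txt", package = "cogdx")
  ))
}

#' @export
print.cogdx_rule <- function(x, ...) {
  cat(serialize_rules(list(x)), "\n")
  invisible(x)
}
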