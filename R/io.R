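# File formats: schema-versioned cohort JSON, flat marker CSV, scale-bounds
# and report JSON. All writes are atomic (write temp file, then rename).

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    cogdx_stop(paste0("could not write ", path), "cogdx_io_error")
  }
  invisible(path)
}

#' Write a cohort to schema-versioned JSON
#'
#' @param cohort A cohort object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  payload <- list(
    schema_version = cohort$schema_version,
    config = unclass(cohort$config),
    participants = lapply(cohort$participants, function(p) {
      p$interview_ratings <- as.list(p$interview_ratings)
      p
    })
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp,
      dataframe = "columns", auto_unbox = TRUE, na = "null", digits = I(17)
    )
  })
}

coerce_df <- function(x, types) {
  cols <- lapply(names(types), function(nm) {
    v <- unlist(lapply(x[[nm]], function(e) {
      if (is.null(e) || length(e) == 0) NA else e
    }))
    as.vector(v %||% vector(types[[nm]], 0), types[[nm]])
  })
  stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE), names(types))
}

#' Read a cohort from JSON
#'
#' Rejects unknown schema versions and records with missing required
#' fields, naming the offending participant.
#'
#' @param path Cohort JSON path.
#' @return A cohort object.
#' @export
read_cohort <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(raw$schema_version, "1.0")) {
    cogdx_stop(
      paste0("unknown cohort schema version: ",
        raw$schema_version %||% "<absent>"),
      "cogdx_io_error"
    )
  }
  participants <- lapply(raw$participants, function(p) {
    for (f in c("id", "label", "age", "sex", "education_years")) {
      if (is.null(p[[f]])) {
        cogdx_stop(
          paste0("participant '", p$id %||% "<no id>",
            "' is missing field '", f, "'"),
          "cogdx_io_error"
        )
      }
    }
    if (!p$label %in% class_labels()) {
      cogdx_stop(paste0("participant '", p$id, "' has invalid label '",
        p$label, "'"), "cogdx_io_error")
    }
    list(
      id = p$id, pseudonym = p$pseudonym, label = p$label,
      age = as.numeric(p$age),
      sex = p$sex, education_years = as.integer(p$education_years),
      sensor_days = coerce_df(p$sensor_days,
        c(day_index = "integer", accel_total = "double",
          missing = "logical")),
      locations = coerce_df(p$locations,
        c(day_index = "integer", x = "double", y = "double")),
      ema = coerce_df(p$ema,
        c(day_index = "integer", prompt_index = "integer",
          value = "integer")),
      nback = coerce_df(p$nback,
        c(day_index = "integer", accuracy = "double")),
      journal_texts = as.character(unlist(p$journal_texts)),
      interview_ratings = {
        r <- p$interview_ratings
        stats::setNames(as.integer(unlist(r) %||% integer(0)),
          names(r) %||% character(0))
      }
    )
  })
  cfg <- raw$config
  for (f in c("n_total", "n_healthy", "n_mci", "n_female", "min_days",
    "ema_per_day", "readings_per_day", "seed")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.integer(cfg[[f]])
  }
  class(cfg) <- "cohort_config"
  structure(
    list(participants = participants, config = cfg,
      schema_version = raw$schema_version),
    class = "cohort"
  )
}

#' Write the flat marker table as CSV
#'
#' One row per participant; marker columns carry the canonical marker
#' identifiers.
#'
#' @param markers Marker table from [extract_markers()] (raw or scaled).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  cols <- c("id", "pseudonym", "label", marker_names())
  out <- markers[, intersect(cols, names(markers)), drop = FALSE]
  atomic_write(path, function(tmp) {
    utils::write.csv(out, tmp, row.names = FALSE)
  })
}

#' Read a marker table CSV
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_marker_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write scale bounds as JSON
#'
#' @param bounds A [fit_scale()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bounds <- function(bounds, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(lapply(unclass(bounds), as.list), tmp,
      auto_unbox = TRUE, digits = I(17))
  })
}

#' Read scale bounds from JSON
#'
#' @param path Bounds JSON path.
#' @return A `scale_bounds` object.
#' @export
read_bounds <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(
    lapply(raw, function(b) c(min = b$min, max = b$max)),
    class = "scale_bounds"
  )
}

#' Write an evaluation report as JSON
#'
#' Schema: `runs[]`, `mean{}`, `sd{}`, `n_runs`, `mode`,
#' `selected_groups[]`, `config{}`.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    runs = report$runs, mean = as.list(report$mean),
    sd = as.list(report$sd), n_runs = report$n_runs, mode = report$mode,
    selected_groups = report$selected, config = report$config
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp,
      dataframe = "rows", auto_unbox = TRUE, na = "null", digits = I(17))
  })
}
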