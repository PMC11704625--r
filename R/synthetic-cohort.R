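# Seeded synthetic cohort emulating a smartwatch digital-phenotyping study:
# daily acceleration totals, location traces, EMA responses, daily n-back
# accuracies, journal texts and interview ratings, with class-conditional
# marker structure planted per the configured effects.

# Sentence pools backing the journal generator. The rich pool has long,
# clause-heavy sentences, a wide vocabulary and positive emotion words; the
# sparse pool has short sentences, a narrow vocabulary and negative words.
journal_pools <- function() {
  list(
    rich = c(
      "This morning I walked along the river with my neighbor, and we felt happy watching the herons wade through the shallows.",
      "After breakfast I tended the tomatoes and marigolds in the garden, which always leaves me feeling peaceful and satisfied.",
      "I spent a delightful afternoon at the library, because the reading group discussed a wonderful novel about lighthouse keepers.",
      "My granddaughter called before lunch, and hearing about her chemistry project made me feel proud and grateful.",
      "We drove out to the orchard stand, bought cider and honeycrisp apples, and enjoyed the brilliant autumn foliage along the highway.",
      "Although the forecast threatened rain, I finished painting the birdhouse, which was satisfying after weeks of procrastination.",
      "I volunteered at the food pantry this afternoon, where the cheerful bustle of sorting donations kept my spirits bright.",
      "After my swim at the community pool I felt energetic, so I reorganized the pantry shelves and labeled every jar.",
      "The choir rehearsal ran long, but singing the new arrangement with friends left me feeling joyful and refreshed.",
      "I baked sourdough and delivered a warm loaf to the widower next door, who seemed genuinely delighted by the visit.",
      "While balancing the checkbook I discovered a small refund, which felt like a lucky omen for the whole week.",
      "My husband and I played bridge with the Hendersons, and although we lost the rubber, the conversation was marvelous.",
      "I repotted the ferns on the porch, swept the walk, and admired how the afternoon light made everything look radiant.",
      "The lecture on migratory songbirds was fascinating, and afterwards we lingered over coffee discussing the speaker's photographs.",
      "I finished the crossword before noon, which always makes me feel sharp, accomplished, and ready for the day.",
      "We celebrated my sister's birthday with lemon cake and old photographs, laughing until the candles had long burned out.",
      "Despite the chilly wind I walked the full loop around the lake, and the exercise left me invigorated and calm.",
      "I sorted the quilting fabrics by color, planned a new star pattern, and felt excited about starting it tomorrow.",
      "The farmers market was crowded and lively, so I bought dahlias, fresh trout, and a jar of clover honey.",
      "After supper we watched the documentary about coral reefs, which was beautiful, and then discussed our travel memories.",
      "I wrote letters to two old colleagues, because keeping those friendships alive has always felt rewarding and important.",
      "My physical therapist praised my progress, and walking without the cane afterwards felt like a splendid little triumph.",
      "The grandchildren visited after school, and we built an elaborate domino run that rattled wonderfully across the kitchen floor.",
      "I pruned the roses while listening to the opera broadcast, grateful for such a tranquil and productive afternoon."
    ),
    sparse = c(
      "I stayed home.",
      "I felt tired.",
      "I was sad today.",
      "I forgot my keys.",
      "Nothing much happened.",
      "I watched television.",
      "I felt lonely.",
      "My back hurt.",
      "I was confused.",
      "I did not go out.",
      "I slept a lot.",
      "I felt worried."
    )
  )
}

journal_entry <- function(pool_name, n_sentences) {
  pool <- journal_pools()[[pool_name]]
  paste(sample(pool, n_sentences, replace = n_sentences > length(pool)),
    collapse = " "
  )
}

#' Generate one journal entry
#'
#' Healthy entries are drawn from a long-sentence, large-vocabulary pool with
#' positive emotion words and are never empty; MCI entries come from a short,
#' narrow pool with negative emotion words and are empty (`""`) with the
#' class's configured probability.
#'
#' @param label `"healthy"` or `"mci"`.
#' @param effects Class-effects list, see [default_class_effects()].
#' @param seed Optional integer seed; without it the current RNG stream is
#'   used.
#' @return A single string (possibly empty for MCI).
#' @export
generate_journal <- function(label, effects = default_class_effects(),
                             seed = NULL) {
  label <- match.arg(label, class_labels())
  eff <- effects[[label]]
  draw <- function() {
    if (stats::runif(1) < eff$journal_empty_prob) {
      return("")
    }
    ns <- sample(seq(eff$journal_sentences[1], eff$journal_sentences[2]), 1)
    journal_entry(eff$journal_pool, ns)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

rating_test_names <- function() {
  c(
    "Category Fluency (Animals)", "Letter Fluency (F)", "Letter Fluency (S)",
    "List Learning", "Delayed Recall", "Cognitive Screening",
    "Health Literacy", "Orientation"
  )
}

# One participant's raw streams, drawn from the current RNG stream.
gen_participant_streams <- function(eff, cfg) {
  n_days <- cfg$min_days + stats::rpois(1, cfg$extra_days_mean)
  missing <- stats::runif(n_days) < cfg$missing_day_rate
  day_index <- seq_len(n_days) - 1L
  present <- which(!missing)
  np <- length(present)
  R <- cfg$readings_per_day

  accel <- rep(NA_real_, n_days)
  person_ml <- stats::rnorm(1, eff$activity_meanlog, eff$activity_meanlog_sd)
  accel[present] <- stats::rlnorm(np, person_ml, eff$activity_sdlog)

  # Location model: home cluster at the origin plus, on excursion days, a
  # second cluster at a class-dependent radius. Home keeps >= 55% of each
  # day's readings, so the home cell holds the plurality by construction.
  if (np > 0) {
    ex_day <- stats::runif(np) < eff$excursion_prob
    home_frac <- ifelse(ex_day, stats::runif(np, 0.55, 0.9), 1)
    n_home <- pmax(ceiling(0.55 * R), round(R * home_frac))
    n_out <- R - n_home
    day_present <- day_index[present]
    hx <- stats::rnorm(sum(n_home), 0, 2)
    hy <- stats::rnorm(sum(n_home), 0, 2)
    n_ex <- sum(n_out > 0)
    if (n_ex > 0) {
      radius <- stats::rgamma(n_ex, shape = 2,
        scale = eff$excursion_radius_mean / 2)
      angle <- stats::runif(n_ex, 0, 2 * pi)
      cx <- rep(radius * cos(angle), n_out[n_out > 0])
      cy <- rep(radius * sin(angle), n_out[n_out > 0])
      ox <- cx + stats::rnorm(length(cx), 0, 30)
      oy <- cy + stats::rnorm(length(cy), 0, 30)
    } else {
      ox <- oy <- numeric(0)
    }
    day_col <- c(rep(day_present, n_home), rep(day_present, n_out))
    part <- c(rep(0L, sum(n_home)), rep(1L, sum(n_out)))
    ord <- order(day_col, part, method = "radix")
    locations <- data.frame(
      day_index = day_col[ord], x = c(hx, ox)[ord], y = c(hy, oy)[ord]
    )
  } else {
    locations <- data.frame(
      day_index = integer(0), x = numeric(0), y = numeric(0)
    )
  }

  # EMA: prompts are only answerable on wear (non-missing) days; compliance
  # is measured against all scheduled prompts, so missingness lowers it.
  answer_p <- stats::rbeta(1, eff$ema_answer_shape1, eff$ema_answer_shape2)
  sched_day <- rep(day_index, each = cfg$ema_per_day)
  sched_prompt <- rep(seq_len(cfg$ema_per_day) - 1L, times = n_days)
  answered <- !missing[sched_day + 1L] & stats::runif(length(sched_day)) < answer_p
  pm <- stats::rnorm(1, eff$sharp_mean_mu, eff$sharp_mean_sd)
  vals <- as.integer(clamp(
    round_half_up(stats::rnorm(sum(answered), pm, eff$sharp_within_sd)), 1, 5
  ))
  ema <- data.frame(
    day_index = sched_day[answered], prompt_index = sched_prompt[answered],
    value = vals
  )

  # n-back: linear ramp from a start accuracy to a plateau over the first 6
  # scores (the learning phase), then plateau, with class-dependent noise.
  s0 <- stats::rnorm(1, eff$nback_start_mu, eff$nback_start_sd)
  pl <- stats::rnorm(1, eff$nback_plateau_mu, eff$nback_plateau_sd)
  k <- seq_len(np) - 1L
  ramp <- s0 + (pl - s0) * pmin(k, 5L) / 5
  acc <- clamp(ramp + stats::rnorm(np, 0, eff$nback_noise_sd), 0, 1)
  nback <- data.frame(day_index = day_index[present], accuracy = acc)

  list(
    sensor_days = data.frame(
      day_index = day_index, accel_total = accel, missing = missing
    ),
    locations = locations, ema = ema, nback = nback
  )
}

gen_journal_texts <- function(label, eff) {
  if (label == "mci" && stats::runif(1) < eff$journal_empty_prob) {
    return(character(0))
  }
  n <- sample(seq(eff$journal_entries[1], eff$journal_entries[2]), 1)
  vapply(seq_len(n), function(i) {
    ns <- sample(seq(eff$journal_sentences[1], eff$journal_sentences[2]), 1)
    journal_entry(eff$journal_pool, ns)
  }, character(1))
}

gen_ratings <- function(eff, missing_prob = 0.06) {
  if (stats::runif(1) < missing_prob) {
    return(stats::setNames(integer(0), character(0)))
  }
  tests <- rating_test_names()
  stats::setNames(
    as.integer(sample(1:5, length(tests), replace = TRUE,
      prob = eff$rating_probs)),
    tests
  )
}

#' Generate a synthetic cohort
#'
#' Produces `n_total` participant records with exact label and sex counts,
#' per-day sensor streams (total acceleration, 300 location readings on
#' non-missing days), EMA responses, daily n-back accuracies, journal texts
#' and interview ratings. Class-conditional effects are planted per
#' `config$class_effects`. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `cohort` object: list with `participants`, `config`,
#'   `schema_version`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  participants <- withr::with_seed(cfg$seed, {
    labels <- sample(rep(class_labels(), c(cfg$n_healthy, cfg$n_mci)))
    sexes <- sample(rep(
      c("female", "male"), c(cfg$n_female, cfg$n_total - cfg$n_female)
    ))
    ages <- round(draw_ages(cfg$n_total, cfg$age_mean, cfg$age_sd,
      cfg$min_age), 1)
    edu <- as.integer(clamp(round_half_up(stats::rnorm(cfg$n_total, 16, 2.5)),
      8, 22))
    pool <- pseudonym_pool()
    if (cfg$n_total <= length(pool)) {
      nms <- sample(pool, cfg$n_total)
    } else {
      nms <- paste0(
        sample(pool, cfg$n_total, replace = TRUE), "-", seq_len(cfg$n_total)
      )
    }
    lapply(seq_len(cfg$n_total), function(i) {
      eff <- cfg$class_effects[[labels[i]]]
      streams <- gen_participant_streams(eff, cfg)
      c(
        list(
          id = sprintf("P%04d", i), pseudonym = nms[i], label = labels[i],
          age = ages[i], sex = sexes[i], education_years = edu[i]
        ),
        streams,
        list(
          journal_texts = gen_journal_texts(labels[i], eff),
          interview_ratings = gen_ratings(eff)
        )
      )
    })
  })
  structure(
    list(participants = participants, config = cfg, schema_version = "1.0"),
    class = "cohort"
  )
}

pseudonym_pool <- function() {
  readLines(system.file("extdata", "pseudonyms.txt", package = "cogdx"))
}

#' @export
print.cohort <- function(x, ...) {
  labs <- vapply(x$participants, `[[`, character(1), "label")
  cat(sprintf(
    "<cohort> %d participants (%d healthy, %d mci), seed %d\n",
    length(labs), sum(labs == "healthy"), sum(labs == "mci"), x$config$seed
  ))
  invisible(x)
}
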