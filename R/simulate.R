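#' Specification of a synthetic study population
#'
#' Defaults emulate the study system the toolkit was built for: around 250
#' individuals in 11 social groups of 10–30, an even sex ratio, ages spread
#' uniformly over 0–8 years. The generator is fully deterministic given the
#' seed: every draw comes from a labelled substream of the master seed, so
#' adding a generator never perturbs another's stream.
#'
#' @param n_packs number of social groups
#' @param pack_size_range `c(min, max)` individuals per group
#' @param sex_ratio probability an individual is female
#' @param max_age_years upper bound of the uniform age distribution
#' @param as_of reference date individuals are aged against
#' @param seed master integer seed
#' @return a list of class `fs_population_spec`
#' @export
population_spec <- function(n_packs = 11L, pack_size_range = c(10L, 30L),
                            sex_ratio = 0.5, max_age_years = 8,
                            as_of = as.Date("2015-01-15"), seed = 1L) {
  if (n_packs < 1L) fs_invalid("n_packs must be at least 1")
  if (length(pack_size_range) != 2L || pack_size_range[1] > pack_size_range[2] ||
      pack_size_range[1] < 1L) {
    fs_invalid("pack_size_range must be c(min, max) with 1 <= min <= max")
  }
  if (sex_ratio < 0 || sex_ratio > 1) fs_invalid("sex_ratio must be in [0, 1]")
  structure(list(n_packs = as.integer(n_packs),
                 pack_size_range = as.integer(pack_size_range),
                 sex_ratio = sex_ratio, max_age_years = max_age_years,
                 as_of = as.Date(as_of), seed = as.integer(seed)),
            class = "fs_population_spec")
}

#' Generate a synthetic population store
#'
#' Creates packs named `"1A"`, `"1B"`, … and their rosters through the
#' public pack-management API (never raw store writes), so everything the
#' generator produces satisfies the same gating as field-entered data.
#' Individuals are named with globally unique numeric codes, as in the field.
#'
#' @param spec a [population_spec()]
#' @param device_tag device tag for the store the population is created on
#' @return an [eav_store()] containing the population
#' @export
simulate_population <- function(spec = population_spec(), device_tag = "T1") {
  stopifnot(inherits(spec, "fs_population_spec"))
  store <- eav_store(device_tag)
  with_substream(spec$seed, "population", {
    code <- 100L
    for (p in seq_len(spec$n_packs)) {
      pack_name <- paste0("1", LETTERS[((p - 1L) %% 26L) + 1L],
                          if (p > 26L) (p - 1L) %/% 26L else "")
      pack_id <- add_pack(store, pack_name)
      n <- sample(spec$pack_size_range[1]:spec$pack_size_range[2], 1L)
      for (k in seq_len(n)) {
        sex <- if (stats::runif(1) < spec$sex_ratio) "F" else "M"
        age_days <- sample(0:as.integer(spec$max_age_years * 365.25), 1L)
        add_individual(store, pack_id, name = as.character(code), sex = sex,
                       date_of_birth = spec$as_of - age_days, today = spec$as_of)
        code <- code + 1L
      }
    }
  })
  store
}

#' Parameters of a simulated group visit
#'
#' Presence probability, visit duration, weighing-day rule and the weight
#' distribution are invented defaults (the field protocol fixes the visit
#' cadence and weekly weighing, not these distributions): individuals are
#' present with probability 0.95; visits last 20–40 minutes; weighing
#' happens on one weekday each week; weights are normal with mean 1500 g and
#' sd 250 g, truncated below at 300 g, scaled down for juveniles and pups.
#'
#' @param p_present per-individual presence probability
#' @param duration_min_range visit duration range, minutes
#' @param weigh_weekday weekday of the weekly weighing (1 = Monday)
#' @param weight_mean,weight_sd,weight_floor adult weight distribution (grams)
#' @param p_pregnancy probability an eligible present female gets a pregnancy record
#' @param p_mate_guard probability a present male/female pair is recorded guarding
#' @param p_escort probability a present pup gets an escort record
#' @param p_babysit probability an absent individual is inferred babysitting
#' @return a list of class `fs_visit_params`
#' @export
visit_params <- function(p_present = 0.95, duration_min_range = c(20L, 40L),
                         weigh_weekday = 1L,
                         weight_mean = 1500, weight_sd = 250, weight_floor = 300,
                         p_pregnancy = 0.1, p_mate_guard = 0.1,
                         p_escort = 0.2, p_babysit = 0.1) {
  structure(as.list(environment()), class = "fs_visit_params")
}

draw_weight <- function(age_years, params) {
  scale <- if (age_years < 0.25) 0.25 else if (age_years < 1) 0.6 else 1
  g <- stats::rnorm(1, params$weight_mean * scale, params$weight_sd * scale)
  as.integer(round(max(params$weight_floor * scale, g)))
}

#' Simulate one group-composition visit
#'
#' Runs an entire visit through the public observation API on a simulated
#' clock: presence drawn per individual, weights for present individuals on
#' the weekly weighing day, pregnancy records only among eligible females,
#' occasional mate-guard/escort/babysit records, and the automatic GPS track
#' (a >= 20-minute visit always has >= 7 fixes).
#'
#' @param store a population store
#' @param pack_id the pack to visit
#' @param date visit `Date`
#' @param params a [visit_params()]
#' @param seed integer seed for this visit's substream
#' @return the closed session handle (class `fs_session`)
#' @export
simulate_visit <- function(store, pack_id, date, params = visit_params(), seed = 1L) {
  date <- as.Date(date)
  with_substream(seed, paste0("visit:", pack_id, ":", format(date)), {
    start <- as.POSIXct(paste(format(date), "08:00:00"), tz = "UTC")
    session <- start_visit(store, pack_id, start)
    roster <- pack_roster(store, pack_id)
    present <- stats::runif(nrow(roster)) < params$p_present
    for (i in seq_len(nrow(roster))) {
      record_presence(session, roster$entity_id[i], present[i])
    }
    is_weigh_day <- (as.integer(format(date, "%u")) == params$weigh_weekday)
    ages <- age_months(roster[["date-of-birth"]], date) / 12
    if (is_weigh_day) {
      for (i in which(present)) {
        record_weight(session, roster$entity_id[i], draw_weight(ages[i], params),
                      period = if (as.integer(format(start, "%H")) < 12) "morning" else "evening")
      }
    }
    eligible_f <- which(present & roster$sex == "F" &
                          age_months(roster[["date-of-birth"]], date) >
                            session$config$adult_female_months)
    for (i in eligible_f) {
      if (stats::runif(1) < params$p_pregnancy) {
        record_status(session, "pregnancy", individual = roster$entity_id[i])
      }
    }
    males <- which(present & roster$sex == "M")
    if (length(males) && length(eligible_f) && stats::runif(1) < params$p_mate_guard) {
      record_status(session, "mate-guard",
                    male = roster$entity_id[sample(males, 1L)],
                    female = roster$entity_id[if (length(eligible_f) == 1L) eligible_f
                                              else sample(eligible_f, 1L)],
                    strength = sample(session$config$score_levels, 1L),
                    accuracy = sample(session$config$score_levels, 1L),
                    primary = stats::runif(1) < 0.5)
    }
    pups <- which(present & vapply(roster$entity_id, is_pup, logical(1),
                                   store = store, on_date = date))
    adults <- setdiff(which(present), pups)
    for (i in pups) {
      if (length(adults) && stats::runif(1) < params$p_escort) {
        record_status(session, "escort",
                      pup = roster$entity_id[i],
                      escort = roster$entity_id[if (length(adults) == 1L) adults
                                                else sample(adults, 1L)],
                      strength = sample(session$config$score_levels, 1L),
                      accuracy = sample(session$config$score_levels, 1L))
      }
    }
    for (i in which(!present)) {
      if (stats::runif(1) < params$p_babysit) {
        record_status(session, "babysit", individual = roster$entity_id[i],
                      evidence = "inferred")
      }
    }
    duration <- sample(params$duration_min_range[1]:params$duration_min_range[2], 1L)
    end_visit(session, start + duration * 60)
    session
  })
}

#' Simulate a completed focal follow
#'
#' Twenty per-minute scans with neighbours drawn from the focal's packmates,
#' a Poisson number of interactions (default mean 3), and optionally an
#' injected pause; everything goes through the focal API on a simulated
#' clock, so a completed follow always has exactly 20 scan slots and its
#' wall-clock length is 1200 s plus the paused time.
#'
#' @param store a population store
#' @param protocol focal protocol (`"pup"`, `"pregnant-female"`, `"oestrus-female"`)
#' @param focal_id the focal individual (must match the protocol)
#' @param start start time (`POSIXct`)
#' @param mean_interactions Poisson mean interactions per follow
#' @param pause_seconds inject one pause of this many seconds (0 = none)
#' @param seed integer seed
#' @return the completed follow handle (class `fs_focal`)
#' @export
simulate_focal <- function(store, protocol, focal_id,
                           start = as.POSIXct("2015-01-20 09:00:00", tz = "UTC"),
                           mean_interactions = 3, pause_seconds = 0L, seed = 1L) {
  with_substream(seed, paste0("focal:", focal_id), {
    follow <- start_focal(store, protocol, focal_id, start)
    pack <- entity_attr(store, focal_id, "pack")
    mates <- setdiff(pack_roster(store, pack)$entity_id, focal_id)
    pause_at <- if (pause_seconds > 0) sample(1:19, 1L) else NA_integer_
    offset <- 0
    for (m in 1:20) {
      if (!is.na(pause_at) && m == pause_at + 1L) {
        pause_focal(follow, start + offset + (m - 1L) * 60)
        offset <- offset + pause_seconds
        resume_focal(follow, start + offset + (m - 1L) * 60)
      }
      n_near <- sample(0:min(4L, length(mates)), 1L)
      within <- if (n_near > 0) sample(mates, n_near) else character(0)
      record_scan(follow, m,
                  nearest = if (n_near > 0) within[1] else "none-visible",
                  within_2m = within)
    }
    n_int <- if (length(mates)) stats::rpois(1, mean_interactions) else 0L
    for (j in seq_len(n_int)) {
      kind <- sample(c("affiliative", "agonistic"), 1L)
      record_interaction(
        follow, kind, partner = sample(mates, 1L),
        initiator = sample(c("focal", "partner"), 1L),
        intensity = sample(c("body-block", "attack", "groom", "play"), 1L),
        context = sample(c("food", "social-partner", "other"), 1L),
        winner = if (kind == "agonistic") sample(c("focal", "partner", "none"), 1L) else "none",
        at = start + sample(0:1199, 1L) + offset
      )
    }
    complete_focal(follow, start + 1200 + offset)
    follow
  })
}

#' Inject single-digit typos into recorded values
#'
#' Emulates the residual error mode of touchscreen data entry: one digit of
#' a value replaced by another (1234 becoming 1334). Returns the corrupted
#' copy together with the exact ground-truth index set, for recall tests of
#' feasibility screens.
#'
#' @param values integer vector (e.g. weights in grams)
#' @param n_errors number of values to corrupt (or give `rate`)
#' @param rate fraction of values to corrupt, in `[0, 1]`
#' @param seed integer seed
#' @param force_infeasible if not `NULL`, `c(lower, upper)` bounds the
#'   corrupted values are guaranteed to violate (substitutes the leading
#'   digit upward), making a bounds screen's recall 1 by construction
#' @return a list: `values` (corrupted copy), `corrupted_idx`, `original`
#' @export
inject_typos <- function(values, n_errors = NULL, rate = NULL, seed = 1L,
                         force_infeasible = NULL) {
  if (is.null(n_errors)) {
    if (is.null(rate)) fs_invalid("give n_errors or rate")
    if (rate < 0 || rate > 1) fs_invalid("rate must be in [0, 1]")
    n_errors <- round(rate * length(values))
  }
  if (n_errors > length(values)) fs_invalid("n_errors exceeds record count")
  original <- values
  with_substream(seed, "typos", {
    idx <- sort(sample(seq_along(values), n_errors))
    for (i in idx) {
      digits <- strsplit(as.character(values[i]), "")[[1]]
      if (!is.null(force_infeasible)) {
        pos <- 1L
        hi_first <- as.integer(force_infeasible[2] %/% 10^(length(digits) - 1L))
        new_digit <- sample(setdiff((hi_first + 1L):9L, as.integer(digits[1])), 1L)
      } else {
        pos <- sample(seq_along(digits), 1L)
        new_digit <- sample(setdiff(0:9, as.integer(digits[pos])), 1L)
      }
      digits[pos] <- as.character(new_digit)
      values[i] <- as.integer(paste(digits, collapse = ""))
    }
    list(values = values, corrupted_idx = idx, original = original)
  })
}

#' The canonical 720-weight field-test fixture
#'
#' 720 weight values drawn from the generator's weight distribution but
#' constrained to [1000, 2499] g (4-digit values inside the feasibility
#' bounds), of which 18 are corrupted by a leading-digit typo that pushes
#' them above the upper feasibility bound — so screening with the generating
#' bounds flags exactly the corrupted set. This reproduces the scale of the
#' field-test frame (a 2.5% corruption rate over 720 records) used to
#' exercise [screen_weights()].
#'
#' @param seed integer seed
#' @param n number of records
#' @param n_errors number corrupted
#' @param bounds feasibility bounds the clean values respect
#' @return a list: `grams` (with typos), `corrupted_idx`, `original`, `bounds`
#' @export
weights_fixture <- function(seed = 1L, n = 720L, n_errors = 18L,
                            bounds = c(300L, 2500L)) {
  clean <- with_substream(seed, "weights-fixture", {
    g <- as.integer(round(stats::rnorm(n, 1500, 250)))
    pmin(pmax(g, 1000L), 2499L)
  })
  typo <- inject_typos(clean, n_errors = n_errors, seed = seed,
                       force_infeasible = bounds)
  list(grams = typo$values, corrupted_idx = typo$corrupted_idx,
       original = typo$original, bounds = bounds)
}
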