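# Run code with a locally seeded RNG, restoring any prior RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic assessment campaign
#'
#' Defaults emulate the large school-district campaigns the instrument was
#' used in: 16 buildings of 142 rooms each, with room-level factor
#' prevalences taken from field observations in schools (water damage/stains
#' by far the most prevalent sign, visible mold and wetness rare, mold odor
#' intermediate) and most damage scored 1.
#'
#' @param n_buildings,rooms_per_building Positive integers.
#' @param component_presence_probs Named probabilities that each component
#'   exists in a room; ceiling, walls and floor are basic components and are
#'   fixed at 1.
#' @param factor_prevalence Named room-level probabilities that a room is
#'   affected by each factor (including `mold_odor`).
#' @param severity_distribution Probabilities of scores 1..3 given affected;
#'   must sum to 1.
#' @param near_exterior_prob Probability that a damaged component is flagged
#'   near an exterior wall.
#' @param component_spread Given an affected room, each additional present
#'   component (beyond one guaranteed) carries the damage with this
#'   probability.
#' @param seed Integer seed; the generator is fully reproducible given the
#'   spec.
#' @return A list of class `campaign_spec`.
#' @export
campaign_spec <- function(n_buildings = 16L, rooms_per_building = 142L,
                          component_presence_probs = c(
                            ceiling = 1, walls = 1, floor = 1,
                            windows = 0.9, furnishings = 0.95, hvac = 0.8,
                            supplies_materials = 0.7, pipes = 0.3),
                          factor_prevalence = c(
                            water_damage_stains = 0.52, visible_mold = 0.02,
                            wet_damp = 0.02, mold_odor = 0.17),
                          severity_distribution = c(0.7, 0.2, 0.1),
                          near_exterior_prob = 0.3,
                          component_spread = 0.3,
                          seed = 1L) {
  stopifnot(n_buildings >= 1, rooms_per_building >= 1)
  probs <- rep(NA_real_, length(dmat_components()))
  names(probs) <- dmat_components()
  probs[names(component_presence_probs)] <- component_presence_probs
  probs[basic_components()] <- 1
  if (anyNA(probs)) stop("component_presence_probs must cover: ",
                         paste(names(probs)[is.na(probs)], collapse = ", "))
  need <- c(dmat_factors(), "mold_odor")
  if (!all(need %in% names(factor_prevalence))) {
    stop("factor_prevalence must name: ", paste(need, collapse = ", "))
  }
  if (any(factor_prevalence < 0 | factor_prevalence > 1) ||
      any(probs < 0 | probs > 1) ||
      near_exterior_prob < 0 || near_exterior_prob > 1 ||
      component_spread < 0 || component_spread > 1) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (length(severity_distribution) != 3L ||
      any(severity_distribution < 0) ||
      abs(sum(severity_distribution) - 1) > 1e-9) {
    stop("severity_distribution must be 3 probabilities summing to 1")
  }
  structure(list(n_buildings = as.integer(n_buildings),
                 rooms_per_building = as.integer(rooms_per_building),
                 component_presence_probs = probs,
                 factor_prevalence = factor_prevalence[need],
                 severity_distribution = severity_distribution,
                 near_exterior_prob = near_exterior_prob,
                 component_spread = component_spread,
                 seed = as.integer(seed)),
            class = "campaign_spec")
}

sample_severity <- function(n, probs) {
  sample.int(3L, n, replace = TRUE, prob = probs)
}

#' Generate a synthetic assessment campaign
#'
#' Draws, for every room, the set of existing components, a Bernoulli
#' room-level affected state per factor at the spec prevalence, and — in
#' affected rooms — damage on one guaranteed component plus each further
#' present component with probability `component_spread`, with severities
#' from the spec distribution. Mold-odor intensity in affected rooms follows
#' the same severity distribution. Every generated record passes
#' [validate_assessment()], and the empirical room-level prevalence of each
#' factor is binomial around the spec value.
#'
#' @param spec A [campaign_spec()].
#' @param date Assessment date stamped on every record.
#' @param observer_id Observer identifier stamped on every record.
#' @return List of [room_assessment()] objects.
#' @export
generate_campaign <- function(spec = campaign_spec(),
                              date = as.Date("2024-05-01"),
                              observer_id = "obs1") {
  stopifnot(inherits(spec, "campaign_spec"))
  with_seed(spec$seed, {
    records <- list()
    for (b in seq_len(spec$n_buildings)) {
      bid <- sprintf("B%02d", b)
      for (r in seq_len(spec$rooms_per_building)) {
        present <- dmat_components()[
          stats::runif(8) < spec$component_presence_probs]
        scores <- matrix(0L, nrow = length(present), ncol = 3L,
                         dimnames = list(present, dmat_factors()))
        for (f in dmat_factors()) {
          if (stats::runif(1) < spec$factor_prevalence[[f]]) {
            hit <- stats::runif(length(present)) < spec$component_spread
            hit[sample.int(length(present), 1L)] <- TRUE
            scores[hit, f] <- sample_severity(sum(hit),
                                              spec$severity_distribution)
          }
        }
        odor <- if (stats::runif(1) < spec$factor_prevalence[["mold_odor"]]) {
          intensity <- dmat_odor_intensities()[
            1L + sample_severity(1L, spec$severity_distribution)]
          unknown <- stats::runif(1) < 0.5
          odor_observation(intensity,
                           source_description = if (unknown) "" else
                             "visible source",
                           source_unknown = unknown)
        } else odor_observation("none")
        obs <- lapply(present, function(cc) {
          damaged <- any(scores[cc, ] > 0)
          component_observation(
            component = cc,
            damage_stain = scores[cc, "water_damage_stains"],
            visible_mold = scores[cc, "visible_mold"],
            wet_damp = scores[cc, "wet_damp"],
            near_exterior_wall = damaged &&
              stats::runif(1) < spec$near_exterior_prob)
        })
        records[[length(records) + 1L]] <- room_assessment(
          building_id = bid, room_id = sprintf("R%04d", r),
          assessment_date = date, observer_id = observer_id,
          floor_level = as.character(1L + (r - 1L) %/%
                                       ceiling(spec$rooms_per_building / 3)),
          room_type = "classroom", odor = odor, observations = obs)
      }
    }
    records
  })
}

#' Generate a second observer's assessments of the same campaign
#'
#' Simulates an independent observer who reproduces the first observer's
#' room-level presence/absence call for each factor with probability
#' `agreement_prob`, independently per room and factor. On agreement the
#' scores are copied; on disagreement the factor is either cleared from the
#' room or minimal damage (score 1 on one component; mild odor) is recorded
#' where the first observer saw none. Expected concordance is therefore
#' `100 * agreement_prob`.
#'
#' @param campaign List of [room_assessment()] objects.
#' @param agreement_prob Probability of agreeing on each room-level call.
#' @param seed Integer seed.
#' @param observer_id Identifier stamped on the second observer's records.
#' @return List of [room_assessment()] objects matching `campaign` room for
#'   room.
#' @export
generate_observer_pair <- function(campaign, agreement_prob = 0.75,
                                   seed = 1L, observer_id = "obs2") {
  if (agreement_prob < 0 || agreement_prob > 1) {
    stop("agreement_prob must lie in [0, 1]")
  }
  with_seed(seed, {
    lapply(campaign, function(r) {
      r2 <- r
      r2$observer_id <- observer_id
      for (f in dmat_factors()) {
        agree <- stats::runif(1) < agreement_prob
        was <- room_factor_present(r, f)
        fld <- factor_field(f)
        if ((agree && !was) || (!agree && was)) {
          # second observer records absence: clear the factor
          r2$observations <- lapply(r2$observations, function(o) {
            o[[fld]] <- 0L
            o$nothing_found <- component_total(o) == 0L
            o$near_exterior_wall <- o$near_exterior_wall &&
              component_total(o) > 0L
            o
          })
        } else if (!agree && !was) {
          # second observer records presence the first missed
          i <- sample.int(length(r2$observations), 1L)
          r2$observations[[i]][[fld]] <- 1L
          r2$observations[[i]]$nothing_found <- FALSE
        }
        # agree && was: copy unchanged
      }
      agree_od <- stats::runif(1) < agreement_prob
      was_od <- r$odor$score > 0
      if ((agree_od && !was_od) || (!agree_od && was_od)) {
        r2$odor <- odor_observation("none")
      } else if (!agree_od && !was_od) {
        r2$odor <- odor_observation("mild", source_unknown = TRUE)
      }
      r2
    })
  })
}

#' Specification of synthetic microbial measurements
#'
#' Concentrations are log-normal — the standard model for environmental
#' microbial counts — with an agent-specific baseline log-location and a
#' shared additive shift in log-location per unit of room dampness score.
#'
#' @param meanlog Named numeric baseline log-locations per agent (defaults
#'   span the orders of magnitude typical of dust measurements).
#' @param sdlog Log-scale standard deviation (> 0), shared across agents.
#' @param score_effect Additive shift in log-location per unit room total
#'   score; positive values make damp rooms more contaminated.
#' @param seed Integer seed.
#' @return A list of class `microbial_spec`.
#' @export
microbial_spec <- function(meanlog = stats::setNames(
                             c(10, 11, 9, 8, 4, 2, 6, 3), mmei_agents()),
                           sdlog = 1, score_effect = 0.15, seed = 1L) {
  if (sdlog <= 0) stop("sdlog must be positive")
  if (!all(mmei_agents() %in% names(meanlog))) {
    stop("meanlog must name all eight agents")
  }
  structure(list(meanlog = meanlog[mmei_agents()], sdlog = sdlog,
                 score_effect = score_effect, seed = as.integer(seed)),
            class = "microbial_spec")
}

#' Generate synthetic microbial samples for a campaign
#'
#' One sample per room, eight agents each, log-normal with the log-location
#' shifted by `score_effect` times the room's total dampness score — so a
#' positive effect reproduces the field observation that damper rooms carry
#' higher microbial loads and a higher mixed microbial exposure index.
#'
#' @param campaign List of [room_assessment()] objects.
#' @param spec A [microbial_spec()].
#' @return Data frame with `room_id` (building/room key), the eight agent
#'   columns, and the generating `room_score`.
#' @export
generate_microbial <- function(campaign, spec = microbial_spec()) {
  stopifnot(inherits(spec, "microbial_spec"))
  if (length(campaign) == 0L) stop("empty campaign")
  with_seed(spec$seed, {
    scores <- vapply(campaign, room_total, integer(1))
    keys <- vapply(campaign, room_key, character(1))
    df <- data.frame(room_id = keys, stringsAsFactors = FALSE)
    for (a in mmei_agents()) {
      df[[a]] <- stats::rlnorm(length(campaign),
                               meanlog = spec$meanlog[[a]] +
                                 spec$score_effect * scores,
                               sdlog = spec$sdlog)
    }
    df$room_score <- scores
    df
  })
}

#' Generate a synthetic room-time table
#'
#' Each person is assigned a handful of rooms from the campaign with
#' positive time weights, for exercising the time-weighted average exposure
#' index.
#'
#' @param campaign List of [room_assessment()] objects.
#' @param n_people Number of people.
#' @param max_rooms Maximum rooms per person.
#' @param seed Integer seed.
#' @return Data frame with columns `person_id`, `room_id`, `weight`.
#' @export
generate_room_time <- function(campaign, n_people = 50L, max_rooms = 5L,
                               seed = 1L) {
  if (length(campaign) == 0L) stop("empty campaign")
  with_seed(seed, {
    keys <- vapply(campaign, room_key, character(1))
    rows <- lapply(seq_len(n_people), function(p) {
      k <- sample.int(max_rooms, 1L)
      data.frame(person_id = sprintf("P%03d", p),
                 room_id = sample(keys, min(k, length(keys))),
                 weight = round(stats::runif(min(k, length(keys)),
                                             0.5, 8), 2),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
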