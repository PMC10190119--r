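#' Microbial agents of the mixed microbial exposure index
#'
#' The eight agents measured in floor-dust samples: total culturable fungi
#' and bacteria, Gram-positive and Gram-negative bacteria, endotoxin,
#' ergosterol, (1-3)-beta-D-glucan, and muramic acid.
#'
#' @return Character vector of the eight agent labels.
#' @export
mmei_agents <- function() {
  c("total_culturable_fungi", "total_culturable_bacteria",
    "gram_positive", "gram_negative", "endotoxin", "ergosterol",
    "beta_glucan", "muramic_acid")
}

#' Time-weighted average exposure index
#'
#' An individual's dampness/mold exposure index: the average of the scores
#' of the rooms where the person spends time, weighted by the time spent in
#' each. Weights may be hours, fractions, semester shares — any nonnegative
#' quantities; no normalisation is imposed.
#'
#' @param rooms Character vector of room keys visited.
#' @param weights Nonnegative numeric time weights, same length as `rooms`;
#'   must not all be zero.
#' @param room_scores Named numeric vector mapping room keys to dampness
#'   scores.
#' @return The weighted mean score.
#' @examples
#' twa_exposure(c("r1", "r2"), c(1, 1), c(r1 = 2, r2 = 4))
#' @export
twa_exposure <- function(rooms, weights, room_scores) {
  stopifnot(length(rooms) == length(weights))
  if (any(weights < 0)) stop("time weights must be nonnegative")
  if (sum(weights) <= 0) stop("time weights must not all be zero")
  unknown <- setdiff(rooms, names(room_scores))
  if (length(unknown) > 0L) {
    stop("no score for room(s): ", paste(unknown, collapse = ", "))
  }
  sum(room_scores[rooms] * weights) / sum(weights)
}

#' Decile ranks of a set of values
#'
#' Each value is ranked ordinally (ties broken by stable input order) and
#' assigned the decile `ceiling(10 * rank / n)`, an integer in 1..10. This
#' fixed tie rule makes rank-based composite indices reproducible for tied
#' data.
#'
#' @param values Nonnegative numeric vector, length >= 1.
#' @return Integer vector of deciles in input order.
#' @examples
#' decile_ranks(1:10)
#' decile_ranks(rep(5, 5))
#' @export
decile_ranks <- function(values) {
  n <- length(values)
  if (n == 0L) stop("values must be non-empty")
  if (any(is.na(values))) stop("values must not contain NA")
  r <- rank(values, ties.method = "first")
  as.integer(ceiling(10 * r / n))
}

#' Mixed microbial exposure index (MMEI)
#'
#' A composite index of overall microbial contamination: for each of the
#' eight agents, samples are decile-ranked across the sample set, and a
#' sample's MMEI is the sum of its eight agent-specific decile ranks. The
#' index therefore ranges from 8 (lowest decile on every agent) to 80
#' (highest decile on every agent).
#'
#' @param samples Data frame with one row per sample: a `room_id` column
#'   (any identifier) plus the eight agent columns of [mmei_agents()],
#'   nonnegative concentrations.
#' @return Data frame with columns `room_id` and `mmei`, in input order.
#' @export
mmei <- function(samples) {
  if (nrow(samples) == 0L) stop("need at least one sample")
  missing <- setdiff(mmei_agents(), names(samples))
  if (length(missing) > 0L) {
    stop("missing microbial agent column(s): ",
         paste(missing, collapse = ", "))
  }
  deciles <- vapply(mmei_agents(),
                    function(a) decile_ranks(samples[[a]]),
                    integer(nrow(samples)))
  if (nrow(samples) == 1L) deciles <- matrix(deciles, nrow = 1L)
  data.frame(room_id = samples$room_id,
             mmei = as.integer(rowSums(deciles)),
             stringsAsFactors = FALSE)
}

#' Inter-observer concordance rate
#'
#' Percent of rooms on which two observers agree about the presence or
#' absence of a dampness/mold factor. Assessments are matched by
#' (building, room) key; the factor is judged present in a room when any
#' component scores non-zero (for mold odor, when the room odor score is
#' non-zero). Concordance on presence/absence is the field's crosscheck
#' statistic; `exact_scores = TRUE` instead requires the full score
#' pattern for the factor to match.
#'
#' @param a,b Lists of [room_assessment()] covering the same rooms.
#' @param factor One of [dmat_factors()] or `"mold_odor"`.
#' @param exact_scores Logical; require exact score agreement rather than
#'   presence/absence agreement.
#' @return Percentage in \[0, 100\], rounded to the whole percent.
#' @export
concordance_rate <- function(a, b, factor, exact_scores = FALSE) {
  factor <- factor_or_odor(factor)
  ka <- vapply(a, room_key, character(1))
  kb <- vapply(b, room_key, character(1))
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("each observer must assess each room once")
  }
  if (!setequal(ka, kb)) {
    stop("observers assessed different room sets; unmatched keys: ",
         paste(union(setdiff(ka, kb), setdiff(kb, ka)), collapse = ", "))
  }
  if (length(a) == 0L) stop("no rooms to compare")
  b <- b[match(ka, kb)]
  agree <- vapply(seq_along(a), function(i) {
    if (exact_scores) {
      pattern <- function(r) {
        if (factor == "mold_odor") return(as.character(r$odor$score))
        f <- factor_field(factor)
        sc <- vapply(r$observations, function(o) o[[f]], integer(1))
        paste(sort(paste(components_present(r), sc)), collapse = ";")
      }
      identical(pattern(a[[i]]), pattern(b[[i]]))
    } else {
      room_factor_present(a[[i]], factor) ==
        room_factor_present(b[[i]], factor)
    }
  }, logical(1))
  round(100 * mean(agree))
}

#' Read a room-time table
#'
#' @param path CSV with columns `person_id`, `room_id`, `weight`.
#' @return Data frame with those columns (`weight` numeric).
#' @export
read_room_time <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "room_id", "weight")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column(s): ",
                            paste(missing, collapse = ", "))
  df$weight <- as.numeric(df$weight)
  df[need]
}

#' Read a microbial measurement table
#'
#' @param path CSV with a `room_id` column and the eight agent columns of
#'   [mmei_agents()].
#' @return Data frame ready for [mmei()].
#' @export
read_microbial <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("room_id", mmei_agents()), names(df))
  if (length(missing)) stop("missing column(s): ",
                            paste(missing, collapse = ", "))
  for (a in mmei_agents()) df[[a]] <- as.numeric(df[[a]])
  df[c("room_id", mmei_agents())]
}

#' Time-weighted exposure for every person in a room-time table
#'
#' @param room_time Data frame as from [read_room_time()].
#' @param room_scores Named numeric vector of room scores keyed by room id.
#' @return Data frame with columns `person_id`, `exposure`.
#' @export
twa_exposure_table <- function(room_time, room_scores) {
  people <- sort(unique(room_time$person_id))
  data.frame(
    person_id = people,
    exposure = vapply(people, function(p) {
      sub <- room_time[room_time$person_id == p, , drop = FALSE]
      twa_exposure(sub$room_id, sub$weight, room_scores)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
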