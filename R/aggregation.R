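# Factor argument accepted by room-level aggregations: the three
# component-level factors plus room-level mold odor.
factor_or_odor <- function(factor) {
  match.arg(factor, c(dmat_factors(), "mold_odor"))
}

factor_field <- function(factor) {
  c(water_damage_stains = "damage_stain", visible_mold = "visible_mold",
    wet_damp = "wet_damp")[[factor]]
}

#' Keep only the latest assessment of each room
#'
#' Rooms may be assessed repeatedly; building-level summaries use the most
#' recent assessment of each room (ties on date broken by observer id).
#' Earlier assessments remain available to [diff_assessments()].
#'
#' @param records List of [room_assessment()] objects.
#' @return The subset of `records`, one per (building, room).
#' @export
latest_assessments <- function(records) {
  if (length(records) == 0L) return(records)
  keys <- vapply(records, room_key, character(1))
  dates <- vapply(records, function(r) format(r$assessment_date), character(1))
  obs <- vapply(records, function(r) r$observer_id, character(1))
  ord <- order(keys, dates, obs)
  keep <- ord[!duplicated(keys[ord], fromLast = TRUE)]
  records[sort(keep)]
}

room_factor_present <- function(record, factor) {
  if (factor == "mold_odor") return(record$odor$score > 0)
  f <- factor_field(factor)
  any(vapply(record$observations, function(o) o[[f]] > 0, logical(1)))
}

#' Frequency of non-zero scores by component
#'
#' Counts, over the rooms of a campaign, how many rooms carry each non-zero
#' score (1-3) of a factor on each component — the tabulation behind
#' "which components are the most damaged" bar charts. Mold odor is a
#' room-level observation and is counted per room under the pseudo-component
#' `"mold_odor"`.
#'
#' @param records List of [room_assessment()] objects (latest assessment per
#'   room is used).
#' @param factor One of [dmat_factors()] or `"mold_odor"`.
#' @return Data frame with columns `component`, `score`, `n`; zero-count
#'   combinations are omitted.
#' @export
score_frequency <- function(records, factor) {
  factor <- factor_or_odor(factor)
  records <- latest_assessments(records)
  out <- data.frame(component = character(), score = integer(),
                    n = integer(), stringsAsFactors = FALSE)
  if (factor == "mold_odor") {
    sc <- vapply(records, function(r) r$odor$score, integer(1))
    tab <- table(factor(sc[sc > 0], levels = 1:3))
    keep <- tab > 0
    if (any(keep)) {
      out <- data.frame(component = "mold_odor",
                        score = as.integer(names(tab))[keep],
                        n = as.integer(tab)[keep], stringsAsFactors = FALSE)
    }
    return(out)
  }
  f <- factor_field(factor)
  for (cc in dmat_components()) {
    sc <- unlist(lapply(records, function(r) {
      for (o in r$observations) if (o$component == cc) return(o[[f]])
      NULL
    }))
    if (is.null(sc)) next
    tab <- table(factor(sc[sc > 0], levels = 1:3))
    keep <- tab > 0
    if (any(keep)) {
      out <- rbind(out, data.frame(
        component = cc, score = as.integer(names(tab))[keep],
        n = as.integer(tab)[keep], stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Component-specific school (building) average score
#'
#' Sums a component's total score (its three factor scores added) over all
#' assessed rooms and divides by the number of rooms assessed. Rooms lacking
#' the component contribute zero to the numerator but still count in the
#' denominator.
#'
#' @param records List of [room_assessment()] objects from one building or
#'   school.
#' @param component One of [dmat_components()].
#' @return Nonnegative numeric.
#' @export
component_school_average <- function(records, component) {
  component <- match.arg(component, dmat_components())
  records <- latest_assessments(records)
  if (length(records) == 0L) stop("no assessed rooms")
  tot <- vapply(records, function(r) {
    for (o in r$observations) {
      if (o$component == component) return(component_total(o))
    }
    0L
  }, integer(1))
  sum(tot) / length(records)
}

#' School (building) average dampness/mold score
#'
#' The room total scores summed across all assessed rooms of a school and
#' averaged by the number of rooms — the building-level exposure summary
#' used to dichotomize schools for epidemiologic analysis.
#'
#' @param records List of [room_assessment()] objects from one school.
#' @return Nonnegative numeric.
#' @export
school_average_score <- function(records) {
  records <- latest_assessments(records)
  if (length(records) == 0L) stop("no assessed rooms")
  mean(vapply(records, room_total, numeric(1)))
}

#' Dichotomize schools by their median average score
#'
#' Schools strictly above the median of all school average scores are
#' classed `"above"`, all others `"at_or_below"`. The median is the midpoint
#' of the two central order statistics for even counts; schools exactly at
#' the median fall in the lower group.
#'
#' @param school_scores Named numeric vector of school average scores.
#' @return Named character vector with values `"above"` / `"at_or_below"`.
#' @export
dichotomize_by_median <- function(school_scores) {
  if (length(school_scores) < 2L) stop("need at least two schools")
  med <- stats::median(school_scores)
  stats::setNames(ifelse(school_scores > med, "above", "at_or_below"),
                  names(school_scores))
}

#' Color-band every room of a campaign
#'
#' Applies [classify_room()] to each room's total score and returns a tidy
#' table suitable for joining to a floor map.
#'
#' @param records List of [room_assessment()] objects (latest assessment per
#'   room is used).
#' @return Data frame with columns `building_id`, `room_id`, `floor_level`,
#'   `room_total`, `color_band`, sorted by building and room.
#' @export
band_rooms <- function(records) {
  records <- latest_assessments(records)
  if (length(records) == 0L) {
    return(data.frame(building_id = character(), room_id = character(),
                      floor_level = character(), room_total = integer(),
                      color_band = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    building_id = vapply(records, function(r) r$building_id, character(1)),
    room_id = vapply(records, function(r) r$room_id, character(1)),
    floor_level = vapply(records, function(r) r$floor_level, character(1)),
    room_total = vapply(records, room_total, integer(1)),
    stringsAsFactors = FALSE)
  df$color_band <- as.character(classify_room(df$room_total))
  df <- df[order(df$building_id, df$room_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Room-level prevalence of a factor
#'
#' Proportion of assessed rooms affected by the factor: a room counts as
#' affected if any of its components carries a non-zero score for the factor
#' (for mold odor, if the room's odor score is non-zero).
#'
#' @param records List of [room_assessment()] objects.
#' @param factor One of [dmat_factors()] or `"mold_odor"`.
#' @return Proportion in \[0, 1\].
#' @export
factor_prevalence <- function(records, factor) {
  factor <- factor_or_odor(factor)
  records <- latest_assessments(records)
  if (length(records) == 0L) stop("no assessed rooms")
  mean(vapply(records, room_factor_present, logical(1), factor = factor))
}

#' Summarise a campaign by building/school
#'
#' Computes, per group (building by default), the number of assessed rooms,
#' the school average score, every component-specific school average, and
#' the room-level prevalence of each factor and of mold odor.
#'
#' @param records List of [room_assessment()] objects.
#' @param group Function mapping a record to its group key; defaults to the
#'   building id.
#' @return Data frame, one row per group, sorted by group key.
#' @export
campaign_summary <- function(records, group = function(r) r$building_id) {
  records <- latest_assessments(records)
  if (length(records) == 0L) stop("no assessed rooms")
  keys <- vapply(records, group, character(1))
  rows <- lapply(sort(unique(keys)), function(k) {
    sub <- records[keys == k]
    df <- data.frame(group = k, n_rooms = length(sub),
                     school_average_score = school_average_score(sub),
                     stringsAsFactors = FALSE)
    for (cc in dmat_components()) {
      df[[paste0("avg_", cc)]] <- component_school_average(sub, cc)
    }
    for (f in c(dmat_factors(), "mold_odor")) {
      df[[paste0("prev_", f)]] <- factor_prevalence(sub, f)
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
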