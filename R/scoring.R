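# Reference areas for the size-to-score mapping, in square inches:
# a standard paper sheet (8.5 x 11) and a standard interior door (32 x 80).
PAPER_SHEET_IN2 <- 8.5 * 11   # 93.5
INTERIOR_DOOR_IN2 <- 32 * 80  # 2560

#' Map a combined damage area to its ordinal score
#'
#' Damage on one component is sized by the combined area of all patches:
#' score 1 for damage up to the size of a standard sheet of paper
#' (8.5 x 11 in = 93.5 in^2), 2 for damage up to the size of a standard
#' interior door (32 x 80 in = 2560 in^2), 3 beyond that, and 0 for no
#' damage. Areas exactly at a threshold take the lower score (closed lower
#' interval). Observers normally judge the category directly in the field;
#' this mapping serves training and synthetic data.
#'
#' @param area Numeric vector of combined damaged areas in square inches.
#' @return Integer scores in 0..3.
#' @examples
#' size_to_score(c(0, 60, 500, 3000))
#' @export
size_to_score <- function(area) {
  if (any(is.na(area))) stop("area must not contain NA")
  if (any(area < 0)) stop("area must be nonnegative")
  ifelse(area == 0, 0L,
         ifelse(area <= PAPER_SHEET_IN2, 1L,
                ifelse(area <= INTERIOR_DOOR_IN2, 2L, 3L)))
}

#' Component-specific total score
#'
#' Sum of the three dampness/mold-related factor scores (water
#' damage/stains, visible mold, wet/damp) for one component; range 0-9.
#'
#' @param obs A [component_observation()].
#' @return Integer in 0..9.
#' @export
component_total <- function(obs) {
  obs$damage_stain + obs$visible_mold + obs$wet_damp
}

#' Total room score
#'
#' Sum of all component-specific total scores over the room's existing
#' components, plus the mold-odor score. With all eight components present
#' the attainable range is 0-75.
#'
#' @param record A [room_assessment()].
#' @return Integer.
#' @export
room_total <- function(record) {
  sum(vapply(record$observations, component_total, integer(1))) +
    record$odor$score
}

#' Factor-specific average score
#'
#' A factor's scores summed over the room's existing components, divided by
#' the number of existing components. Components that do not exist in the
#' room are excluded from both numerator and denominator.
#'
#' @param record A [room_assessment()].
#' @param factor One of [dmat_factors()].
#' @return Nonnegative numeric.
#' @export
factor_average <- function(record, factor) {
  factor <- match.arg(factor, dmat_factors())
  n <- length(record$observations)
  if (n == 0L) stop("record has no existing components")
  key <- c(water_damage_stains = "damage_stain", visible_mold = "visible_mold",
           wet_damp = "wet_damp")[[factor]]
  sum(vapply(record$observations, function(o) o[[key]], numeric(1))) / n
}

#' Total average room score
#'
#' Sum of the three factor-specific average scores plus the mold-odor score.
#' The odor score enters undivided: it is a room-level observation, not a
#' per-component one.
#'
#' @param record A [room_assessment()].
#' @return Nonnegative numeric; at most 12 (three factor averages of 3 plus
#'   odor 3).
#' @export
room_average <- function(record) {
  sum(vapply(dmat_factors(), function(f) factor_average(record, f),
             numeric(1))) + record$odor$score
}

#' Classify a room total score into a floor-map color band
#'
#' Low scores 1-2 map to green, medium scores 3-6 to yellow, and high
#' scores of 7 or more to red. A total of 0 (no damage at all) falls below
#' the green band and is classified `"none"`.
#'
#' @param total Nonnegative integer vector of room total scores.
#' @return Factor with ordered levels `none < green < yellow < red`.
#' @examples
#' classify_room(c(0, 2, 5, 9))
#' @export
classify_room <- function(total) {
  if (any(is.na(total))) stop("total must not contain NA")
  if (any(total < 0)) stop("total must be nonnegative")
  bands <- c("none", "green", "yellow", "red")
  idx <- ifelse(total == 0, 1L,
                ifelse(total <= 2, 2L, ifelse(total <= 6, 3L, 4L)))
  factor(bands[idx], levels = bands, ordered = TRUE)
}

#' Score a room assessment
#'
#' Computes every room-level summary from the raw factor scores: the
#' component-specific totals, the total room score, the three
#' factor-specific averages, the total average room score, and the color
#' band of the total.
#'
#' @param record A valid [room_assessment()].
#' @return An object of class `room_scores`: a list with elements
#'   `building_id`, `room_id`, `assessment_date`, `observer_id`,
#'   `component_totals` (named integer vector over existing components),
#'   `room_total`, `factor_averages` (named numeric over the three factors),
#'   `room_average`, `odor_score`, `n_components`, `color_band`.
#' @export
score_room <- function(record) {
  rep <- validate_assessment(record)
  if (!is_clean(rep)) {
    stop("invalid record: ", paste(rep$message[rep$severity == "error"],
                                   collapse = "; "))
  }
  totals <- vapply(record$observations, component_total, integer(1))
  names(totals) <- components_present(record)
  fav <- vapply(dmat_factors(), function(f) factor_average(record, f),
                numeric(1))
  structure(
    list(building_id = record$building_id,
         room_id = record$room_id,
         assessment_date = record$assessment_date,
         observer_id = record$observer_id,
         component_totals = totals,
         room_total = room_total(record),
         factor_averages = fav,
         room_average = room_average(record),
         odor_score = record$odor$score,
         n_components = length(record$observations),
         color_band = as.character(classify_room(room_total(record)))),
    class = "room_scores"
  )
}

#' @export
print.room_scores <- function(x, ...) {
  cat(sprintf("Room scores: building %s, room %s (%s)\n",
              x$building_id, x$room_id, format(x$assessment_date)))
  cat("  component totals: ",
      paste(sprintf("%s=%d", names(x$component_totals), x$component_totals),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  room total %d (band: %s), odor %d\n",
              x$room_total, x$color_band, x$odor_score))
  cat("  factor averages: ",
      paste(sprintf("%s=%.2f", names(x$factor_averages), x$factor_averages),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  room average %.2f over %d components\n",
              x$room_average, x$n_components))
  invisible(x)
}

#' Score every room in a campaign
#'
#' Applies [score_room()] to each record and assembles a flat table, one
#' row per room, with component totals (`NA` for components that do not
#' exist in the room), the room total and average, factor averages, the
#' odor score and the color band.
#'
#' @param records List of [room_assessment()] objects.
#' @return A data frame with one row per record.
#' @export
score_rooms <- function(records) {
  comps <- dmat_components()
  rows <- lapply(records, function(r) {
    s <- score_room(r)
    ct <- rep(NA_integer_, length(comps))
    names(ct) <- comps
    ct[names(s$component_totals)] <- s$component_totals
    df <- data.frame(building_id = s$building_id, room_id = s$room_id,
                     assessment_date = s$assessment_date,
                     observer_id = s$observer_id,
                     n_components = s$n_components,
                     stringsAsFactors = FALSE)
    for (cc in comps) df[[paste0(cc, "_total")]] <- ct[[cc]]
    df$odor_score <- s$odor_score
    df$room_total <- s$room_total
    df$avg_water_damage_stains <- s$factor_averages[["water_damage_stains"]]
    df$avg_visible_mold <- s$factor_averages[["visible_mold"]]
    df$avg_wet_damp <- s$factor_averages[["wet_damp"]]
    df$room_average <- s$room_average
    df$color_band <- s$color_band
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- score_rooms_header()
  rownames(out) <- NULL
  out
}

score_rooms_header <- function() {
  comps <- dmat_components()
  df <- data.frame(building_id = character(), room_id = character(),
                   assessment_date = as.Date(character()),
                   observer_id = character(),
                   n_components = integer(), stringsAsFactors = FALSE)
  for (cc in comps) df[[paste0(cc, "_total")]] <- integer()
  df$odor_score <- integer()
  df$room_total <- integer()
  df$avg_water_damage_stains <- numeric()
  df$avg_visible_mold <- numeric()
  df$avg_wet_damp <- numeric()
  df$room_average <- numeric()
  df$color_band <- character()
  df
}
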