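#' Controlled vocabularies for dampness/mold assessments
#'
#' The assessment instrument scores four dampness/mold-related factors on a
#' 0-3 ordinal scale. Mold odor is judged once per room by intensity; the
#' three remaining factors (water damage/stains, visible mold, wet/damp
#' materials) are judged per room component by combined damage size. Eight
#' room components are recognised; the ceiling, walls and floor are the
#' basic components expected in every enclosed room.
#'
#' @return Character vectors of the canonical labels, in canonical order.
#' @examples
#' dmat_components()
#' dmat_factors()
#' @export
dmat_components <- function() {
  c("ceiling", "walls", "floor", "windows", "furnishings", "hvac",
    "supplies_materials", "pipes")
}

#' @rdname dmat_components
#' @export
dmat_factors <- function() {
  c("water_damage_stains", "visible_mold", "wet_damp")
}

#' @rdname dmat_components
#' @export
dmat_odor_intensities <- function() {
  c("none", "mild", "moderate", "strong")
}

# Basic components pre-marked on the form.
basic_components <- function() c("ceiling", "walls", "floor")

#' Map a mold-odor intensity to its ordinal score
#'
#' Intensities map none=0, mild=1, moderate=2, strong=3, mirroring the 0-3
#' size scale used for the component-level factors.
#'
#' @param intensity Character vector of intensities.
#' @return Integer scores in 0..3.
#' @export
odor_intensity_score <- function(intensity) {
  m <- match(intensity, dmat_odor_intensities())
  if (anyNA(m)) {
    stop("unknown odor intensity: ",
         paste(unique(intensity[is.na(m)]), collapse = ", "))
  }
  m - 1L
}

#' Construct a mold-odor observation
#'
#' @param intensity One of `"none"`, `"mild"`, `"moderate"`, `"strong"`.
#' @param source_description Free text locating the odor source (empty if
#'   none identified).
#' @param source_unknown Logical; `TRUE` when odor is present but its source
#'   could not be identified (a marker of potential hidden mold). Only
#'   meaningful when `intensity != "none"`.
#' @return An object of class `odor_observation`.
#' @export
odor_observation <- function(intensity = "none", source_description = "",
                             source_unknown = FALSE) {
  stopifnot(length(intensity) == 1L, is.character(source_description),
            is.logical(source_unknown), length(source_unknown) == 1L)
  structure(
    list(intensity = intensity,
         score = if (intensity %in% dmat_odor_intensities())
           odor_intensity_score(intensity) else NA_integer_,
         source_description = as.character(source_description),
         source_unknown = source_unknown),
    class = "odor_observation"
  )
}

#' Construct a component observation
#'
#' One room component's three factor scores plus the near-exterior-wall and
#' nothing-found flags. Scores are ordinal 0-3: 0 no damage, 1 combined
#' damage smaller than a standard paper sheet, 2 between a paper sheet and a
#' standard interior door, 3 larger than a door (see [size_to_score()]).
#'
#' @param component One of [dmat_components()].
#' @param damage_stain,visible_mold,wet_damp Integer scores in 0..3.
#' @param near_exterior_wall Logical; damage within three feet of an
#'   exterior wall (qualifies observed damage, so requires a non-zero score).
#' @param nothing_found Logical; shorthand for all three factors scoring 0.
#'   Defaults to `TRUE` exactly when all scores are 0.
#' @param component_note,assessment_note Free text.
#' @return An object of class `component_observation`.
#' @export
component_observation <- function(component,
                                  damage_stain = 0L, visible_mold = 0L,
                                  wet_damp = 0L,
                                  near_exterior_wall = FALSE,
                                  nothing_found = NULL,
                                  component_note = "",
                                  assessment_note = "") {
  scores <- c(damage_stain, visible_mold, wet_damp)
  if (is.null(nothing_found)) nothing_found <- all(scores == 0)
  structure(
    list(component = component,
         damage_stain = as.integer(damage_stain),
         visible_mold = as.integer(visible_mold),
         wet_damp = as.integer(wet_damp),
         near_exterior_wall = isTRUE(near_exterior_wall),
         nothing_found = isTRUE(nothing_found),
         component_note = as.character(component_note),
         assessment_note = as.character(assessment_note)),
    class = "component_observation"
  )
}

#' Construct a room assessment record
#'
#' One visit to one room/area: identifying metadata, the room-level mold
#' odor observation, and one [component_observation()] per existing room
#' component. Components not listed in `observations` are treated as not
#' existing in the room and are excluded from averages.
#'
#' @param building_id,room_id,observer_id Identifiers.
#' @param assessment_date A `Date` (or string coercible to one).
#' @param floor_level,room_type Free-text descriptors.
#' @param odor An [odor_observation()].
#' @param observations List of [component_observation()] (at most one per
#'   component).
#' @return An object of class `room_assessment`.
#' @export
room_assessment <- function(building_id, room_id, assessment_date,
                            observer_id = "obs1",
                            floor_level = "", room_type = "",
                            odor = odor_observation(),
                            observations = list()) {
  structure(
    list(building_id = as.character(building_id),
         room_id = as.character(room_id),
         floor_level = as.character(floor_level),
         room_type = as.character(room_type),
         assessment_date = as.Date(assessment_date),
         observer_id = as.character(observer_id),
         odor = odor,
         observations = observations),
    class = "room_assessment"
  )
}

#' @export
print.room_assessment <- function(x, ...) {
  cat(sprintf("Room assessment: building %s, room %s (%s), observer %s\n",
              x$building_id, x$room_id, format(x$assessment_date),
              x$observer_id))
  cat(sprintf("  mold odor: %s (score %d)\n", x$odor$intensity, x$odor$score))
  for (obs in x$observations) {
    cat(sprintf("  %-18s damage/stains %d, visible mold %d, wet/damp %d%s%s\n",
                obs$component, obs$damage_stain, obs$visible_mold,
                obs$wet_damp,
                if (obs$near_exterior_wall) " [near exterior wall]" else "",
                if (obs$nothing_found) " [nothing found]" else ""))
  }
  invisible(x)
}

# Key identifying a room across campaigns.
room_key <- function(record) paste(record$building_id, record$room_id, sep = "/")

components_present <- function(record) {
  vapply(record$observations, function(o) o$component, character(1))
}

violation <- function(field, message, severity = "error") {
  data.frame(field = field, message = message, severity = severity,
             stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(field = character(), message = character(),
             severity = character(), stringsAsFactors = FALSE)
}

valid_score <- function(s) {
  length(s) == 1L && !is.na(s) && s %in% 0:3
}

#' Validate a room assessment record
#'
#' Checks every structural invariant of the data model and returns the
#' violations as data, not exceptions: an empty report means the record is
#' valid. Violations carry a field path, a message, and a severity;
#' `"warning"` rows (e.g. an unlisted school room type, or a missing basic
#' component) flag unusual but acceptable records and do not make the record
#' invalid.
#'
#' Checked invariants: scores in 0..3; the odor score matches its intensity;
#' `source_unknown` only with odor present; `nothing_found` only with all
#' three factor scores 0; `near_exterior_wall` only qualifying a non-zero
#' score; known component names, at most one observation per component, at
#' least one existing component.
#'
#' @param record A [room_assessment()].
#' @param room_types Optional character vector of allowed room types (e.g.
#'   the school form's controlled list); unlisted types produce a warning
#'   row, never a rejection.
#' @return A data frame with columns `field`, `message`, `severity`;
#'   zero rows iff the record is fully clean.
#' @export
validate_assessment <- function(record, room_types = NULL) {
  rep <- empty_report()
  add <- function(...) rep <<- rbind(rep, violation(...))

  if (!inherits(record, "room_assessment")) {
    return(violation("record", "not a room_assessment object"))
  }
  for (f in c("building_id", "room_id", "observer_id")) {
    if (is.na(record[[f]]) || !nzchar(record[[f]]))
      add(f, "identifier must be non-empty")
  }
  if (is.na(record$assessment_date))
    add("assessment_date", "missing or unparseable date")

  od <- record$odor
  if (!od$intensity %in% dmat_odor_intensities()) {
    add("odor.intensity", paste0("unknown intensity '", od$intensity, "'"))
  } else if (is.na(od$score) ||
             od$score != odor_intensity_score(od$intensity)) {
    add("odor.score", sprintf("score %s does not match intensity '%s'",
                              od$score, od$intensity))
  }
  if (isTRUE(od$source_unknown) && identical(od$intensity, "none"))
    add("odor.source_unknown", "source_unknown set but no odor observed")

  comps <- character(0)
  for (i in seq_along(record$observations)) {
    obs <- record$observations[[i]]
    path <- function(f) sprintf("observations[%s].%s", obs$component, f)
    if (!obs$component %in% dmat_components()) {
      add(sprintf("observations[[%d]].component", i),
          paste0("unknown component '", obs$component, "'"))
      next
    }
    if (obs$component %in% comps)
      add(path("component"), "duplicate component")
    comps <- c(comps, obs$component)
    scores <- c(damage_stain = obs$damage_stain,
                visible_mold = obs$visible_mold, wet_damp = obs$wet_damp)
    for (f in names(scores)) {
      if (!valid_score(scores[[f]]))
        add(path(f), sprintf("score must be an integer in 0..3, got %s",
                             scores[[f]]))
    }
    ok <- all(vapply(scores, valid_score, logical(1)))
    if (ok) {
      if (obs$nothing_found && any(scores > 0))
        add(path("nothing_found"),
            "nothing_found set but a factor score is non-zero")
      if (obs$near_exterior_wall && all(scores == 0))
        add(path("near_exterior_wall"),
            "near_exterior_wall qualifies damage; all scores are zero")
    }
  }
  if (length(record$observations) == 0L)
    add("observations", "no existing components recorded")
  missing_basic <- setdiff(basic_components(), comps)
  if (length(record$observations) > 0L && length(missing_basic) > 0L)
    add("observations",
        paste("basic component(s) not recorded:",
              paste(missing_basic, collapse = ", ")),
        severity = "warning")
  if (!is.null(room_types) && nzchar(record$room_type) &&
      !record$room_type %in% room_types)
    add("room_type",
        paste0("room type '", record$room_type, "' not in controlled list"),
        severity = "warning")
  rep
}

#' Validate a collection of assessments
#'
#' Runs [validate_assessment()] on every record and additionally checks the
#' collection-level uniqueness of the (building, room, date, observer) key.
#'
#' @param records List of [room_assessment()] objects.
#' @param room_types Passed to [validate_assessment()].
#' @return A data frame with columns `row`, `field`, `message`, `severity`.
#' @export
validate_campaign <- function(records, room_types = NULL) {
  reps <- lapply(seq_along(records), function(i) {
    r <- validate_assessment(records[[i]], room_types = room_types)
    if (nrow(r)) cbind(row = i, r) else NULL
  })
  out <- do.call(rbind, c(list(cbind(row = integer(0), empty_report())), reps))
  keys <- vapply(records, function(r)
    paste(r$building_id, r$room_id, format(r$assessment_date),
          r$observer_id, sep = "|"), character(1))
  dup <- which(duplicated(keys))
  for (i in dup) {
    out <- rbind(out, cbind(row = i, violation(
      "key", "duplicate (building, room, date, observer) key")))
  }
  rownames(out) <- NULL
  out
}

#' Does a validation report contain no errors?
#'
#' @param report A report from [validate_assessment()] or
#'   [validate_campaign()].
#' @return Logical.
#' @export
is_clean <- function(report) {
  !any(report$severity == "error")
}
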