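# Flat CSV layout: the two-level spreadsheet headers (metadata block, mold
# odor block, one block per component) flattened to snake_case columns.
DMAT_SCHEMA_VERSION <- "1.0"

component_columns <- function(component) {
  paste0(component, c("_present", "_damage_stain", "_visible_mold",
                      "_wet_damp", "_near_exterior", "_nothing_found",
                      "_note", "_assessment_note"))
}

#' Column layout of the flat assessment CSV
#'
#' The canonical, versioned header of the assessment CSV dialect: record
#' metadata, the mold-odor block, then eight columns per room component
#' (presence marker, the three factor scores, the near-exterior-wall and
#' nothing-found flags, and the two note fields), and a trailing schema
#' version column. Unknown columns in input files are ignored.
#'
#' @return Character vector of column names in file order.
#' @export
assessment_columns <- function() {
  c("building_id", "room_id", "floor_level", "room_type", "date",
    "observer_id", "odor_intensity", "odor_score", "odor_source",
    "odor_source_unknown",
    unlist(lapply(dmat_components(), component_columns)),
    "dmat_schema")
}

# Cell conventions shared by reader and writer ------------------------------

cell_truthy <- function(x) {
  !is.na(x) & trimws(x) %in% c("1", "TRUE", "true", "T", "yes")
}

parse_score_cell <- function(x) {
  # empty cell means 0 on a present component
  x <- trimws(x)
  if (is.na(x) || !nzchar(x)) return(0L)
  v <- suppressWarnings(as.integer(x))
  if (is.na(v)) return(NA_integer_)
  v
}

#' Read assessment records from a flat CSV file
#'
#' Decodes the spreadsheet conventions of the field: an empty factor-score
#' cell on a present component means a score of 0; an empty
#' `<component>_present` cell means the component does not exist in the room
#' and contributes no observation; the mold-odor score cell must always be
#' filled (no odor is entered as `0`, never left blank). A non-zero factor
#' score on a non-present component is reported as a violation and the score
#' is dropped.
#'
#' @param path Path to a CSV file with the header of [assessment_columns()]
#'   (extra columns are ignored).
#' @return A list with elements `records` (list of [room_assessment()]) and
#'   `report` (data frame of per-row violations with columns `row`, `field`,
#'   `message`, `severity`; file rows are numbered from 1).
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  mandatory <- setdiff(assessment_columns(),
                       c("dmat_schema",
                         unlist(lapply(dmat_components(), function(cc)
                           paste0(cc, c("_note", "_assessment_note"))))))
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  cellv <- function(row, col) {
    if (!col %in% names(df)) "" else {
      v <- df[[col]][row]
      if (is.na(v)) "" else v
    }
  }

  records <- vector("list", nrow(df))
  report <- cbind(row = integer(0), empty_report())
  add <- function(row, field, message, severity = "error") {
    report <<- rbind(report, cbind(row = row,
                                   violation(field, message, severity)))
  }

  for (i in seq_len(nrow(df))) {
    odor_score_cell <- trimws(cellv(i, "odor_score"))
    odor_int <- trimws(cellv(i, "odor_intensity"))
    if (!nzchar(odor_score_cell)) {
      add(i, "odor_score",
          "mold-odor score must be entered explicitly ('0' for no odor)")
      if (!nzchar(odor_int)) odor_int <- "none"
    } else {
      sc <- suppressWarnings(as.integer(odor_score_cell))
      if (is.na(sc) || !sc %in% 0:3) {
        add(i, "odor_score", paste0("unparseable odor score '",
                                    odor_score_cell, "'"))
        if (!nzchar(odor_int)) odor_int <- "none"
      } else if (!nzchar(odor_int)) {
        odor_int <- dmat_odor_intensities()[sc + 1L]
      }
    }
    odor <- odor_observation(
      intensity = if (odor_int %in% dmat_odor_intensities()) odor_int else odor_int,
      source_description = cellv(i, "odor_source"),
      source_unknown = cell_truthy(cellv(i, "odor_source_unknown")))

    obs <- list()
    for (cc in dmat_components()) {
      present <- cell_truthy(cellv(i, paste0(cc, "_present")))
      scores <- vapply(c("_damage_stain", "_visible_mold", "_wet_damp"),
                       function(sfx) parse_score_cell(cellv(i, paste0(cc, sfx))),
                       integer(1))
      if (!present) {
        if (any(!is.na(scores) & scores > 0)) {
          add(i, paste0(cc, "_present"),
              "factor score recorded on a non-present component")
        }
        next
      }
      if (anyNA(scores)) {
        add(i, cc, "unparseable factor score")
        scores[is.na(scores)] <- 0L
      }
      obs[[length(obs) + 1L]] <- component_observation(
        component = cc,
        damage_stain = scores[[1L]], visible_mold = scores[[2L]],
        wet_damp = scores[[3L]],
        near_exterior_wall = cell_truthy(cellv(i, paste0(cc, "_near_exterior"))),
        nothing_found = cell_truthy(cellv(i, paste0(cc, "_nothing_found"))) ||
          all(scores == 0L),
        component_note = cellv(i, paste0(cc, "_note")),
        assessment_note = cellv(i, paste0(cc, "_assessment_note")))
    }

    rec <- room_assessment(
      building_id = cellv(i, "building_id"), room_id = cellv(i, "room_id"),
      assessment_date = {
        d <- suppressWarnings(as.Date(cellv(i, "date")))
        if (length(d) == 0L) NA else d
      },
      observer_id = cellv(i, "observer_id"),
      floor_level = cellv(i, "floor_level"),
      room_type = cellv(i, "room_type"),
      odor = odor, observations = obs)
    records[[i]] <- rec
    vr <- validate_assessment(rec)
    if (nrow(vr)) report <- rbind(report, cbind(row = i, vr))
  }
  rownames(report) <- NULL
  list(records = records, report = report)
}

record_order <- function(records) {
  order(vapply(records, function(r) r$building_id, character(1)),
        vapply(records, function(r) r$room_id, character(1)),
        vapply(records, function(r) format(r$assessment_date), character(1)),
        vapply(records, function(r) r$observer_id, character(1)))
}

#' Write assessment records to a flat CSV file
#'
#' Rows are sorted by building, room, date and observer, so output is
#' byte-identical regardless of input order. Zeros and flags are written
#' explicitly (never as blanks) to keep "assessed as 0" distinct from "not
#' assessed"; columns of non-present components are left empty. Dates are
#' ISO-8601, the file is UTF-8 comma-separated with RFC-4180 quoting.
#'
#' @param records List of [room_assessment()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(records, path) {
  cols <- assessment_columns()
  rows <- lapply(records[record_order(records)], function(r) {
    row <- stats::setNames(as.list(rep("", length(cols))), cols)
    row$building_id <- r$building_id
    row$room_id <- r$room_id
    row$floor_level <- r$floor_level
    row$room_type <- r$room_type
    row$date <- format(r$assessment_date)
    row$observer_id <- r$observer_id
    row$odor_intensity <- r$odor$intensity
    row$odor_score <- as.character(r$odor$score)
    row$odor_source <- r$odor$source_description
    row$odor_source_unknown <- if (r$odor$source_unknown) "1" else "0"
    for (obs in r$observations) {
      cc <- obs$component
      row[[paste0(cc, "_present")]] <- "1"
      row[[paste0(cc, "_damage_stain")]] <- as.character(obs$damage_stain)
      row[[paste0(cc, "_visible_mold")]] <- as.character(obs$visible_mold)
      row[[paste0(cc, "_wet_damp")]] <- as.character(obs$wet_damp)
      row[[paste0(cc, "_near_exterior")]] <- if (obs$near_exterior_wall) "1" else "0"
      row[[paste0(cc, "_nothing_found")]] <- if (obs$nothing_found) "1" else "0"
      row[[paste0(cc, "_note")]] <- obs$component_note
      row[[paste0(cc, "_assessment_note")]] <- obs$assessment_note
    }
    row$dmat_schema <- DMAT_SCHEMA_VERSION
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "",
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Write room summary scores to a CSV file
#'
#' One row per room with the component totals, room total, factor averages
#' (formatted to 6 decimals), room average, odor score and color band.
#' Rows are sorted by building, room and date for deterministic output.
#'
#' @param scores Data frame from [score_rooms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- scores[order(scores$building_id, scores$room_id,
                     scores$assessment_date, scores$observer_id), ,
               drop = FALSE]
  df$assessment_date <- format(df$assessment_date)
  for (col in c("avg_water_damage_stains", "avg_visible_mold",
                "avg_wet_damp", "room_average")) {
    df[[col]] <- sprintf("%.6f", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "",
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
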