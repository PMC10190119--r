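#' Classify the change between two scores
#'
#' Pure function of (previous, current): damage appearing from zero is
#' `new`, rising is `worsened`, equal (including 0 to 0) is `unchanged`,
#' falling but still present is `improved`, and disappearing to zero is
#' `resolved`.
#'
#' @param previous,current Integer score vectors (0..3).
#' @return Character vector of statuses.
#' @export
change_status <- function(previous, current) {
  stopifnot(length(previous) == length(current))
  ifelse(current == previous, "unchanged",
         ifelse(previous == 0, "new",
                ifelse(current == 0, "resolved",
                       ifelse(current > previous, "worsened", "improved"))))
}

obs_by_component <- function(record) {
  stats::setNames(record$observations, components_present(record))
}

#' Compare two assessment campaigns room by room
#'
#' Matches the two campaigns on (building, room) keys and emits one change
#' record per (room, component, factor) observed in both campaigns, plus the
#' room-level change in total score and band transition. Mold odor is
#' compared at room level under the pseudo-component `"mold_odor"`.
#' Components existing in only one campaign (e.g. furnishings removed) are
#' listed as structural changes and excluded from score deltas; rooms in
#' only one campaign are listed as added/removed. Mismatches are reported,
#' never fatal.
#'
#' @param previous,current Lists of [room_assessment()] objects (latest
#'   assessment per room is used within each campaign).
#' @return A list of class `dmat_diff` with elements `changes`, `rooms`,
#'   `structural`, `added_rooms`, `removed_rooms` (all data frames /
#'   character vectors with deterministic ordering).
#' @export
diff_assessments <- function(previous, current) {
  previous <- latest_assessments(previous)
  current <- latest_assessments(current)
  kp <- vapply(previous, room_key, character(1))
  kc <- vapply(current, room_key, character(1))
  common <- sort(intersect(kp, kc))

  changes <- data.frame(building_id = character(), room_id = character(),
                        component = character(), factor = character(),
                        previous = integer(), current = integer(),
                        status = character(), stringsAsFactors = FALSE)
  rooms <- data.frame(building_id = character(), room_id = character(),
                      previous_total = integer(), current_total = integer(),
                      delta_total = integer(), previous_band = character(),
                      current_band = character(), stringsAsFactors = FALSE)
  structural <- data.frame(building_id = character(), room_id = character(),
                           component = character(), change = character(),
                           stringsAsFactors = FALSE)

  for (k in common) {
    rp <- previous[[match(k, kp)]]
    rc <- current[[match(k, kc)]]
    op <- obs_by_component(rp)
    oc <- obs_by_component(rc)
    both <- intersect(dmat_components(), intersect(names(op), names(oc)))
    for (cc in both) {
      for (f in dmat_factors()) {
        fld <- factor_field(f)
        changes <- rbind(changes, data.frame(
          building_id = rc$building_id, room_id = rc$room_id,
          component = cc, factor = f,
          previous = op[[cc]][[fld]], current = oc[[cc]][[fld]],
          status = change_status(op[[cc]][[fld]], oc[[cc]][[fld]]),
          stringsAsFactors = FALSE))
      }
    }
    changes <- rbind(changes, data.frame(
      building_id = rc$building_id, room_id = rc$room_id,
      component = "mold_odor", factor = "mold_odor",
      previous = rp$odor$score, current = rc$odor$score,
      status = change_status(rp$odor$score, rc$odor$score),
      stringsAsFactors = FALSE))
    for (cc in intersect(dmat_components(),
                         setdiff(names(op), names(oc)))) {
      structural <- rbind(structural, data.frame(
        building_id = rc$building_id, room_id = rc$room_id,
        component = cc, change = "removed", stringsAsFactors = FALSE))
    }
    for (cc in intersect(dmat_components(),
                         setdiff(names(oc), names(op)))) {
      structural <- rbind(structural, data.frame(
        building_id = rc$building_id, room_id = rc$room_id,
        component = cc, change = "added", stringsAsFactors = FALSE))
    }
    pt <- room_total(rp)
    ct <- room_total(rc)
    rooms <- rbind(rooms, data.frame(
      building_id = rc$building_id, room_id = rc$room_id,
      previous_total = pt, current_total = ct, delta_total = ct - pt,
      previous_band = as.character(classify_room(pt)),
      current_band = as.character(classify_room(ct)),
      stringsAsFactors = FALSE))
  }
  rownames(changes) <- rownames(rooms) <- rownames(structural) <- NULL
  structure(
    list(changes = changes, rooms = rooms, structural = structural,
         added_rooms = sort(setdiff(kc, kp)),
         removed_rooms = sort(setdiff(kp, kc))),
    class = "dmat_diff")
}

#' @export
print.dmat_diff <- function(x, ...) {
  changed <- x$changes[x$changes$status != "unchanged", , drop = FALSE]
  cat(sprintf("Campaign comparison: %d matched rooms, %d changed scores\n",
              nrow(x$rooms), nrow(changed)))
  if (length(x$added_rooms))
    cat("  added rooms:", paste(x$added_rooms, collapse = ", "), "\n")
  if (length(x$removed_rooms))
    cat("  removed rooms:", paste(x$removed_rooms, collapse = ", "), "\n")
  tab <- table(factor(x$changes$status,
                      levels = c("new", "worsened", "unchanged",
                                 "improved", "resolved")))
  cat("  statuses:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Prioritize rooms for remediation action
#'
#' Ranks rooms for follow-up. Rooms with any current wet/damp material,
#' visible mold, or mold odor form the immediate-action tier (these factors
#' signal ongoing or recent water incursion); within and below that tier,
#' rooms sort by the number of new-or-worsened change records, then by
#' current room total descending, with ties broken by room key.
#'
#' @param current List of [room_assessment()] objects (the current
#'   campaign).
#' @param diff Optional `dmat_diff` against a previous campaign; supplies
#'   the new/worsened counts (0 for all rooms when absent).
#' @return Data frame of rooms needing action (immediate tier or any
#'   damage), ranked; columns `building_id`, `room_id`, `immediate`,
#'   `n_new_worse`, `room_total`, `color_band`. All-clear rooms are omitted.
#' @export
flag_for_action <- function(current, diff = NULL) {
  current <- latest_assessments(current)
  if (length(current) == 0L) {
    return(data.frame(building_id = character(), room_id = character(),
                      immediate = logical(), n_new_worse = integer(),
                      room_total = integer(), color_band = character(),
                      stringsAsFactors = FALSE))
  }
  keys <- vapply(current, room_key, character(1))
  nw <- stats::setNames(rep(0L, length(keys)), keys)
  if (!is.null(diff)) {
    ch <- diff$changes
    ch <- ch[ch$status %in% c("new", "worsened"), , drop = FALSE]
    if (nrow(ch)) {
      ck <- paste(ch$building_id, ch$room_id, sep = "/")
      tab <- table(ck)
      nw[names(tab)[names(tab) %in% keys]] <-
        as.integer(tab[names(tab) %in% keys])
    }
  }
  df <- data.frame(
    building_id = vapply(current, function(r) r$building_id, character(1)),
    room_id = vapply(current, function(r) r$room_id, character(1)),
    immediate = vapply(current, function(r) {
      r$odor$score > 0 ||
        any(vapply(r$observations,
                   function(o) o$visible_mold > 0 || o$wet_damp > 0,
                   logical(1)))
    }, logical(1)),
    n_new_worse = as.integer(nw[keys]),
    room_total = vapply(current, room_total, integer(1)),
    stringsAsFactors = FALSE)
  df$color_band <- as.character(classify_room(df$room_total))
  df <- df[df$immediate | df$room_total > 0 | df$n_new_worse > 0, ,
           drop = FALSE]
  df <- df[order(-df$immediate, -df$n_new_worse, -df$room_total,
                 df$building_id, df$room_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a change report to CSV
#'
#' @param diff A `dmat_diff` from [diff_assessments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_changes <- function(diff, path) {
  ch <- diff$changes
  ch <- ch[order(ch$building_id, ch$room_id,
                 match(ch$component, c(dmat_components(), "mold_odor")),
                 ch$factor), , drop = FALSE]
  utils::write.csv(ch, path, row.names = FALSE, quote = TRUE, na = "",
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
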