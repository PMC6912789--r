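#' Construct an agonistic-interaction event table
#'
#' Events are stored as a plain `data.frame`, one row per agonistic
#' interaction. A *decisive* interaction ended with clear submissive
#' behaviour, so it has a winner and a loser; indecisive interactions are
#' retained with the `decisive` flag set to `FALSE` and empty outcome
#' fields, so that exclusion rates can be reported before analysis.
#'
#' @param pen_id character, pen identifier (recycled if length 1).
#' @param t_obs numeric, cumulative observed hours since mixing start
#'   (observation gaps removed).
#' @param initiator,receiver character animal ids; must differ row-wise.
#' @param winner,loser character animal ids or `NA` for indecisive events.
#' @param decisive logical; if missing, inferred from `winner`/`loser`.
#' @return `data.frame` with columns `pen_id`, `t_obs`, `initiator`,
#'   `receiver`, `winner`, `loser`, `decisive`.
#' @examples
#' interaction_events("P1", 0.5, "4", "3", "4", "3")
#' @export
interaction_events <- function(pen_id, t_obs, initiator, receiver,
                               winner = NA_character_, loser = NA_character_,
                               decisive = NULL) {
  n <- max(length(t_obs), length(initiator), length(receiver))
  ev <- data.frame(
    pen_id    = rep_len(as.character(pen_id), n),
    t_obs     = as.numeric(rep_len(t_obs, n)),
    initiator = rep_len(as.character(initiator), n),
    receiver  = rep_len(as.character(receiver), n),
    winner    = rep_len(as.character(winner), n),
    loser     = rep_len(as.character(loser), n),
    stringsAsFactors = FALSE
  )
  ev$winner[!nzchar(ev$winner) | is.na(ev$winner)] <- NA_character_
  ev$loser[!nzchar(ev$loser) | is.na(ev$loser)] <- NA_character_
  ev$decisive <- if (is.null(decisive)) {
    !is.na(ev$winner) & !is.na(ev$loser)
  } else {
    as.logical(rep_len(decisive, n))
  }
  validate_events(ev)
  ev
}

#' Construct a pen roster
#'
#' @param pen_id pen identifier.
#' @param animals character vector of animal ids (>= 2, unique).
#' @param profile age-group label: `"piglet"`, `"fattener"`, `"gilt"` or
#'   `"custom"`.
#' @return `data.frame` with columns `pen_id`, `animal_id`, `profile`.
#' @export
pen_roster <- function(pen_id, animals, profile = "custom") {
  animals <- as.character(animals)
  if (length(animals) < 2L)
    stop("a pen roster needs at least 2 animals", call. = FALSE)
  if (anyDuplicated(animals))
    stop("duplicate animal ids in roster", call. = FALSE)
  data.frame(pen_id = as.character(pen_id), animal_id = animals,
             profile = as.character(profile), stringsAsFactors = FALSE)
}

event_columns <- c("pen_id", "t_obs", "initiator", "receiver",
                   "winner", "loser", "decisive")

#' Validate an event table against the data-model invariants
#'
#' Checks, row by row: initiator differs from receiver; decisive events have
#' winner and loser drawn from the two participants; indecisive events have
#' no outcome fields; all participants belong to the roster when one is
#' supplied.
#'
#' @param events event `data.frame` (see [interaction_events()]).
#' @param roster optional roster `data.frame` (see [pen_roster()]).
#' @return `events`, invisibly, if valid; otherwise an error naming the
#'   offending row.
#' @export
validate_events <- function(events, roster = NULL) {
  stopifnot(is.data.frame(events))
  missing_cols <- setdiff(event_columns, names(events))
  if (length(missing_cols))
    stop("event table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("event row %d: %s", i[1L], msg), call. = FALSE)
  }
  bad(is.na(events$t_obs) | events$t_obs < 0, "t_obs must be non-negative")
  bad(events$initiator == events$receiver, "initiator equals receiver")
  dec <- events$decisive
  bad(dec & (is.na(events$winner) | is.na(events$loser)),
      "decisive event lacks winner or loser")
  bad(!dec & (!is.na(events$winner) | !is.na(events$loser)),
      "indecisive event carries winner or loser")
  both <- dec & !is.na(events$winner) & !is.na(events$loser)
  if (any(both)) {
    w <- events$winner[both]; l <- events$loser[both]
    a <- events$initiator[both]; b <- events$receiver[both]
    ok <- (w == a & l == b) | (w == b & l == a)
    if (!all(ok)) {
      i <- which(both)[which(!ok)[1L]]
      stop(sprintf("event row %d: {winner, loser} must equal {initiator, receiver}", i),
           call. = FALSE)
    }
  }
  if (!is.null(roster)) {
    for (p in unique(events$pen_id)) {
      ids <- roster$animal_id[roster$pen_id == p]
      if (!length(ids))
        stop("pen '", p, "' not present in roster", call. = FALSE)
      rows <- events$pen_id == p
      unknown <- !(events$initiator[rows] %in% ids) |
                 !(events$receiver[rows] %in% ids)
      if (any(unknown)) {
        i <- which(rows)[which(unknown)[1L]]
        stop(sprintf("event row %d: participant not in roster of pen '%s'", i, p),
             call. = FALSE)
      }
    }
  }
  invisible(events)
}

#' Read an event log from CSV
#'
#' The file dialect is comma-separated UTF-8 with one header line and
#' columns `pen_id,t_obs,initiator,receiver,winner,loser,decisive`; winner
#' and loser cells are empty exactly when `decisive` is false.
#'
#' @param path path to the events CSV.
#' @param roster optional roster used to validate participant ids.
#' @return validated event `data.frame`.
#' @export
read_events <- function(path, roster = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), event_columns))
    stop("unexpected header in ", path, "; expected: ",
         paste(event_columns, collapse = ","), call. = FALSE)
  ev <- interaction_events(raw$pen_id, as.numeric(raw$t_obs),
                           raw$initiator, raw$receiver,
                           raw$winner, raw$loser,
                           decisive = tolower(raw$decisive) %in% c("true", "1"))
  validate_events(ev, roster)
  ev
}

#' Write an event log to CSV
#'
#' Inverse of [read_events()]: `read_events(write_events(ev, f))` reproduces
#' `ev` up to float formatting.
#'
#' @param events event `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  out <- events[, event_columns]
  out$winner[is.na(out$winner)] <- ""
  out$loser[is.na(out$loser)] <- ""
  out$decisive <- ifelse(events$decisive, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pen roster from CSV (columns `pen_id,animal_id,profile`)
#'
#' @param path path to the roster CSV.
#' @return roster `data.frame`.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  r <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("pen_id", "animal_id", "profile")
  if (!all(need %in% names(r)))
    stop("roster file needs columns ", paste(need, collapse = ","), call. = FALSE)
  r[, need]
}

#' Write a pen roster to CSV
#' @param roster roster `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster[, c("pen_id", "animal_id", "profile")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only decisive interactions
#'
#' Only interactions with a clear winner and loser enter the dominance
#' indices and the winner-loser networks; this filter is applied by every
#' analysis stage. Idempotent, order-preserving.
#'
#' @param events event `data.frame`.
#' @return the decisive subset, original order.
#' @export
filter_decisive <- function(events) {
  events[events$decisive, , drop = FALSE]
}
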