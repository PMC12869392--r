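# Phenotyping: derive the three time-to-event transition tables from a
# person's coded event stream, with end-of-data censoring.
#
# Definitions:
#   onset     -- time from cohort entry (day 0) to the first qualifying
#                OUD-concept event; one record per person.
#   remission -- among persons with OUD, time from the last OUD event
#                preceding the remission code (or preceding end of data,
#                for censored persons) to the first remission-concept
#                event.
#   relapse   -- among persons with an observed remission, time from the
#                remission day to the first OUD-concept event strictly
#                after it.
#
# Only the first remission and first relapse per person are modelled;
# repeat remission/relapse cycles are out of scope.  Records whose duration
# would be zero (e.g. an OUD code and a remission code on the same day)
# are dropped with a warning, since start-stop risk intervals require
# strictly positive length.

#' Read a concept set from a plain-text file
#'
#' One concept id per line; blank lines and leading/trailing whitespace are
#' ignored.
#'
#' @param path File path.
#' @return Character vector of concept ids.
#' @export
read_concept_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Derive onset, remission and relapse transition records
#'
#' @param events Data frame with columns \code{person_id},
#'   \code{concept_id}, \code{day} (integer days from cohort entry).
#' @param oud_concepts Character vector of concept ids whose occurrence
#'   qualifies as an OUD event.
#' @param remission_concepts Character vector of remission concept ids;
#'   must be disjoint from \code{oud_concepts}.
#' @param end_of_data Last observed day; all transitions are censored here.
#' @param persons Optional vector of all person ids in the cohort; persons
#'   with no events still contribute a censored onset record.  Defaults to
#'   the persons present in \code{events}.
#' @return Data frame with one row per (person, transition): columns
#'   \code{person_id}, \code{transition}, \code{origin_day},
#'   \code{event_day} (\code{NA} when censored), \code{censor_day},
#'   \code{event}.
#' @export
derive_transitions <- function(events, oud_concepts, remission_concepts,
                               end_of_data, persons = NULL) {
  if (length(intersect(oud_concepts, remission_concepts)))
    stop_input("OUD and remission concept sets must be disjoint")
  if (any(events$day < 0)) stop_input("event days must be nonnegative")
  end_of_data <- check_positive_int(end_of_data, "end_of_data")
  events <- events[events$day <= end_of_data, , drop = FALSE]

  rec <- function(person, transition, origin, event_day) {
    event <- !is.na(event_day)
    stop_day <- if (event) event_day else end_of_data
    if (stop_day - origin <= 0) {
      warning(sprintf(
        "person %s: zero-duration %s record dropped (origin day %d)",
        person, transition, origin), call. = FALSE)
      return(NULL)
    }
    data.frame(person_id = person, transition = transition,
               origin_day = as.integer(origin),
               event_day = if (event) as.integer(event_day) else NA_integer_,
               censor_day = end_of_data, event = as.integer(event),
               stringsAsFactors = FALSE)
  }

  per_person <- function(person, df) {
    oud <- sort(df$day[df$concept_id %in% oud_concepts])
    rem <- sort(df$day[df$concept_id %in% remission_concepts])
    out <- list()
    first_oud <- if (length(oud)) oud[1] else NA_integer_
    out$onset <- rec(person, "onset", 0L, first_oud)
    if (!length(oud)) {
      if (length(rem))
        warning(sprintf(
          "person %s: remission code with no preceding OUD event skipped",
          person), call. = FALSE)
      return(do.call(rbind, out))
    }
    orphan <- rem[rem < first_oud]
    if (length(orphan)) {
      warning(sprintf(
        "person %s: remission code on day %d precedes any OUD event; skipped",
        person, orphan[1]), call. = FALSE)
      rem <- rem[rem >= first_oud]
    }
    rem_day <- if (length(rem)) rem[1] else NA_integer_
    rem_origin <- if (is.na(rem_day)) max(oud) else max(oud[oud <= rem_day])
    out$remission <- rec(person, "remission", rem_origin, rem_day)
    if (!is.na(rem_day) && !is.null(out$remission)) {
      relapse_day <- oud[oud > rem_day]
      relapse_day <- if (length(relapse_day)) relapse_day[1] else NA_integer_
      out$relapse <- rec(person, "relapse", rem_day, relapse_day)
    }
    do.call(rbind, out)
  }

  pieces <- lapply(split(events, events$person_id),
                   function(df) per_person(df$person_id[1], df))
  if (!is.null(persons)) {
    absent <- setdiff(persons, events$person_id)
    pieces <- c(pieces, lapply(absent, function(p)
      rec(p, "onset", 0L, NA_integer_)))
  }
  res <- do.call(rbind, pieces)
  if (is.null(res))
    res <- data.frame(person_id = integer(0), transition = character(0),
                      origin_day = integer(0), event_day = integer(0),
                      censor_day = integer(0), event = integer(0))
  rownames(res) <- NULL
  res
}
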