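# Counting-process person-period construction.
#
# For one transition record, a person's follow-up [0, duration) on the
# transition clock is tiled by start-stop rows split at every day a new
# event arrives (features are step functions between events, so splitting
# at event days leaves the partial likelihood unchanged while keeping the
# row count proportional to the number of events, not days).  Each row's
# features are evaluated at the row's start on the absolute-day axis.
#
# Five transforms are computed per concept under the half-open (t - w, t]
# window convention:
#   cnt_30d / cnt_90d / cnt_365d -- occurrences in the trailing window;
#   cum                          -- occurrences up to and including t;
#   days_since_last              -- recency; a finite sentinel
#                                   (follow-up + 1) for never-seen
#                                   concepts keeps the column dense.
# Count transforms are reported after log(1 + x); recency is untouched.

.id_cols <- c("person_id", "t_start", "t_stop", "event")

#' Build start-stop person-period rows for one transition record
#'
#' @param events Data frame of this person's concept events
#'   (\code{concept_id}, \code{day}); events after the record's end are
#'   ignored as unobservable at risk time.
#' @param record One-row data frame (or list) with \code{person_id},
#'   \code{origin_day}, \code{event_day}, \code{censor_day}, \code{event}
#'   as produced by \code{\link{derive_transitions}}.
#' @param spec A \code{\link{feature_spec}}.
#' @param concepts Character vector fixing the feature column set; defaults
#'   to the concepts present in \code{events}.
#' @return Data frame of start-stop rows: \code{person_id},
#'   \code{t_start}, \code{t_stop} (transition clock), \code{event}
#'   (1 only on the terminal row of an event record), then one column per
#'   concept-transform pair.
#' @export
build_person_periods <- function(events, record, spec = feature_spec(),
                                 concepts = NULL) {
  record <- as.list(record)
  if (is.null(concepts)) concepts <- sort(unique(events$concept_id))
  m <- .person_period_matrix(events, record, spec, concepts)
  cbind(data.frame(person_id = rep(record$person_id, nrow(m$feat)),
                   t_start = m$t_start, t_stop = m$t_stop, event = m$event),
        as.data.frame(m$feat))
}

# Matrix-valued worker shared by the single-person and cohort builders.
.person_period_matrix <- function(events, record, spec, concepts) {
  if (any(events$day < 0)) stop_input("event days must be nonnegative")
  origin <- record$origin_day
  end <- if (record$event == 1) record$event_day else record$censor_day
  if (end - origin <= 0) stop_input("record duration must be positive")
  keep <- events$day <= end & events$concept_id %in% concepts
  ev_day <- events$day[keep]
  ev_concept <- events$concept_id[keep]

  brk <- sort(unique(ev_day[ev_day > origin & ev_day < end]))
  t_start <- c(0L, brk - origin)
  t_stop <- c(brk - origin, end - origin)
  tt <- origin + t_start  # absolute evaluation times
  n <- length(t_start)

  days_by_c <- split(ev_day, factor(ev_concept, levels = concepts))
  feat <- matrix(0, nrow = n, ncol = length(concepts) * length(.TRANSFORMS))
  colnames(feat) <- as.vector(t(outer(concepts, .TRANSFORMS, paste,
                                      sep = "_")))
  j <- 0L
  for (cc in concepts) {
    d <- sort(days_by_c[[cc]])
    for (tr in .TRANSFORMS) {
      j <- j + 1L
      feat[, j] <- .feature_value_model(d, tt, tr, spec)
    }
  }
  list(t_start = t_start, t_stop = t_stop,
       event = c(rep(0L, n - 1L), as.integer(record$event)), feat = feat)
}

#' Build a cohort-level person-period table for one transition
#'
#' Applies \code{\link{build_person_periods}} to every record of the
#' requested transition, over a common concept column set, and appends
#' static covariates (carried unchanged on every row; categorical
#' covariates are expanded to indicator columns against the most frequent
#' level).
#'
#' @param events Cohort concept-event table (\code{person_id},
#'   \code{concept_id}, \code{day}).
#' @param transitions Transition-record table from
#'   \code{\link{derive_transitions}} (or a simulator truth table).
#' @param transition Which transition to build (\code{"onset"},
#'   \code{"remission"} or \code{"relapse"}).
#' @param spec A \code{\link{feature_spec}}.
#' @param covariates Optional data frame of static covariates with a
#'   \code{person_id} column.
#' @param exclude_concepts Concept ids to omit from the feature set
#'   (e.g. the phenotype-defining codes themselves).
#' @return A \code{"person_periods"} data frame with attributes
#'   \code{transition} and \code{features}.
#' @export
build_cohort_periods <- function(events, transitions,
                                 transition = c("onset", "remission",
                                                "relapse"),
                                 spec = feature_spec(), covariates = NULL,
                                 exclude_concepts = NULL) {
  transition <- match.arg(transition)
  recs <- transitions[transitions$transition == transition, , drop = FALSE]
  if (!nrow(recs)) stop_input("no records for transition ", transition)
  concepts <- sort(setdiff(unique(events$concept_id), exclude_concepts))
  if (!length(concepts)) stop_input("no concepts left to build features on")
  ev_by_p <- split(events[c("concept_id", "day")], events$person_id)
  empty <- data.frame(concept_id = character(0), day = integer(0))
  recs_l <- split(recs, seq_len(nrow(recs)))
  mats <- lapply(seq_len(nrow(recs)), function(i) {
    p <- as.character(recs$person_id[i])
    ev <- if (p %in% names(ev_by_p)) ev_by_p[[p]] else empty
    .person_period_matrix(ev, as.list(recs_l[[i]]), spec, concepts)
  })
  n_rows <- vapply(mats, function(m) length(m$t_start), integer(1))
  out <- data.frame(
    person_id = rep(recs$person_id, n_rows),
    t_start = unlist(lapply(mats, `[[`, "t_start")),
    t_stop = unlist(lapply(mats, `[[`, "t_stop")),
    event = unlist(lapply(mats, `[[`, "event")))
  out <- cbind(out, as.data.frame(do.call(rbind,
                                          lapply(mats, `[[`, "feat"))))
  if (!is.null(covariates)) {
    cov <- expand_covariates(covariates)
    idx <- match(out$person_id, cov$person_id)
    if (anyNA(idx)) stop_input("covariates missing for some persons")
    out <- cbind(out, cov[idx, setdiff(names(cov), "person_id"),
                          drop = FALSE])
    rownames(out) <- NULL
  }
  structure(out, transition = transition,
            features = setdiff(names(out), .id_cols),
            class = c("person_periods", "data.frame"))
}

#' Expand categorical covariates to indicator columns
#'
#' Character and factor columns become 0/1 indicators for every level
#' except the most frequent one, which serves as the reference.
#'
#' @param covariates Data frame with a \code{person_id} column.
#' @return Data frame with \code{person_id} and numeric columns only.
#' @export
expand_covariates <- function(covariates) {
  out <- covariates["person_id"]
  for (nm in setdiff(names(covariates), "person_id")) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      out[[nm]] <- v
    } else {
      v <- as.character(v)
      ref <- names(sort(table(v), decreasing = TRUE))[1]
      for (lv in setdiff(sort(unique(v)), ref))
        out[[paste0(nm, "_", lv)]] <- as.numeric(v == lv)
    }
  }
  out
}

#' Write a person-period table as tab-delimited long format
#'
#' @param pp A \code{"person_periods"} data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_person_periods <- function(pp, path) {
  utils::write.table(pp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
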