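# Synthetic cohort generator.
#
# Concept events are drawn from an inhomogeneous Poisson process per
# (person, concept): a person-level log-normal frailty scales all of a
# person's intensities, and a per-(person, concept) Beta-shaped intensity
# profile makes occurrence times cluster, so windowed counts genuinely vary
# within a person over follow-up.  Transition times are then sampled by
# inversion from a proportional-hazards model whose log-hazard is the
# planted linear predictor evaluated over the SAME step-function features
# the feature builder computes (piecewise-constant between a person's event
# days, left-evaluated), so the simulation is exactly consistent with the
# counting-process likelihood downstream models maximize.

.concept_ids <- function(config) {
  n <- config$n_concepts
  ids <- c(
    paste0("cond", seq_len(n[["condition"]] + config$noise_concepts)),
    paste0("rx",   seq_len(n[["drug"]])),
    paste0("svy",  seq_len(n[["survey"]])),
    paste0("proc", seq_len(n[["procedure"]])))
  dom <- c(rep("condition", n[["condition"]] + config$noise_concepts),
           rep("drug", n[["drug"]]), rep("survey", n[["survey"]]),
           rep("procedure", n[["procedure"]]))
  data.frame(concept_id = ids, domain = dom, stringsAsFactors = FALSE)
}

# Untransformed feature value of one concept (sorted integer days) at
# absolute times tt, under the half-open (t - w, t] window convention.
.feature_value <- function(days, tt, transform, spec) {
  n_le <- function(t) findInterval(t, days)
  raw <- switch(transform,
    cnt_30d  = n_le(tt) - n_le(tt - 30),
    cnt_90d  = n_le(tt) - n_le(tt - 90),
    cnt_365d = n_le(tt) - n_le(tt - 365),
    cum      = n_le(tt),
    days_since_last = {
      idx <- findInterval(tt, days)
      out <- rep(spec$sentinel_days, length(tt))
      out[idx > 0] <- tt[idx > 0] - days[idx[idx > 0]]
      out
    },
    stop_input("unknown transform: ", transform))
  raw
}

# Transformed (model-scale) feature value: log1p for counts, raw recency.
.feature_value_model <- function(days, tt, transform, spec) {
  v <- .feature_value(days, tt, transform, spec)
  if (transform == "days_since_last") v else spec$transform(v)
}

# Sample one event time on (origin, followup] by inversion of the
# piecewise-constant cumulative hazard.  `grid` are the absolute days at
# which the linear predictor steps (the person's event days); `eta_at`
# evaluates the linear predictor at a vector of absolute times.
.sample_piecewise <- function(origin, followup, base_rate, grid, eta_at) {
  starts <- sort(unique(c(origin, grid[grid > origin & grid < followup])))
  stops <- c(starts[-1], followup)
  haz <- base_rate * exp(eta_at(starts))
  cumhaz <- cumsum(haz * (stops - starts))
  target <- stats::rexp(1)
  k <- which(cumhaz >= target)[1]
  if (is.na(k)) return(NA_real_)  # censored at followup
  prev <- if (k == 1) 0 else cumhaz[k - 1]
  starts[k] + (target - prev) / haz[k]
}

#' Simulate a cohort of concept-event streams with planted hazard effects
#'
#' Generates sparse, irregular coded-event histories for a synthetic cohort
#' and draws onset, remission and relapse times from proportional-hazards
#' models whose log-hazard is the planted linear predictor over the same
#' windowed, log1p-transformed features the feature builder produces.  The
#' latent transition times are returned alongside the observable events so
#' parameter-recovery tests can compare against ground truth.
#'
#' Remission is simulated only for persons whose onset event occurred, with
#' the remission clock starting at the onset day; relapse likewise follows
#' an observed remission.  When \code{emit_markers} is \code{TRUE} the
#' event stream additionally carries condition-domain marker concepts
#' (\code{"oud1"} at onset and relapse days, \code{"rem1"} at the remission
#' day) so the phenotyping rules can reconstruct the transitions from the
#' stream alone.
#'
#' @param config A \code{\link{sim_config}} object.
#' @param emit_markers Add OUD / remission marker concept events at the
#'   simulated transition days.
#' @return A list of class \code{"oud_sim"} with elements \code{events}
#'   (columns \code{person_id}, \code{concept_id}, \code{domain},
#'   \code{day}), \code{truth} (columns \code{person_id},
#'   \code{transition}, \code{origin_day}, \code{event_day},
#'   \code{censor_day}, \code{event}) and \code{config}.
#' @export
simulate_cohort_events <- function(config, emit_markers = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  spec <- feature_spec(sentinel_days = config$followup_days + 1)
  concepts <- .concept_ids(config)
  TT <- config$followup_days
  np <- config$n_persons
  with_seed(config$seed, {
    frailty <- exp(stats::rnorm(np, 0, config$frailty_sd) -
                     config$frailty_sd^2 / 2)
    concept_scale <- exp(stats::rnorm(nrow(concepts), 0, 0.3) - 0.3^2 / 2)
    ev_list <- vector("list", nrow(concepts))
    for (j in seq_len(nrow(concepts))) {
      lambda <- config$event_rate * (TT / 365) * frailty * concept_scale[j]
      n_ev <- stats::rpois(np, lambda)
      tot <- sum(n_ev)
      if (tot == 0L) next
      pid <- rep.int(seq_len(np), n_ev)
      # Beta-shaped intensity profile per (person, concept): clustered days.
      a <- stats::runif(np, 0.6, 1.8)
      b <- stats::runif(np, 0.6, 1.8)
      u <- stats::rbeta(tot, a[pid], b[pid])
      day <- pmin(floor(u * (TT + 1)), TT)
      ev_list[[j]] <- data.frame(person_id = pid,
                                 concept_id = concepts$concept_id[j],
                                 domain = concepts$domain[j],
                                 day = as.integer(day),
                                 stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
    if (is.null(events))
      events <- data.frame(person_id = integer(0), concept_id = character(0),
                           domain = character(0), day = integer(0))
    events <- events[order(events$person_id, events$day, events$concept_id), ]
    rownames(events) <- NULL

    # Per-person event-day index for hazard evaluation.
    days_by_pc <- split(events$day,
                        list(factor(events$person_id, levels = seq_len(np)),
                             factor(events$concept_id,
                                    levels = concepts$concept_id)),
                        drop = FALSE)
    pc_key <- function(p, c) paste(p, c, sep = ".")
    grid_by_p <- split(events$day,
                       factor(events$person_id, levels = seq_len(np)))

    planted <- config$planted_effects
    parsed <- lapply(planted, function(v) {
      if (!length(v)) return(NULL)
      pf <- parse_feature_name(names(v))
      if (anyNA(pf$concept))
        stop_input("planted effect name does not follow the ",
                   "<concept>_<transform> scheme: ",
                   names(v)[which(is.na(pf$concept))[1]])
      bad <- setdiff(pf$concept, concepts$concept_id)
      if (length(bad)) stop_input("planted concept not simulated: ", bad[1])
      cbind(pf, beta = as.numeric(v))
    })

    eta_fun <- function(p, transition) {
      pf <- parsed[[transition]]
      if (is.null(pf)) return(function(tt) rep(0, length(tt)))
      function(tt) {
        eta <- rep(0, length(tt))
        for (i in seq_len(nrow(pf))) {
          d <- sort(days_by_pc[[pc_key(p, pf$concept[i])]])
          eta <- eta + pf$beta[i] *
            .feature_value_model(d, tt, pf$transform[i], spec)
        }
        eta
      }
    }

    truth <- vector("list", np)
    base <- config$baseline_hazard
    for (p in seq_len(np)) {
      grid <- sort(unique(grid_by_p[[p]]))
      rows <- list()
      t_on <- .sample_piecewise(0, TT, base[["onset"]], grid,
                                eta_fun(p, "onset"))
      on_day <- if (is.na(t_on)) NA_integer_ else as.integer(floor(t_on) + 1)
      rows$onset <- data.frame(person_id = p, transition = "onset",
                               origin_day = 0L, event_day = on_day,
                               censor_day = TT, event = as.integer(!is.na(on_day)))
      if (!is.na(on_day) && on_day < TT) {
        t_rem <- .sample_piecewise(on_day, TT, base[["remission"]], grid,
                                   eta_fun(p, "remission"))
        rem_day <- if (is.na(t_rem)) NA_integer_ else as.integer(floor(t_rem) + 1)
        rows$remission <- data.frame(person_id = p, transition = "remission",
                                     origin_day = on_day, event_day = rem_day,
                                     censor_day = TT,
                                     event = as.integer(!is.na(rem_day)))
        if (!is.na(rem_day) && rem_day < TT) {
          t_rel <- .sample_piecewise(rem_day, TT, base[["relapse"]], grid,
                                     eta_fun(p, "relapse"))
          rel_day <- if (is.na(t_rel)) NA_integer_
                     else as.integer(floor(t_rel) + 1)
          rows$relapse <- data.frame(person_id = p, transition = "relapse",
                                     origin_day = rem_day, event_day = rel_day,
                                     censor_day = TT,
                                     event = as.integer(!is.na(rel_day)))
        }
      }
      truth[[p]] <- do.call(rbind, rows)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    if (emit_markers) {
      mk <- function(df, concept) {
        keep <- df$event == 1L
        if (!any(keep)) return(NULL)
        data.frame(person_id = df$person_id[keep], concept_id = concept,
                   domain = "condition", day = df$event_day[keep],
                   stringsAsFactors = FALSE)
      }
      markers <- rbind(
        mk(truth[truth$transition == "onset", ], "oud1"),
        mk(truth[truth$transition == "relapse", ], "oud1"),
        mk(truth[truth$transition == "remission", ], "rem1"))
      if (!is.null(markers)) {
        events <- rbind(events, markers)
        events <- events[order(events$person_id, events$day,
                               events$concept_id), ]
        rownames(events) <- NULL
      }
    }

    structure(list(events = events, truth = truth, config = config),
              class = "oud_sim")
  })
}

#' @export
print.oud_sim <- function(x, ...) {
  cat("Synthetic OUD cohort:", x$config$n_persons, "persons,",
      nrow(x$events), "concept events over", x$config$followup_days,
      "days\n")
  tab <- table(x$truth$transition, x$truth$event)
  cat("Transition records (censored / event):\n")
  print(tab)
  invisible(x)
}

#' Write simulated cohort tables to tab-delimited files
#'
#' @param sim An \code{"oud_sim"} object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (\code{events.tsv},
#'   \code{truth.tsv}).
#' @export
write_sim_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "oud_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("events.tsv", "truth.tsv"))
  utils::write.table(sim$events, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Simulate knowledge-graph evidence tables
#'
#' Builds a gene-evidence table in which each seed gene carries exactly one
#' direct-evidence branch (drawn from \code{evidence_mix}), a pathway
#' membership list guaranteed to contain at least one pathway with
#' \code{m_min} or more seed genes plus a non-seed member (so pathway
#' bridging is exercised), and a gene-drug target table containing at least
#' one approved drug, one research-only drug and one pair with missing
#' potency.
#'
#' @param config A \code{\link{sim_kg_config}} object.
#' @return A list of class \code{"kg_sim"} with elements
#'   \code{gene_evidence} (data frame), \code{pathways} (named list of
#'   member vectors) and \code{drug_targets} (data frame).
#' @export
simulate_kg_tables <- function(config) {
  stopifnot(inherits(config, "sim_kg_config"))
  with_seed(config$seed, {
    ns <- config$n_seed_genes
    seed_genes <- sprintf("G%02d", seq_len(ns))
    bridge_genes <- sprintf("B%02d", seq_len(config$n_bridge_genes))
    branches <- names(config$evidence_mix)
    n_per <- stats::setNames(
      diff(c(0, round(cumsum(config$evidence_mix) * ns))), branches)
    branch_of <- sample(rep(branches, n_per))
    ev <- data.frame(gene = seed_genes, r_rep = NA_real_,
                     flag_mvp = 0L, flag_oud_only = 0L, flag_mtag = 0L,
                     posterior = NA_real_, p_rank = NA_integer_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(ns)) {
      switch(branch_of[i],
        rep = ev$r_rep[i] <- sample(1:3, 1),
        mvp = ev$flag_mvp[i] <- 1L,
        oud_only = ev$flag_oud_only[i] <- 1L,
        mtag = ev$flag_mtag[i] <- 1L,
        posterior = ev$posterior[i] <- round(stats::runif(1), 3),
        p_rank = ev$p_rank[i] <- sample(1:50, 1),
        none = invisible(NULL))
    }
    # Pathway 1 always bridges: m_min seed genes plus >= 1 non-seed member.
    pws <- vector("list", config$n_pathways)
    names(pws) <- sprintf("PW%02d", seq_len(config$n_pathways))
    pws[[1]] <- c(seed_genes[seq_len(min(config$m_min, ns))],
                  bridge_genes[1])
    if (config$n_pathways > 1) {
      pool <- c(seed_genes, bridge_genes)
      for (k in 2:config$n_pathways)
        pws[[k]] <- sort(sample(pool, min(length(pool),
                                          sample(2:4, 1))))
    }
    # Drugs: each targets >= 1 gene; guarantee annotation variety.
    drugs <- sprintf("D%03d", seq_len(config$n_drugs))
    gene_pool <- c(seed_genes, bridge_genes)
    tg <- lapply(seq_len(config$n_drugs), function(k) {
      genes <- sample(gene_pool, sample(1:2, 1))
      data.frame(gene = genes, drug_id = drugs[k],
                 drug_name = paste0("drug", k),
                 pchembl = round(stats::runif(length(genes), 4.5, 9.5), 2),
                 ant = stats::rbinom(length(genes), 1, 0.4),
                 ago = stats::rbinom(length(genes), 1, 0.3),
                 ph3 = 0L, app = 0L,
                 bbb = stats::rbinom(length(genes), 1, 0.5),
                 res = 0L, stringsAsFactors = FALSE)
    })
    tg <- do.call(rbind, tg)
    tg$app[tg$drug_id == drugs[1]] <- 1L
    tg$ph3[tg$drug_id == drugs[1]] <- 1L
    if (config$n_drugs >= 2) tg$res[tg$drug_id == drugs[2]] <- 1L
    if (config$n_drugs >= 3)
      tg$pchembl[which(tg$drug_id == drugs[3])[1]] <- NA_real_
    if (config$n_drugs >= 4) tg$ph3[tg$drug_id == drugs[4]] <- 1L
    rownames(tg) <- NULL
    structure(list(gene_evidence = ev, pathways = pws, drug_targets = tg,
                   config = config), class = "kg_sim")
  })
}

#' Write simulated knowledge-graph tables to disk
#'
#' @param sim A \code{"kg_sim"} object.
#' @param dir Output directory.
#' @return Invisibly, the paths written (\code{gene_evidence.tsv},
#'   \code{pathways.gmt}, \code{drug_targets.tsv}).
#' @export
write_kg_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "kg_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("gene_evidence.tsv", "pathways.gmt",
                            "drug_targets.tsv"))
  utils::write.table(sim$gene_evidence, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  write_gmt(sim$pathways, paths[2])
  utils::write.table(sim$drug_targets, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(paths)
}
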