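# Pipeline orchestration: run the simulate / survival / kg legs from one
# flat configuration with seeded reproducibility and a hashed output
# manifest.

.default_run_config <- function() {
  list(
    mode = "all", out_dir = "oudpath_out", seed = 1L,
    # simulate leg
    n_persons = 500L, followup_days = 730L, noise_concepts = 0L,
    # survival leg
    events = NULL, truth = NULL, transition = "onset",
    oud_concept_file = NULL, remission_concept_file = NULL,
    n_shards = 5L, cv_folds = 10L, min_frequency = 0.5, top_n = 25L,
    # kg leg
    gene_evidence = NULL, pathways = NULL, drug_targets = NULL,
    alpha = 0.85, gamma = 0.5, bmax = 50L, mmin = 2L,
    approved_prior = 0, alias_mode = "keep", why_top = 3L)
}

#' Read a flat run configuration file
#'
#' The configuration is a plain-text YAML file of flat keys mirroring the
#' command-line flags (e.g. \code{mode}, \code{out_dir}, \code{seed},
#' \code{n_persons}, \code{alpha}, \code{alias_mode}); unknown keys are an
#' error, and omitted keys take the package defaults.
#'
#' @param path Config file path.
#' @param overrides Named list applied on top of the file (CLI overrides
#'   config).
#' @return Fully resolved configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop_input("unknown config key(s): ",
                                paste(bad, collapse = ", "))
    cfg[names(user)] <- user
  }
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop_input("unknown override key(s): ",
                              paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full pipeline from a resolved configuration
#'
#' Modes: \code{"simulate"} writes synthetic cohort and knowledge-graph
#' tables; \code{"survival"} phenotypes (or reads) transition records,
#' builds person-period data and fits the stability-selection lasso-Cox
#' model; \code{"kg"} builds the therapy graph and writes the ranked drug
#' table; \code{"all"} chains simulate into both analysis legs.  Every
#' output file is listed in \code{manifest.tsv} with its MD5 hash, and the
#' fully resolved parameter set is written alongside, so identical
#' configuration and seed reproduce identical manifests.
#'
#' @param config Configuration list from \code{\link{read_run_config}}, or
#'   a path to a config file.
#' @return Invisibly, the manifest data frame.
#' @export
run_pipeline <- function(config = read_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- .default_run_config()
  cfg[names(config)] <- config
  mode <- match.arg(cfg$mode, c("simulate", "survival", "kg", "all"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)

  need <- function(keys, stage) {
    for (k in keys) {
      if (is.null(cfg[[k]]))
        stop(sprintf("stage '%s' failed: required input '%s' not set",
                     stage, k), call. = FALSE)
      if (!file.exists(cfg[[k]]))
        stop(sprintf("stage '%s' failed: input path '%s' does not exist",
                     stage, cfg[[k]]), call. = FALSE)
    }
  }

  if (mode %in% c("simulate", "all")) {
    paths <- .stage("simulate", {
      sim <- simulate_cohort_events(sim_config(
        n_persons = cfg$n_persons, followup_days = cfg$followup_days,
        noise_concepts = cfg$noise_concepts, seed = cfg$seed))
      kgsim <- simulate_kg_tables(sim_kg_config(seed = cfg$seed))
      c(write_sim_tables(sim, file.path(cfg$out_dir, "sim")),
        write_kg_tables(kgsim, file.path(cfg$out_dir, "sim")))
    })
    outputs <- c(outputs, paths)
    if (mode == "all") {
      sim_dir <- file.path(cfg$out_dir, "sim")
      cfg$events <- file.path(sim_dir, "events.tsv")
      cfg$truth <- file.path(sim_dir, "truth.tsv")
      cfg$gene_evidence <- file.path(sim_dir, "gene_evidence.tsv")
      cfg$pathways <- file.path(sim_dir, "pathways.gmt")
      cfg$drug_targets <- file.path(sim_dir, "drug_targets.tsv")
    }
  }

  if (mode %in% c("survival", "all")) {
    paths <- .stage("survival", {
      need("events", "survival")
      events <- utils::read.delim(cfg$events, stringsAsFactors = FALSE)
      oud_set <- if (is.null(cfg$oud_concept_file)) "oud1"
                 else read_concept_set(cfg$oud_concept_file)
      rem_set <- if (is.null(cfg$remission_concept_file)) "rem1"
                 else read_concept_set(cfg$remission_concept_file)
      if (!is.null(cfg$truth) && file.exists(cfg$truth)) {
        transitions <- utils::read.delim(cfg$truth,
                                         stringsAsFactors = FALSE)
      } else {
        transitions <- derive_transitions(
          events, oud_concepts = oud_set, remission_concepts = rem_set,
          end_of_data = max(events$day))
      }
      ph_path <- file.path(cfg$out_dir, "transitions.tsv")
      utils::write.table(transitions, ph_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      pp <- build_cohort_periods(
        events, transitions, transition = cfg$transition,
        spec = feature_spec(sentinel_days = cfg$followup_days + 1),
        exclude_concepts = c(oud_set, rem_set))
      fit <- oud_coxstab(pp, n_shards = cfg$n_shards, K = cfg$cv_folds,
                         seed = cfg$seed)
      agg_path <- file.path(cfg$out_dir,
                            paste0("aggregated_", cfg$transition, ".tsv"))
      write_aggregated_tsv(fit$aggregate, agg_path)
      pri_path <- file.path(cfg$out_dir,
                            paste0("prioritized_", cfg$transition, ".tsv"))
      utils::write.table(
        summary(fit, min_frequency = cfg$min_frequency,
                top_n = cfg$top_n),
        pri_path, sep = "\t", quote = FALSE, row.names = FALSE)
      c(ph_path, agg_path, pri_path)
    })
    outputs <- c(outputs, paths)
  }

  if (mode %in% c("kg", "all")) {
    paths <- .stage("kg", {
      need(c("gene_evidence", "pathways", "drug_targets"), "kg")
      params <- kg_params(gamma = cfg$gamma, m_min = cfg$mmin,
                          b_max = cfg$bmax, alpha = cfg$alpha,
                          approved_prior = cfg$approved_prior)
      kg <- therapy_kg(
        utils::read.delim(cfg$gene_evidence, stringsAsFactors = FALSE),
        read_gmt(cfg$pathways),
        utils::read.delim(cfg$drug_targets, stringsAsFactors = FALSE),
        params)
      ranked <- rank_drugs(kg, alias_mode = cfg$alias_mode,
                           why_top = cfg$why_top)
      write_ranked_tsv(ranked, file.path(cfg$out_dir, "ranked_drugs.tsv"))
    })
    outputs <- c(outputs, paths)
  }

  params_path <- file.path(cfg$out_dir, "resolved_params.yaml")
  yaml::write_yaml(cfg[order(names(cfg))], params_path)
  outputs <- c(outputs, params_path)
  manifest <- data.frame(
    file = sub(paste0("^", cfg$out_dir, "/?"), "", outputs),
    md5 = unname(tools::md5sum(outputs)),
    bytes = unname(file.size(outputs)), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
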