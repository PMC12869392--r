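# Configuration objects for the simulator, the feature builder and the
# knowledge graph.  Each constructor validates its invariants once so the
# worker functions can assume a well-formed object.

.TRANSITIONS <- c("onset", "remission", "relapse")
.DOMAINS <- c(condition = "cond", drug = "rx", survey = "svy", procedure = "proc")
.TRANSFORMS <- c("cnt_30d", "cnt_90d", "cnt_365d", "cum", "days_since_last")
.WINDOWS <- c(cnt_30d = 30, cnt_90d = 90, cnt_365d = 365)

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions under which concept-event streams and
#' transition times are simulated: cohort size, follow-up, per-domain
#' concept counts, per-day baseline hazards for the three transitions, and
#' the planted log-hazard coefficients that downstream models should
#' recover.
#'
#' @param n_persons Number of persons in the cohort.
#' @param n_concepts Named integer vector of concepts per domain
#'   (\code{condition}, \code{drug}, \code{survey}, \code{procedure}); a
#'   single integer is recycled across the four domains.
#' @param followup_days Length of follow-up, in integer days from cohort
#'   entry (day 0).
#' @param baseline_hazard Named per-day event rates (> 0) for
#'   \code{onset}, \code{remission} and \code{relapse}.
#' @param planted_effects Named numeric vector of true log-hazard
#'   coefficients.  Names must follow the feature naming scheme,
#'   e.g. \code{"cond1_cnt_30d"}; coefficients apply to the transformed
#'   feature (\code{log1p} for counts).  Applied to every transition unless
#'   a named list with per-transition elements is supplied.
#' @param noise_concepts Extra null condition-domain concepts appended
#'   beyond \code{n_concepts["condition"]}; they receive events but carry
#'   no planted effect.
#' @param event_rate Expected number of events per concept per 365 days of
#'   follow-up (before person-level frailty).
#' @param frailty_sd Standard deviation of the person-level log-normal
#'   frailty multiplying all of a person's concept-event intensities.
#' @param seed Integer seed; fully determines the simulated tables.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_persons = 2000,
                       n_concepts = c(condition = 4, drug = 2, survey = 1,
                                      procedure = 1),
                       followup_days = 730,
                       baseline_hazard = c(onset = 3e-4, remission = 1e-3,
                                           relapse = 8e-4),
                       planted_effects = c(cond1_cnt_30d = 1.0),
                       noise_concepts = 2,
                       event_rate = 0.35,
                       frailty_sd = 0.5,
                       seed = 1L) {
  n_persons <- check_positive_int(n_persons, "n_persons")
  if (length(n_concepts) == 1L && is.null(names(n_concepts)))
    n_concepts <- stats::setNames(rep(n_concepts, 4L), names(.DOMAINS))
  if (!all(names(.DOMAINS) %in% names(n_concepts)))
    stop_input("n_concepts must name all four domains")
  n_concepts <- vapply(names(.DOMAINS), function(d)
    check_positive_int(n_concepts[[d]], paste0("n_concepts[", d, "]")),
    integer(1))
  followup_days <- check_positive_int(followup_days, "followup_days")
  if (!all(.TRANSITIONS %in% names(baseline_hazard)))
    stop_input("baseline_hazard must name onset, remission and relapse")
  if (any(baseline_hazard <= 0)) stop_input("baseline hazards must be > 0")
  if (is.list(planted_effects)) {
    bad <- setdiff(names(planted_effects), .TRANSITIONS)
    if (length(bad)) stop_input("unknown transition in planted_effects: ", bad[1])
    planted <- lapply(stats::setNames(.TRANSITIONS, .TRANSITIONS), function(tr) {
      v <- planted_effects[[tr]]
      if (is.null(v)) stats::setNames(numeric(0), character(0)) else v
    })
  } else {
    planted <- stats::setNames(rep(list(planted_effects), 3L), .TRANSITIONS)
  }
  for (v in planted)
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
      stop_input("planted_effects must be a named numeric vector")
  if (noise_concepts < 0) stop_input("noise_concepts must be >= 0")
  structure(list(
    n_persons = n_persons, n_concepts = n_concepts,
    followup_days = followup_days,
    baseline_hazard = baseline_hazard[.TRANSITIONS],
    planted_effects = planted,
    noise_concepts = as.integer(noise_concepts),
    event_rate = event_rate, frailty_sd = frailty_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' Configuration for the synthetic knowledge-graph evidence tables
#'
#' @param n_seed_genes Genes carrying direct disease evidence.
#' @param n_bridge_genes Extra pathway-only genes available for bridging.
#' @param n_pathways Number of gene sets to emit (GMT lines).
#' @param n_drugs Number of drugs; every drug targets at least one gene.
#' @param evidence_mix Named proportions over the direct-evidence branches
#'   (\code{rep}, \code{mvp}, \code{oud_only}, \code{mtag},
#'   \code{posterior}, \code{p_rank}, \code{none}); must sum to 1.  Each
#'   seed gene carries exactly one branch.
#' @param m_min Minimum seed genes a pathway must contain before its other
#'   members are bridged (used to guarantee at least one bridgeable
#'   pathway exists in the output).
#' @param seed Integer seed.
#' @return An object of class \code{"sim_kg_config"}.
#' @export
sim_kg_config <- function(n_seed_genes = 8,
                          n_bridge_genes = 4,
                          n_pathways = 3,
                          n_drugs = 10,
                          evidence_mix = c(rep = 0.25, mvp = 0.2,
                                           oud_only = 0.15, mtag = 0.1,
                                           posterior = 0.15, p_rank = 0.1,
                                           none = 0.05),
                          m_min = 2,
                          seed = 1L) {
  branches <- c("rep", "mvp", "oud_only", "mtag", "posterior", "p_rank", "none")
  n_seed_genes <- check_positive_int(n_seed_genes, "n_seed_genes")
  n_bridge_genes <- check_positive_int(n_bridge_genes, "n_bridge_genes")
  n_pathways <- check_positive_int(n_pathways, "n_pathways")
  n_drugs <- check_positive_int(n_drugs, "n_drugs")
  if (!all(names(evidence_mix) %in% branches))
    stop_input("unknown evidence branch in evidence_mix")
  mix <- stats::setNames(rep(0, length(branches)), branches)
  mix[names(evidence_mix)] <- evidence_mix
  if (abs(sum(mix) - 1) > 1e-8) stop_input("evidence_mix must sum to 1")
  structure(list(n_seed_genes = n_seed_genes, n_bridge_genes = n_bridge_genes,
                 n_pathways = n_pathways, n_drugs = n_drugs,
                 evidence_mix = mix, m_min = check_positive_int(m_min, "m_min"),
                 seed = as.integer(seed)),
            class = "sim_kg_config")
}

#' Knowledge-graph weighting and ranking parameters
#'
#' @param eps Small positive floor applied to every edge weight.
#' @param c_max Cap on the direct disease-gene weight.
#' @param gamma Bridging penalty in (0, 1]: fraction of the per-member
#'   average direct weight granted to pathway co-members.
#' @param m_min Minimum number of direct seed genes a pathway must contain
#'   to bridge its other members.
#' @param b_max Cap on the total number of bridged genes; the
#'   highest-bonus genes are kept.
#' @param alpha Personalized PageRank damping factor in (0, 1).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter Iteration cap for the power iteration.
#' @param approved_prior Total personalization mass spread equally over
#'   approved drugs (0 puts all restart mass on the disease node).  Must be
#'   < 1.
#' @return An object of class \code{"kg_params"}.
#' @export
kg_params <- function(eps = 1e-6, c_max = 1.0, gamma = 0.5, m_min = 2,
                      b_max = 50, alpha = 0.85, tol = 1e-10, max_iter = 1000,
                      approved_prior = 0) {
  if (eps <= 0 || eps >= c_max) stop_input("need 0 < eps < c_max")
  if (gamma <= 0 || gamma > 1) stop_input("gamma must be in (0, 1]")
  if (m_min < 1) stop_input("m_min must be >= 1")
  if (b_max < 0) stop_input("b_max must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  if (approved_prior < 0 || approved_prior >= 1)
    stop_input("approved_prior must be in [0, 1)")
  structure(list(eps = eps, c_max = c_max, gamma = gamma,
                 m_min = as.integer(m_min), b_max = as.integer(b_max),
                 alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 approved_prior = approved_prior),
            class = "kg_params")
}

#' Time-indexed feature specification
#'
#' Fixes the windowed transforms computed per concept and the window
#' convention.  Windows are half-open \code{(t - w, t]}: an occurrence
#' exactly \code{w} days before the evaluation time falls outside the
#' \code{w}-day window, while an occurrence on the evaluation day itself is
#' included.
#'
#' @param windows Strictly increasing window lengths in days for the count
#'   transforms.
#' @param sentinel_days Value of \code{days_since_last} for a concept never
#'   observed up to the evaluation time; conventionally follow-up length
#'   plus one, so it exceeds every observable recency.
#' @param transform Function applied to count-valued features
#'   (\code{cnt_*}, \code{cum}); recency features are never transformed.
#' @return An object of class \code{"feature_spec"}.
#' @export
feature_spec <- function(windows = c(30, 90, 365),
                         sentinel_days = 731,
                         transform = transform_counts) {
  if (is.unsorted(windows, strictly = TRUE))
    stop_input("windows must be strictly increasing")
  structure(list(windows = windows, sentinel_days = sentinel_days,
                 transform = transform),
            class = "feature_spec")
}

#' Parse a generated feature name back to concept and transform
#'
#' @param x Character vector of feature names such as
#'   \code{"cond2_cnt_30d"}.
#' @return Data frame with columns \code{concept} and \code{transform};
#'   rows are \code{NA} where the name does not parse.
#' @export
parse_feature_name <- function(x) {
  pat <- paste0("^(.*)_(", paste(.TRANSFORMS, collapse = "|"), ")$")
  ok <- grepl(pat, x)
  data.frame(concept = ifelse(ok, sub(pat, "\\1", x), NA_character_),
             transform = ifelse(ok, sub(pat, "\\2", x), NA_character_),
             stringsAsFactors = FALSE)
}
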