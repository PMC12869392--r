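# Penalized counting-process Cox fitting, stability aggregation across
# shards, and the unpenalized summary-feature analysis with FDR control.
#
# Each shard is an L1-penalized Cox model on start-stop rows (glmnet,
# Breslow ties), with the penalty chosen as the K-fold cross-validated
# deviance minimizer.  Fold assignment is at the person level (all of a
# person's rows share a fold) and seeded, so a shard fit is deterministic.
# Across shards we record, per feature, how often it was selected and the
# arithmetic mean of exp(beta) over the shards that selected it.

.pp_design <- function(pp, features = NULL) {
  if (is.null(features)) {
    features <- attr(pp, "features")
    if (is.null(features)) features <- setdiff(names(pp), .id_cols)
  }
  x <- as.matrix(pp[features])
  storage.mode(x) <- "double"
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    message("dropping ", sum(const), " constant column(s): ",
            paste(utils::head(features[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ...")
    x <- x[, !const, drop = FALSE]
  }
  x
}

#' Fit one L1-penalized Cox shard
#'
#' Fits a lasso-penalized proportional-hazards model to start-stop rows,
#' standardizing the design matrix internally and reporting coefficients on
#' the original scale, with the penalty chosen by seeded person-level
#' K-fold cross-validation at the deviance-minimizing lambda.
#'
#' @param pp A \code{"person_periods"} data frame (or any data frame with
#'   \code{person_id}, \code{t_start}, \code{t_stop}, \code{event} plus
#'   numeric feature columns).
#' @param K Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment.
#' @param shard Identifier stored with the result.
#' @param features Optional feature subset; defaults to all feature
#'   columns.
#' @param nlambda,lambda.min.ratio,thresh,dfmax Penalty-path controls
#'   passed to \code{\link[glmnet]{cv.glmnet}}.  The defaults trade a
#'   slightly coarser path for tractable fits on large person-period
#'   tables; the deviance-minimizing lambda on that path is used.
#' @return An object of class \code{"shard_fit"}: the nonzero coefficients
#'   at the chosen penalty (\code{selected}), the penalty (\code{lambda}),
#'   and fit metadata.
#' @export
fit_penalized_cox_shard <- function(pp, K = 10, seed = 1L, shard = 1L,
                                    features = NULL, nlambda = 30,
                                    lambda.min.ratio = 0.05, thresh = 1e-5,
                                    dfmax = 50) {
  n_events <- sum(pp$event)
  if (n_events < 2)
    stop_input("shard has ", n_events,
               " event(s); at least 2 required to fit")
  x <- .pp_design(pp, features)
  y <- survival::Surv(pp$t_start, pp$t_stop, pp$event)
  persons <- unique(pp$person_id)
  foldid <- with_seed(seed, {
    pf <- sample(rep_len(seq_len(K), length(persons)))
    pf[match(pp$person_id, persons)]
  })
  cvfit <- suppressWarnings(glmnet::cv.glmnet(
    x, y, family = "cox", foldid = foldid, standardize = TRUE,
    nlambda = nlambda, lambda.min.ratio = lambda.min.ratio,
    thresh = thresh, dfmax = dfmax))
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  names(beta) <- rownames(stats::coef(cvfit, s = "lambda.min"))
  selected <- beta[beta != 0]
  if (length(selected) && any(abs(selected) > 10))
    warning("very large |coefficient| (possible separation): ",
            paste(names(selected)[abs(selected) > 10], collapse = ", "),
            call. = FALSE)
  structure(list(transition = attr(pp, "transition"), shard = shard,
                 selected = selected, lambda = cvfit$lambda.min, K = K,
                 seed = seed, n_events = n_events, n_rows = nrow(pp),
                 n_features = ncol(x)),
            class = "shard_fit")
}

#' @export
print.shard_fit <- function(x, ...) {
  cat("Penalized Cox shard", x$shard,
      if (!is.null(x$transition)) paste0("(", x$transition, ")"), "\n")
  cat(sprintf("  %d rows, %d events, %d features; lambda = %.4g; %d selected\n",
              x$n_rows, x$n_events, x$n_features, x$lambda,
              length(x$selected)))
  invisible(x)
}

#' Aggregate shard fits into selection frequencies and mean hazard ratios
#'
#' @param results List of \code{"shard_fit"} objects sharing one
#'   transition.
#' @return Data frame with one row per feature ever selected:
#'   \code{feature}, \code{selection_count}, \code{n_shards},
#'   \code{mean_HR} (arithmetic mean of exp(beta) over selecting shards)
#'   and \code{mean_beta}.
#' @export
aggregate_shards <- function(results) {
  if (!length(results))
    return(data.frame(feature = character(0), selection_count = integer(0),
                      n_shards = integer(0), mean_HR = numeric(0),
                      mean_beta = numeric(0)))
  trans <- unique(vapply(results, function(r)
    as.character(r$transition %||% NA_character_), character(1)))
  if (length(trans) > 1)
    stop_input("shard fits span multiple transitions: ",
               paste(trans, collapse = ", "))
  betas <- lapply(results, `[[`, "selected")
  feats <- sort(unique(unlist(lapply(betas, names))))
  if (!length(feats))
    return(data.frame(feature = character(0), selection_count = integer(0),
                      n_shards = integer(0), mean_HR = numeric(0),
                      mean_beta = numeric(0)))
  count <- vapply(feats, function(f)
    sum(vapply(betas, function(b) f %in% names(b), logical(1))), integer(1))
  mean_hr <- vapply(feats, function(f)
    mean(exp(unlist(lapply(betas, function(b) b[names(b) == f])))),
    numeric(1))
  mean_beta <- vapply(feats, function(f)
    mean(unlist(lapply(betas, function(b) b[names(b) == f]))), numeric(1))
  out <- data.frame(feature = feats, selection_count = count,
                    n_shards = length(results), mean_HR = mean_hr,
                    mean_beta = mean_beta, stringsAsFactors = FALSE)
  out <- out[order(-out$selection_count, out$feature), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prioritize aggregated features by stability and effect magnitude
#'
#' Keeps features selected in at least \code{min_frequency} of shards, then
#' orders by selection frequency (descending) and by the magnitude of the
#' log mean hazard ratio (descending), truncating to \code{top_n}.
#'
#' @param agg Output of \code{\link{aggregate_shards}}.
#' @param min_frequency Minimum selection proportion in (0, 1].
#' @param top_n Maximum number of features returned.
#' @return Filtered, ordered subset of \code{agg}.
#' @export
prioritize_features <- function(agg, min_frequency = 0.5, top_n = 25L) {
  if (min_frequency <= 0 || min_frequency > 1)
    stop_input("min_frequency must be in (0, 1]")
  keep <- agg[agg$selection_count / agg$n_shards >= min_frequency, ,
              drop = FALSE]
  keep <- keep[order(-keep$selection_count / keep$n_shards,
                     -abs(log(keep$mean_HR)), keep$feature), , drop = FALSE]
  keep <- utils::head(keep, max(0L, as.integer(top_n)))
  rownames(keep) <- NULL
  keep
}

#' Unpenalized summary-feature Cox fit with FDR control
#'
#' Fits a single counting-process proportional-hazards model (Breslow
#' ties) to a low-dimensional set of summary features, reporting hazard
#' ratios with Wald 95\% confidence intervals and Benjamini-Hochberg
#' adjusted q-values across the feature set.
#'
#' @param pp A \code{"person_periods"} data frame.
#' @param features Feature columns to include; defaults to all feature
#'   columns (intended to be at most a few dozen).
#' @return Data frame of class \code{"summary_cox"}: \code{feature},
#'   \code{HR}, \code{CI_low}, \code{CI_high}, \code{p}, \code{q},
#'   \code{significant} (q < 0.05).  Non-converged fits yield \code{NA}
#'   estimates with a warning rather than failing silently.
#' @export
fit_summary_cox_with_fdr <- function(pp, features = NULL) {
  x <- .pp_design(pp, features)
  if (ncol(x) > 60)
    warning("summary fit has ", ncol(x),
            " columns; intended for a compact summary feature set",
            call. = FALSE)
  df <- data.frame(t_start = pp$t_start, t_stop = pp$t_stop,
                   event = pp$event, x, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(t_start, t_stop, event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  converged <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(fml, data = df, ties = "breslow"),
      warning = function(w) {
        converged <<- FALSE
        warning("summary Cox fit did not converge cleanly: ",
                conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("summary Cox fit failed: ", conditionMessage(fit),
            call. = FALSE)
    out <- data.frame(feature = colnames(x), HR = NA_real_,
                      CI_low = NA_real_, CI_high = NA_real_, p = NA_real_,
                      q = NA_real_, significant = NA)
    class(out) <- c("summary_cox", "data.frame")
    return(out)
  }
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  p <- sm$coefficients[, "Pr(>|z|)"]
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature = colnames(x), HR = exp(beta),
                    CI_low = exp(beta - stats::qnorm(0.975) * se),
                    CI_high = exp(beta + stats::qnorm(0.975) * se),
                    p = as.numeric(p), q = as.numeric(q),
                    significant = as.numeric(q) < 0.05,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("summary_cox", "data.frame")
  out
}

#' Fit a stability-selection lasso-Cox model for one transition
#'
#' The central fitting routine of the survival half: persons are randomly
#' partitioned into \code{n_shards} shards by a seeded draw, an
#' L1-penalized Cox model is fitted per shard with K-fold cross-validated
#' penalty selection, and the shard results are aggregated into per-feature
#' selection frequencies and mean hazard ratios.
#'
#' @param pp A \code{"person_periods"} data frame from
#'   \code{\link{build_cohort_periods}}.
#' @param n_shards Number of person-level shards.
#' @param K Cross-validation folds per shard.
#' @param seed Integer seed; drives both the shard partition and each
#'   shard's fold assignment.
#' @param features Optional feature subset.
#' @param ... Further arguments (penalty-path controls) passed to
#'   \code{\link{fit_penalized_cox_shard}}; unused by the methods.
#' @return An object of class \code{"oud_coxstab"} with components
#'   \code{shards} (list of \code{"shard_fit"}), \code{aggregate}
#'   (see \code{\link{aggregate_shards}}) and the call parameters.
#'   Methods: \code{print}, \code{summary} (prioritized feature table),
#'   \code{coef} (mean log hazard ratio among selecting shards).
#' @export
oud_coxstab <- function(pp, n_shards = 5L, K = 10L, seed = 1L,
                        features = NULL, ...) {
  n_shards <- check_positive_int(n_shards, "n_shards")
  persons <- unique(pp$person_id)
  assignment <- with_seed(seed,
    sample(rep_len(seq_len(n_shards), length(persons))))
  shard_of <- assignment[match(pp$person_id, persons)]
  shards <- lapply(seq_len(n_shards), function(s) {
    sub <- pp[shard_of == s, , drop = FALSE]
    attr(sub, "transition") <- attr(pp, "transition")
    attr(sub, "features") <- attr(pp, "features")
    fit_penalized_cox_shard(sub, K = K, seed = seed + s, shard = s,
                            features = features, ...)
  })
  structure(list(shards = shards, aggregate = aggregate_shards(shards),
                 transition = attr(pp, "transition"),
                 n_shards = n_shards, K = K, seed = seed,
                 n_persons = length(persons)),
            class = "oud_coxstab")
}

#' @export
print.oud_coxstab <- function(x, ...) {
  cat("Stability-selection lasso-Cox fit",
      if (!is.null(x$transition)) paste0("(", x$transition, ")"), "\n")
  cat(sprintf("  %d persons in %d shards, %d-fold CV per shard\n",
              x$n_persons, x$n_shards, x$K))
  cat(sprintf("  %d features selected in at least one shard\n",
              nrow(x$aggregate)))
  invisible(x)
}

#' @rdname oud_coxstab
#' @param object,x An \code{"oud_coxstab"} object.
#' @param min_frequency,top_n Passed to \code{\link{prioritize_features}}.
#' @export
summary.oud_coxstab <- function(object, min_frequency = 0.5, top_n = 25L,
                                ...) {
  out <- prioritize_features(object$aggregate, min_frequency, top_n)
  attr(out, "transition") <- object$transition
  out
}

#' @rdname oud_coxstab
#' @export
coef.oud_coxstab <- function(object, ...) {
  stats::setNames(object$aggregate$mean_beta, object$aggregate$feature)
}

#' Write the aggregated feature table as TSV
#'
#' Columns: \code{feature}, \code{selection_count}, \code{n_shards},
#' \code{mean_HR}.
#'
#' @param agg Output of \code{\link{aggregate_shards}} (or the
#'   \code{aggregate} component of an \code{"oud_coxstab"} fit).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_aggregated_tsv <- function(agg, path) {
  utils::write.table(
    agg[c("feature", "selection_count", "n_shards", "mean_HR")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the summary-feature result table as TSV
#'
#' Columns: \code{feature}, \code{HR}, \code{CI_low}, \code{CI_high},
#' \code{p}, \code{q}.
#'
#' @param res A \code{"summary_cox"} data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_summary_tsv <- function(res, path) {
  utils::write.table(res[c("feature", "HR", "CI_low", "CI_high", "p", "q")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
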