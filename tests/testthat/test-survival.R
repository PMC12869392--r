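# Penalized and unpenalized counting-process Cox fitting, aggregation and
# prioritization.

fake_shard <- function(shard, selected, transition = "onset")
  structure(list(transition = transition, shard = shard,
                 selected = selected, lambda = 0.1, K = 10, seed = shard,
                 n_events = 10, n_rows = 100, n_features = 5),
            class = "shard_fit")

test_that("unpenalized fit matches a brute-force partial-likelihood grid", {
  # four subjects, one binary covariate, Breslow ties; the 1-D partial
  # likelihood is maximized by grid search as an independent oracle.
  pp <- data.frame(person_id = 1:4, t_start = 0, t_stop = c(1, 3, 2, 3),
                   event = c(1L, 0L, 1L, 0L), x = c(1, 1, 0, 0))
  # risk sets: at t=1 all four; at t=2 subjects 2,3,4
  logpl <- function(b)
    (b - log(2 * exp(b) + 2)) + (0 - log(exp(b) + 2))
  grid <- seq(-4, 4, by = 1e-4)
  b_oracle <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  res <- fit_summary_cox_with_fdr(pp, features = "x")
  expect_equal(log(res$HR), b_oracle, tolerance = 1e-3)
  expect_equal(res$q, res$p)   # single feature: q = p
  expect_true(res$CI_low <= res$HR && res$HR <= res$CI_high)
})

test_that("summary fit q-values reproduce the BH step-up rule", {
  sim <- simulate_cohort_events(sim_config(n_persons = 250, seed = 17))
  pp <- build_cohort_periods(sim$events, sim$truth, "onset",
                             spec = feature_spec(sentinel_days = 731),
                             exclude_concepts = c("oud1", "rem1"))
  feats <- grep("cond[12]_|rx1_", attr(pp, "features"), value = TRUE)
  res <- fit_summary_cox_with_fdr(pp, features = feats)
  # independent BH oracle: q_i = min over j >= i of p_(j) * m / j
  m <- nrow(res)
  o <- order(res$p)
  q_oracle <- numeric(m)
  q_oracle[o] <- rev(cummin(rev(res$p[o] * m / seq_len(m))))
  q_oracle <- pmin(q_oracle, 1)
  expect_equal(res$q, q_oracle)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$CI_low <= res$HR & res$HR <= res$CI_high))
})

test_that("a strong planted effect is significant in the summary fit", {
  sim <- simulate_cohort_events(sim_config(n_persons = 1500, seed = 23))
  pp <- build_cohort_periods(sim$events, sim$truth, "onset",
                             spec = feature_spec(sentinel_days = 731),
                             exclude_concepts = c("oud1", "rem1"))
  # compact summary set, as this analysis is meant to be used
  feats <- grep("^(cond1|rx1|svy1)_", attr(pp, "features"), value = TRUE)
  res <- fit_summary_cox_with_fdr(pp, features = feats)
  planted <- res[res$feature == "cond1_cnt_30d", ]
  expect_gt(planted$HR, 1)
  expect_lt(planted$q, 0.05)
})

test_that("penalized shard fit recovers a planted effect and handles edge cases", {
  sim <- simulate_cohort_events(sim_config(n_persons = 1000, seed = 31))
  pp <- build_cohort_periods(sim$events, sim$truth, "onset",
                             spec = feature_spec(sentinel_days = 731),
                             exclude_concepts = c("oud1", "rem1"))
  fit <- fit_penalized_cox_shard(pp, K = 3, seed = 1, nlambda = 15,
                                 lambda.min.ratio = 0.15, thresh = 1e-4,
                                 dfmax = 25)
  expect_true("cond1_cnt_30d" %in% names(fit$selected))
  expect_gt(fit$selected[["cond1_cnt_30d"]], 0)
  expect_true(all(fit$selected != 0))
  # sign agreement between penalized and unpenalized routes
  res <- fit_summary_cox_with_fdr(pp, features = "cond1_cnt_30d")
  expect_gt(res$HR, 1)
  # refusal with < 2 events
  few <- pp[pp$person_id %in% pp$person_id[1], , drop = FALSE]
  expect_error(fit_penalized_cox_shard(few), "event")
  # constant columns are dropped with a note
  pp$dead_col <- 1
  attr(pp, "features") <- c(attr(pp, "features"), "dead_col")
  expect_message(
    fit2 <- fit_penalized_cox_shard(pp, K = 3, seed = 1, nlambda = 10,
                                    lambda.min.ratio = 0.2, thresh = 1e-3,
                                    dfmax = 10),
    "constant")
  expect_false("dead_col" %in% names(fit2$selected))
})

test_that("aggregation computes selection counts and mean HR as stated", {
  shards <- list(
    fake_shard(1, c(f1 = log(2), f2 = 0.5)),
    fake_shard(2, c(f1 = log(4))),
    fake_shard(3, c(f1 = log(3))),
    fake_shard(4, c(f3 = -1)),
    fake_shard(5, stats::setNames(numeric(0), character(0))))
  agg <- aggregate_shards(shards)
  f1 <- agg[agg$feature == "f1", ]
  expect_equal(f1$selection_count, 3L)
  expect_equal(f1$n_shards, 5L)
  expect_equal(f1$mean_HR, mean(c(2, 4, 3)))   # arithmetic mean of HRs
  # single-shard selection: mean_HR = exp(beta)
  f3 <- agg[agg$feature == "f3", ]
  expect_equal(f3$selection_count, 1L)
  expect_equal(f3$mean_HR, exp(-1))
  # never-selected features are absent
  expect_false("f9" %in% agg$feature)
  # conservation: total counts equal total selections
  expect_equal(sum(agg$selection_count),
               sum(vapply(shards, function(s) length(s$selected),
                          integer(1))))
  # permutation invariance
  agg_perm <- aggregate_shards(shards[c(3, 5, 1, 4, 2)])
  expect_equal(agg, agg_perm)
  # empty input and mixed transitions
  expect_equal(nrow(aggregate_shards(list())), 0L)
  expect_error(aggregate_shards(list(fake_shard(1, c(a = 1), "onset"),
                                     fake_shard(2, c(a = 1), "relapse"))),
               "transitions")
})

test_that("prioritization filters by frequency and orders by |log HR|", {
  agg <- data.frame(feature = c("a", "b", "c"),
                    selection_count = c(5L, 2L, 5L), n_shards = 5L,
                    mean_HR = c(3.0, 10, 0.25),
                    mean_beta = log(c(3, 10, 0.25)))
  out <- prioritize_features(agg, min_frequency = 0.5, top_n = 10)
  expect_setequal(out$feature, c("a", "c"))       # b fails the threshold
  expect_equal(out$feature[1], "c")               # |ln .25| > |ln 3|
  expect_equal(nrow(prioritize_features(agg, 0.5, 0)), 0L)
  expect_error(prioritize_features(agg, 0), "min_frequency")
})

test_that("the sharded stability fit aggregates deterministically", {
  sim <- simulate_cohort_events(sim_config(n_persons = 400, seed = 8))
  pp <- build_cohort_periods(sim$events, sim$truth, "onset",
                             spec = feature_spec(sentinel_days = 731),
                             exclude_concepts = c("oud1", "rem1"))
  fit <- oud_coxstab(pp, n_shards = 2, K = 3, seed = 4, nlambda = 10,
                     lambda.min.ratio = 0.2, thresh = 1e-3, dfmax = 15)
  fit2 <- oud_coxstab(pp, n_shards = 2, K = 3, seed = 4, nlambda = 10,
                      lambda.min.ratio = 0.2, thresh = 1e-3, dfmax = 15)
  expect_equal(fit$aggregate, fit2$aggregate)
  expect_identical(fit$n_shards, 2L)
  expect_true(all(fit$aggregate$selection_count <= 2))
  expect_output(print(fit), "Stability-selection")
  co <- coef(fit)
  expect_identical(names(co), fit$aggregate$feature)
  sm <- summary(fit, min_frequency = 1, top_n = 5)
  expect_lte(nrow(sm), 5)
})
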