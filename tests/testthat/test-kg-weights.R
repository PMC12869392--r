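# Edge-weight rules of the therapy graph: the ordered piecewise
# disease-gene evidence rule, its cap, the bridging bonus and the
# gene-drug scoring.

test_that("disease-gene evidence branches fire in order with printed constants", {
  p <- kg_params()
  ev0 <- list(r_rep = NA, flag_mvp = 0, flag_oud_only = 0, flag_mtag = 0,
              posterior = NA, p_rank = NA)
  cases <- list(
    list(mod = list(flag_mvp = 1), a = 1.0, branch = "mvp"),
    list(mod = list(flag_oud_only = 1), a = 0.8, branch = "oud_only"),
    list(mod = list(flag_mtag = 1), a = 0.5, branch = "mtag"),
    list(mod = list(posterior = 0), a = 0.2, branch = "posterior"),
    list(mod = list(posterior = 0.35), a = 0.55, branch = "posterior"),
    list(mod = list(r_rep = 1), a = 0.8, branch = "replication"),
    list(mod = list(r_rep = 2), a = 1.1, branch = "replication"),
    list(mod = list(), a = p$eps, branch = "none"))
  for (cs in cases) {
    ev <- utils::modifyList(ev0, cs$mod)
    res <- gene_direct_weight(ev, p)
    expect_equal(res$a_g, cs$a, info = cs$branch)
    expect_identical(res$branch, cs$branch)
    expect_equal(res$w_direct, max(p$eps, min(cs$a, p$c_max)))
  }
  # p-rank branch: literal reading ln(3 + k/e)
  res <- gene_direct_weight(utils::modifyList(ev0, list(p_rank = 5)), p)
  expect_equal(res$a_g, log(3 + 5 / exp(1)))
  expect_identical(res$branch, "p_rank")
})

test_that("replication count takes precedence and the cap binds", {
  p <- kg_params(c_max = 1)
  # gene with both replication and MVP evidence: replication branch wins
  res <- gene_direct_weight(list(r_rep = 2, flag_mvp = 1), p)
  expect_identical(res$branch, "replication")
  expect_equal(res$a_g, 1.1)
  expect_equal(res$w_direct, 1)  # capped at c_max
  expect_error(gene_direct_weight(list(r_rep = -1), p), "nonnegative")
  expect_error(gene_direct_weight(list(posterior = 1.2), p), "posterior")
})

test_that("gene-drug score follows the indicator arithmetic", {
  p <- kg_params()
  base <- list(pchembl = 5, ant = 0, ago = 0, ph3 = 0, app = 0, bbb = 0,
               res = 0)
  expect_equal(gene_drug_weight(base, p)$t, 1)          # clip(0) = 0
  expect_equal(gene_drug_weight(
    utils::modifyList(base, list(pchembl = 9, app = 1, ph3 = 1)), p)$t, 3.0)
  # missing potency contributes 0; research-only subtracts 0.5
  expect_equal(gene_drug_weight(
    utils::modifyList(base, list(pchembl = NA, res = 1)), p)$t, 0.5)
  # potency clipped at both ends
  expect_equal(gene_drug_weight(
    utils::modifyList(base, list(pchembl = 13)), p)$t, 2)
  expect_equal(gene_drug_weight(
    utils::modifyList(base, list(pchembl = 3)), p)$t, 1)
  # approval implies late phase: app=1 with ph3=0 still adds both terms
  expect_equal(gene_drug_weight(
    utils::modifyList(base, list(app = 1)), p)$t, 1 + 0.7 + 0.3)
  # both mechanism flags are additive
  expect_equal(gene_drug_weight(
    utils::modifyList(base, list(ant = 1, ago = 1)), p)$t, 1.3)
  # weight floored at eps
  res_only <- utils::modifyList(base, list(pchembl = NA, res = 1))
  expect_equal(gene_drug_weight(res_only, p)$w, 0.5)
  heavy <- utils::modifyList(base, list(pchembl = NA, res = 1, ago = 0))
  expect_gte(gene_drug_weight(heavy, p)$w, p$eps)
})

test_that("pathway bridging computes the gamma-penalized bonus", {
  # 4-member pathway with 2 seed genes of direct weight 1.0 and 0.8,
  # gamma = 0.5, m_min = 2: bonus = 0.5 * 1.8 / 4 = 0.225 to both
  # non-seed members.
  p <- kg_params(gamma = 0.5, m_min = 2)
  ev <- data.frame(gene = c("g1", "g2"), r_rep = NA, flag_mvp = c(1L, 0L),
                   flag_oud_only = c(0L, 1L), flag_mtag = 0L,
                   posterior = NA_real_, p_rank = NA_integer_)
  pw <- list(P1 = c("g1", "g2", "h1", "h2"))
  tg <- data.frame(gene = "g1", drug_id = "d", drug_name = "d", pchembl = 6,
                   ant = 0L, ago = 0L, ph3 = 0L, app = 0L, bbb = 0L,
                   res = 0L)
  kg <- therapy_kg(ev, pw, tg, p)
  br <- kg$edges[kg$edges$type == "HAS_GENE_BRIDGED", ]
  expect_setequal(br$to, c("h1", "h2"))
  expect_equal(br$weight, c(0.225, 0.225))
  # below m_min: no bridging
  p1 <- kg_params(gamma = 0.5, m_min = 3)
  kg1 <- therapy_kg(ev, pw, tg, p1)
  expect_identical(nrow(kg1$edges[kg1$edges$type == "HAS_GENE_BRIDGED", ]),
                   0L)
})

test_that("bridging keeps the max bonus, records all pathways, caps at b_max", {
  p <- kg_params(gamma = 0.5, m_min = 1)
  ev <- data.frame(gene = c("g1", "g2"), r_rep = NA, flag_mvp = 1L,
                   flag_oud_only = 0L, flag_mtag = 0L, posterior = NA_real_,
                   p_rank = NA_integer_)
  # h1 sits in both pathways with different bonuses:
  # P1: members {g1, h1} -> bonus = 0.5 * 1 / 2 = 0.25
  # P2: members {g1, g2, h1, h2} -> bonus = 0.5 * 2 / 4 = 0.25... use
  # unequal sizes to split them:
  pw <- list(P1 = c("g1", "h1"), P2 = c("g1", "g2", "h1", "h2", "h3"))
  tg <- data.frame(gene = "g1", drug_id = "d", drug_name = "d", pchembl = 6,
                   ant = 0L, ago = 0L, ph3 = 0L, app = 0L, bbb = 0L,
                   res = 0L)
  kg <- therapy_kg(ev, pw, tg, p)
  br <- kg$edges[kg$edges$type == "HAS_GENE_BRIDGED", ]
  h1 <- br[br$to == "h1", ]
  expect_equal(h1$weight, max(0.25, 0.5 * 2 / 5))   # max, not sum
  expect_match(h1$provenance, "P1")
  expect_match(h1$provenance, "P2")
  # cap: only the highest-bonus gene is kept
  p_cap <- kg_params(gamma = 0.5, m_min = 1, b_max = 1)
  kg_cap <- therapy_kg(ev, pw, tg, p_cap)
  br_cap <- kg_cap$edges[kg_cap$edges$type == "HAS_GENE_BRIDGED", ]
  expect_identical(br_cap$to, "h1")  # 0.25 from P1 beats 0.2 for h2/h3
})

test_that("graph invariants hold on simulated inputs", {
  for (seed in 1:5) {
    kg <- random_kg(seed)
    expect_true(all(kg$edges$weight >= kg$params$eps - 1e-15))
    expect_identical(sum(kg$nodes$type == "OUD"), 1L)
    oud_edges <- kg$edges[kg$edges$from == "OUD", ]
    expect_true(all(oud_edges$type %in% c("HAS_GENE", "HAS_GENE_BRIDGED")))
    tgt <- kg$edges[kg$edges$type == "TARGETED_BY", ]
    gene_ids <- kg$nodes$id[kg$nodes$type == "gene"]
    expect_true(all(tgt$from %in% gene_ids))
  }
})
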