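# Projection, row normalization, Personalized PageRank and drug ranking.

test_that("projection removes pathway nodes and rows normalize to 1", {
  kg <- tiny_kg()
  proj <- project_and_normalize(kg)
  expect_false(any(proj$nodes %in% kg$nodes$id[kg$nodes$type == "pathway"]))
  rs <- rowSums(proj$P)
  expect_true(all(abs(rs[!proj$dangling] - 1) < 1e-12))
  expect_true(all(rs[proj$dangling] == 0))
  # drugs are the dangling nodes
  drugs <- kg$nodes$id[kg$nodes$type == "drug"]
  expect_true(all(proj$dangling[match(drugs, proj$nodes)]))
  # explicit normalization example: two outgoing weights 2 and 3 -> .4/.6
  P <- matrix(c(0, 2, 3, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE)
  expect_equal(P[1, ] / sum(P[1, ]), c(0, 0.4, 0.6))
})

test_that("personalization vector is a probability vector", {
  nodes <- c("OUD", "g1", "d1", "d2")
  s0 <- build_personalization(nodes, character(0), kg_params())
  expect_equal(unname(s0), c(1, 0, 0, 0))
  p <- kg_params(approved_prior = 0.2)
  s <- build_personalization(nodes, c("d1", "d2"), p)
  expect_equal(unname(s), c(0.8, 0, 0.1, 0.1))
  expect_equal(sum(s), 1)
  expect_error(kg_params(approved_prior = 1), "approved_prior")
})

test_that("power iteration matches a dense linear solve on small random graphs", {
  for (seed in 1:50) {
    kg <- random_kg(seed, n_genes = sample(3:6, 1), n_drugs = sample(2:5, 1))
    proj <- project_and_normalize(kg)
    expect_lte(length(proj$nodes), 20)
    s <- build_personalization(proj$nodes, character(0), kg$params)
    r <- personalized_pagerank(proj$P, s, kg$params, proj$dangling)
    oracle <- ppr_linear_oracle(proj$P, s, kg$params$alpha)
    expect_lt(max(abs(as.numeric(r) - oracle)), 1e-8)
    expect_equal(sum(r), 1, tolerance = 1e-10)
  }
})

test_that("pagerank degenerates to s at alpha near 0 and conserves mass", {
  kg <- tiny_kg()
  proj <- project_and_normalize(kg)
  s <- build_personalization(proj$nodes, character(0), kg$params)
  p_small <- kg_params(alpha = 1e-12)
  r <- personalized_pagerank(proj$P, s, p_small, proj$dangling)
  expect_equal(as.numeric(r), as.numeric(s), tolerance = 1e-9)
  for (seed in 6:15) {
    kg <- random_kg(seed)
    proj <- project_and_normalize(kg)
    s <- build_personalization(proj$nodes, character(0), kg$params)
    r <- personalized_pagerank(proj$P, s, kg$params, proj$dangling)
    expect_equal(sum(r), 1, tolerance = 1e-10)
    expect_true(all(r >= 0))
  }
})

test_that("pagerank agrees with igraph on a graph without dangling nodes", {
  skip_if_not_installed("igraph")
  # add a drug -> OUD back edge so every node has out-degree > 0
  kg <- tiny_kg()
  proj <- project_and_normalize(kg)
  P <- proj$P
  for (d in which(proj$dangling)) P[d, "OUD"] <- 1
  s <- build_personalization(proj$nodes, character(0), kg$params)
  r <- personalized_pagerank(P, s, kg_params(alpha = 0.85, tol = 1e-12),
                             dangling = rep(FALSE, nrow(P)))
  g <- igraph::graph_from_adjacency_matrix(P, weighted = TRUE,
                                           mode = "directed")
  ig <- igraph::page_rank(g, damping = 0.85, personalized = s,
                          weights = igraph::E(g)$weight)$vector
  expect_equal(as.numeric(r), as.numeric(ig), tolerance = 1e-6)
})

test_that("drug score never decreases when its incoming weight grows", {
  inp <- tiny_kg_inputs()
  score_of <- function(pchembl) {
    tg <- inp$drug_targets
    tg$pchembl[tg$drug_id == "D3"] <- pchembl
    kg <- therapy_kg(inp$gene_evidence, inp$pathways, tg, kg_params())
    rk <- rank_drugs(kg)
    rk$score[rk$drug_id == "D3"]
  }
  scores <- vapply(c(5, 6, 7, 8, 9), score_of, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("ranking sorts by score, labels bridged support, is deterministic", {
  kg <- tiny_kg()
  rk <- rank_drugs(kg, why_top = 3)
  expect_identical(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$score) <= 1e-15))
  # D3 is reachable only through the bridged gene KCNN1
  d3 <- rk[rk$drug_id == "D3", ]
  expect_match(d3$supporting_genes, "KCNN1")
  expect_match(d3$gene_labels, "bridged")
  expect_match(d3$supporting_pathways, "PW1")
  # byte-determinism of the TSV writer
  f1 <- tempfile(); f2 <- tempfile()
  write_ranked_tsv(rk, f1)
  write_ranked_tsv(rank_drugs(tiny_kg(), why_top = 3), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  header <- readLines(f1, n = 1)
  expect_identical(header, paste(
    c("rank", "drug_id", "drug_name", "score", "supporting_genes",
      "gene_labels", "supporting_pathways", "approved", "bbb"),
    collapse = "\t"))
  # empty ranking -> header-only file
  f3 <- tempfile()
  write_ranked_tsv(rk[0, ], f3)
  expect_identical(length(readLines(f3)), 1L)
})

test_that("additive per-drug score offsets reorder the ranking", {
  kg <- tiny_kg()
  base <- rank_drugs(kg)
  bottom <- base$drug_id[nrow(base)]
  boosted <- rank_drugs(kg, score_offsets = stats::setNames(1, bottom))
  expect_identical(boosted$drug_id[1], bottom)
  expect_equal(boosted$score[1],
               base$score[base$drug_id == bottom] + 1)
  expect_error(rank_drugs(kg, score_offsets = 1), "named")
})

test_that("salt-form aliases merge to the maximum score", {
  inp <- tiny_kg_inputs()
  tg <- rbind(inp$drug_targets, data.frame(
    gene = "OPRM1", drug_id = "D9", drug_name = "Naltrexone Hydrochloride",
    pchembl = 6, ant = 1L, ago = 0L, ph3 = 1L, app = 1L, bbb = 1L,
    res = 0L))
  kg <- therapy_kg(inp$gene_evidence, inp$pathways, tg, kg_params())
  keep <- rank_drugs(kg, alias_mode = "keep")
  merged <- rank_drugs(kg, alias_mode = "merge")
  expect_identical(nrow(merged), nrow(keep) - 1L)
  nal_keep <- keep[normalize_drug_name(keep$drug_name) == "naltrexone", ]
  nal_merged <- merged[normalize_drug_name(merged$drug_name) == "naltrexone", ]
  expect_identical(nrow(nal_merged), 1L)
  expect_equal(nal_merged$score, max(nal_keep$score))
  expect_identical(normalize_drug_name("Buprenorphine  "), "buprenorphine")
  expect_identical(normalize_drug_name("naloxone hydrochloride"),
                   "naloxone")
})

test_that("approved drugs targeting the top seed gene occupy the top ranks", {
  # Face-validity harness: three approved MAT-like drugs all target the
  # maximal-weight seed gene; unapproved decoys target weaker genes.
  ev <- data.frame(
    gene = c("OPRM1", "Gwk1", "Gwk2"),
    r_rep = c(3, NA, NA), flag_mvp = 0L, flag_oud_only = 0L, flag_mtag = 0L,
    posterior = c(NA, 0.02, 0.05), p_rank = NA_integer_)
  tg <- data.frame(
    gene = c("OPRM1", "OPRM1", "OPRM1", "Gwk1", "Gwk2"),
    drug_id = c("MAT1", "MAT2", "MAT3", "X1", "X2"),
    drug_name = c("buprenorphine", "methadone", "naltrexone",
                  "decoy1", "decoy2"),
    pchembl = c(9, 9, 9, 6, 6),
    ant = c(0L, 0L, 1L, 0L, 0L), ago = c(1L, 1L, 0L, 0L, 0L),
    ph3 = 1L, app = c(1L, 1L, 1L, 0L, 0L), bbb = 1L,
    res = c(0L, 0L, 0L, 1L, 1L))
  kg <- therapy_kg(ev, list(), tg, kg_params())
  rk <- rank_drugs(kg)
  expect_setequal(rk$drug_id[1:3], c("MAT1", "MAT2", "MAT3"))
  expect_true(all(rk$approved[1:3] == 1))
})
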