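# Shared fixtures, built in code.

# Tiny hand-checkable therapy-graph inputs: two seed genes, one bridging
# pathway, three drugs (one approved dual-target, one research-only, one
# reachable only through the bridged gene).
tiny_kg_inputs <- function() {
  list(
    gene_evidence = data.frame(
      gene = c("OPRM1", "PDE4B"),
      r_rep = c(NA, NA), flag_mvp = c(1L, 0L), flag_oud_only = c(0L, 1L),
      flag_mtag = 0L, posterior = NA_real_, p_rank = NA_integer_,
      stringsAsFactors = FALSE),
    pathways = list(PW1 = c("OPRM1", "PDE4B", "KCNN1", "DRD2")),
    drug_targets = data.frame(
      gene = c("OPRM1", "PDE4B", "OPRM1", "KCNN1"),
      drug_id = c("D1", "D1", "D2", "D3"),
      drug_name = c("naltrexone", "naltrexone", "methadone", "ns309"),
      pchembl = c(8, 7, 9, NA),
      ant = c(1L, 0L, 0L, 0L), ago = c(0L, 0L, 1L, 1L),
      ph3 = c(1L, 1L, 1L, 0L), app = c(1L, 1L, 1L, 0L),
      bbb = c(1L, 1L, 1L, 1L), res = c(0L, 0L, 0L, 1L),
      stringsAsFactors = FALSE))
}

tiny_kg <- function(params = kg_params()) {
  inp <- tiny_kg_inputs()
  therapy_kg(inp$gene_evidence, inp$pathways, inp$drug_targets, params)
}

# Random small graph in the therapy-graph input format, for property
# tests: n_genes seed genes with random evidence, a few pathways, n_drugs
# drugs with random annotations.
random_kg <- function(seed, n_genes = 6, n_drugs = 5, n_pathways = 2,
                      params = kg_params()) {
  sim <- simulate_kg_tables(sim_kg_config(
    n_seed_genes = n_genes, n_bridge_genes = 3, n_pathways = n_pathways,
    n_drugs = n_drugs, seed = seed))
  therapy_kg(sim$gene_evidence, sim$pathways, sim$drug_targets, params)
}

# Dense linear-solve oracle for personalized PageRank with dangling mass
# redirected to s: solve (I - alpha * t(Ptilde)) r = (1 - alpha) s where
# Ptilde replaces dangling rows by s.
ppr_linear_oracle <- function(P, s, alpha) {
  dangling <- rowSums(P) == 0
  Pt <- P
  if (any(dangling)) Pt[dangling, ] <- matrix(s, sum(dangling),
                                              length(s), byrow = TRUE)
  as.numeric(solve(diag(length(s)) - alpha * t(Pt), (1 - alpha) * s))
}

# Small event stream for feature tests: one person, two concepts.
toy_events <- function() {
  data.frame(
    person_id = 1L,
    concept_id = c("condA", "condA", "condB"),
    day = c(0L, 50L, 10L),
    stringsAsFactors = FALSE)
}
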