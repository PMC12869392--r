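# Evidence-weighted therapy knowledge graph.
#
# A directed, weighted graph over {OUD} U genes U pathways U drugs.
# Disease-gene edges carry an association weight derived from GWAS-style
# evidence through an ordered piecewise rule (first matching branch wins):
#
#   replication count r     -> 0.5 + 0.3 r
#   cross-ancestry MVP flag -> 1.0
#   OUD-only study flag     -> 0.8
#   OUD-only MTAG flag      -> 0.5
#   fine-mapping posterior  -> 0.2 + posterior
#   p-value rank k          -> ln(3 + k / e)
#   otherwise               -> eps
#
# capped into [eps, c_max].  Pathways with at least m_min seed genes grant
# their non-seed members a gamma-penalized bridged edge (bonus = gamma *
# sum of member seed weights / pathway size); gene-drug edges score potency
# (pChEMBL) plus mechanism and development-status indicators.  After
# projecting pathway nodes out, outgoing weights are row-normalized and
# drugs are ranked by Personalized PageRank restarted at the disease node.

#' Direct disease-gene association weight
#'
#' Evaluates the ordered piecewise evidence rule for one gene and applies
#' the cap.  Branch precedence is fixed: replication count, MVP
#' cross-ancestry flag, OUD-only flag, OUD-only MTAG flag, posterior,
#' p-value rank, else the floor \code{eps}.
#'
#' @param ev One gene-evidence record: a list or one-row data frame with
#'   fields \code{r_rep}, \code{flag_mvp}, \code{flag_oud_only},
#'   \code{flag_mtag}, \code{posterior}, \code{p_rank} (\code{NA}/0 =
#'   absent).
#' @param params A \code{\link{kg_params}} object.
#' @return List with \code{a_g} (pre-cap weight), \code{w_direct}
#'   (\code{max(eps, min(a_g, c_max))}) and \code{branch} (which evidence
#'   branch fired).
#' @export
gene_direct_weight <- function(ev, params = kg_params()) {
  ev <- as.list(ev)
  has <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)
  flag <- function(x) has(x) && x == 1
  if (has(ev$r_rep) && ev$r_rep < 0)
    stop_input("replication count must be nonnegative")
  if (has(ev$posterior) && (ev$posterior < 0 || ev$posterior > 1))
    stop_input("posterior must lie in [0, 1]")
  if (has(ev$r_rep)) {
    a <- 0.5 + 0.3 * ev$r_rep; branch <- "replication"
  } else if (flag(ev$flag_mvp)) {
    a <- 1.0; branch <- "mvp"
  } else if (flag(ev$flag_oud_only)) {
    a <- 0.8; branch <- "oud_only"
  } else if (flag(ev$flag_mtag)) {
    a <- 0.5; branch <- "mtag"
  } else if (has(ev$posterior)) {
    a <- 0.2 + ev$posterior; branch <- "posterior"
  } else if (has(ev$p_rank)) {
    a <- log(3 + ev$p_rank / exp(1)); branch <- "p_rank"
  } else {
    a <- params$eps; branch <- "none"
  }
  list(a_g = a, w_direct = max(params$eps, min(a, params$c_max)),
       branch = branch)
}

#' Gene-drug target edge weight
#'
#' Scores one gene-drug pair as
#' \code{t = 1 + clip((pChEMBL - 5)/4, 0, 1) + 0.2 ant + 0.1 ago +
#' 0.3 ph3 + 0.7 app + 0.2 bbb - 0.5 res}, with the potency term 0 when
#' pChEMBL is missing, and floors the edge weight at \code{eps}.  An
#' approved drug is treated as having reached phase 3.
#'
#' @param ev One target record: list or one-row data frame with
#'   \code{pchembl} and 0/1 indicators \code{ant} (antagonist/inhibitor),
#'   \code{ago} (agonist/activator), \code{ph3} (phase >= 3), \code{app}
#'   (approved), \code{bbb} (blood-brain-barrier permeable), \code{res}
#'   (research-only).
#' @param params A \code{\link{kg_params}} object.
#' @return List with \code{t} (raw score) and \code{w}
#'   (\code{max(eps, t)}).
#' @export
gene_drug_weight <- function(ev, params = kg_params()) {
  ev <- as.list(ev)
  ind <- function(x) if (is.null(x) || is.na(x)) 0 else as.numeric(x != 0)
  clip01 <- function(x) min(1, max(0, x))
  potency <- if (is.null(ev$pchembl) || is.na(ev$pchembl)) 0
             else clip01((ev$pchembl - 5) / 4)
  ph3 <- max(ind(ev$ph3), ind(ev$app))  # approval implies late phase
  t <- 1 + potency + 0.2 * ind(ev$ant) + 0.1 * ind(ev$ago) +
    0.3 * ph3 + 0.7 * ind(ev$app) + 0.2 * ind(ev$bbb) - 0.5 * ind(ev$res)
  list(t = t, w = max(params$eps, t))
}

#' Read / write GMT gene-set files
#'
#' @param path GMT file path.
#' @return \code{read_gmt}: named list of member-gene vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param pathways Named list of member-gene character vectors.
#' @return \code{write_gmt}: invisibly, \code{path}.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, nm, pathways[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build the evidence-weighted therapy knowledge graph
#'
#' Constructs the directed graph {OUD} U genes U pathways U drugs: direct
#' disease-gene edges from the evidence table, pathway-bridged
#' disease-gene edges for co-members of seed-gene-rich pathways, gene
#' membership edges to pathway nodes (provenance only), and gene-drug
#' target edges.  When several pathways bridge the same gene the maximum
#' bonus is kept and every supporting pathway recorded; the number of
#' bridged genes is capped at \code{b_max}, keeping the highest bonuses.
#'
#' @param gene_evidence Data frame: \code{gene}, \code{r_rep},
#'   \code{flag_mvp}, \code{flag_oud_only}, \code{flag_mtag},
#'   \code{posterior}, \code{p_rank} (empty/NA = absent).
#' @param pathways Named list of member-gene vectors, or a GMT file path.
#' @param drug_targets Data frame: \code{gene}, \code{drug_id},
#'   \code{drug_name}, \code{pchembl}, \code{ant}, \code{ago}, \code{ph3},
#'   \code{app}, \code{bbb}, \code{res}.
#' @param params A \code{\link{kg_params}} object.
#' @return An object of class \code{"therapy_kg"}: \code{nodes} (data
#'   frame \code{id}, \code{type}, \code{label}), \code{edges} (data frame
#'   \code{from}, \code{to}, \code{type}, \code{weight},
#'   \code{provenance}), \code{drug_info}, and \code{params}.
#' @export
therapy_kg <- function(gene_evidence, pathways, drug_targets,
                       params = kg_params()) {
  if (is.character(pathways) && length(pathways) == 1L)
    pathways <- read_gmt(pathways)
  seed_genes <- as.character(gene_evidence$gene)
  if (anyDuplicated(seed_genes))
    stop_input("duplicate gene ids in gene_evidence")

  dw <- lapply(seq_len(nrow(gene_evidence)), function(i)
    gene_direct_weight(gene_evidence[i, ], params))
  w_direct <- stats::setNames(vapply(dw, `[[`, numeric(1), "w_direct"),
                              seed_genes)
  branch <- stats::setNames(vapply(dw, `[[`, character(1), "branch"),
                            seed_genes)
  edges <- data.frame(
    from = "OUD", to = seed_genes, type = "HAS_GENE",
    weight = as.numeric(w_direct), provenance = as.character(branch),
    stringsAsFactors = FALSE)

  # Pathway bridging.
  bridged <- .bridge_pathway_genes(pathways, seed_genes, w_direct, params)
  if (nrow(bridged$edges)) edges <- rbind(edges, bridged$edges)

  # Membership edges (provenance only; projected out before ranking).
  pw_names <- if (is.null(names(pathways))) character(0) else names(pathways)
  mem <- do.call(rbind, lapply(pw_names, function(p) {
    m <- unique(pathways[[p]])
    if (!length(m)) return(NULL)
    data.frame(from = m, to = p, type = "IN_PATHWAY", weight = 1,
               provenance = "", stringsAsFactors = FALSE)
  }))
  if (!is.null(mem)) edges <- rbind(edges, mem)

  # Gene-drug target edges.
  td <- lapply(seq_len(nrow(drug_targets)), function(i)
    gene_drug_weight(drug_targets[i, ], params))
  tgt <- data.frame(
    from = as.character(drug_targets$gene),
    to = as.character(drug_targets$drug_id), type = "TARGETED_BY",
    weight = vapply(td, `[[`, numeric(1), "w"),
    provenance = ifelse(is.na(drug_targets$pchembl), "no_potency",
                        sprintf("pchembl=%.3g", drug_targets$pchembl)),
    stringsAsFactors = FALSE)
  edges <- rbind(edges, tgt)
  if (any(edges$weight < params$eps - 1e-15))
    stop_input("internal error: edge weight below floor")

  drug_info <- unique(data.frame(
    drug_id = as.character(drug_targets$drug_id),
    drug_name = as.character(drug_targets$drug_name),
    approved = as.integer(tapply(drug_targets$app, drug_targets$drug_id,
                                 max)[as.character(drug_targets$drug_id)] > 0),
    bbb = as.integer(tapply(drug_targets$bbb, drug_targets$drug_id,
                            max)[as.character(drug_targets$drug_id)] > 0),
    stringsAsFactors = FALSE))
  rownames(drug_info) <- NULL

  genes <- sort(unique(c(seed_genes, bridged$genes,
                         as.character(drug_targets$gene))))
  gene_label <- ifelse(genes %in% seed_genes, "direct",
                       ifelse(genes %in% bridged$genes, "bridged",
                              "non-seed"))
  nodes <- rbind(
    data.frame(id = "OUD", type = "OUD", label = "disease",
               stringsAsFactors = FALSE),
    data.frame(id = genes, type = "gene", label = gene_label,
               stringsAsFactors = FALSE),
    data.frame(id = pw_names, type = rep("pathway", length(pw_names)),
               label = rep("pathway", length(pw_names)),
               stringsAsFactors = FALSE),
    data.frame(id = unique(drug_info$drug_id), type = "drug", label = "drug",
               stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$id))
    stop_input("node id used by more than one node type")

  structure(list(nodes = nodes, edges = edges, drug_info = drug_info,
                 bridged = bridged$support, params = params),
            class = "therapy_kg")
}

# Bridging rule: pathway p with member set M_p and seed members S_p
# (|S_p| >= m_min) grants each non-seed member the bonus
# b_p = gamma * sum(w_direct[S_p]) / |M_p|.  Returns the bridged edges
# (max bonus per gene, all supporting pathways recorded) and support map.
.bridge_pathway_genes <- function(pathways, seed_genes, w_direct, params) {
  cand <- list()
  for (p in names(pathways)) {
    members <- unique(pathways[[p]])
    if (!length(members)) {
      warning("pathway ", p, " has no members; skipped", call. = FALSE)
      next
    }
    sp <- intersect(members, seed_genes)
    if (length(sp) < params$m_min) next
    bonus <- params$gamma * sum(w_direct[sp]) / length(members)
    for (h in setdiff(members, seed_genes))
      cand[[length(cand) + 1L]] <- data.frame(
        gene = h, pathway = p, bonus = bonus, stringsAsFactors = FALSE)
  }
  empty <- list(edges = data.frame(from = character(0), to = character(0),
                                   type = character(0), weight = numeric(0),
                                   provenance = character(0)),
                genes = character(0), support = list())
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  per_gene <- split(cand, cand$gene)
  best <- do.call(rbind, lapply(per_gene, function(df) {
    data.frame(gene = df$gene[1], bonus = max(df$bonus),
               pathways = paste(sort(df$pathway), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  best <- best[order(-best$bonus, best$gene), , drop = FALSE]
  best <- utils::head(best, params$b_max)
  if (!nrow(best)) return(empty)
  list(edges = data.frame(from = "OUD", to = best$gene,
                          type = "HAS_GENE_BRIDGED",
                          weight = pmax(params$eps, best$bonus),
                          provenance = paste0("pathways=", best$pathways),
                          stringsAsFactors = FALSE),
       genes = best$gene,
       support = stats::setNames(strsplit(best$pathways, ",", fixed = TRUE),
                                 best$gene))
}

#' @export
print.therapy_kg <- function(x, ...) {
  ct <- function(tp) sum(x$nodes$type == tp)
  cat("Therapy knowledge graph:", nrow(x$nodes) - 1L, "entities\n")
  cat(sprintf("  %d genes (%d direct, %d bridged), %d pathways, %d drugs\n",
              ct("gene"),
              sum(x$nodes$label == "direct"),
              sum(x$nodes$label == "bridged"),
              ct("pathway"), ct("drug")))
  cat(" ", nrow(x$edges), "edges:",
      paste(names(table(x$edges$type)), table(x$edges$type),
            collapse = ", "), "\n")
  invisible(x)
}

#' Project pathway nodes out and row-normalize transition weights
#'
#' Removes pathway nodes (their influence is already folded into the
#' bridged disease-gene edges) and normalizes each remaining node's
#' outgoing weights to sum to 1, yielding the row-stochastic transition
#' structure of the random walk.  Nodes without outgoing edges (drugs) are
#' flagged dangling; their walk mass is redirected to the personalization
#' vector during ranking.
#'
#' @param kg A \code{"therapy_kg"} object.
#' @return List with \code{nodes} (character vector), \code{P} (dense
#'   row-stochastic matrix; dangling rows all zero), \code{dangling}
#'   (logical vector) and \code{edges} (the normalized edge list).
#' @export
project_and_normalize <- function(kg) {
  stopifnot(inherits(kg, "therapy_kg"))
  keep_nodes <- kg$nodes$id[kg$nodes$type != "pathway"]
  e <- kg$edges[kg$edges$type != "IN_PATHWAY", , drop = FALSE]
  e <- e[e$from %in% keep_nodes & e$to %in% keep_nodes, , drop = FALSE]
  n <- length(keep_nodes)
  P <- matrix(0, n, n, dimnames = list(keep_nodes, keep_nodes))
  if (nrow(e))
    P[cbind(match(e$from, keep_nodes), match(e$to, keep_nodes))] <-
      P[cbind(match(e$from, keep_nodes), match(e$to, keep_nodes))] + e$weight
  rs <- rowSums(P)
  dangling <- rs == 0
  if (any(rs < 0) || any(!dangling & rs < kg$params$eps))
    stop_input("node with all-zero outgoing weights")
  P[!dangling, ] <- P[!dangling, , drop = FALSE] / rs[!dangling]
  e$weight <- e$weight / rs[match(e$from, keep_nodes)]
  list(nodes = keep_nodes, P = P, dangling = dangling, edges = e)
}

#' Build the personalization (restart) vector
#'
#' All restart mass sits on the disease node unless an approved-drug prior
#' is requested, in which case \code{approved_prior} total mass is split
#' equally over the approved drugs and the remainder stays on the disease
#' node.
#'
#' @param nodes Character vector of projected node ids (must contain
#'   \code{"OUD"}).
#' @param approved_drugs Character vector of approved drug ids.
#' @param params A \code{\link{kg_params}} object.
#' @return Named numeric vector summing to 1.
#' @export
build_personalization <- function(nodes, approved_drugs = character(0),
                                  params = kg_params()) {
  if (!"OUD" %in% nodes) stop_input("projected graph lacks the OUD node")
  s <- stats::setNames(rep(0, length(nodes)), nodes)
  approved_drugs <- intersect(approved_drugs, nodes)
  mass <- if (length(approved_drugs)) params$approved_prior else 0
  if (mass > 0) s[approved_drugs] <- mass / length(approved_drugs)
  s[["OUD"]] <- 1 - mass
  s
}

#' Personalized PageRank by power iteration
#'
#' Solves \code{r = alpha * t(P) r + (1 - alpha) * s} with dangling-node
#' mass redirected to \code{s}, iterating until the L1 change drops below
#' \code{tol}.
#'
#' @param P Row-stochastic matrix (dangling rows all zero).
#' @param s Personalization vector (probability vector over the rows of
#'   \code{P}).
#' @param params A \code{\link{kg_params}} object (\code{alpha},
#'   \code{tol}, \code{max_iter}).
#' @param dangling Logical vector marking all-zero rows; derived from
#'   \code{P} when omitted.
#' @return Named probability vector \code{r} (sums to 1) with attribute
#'   \code{iterations}.
#' @export
personalized_pagerank <- function(P, s, params = kg_params(),
                                  dangling = NULL) {
  n <- nrow(P)
  if (is.null(dangling)) dangling <- rowSums(P) == 0
  if (abs(sum(s) - 1) > 1e-9 || any(s < 0))
    stop_input("s must be a probability vector")
  alpha <- params$alpha
  r <- s
  for (it in seq_len(params$max_iter)) {
    r_new <- alpha * (as.numeric(crossprod(P, r)) +
                        sum(r[dangling]) * s) + (1 - alpha) * s
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < params$tol) {
      r <- r / sum(r)
      names(r) <- rownames(P)
      attr(r, "iterations") <- it
      return(r)
    }
  }
  stop_input(sprintf(
    "personalized PageRank did not converge in %d iterations (residual %.3g)",
    params$max_iter, delta))
}

.SALT_SUFFIXES <- c(
  "hydrochloride", "dihydrochloride", "hydrobromide", "sulfate", "sulphate",
  "tartrate", "bitartrate", "citrate", "maleate", "mesylate", "besylate",
  "tosylate", "phosphate", "acetate", "succinate", "fumarate", "lactate",
  "nitrate", "oxalate", "pamoate", "decanoate", "sodium", "potassium",
  "calcium", "chloride", "bromide", "hcl")

#' Normalize a drug name to its ingredient form
#'
#' Lowercases and strips trailing salt/ester designators (hydrochloride,
#' sulfate, tartrate, ...) so ingredient and salt entries merge.
#'
#' @param name Character vector of drug names.
#' @return Normalized names.
#' @export
normalize_drug_name <- function(name) {
  x <- tolower(trimws(name))
  pat <- paste0("\\s+(", paste(.SALT_SUFFIXES, collapse = "|"), ")$")
  repeat {
    y <- sub(pat, "", x)
    if (identical(y, x)) break
    x <- y
  }
  x
}

#' Rank drugs by Personalized PageRank score
#'
#' Runs the full ranking leg: projection, row normalization,
#' personalization, power iteration, drug sorting (score descending, drug
#' id as tie-break) and per-drug explanation: the top \code{why_top}
#' supporting genes ordered by their walk contribution
#' \code{r(g) * P(g -> d)}, labelled direct / bridged / non-seed, with the
#' bridging pathways for bridged genes.  With \code{alias_mode = "merge"},
#' drugs sharing a normalized ingredient name are merged, keeping the
#' maximum score and the union of supporting genes and pathways.
#'
#' @param kg A \code{"therapy_kg"} object.
#' @param alias_mode \code{"keep"} or \code{"merge"}.
#' @param why_top Number of supporting genes reported per drug.
#' @param params Optional \code{\link{kg_params}} override; defaults to
#'   the parameters stored in \code{kg}.
#' @param score_offsets Optional named numeric vector of additive
#'   per-drug score offsets (node-level priors) applied before sorting;
#'   names are drug ids.  Off by default.
#' @return A \code{"ranked_drugs"} data frame: \code{rank},
#'   \code{drug_id}, \code{drug_name}, \code{score},
#'   \code{supporting_genes}, \code{gene_labels},
#'   \code{supporting_pathways}, \code{approved}, \code{bbb}.
#' @export
rank_drugs <- function(kg, alias_mode = c("keep", "merge"), why_top = 3L,
                       params = NULL, score_offsets = NULL) {
  alias_mode <- match.arg(alias_mode)
  if (is.null(params)) params <- kg$params
  proj <- project_and_normalize(kg)
  approved <- kg$drug_info$drug_id[kg$drug_info$approved == 1]
  s <- build_personalization(proj$nodes, approved, params)
  r <- personalized_pagerank(proj$P, s, params, proj$dangling)

  drug_ids <- kg$nodes$id[kg$nodes$type == "drug"]
  gene_label <- stats::setNames(kg$nodes$label, kg$nodes$id)
  info <- kg$drug_info[match(drug_ids, kg$drug_info$drug_id), ]

  why <- lapply(drug_ids, function(d) {
    contrib <- r[proj$nodes] * proj$P[, d]
    contrib <- contrib[contrib > 0]
    genes <- names(sort(contrib, decreasing = TRUE))
    genes <- genes[genes != "OUD"]
    genes <- utils::head(genes, max(0L, as.integer(why_top)))
    labels <- unname(gene_label[genes])
    pw <- unlist(lapply(genes[labels == "bridged"],
                        function(g) kg$bridged[[g]]))
    list(genes = genes, labels = labels,
         pathways = sort(unique(pw)))
  })

  score <- as.numeric(r[drug_ids])
  if (!is.null(score_offsets)) {
    if (is.null(names(score_offsets)))
      stop_input("score_offsets must be named by drug id")
    idx <- match(drug_ids, names(score_offsets))
    score <- score + ifelse(is.na(idx), 0, score_offsets[idx])
  }
  out <- data.frame(
    drug_id = drug_ids,
    drug_name = info$drug_name,
    score = score,
    supporting_genes = vapply(why, function(w)
      paste(w$genes, collapse = ","), character(1)),
    gene_labels = vapply(why, function(w)
      paste(w$labels, collapse = ","), character(1)),
    supporting_pathways = vapply(why, function(w)
      paste(w$pathways, collapse = ","), character(1)),
    approved = info$approved, bbb = info$bbb,
    stringsAsFactors = FALSE)

  if (alias_mode == "merge") {
    key <- normalize_drug_name(out$drug_name)
    merged <- lapply(split(seq_len(nrow(out)), key), function(idx) {
      sub <- out[idx, , drop = FALSE]
      top <- sub[order(-sub$score, sub$drug_id), ][1, ]
      top$supporting_genes <- paste(
        unique(unlist(strsplit(sub$supporting_genes, ","))), collapse = ",")
      genes <- strsplit(top$supporting_genes, ",")[[1]]
      top$gene_labels <- paste(unname(gene_label[genes]), collapse = ",")
      top$supporting_pathways <- paste(
        sort(unique(unlist(strsplit(sub$supporting_pathways, ",")))),
        collapse = ",")
      top$approved <- max(sub$approved)
      top$bbb <- max(sub$bbb)
      top
    })
    out <- do.call(rbind, merged)
  }

  out <- out[order(-out$score, out$drug_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("ranked_drugs", "data.frame")
  attr(out, "pagerank") <- r
  out
}

#' Write a ranked drug table as TSV
#'
#' Tab-delimited with header \code{rank, drug_id, drug_name, score,
#' supporting_genes, gene_labels, supporting_pathways, approved, bbb};
#' scores are printed with 6 significant digits and the byte output is
#' deterministic for fixed input.
#'
#' @param rows A \code{"ranked_drugs"} data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ranked_tsv <- function(rows, path) {
  cols <- c("rank", "drug_id", "drug_name", "score", "supporting_genes",
            "gene_labels", "supporting_pathways", "approved", "bbb")
  df <- as.data.frame(rows)[, cols, drop = FALSE]
  df$score <- formatC(signif(df$score, 6), format = "g", digits = 6)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  invisible(path)
}
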