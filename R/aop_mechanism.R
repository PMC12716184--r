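## Mechanistic layer: hypergeometric over-representation of dose-dependent
## genes in key events, AOPs and generic gene sets; AOP fingerprints across
## strata; KE-KE network assembly with MIE/AO path connectors; single-AOP
## detail views with PPI bundles and TF edges; per-KE gene prioritization;
## hazard-class rollups.

#' One-tailed Fisher (hypergeometric) over-representation test
#'
#' For each target set, the probability of observing at least the attained
#' overlap between the query and the target under hypergeometric sampling
#' from the universe: P(X >= overlap), X ~ Hypergeom(|universe|, |target|,
#' |query|). Targets are intersected with the universe before testing;
#' Benjamini-Hochberg adjustment is applied across all tested targets.
#'
#' @param query character vector of gene ids (must be within the universe).
#' @param targets named list of character vectors (target gene sets).
#' @param universe character vector: the enrichment background.
#' @param alpha FDR threshold for the enriched flag (default 0.05).
#' @param drop_zero_overlap exclude targets with no overlap from the output
#'   (they are still tested and counted in the BH correction).
#' @return data.frame of class \code{EnrichmentRow}s: target, target_size,
#'   query_size, overlap, overlap_genes, p, p_adj, enriched.
#' @export
fisher_enrich <- function(query, targets, universe, alpha = 0.05,
                          drop_zero_overlap = FALSE) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  stopifnot(is.list(targets), !is.null(names(targets)))
  N <- length(universe); q <- length(query)
  nt <- length(targets)
  m_vec <- integer(nt); ov_vec <- integer(nt); ov_genes <- character(nt)
  in_query <- function(x) x %in% query
  for (i in seq_len(nt)) {
    tset <- unique(targets[[i]])
    tset <- tset[tset %in% universe]
    m_vec[i] <- length(tset)
    hits <- tset[in_query(tset)]
    ov_vec[i] <- length(hits)
    ov_genes[i] <- paste(sort(hits), collapse = ",")
  }
  p <- ifelse(m_vec == 0, 1,
              stats::phyper(ov_vec - 1, m_vec, N - m_vec, q,
                            lower.tail = FALSE))
  out <- data.frame(target = names(targets), target_size = m_vec,
                    query_size = q, overlap = ov_vec,
                    overlap_genes = ov_genes, p = p, stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$enriched <- out$p_adj < alpha
  if (drop_zero_overlap) out <- out[out$overlap > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alpha = alpha, class = c("EnrichmentResult", "data.frame"))
}

# gene sets per KE / per AOP (union of member KEs) from the knowledge tables
ke_gene_sets <- function(knowledge) {
  split(knowledge$gene_to_ke$gene_id, knowledge$gene_to_ke$ke_id)
}
aop_gene_sets <- function(knowledge) {
  ke_sets <- ke_gene_sets(knowledge)
  aops <- split(knowledge$ke_to_aop$ke_id, knowledge$ke_to_aop$aop_id)
  lapply(aops, function(kes)
    unique(unlist(ke_sets[intersect(kes, names(ke_sets))], use.names = FALSE)))
}

#' Enrich dose-dependent genes at the KE and AOP level
#'
#' Runs \code{\link{fisher_enrich}} against the key-event gene sets and the
#' AOP gene sets (union of member KEs). The default universe is all analyzed
#' features carrying at least one KE annotation; the query is intersected
#' with it.
#'
#' @param ddgs character vector of dose-dependent gene ids.
#' @param knowledge an \code{AOPKnowledge}.
#' @param analyzed character vector of all analyzed features (used to build
#'   the default universe).
#' @param universe optional explicit universe override.
#' @param alpha FDR threshold (default 0.05).
#' @return list with elements \code{ke} and \code{aop}, each an enrichment
#'   table, plus \code{universe}.
#' @export
enrich_ddgs <- function(ddgs, knowledge, analyzed, universe = NULL,
                        alpha = 0.05) {
  annotated <- unique(knowledge$gene_to_ke$gene_id)
  if (is.null(universe)) universe <- intersect(analyzed, annotated)
  query <- intersect(ddgs, universe)
  if (!length(query)) stop("no dose-dependent genes in the universe")
  list(ke = fisher_enrich(query, ke_gene_sets(knowledge), universe, alpha),
       aop = fisher_enrich(query, aop_gene_sets(knowledge), universe, alpha),
       universe = universe)
}

#' AOP fingerprint across strata
#'
#' Long-format matrix of AOP enrichment across experimental strata (e.g.
#' time points): adjusted p-value and the number of contributing enriched
#' KEs belonging to the AOP in that stratum.
#'
#' @param enrichments named list (stratum -> list(ke = ..., aop = ...) as
#'   returned by \code{\link{enrich_ddgs}}).
#' @param knowledge an \code{AOPKnowledge}.
#' @param include_all keep AOPs never enriched in any stratum (default
#'   FALSE).
#' @return data.frame: aop, stratum, p_adj, n_contributing_kes, enriched.
#' @export
aop_fingerprint <- function(enrichments, knowledge, include_all = FALSE) {
  stopifnot(length(enrichments) >= 1, !is.null(names(enrichments)))
  aop_kes <- split(knowledge$ke_to_aop$ke_id, knowledge$ke_to_aop$aop_id)
  rows <- list()
  for (st in names(enrichments)) {
    ke_t <- enrichments[[st]]$ke
    aop_t <- enrichments[[st]]$aop
    enriched_kes <- ke_t$target[ke_t$enriched]
    for (i in seq_len(nrow(aop_t))) {
      aop <- aop_t$target[i]
      rows[[length(rows) + 1L]] <- data.frame(
        aop = aop, stratum = st, p_adj = aop_t$p_adj[i],
        n_contributing_kes = length(intersect(aop_kes[[aop]], enriched_kes)),
        enriched = aop_t$enriched[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!include_all) {
    keep_aops <- unique(out$aop[out$enriched])
    out <- out[out$aop %in% keep_aops, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# nodes on at least one shortest directed path from `from` to `to` in graph g
nodes_on_shortest_paths <- function(g, from, to) {
  if (!(from %in% igraph::V(g)$name) || !(to %in% igraph::V(g)$name))
    return(character(0))
  sp <- suppressWarnings(
    igraph::all_shortest_paths(g, from = from, to = to, mode = "out"))
  if (!length(sp$res)) return(character(0))
  unique(unlist(lapply(sp$res, function(p) igraph::as_ids(p))))
}

#' Assemble the KE-KE network around enriched key events
#'
#' The node set is the enriched KEs plus connector KEs: all KEs lying on at
#' least one shortest directed KER path from any MIE to an enriched KE, or
#' from an enriched KE to any AO, within the KER graph restricted to the
#' AOPs containing that enriched KE. Edges are the KER edges induced on the
#' node set; each node carries the mean BMD of its mapped dose-dependent
#' genes. An enriched KE belonging to no AOP stays as an isolated node with
#' a warning.
#'
#' @param gene_bmds named numeric vector: DDG id -> BMD.
#' @param knowledge an \code{AOPKnowledge}.
#' @param ke_enrich KE enrichment table from \code{\link{enrich_ddgs}}.
#' @return list of class \code{KENetwork}: nodes (ke_id, ke_type, enriched,
#'   connector, mean_bmd, n_ddgs), edges (upstream_ke, downstream_ke, aops).
#' @export
build_ke_network <- function(gene_bmds, knowledge, ke_enrich) {
  enriched <- ke_enrich$target[ke_enrich$enriched]
  cat_types <- setNames(knowledge$ke_catalog$ke_type, knowledge$ke_catalog$ke_id)
  aop_kes <- split(knowledge$ke_to_aop$ke_id, knowledge$ke_to_aop$aop_id)
  ke_aops <- split(knowledge$ke_to_aop$aop_id, knowledge$ke_to_aop$ke_id)
  connectors <- character(0)
  for (e in enriched) {
    aops <- ke_aops[[e]]
    if (is.null(aops) || !length(aops)) {
      warning("enriched KE '", e, "' belongs to no AOP; kept isolated")
      next
    }
    restricted <- unique(unlist(aop_kes[aops], use.names = FALSE))
    edges <- knowledge$ker_edges[
      knowledge$ker_edges$upstream_ke %in% restricted &
        knowledge$ker_edges$downstream_ke %in% restricted, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      edges, directed = TRUE,
      vertices = data.frame(name = restricted, stringsAsFactors = FALSE))
    mies <- restricted[cat_types[restricted] == "MIE"]
    aos <- restricted[cat_types[restricted] == "AO"]
    for (m in mies)
      connectors <- c(connectors, nodes_on_shortest_paths(g, m, e))
    for (a in aos)
      connectors <- c(connectors, nodes_on_shortest_paths(g, e, a))
  }
  connectors <- setdiff(unique(connectors), enriched)
  node_ids <- union(enriched, connectors)
  ke_sets <- ke_gene_sets(knowledge)
  mean_bmd <- vapply(node_ids, function(k) {
    mapped <- intersect(ke_sets[[k]], names(gene_bmds))
    if (!length(mapped)) NA_real_ else mean(gene_bmds[mapped])
  }, numeric(1))
  n_ddgs <- vapply(node_ids, function(k)
    length(intersect(ke_sets[[k]], names(gene_bmds))), integer(1))
  nodes <- data.frame(ke_id = node_ids,
                      ke_type = unname(cat_types[node_ids]),
                      enriched = node_ids %in% enriched,
                      connector = node_ids %in% connectors,
                      mean_bmd = unname(mean_bmd),
                      n_ddgs = unname(n_ddgs),
                      stringsAsFactors = FALSE)
  edges <- knowledge$ker_edges[
    knowledge$ker_edges$upstream_ke %in% node_ids &
      knowledge$ker_edges$downstream_ke %in% node_ids, , drop = FALSE]
  if (nrow(edges)) {
    edges$aops <- vapply(seq_len(nrow(edges)), function(i) {
      a <- intersect(ke_aops[[edges$upstream_ke[i]]],
                     ke_aops[[edges$downstream_ke[i]]])
      paste(sort(a), collapse = ",")
    }, character(1))
  } else edges$aops <- character(0)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "KENetwork")
}

#' Rank the genes mapped to one key event
#'
#' Six criteria per gene: transcription-factor status, PPI degree, harmonic
#' closeness and eigenvector centrality (computed on the PPI subgraph induced
#' by the mapped genes; all higher-better), mean absolute correlation to the
#' other mapped genes (higher better), and BMD (lower better). Each criterion
#' is converted to a dense rank (best = 1); the aggregate score is the
#' unweighted mean rank. Ties are broken by lower BMD, then gene id.
#'
#' @param mapped_bmds named numeric vector: mapped DDG id -> BMD.
#' @param ppi a \code{PPINetwork}. @param tf a \code{TFTable}.
#' @param corr optional \code{CorrelationResult} supplying gene-gene r.
#' @param top_n how many genes to return (default 5; all if fewer mapped).
#' @return data.frame ranked by aggregate score: gene, tf, degree, closeness,
#'   eigenvector, mean_abs_r, bmd, score, rank.
#' @export
prioritize_genes <- function(mapped_bmds, ppi, tf, corr = NULL, top_n = 5) {
  genes <- sort(names(mapped_bmds))
  stopifnot(length(genes) >= 1)
  bmds <- mapped_bmds[genes]
  cs <- ppi_centralities(genes, ppi)$nodes
  rownames(cs) <- cs$gene
  mean_abs_r <- setNames(rep(0, length(genes)), genes)
  if (!is.null(corr) && length(genes) > 1) {
    have <- intersect(genes, rownames(corr$r))
    if (length(have) > 1) {
      sub <- abs(corr$r[have, have, drop = FALSE])
      diag(sub) <- NA
      mean_abs_r[have] <- rowMeans(sub, na.rm = TRUE)
    }
  }
  dense_rank <- function(x, higher_better = TRUE) {
    v <- if (higher_better) -x else x
    match(v, sort(unique(v)))
  }
  crit <- cbind(
    tf = dense_rank(as.numeric(genes %in% tf$tfs)),
    degree = dense_rank(cs[genes, "degree"]),
    closeness = dense_rank(cs[genes, "closeness"]),
    eigenvector = dense_rank(cs[genes, "eigenvector"]),
    mean_abs_r = dense_rank(mean_abs_r),
    bmd = dense_rank(unname(bmds), higher_better = FALSE))
  score <- rowMeans(crit)
  ord <- order(score, unname(bmds), genes)
  out <- data.frame(gene = genes,
                    tf = genes %in% tf$tfs,
                    degree = cs[genes, "degree"],
                    closeness = cs[genes, "closeness"],
                    eigenvector = cs[genes, "eigenvector"],
                    mean_abs_r = unname(mean_abs_r),
                    bmd = unname(bmds),
                    score = unname(score),
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Detail view of one AOP
#'
#' For every KER edge of the AOP: the PPI bundle weight (number of unordered
#' interacting protein pairs between the dose-dependent genes mapped to the
#' upstream and downstream KE) and the TF edges (TF mapped to the upstream
#' KE regulating a target mapped to the downstream KE). Each member KE
#' carries the mean BMD of its mapped DDGs and its top prioritized genes.
#'
#' @param aop_id AOP identifier present in the knowledge.
#' @param ddg_bmds named numeric vector: DDG id -> BMD.
#' @param knowledge an \code{AOPKnowledge}. @param ppi a \code{PPINetwork}.
#' @param tf a \code{TFTable}. @param corr optional \code{CorrelationResult}.
#' @param top_n top genes per KE (default 5).
#' @return list of class \code{AOPDetail}: aop_id, ke_nodes (ke_id, ke_type,
#'   mean_bmd, n_ddgs, top_genes), ker_edges (with ppi_bundle weight),
#'   tf_edges (tf, target, upstream_ke, downstream_ke).
#' @export
aop_detail <- function(aop_id, ddg_bmds, knowledge, ppi, tf, corr = NULL,
                       top_n = 5) {
  member_kes <- knowledge$ke_to_aop$ke_id[knowledge$ke_to_aop$aop_id == aop_id]
  if (!length(member_kes)) stop("unknown AOP: ", aop_id)
  ke_sets <- ke_gene_sets(knowledge)
  cat_types <- setNames(knowledge$ke_catalog$ke_type, knowledge$ke_catalog$ke_id)
  mapped_ddg <- function(k) intersect(ke_sets[[k]], names(ddg_bmds))
  ke_nodes <- data.frame(ke_id = member_kes,
                         ke_type = unname(cat_types[member_kes]),
                         stringsAsFactors = FALSE)
  ke_nodes$n_ddgs <- vapply(member_kes, function(k) length(mapped_ddg(k)),
                            integer(1))
  ke_nodes$mean_bmd <- vapply(member_kes, function(k) {
    m <- mapped_ddg(k)
    if (!length(m)) NA_real_ else mean(ddg_bmds[m])
  }, numeric(1))
  ke_nodes$top_genes <- vapply(member_kes, function(k) {
    m <- mapped_ddg(k)
    if (!length(m)) return("")
    pr <- prioritize_genes(ddg_bmds[m], ppi, tf, corr, top_n = top_n)
    paste(pr$gene, collapse = ",")
  }, character(1))

  edges <- knowledge$ker_edges[
    knowledge$ker_edges$upstream_ke %in% member_kes &
      knowledge$ker_edges$downstream_ke %in% member_kes, , drop = FALSE]
  ppi_key <- paste(ppi$edges$gene_a, ppi$edges$gene_b, sep = "\r")
  tf_rows <- list()
  if (nrow(edges)) {
    edges$ppi_bundle <- vapply(seq_len(nrow(edges)), function(i) {
      gu <- mapped_ddg(edges$upstream_ke[i])
      gv <- mapped_ddg(edges$downstream_ke[i])
      if (!length(gu) || !length(gv)) return(0L)
      pairs <- expand.grid(a = gu, b = gv, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      key <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b), sep = "\r")
      length(unique(key[key %in% ppi_key]))
    }, integer(1))
    for (i in seq_len(nrow(edges))) {
      up_genes <- intersect(ke_sets[[edges$upstream_ke[i]]], tf$tfs)
      dn_genes <- ke_sets[[edges$downstream_ke[i]]]
      hits <- tf$pairs[tf$pairs$tf_gene_id %in% up_genes &
                         tf$pairs$target_gene_id %in% dn_genes, , drop = FALSE]
      if (nrow(hits))
        tf_rows[[length(tf_rows) + 1L]] <- data.frame(
          tf = hits$tf_gene_id, target = hits$target_gene_id,
          upstream_ke = edges$upstream_ke[i],
          downstream_ke = edges$downstream_ke[i], stringsAsFactors = FALSE)
    }
  } else edges$ppi_bundle <- integer(0)
  tf_edges <- if (length(tf_rows)) unique(do.call(rbind, tf_rows)) else
    data.frame(tf = character(), target = character(),
               upstream_ke = character(), downstream_ke = character())
  rownames(edges) <- rownames(tf_edges) <- NULL
  structure(list(aop_id = aop_id, ke_nodes = ke_nodes, ker_edges = edges,
                 tf_edges = tf_edges), class = "AOPDetail")
}

#' Roll enriched AOPs up to hazard classes
#'
#' Counts enriched AOPs per hazard class (AOPs without an annotation fall
#' under \code{"unclassified"}) and reports per-AOP transcriptomic points of
#' departure: by default the median BMD of the DDGs mapped to the AOP's
#' enriched KEs.
#'
#' @param aop_enrich AOP enrichment table from \code{\link{enrich_ddgs}}.
#' @param ke_enrich KE enrichment table (defines which KEs count as
#'   enriched for the tPOD).
#' @param knowledge an \code{AOPKnowledge}.
#' @param gene_bmds named numeric vector: DDG id -> BMD.
#' @param stat \code{"median"} (default) or \code{"mean"} for the AOP tPOD.
#' @return list of class \code{HazardRollup}: counts (hazard_class,
#'   n_enriched_aops), aop_tpods (aop, hazard_class, tpod, n_genes).
#' @export
hazard_rollup <- function(aop_enrich, ke_enrich, knowledge, gene_bmds,
                          stat = c("median", "mean")) {
  stat <- match.arg(stat)
  agg <- if (stat == "median") stats::median else mean
  enriched_aops <- aop_enrich$target[aop_enrich$enriched]
  enriched_kes <- ke_enrich$target[ke_enrich$enriched]
  haz <- setNames(knowledge$aop_hazard$hazard_class, knowledge$aop_hazard$aop_id)
  cls <- vapply(enriched_aops, function(a) {
    h <- haz[a]
    if (is.na(h)) "unclassified" else unname(h)
  }, character(1))
  counts <- if (length(cls)) {
    tb <- table(cls)
    data.frame(hazard_class = names(tb), n_enriched_aops = as.integer(tb),
               stringsAsFactors = FALSE)
  } else {
    data.frame(hazard_class = character(), n_enriched_aops = integer())
  }
  counts <- counts[order(-counts$n_enriched_aops, counts$hazard_class), ,
                   drop = FALSE]
  ke_sets <- ke_gene_sets(knowledge)
  aop_kes <- split(knowledge$ke_to_aop$ke_id, knowledge$ke_to_aop$aop_id)
  tpods <- do.call(rbind, lapply(enriched_aops, function(a) {
    kes <- intersect(aop_kes[[a]], enriched_kes)
    genes <- intersect(unique(unlist(ke_sets[kes], use.names = FALSE)),
                       names(gene_bmds))
    data.frame(aop = a,
               hazard_class = if (a %in% names(haz)) unname(haz[a])
                              else "unclassified",
               tpod = if (length(genes)) agg(gene_bmds[genes]) else NA_real_,
               n_genes = length(genes), stringsAsFactors = FALSE)
  }))
  if (is.null(tpods))
    tpods <- data.frame(aop = character(), hazard_class = character(),
                        tpod = numeric(), n_genes = integer())
  rownames(counts) <- rownames(tpods) <- NULL
  structure(list(counts = counts, aop_tpods = tpods), class = "HazardRollup")
}
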