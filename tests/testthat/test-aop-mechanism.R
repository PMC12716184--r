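test_that("hypergeometric enrichment matches the summation oracle", {
  universe <- paste0("g", 1:100)
  query <- paste0("g", 1:20)
  # target of size 10 overlapping the query in 6 genes
  target <- c(paste0("g", 1:6), paste0("g", 50:53))
  out <- fisher_enrich(query, list(t1 = target), universe)
  expect_equal(out$overlap, 6)
  expect_equal(out$p, hyper_tail_oracle(100, 10, 20, 6), tolerance = 1e-12)
  # target identical to the query is minimal among same-size targets
  out2 <- fisher_enrich(query, list(self = query,
                                    other = paste0("g", 30:49)), universe)
  expect_lt(out2$p[out2$target == "self"], out2$p[out2$target == "other"])
  expect_equal(out2$overlap[out2$target == "self"], 20)
  # zero overlap: P(X >= 0) = 1
  out3 <- fisher_enrich(query, list(z = "g99"), universe)
  expect_equal(out3$p, 1)
  expect_error(fisher_enrich(character(0), list(a = "g1"), universe), "query")
  expect_error(fisher_enrich("zz", list(a = "g1"), universe), "outside")
})

test_that("BH keeps order and the enriched set shrinks as alpha drops", {
  set.seed(6)
  universe <- paste0("g", 1:200)
  targets <- lapply(1:30, function(i) sample(universe, 20))
  names(targets) <- paste0("t", 1:30)
  query <- sample(universe, 40)
  res5 <- fisher_enrich(query, targets, universe, alpha = 0.05)
  res1 <- fisher_enrich(query, targets, universe, alpha = 0.01)
  expect_true(all(res5$p_adj >= res5$p - 1e-15))
  ord <- order(res5$p)
  expect_true(all(diff(res5$p_adj[ord]) >= -1e-15))
  expect_true(all(res1$target[res1$enriched] %in% res5$target[res5$enriched]))
})

test_that("KE network completes the chain around a single enriched KE", {
  kn <- toy_knowledge()
  net <- build_ke_network(c(g1 = 1, g2 = 3),
                          kn, fake_ke_enrich("K2", c("K1", "K2")))
  # chain M1 -> K1 -> K2 -> A1 with only K2 enriched: all others connect it
  expect_setequal(net$nodes$ke_id, c("M1", "K1", "K2", "A1"))
  expect_setequal(net$nodes$ke_id[net$nodes$connector], c("M1", "K1", "A1"))
  expect_equal(nrow(net$edges), 3)
  # node BMD annotation averages mapped DDGs
  expect_equal(net$nodes$mean_bmd[net$nodes$ke_id == "K1"], 2)  # mean(1, 3)
})

test_that("diamond topologies keep only shortest-path connectors", {
  kn <- AOPKnowledge(
    ke_catalog = data.frame(ke_id = c("M1", "K1", "K2", "A1"),
                            title = letters[1:4],
                            ke_type = c("MIE", "KE", "KE", "AO")),
    ker_edges = data.frame(upstream_ke = c("M1", "M1", "K1", "K2"),
                           downstream_ke = c("K1", "K2", "A1", "A1")),
    gene_to_ke = data.frame(gene_id = "g1", ke_id = "K1"),
    ke_to_aop = data.frame(ke_id = c("M1", "K1", "K2", "A1"), aop_id = "A"))
  net <- build_ke_network(c(g1 = 1), kn, fake_ke_enrich("K1", c("K1", "K2")))
  expect_setequal(net$nodes$ke_id, c("M1", "K1", "A1"))
  expect_false("K2" %in% net$nodes$ke_id)   # on no shortest path through K1
})

test_that("connector sets equal brute-force path enumeration on random DAGs", {
  set.seed(17)
  for (trial in 1:60) {
    n <- sample(5:12, 1)
    ids <- sprintf("N%02d", 1:n)            # topological order by construction
    edges <- do.call(rbind, lapply(1:(n - 1), function(i) {
      to <- which(runif(n - i) < 0.35) + i
      if (!length(to)) return(NULL)
      data.frame(upstream_ke = ids[i], downstream_ke = ids[to])
    }))
    if (is.null(edges) || nrow(edges) < 2) next
    types <- rep("KE", n)
    types[1] <- "MIE"; types[n] <- "AO"
    if (n > 6) types[2] <- "MIE"
    kn <- AOPKnowledge(
      ke_catalog = data.frame(ke_id = ids, title = ids, ke_type = types),
      ker_edges = edges,
      gene_to_ke = data.frame(gene_id = character(), ke_id = character()),
      ke_to_aop = data.frame(ke_id = ids, aop_id = "A"))
    enriched <- sample(ids[types == "KE"], 1)
    net <- build_ke_network(setNames(numeric(0), character(0)), kn,
                            fake_ke_enrich(enriched, ids))
    # oracle: nodes on any minimum-length path MIE -> e or e -> AO
    oracle <- character(0)
    for (m in ids[types == "MIE"])
      oracle <- c(oracle, shortest_path_nodes_oracle(edges, m, enriched))
    for (a in ids[types == "AO"])
      oracle <- c(oracle, shortest_path_nodes_oracle(edges, enriched, a))
    oracle <- setdiff(unique(oracle), enriched)
    expect_setequal(net$nodes$ke_id[net$nodes$connector], oracle)
  }
})

test_that("fingerprint cells carry adjusted p and contributing-KE counts", {
  kn <- toy_knowledge()
  # stratum with the planted situation: both K1-mapped genes dose dependent;
  # AOP1 holds only the signal KE, AOP2 the diluted background events
  universe <- c("g1", "g2", "g3", paste0("bg", 1:30))
  kn_big <- AOPKnowledge(
    ke_catalog = kn$ke_catalog, ker_edges = kn$ker_edges,
    gene_to_ke = rbind(kn$gene_to_ke[kn$gene_to_ke$gene_id != "g3", ],
                       data.frame(gene_id = c("g3", paste0("bg", 1:30)),
                                  ke_id = rep(c("M1", "K2", "A1"),
                                              length.out = 31))),
    ke_to_aop = data.frame(ke_id = c("K1", "M1", "K2", "A1"),
                           aop_id = c("AOP1", "AOP2", "AOP2", "AOP2")),
    aop_hazard = kn$aop_hazard)
  enr <- enrich_ddgs(c("g1", "g2"), kn_big, analyzed = universe)
  expect_true(enr$ke$enriched[enr$ke$target == "K1"])
  fp <- aop_fingerprint(list(`24h` = enr, `48h` = enr), kn_big)
  fp1 <- fp[fp$aop == "AOP1", ]
  expect_equal(nrow(fp1), 2)                 # enriched AOP x two strata
  expect_equal(fp1$p_adj[1], fp1$p_adj[2])   # identical inputs, identical cells
  expect_equal(fp1$n_contributing_kes, c(1, 1))   # K1 is its one enriched KE
  expect_false("AOP2" %in% fp$aop)           # never enriched, not reported
  fp_all <- aop_fingerprint(list(`24h` = enr), kn_big, include_all = TRUE)
  expect_true("AOP2" %in% fp_all$aop)
})

test_that("AOP detail counts PPI bundles, TF edges and per-KE BMDs", {
  kn <- AOPKnowledge(
    ke_catalog = data.frame(ke_id = c("KU", "KV"), title = c("up", "down"),
                            ke_type = c("KE", "KE")),
    ker_edges = data.frame(upstream_ke = "KU", downstream_ke = "KV"),
    gene_to_ke = data.frame(gene_id = c("a", "b", "c"),
                            ke_id = c("KU", "KU", "KV")),
    ke_to_aop = data.frame(ke_id = c("KU", "KV"), aop_id = "X"))
  ppi <- PPINetwork(data.frame(x = "a", y = "c"))
  tf <- TFTable(data.frame(tf = "b", tgt = "c"))
  det <- aop_detail("X", c(a = 1, b = 3, c = 2), kn, ppi, tf)
  expect_equal(det$ker_edges$ppi_bundle, 1)          # only a - c crosses
  expect_equal(nrow(det$tf_edges), 1)
  expect_equal(det$tf_edges$tf, "b")
  expect_equal(det$tf_edges$target, "c")
  expect_equal(det$ke_nodes$mean_bmd[det$ke_nodes$ke_id == "KU"], 2) # mean(1,3)
  # no mapped DDGs: empty bundles, NA BMDs
  det0 <- aop_detail("X", c(zz = 1), kn, ppi, tf)
  expect_true(all(is.na(det0$ke_nodes$mean_bmd)))
  expect_equal(det0$ker_edges$ppi_bundle, 0)
})

test_that("gene prioritization follows mean dense rank with BMD tie-break", {
  ppi0 <- PPINetwork(data.frame(a = character(), b = character()))
  tf0 <- TFTable(data.frame(a = character(), b = character()))
  # singleton is rank 1
  expect_equal(prioritize_genes(c(solo = 4), ppi0, tf0)$gene, "solo")
  # identical on five criteria: lower BMD wins
  two <- prioritize_genes(c(g1 = 1, g2 = 2), ppi0, tf0)
  expect_equal(two$gene, c("g1", "g2"))
  # random 10-gene fixture vs independent mean-of-ranks oracle
  set.seed(23)
  genes <- paste0("g", 1:10)
  bmds <- setNames(runif(10, 1, 10), genes)
  pairs <- t(combn(genes, 2))
  ppi <- PPINetwork(as.data.frame(pairs[runif(nrow(pairs)) < 0.3, ]))
  tf <- TFTable(data.frame(tf = c("g2", "g7"), tgt = c("g1", "g3")))
  grid <- structure(list(
    doses = seq(0, 20, length.out = 100),
    predicted = matrix(rnorm(1000), 10, 100, dimnames = list(genes, NULL)),
    condition = "trt", timepoint = "24h"), class = "CurveGrid")
  corr <- correlate_pairs(grid)
  out <- prioritize_genes(bmds, ppi, tf, corr, top_n = 10)
  cs <- omicspod:::ppi_centralities(sort(genes), ppi)$nodes
  rownames(cs) <- cs$gene
  dr <- function(x, hb = TRUE) {
    v <- if (hb) -x else x
    match(v, sort(unique(v)))
  }
  g_sorted <- sort(genes)
  mabs <- sapply(g_sorted, function(g)
    mean(abs(corr$r[g, setdiff(g_sorted, g)])))
  score_oracle <- rowMeans(cbind(
    dr(as.numeric(g_sorted %in% tf$tfs)), dr(cs[g_sorted, "degree"]),
    dr(cs[g_sorted, "closeness"]), dr(cs[g_sorted, "eigenvector"]),
    dr(unname(mabs)), dr(unname(bmds[g_sorted]), hb = FALSE)))
  ord_oracle <- g_sorted[order(score_oracle, bmds[g_sorted], g_sorted)]
  expect_equal(out$gene, ord_oracle)
  # invariance to input order
  out_perm <- prioritize_genes(bmds[sample(genes)], ppi, tf, corr, top_n = 10)
  expect_equal(out_perm$gene, out$gene)
  # top_n larger than the mapped set returns all, unpadded
  expect_equal(nrow(prioritize_genes(bmds[1:3], ppi0, tf0, top_n = 5)), 3)
})

test_that("hazard rollup counts classes and computes AOP-level tPODs", {
  kn <- AOPKnowledge(
    ke_catalog = data.frame(ke_id = c("K1", "K2", "K3"),
                            title = letters[1:3], ke_type = "KE"),
    ker_edges = data.frame(upstream_ke = character(),
                           downstream_ke = character()),
    gene_to_ke = data.frame(gene_id = c("a", "b", "c"),
                            ke_id = c("K1", "K1", "K1")),
    ke_to_aop = data.frame(ke_id = c("K1", "K2", "K3"),
                           aop_id = c("A1", "A2", "A3")),
    aop_hazard = data.frame(aop_id = c("A1", "A2"),
                            hazard_class = c("carcinogenicity",
                                             "carcinogenicity")))
  aop_enr <- data.frame(target = c("A1", "A2", "A3"),
                        enriched = c(TRUE, TRUE, TRUE))
  ke_enr <- data.frame(target = c("K1", "K2", "K3"),
                       enriched = c(TRUE, FALSE, FALSE))
  roll <- hazard_rollup(aop_enr, ke_enr, kn, c(a = 1, b = 2, c = 9))
  expect_equal(roll$counts$n_enriched_aops[
    roll$counts$hazard_class == "carcinogenicity"], 2)
  expect_equal(roll$counts$n_enriched_aops[
    roll$counts$hazard_class == "unclassified"], 1)   # A3 unannotated
  expect_equal(roll$aop_tpods$tpod[roll$aop_tpods$aop == "A1"], 2)  # median
})
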