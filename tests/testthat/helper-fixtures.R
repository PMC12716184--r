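# Shared in-code fixtures and independent oracles for the suite.

default_doses <- function() rep(c(0, 1, 2.5, 5, 10, 20), each = 3)

# small complete dataset: n_feat features, one stratum, optional NA cells
make_dataset <- function(n_feat = 4, doses = c(0, 1, 5, 10), reps = 3,
                         seed = 1, layer = "expression") {
  set.seed(seed)
  d <- rep(doses, each = reps)
  samples <- sprintf("s%02d", seq_along(d))
  vals <- matrix(rnorm(n_feat * length(d), 5, 1), n_feat,
                 dimnames = list(sprintf("f%02d", seq_len(n_feat)), samples))
  meta <- data.frame(sample = samples, dose = d, condition = "trt",
                     timepoint = "24h", stringsAsFactors = FALSE)
  list(values = vals, meta = meta,
       ds = DoseResponseDataset(vals, meta, layer_name = layer))
}

# dataset built from explicit per-feature curves + noise
make_curve_dataset <- function(curves, doses = c(0, 1, 2.5, 5, 10, 20),
                               reps = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  d <- rep(doses, each = reps)
  samples <- sprintf("s%02d", seq_along(d))
  vals <- t(vapply(curves, function(f) f(d) + rnorm(length(d), 0, noise_sd),
                   numeric(length(d))))
  rownames(vals) <- names(curves)
  colnames(vals) <- samples
  meta <- data.frame(sample = samples, dose = d, condition = "trt",
                     timepoint = "24h", stringsAsFactors = FALSE)
  DoseResponseDataset(vals, meta)
}

# toy AOP knowledge: chain M1 -> K1 -> K2 -> A1 in one AOP
toy_knowledge <- function() {
  AOPKnowledge(
    ke_catalog = data.frame(
      ke_id = c("M1", "K1", "K2", "A1"),
      title = c("mie", "ke one", "ke two", "ao"),
      ke_type = c("MIE", "KE", "KE", "AO")),
    ker_edges = data.frame(upstream_ke = c("M1", "K1", "K2"),
                           downstream_ke = c("K1", "K2", "A1")),
    gene_to_ke = data.frame(gene_id = c("g1", "g2", "g3"),
                            ke_id = c("K1", "K1", "K2")),
    ke_to_aop = data.frame(ke_id = c("M1", "K1", "K2", "A1"),
                           aop_id = "AOP1"),
    aop_hazard = data.frame(aop_id = "AOP1",
                            hazard_class = "carcinogenicity"))
}

# enrichment table stub accepted by build_ke_network
fake_ke_enrich <- function(enriched_kes, all_kes = enriched_kes) {
  data.frame(target = all_kes, enriched = all_kes %in% enriched_kes,
             stringsAsFactors = FALSE)
}

# --- independent oracles -------------------------------------------------

# hypergeometric upper tail by explicit binomial-coefficient summation
hyper_tail_oracle <- function(N, m, q, ov) {
  if (m == 0) return(1)
  ks <- ov:min(m, q)
  ks <- ks[q - ks <= N - m & ks >= 0]
  if (!length(ks)) return(0)
  sum(choose(m, ks) * choose(N - m, q - ks)) / choose(N, q)
}

# all simple directed paths from `from` to `to` in an adjacency list
all_paths <- function(adj, from, to) {
  out <- list()
  walk <- function(node, path) {
    if (node == to) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (nxt in adj[[node]])
      if (!(nxt %in% path)) walk(nxt, c(path, nxt))
  }
  walk(from, from)
  out
}

# nodes on minimum-length paths from -> to (brute force)
shortest_path_nodes_oracle <- function(edges_df, from, to) {
  nodes <- unique(c(edges_df[[1]], edges_df[[2]], from, to))
  adj <- setNames(lapply(nodes, function(n)
    edges_df[[2]][edges_df[[1]] == n]), nodes)
  paths <- all_paths(adj, from, to)
  if (!length(paths)) return(character(0))
  lens <- lengths(paths)
  unique(unlist(paths[lens == min(lens)]))
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Jonckheere-Terpstra statistic recomputed independently
jt_stat_oracle <- function(x, g) {
  u <- 0
  gs <- sort(unique(g))
  for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
    for (a in x[g == gs[i]]) for (b in x[g == gs[j]])
      u <- u + (a < b) + 0.5 * (a == b)
  }
  u
}

# all permutations of a vector (for small n)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
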