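# curve grid built directly from known mean functions (no fitting involved)
make_grid <- function(curves, d_max = 20, n_points = 200) {
  doses <- seq(0, d_max, length.out = n_points)
  pred <- t(vapply(curves, function(f) f(doses), numeric(n_points)))
  rownames(pred) <- names(curves)
  structure(list(doses = doses, predicted = pred, condition = "trt",
                 timepoint = "24h"), class = "CurveGrid")
}

test_that("predict_grid evaluates selected curves on the exact dose grid", {
  lin_up <- function(d) 1 + 1 * d
  ds <- make_curve_dataset(list(gA = lin_up, gB = function(d) 8 - 0.3 * d),
                           doses = c(0, 1, 2.5, 5, 10), noise_sd = 0)
  res <- run_bmd(ds, "trt", "24h", prefilter = NULL, seed = 1)
  grid <- predict_grid(res, n_points = 1000)
  expect_equal(ncol(grid$predicted), 1000)
  expect_equal(diff(grid$doses)[1], 10 / 999, tolerance = 1e-12)
  expect_equal(grid$doses[1], 0)
  expect_equal(grid$doses[1000], 10)
  expect_equal(unname(grid$predicted["gA", c(1, 1000)]), c(1, 11),
               tolerance = 1e-6)
})

test_that("correlation obeys affine invariance and matches the dot-product oracle", {
  a_curve <- function(d) 2 + 0.5 * d + 0.02 * d^2
  grid <- make_grid(list(
    A = a_curve,
    B = function(d) 2 * a_curve(d) + 3,       # affine image of A
    C = function(d) -a_curve(d),              # negated
    D = function(d) 5 / (1 + exp(-(d - 8)))))
  corr <- correlate_pairs(grid)
  expect_equal(corr$r["A", "B"], 1, tolerance = 1e-12)
  expect_equal(corr$r["A", "C"], -1, tolerance = 1e-12)
  expect_true(isSymmetric(corr$r))
  expect_equal(unname(diag(corr$r)), rep(1, 4))
  # independent covariance-formula recomputation for the (A, D) pair
  x <- grid$predicted["A", ]; y <- grid$predicted["D", ]
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(corr$r["A", "D"], r_oracle, tolerance = 1e-12)
  # p-value convention: two-tailed t with N - 2 df at the grid size
  N <- corr$n_grid
  t_stat <- abs(r_oracle) * sqrt((N - 2) / (1 - r_oracle^2))
  expect_equal(corr$p["A", "D"], 2 * pt(t_stat, N - 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # constant curve: r recorded as 0 and flagged
  grid2 <- make_grid(list(A = a_curve, K = function(d) rep(4, length(d))))
  corr2 <- correlate_pairs(grid2)
  expect_equal(corr2$r["A", "K"], 0)
  expect_equal(corr2$constant_genes, "K")
})

test_that("antipodal curve groups split into two perfect clusters", {
  a_curve <- function(d) 1 + d
  curves <- c(
    setNames(lapply(1:5, function(i) function(d) i * a_curve(d)),
             paste0("up", 1:5)),
    setNames(lapply(1:5, function(i) function(d) -i * a_curve(d) + i),
             paste0("dn", 1:5)))
  corr <- correlate_pairs(make_grid(curves))
  cl <- cluster_genes(corr)
  expect_equal(attr(cl, "k"), 2L)
  expect_length(unique(cl[paste0("up", 1:5)]), 1)
  expect_length(unique(cl[paste0("dn", 1:5)]), 1)
  expect_false(cl[["up1"]] == cl[["dn1"]])
  # forcing k = 1 collapses everything
  cl1 <- cluster_genes(corr, k = 1)
  expect_equal(attr(cl1, "k"), 1L)
  expect_length(unique(cl1), 1)
  # clustering is invariant to gene order
  perm <- sample(rownames(corr$r))
  corr_p <- correlate_pairs(make_grid(curves[perm]))
  cl_p <- cluster_genes(corr_p)
  expect_equal(adjusted_rand_index(cl[perm], cl_p[perm]), 1)
})

test_that("PPI overlay centralities match dense linear-algebra oracles", {
  # path graph x - y - z: middle node tops every centrality
  grid <- make_grid(list(x = function(d) d, y = function(d) 2 * d,
                         z = function(d) 3 * d))
  corr <- correlate_pairs(grid)
  ppi <- PPINetwork(data.frame(a = c("x", "y"), b = c("y", "z")))
  tf <- TFTable(data.frame(tf = "x", tgt = "z"))
  out <- overlay_ppi(corr, ppi, tf)
  nd <- out$nodes
  expect_equal(nd$gene[which.max(nd$degree)], "y")
  expect_equal(nd$gene[which.max(nd$closeness)], "y")
  expect_equal(nd$gene[which.max(nd$eigenvector)], "y")
  expect_true(nd$tf[nd$gene == "x"])
  expect_true(out$ppi_edge["x", "y"])
  expect_false(out$ppi_edge["x", "z"])      # no inferred edges
  # empty PPI: all zero, all isolated
  out0 <- overlay_ppi(corr, PPINetwork(data.frame(a = character(),
                                                  b = character())), tf)
  expect_true(all(out0$nodes$degree == 0))
  expect_true(all(out0$nodes$isolated))
  # random 12-node graph vs brute force
  set.seed(31)
  genes <- sprintf("n%02d", 1:12)
  grid_r <- make_grid(setNames(lapply(1:12, function(i) {
    function(d) i + d
  }), genes))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < 0.25
  ppi_r <- PPINetwork(as.data.frame(pairs[keep, , drop = FALSE]))
  out_r <- overlay_ppi(correlate_pairs(grid_r), ppi_r,
                       TFTable(data.frame(a = character(), b = character())))
  A <- matrix(0, 12, 12, dimnames = list(genes, genes))
  A[cbind(ppi_r$edges$gene_a, ppi_r$edges$gene_b)] <- 1
  A <- A + t(A)
  expect_equal(out_r$nodes$degree, unname(rowSums(A)))
  # Floyd-Warshall distances -> harmonic closeness
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in 1:12) for (i in 1:12) for (j in 1:12)
    D[i, j] <- min(D[i, j], D[i, k] + D[k, j])
  harm <- rowSums(ifelse(is.finite(1 / D) & D > 0, 1 / D, 0)) / 11
  harm[rowSums(A) == 0] <- 0
  expect_equal(out_r$nodes$closeness, unname(harm), tolerance = 1e-10)
  # eigen() oracle per component, globally max-normalized
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(A, mode = "undirected"))$membership
  ev <- setNames(numeric(12), genes)
  for (cc in unique(comp[rowSums(A) > 0])) {
    mem <- names(comp)[comp == cc & rowSums(A) > 0]
    if (length(mem) < 2) next
    e1 <- eigen(A[mem, mem])$vectors[, 1]
    ev[mem] <- abs(e1)
  }
  if (max(ev) > 0) ev <- ev / max(ev)
  expect_equal(out_r$nodes$eigenvector, unname(ev), tolerance = 1e-6)
})

test_that("cross-layer correlation classifies by the tau threshold", {
  a_curve <- function(d) 1 + d
  ga <- make_grid(list(g1 = a_curve, g2 = a_curve, g3 = a_curve))
  gb <- make_grid(list(g1 = function(d) 10 - a_curve(d),     # mirrored
                       g2 = a_curve,                          # identical
                       g3 = function(d) {                     # weak relation
                         set.seed(4); a_curve(d) * 0.05 + rnorm(length(d))
                       }))
  out <- cross_layer_correlation(ga, gb, tau = 0.5)
  expect_equal(out$class[out$gene == "g1"], "inverse")
  expect_equal(out$r[out$gene == "g1"], -1, tolerance = 1e-12)
  expect_equal(out$class[out$gene == "g2"], "concordant")
  expect_equal(out$class[out$gene == "g3"], "unclassified")
  # mismatched grids must error with re-gridding advice
  gshort <- make_grid(list(g1 = a_curve), d_max = 10)
  expect_error(cross_layer_correlation(ga, gshort), "re-grid")
})
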