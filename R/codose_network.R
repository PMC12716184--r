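## Co-dose-dependency analysis: model-predicted response curves on a uniform
## dose grid, gene-pair Pearson correlation with the grid-size-N t test,
## hierarchical clustering of genes by correlation distance, PPI/TF overlay
## with node centralities, and cross-layer (expression vs methylation) curve
## correlation.

#' Predict fitted dose-response curves on a uniform dose grid
#'
#' Evaluates each dose-dependent gene's selected model (AIC mode) or
#' Akaike-weighted model mixture (average mode) on \code{n_points} uniformly
#' spaced doses from 0 to the maximum tested dose, inclusive.
#'
#' @param bmd_result a \code{BMDResult} from \code{\link{run_bmd}}.
#' @param n_points grid size (default 1000).
#' @param ddg_only restrict to dose-dependent genes (default TRUE).
#' @return list of class \code{CurveGrid}: doses (length n_points),
#'   predicted (gene x n_points matrix), condition, timepoint.
#' @export
predict_grid <- function(bmd_result, n_points = 1000, ddg_only = TRUE) {
  stopifnot(inherits(bmd_result, "BMDResult"), n_points >= 2)
  doses <- seq(0, bmd_result$d_max, length.out = n_points)
  tab <- bmd_result$table
  genes <- tab$feature[if (ddg_only) tab$ddg else tab$status == "ok"]
  skipped <- 0L
  rows <- lapply(genes, function(g) {
    st <- bmd_result$fits[[g]]
    sel <- st$selection
    if (!length(sel$models)) { skipped <<- skipped + 1L; return(NULL) }
    curves <- vapply(seq_along(sel$models), function(i) {
      ft <- st$per_model[[sel$models[i]]]$fit
      ft$fun(doses, ft$theta)
    }, numeric(n_points))
    as.vector(curves %*% sel$weights)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (skipped > 0) message(skipped, " gene(s) without an ok fit excluded")
  pred <- do.call(rbind, rows[keep])
  rownames(pred) <- genes[keep]
  structure(list(doses = doses, predicted = pred,
                 condition = bmd_result$condition,
                 timepoint = bmd_result$timepoint),
            class = "CurveGrid")
}

#' Pairwise Pearson correlation of predicted curves
#'
#' Pearson r between every pair of predicted gene curves, with a two-tailed
#' t-test p-value using the grid size N as the sample size (N - 2 degrees of
#' freedom). Note the statistical caveat: grid points are model predictions,
#' not independent observations, so these p-values replicate a reporting
#' convention rather than a calibrated test. Constant curves have undefined
#' correlation; their entries are set to 0 and the genes flagged.
#'
#' @param grid a \code{CurveGrid}.
#' @param genes optional subset of gene ids.
#' @return list of class \code{CorrelationResult}: r, p (symmetric matrices),
#'   n_grid, constant_genes.
#' @export
correlate_pairs <- function(grid, genes = NULL) {
  stopifnot(inherits(grid, "CurveGrid"))
  pred <- grid$predicted
  if (!is.null(genes)) pred <- pred[intersect(genes, rownames(pred)), ,
                                    drop = FALSE]
  if (nrow(pred) < 2) stop("need >= 2 genes on a common grid")
  sds <- apply(pred, 1, stats::sd)
  constant <- rownames(pred)[sds == 0]
  r <- suppressWarnings(stats::cor(t(pred)))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  N <- ncol(pred)
  tt <- abs(r) * sqrt((N - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = N - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  structure(list(r = r, p = p, n_grid = N, constant_genes = constant),
            class = "CorrelationResult")
}

#' Cluster genes by correlation distance
#'
#' Hierarchical agglomerative clustering with distance 1 - r and average
#' linkage. When \code{k} is not given it is chosen to maximize the mean
#' silhouette width over k in 2..10 (bounded by the number of genes); with
#' all-identical curves a single cluster is returned and the silhouette step
#' skipped.
#'
#' @param corr a \code{CorrelationResult} (or a correlation matrix).
#' @param k optional fixed number of clusters.
#' @return named integer vector of cluster ids (attribute \code{k}).
#' @export
cluster_genes <- function(corr, k = NULL) {
  r <- if (inherits(corr, "CorrelationResult")) corr$r else corr
  n <- nrow(r)
  stopifnot(n >= 3 || !is.null(k))
  dist_m <- stats::as.dist(1 - r)
  if (!is.null(k) && k == 1) {
    out <- setNames(rep(1L, n), rownames(r))
    attr(out, "k") <- 1L
    return(out)
  }
  if (max(dist_m) < 1e-12) {     # all curves identical
    out <- setNames(rep(1L, n), rownames(r))
    attr(out, "k") <- 1L
    return(out)
  }
  hc <- stats::hclust(dist_m, method = "average")
  if (is.null(k)) {
    ks <- 2:min(10, n - 1)
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, kk)
      if (length(unique(cl)) < 2) return(-Inf)
      mean(cluster::silhouette(cl, dist_m)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  out <- stats::cutree(hc, k)
  attr(out, "k") <- as.integer(k)
  out
}

# leading eigenvector of a dense adjacency matrix by power iteration; the
# +I shift makes the dominant eigenvalue unique on bipartite graphs without
# changing the eigenvectors
power_iteration_eigen <- function(A, tol = 1e-10, max_iter = 10000) {
  n <- nrow(A)
  if (n == 1) return(1)
  A <- A + diag(n)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.vector(A %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(rep(0, n))
    w <- w / nw
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  abs(v)
}

# degree, harmonic closeness and per-component eigenvector centrality on the
# PPI subgraph induced by `genes`; closeness normalized by (length(genes)-1),
# eigenvector max-normalized globally
ppi_centralities <- function(genes, ppi) {
  n <- length(genes)
  edge_flag <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  e <- ppi$edges[ppi$edges$gene_a %in% genes & ppi$edges$gene_b %in% genes, ,
                 drop = FALSE]
  if (nrow(e)) {
    edge_flag[cbind(e$gene_a, e$gene_b)] <- TRUE
    edge_flag[cbind(e$gene_b, e$gene_a)] <- TRUE
  }
  degree <- rowSums(edge_flag)
  closeness <- eigen_c <- setNames(rep(0, n), genes)
  present <- genes[degree > 0]
  if (length(present) >= 2) {
    g <- igraph::graph_from_adjacency_matrix(
      edge_flag[present, present, drop = FALSE] * 1, mode = "undirected")
    dm <- igraph::distances(g)
    inv <- 1 / dm
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    closeness[present] <- rowSums(inv) / max(n - 1, 1)
    comp <- igraph::components(g)$membership
    ev <- setNames(rep(0, length(present)), present)
    for (cc in unique(comp)) {
      mem <- names(comp)[comp == cc]
      sub <- edge_flag[mem, mem, drop = FALSE] * 1
      ev[mem] <- power_iteration_eigen(sub)
    }
    if (max(ev) > 0) ev <- ev / max(ev)
    eigen_c[present] <- ev
  }
  list(edge_flag = edge_flag,
       nodes = data.frame(gene = genes, degree = unname(degree),
                          closeness = unname(closeness),
                          eigenvector = unname(eigen_c),
                          isolated = unname(degree == 0),
                          stringsAsFactors = FALSE))
}

#' Overlay PPI structure and TF status on a correlation result
#'
#' Marks gene pairs connected in the PPI network, flags transcription
#' factors, and computes degree, harmonic closeness and eigenvector
#' centrality on the PPI subgraph induced by the analyzed genes. Harmonic
#' closeness is the sum of reciprocal shortest-path distances (unreachable
#' pairs contribute 0), normalized by n - 1. Eigenvector centrality is
#' computed per connected component by power iteration (tolerance 1e-10) and
#' max-normalized globally. Genes absent from the PPI get all-zero
#' centralities and an isolated flag.
#'
#' @param corr a \code{CorrelationResult}.
#' @param ppi a \code{PPINetwork}. @param tf a \code{TFTable}.
#' @param clusters optional cluster assignment from
#'   \code{\link{cluster_genes}}.
#' @return the \code{CorrelationResult} completed with \code{ppi_edge}
#'   (logical matrix) and \code{nodes} (data.frame gene, tf, degree,
#'   closeness, eigenvector, isolated, cluster).
#' @export
overlay_ppi <- function(corr, ppi, tf, clusters = NULL) {
  stopifnot(inherits(corr, "CorrelationResult"), inherits(ppi, "PPINetwork"),
            inherits(tf, "TFTable"))
  genes <- rownames(corr$r)
  cs <- ppi_centralities(genes, ppi)
  nodes <- cs$nodes
  nodes$tf <- nodes$gene %in% tf$tfs
  nodes$cluster <- if (!is.null(clusters)) unname(clusters[genes]) else NA_integer_
  nodes <- nodes[c("gene", "tf", "degree", "closeness", "eigenvector",
                   "isolated", "cluster")]
  corr$ppi_edge <- cs$edge_flag
  corr$nodes <- nodes
  corr
}

#' Long-format table of gene-pair correlations
#' @param corr a \code{CorrelationResult} (after \code{\link{overlay_ppi}}
#'   for the ppi_edge column).
#' @param r_min optional absolute-correlation threshold (default 0: all
#'   pairs). Pairs are listed once (i < j).
#' @return data.frame gene_i, gene_j, r, p, ppi_edge.
#' @export
correlation_table <- function(corr, r_min = 0) {
  genes <- rownames(corr$r)
  idx <- which(upper.tri(corr$r), arr.ind = TRUE)
  out <- data.frame(gene_i = genes[idx[, 1]], gene_j = genes[idx[, 2]],
                    r = corr$r[idx], p = corr$p[idx],
                    ppi_edge = if (!is.null(corr$ppi_edge)) corr$ppi_edge[idx]
                               else NA,
                    stringsAsFactors = FALSE)
  out[abs(out$r) >= r_min, , drop = FALSE]
}

#' Correlate predicted curves across two omics layers gene-by-gene
#'
#' For each gene present in both layers' curve grids, the Pearson
#' correlation between the two predicted curves on the common dose grid;
#' genes are classed \code{inverse} when r <= -tau, \code{concordant} when
#' r >= tau, otherwise \code{unclassified}.
#'
#' @param grid_a,grid_b \code{CurveGrid}s from the two layers; they must
#'   share the dose range and grid size (re-grid otherwise).
#' @param tau classification threshold (default 0.5).
#' @return data.frame: gene, r, class.
#' @export
cross_layer_correlation <- function(grid_a, grid_b, tau = 0.5) {
  stopifnot(inherits(grid_a, "CurveGrid"), inherits(grid_b, "CurveGrid"))
  if (length(grid_a$doses) != length(grid_b$doses) ||
      max(abs(range(grid_a$doses) - range(grid_b$doses))) > 1e-9)
    stop("dose grids differ between layers; re-grid with predict_grid ",
         "using a common n_points and dose range")
  common <- intersect(rownames(grid_a$predicted), rownames(grid_b$predicted))
  r <- vapply(common, function(g) {
    a <- grid_a$predicted[g, ]; b <- grid_b$predicted[g, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }, numeric(1))
  cls <- ifelse(r <= -tau, "inverse",
                ifelse(r >= tau, "concordant", "unclassified"))
  data.frame(gene = common, r = unname(r), class = unname(cls),
             stringsAsFactors = FALSE, row.names = NULL)
}
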