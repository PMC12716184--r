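## Aggregation of gene-level BMDs: ECDFs and log-scale kernel density
## summaries (modes/antimodes), transcriptome-wide points of departure by
## five methods, cross-layer sensitivity classification and temporal
## dose-dependency patterns.

#' Summarize the distribution of gene-level BMDs
#'
#' Builds the empirical cumulative distribution over BMDs and a Gaussian
#' kernel density estimate on log10(BMD) (Silverman's rule-of-thumb
#' bandwidth, 512-point grid). Modes are local maxima of the density;
#' antimodes are the local minima between consecutive modes. Both are
#' reported back on the dose scale.
#'
#' @param bmds numeric vector of gene BMDs (positive).
#' @return list of class \code{BMDDistribution}: bmds, ecdf (function),
#'   kde (grid data.frame log10_dose/density), modes, antimodes (dose
#'   scale), n, degenerate flag.
#' @export
bmd_distribution <- function(bmds) {
  bmds <- bmds[!is.na(bmds)]
  stopifnot(all(bmds > 0))
  n <- length(bmds)
  if (n < 1) stop("no BMDs supplied")
  degenerate <- length(unique(bmds)) < 2
  ec <- stats::ecdf(bmds)
  if (degenerate) {
    return(structure(list(bmds = bmds, ecdf = ec, kde = NULL,
                          modes = unique(bmds), antimodes = numeric(0),
                          n = n, degenerate = TRUE),
                     class = "BMDDistribution"))
  }
  kd <- stats::density(log10(bmds), bw = "nrd0", n = 512)
  y <- kd$y
  m <- length(y)
  is_max <- c(FALSE, y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m],
              FALSE)
  modes_idx <- which(is_max)
  antimodes_idx <- integer(0)
  if (length(modes_idx) >= 2) {
    for (i in seq_len(length(modes_idx) - 1)) {
      seg <- (modes_idx[i]):(modes_idx[i + 1])
      antimodes_idx <- c(antimodes_idx, seg[which.min(y[seg])])
    }
  }
  structure(list(bmds = bmds, ecdf = ec,
                 kde = data.frame(log10_dose = kd$x, density = kd$y),
                 modes = 10^kd$x[modes_idx],
                 antimodes = 10^kd$x[antimodes_idx],
                 n = n, degenerate = FALSE),
            class = "BMDDistribution")
}

# discrete curvature of the min-max normalized accumulation curve; returns
# the index of maximum curvature
accumulation_max_curvature <- function(bmds_sorted) {
  m <- length(bmds_sorted)
  stopifnot(m >= 3)
  rngx <- diff(range(bmds_sorted))
  x <- if (rngx > 0) (bmds_sorted - min(bmds_sorted)) / rngx
       else rep(0, m)
  y <- (seq_len(m) - 1) / (m - 1)
  ctr <- function(v) (v[3:m] - v[1:(m - 2)]) / 2
  ctr2 <- function(v) v[3:m] - 2 * v[2:(m - 1)] + v[1:(m - 2)]
  xp <- ctr(x); yp <- ctr(y); xpp <- ctr2(x); ypp <- ctr2(y)
  denom <- (xp^2 + yp^2)^1.5
  kappa <- ifelse(denom > 0, abs(xp * ypp - yp * xpp) / denom, 0)
  which.max(kappa) + 1L           # interior index in the original vector
}

#' Transcriptome-wide point of departure
#'
#' Summarizes the gene-level BMDs of one stratum into a single dose by one
#' of five methods: \code{percentile} (q-th percentile, linear interpolation,
#' default q = 5), \code{mean_lowest_n} (mean of the n smallest BMDs, default
#' n = 20), \code{first_mode} (dose at the first KDE mode),
#' \code{accumulation_curvature} (restrict BMDs below the first antimode of
#' the log-KDE, then take the BMD at the point of maximum discrete curvature
#' of the min-max-normalized accumulation curve; when no antimode exists —
#' e.g. a unimodal distribution — all BMDs are used and the result is
#' flagged), or \code{lowest_geneset} (minimum over enriched gene sets of the
#' median member BMD; requires \code{gene_bmds} names, a
#' \code{GeneSetCollection} and its enrichment table).
#'
#' @param gene_bmds named numeric vector of BMDs (names = gene ids).
#' @param method one of the five method names.
#' @param q percentile (percentile method).
#' @param n number of lowest BMDs (mean_lowest_n method).
#' @param gsc,enrichment collection and \code{fisher_enrich} result for
#'   lowest_geneset.
#' @param min_genes minimum number of BMDs required for the distributional
#'   methods (default 10).
#' @return list of class \code{PodResult}: method, twpod, n_genes,
#'   diagnostics (modes, antimodes, fallback flag).
#' @export
twpod <- function(gene_bmds,
                  method = c("percentile", "mean_lowest_n", "first_mode",
                             "accumulation_curvature", "lowest_geneset"),
                  q = 5, n = 20, gsc = NULL, enrichment = NULL,
                  min_genes = 10) {
  method <- match.arg(method)
  bmds <- gene_bmds[!is.na(gene_bmds)]
  diagnostics <- list()
  if (method %in% c("percentile", "first_mode", "accumulation_curvature") &&
      length(bmds) < min_genes)
    stop("need >= ", min_genes, " BMDs for method '", method, "'")
  value <- switch(method,
    percentile = stats::quantile(bmds, q / 100, names = FALSE, type = 7),
    mean_lowest_n = {
      if (length(bmds) < n) stop("need >= ", n, " BMDs for mean_lowest_n")
      mean(sort(bmds)[seq_len(n)])
    },
    first_mode = {
      dist <- bmd_distribution(bmds)
      diagnostics$modes <- dist$modes
      if (!length(dist$modes)) stop("no mode found")
      dist$modes[1]
    },
    accumulation_curvature = {
      dist <- bmd_distribution(bmds)
      diagnostics$modes <- dist$modes
      diagnostics$antimodes <- dist$antimodes
      if (length(dist$antimodes) >= 1) {
        restricted <- bmds[bmds < dist$antimodes[1]]
        diagnostics$fallback <- FALSE
      } else {
        restricted <- bmds
        diagnostics$fallback <- TRUE
        warning("no antimode found: accumulation method falling back to ",
                "the full BMD set")
      }
      if (length(restricted) < 3) {
        restricted <- bmds
        diagnostics$fallback <- TRUE
      }
      s <- sort(restricted)
      s[accumulation_max_curvature(s)]
    },
    lowest_geneset = {
      if (is.null(gsc) || is.null(enrichment))
        stop("lowest_geneset needs a GeneSetCollection and its enrichment")
      enriched <- enrichment$target[enrichment$enriched]
      if (!length(enriched)) stop("no enriched gene set")
      med <- vapply(enriched, function(sid) {
        members <- intersect(gsc$sets[[sid]], names(bmds))
        if (!length(members)) return(NA_real_)
        stats::median(bmds[members])
      }, numeric(1))
      diagnostics$set_medians <- med
      min(med, na.rm = TRUE)
    })
  structure(list(method = method, twpod = unname(value),
                 n_genes = length(bmds), diagnostics = diagnostics),
            class = "PodResult")
}

#' @export
print.PodResult <- function(x, ...) {
  cat("twPOD (", x$method, "): ", signif(x$twpod, 6), " over ", x$n_genes,
      " genes\n", sep = "")
  invisible(x)
}

#' Classify per-gene sensitivity between two omics layers
#'
#' For every gene present in both layers, labels the layer with the strictly
#' smaller BMD; when the relative gap (difference over the smaller BMD) is at
#' most \code{tie_tol} the gene is a tie.
#'
#' @param bmds_layer_a,bmds_layer_b named numeric BMD vectors.
#' @param layer_names length-2 character labels.
#' @param tie_tol relative-gap tolerance (default 0.05).
#' @return data.frame: gene, bmd_a, bmd_b, more_sensitive_layer.
#' @export
compare_sensitivity <- function(bmds_layer_a, bmds_layer_b,
                                layer_names = c("layer_a", "layer_b"),
                                tie_tol = 0.05) {
  common <- intersect(names(bmds_layer_a), names(bmds_layer_b))
  common <- common[!is.na(bmds_layer_a[common]) & !is.na(bmds_layer_b[common])]
  if (!length(common)) {
    warning("no genes shared between layers")
    return(data.frame(gene = character(), bmd_a = numeric(),
                      bmd_b = numeric(), more_sensitive_layer = character()))
  }
  a <- bmds_layer_a[common]; b <- bmds_layer_b[common]
  rel_gap <- abs(a - b) / pmin(a, b)
  label <- ifelse(rel_gap <= tie_tol, "tie",
                  ifelse(a < b, layer_names[1], layer_names[2]))
  data.frame(gene = common, bmd_a = unname(a), bmd_b = unname(b),
             more_sensitive_layer = unname(label), stringsAsFactors = FALSE,
             row.names = NULL)
}

# categorize one ordered boolean vector of per-timepoint dose dependency
classify_time_course <- function(flags) {
  t_n <- length(flags)
  on <- which(flags)
  if (!length(on)) return("absent")
  if (length(on) == t_n) return("sustained")
  contiguous <- all(diff(on) == 1)
  if (!contiguous) return("other")
  if (on[1] == 1) return("early")
  if (on[length(on)] == t_n) return("late")
  "transient"
}

#' Temporal dose-dependency patterns across layers
#'
#' Given per-gene, per-layer, per-timepoint dose-dependency booleans,
#' classifies each layer's time course as sustained (all time points), early
#' (a prefix only), late (a suffix only), transient (an interior run) or
#' other, and joins the per-layer categories into one combined label, e.g.
#' \code{"sustained transcription + late methylation"}. Genes dose-dependent
#' in no layer are excluded.
#'
#' @param ddg_flags named list: layer name -> gene x timepoint logical matrix
#'   (all layers share the gene set and the ordered timepoint columns).
#' @param timepoints character vector giving the column order; must match
#'   every matrix's column names.
#' @param grammar classification function mapping a logical vector to a
#'   category label (default the built-in five-class grammar).
#' @return data.frame: gene, one category column per layer, pattern.
#' @export
temporal_patterns <- function(ddg_flags, timepoints,
                              grammar = classify_time_course) {
  stopifnot(is.list(ddg_flags), length(ddg_flags) >= 1,
            !is.null(names(ddg_flags)), length(timepoints) >= 2)
  for (nm in names(ddg_flags)) {
    m <- ddg_flags[[nm]]
    if (!identical(colnames(m), timepoints))
      stop("layer '", nm, "': timepoint columns must be ",
           paste(timepoints, collapse = ", "), " in that order")
  }
  genes <- rownames(ddg_flags[[1]])
  cats <- sapply(names(ddg_flags), function(nm)
    apply(ddg_flags[[nm]][genes, , drop = FALSE], 1, grammar))
  cats <- matrix(cats, nrow = length(genes),
                 dimnames = list(genes, names(ddg_flags)))
  keep <- rowSums(cats != "absent") > 0
  cats <- cats[keep, , drop = FALSE]
  pattern <- apply(cats, 1, function(r)
    paste(paste(r, names(ddg_flags)), collapse = " + "))
  out <- data.frame(gene = rownames(cats), cats, pattern = pattern,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  out
}
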