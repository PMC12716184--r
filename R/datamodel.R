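#' Dose-response dataset container
#'
#' Bundles one omics layer's feature-by-sample matrix with per-sample dose,
#' condition and time-point annotations, and validates the design for
#' dose-response modeling: matched sample sets, non-negative doses, a dose-0
#' control and at least three distinct dose levels in every
#' (condition, timepoint) stratum.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names sample ids.
#' @param sample_meta data.frame with columns \code{sample}, \code{dose},
#'   \code{condition}, \code{timepoint}.
#' @param layer_name text label for the omics layer, e.g. \code{"expression"}.
#' @param missing_policy what to do with features containing missing values:
#'   \code{"drop_feature"} removes them (with a message), \code{"error"} aborts.
#' @return An object of class \code{DoseResponseDataset}: a list with elements
#'   \code{layer_name}, \code{values}, \code{features}, \code{samples},
#'   \code{sample_meta}.
#' @export
DoseResponseDataset <- function(values, sample_meta, layer_name = "expression",
                                missing_policy = c("drop_feature", "error")) {
  missing_policy <- match.arg(missing_policy)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("matrix must have feature ids as row names")
  if (is.null(colnames(values))) stop("matrix must have sample ids as column names")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  req <- c("sample", "dose", "condition", "timepoint")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss)) stop("sample_meta lacks column(s): ", paste(miss, collapse = ", "))
  sample_meta$sample <- as.character(sample_meta$sample)
  if (anyDuplicated(sample_meta$sample))
    stop("duplicated sample ids in metadata: ",
         paste(unique(sample_meta$sample[duplicated(sample_meta$sample)]), collapse = ", "))

  only_mat <- setdiff(colnames(values), sample_meta$sample)
  only_meta <- setdiff(sample_meta$sample, colnames(values))
  if (length(only_mat) || length(only_meta))
    stop("sample sets differ between matrix and metadata; only in matrix: {",
         paste(only_mat, collapse = ", "), "}; only in metadata: {",
         paste(only_meta, collapse = ", "), "}")
  # align metadata to matrix column order
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- NULL

  dose_num <- suppressWarnings(as.numeric(sample_meta$dose))
  bad <- which(is.na(dose_num) & !is.na(sample_meta$dose))
  if (length(bad))
    stop("non-numeric dose for sample(s): ",
         paste(sample_meta$sample[bad], collapse = ", "))
  if (anyNA(dose_num)) stop("missing dose values in metadata")
  if (any(dose_num < 0)) stop("doses must be non-negative")
  sample_meta$dose <- dose_num
  sample_meta$condition <- as.character(sample_meta$condition)
  sample_meta$timepoint <- as.character(sample_meta$timepoint)

  # per-stratum design checks
  strata <- split(seq_len(nrow(sample_meta)),
                  paste(sample_meta$condition, sample_meta$timepoint, sep = "\r"))
  for (key in names(strata)) {
    d <- sample_meta$dose[strata[[key]]]
    lab <- sub("\r", " / ", key, fixed = TRUE)
    if (!any(d == 0))
      stop("stratum '", lab, "' has no dose-0 control sample")
    if (length(unique(d)) < 3)
      stop("stratum '", lab, "' has fewer than 3 distinct dose levels")
  }

  if (anyNA(values)) {
    n_na <- which(rowSums(is.na(values)) > 0)
    if (missing_policy == "error")
      stop(length(n_na), " feature(s) contain missing values (policy 'error')")
    message("dropping ", length(n_na), " feature(s) with missing values")
    values <- values[-n_na, , drop = FALSE]
  }
  if (!is.numeric(values)) stop("matrix values must be numeric")

  structure(
    list(layer_name = layer_name, values = values,
         features = rownames(values), samples = colnames(values),
         sample_meta = sample_meta),
    class = "DoseResponseDataset")
}

#' @export
print.DoseResponseDataset <- function(x, ...) {
  cat("DoseResponseDataset '", x$layer_name, "': ",
      nrow(x$values), " features x ", ncol(x$values), " samples\n", sep = "")
  st <- unique(x$sample_meta[c("condition", "timepoint")])
  cat("  strata: ",
      paste(paste(st$condition, st$timepoint, sep = "/"), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' List the (condition, timepoint) strata of a dataset
#' @param ds a \code{DoseResponseDataset}.
#' @return data.frame with columns \code{condition}, \code{timepoint}.
#' @export
dataset_strata <- function(ds) {
  stopifnot(inherits(ds, "DoseResponseDataset"))
  st <- unique(ds$sample_meta[c("condition", "timepoint")])
  rownames(st) <- NULL
  st
}

#' Subset a dataset to one (condition, timepoint) stratum
#' @param ds a \code{DoseResponseDataset}.
#' @param condition,timepoint stratum key values.
#' @return list with \code{values} (feature matrix restricted to the stratum's
#'   samples, columns ordered by increasing dose) and \code{dose} vector.
#' @export
stratum_slice <- function(ds, condition, timepoint) {
  stopifnot(inherits(ds, "DoseResponseDataset"))
  sel <- ds$sample_meta$condition == condition & ds$sample_meta$timepoint == timepoint
  if (!any(sel)) stop("no samples in stratum '", condition, " / ", timepoint, "'")
  ord <- order(ds$sample_meta$dose[sel])
  idx <- which(sel)[ord]
  list(values = ds$values[, idx, drop = FALSE],
       dose = ds$sample_meta$dose[idx],
       samples = ds$samples[idx])
}

#' AOP knowledge container
#'
#' Holds the adverse-outcome-pathway scaffold: the key-event (KE) catalog with
#' MIE/KE/AO types, directed key-event relationships (KERs), gene-to-KE and
#' KE-to-AOP memberships, and an optional AOP-to-hazard-class mapping.
#' Referential integrity is enforced: every KE referenced anywhere must exist
#' in the catalog, and KER self-loops are rejected.
#'
#' @param ke_catalog data.frame(ke_id, title, ke_type) with ke_type in
#'   MIE/KE/AO.
#' @param ker_edges data.frame(upstream_ke, downstream_ke).
#' @param gene_to_ke data.frame(gene_id, ke_id); duplicates deduplicated with
#'   a warning.
#' @param ke_to_aop data.frame(ke_id, aop_id).
#' @param aop_hazard optional data.frame(aop_id, hazard_class). Classes must
#'   come from \code{hazard_vocabulary} unless a custom vocabulary is given.
#' @param hazard_vocabulary character vector of admissible hazard classes;
#'   defaults to the nine CLP/GHS-style classes used in SSbD assessment.
#' @return An object of class \code{AOPKnowledge}.
#' @export
AOPKnowledge <- function(ke_catalog, ker_edges, gene_to_ke, ke_to_aop,
                         aop_hazard = NULL, hazard_vocabulary = NULL) {
  ke_catalog <- as.data.frame(ke_catalog, stringsAsFactors = FALSE)
  stopifnot(all(c("ke_id", "title", "ke_type") %in% names(ke_catalog)))
  ke_catalog[] <- lapply(ke_catalog, as.character)
  bad_type <- setdiff(unique(ke_catalog$ke_type), c("MIE", "KE", "AO"))
  if (length(bad_type))
    stop("unknown ke_type value(s): ", paste(bad_type, collapse = ", "))
  if (anyDuplicated(ke_catalog$ke_id)) stop("duplicated ke_id in catalog")
  known <- ke_catalog$ke_id

  chk <- function(ids, where) {
    unknown <- setdiff(ids, known)
    if (length(unknown))
      stop(where, " references KE(s) absent from the catalog: ",
           paste(unknown, collapse = ", "))
  }

  ker_edges <- as.data.frame(ker_edges, stringsAsFactors = FALSE)
  if (nrow(ker_edges)) {
    stopifnot(all(c("upstream_ke", "downstream_ke") %in% names(ker_edges)))
    ker_edges[] <- lapply(ker_edges, as.character)
    chk(c(ker_edges$upstream_ke, ker_edges$downstream_ke), "ker_edges")
    if (any(ker_edges$upstream_ke == ker_edges$downstream_ke))
      stop("ker_edges contains self-loops")
    ker_edges <- unique(ker_edges[c("upstream_ke", "downstream_ke")])
  } else {
    ker_edges <- data.frame(upstream_ke = character(), downstream_ke = character())
  }

  gene_to_ke <- as.data.frame(gene_to_ke, stringsAsFactors = FALSE)
  if (nrow(gene_to_ke)) {
    stopifnot(all(c("gene_id", "ke_id") %in% names(gene_to_ke)))
    gene_to_ke[] <- lapply(gene_to_ke, as.character)
    chk(gene_to_ke$ke_id, "gene_to_ke")
    ndup <- sum(duplicated(gene_to_ke[c("gene_id", "ke_id")]))
    if (ndup > 0) {
      warning(ndup, " duplicated (gene, KE) row(s) removed")
      gene_to_ke <- unique(gene_to_ke[c("gene_id", "ke_id")])
    }
  } else {
    gene_to_ke <- data.frame(gene_id = character(), ke_id = character())
  }

  ke_to_aop <- as.data.frame(ke_to_aop, stringsAsFactors = FALSE)
  if (nrow(ke_to_aop)) {
    stopifnot(all(c("ke_id", "aop_id") %in% names(ke_to_aop)))
    ke_to_aop[] <- lapply(ke_to_aop, as.character)
    chk(ke_to_aop$ke_id, "ke_to_aop")
    ke_to_aop <- unique(ke_to_aop[c("ke_id", "aop_id")])
  } else {
    ke_to_aop <- data.frame(ke_id = character(), aop_id = character())
  }

  if (is.null(hazard_vocabulary)) hazard_vocabulary <- hazard_classes()
  if (!is.null(aop_hazard)) {
    aop_hazard <- as.data.frame(aop_hazard, stringsAsFactors = FALSE)
    stopifnot(all(c("aop_id", "hazard_class") %in% names(aop_hazard)))
    aop_hazard[] <- lapply(aop_hazard, as.character)
    bad <- setdiff(unique(aop_hazard$hazard_class), hazard_vocabulary)
    if (length(bad))
      stop("hazard_class value(s) outside the declared vocabulary: ",
           paste(bad, collapse = ", "))
  } else {
    aop_hazard <- data.frame(aop_id = character(), hazard_class = character())
  }

  structure(
    list(ke_catalog = ke_catalog, ker_edges = ker_edges,
         gene_to_ke = gene_to_ke, ke_to_aop = ke_to_aop,
         aop_hazard = aop_hazard, hazard_vocabulary = hazard_vocabulary),
    class = "AOPKnowledge")
}

#' @export
print.AOPKnowledge <- function(x, ...) {
  cat("AOPKnowledge: ", nrow(x$ke_catalog), " KEs (",
      sum(x$ke_catalog$ke_type == "MIE"), " MIE, ",
      sum(x$ke_catalog$ke_type == "AO"), " AO), ",
      nrow(x$ker_edges), " KERs, ",
      length(unique(x$ke_to_aop$aop_id)), " AOPs, ",
      nrow(x$gene_to_ke), " gene-KE links\n", sep = "")
  invisible(x)
}

#' Default human-health hazard class vocabulary
#'
#' The nine CLP/GHS-style hazard classes used by Safe-and-Sustainable-by-Design
#' assessment frameworks, plus the reserved class \code{"unclassified"} used by
#' the rollup for unannotated AOPs.
#' @return character vector of class names.
#' @export
hazard_classes <- function() {
  c("acute toxicity", "carcinogenicity", "mutagenicity",
    "reproductive/developmental toxicity", "respiratory sensitization",
    "skin sensitization", "specific target organ toxicity",
    "endocrine disruption", "aspiration hazard", "unclassified")
}

#' Protein-protein interaction network container
#'
#' Stores an undirected PPI edge list with each unordered pair kept once and
#' self-edges removed.
#'
#' @param edges two-column data.frame or matrix of gene ids.
#' @param isolated optional character vector of nodes with no edges.
#' @return object of class \code{PPINetwork} with elements \code{edges}
#'   (data.frame gene_a/gene_b, gene_a < gene_b) and \code{nodes}.
#' @export
PPINetwork <- function(edges, isolated = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2 && nrow(edges) > 0) stop("PPI edge list needs two columns")
  if (nrow(edges)) {
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    lo <- pmin(a, b); hi <- pmax(a, b)
    e <- unique(data.frame(gene_a = lo, gene_b = hi, stringsAsFactors = FALSE))
  } else {
    e <- data.frame(gene_a = character(), gene_b = character())
  }
  structure(list(edges = e,
                 nodes = sort(unique(c(e$gene_a, e$gene_b, as.character(isolated))))),
            class = "PPINetwork")
}

#' Transcription-factor target table container
#' @param pairs two-column data.frame/matrix (tf_gene_id, target_gene_id).
#' @return object of class \code{TFTable}; \code{$tfs} holds the distinct TFs.
#' @export
TFTable <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    p <- unique(data.frame(tf_gene_id = as.character(pairs[[1]]),
                           target_gene_id = as.character(pairs[[2]]),
                           stringsAsFactors = FALSE))
  } else {
    p <- data.frame(tf_gene_id = character(), target_gene_id = character())
  }
  structure(list(pairs = p, tfs = sort(unique(p$tf_gene_id))), class = "TFTable")
}

#' Gene-set collection container (GMT semantics)
#' @param sets named list of character vectors; names are set ids. Members are
#'   de-duplicated within each set.
#' @param descriptions optional named character vector of set descriptions.
#' @return object of class \code{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}
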