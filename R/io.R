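## Table readers/writers. Delimiter is auto-detected between tab and comma on
## input; tab is always written on output, numerics at 17 significant digits so
## write-then-read round-trips to full double precision.

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

read_table_auto <- function(path) {
  utils::read.delim(path, sep = detect_delim(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
}

format_cell <- function(x) {
  if (is.double(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1))
    out
  } else {
    as.character(x)
  }
}

write_tsv17 <- function(df, path) {
  out <- as.data.frame(lapply(df, format_cell), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a dose-response dataset from a matrix file and a metadata file
#'
#' The matrix file is delimited text (tab or comma, auto-detected) with the
#' feature id in the first column and one column per sample. The metadata file
#' has columns \code{sample}, \code{dose}, \code{condition}, \code{timepoint}.
#' Validation (matched samples, controls, >= 3 dose levels per stratum) is
#' performed by \code{\link{DoseResponseDataset}}.
#'
#' @param matrix_path path to the feature-by-sample matrix.
#' @param meta_path path to the sample metadata table.
#' @param layer_name label for the omics layer.
#' @param missing_policy \code{"drop_feature"} (default) or \code{"error"}.
#' @return a validated \code{DoseResponseDataset}.
#' @export
read_dataset <- function(matrix_path, meta_path, layer_name = "expression",
                         missing_policy = "drop_feature") {
  mat_df <- read_table_auto(matrix_path)
  if (ncol(mat_df) < 2) stop("matrix file needs a feature column plus samples")
  feats <- as.character(mat_df[[1]])
  vals <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- feats
  meta <- read_table_auto(meta_path)
  DoseResponseDataset(vals, meta, layer_name = layer_name,
                      missing_policy = missing_policy)
}

#' Read the five AOP knowledge tables
#'
#' @param ke_path TSV with columns ke_id, title, ke_type.
#' @param ker_path TSV with columns upstream_ke, downstream_ke.
#' @param gene_ke_path TSV with columns gene_id, ke_id.
#' @param ke_aop_path TSV with columns ke_id, aop_id.
#' @param hazard_path optional TSV with columns aop_id, hazard_class.
#' @param hazard_vocabulary optional custom vocabulary; when a hazard file is
#'   given and no vocabulary is supplied, the classes present in the file are
#'   accepted as the vocabulary (plus \code{"unclassified"}).
#' @return a validated \code{AOPKnowledge}.
#' @export
read_aop_knowledge <- function(ke_path, ker_path, gene_ke_path, ke_aop_path,
                               hazard_path = NULL, hazard_vocabulary = NULL) {
  haz <- NULL
  if (!is.null(hazard_path)) {
    haz <- read_table_auto(hazard_path)
    if (is.null(hazard_vocabulary))
      hazard_vocabulary <- union(unique(as.character(haz$hazard_class)),
                                 "unclassified")
  }
  AOPKnowledge(ke_catalog = read_table_auto(ke_path),
               ker_edges = read_table_auto(ker_path),
               gene_to_ke = read_table_auto(gene_ke_path),
               ke_to_aop = read_table_auto(ke_aop_path),
               aop_hazard = haz, hazard_vocabulary = hazard_vocabulary)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT lines are tab-separated: set name, description, then member genes.
#' @param path path to a .gmt file.
#' @return a \code{GeneSetCollection}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                        paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  descr <- setNames(vapply(parts, `[`, character(1), 2), names(sets))
  GeneSetCollection(sets, descr)
}

#' Write a gene-set collection to a GMT file
#' @param gsc a \code{GeneSetCollection}.
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PPI edge list (two-column TSV/CSV)
#' @param path path to the edge list; first two columns are gene ids.
#' @return a \code{PPINetwork}.
#' @export
read_ppi <- function(path) PPINetwork(read_table_auto(path))

#' Read a TF-to-target table (two-column TSV/CSV)
#' @param path path; first column TF gene id, second target gene id.
#' @return a \code{TFTable}.
#' @export
read_tf_table <- function(path) TFTable(read_table_auto(path))

#' Write result tables with a traceability manifest
#'
#' Each table is written as a TSV (numerics at 17 significant digits) or JSON.
#' A run manifest (\code{manifest.json}) records the package version, the
#' parameter set, its MD5 hash, MD5 hashes of any declared input files, and
#' the MD5 of every written output, so identical inputs and parameters yield
#' byte-identical manifests.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param formats \code{"tsv"} (default) or \code{"json"}.
#' @param params list of run parameters to record.
#' @param input_paths named character vector of input files to hash.
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, formats = c("tsv", "json"),
                          params = list(), input_paths = character()) {
  formats <- match.arg(formats)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  stopifnot(is.list(tables), !is.null(names(tables)))
  files <- character(0)
  for (nm in names(tables)) {
    ext <- if (formats == "tsv") ".tsv" else ".json"
    path <- file.path(out_dir, paste0(nm, ext))
    if (formats == "tsv") {
      write_tsv17(as.data.frame(tables[[nm]]), path)
    } else {
      jsonlite::write_json(tables[[nm]], path, dataframe = "rows",
                           auto_unbox = TRUE, digits = NA)
    }
    files[nm] <- path
  }
  manifest <- list(
    tool = "omicspod",
    version = as.character(utils::packageVersion("omicspod")),
    config = params,
    config_hash = config_hash(params),
    inputs = lapply(input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Stable hash of a parameter list
#'
#' Canonicalizes the list (keys sorted recursively), serializes it to JSON and
#' returns the MD5 of the serialization, so the hash does not depend on key
#' order.
#' @param params a (possibly nested) list of parameters.
#' @return character MD5 hash.
#' @export
config_hash <- function(params) {
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      lapply(x[order(names(x))], canon)
    } else if (is.list(x)) lapply(x, canon) else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon(params), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Export a network to GraphML
#'
#' @param nodes data.frame with first column node id and further columns as
#'   node attributes.
#' @param edges data.frame with first two columns endpoint ids and further
#'   columns as edge attributes.
#' @param path output .graphml path.
#' @param directed logical.
#' @export
write_graphml <- function(nodes, edges, path, directed = FALSE) {
  g <- igraph::graph_from_data_frame(edges, directed = directed,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
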