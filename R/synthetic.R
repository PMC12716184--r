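## Ground-truthed synthetic fixtures: multi-dose omics matrices with planted
## dose-responsive genes (known generating model, parameters and analytic
## BMD), an optional coupled methylation layer, and a matching AOP scaffold,
## PPI network, TF table and gene-set collection, all written in the formats
## the readers consume.

#' Specification for a synthetic fixture
#'
#' Defaults describe a typical in vitro toxicogenomic design: six dose levels
#' 0/1/2.5/5/10/20 with three replicates, homoscedastic Gaussian noise of SD
#' 0.1 on log-scale responses, 20 dose-responsive genes among 100, and a
#' small AOP scaffold with one planted enriched key event.
#'
#' @param seed integer RNG seed; every random draw derives from it.
#' @param dose_levels numeric vector of dose levels (must include 0).
#' @param replicates replicates per dose level.
#' @param n_flat,n_hill_up,n_exp_down,n_poly2 gene-class counts.
#' @param noise_sd homoscedastic Gaussian noise SD.
#' @param make_methylation also emit a coupled second layer.
#' @param frac_inverse,frac_concordant fractions of responsive genes whose
#'   methylation curve is the mirrored / copied expression curve (must sum to
#'   at most 1; the remainder get a flat methylation profile).
#' @param ppi_density background PPI edge probability.
#' @param n_tf number of transcription factors drawn from the planted genes.
#' @param condition,timepoint stratum labels for the metadata.
#' @return list of class \code{FixtureSpec}.
#' @export
fixture_spec <- function(seed = 1,
                         dose_levels = c(0, 1, 2.5, 5, 10, 20),
                         replicates = 3,
                         n_flat = 80, n_hill_up = 20, n_exp_down = 0,
                         n_poly2 = 0, noise_sd = 0.1,
                         make_methylation = FALSE,
                         frac_inverse = 0.5, frac_concordant = 0.3,
                         ppi_density = 0.02, n_tf = 3,
                         condition = "treated", timepoint = "24h") {
  stopifnot(0 %in% dose_levels, length(unique(dose_levels)) >= 3,
            replicates >= 2, n_flat >= 0, n_hill_up >= 0, n_exp_down >= 0,
            n_poly2 >= 0, noise_sd >= 0,
            frac_inverse >= 0, frac_concordant >= 0,
            frac_inverse + frac_concordant <= 1)
  n_resp <- n_hill_up + n_exp_down + n_poly2
  if (n_resp + n_flat < 1) stop("fixture must contain at least one gene")
  if (n_resp > n_resp + n_flat) stop("more planted genes than total")
  structure(list(seed = seed, dose_levels = sort(dose_levels),
                 replicates = replicates, n_flat = n_flat,
                 n_hill_up = n_hill_up, n_exp_down = n_exp_down,
                 n_poly2 = n_poly2, noise_sd = noise_sd,
                 make_methylation = make_methylation,
                 frac_inverse = frac_inverse,
                 frac_concordant = frac_concordant,
                 ppi_density = ppi_density, n_tf = n_tf,
                 condition = condition, timepoint = timepoint),
            class = "FixtureSpec")
}

#' Analytic benchmark dose of a known generating model
#'
#' Inverts the generating mean function for the configured BMR: closed form
#' for linear, power, Hill and exp2; fine-grid scan plus bisection to
#' relative tolerance 1e-12 for poly2 and exp3-exp5. This is the generator's
#' oracle, independent of the fitting path.
#'
#' @param model model name from \code{\link{model_family}}.
#' @param theta parameter vector in the registry's order.
#' @param cfg a \code{\link{bmr_config}}.
#' @param d_max maximum dose of the design (defines the search range and the
#'   auto direction).
#' @param sd_control control SD, needed for the \code{"sd"} BMR kind.
#' @return the true BMD, or \code{NA} with attribute
#'   \code{status = "unreachable"} when the shift is not reached in range.
#' @export
true_bmd <- function(model, theta, cfg, d_max, sd_control = NULL) {
  stopifnot(inherits(cfg, "BMRConfig"))
  fun <- model_funs[[model]]
  if (is.null(fun)) stop("unknown model: ", model)
  f0 <- fun(0, theta)
  fm <- fun(d_max, theta)
  direction <- switch(cfg$direction_policy,
    auto = if (fm >= f0) "up" else "down",
    up = "up", down = "down")
  sgn <- if (direction == "up") 1 else -1
  shift <- switch(cfg$kind,
    relative = {
      if (f0 == 0) stop("relative BMR undefined at baseline 0")
      abs(f0) * cfg$magnitude
    },
    absolute = cfg$magnitude,
    sd = {
      if (is.null(sd_control)) stop("sd kind needs sd_control")
      cfg$magnitude * sd_control
    })
  unreachable <- structure(NA_real_, status = "unreachable")
  closed <- switch(model,
    linear = {
      b <- theta[2]
      if (b == 0 || sign(b) != sgn) NULL else shift / abs(b)
    },
    power = {
      b <- theta[2]; g <- theta[3]
      if (b == 0 || sign(b) != sgn) NULL else (shift / abs(b))^(1 / g)
    },
    hill = {
      b <- theta[2]; k <- theta[3]; g <- theta[4]
      if (b == 0 || sign(b) != sgn || shift >= abs(b)) NULL
      else k * (shift / (abs(b) - shift))^(1 / g)
    },
    exp2 = {
      a <- theta[1]; b <- theta[2]
      # f - f0 = a (e^{bd} - 1); solve |a| |e^{bd} - 1| = shift on the
      # correct branch
      if (a == 0 || b == 0) NULL else {
        up_branch <- (sign(a) * sign(b)) > 0   # response increases iff a*b>0
        want_up <- direction == "up"
        if (up_branch != want_up) NULL else {
          arg <- 1 + sign(b) * shift / abs(a)
          if (arg <= 0) NULL else log(arg) / b
        }
      }
    },
    NULL)
  if (!is.null(closed)) {
    if (!is.finite(closed) || closed <= 0 || closed > d_max) return(unreachable)
    return(closed)
  }
  if (model %in% c("linear", "power", "hill", "exp2")) return(unreachable)
  # numeric first-crossing inversion
  h <- function(d) (fun(d, theta) - f0) * sgn - shift
  grid <- seq(0, d_max, length.out = 4097)[-1]
  hv <- h(grid)
  idx <- which(hv >= 0)
  if (!length(idx)) return(unreachable)
  i <- idx[1]
  lo <- if (i == 1) 0 else grid[i - 1]
  hi <- grid[i]
  for (iter in 1:300) {
    mid <- (lo + hi) / 2
    if (h(mid) >= 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-12 * max(hi, 1e-30)) break
  }
  hi
}

# draw the generating parameters for one gene of a given class; dose-scaled
draw_gene_model <- function(class, d_max) {
  base <- stats::runif(1, 4, 8)
  switch(class,
    flat = list(model = "linear", theta = c(base, 0)),
    hill_up = list(model = "hill",
                   theta = c(base, stats::runif(1, 1, 2),
                             stats::runif(1, 0.08, 0.4) * d_max,
                             stats::runif(1, 1, 4))),
    exp_down = {
      ratio <- stats::runif(1, 0.3, 0.7)
      list(model = "exp2", theta = c(base, log(ratio) / d_max))
    },
    poly2 = {
      dp <- stats::runif(1, 0.3, 0.7) * d_max
      amp <- stats::runif(1, 1, 2)
      list(model = "poly2", theta = c(base, 2 * amp / dp, -amp / dp^2))
    })
}

#' Generate a complete ground-truthed fixture on disk
#'
#' Writes every input file the pipeline consumes — expression matrix,
#' optional coupled methylation matrix, sample metadata, a GMT collection
#' with one planted set, the five AOP knowledge tables with the responsive
#' genes concentrated in one planted key event, a PPI edge list densified
#' among the planted genes, and a TF table — and returns the ground truth:
#' per-gene generating model, parameters and analytic BMD for the given BMR
#' configuration, plus the planted KE/AOP ids. Fully reproducible from the
#' spec's seed.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param dir output directory (created if needed).
#' @param cfg BMR configuration used to compute true BMDs (default
#'   \code{bmr_config()}).
#' @return list of class \code{SyntheticFixture}: \code{paths} (named file
#'   paths), \code{truth} (data.frame gene/class/model/true_bmd with the
#'   theta list-column), \code{planted} (ke, aop, hazard_class, genes),
#'   \code{spec}.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture"),
                             cfg = bmr_config()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  doses <- rep(spec$dose_levels, each = spec$replicates)
  n_samp <- length(doses)
  d_max <- max(doses)
  samples <- sprintf("s%02d", seq_len(n_samp))
  classes <- c(rep("hill_up", spec$n_hill_up),
               rep("exp_down", spec$n_exp_down),
               rep("poly2", spec$n_poly2),
               rep("flat", spec$n_flat))
  n_gene <- length(classes)
  genes <- sprintf("g%04d", seq_len(n_gene))

  models <- lapply(classes, draw_gene_model, d_max = d_max)
  expr_clean <- t(vapply(models, function(m) model_funs[[m$model]](doses, m$theta),
                         numeric(n_samp)))
  expr <- expr_clean + matrix(stats::rnorm(n_gene * n_samp, 0, spec$noise_sd),
                              n_gene, n_samp)
  dimnames(expr) <- list(genes, samples)

  truth <- data.frame(gene = genes, class = classes,
                      model = vapply(models, `[[`, character(1), "model"),
                      stringsAsFactors = FALSE)
  truth$theta <- lapply(models, `[[`, "theta")
  truth$true_bmd <- vapply(seq_len(n_gene), function(i) {
    if (classes[i] == "flat") return(NA_real_)
    true_bmd(models[[i]]$model, models[[i]]$theta, cfg, d_max,
             sd_control = spec$noise_sd)
  }, numeric(1))

  meta <- data.frame(sample = samples, dose = doses,
                     condition = spec$condition, timepoint = spec$timepoint,
                     stringsAsFactors = FALSE)

  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"))
  write_tsv17(cbind(data.frame(feature = genes, stringsAsFactors = FALSE),
                    as.data.frame(expr)), paths$expression)
  write_tsv17(meta, paths$metadata)

  coupling <- rep("none", n_gene)
  if (spec$make_methylation) {
    resp_idx <- which(classes != "flat")
    n_inv <- round(spec$frac_inverse * length(resp_idx))
    n_con <- round(spec$frac_concordant * length(resp_idx))
    pick <- sample(resp_idx)
    inv_idx <- pick[seq_len(n_inv)]
    con_idx <- pick[seq_len(n_con) + n_inv]
    coupling[inv_idx] <- "inverse"; coupling[con_idx] <- "concordant"
    meth_base <- stats::runif(n_gene, 4, 8)
    dev <- expr_clean - expr_clean[, 1]
    meth_clean <- matrix(meth_base, n_gene, n_samp)
    meth_clean[inv_idx, ] <- meth_base[inv_idx] - dev[inv_idx, ]
    meth_clean[con_idx, ] <- meth_base[con_idx] + dev[con_idx, ]
    meth <- meth_clean + matrix(stats::rnorm(n_gene * n_samp, 0, spec$noise_sd),
                                n_gene, n_samp)
    dimnames(meth) <- list(genes, samples)
    paths$methylation <- file.path(dir, "methylation.tsv")
    write_tsv17(cbind(data.frame(feature = genes, stringsAsFactors = FALSE),
                      as.data.frame(meth)), paths$methylation)
  }
  truth$coupling <- coupling

  ## AOP scaffold: three linear AOPs; the planted KE (K1, inside AOP_planted)
  ## receives most responsive genes, every other KE only flat genes.
  ke_catalog <- data.frame(
    ke_id = c("M1", "M2", "K1", "K2", "K3", "K4", "K5", "K6", "A1", "A2"),
    title = c("MIE one", "MIE two", "planted key event", "downstream event",
              "unrelated event A", "unrelated event B", "unrelated event C",
              "unrelated event D", "adverse outcome one", "adverse outcome two"),
    ke_type = c("MIE", "MIE", "KE", "KE", "KE", "KE", "KE", "KE", "AO", "AO"),
    stringsAsFactors = FALSE)
  ker_edges <- data.frame(
    upstream_ke   = c("M1", "K1", "K2", "M2", "K3", "K4", "M1", "K5", "K6"),
    downstream_ke = c("K1", "K2", "A1", "K3", "K4", "A2", "K5", "K6", "A1"),
    stringsAsFactors = FALSE)
  ke_to_aop <- data.frame(
    ke_id = c("M1", "K1", "K2", "A1", "M2", "K3", "K4", "A2",
              "M1", "K5", "K6", "A1"),
    aop_id = c(rep("AOP_planted", 4), rep("AOP_bg1", 4), rep("AOP_bg2", 4)),
    stringsAsFactors = FALSE)
  aop_hazard <- data.frame(
    aop_id = c("AOP_planted", "AOP_bg1"),
    hazard_class = c("carcinogenicity", "acute toxicity"),
    stringsAsFactors = FALSE)

  resp_genes <- genes[classes != "flat"]
  flat_genes <- genes[classes == "flat"]
  n_planted <- if (length(resp_genes)) max(1, round(0.75 * length(resp_genes)))
               else 0
  planted_genes <- resp_genes[seq_len(n_planted)]
  other_resp <- setdiff(resp_genes, planted_genes)
  other_kes <- c("M1", "M2", "K2", "K3", "K4", "K5", "K6", "A1", "A2")
  g2k <- data.frame(gene_id = planted_genes,
                    ke_id = rep("K1", n_planted), stringsAsFactors = FALSE)
  # flat genes spread across the remaining KEs; leftover responsive genes
  # scattered one per KE so no other KE concentrates signal
  if (length(flat_genes))
    g2k <- rbind(g2k, data.frame(
      gene_id = flat_genes,
      ke_id = rep(other_kes, length.out = length(flat_genes)),
      stringsAsFactors = FALSE))
  if (length(other_resp))
    g2k <- rbind(g2k, data.frame(
      gene_id = other_resp,
      ke_id = rep(other_kes, length.out = length(other_resp)),
      stringsAsFactors = FALSE))

  ## PPI: dense among planted genes, sparse background
  ppi_rows <- list()
  if (length(planted_genes) >= 2) {
    pp <- utils::combn(planted_genes, 2)
    keep <- stats::runif(ncol(pp)) < 0.5
    ppi_rows$planted <- data.frame(gene_a = pp[1, keep], gene_b = pp[2, keep],
                                   stringsAsFactors = FALSE)
  }
  if (n_gene >= 2) {
    nbg <- max(1, round(spec$ppi_density * n_gene * (n_gene - 1) / 2))
    ia <- sample(n_gene, nbg, replace = TRUE)
    ib <- sample(n_gene, nbg, replace = TRUE)
    keep <- ia != ib
    ppi_rows$background <- data.frame(gene_a = genes[ia[keep]],
                                      gene_b = genes[ib[keep]],
                                      stringsAsFactors = FALSE)
  }
  ppi_df <- do.call(rbind, ppi_rows)
  ppi <- PPINetwork(ppi_df)

  n_tf <- min(spec$n_tf, length(planted_genes))
  tfs <- planted_genes[seq_len(n_tf)]
  tf_rows <- do.call(rbind, lapply(tfs, function(tf) {
    targets <- sample(setdiff(genes, tf), min(5, n_gene - 1))
    data.frame(tf_gene_id = tf, target_gene_id = targets,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tf_rows))
    tf_rows <- data.frame(tf_gene_id = character(),
                          target_gene_id = character())

  gmt <- GeneSetCollection(
    list(planted_set = planted_genes,
         random_set = sort(sample(genes, min(10, n_gene)))),
    c(planted_set = "genes planted in the enriched key event",
      random_set = "random background set"))

  paths$ke_catalog <- file.path(dir, "ke_catalog.tsv")
  paths$ker_edges <- file.path(dir, "ker_edges.tsv")
  paths$gene_to_ke <- file.path(dir, "gene_to_ke.tsv")
  paths$ke_to_aop <- file.path(dir, "ke_to_aop.tsv")
  paths$aop_hazard <- file.path(dir, "aop_hazard.tsv")
  paths$ppi <- file.path(dir, "ppi.tsv")
  paths$tf <- file.path(dir, "tf.tsv")
  paths$genesets <- file.path(dir, "genesets.gmt")
  write_tsv17(ke_catalog, paths$ke_catalog)
  write_tsv17(ker_edges, paths$ker_edges)
  write_tsv17(g2k, paths$gene_to_ke)
  write_tsv17(ke_to_aop, paths$ke_to_aop)
  write_tsv17(aop_hazard, paths$aop_hazard)
  write_tsv17(ppi$edges, paths$ppi)
  write_tsv17(tf_rows, paths$tf)
  write_gmt(gmt, paths$genesets)

  structure(list(paths = paths, truth = truth,
                 planted = list(ke = "K1", aop = "AOP_planted",
                                hazard_class = "carcinogenicity",
                                genes = planted_genes, tfs = tfs),
                 spec = spec, cfg = cfg),
            class = "SyntheticFixture")
}
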