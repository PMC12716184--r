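## Pre-filtering: identify features likely to respond to dose before any
## model fitting. Three methods: one-way ANOVA across dose groups, the
## Jonckheere-Terpstra ordered trend test (exact for small samples), and an
## optional variance-moderated linear trend test.

new_prefilter_result <- function(df, method, condition, timepoint, alpha,
                                 adjust) {
  df$pass <- if (adjust == "none") df$p <= alpha else df$p_adj <= alpha
  structure(df, method = method, condition = condition, timepoint = timepoint,
            alpha = alpha, adjust = adjust,
            class = c("PrefilterResult", "data.frame"))
}

#' One-way ANOVA dose-response prefilter
#'
#' Per feature, a fixed-effects one-way F test of equality of means across
#' dose groups within one (condition, timepoint) stratum. Features with zero
#' between-group and zero within-group variance get F = 0, p = 1 (flat
#' feature convention).
#'
#' @param ds a \code{DoseResponseDataset}.
#' @param condition,timepoint stratum key.
#' @param alpha significance level used for the pass flag (default 0.05).
#' @param adjust \code{"none"} (default; a permissive pre-filter) or
#'   \code{"BH"} for Benjamini-Hochberg adjustment.
#' @return a \code{PrefilterResult} data.frame: feature, statistic, p, p_adj,
#'   pass.
#' @export
anova_filter <- function(ds, condition, timepoint, alpha = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  sl <- stratum_slice(ds, condition, timepoint)
  g <- factor(sl$dose)
  n_per <- table(g)
  if (length(n_per) < 2) stop("need >= 2 dose groups")
  if (any(n_per < 2))
    stop("dose group(s) with < 2 replicates: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  Y <- sl$values
  n <- ncol(Y); k <- nlevels(g)
  grand <- rowMeans(Y)
  # group means via rowsum on the transposed matrix
  gm <- t(rowsum(t(Y), g) / as.vector(n_per))        # features x groups
  ssb <- as.vector((gm - grand)^2 %*% as.vector(n_per))
  ssw <- rowSums((Y - gm[, as.integer(g), drop = FALSE])^2)
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  Fstat <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- ifelse(is.infinite(Fstat), 0,
              stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE))
  p[Fstat == 0] <- 1
  df <- data.frame(feature = rownames(Y), statistic = Fstat, p = p,
                   p_adj = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  new_prefilter_result(df, "anova", condition, timepoint, alpha, adjust)
}

## Jonckheere-Terpstra statistic: sum over ordered group pairs (i < j) of
## concordant between-group pairs, ties counted 1/2.
jt_statistic <- function(x, g_int) {
  k <- max(g_int)
  u <- 0
  for (i in seq_len(k - 1)) {
    xi <- x[g_int == i]
    for (j in (i + 1):k) {
      xj <- x[g_int == j]
      cmp <- outer(xi, xj, "<")
      tie <- outer(xi, xj, "==")
      u <- u + sum(cmp) + 0.5 * sum(tie)
    }
  }
  u
}

## Exact null distribution of the JT statistic for tie-free data, via the
## decomposition into independent Mann-Whitney statistics: the polynomial
## (in the rank-generating variable) of JT is the product over groups j of
## the Gaussian binomial coefficient [m_j + n_j choose n_j], m_j the number
## of observations in earlier groups. Coefficients counted in doubles.
gaussian_binomial <- function(a, b, memo = new.env(parent = emptyenv())) {
  key <- paste(a, b)
  hit <- get0(key, memo)
  if (!is.null(hit)) return(hit)
  val <- if (a == 0 || b == 0) 1 else {
    # C_q(a+b, b) = C_q(a+b-1, b-1) + q^b C_q(a+b-1, b)
    p1 <- gaussian_binomial(a, b - 1, memo)
    p2 <- gaussian_binomial(a - 1, b, memo)
    n_out <- max(length(p1), length(p2) + b)
    out <- numeric(n_out)
    out[seq_along(p1)] <- p1
    out[b + seq_along(p2)] <- out[b + seq_along(p2)] + p2
    out
  }
  assign(key, val, memo)
  val
}

jt_exact_pvals_noties <- function(sizes, u_obs) {
  memo <- new.env(parent = emptyenv())
  dist <- 1                                    # polynomial coefficients
  m_cum <- sizes[1]
  for (j in 2:length(sizes)) {
    gb <- gaussian_binomial(m_cum, sizes[j], memo)
    dist <- as.vector(convolve(dist, rev(gb), type = "open"))
    m_cum <- m_cum + sizes[j]
  }
  dist[dist < 0] <- 0                          # FFT round-off
  u <- seq_along(dist) - 1
  total <- sum(dist)
  eps <- 1e-9
  c(p_ge = sum(dist[u >= u_obs - eps]) / total,
    p_le = sum(dist[u <= u_obs + eps]) / total)
}

# number of distinct group-label assignments (multinomial coefficient)
jt_enum_count <- function(sizes) {
  exp(lfactorial(sum(sizes)) - sum(lfactorial(sizes)))
}

## Exact permutation distribution with ties: enumerate all distinct
## assignments of the observed values to the groups (sizes fixed).
jt_exact_pvals <- function(x, g_int, u_obs) {
  sizes <- tabulate(g_int)
  n <- length(x)
  idx_all <- seq_len(n)
  stats_acc <- numeric(0)
  rec <- function(remaining, gi, labels) {
    if (gi > length(sizes)) {
      stats_acc[[length(stats_acc) + 1L]] <<- jt_statistic(x, labels)
      return(invisible(NULL))
    }
    if (gi == length(sizes)) {        # last group forced
      labels[remaining] <- gi
      rec(integer(0), gi + 1L, labels)
      return(invisible(NULL))
    }
    combs <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (cc in combs) {
      lab2 <- labels; lab2[cc] <- gi
      rec(setdiff(remaining, cc), gi + 1L, lab2)
    }
  }
  rec(idx_all, 1L, integer(n))
  stats_acc <- unlist(stats_acc)
  eps <- 1e-9
  c(p_ge = mean(stats_acc >= u_obs - eps),
    p_le = mean(stats_acc <= u_obs + eps))
}

## Normal approximation with tie correction (Hollander & Wolfe).
jt_normal_pvals <- function(x, g_int, u_obs) {
  n_i <- tabulate(g_int); N <- length(x)
  t_j <- as.vector(table(x))
  mu <- (N^2 - sum(n_i^2)) / 4
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
           sum(t_j * (t_j - 1) * (2 * t_j + 5))) / 72
  v2 <- sum(n_i * (n_i - 1) * (n_i - 2)) * sum(t_j * (t_j - 1) * (t_j - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(n_i * (n_i - 1)) * sum(t_j * (t_j - 1)) / (8 * N * (N - 1))
  v <- v1 + v2 + v3
  if (v <= 0) return(c(p_ge = 1, p_le = 1))
  z <- (u_obs - mu) / sqrt(v)
  c(p_ge = stats::pnorm(z, lower.tail = FALSE), p_le = stats::pnorm(z))
}

#' Jonckheere-Terpstra ordered trend prefilter
#'
#' Per feature, tests for a monotone trend across ordered dose groups. The
#' two-sided p-value doubles the smaller of the increasing/decreasing
#' one-sided tails (capped at 1). For total sample size <= \code{exact_n} the
#' exact null distribution is used: computed by the Mann-Whitney convolution
#' (Gaussian-binomial) algorithm when the feature has no tied values, or by
#' enumeration of all group-label assignments when ties are present and the
#' assignment count is small; otherwise (and for larger samples) the normal
#' approximation with tie correction is used. Features
#' with all values identical get p = 1 (with one warning for the batch).
#'
#' @inheritParams anova_filter
#' @param exact_n use exact enumeration when the stratum has at most this
#'   many samples (default 12).
#' @return a \code{PrefilterResult}.
#' @export
trend_filter <- function(ds, condition, timepoint, alpha = 0.05,
                         adjust = c("none", "BH"), exact_n = 12) {
  adjust <- match.arg(adjust)
  sl <- stratum_slice(ds, condition, timepoint)
  g_int <- as.integer(factor(sl$dose))   # doses already sorted ascending
  if (max(g_int) < 3) stop("need >= 3 ordered dose groups")
  n <- ncol(sl$values)
  use_exact <- n <= exact_n
  n_const <- 0L
  res <- t(apply(sl$values, 1, function(x) {
    if (length(unique(x)) == 1L) {
      n_const <<- n_const + 1L
      return(c(u = jt_statistic(x, g_int), p = 1))
    }
    u <- jt_statistic(x, g_int)
    tails <- if (use_exact && !anyDuplicated(x)) {
      jt_exact_pvals_noties(tabulate(g_int), u)
    } else if (use_exact && jt_enum_count(tabulate(g_int)) <= 20000) {
      jt_exact_pvals(x, g_int, u)
    } else jt_normal_pvals(x, g_int, u)
    c(u = u, p = min(1, 2 * min(tails)))
  }))
  if (n_const > 0)
    warning(n_const, " feature(s) with all values identical: p set to 1")
  df <- data.frame(feature = rownames(sl$values), statistic = res[, "u"],
                   p = res[, "p"], p_adj = stats::p.adjust(res[, "p"], "BH"),
                   stringsAsFactors = FALSE)
  new_prefilter_result(df, "trend", condition, timepoint, alpha, adjust)
}

#' Variance-moderated linear trend prefilter
#'
#' Per feature, fits the simple regression response ~ dose and tests the
#' slope with an empirical-Bayes moderated t statistic: the ensemble of
#' per-feature residual variances is used to estimate a prior (d0, s0^2) by
#' moment matching on the scaled-F distribution, each feature's variance is
#' shrunk to the posterior s2_tilde = (d0 s0^2 + d s^2) / (d0 + d), and the
#' slope t statistic with d0 + d degrees of freedom is computed. The prior
#' moment estimation uses \code{limma::fitFDist}.
#'
#' @inheritParams anova_filter
#' @param d0_override force the prior degrees of freedom (0 recovers the
#'   ordinary t-test, Inf fully pools variances); \code{NULL} (default)
#'   estimates it from the data.
#' @return a \code{PrefilterResult}.
#' @export
moderated_trend_filter <- function(ds, condition, timepoint, alpha = 0.05,
                                   adjust = c("none", "BH"),
                                   d0_override = NULL) {
  adjust <- match.arg(adjust)
  sl <- stratum_slice(ds, condition, timepoint)
  n <- ncol(sl$values)
  if (n < 4) stop("need >= 4 samples in the stratum")
  d <- sl$dose
  dc <- d - mean(d)
  sxx <- sum(dc^2)
  Y <- sl$values
  bhat <- as.vector(Y %*% dc) / sxx
  fitted_dev <- outer(bhat, dc)                 # slope part of fitted values
  resid <- Y - rowMeans(Y) - fitted_dev
  dfres <- n - 2
  s2 <- rowSums(resid^2) / dfres
  if (is.null(d0_override)) {
    fd <- limma::fitFDist(s2, df1 = dfres)
    d0 <- fd$df2; s02 <- fd$scale
  } else {
    d0 <- d0_override
    s02 <- mean(s2)
  }
  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2))
              else (d0 * s02 + dfres * s2) / (d0 + dfres)
  se <- sqrt(s2_tilde / sxx)
  tmod <- ifelse(se > 0, bhat / se, 0)
  dftot <- if (is.infinite(d0)) Inf else d0 + dfres
  p <- 2 * stats::pt(-abs(tmod), df = dftot)
  p[se == 0] <- 1
  df <- data.frame(feature = rownames(Y), statistic = tmod, p = p,
                   p_adj = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  out <- new_prefilter_result(df, "moderated_trend", condition, timepoint,
                              alpha, adjust)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}
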