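## Benchmark-dose core: a registry of dose-response mean functions, bounded
## multi-start least-squares fitting, BMR target mapping, BMD root finding,
## residual-bootstrap BMDL/BMDU, and AIC selection / Akaike-weight averaging.

BIG_RSS <- 1e300

#' Benchmark-response configuration
#'
#' @param kind \code{"relative"} (fractional shift r from baseline),
#'   \code{"absolute"} (shift A in response units) or \code{"sd"} (shift of k
#'   control standard deviations).
#' @param magnitude positive real: r, A or k for the respective kind. For the
#'   relative kind the magnitude must be < 1.
#' @param direction_policy \code{"auto"} (sign of the fitted response change
#'   over the tested range), \code{"up"} or \code{"down"}.
#' @return list of class \code{BMRConfig}.
#' @export
bmr_config <- function(kind = c("relative", "absolute", "sd"),
                       magnitude = 0.1,
                       direction_policy = c("auto", "up", "down")) {
  kind <- match.arg(kind)
  direction_policy <- match.arg(direction_policy)
  stopifnot(is.numeric(magnitude), length(magnitude) == 1, magnitude > 0)
  if (kind == "relative" && magnitude >= 1)
    stop("relative BMR magnitude must be < 1")
  structure(list(kind = kind, magnitude = magnitude,
                 direction_policy = direction_policy), class = "BMRConfig")
}

# ---------------------------------------------------------------------------
# Model registry

model_funs <- list(
  linear = function(d, th) th[1] + th[2] * d,
  power  = function(d, th) th[1] + th[2] * d^th[3],
  hill   = function(d, th) th[1] + th[2] * d^th[4] / (th[3]^th[4] + d^th[4]),
  exp2   = function(d, th) th[1] * exp(pmin(pmax(th[2] * d, -700), 700)),
  exp3   = function(d, th) th[1] * exp(pmin(pmax(th[4] * (d / th[2])^th[3], -700), 700)),
  exp4   = function(d, th) th[1] * (th[3] - (th[3] - 1) * exp(-d / th[2])),
  exp5   = function(d, th) th[1] * (th[3] - (th[3] - 1) * exp(-(d / th[2])^th[4]))
)
model_funs$poly2 <- function(d, th) th[1] + th[2] * d + th[3] * d^2

model_npar <- c(linear = 2, power = 3, hill = 4, exp2 = 2, exp3 = 4,
                exp4 = 3, exp5 = 4, poly2 = 3)

#' Dose-response model family
#'
#' The canonical benchmark-dose family: linear a + b d; power a + b d^g;
#' Hill a + b d^g / (k^g + d^g); exponential exp2 a e^{b d}; exp3
#' a e^{s (d/b)^g}; exp4 a (c - (c-1) e^{-d/b}); exp5
#' a (c - (c-1) e^{-(d/b)^g}); quadratic poly2 a + b1 d + b2 d^2. Power and
#' Hill exponents are bounded to [0.5, 18] to rule out infinite slope at
#' dose 0.
#'
#' @param names optional subset of model names; default all eight.
#' @return named list of \code{ModelSpec} objects (name, fun, npar).
#' @export
model_family <- function(names = NULL) {
  all <- names(model_funs)
  if (is.null(names)) names <- all
  unknown <- setdiff(names, all)
  if (length(unknown)) stop("unknown model(s): ", paste(unknown, collapse = ", "))
  out <- lapply(names, function(nm)
    structure(list(name = nm, fun = model_funs[[nm]],
                   npar = unname(model_npar[nm])), class = "ModelSpec"))
  names(out) <- names
  out
}

# parameter bounds for one model, dose-scaled so fits are equivariant to
# rescaling the dose axis
model_bounds <- function(name, d, y) {
  dmax <- max(d)
  amp <- max(abs(y), 1e-6)
  sgn <- if (mean(y) >= 0) 1 else -1
  switch(name,
    linear = list(lower = c(-1e9, -1e9), upper = c(1e9, 1e9)),
    poly2  = list(lower = rep(-1e9, 3), upper = rep(1e9, 3)),
    power  = list(lower = c(-1e9, -1e9, 0.5), upper = c(1e9, 1e9, 18)),
    hill   = list(lower = c(-1e9, -1e9, dmax * 1e-6, 0.5),
                  upper = c(1e9, 1e9, dmax * 1e3, 18)),
    exp2   = if (sgn > 0)
               list(lower = c(amp * 1e-9, -600 / dmax), upper = c(1e9, 600 / dmax))
             else
               list(lower = c(-1e9, -600 / dmax), upper = c(-amp * 1e-9, 600 / dmax)),
    exp3   = if (sgn > 0)
               list(lower = c(amp * 1e-9, dmax * 1e-3, 0.5, NA),
                    upper = c(1e9, dmax * 1e6, 18, NA))
             else
               list(lower = c(-1e9, dmax * 1e-3, 0.5, NA),
                    upper = c(-amp * 1e-9, dmax * 1e6, 18, NA)),
    exp4   = if (sgn > 0)
               list(lower = c(amp * 1e-9, dmax * 1e-3, 1e-6),
                    upper = c(1e9, dmax * 1e6, 1e6))
             else
               list(lower = c(-1e9, dmax * 1e-3, 1e-6),
                    upper = c(-amp * 1e-9, dmax * 1e6, 1e6)),
    exp5   = if (sgn > 0)
               list(lower = c(amp * 1e-9, dmax * 1e-3, 1e-6, 0.5),
                    upper = c(1e9, dmax * 1e6, 1e6, 18))
             else
               list(lower = c(-1e9, dmax * 1e-3, 1e-6, 0.5),
                    upper = c(-amp * 1e-9, dmax * 1e6, 1e6, 18))
  )
}

# 5 deterministic, data-driven starting points per model
model_starts <- function(name, d, y) {
  dmax <- max(d)
  y0 <- mean(y[d == min(d)])
  ym <- mean(y[d == max(d)])
  rng <- ym - y0
  if (rng == 0) rng <- max(stats::sd(y), 1e-3)
  a0 <- if (abs(y0) > 1e-9) y0 else sign(mean(y) + 1e-12) * max(abs(mean(y)), 1e-3)
  switch(name,
    linear = list(c(y0, rng / dmax)),
    poly2  = list(c(y0, rng / dmax, 0)),
    power  = lapply(c(0.5, 1, 2, 4, 8),
                    function(g) c(y0, rng / dmax^g, g)),
    hill   = list(c(y0, rng, dmax / 4, 1), c(y0, rng, dmax / 2, 2),
                  c(y0, 1.5 * rng, dmax / 4, 2), c(y0, rng, dmax / 8, 4),
                  c(y0, 2 * rng, dmax, 1)),
    exp2   = {
      b0 <- if (a0 != 0 && ym / a0 > 0) log(ym / a0) / dmax else
        sign(rng) * 0.1 / dmax
      list(c(a0, b0), c(a0, b0 / 2), c(a0, 2 * b0),
           c(mean(y), b0), c(a0, sign(rng) * 1 / dmax))
    },
    exp3   = {
      s <- if (rng >= 0) 1 else -1
      mag <- if (a0 != 0 && ym / a0 > 0) abs(log(ym / a0)) else 0.5
      mag <- max(mag, 1e-3)
      lapply(list(c(1, 1), c(2, 1), c(4, 1), c(1, 2), c(2, 2)), function(bg)
        c(a0, dmax / bg[1] * mag^(-1 / bg[2]), bg[2], s))
    },
    exp4   = {
      c0 <- if (a0 != 0) max(ym / a0, 1e-3) else 2
      list(c(a0, dmax / 2, c0), c(a0, dmax / 4, c0), c(a0, dmax, c0),
           c(a0, dmax / 2, 2 * c0), c(a0, dmax / 8, c0))
    },
    exp5   = {
      c0 <- if (a0 != 0) max(ym / a0, 1e-3) else 2
      list(c(a0, dmax / 2, c0, 1), c(a0, dmax / 4, c0, 2),
           c(a0, dmax, c0, 1), c(a0, dmax / 2, c0, 4),
           c(a0, dmax / 8, c0, 2))
    }
  )
}

# random starts: uniform within a dose- and amplitude-scaled box
model_random_start <- function(name, d, y) {
  dmax <- max(d)
  amp <- max(abs(y) - min(abs(y)), stats::sd(y), 1e-3)
  base <- mean(y)
  u <- function(lo, hi) stats::runif(1, lo, hi)
  switch(name,
    linear = c(u(base - amp, base + amp), u(-2 * amp / dmax, 2 * amp / dmax)),
    poly2  = c(u(base - amp, base + amp), u(-2 * amp / dmax, 2 * amp / dmax),
               u(-2 * amp / dmax^2, 2 * amp / dmax^2)),
    power  = c(u(base - amp, base + amp), u(-2 * amp, 2 * amp) / dmax^1,
               u(0.5, 8)),
    hill   = c(u(base - amp, base + amp), u(-3 * amp, 3 * amp),
               u(dmax / 20, dmax), u(0.5, 8)),
    exp2   = c(sign(base + 1e-12) * max(abs(base), 1e-3) * u(0.5, 1.5),
               u(-3, 3) / dmax),
    exp3   = c(sign(base + 1e-12) * max(abs(base), 1e-3) * u(0.5, 1.5),
               u(dmax / 10, 2 * dmax), u(0.5, 4), sample(c(-1, 1), 1)),
    exp4   = c(sign(base + 1e-12) * max(abs(base), 1e-3) * u(0.5, 1.5),
               u(dmax / 10, 2 * dmax), u(0.1, 5)),
    exp5   = c(sign(base + 1e-12) * max(abs(base), 1e-3) * u(0.5, 1.5),
               u(dmax / 10, 2 * dmax), u(0.1, 5), u(0.5, 4))
  )
}

rss_objective <- function(fun, d, y, fixed_tail = NULL) {
  function(th) {
    if (!is.null(fixed_tail)) th <- c(th, fixed_tail)
    f <- fun(d, th)
    if (any(!is.finite(f))) return(BIG_RSS)
    sum((y - f)^2)
  }
}

# single bounded optimization from one start; returns list(theta, rss) or NULL
optimize_from <- function(fun, d, y, start, lower, upper, fixed_tail = NULL,
                          factr = 1e7, maxit = 200, ndeps = 1e-3) {
  obj <- rss_objective(fun, d, y, fixed_tail)
  start <- pmin(pmax(start, lower), upper)
  fit <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = factr,
                                ndeps = rep(ndeps, length(start)))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= BIG_RSS) return(NULL)
  list(theta = if (is.null(fixed_tail)) fit$par else c(fit$par, fixed_tail),
       rss = fit$value)
}

#' Fit one dose-response model to one feature
#'
#' Bounded nonlinear least squares with multi-start: 5 deterministic
#' data-driven starts plus 5 seeded random starts; the best (lowest-RSS)
#' converged solution is kept. Linear and quadratic models are solved in
#' closed form. Reports RSS, R-squared (1 - RSS/TSS, with the 0/0 -> 0
#' convention for flat features) and the Gaussian AIC
#' n log(RSS/n) + 2 (p + 1), the error variance counted as a parameter.
#'
#' @param y response vector. @param d dose vector (same length).
#' @param spec a \code{ModelSpec} from \code{\link{model_family}}.
#' @param seed integer seed for the random starts (default 0).
#' @return list: model, theta, rss, r2, aic, npar, status
#'   (\code{"ok"}/\code{"fit_failed"}), fun.
#' @export
fit_feature <- function(y, d, spec, seed = 0) {
  stopifnot(length(y) == length(d), length(unique(d)) >= 3,
            length(y) >= spec$npar + 1)
  name <- spec$name
  if (name %in% c("linear", "poly2")) {
    X <- if (name == "linear") cbind(1, d) else cbind(1, d, d^2)
    cf <- stats::lm.fit(X, y)$coefficients
    cf[is.na(cf)] <- 0
    theta <- unname(cf)
    rss <- sum((y - spec$fun(d, theta))^2)
    best <- list(theta = theta, rss = rss)
  } else {
    bounds <- model_bounds(name, d, y)
    fixed_tail <- NULL
    lower <- bounds$lower; upper <- bounds$upper
    if (name == "exp3") {       # trend sign s is fixed from the data, not fit
      s <- if (mean(y[d == max(d)]) >= mean(y[d == min(d)])) 1 else -1
      fixed_tail <- s
      lower <- lower[1:3]; upper <- upper[1:3]
    }
    starts <- model_starts(name, d, y)
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(seed + 1000L)
    rand_starts <- replicate(5, model_random_start(name, d, y),
                             simplify = FALSE)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    all_starts <- c(starts, rand_starts)
    best <- NULL
    for (st in all_starts) {
      st_use <- if (!is.null(fixed_tail)) st[seq_along(lower)] else st
      res <- optimize_from(spec$fun, d, y, st_use, lower, upper, fixed_tail)
      if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
    }
    if (!is.null(best)) {      # polish the winner at tight tolerance
      st_use <- if (!is.null(fixed_tail)) best$theta[seq_along(lower)]
                else best$theta
      pol <- optimize_from(spec$fun, d, y, st_use, lower, upper, fixed_tail,
                           factr = 10, maxit = 1000, ndeps = 1e-7)
      if (!is.null(pol) && pol$rss < best$rss) best <- pol
      # a second polish pass helps when the first moved a long way
      st_use <- if (!is.null(fixed_tail)) best$theta[seq_along(lower)]
                else best$theta
      pol <- optimize_from(spec$fun, d, y, st_use, lower, upper, fixed_tail,
                           factr = 10, maxit = 1000, ndeps = 1e-7)
      if (!is.null(pol) && pol$rss < best$rss) best <- pol
    }
    if (is.null(best))
      return(list(model = name, theta = NULL, rss = NA_real_, r2 = NA_real_,
                  aic = NA_real_, npar = spec$npar, status = "fit_failed",
                  fun = spec$fun))
  }
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else 0
  rss_c <- max(best$rss, 1e-300)
  aic <- n * log(rss_c / n) + 2 * (spec$npar + 1)
  list(model = name, theta = best$theta, rss = best$rss, r2 = r2, aic = aic,
       npar = spec$npar, status = "ok", fun = spec$fun)
}

#' Map a benchmark response onto a fitted curve
#'
#' Baseline is the fitted response at dose 0. The target level is
#' baseline * (1 +/- r) for the relative kind, baseline +/- A for absolute,
#' baseline +/- k * SD(controls) for the SD kind, the sign following the
#' response direction (the sign of f(d_max) - f(0) under the auto policy).
#'
#' @param fit a fit from \code{\link{fit_feature}} with status ok.
#' @param y_control observed control (dose 0) responses; needed (>= 2 values)
#'   for the SD kind.
#' @param cfg a \code{\link{bmr_config}}.
#' @param d_max maximum tested dose (defines the auto direction).
#' @return list: target, direction (\code{"up"}/\code{"down"}), baseline.
#' @export
bmr_target <- function(fit, y_control, cfg, d_max) {
  stopifnot(inherits(cfg, "BMRConfig"), fit$status == "ok")
  f0 <- fit$fun(0, fit$theta)
  fm <- fit$fun(d_max, fit$theta)
  direction <- switch(cfg$direction_policy,
    auto = if (fm >= f0) "up" else "down",
    up = "up", down = "down")
  sgn <- if (direction == "up") 1 else -1
  target <- switch(cfg$kind,
    relative = {
      if (f0 == 0) stop("relative BMR undefined at baseline 0")
      f0 * (1 + sgn * cfg$magnitude * sign(f0))
    },
    absolute = f0 + sgn * cfg$magnitude,
    sd = {
      if (length(y_control) < 2)
        stop("SD-based BMR needs >= 2 control replicates")
      f0 + sgn * cfg$magnitude * stats::sd(y_control)
    })
  list(target = target, direction = direction, baseline = f0)
}

#' Solve for the benchmark dose on a fitted curve
#'
#' Finds the smallest dose in (0, d_max] at which the fitted response shift
#' from baseline reaches the target shift in the required direction, by
#' scanning 1024 uniformly spaced grid points and refining the bracketing
#' interval by bisection to relative tolerance 1e-8.
#'
#' @param fit fit from \code{\link{fit_feature}}.
#' @param target target response level (from \code{\link{bmr_target}}).
#' @param direction \code{"up"} or \code{"down"}.
#' @param d_max maximum tested dose.
#' @return the BMD (numeric) or \code{NA} when the shift is never reached
#'   within the tested range (no crossing).
#' @export
solve_bmd <- function(fit, target, direction, d_max) {
  f <- fit$fun; th <- fit$theta
  f0 <- f(0, th)
  shift <- abs(target - f0)
  if (shift == 0) return(NA_real_)
  sgn <- if (direction == "up") 1 else -1
  h <- function(d) (f(d, th) - f0) * sgn - shift
  grid <- seq(0, d_max, length.out = 1025)[-1]
  hv <- h(grid)
  idx <- which(hv >= 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  lo <- if (i == 1) 0 else grid[i - 1]
  hi <- grid[i]
  # bisection: h(lo) < 0 <= h(hi)
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) >= 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-8 * hi) break
  }
  hi
}

#' Residual-bootstrap confidence bounds for a BMD
#'
#' Centers the fit residuals, inflates them by sqrt(n / (n - p)) to undo the
#' variance deflation of least-squares residuals, resamples them with
#' replacement B times, refits the model (starting from the original
#' estimate), recomputes the BMR target and re-solves the BMD. BMDL and BMDU
#' are the 2.5th and 97.5th percentiles of the successful bootstrap BMDs,
#' reported only when at least half of the replicates yield a BMD.
#'
#' @param y,d data used for the original fit. @param spec the ModelSpec.
#' @param fit the original fit (status ok, with a valid BMD).
#' @param cfg a \code{\link{bmr_config}}. @param B replicates (default 250).
#' @param seed integer seed. @param level confidence level (default 0.95).
#' @return list: bmdl, bmdu (NA when < 50 percent of replicates succeed),
#'   n_success.
#' @export
bmd_interval <- function(y, d, spec, fit, cfg, B = 250, seed = 1,
                         level = 0.95) {
  stopifnot(fit$status == "ok")
  fitted <- fit$fun(d, fit$theta)
  res <- y - fitted
  res <- res - mean(res)
  if (any(res != 0))
    res <- res * sqrt(length(y) / max(length(y) - spec$npar, 1))
  d_max <- max(d)
  is_closed <- spec$name %in% c("linear", "poly2")
  bounds <- if (!is_closed) model_bounds(spec$name, d, y) else NULL
  fixed_tail <- NULL
  if (!is_closed && spec$name == "exp3") {
    fixed_tail <- fit$theta[4]
    bounds$lower <- bounds$lower[1:3]; bounds$upper <- bounds$upper[1:3]
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  boot_bmd <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    ystar <- fitted + sample(res, length(res), replace = TRUE)
    if (is_closed) {
      X <- if (spec$name == "linear") cbind(1, d) else cbind(1, d, d^2)
      cf <- stats::lm.fit(X, ystar)$coefficients
      cf[is.na(cf)] <- 0
      refit <- list(model = spec$name, theta = unname(cf), fun = spec$fun,
                    status = "ok")
    } else {
      start <- if (is.null(fixed_tail)) fit$theta
               else fit$theta[seq_along(bounds$lower)]
      opt <- optimize_from(spec$fun, d, ystar, start, bounds$lower,
                           bounds$upper, fixed_tail)
      if (is.null(opt)) next
      refit <- list(model = spec$name, theta = opt$theta, fun = spec$fun,
                    status = "ok")
    }
    tg <- tryCatch(
      bmr_target(refit, ystar[d == min(d)], cfg, d_max),
      error = function(e) NULL)
    if (is.null(tg)) next
    boot_bmd[b] <- solve_bmd(refit, tg$target, tg$direction, d_max)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  ok <- boot_bmd[!is.na(boot_bmd)]
  if (length(ok) < B / 2)
    return(list(bmdl = NA_real_, bmdu = NA_real_, n_success = length(ok)))
  alpha <- (1 - level) / 2
  q <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(bmdl = q[1], bmdu = q[2], n_success = length(ok))
}

#' Akaike weights
#' @param aic vector of AIC values.
#' @return weights exp(-(AIC - min AIC)/2), normalized to sum 1.
#' @export
akaike_weights <- function(aic) {
  w <- exp(-(aic - min(aic)) / 2)
  w / sum(w)
}

#' Select the best model or average across models for one feature
#'
#' Fits with R-squared below \code{r2_min} (default 0.6) or without a valid
#' BMD are discarded. In AIC mode the minimum-AIC survivor provides the BMD
#' triple; in average mode survivors are combined with Akaike weights
#' (weighted arithmetic means of BMD, BMDL, BMDU). The dose-dependent-gene
#' (ddg) flag is true iff at least one survivor remains.
#'
#' @param fits data.frame of per-model fit rows with columns model, r2, aic,
#'   bmd, bmdl, bmdu, status.
#' @param mode \code{"AIC"} or \code{"average"}.
#' @param r2_min minimum R-squared for a fit to survive (default 0.6).
#' @return list: bmd, bmdl, bmdu, models, weights, ddg, n_survivors.
#' @export
select_or_average <- function(fits, mode = c("AIC", "average"), r2_min = 0.6) {
  mode <- match.arg(mode)
  stopifnot(nrow(fits) >= 1)
  surv <- fits[fits$status == "ok" & !is.na(fits$bmd) &
                 !is.na(fits$r2) & fits$r2 >= r2_min, , drop = FALSE]
  if (nrow(surv) == 0)
    return(list(bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
                models = character(0), weights = numeric(0), ddg = FALSE,
                n_survivors = 0L))
  if (mode == "AIC") {
    i <- which.min(surv$aic)
    sel <- surv[i, ]
    return(list(bmd = sel$bmd, bmdl = sel$bmdl, bmdu = sel$bmdu,
                models = sel$model, weights = 1, ddg = TRUE,
                n_survivors = nrow(surv)))
  }
  w <- akaike_weights(surv$aic)
  wmean <- function(x) if (anyNA(x)) NA_real_ else sum(w * x)
  list(bmd = wmean(surv$bmd), bmdl = wmean(surv$bmdl),
       bmdu = wmean(surv$bmdu), models = surv$model, weights = w, ddg = TRUE,
       n_survivors = nrow(surv))
}

#' Run benchmark-dose modeling on a stratum
#'
#' Fits the full model family to every feature passing the prefilter, maps
#' the configured BMR onto each fitted curve, solves for the BMD, optionally
#' bootstraps BMDL/BMDU for the surviving fits, and selects or averages
#' across models. Per-feature failures become status codes; the batch never
#' aborts. BMDs beyond the highest tested dose are never reported (the root
#' search is confined to the tested range).
#'
#' @param ds a \code{DoseResponseDataset}. @param condition,timepoint stratum.
#' @param prefilter a \code{PrefilterResult} computed on the same stratum
#'   (only passing features are fitted); \code{NULL} fits all features.
#' @param cfg a \code{\link{bmr_config}}.
#' @param mode \code{"AIC"} or \code{"average"}. @param r2_min default 0.6.
#' @param models optional model-name subset.
#' @param bootstrap_B bootstrap replicates for BMDL/BMDU (0 disables bounds).
#' @param seed integer seed for random starts and bootstrap.
#' @param ratio_max optional BMDU/BMDL precision filter (NA = off).
#' @param bmd_bmdl_max optional BMD/BMDL filter (NA = off).
#' @return object of class \code{BMDResult}: \code{$table} (one row per
#'   fitted feature: feature, condition, timepoint, bmd, bmdl, bmdu, models,
#'   weights, best_r2, status, ddg) and \code{$fits} (per-feature model fits
#'   for downstream curve prediction), plus the run configuration.
#' @export
run_bmd <- function(ds, condition, timepoint, prefilter = NULL,
                    cfg = bmr_config(), mode = c("AIC", "average"),
                    r2_min = 0.6, models = NULL, bootstrap_B = 0, seed = 1,
                    ratio_max = NA, bmd_bmdl_max = NA) {
  mode <- match.arg(mode)
  sl <- stratum_slice(ds, condition, timepoint)
  feats <- rownames(sl$values)
  if (!is.null(prefilter)) {
    stopifnot(inherits(prefilter, "PrefilterResult"))
    feats <- intersect(feats, prefilter$feature[prefilter$pass])
  }
  d <- sl$dose
  d_max <- max(d)
  specs <- model_family(models)
  rows <- vector("list", length(feats))
  fit_store <- vector("list", length(feats))
  names(fit_store) <- feats
  for (fi in seq_along(feats)) {
    fname <- feats[fi]
    y <- sl$values[fname, ]
    y_ctrl <- y[d == min(d)]
    per_model <- lapply(specs, function(sp) {
      ft <- fit_feature(y, d, sp, seed = seed)
      bmd <- bmdl <- bmdu <- NA_real_
      status <- ft$status
      if (ft$status == "ok") {
        tg <- tryCatch(bmr_target(ft, y_ctrl, cfg, d_max),
                       error = function(e) NULL)
        if (is.null(tg)) {
          status <- "fit_failed"
        } else {
          bmd <- solve_bmd(ft, tg$target, tg$direction, d_max)
          status <- if (is.na(bmd)) "no_crossing" else "ok"
        }
      }
      list(fit = ft, bmd = bmd, bmdl = bmdl, bmdu = bmdu, status = status)
    })
    fdf <- data.frame(
      model = vapply(per_model, function(m) m$fit$model, character(1)),
      r2 = vapply(per_model, function(m) m$fit$r2, numeric(1)),
      aic = vapply(per_model, function(m) m$fit$aic, numeric(1)),
      bmd = vapply(per_model, function(m) m$bmd, numeric(1)),
      bmdl = NA_real_, bmdu = NA_real_,
      status = vapply(per_model, function(m) m$status, character(1)),
      stringsAsFactors = FALSE)
    if (bootstrap_B > 0) {
      for (mi in seq_len(nrow(fdf))) {
        if (fdf$status[mi] == "ok" && !is.na(fdf$r2[mi]) &&
            fdf$r2[mi] >= r2_min) {
          iv <- bmd_interval(y, d, specs[[fdf$model[mi]]],
                             per_model[[mi]]$fit, cfg, B = bootstrap_B,
                             seed = seed + mi)
          fdf$bmdl[mi] <- iv$bmdl; fdf$bmdu[mi] <- iv$bmdu
        }
      }
    }
    sel <- select_or_average(fdf, mode = mode, r2_min = r2_min)
    status <- if (sel$ddg) "ok" else if (all(fdf$status == "no_crossing"))
      "no_crossing" else if (all(fdf$status == "fit_failed")) "fit_failed"
      else "filtered"
    ddg <- sel$ddg
    # optional precision filters
    if (ddg && !is.na(ratio_max) && !is.na(sel$bmdl) && !is.na(sel$bmdu) &&
        sel$bmdl > 0 && sel$bmdu / sel$bmdl > ratio_max) {
      ddg <- FALSE; status <- "filtered"
    }
    if (ddg && !is.na(bmd_bmdl_max) && !is.na(sel$bmdl) && sel$bmdl > 0 &&
        sel$bmd / sel$bmdl > bmd_bmdl_max) {
      ddg <- FALSE; status <- "filtered"
    }
    rows[[fi]] <- data.frame(
      feature = fname, condition = condition, timepoint = timepoint,
      bmd = sel$bmd, bmdl = sel$bmdl, bmdu = sel$bmdu,
      models = paste(sel$models, collapse = ","),
      weights = paste(sprintf("%.6g", sel$weights), collapse = ","),
      best_r2 = if (any(!is.na(fdf$r2))) max(fdf$r2, na.rm = TRUE) else NA_real_,
      status = status, ddg = ddg, stringsAsFactors = FALSE)
    fit_store[[fname]] <- list(per_model = per_model, selection = sel,
                               fits_table = fdf)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), condition = character(),
               timepoint = character(), bmd = numeric(), bmdl = numeric(),
               bmdu = numeric(), models = character(), weights = character(),
               best_r2 = numeric(), status = character(), ddg = logical())
  rownames(table) <- NULL
  structure(list(table = table, fits = fit_store, cfg = cfg, mode = mode,
                 r2_min = r2_min, d_max = d_max, condition = condition,
                 timepoint = timepoint),
            class = "BMDResult")
}

#' @export
print.BMDResult <- function(x, ...) {
  cat("BMDResult (", x$condition, "/", x$timepoint, "): ",
      nrow(x$table), " features fitted, ", sum(x$table$ddg),
      " dose-dependent (mode ", x$mode, ")\n", sep = "")
  invisible(x)
}
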