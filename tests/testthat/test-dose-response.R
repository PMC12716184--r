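test_that("the model registry has the full family with correct limits", {
  fam <- model_family()
  expect_length(fam, 8)
  expect_setequal(names(fam), c("linear", "power", "hill", "exp2", "exp3",
                                "exp4", "exp5", "poly2"))
  expect_error(model_family("logistic9"), "unknown model")
  # hill at dose 0 reduces to the baseline parameter
  hill <- fam$hill$fun
  for (th in list(c(2, 1, 5, 2), c(-1, 3, 0.5, 1), c(0, 1, 10, 4)))
    expect_equal(hill(0, th), th[1])
  # exp4 saturates at a * c
  exp4 <- fam$exp4$fun
  expect_equal(exp4(1e9, c(2, 3, 1.5)), 2 * 1.5, tolerance = 1e-12)
})

test_that("fit_feature interpolates exact data and honors conventions", {
  d <- default_doses()
  fam <- model_family()
  # exact linear data
  ft <- fit_feature(2 + 3 * d, d, fam$linear)
  expect_equal(ft$theta, c(2, 3), tolerance = 1e-9)
  expect_equal(ft$r2, 1)
  expect_lt(ft$rss, 1e-18)
  # constant response: zero slope and the R2 = 0 convention for TSS = 0
  ft0 <- fit_feature(rep(4, length(d)), d, fam$linear)
  expect_equal(ft0$theta[2], 0, tolerance = 1e-12)
  expect_equal(ft0$r2, 0)
  # noiseless hill data recovers the generating parameters
  th <- c(0, 1, 5, 2)
  ft_h <- fit_feature(fam$hill$fun(d, th), d, fam$hill, seed = 1)
  expect_equal(ft_h$theta, th, tolerance = 1e-3)
  expect_gt(ft_h$r2, 1 - 1e-9)
})

test_that("bmr_target maps each BMR kind onto the fitted curve", {
  lin_up <- list(fun = model_family("linear")[[1]]$fun, theta = c(10, 2),
                 status = "ok")
  tg <- bmr_target(lin_up, y_control = c(10, 10), bmr_config("relative", 0.1),
                   d_max = 10)
  expect_equal(tg$target, 11)
  expect_equal(tg$direction, "up")
  lin_down <- list(fun = lin_up$fun, theta = c(10, -2), status = "ok")
  tg2 <- bmr_target(lin_down, c(10, 10), bmr_config("absolute", 0.5), 10)
  expect_equal(tg2$target, 9.5)
  expect_equal(tg2$direction, "down")
  tg3 <- bmr_target(lin_up, y_control = c(1, 2, 3), bmr_config("sd", 1), 10)
  expect_equal(tg3$target, 10 + sd(c(1, 2, 3)))  # baseline 10 + 1 SD = 11
  expect_error(bmr_target(lin_up, y_control = c(5), bmr_config("sd", 1), 10),
               "control replicates")
  zero_base <- list(fun = lin_up$fun, theta = c(0, 2), status = "ok")
  expect_error(bmr_target(zero_base, c(0, 0), bmr_config("relative", 0.1), 10),
               "baseline 0")
})

test_that("solve_bmd matches closed-form inversions and flags no crossing", {
  fam <- model_family()
  lin <- list(fun = fam$linear$fun, theta = c(10, 2))
  expect_equal(solve_bmd(lin, target = 11, "up", 10), 0.5, tolerance = 1e-7)
  hill <- list(fun = fam$hill$fun, theta = c(0, 1, 5, 2))
  # d^2/(25+d^2) = 0.1  =>  d = 5/3
  expect_equal(solve_bmd(hill, target = 0.1, "up", 20), 5 / 3,
               tolerance = 1e-6)
  # rising-then-falling quadratic never reaches a target above its maximum
  pol <- list(fun = fam$poly2$fun, theta = c(0, 2, -0.5))  # peak 2 at d = 2
  expect_true(is.na(solve_bmd(pol, target = 5, "up", 10)))
})

test_that("bmd_interval degenerates correctly and is deterministic", {
  d <- default_doses()
  fam <- model_family()
  cfg <- bmr_config("relative", 0.1)
  y <- fam$linear$fun(d, c(5, 0.5))
  ft <- fit_feature(y, d, fam$linear)
  tg <- bmr_target(ft, y[d == 0], cfg, max(d))
  bmd <- solve_bmd(ft, tg$target, tg$direction, max(d))
  # all-zero residuals: bounds collapse onto the BMD
  iv <- bmd_interval(y, d, fam$linear, ft, cfg, B = 50, seed = 3)
  expect_equal(iv$bmdl, bmd, tolerance = 1e-9)
  expect_equal(iv$bmdu, bmd, tolerance = 1e-9)
  # fixed seed, noisy data: identical bounds across runs
  set.seed(10); yn <- y + rnorm(length(y), 0, 0.2)
  ftn <- fit_feature(yn, d, fam$linear)
  iv1 <- bmd_interval(yn, d, fam$linear, ftn, cfg, B = 100, seed = 11)
  iv2 <- bmd_interval(yn, d, fam$linear, ftn, cfg, B = 100, seed = 11)
  expect_identical(iv1, iv2)
  expect_true(iv1$bmdl <= iv1$bmdu)
})

test_that("select_or_average follows the Akaike-weight algebra", {
  base <- data.frame(model = c("m1", "m2"), r2 = c(0.9, 0.9),
                     aic = c(100, 102), bmd = c(1, 2), bmdl = c(0.5, 1.5),
                     bmdu = c(1.5, 2.5), status = "ok",
                     stringsAsFactors = FALSE)
  out <- select_or_average(base, mode = "average")
  w1 <- 1 / (1 + exp(-1))
  expect_equal(out$weights, c(w1, 1 - w1), tolerance = 1e-12)
  expect_equal(sum(out$weights), 1, tolerance = 1e-12)
  expect_equal(out$bmd, w1 * 1 + (1 - w1) * 2)
  # equal AIC averages plainly
  eq <- base; eq$aic <- c(100, 100)
  expect_equal(select_or_average(eq, mode = "average")$bmd, 1.5)
  # AIC mode picks the minimum-AIC survivor
  sel <- select_or_average(base, mode = "AIC")
  expect_equal(sel$models, "m1")
  expect_equal(sel$bmd, 1)
  # single survivor: averaging is the identity
  one <- base[1, ]
  avg1 <- select_or_average(one, mode = "average")
  expect_equal(avg1$bmd, one$bmd)
  expect_equal(avg1$bmdl, one$bmdl)
  expect_equal(avg1$weights, 1)
  # R2 filter removes poor fits; none left -> no ddg
  poor <- base; poor$r2 <- c(0.5, 0.55)
  none <- select_or_average(poor, mode = "AIC")
  expect_false(none$ddg)
  expect_true(is.na(none$bmd))
  # mixed: only the good fit survives
  mix <- base; mix$r2 <- c(0.95, 0.3)
  expect_equal(select_or_average(mix, mode = "average")$models, "m1")
})

test_that("run_bmd flags planted genes, not flat ones, and is reproducible", {
  fam <- model_family()
  curves <- c(
    lapply(1:4, function(i) {
      th <- c(5, 1.5, 2 + i, 2)
      function(d) fam$hill$fun(d, th)
    }),
    lapply(1:6, function(i) function(d) rep(5 + 0.1 * i, length(d))))
  names(curves) <- sprintf("g%02d", 1:10)
  ds <- make_curve_dataset(curves, noise_sd = 0.1, seed = 21)
  pf <- anova_filter(ds, "trt", "24h")
  res1 <- run_bmd(ds, "trt", "24h", prefilter = pf, seed = 5)
  res2 <- run_bmd(ds, "trt", "24h", prefilter = pf, seed = 5)
  expect_identical(res1$table, res2$table)
  ddgs <- res1$table$feature[res1$table$ddg]
  expect_true(all(ddgs %in% sprintf("g%02d", 1:4)))
  expect_gte(length(ddgs), 3)
  # every reported BMD respects its bounds and the tested range
  ok <- res1$table[res1$table$ddg, ]
  expect_true(all(ok$bmd > 0 & ok$bmd <= 20))
})

test_that("BMDs scale with the dose axis (equivariance)", {
  fam <- model_family()
  th <- c(5, 1.5, 4, 2)
  cfg <- bmr_config("relative", 0.1)
  for (c_scale in c(0.5, 3)) {
    d1 <- default_doses()
    d2 <- d1 * c_scale
    y <- fam$hill$fun(d1, th)          # same responses, rescaled doses
    f1 <- fit_feature(y, d1, fam$hill, seed = 2)
    f2 <- fit_feature(y, d2, fam$hill, seed = 2)
    t1 <- bmr_target(f1, y[d1 == 0], cfg, max(d1))
    t2 <- bmr_target(f2, y[d2 == 0], cfg, max(d2))
    b1 <- solve_bmd(f1, t1$target, t1$direction, max(d1))
    b2 <- solve_bmd(f2, t2$target, t2$direction, max(d2))
    expect_equal(b2 / b1, c_scale, tolerance = 1e-4)
  }
})
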