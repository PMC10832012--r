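test_that("the default registry holds the seven clinical pairings", {
  reg <- kbp_default_models()
  expect_length(reg, 7)
  key <- vapply(reg, function(s)
    paste(s$oar, s$metric, s$predictor, s$target), "")
  expect_setequal(unname(key), c(
    "Rectum V60Gy overlap_fraction PTV76",
    "Rectum V70Gy overlap_fraction PTV76",
    "Bladder V60Gy overlap_fraction PTV76",
    "Bladder V70Gy overlap_fraction PTV76",
    "PeritonealCavity Davg centroid_distance PTV46",
    "PeritonealCavity V45Gy overlap_fraction PTV46",
    "PeritonealCavity V15Gy overlap_times_volume PTV46"))
  expect_equal(reg$cavity_v15$predictor_unit, "cc2")
})

test_that("predictors dispatch to the right geometric feature", {
  g <- grid_geometry(spacing = 1, dim = c(20, 20, 12))  # 1 cc voxels
  rectum <- box_mask(g, c(1, 4), c(1, 4), c(1, 4), "Rectum")
  ptv76 <- box_mask(g, c(10, 14), c(10, 14), c(5, 8), "PTV76")
  structures <- list(Rectum = rectum, PTV76 = ptv76)
  reg <- kbp_default_models()
  expect_equal(extract_predictor(reg$rectum_v60, structures), 0)  # fully outside

  # cavity centroid exactly 5 cm from the PTV46 centroid
  ptv46 <- box_mask(g, c(3, 5), c(3, 5), c(3, 5), "PTV46")   # centroid (3,3,3)
  cav <- box_mask(g, c(6, 8), c(7, 9), c(3, 5), "PeritonealCavity")  # (6,7,3)
  st2 <- list(PTV46 = ptv46, PeritonealCavity = cav)
  expect_equal(extract_predictor(reg$cavity_davg, st2), 5)

  # product predictor: 1000 cc cavity with 50 cc overlap -> 5e4 cc^2
  cav2 <- box_mask(g, c(1, 10), c(1, 10), c(1, 10), "PeritonealCavity")
  ptv46b <- box_mask(g, c(1, 10), c(1, 5), c(1, 1), "PTV46")
  expect_equal(structure_volume(cav2), 1000)
  expect_equal(overlap_volume(cav2, ptv46b), 50)
  expect_equal(extract_predictor(reg$cavity_v15,
                                 list(PeritonealCavity = cav2, PTV46 = ptv46b)),
               5e4)

  expect_error(extract_predictor(reg$bladder_v60, structures), "bladder_v60")
})

test_that("OLS fit recovers exact lines and minimizes SSE", {
  spec <- kbp_default_models()$rectum_v60
  x <- c(0, 5, 12, 20, 30)
  fit <- fit_kbp_model(spec, x, 2 * x + 1)
  expect_equal(fit$A, 2)
  expect_equal(fit$B, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$residual_sd, 0)

  # grid-search oracle on {(0,0),(1,1),(2,0)} -> A = 0, B = 1/3
  fit2 <- fit_kbp_model(spec, c(0, 1, 2), c(0, 1, 0))
  grid <- expand.grid(A = seq(-1, 1, by = 0.001), B = seq(-1, 1, by = 0.001))
  sse <- with(grid, (0 - (A * 0 + B))^2 + (1 - (A * 1 + B))^2 + (0 - (A * 2 + B))^2)
  best <- grid[which.min(sse), ]
  expect_equal(fit2$A, best$A, tolerance = 2e-3)
  expect_equal(fit2$B, best$B, tolerance = 2e-3)
  expect_equal(fit2$A, 0, tolerance = 1e-12)
  expect_equal(fit2$B, 1 / 3)

  expect_error(fit_kbp_model(spec, c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_kbp_model(spec, c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("R-squared equals the squared Pearson correlation", {
  spec <- kbp_default_models()$bladder_v60
  set.seed(101)
  x <- runif(30, 0, 25)
  y <- 1.3 * x + 2 + rnorm(30, 0, 2)
  fit <- fit_kbp_model(spec, x, y)
  expect_equal(fit$r_squared, cor(x, y)^2)
})

test_that("parameter estimates cover the truth at their nominal rate", {
  spec <- kbp_default_models()$rectum_v60
  A <- 0.9; B <- 2; s <- 1; n <- 25
  hits_A <- 0; hits_B <- 0
  set.seed(2024)
  for (r in 1:500) {
    x <- runif(n, 0, 30)
    y <- A * x + B + rnorm(n, 0, s)
    f <- fit_kbp_model(spec, x, y)
    tq <- qt(0.975, n - 2)
    se_A <- f$residual_sd / sqrt(f$sxx)
    se_B <- f$residual_sd * sqrt(1 / n + f$x_bar^2 / f$sxx)
    if (abs(f$A - A) <= tq * se_A) hits_A <- hits_A + 1
    if (abs(f$B - B) <= tq * se_B) hits_B <- hits_B + 1
  }
  expect_gte(hits_A / 500, 0.93)
  expect_gte(hits_B / 500, 0.93)
})

test_that("slope and intercept bias shrink as the cohort grows", {
  spec <- kbp_default_models()$rectum_v60
  A <- 1.6; B <- 2; s <- 2
  rmse_A <- sapply(c(10, 25, 100), function(n) {
    set.seed(300 + n)
    errs <- replicate(200, {
      x <- runif(n, 0, 30)
      fit_kbp_model(spec, x, A * x + B + rnorm(n, 0, s))$A - A
    })
    sqrt(mean(errs^2))
  })
  expect_true(all(diff(rmse_A) < 0))
  expect_lt(rmse_A[3], 0.1)
})

test_that("prediction intervals behave and match the lm oracle", {
  spec <- kbp_default_models()$rectum_v60
  x <- c(0, 4, 9, 15, 22, 30)
  y_exact <- 1.5 * x + 3
  fit0 <- fit_kbp_model(spec, x, y_exact)
  pr0 <- predict_with_interval(fit0, 10)
  expect_equal(pr0$lower, pr0$predicted)   # residual sd 0 collapses the band
  expect_equal(pr0$upper, pr0$predicted)

  set.seed(7)
  y <- 1.5 * x + 3 + rnorm(6)
  fit <- fit_kbp_model(spec, x, y)
  # at the training mean the prediction is exactly the response mean
  pr_mean <- predict_with_interval(fit, mean(x))
  expect_equal(pr_mean$predicted, mean(y))
  # half-width is minimal at x_bar and grows with |x - x_bar|
  xs <- seq(-10, 40, by = 1)
  hw <- with(predict_with_interval(fit, xs), (upper - lower) / 2)
  expect_equal(xs[which.min(hw)], xs[which.min(abs(xs - mean(x)))])
  expect_true(all(diff(hw[xs >= mean(x)]) > 0))
  expect_true(all(diff(hw[xs <= mean(x)]) < 0))
  # closed-form large-n limit at x = x_bar
  expect_equal(hw[xs == 15][1],
               qt(0.975, fit$n - 2) * fit$residual_sd *
                 sqrt(1 + 1 / fit$n + (15 - fit$x_bar)^2 / fit$sxx))

  # independent oracle: predict.lm with interval = "prediction"
  lmfit <- lm(y ~ x, data = data.frame(x = x, y = y))
  new <- data.frame(x = c(2.5, 15, 33))
  orc <- predict(lmfit, new, interval = "prediction", level = 0.95)
  mine <- predict_with_interval(fit, new$x)
  expect_equal(mine$predicted, unname(orc[, "fit"]))
  expect_equal(mine$lower, unname(orc[, "lwr"]))
  expect_equal(mine$upper, unname(orc[, "upr"]))

  expect_error(predict_with_interval(fit, 5, level = 1.2), "level")
})

test_that("fitted models serialize to YAML and reload exactly", {
  cohort <- make_cohort(cohort_spec(n = 20, seed = 5))
  models <- fit_models_from_table(kbp_default_models(), cohort$table)
  path <- tempfile(fileext = ".yaml")
  write_kbp_models(models, path)
  back <- read_kbp_models(path)
  expect_setequal(names(back), names(models))
  for (id in names(models)) {
    for (field in c("A", "B", "n", "r_squared", "residual_sd", "x_bar", "sxx"))
      expect_identical(back[[id]][[field]], models[[id]][[field]],
                       label = paste(id, field))
    expect_equal(predict_with_interval(back[[id]], 7),
                 predict_with_interval(models[[id]], 7))
  }
  expect_error(suppressWarnings(read_kbp_models(tempfile())), "cannot open")
  writeLines("format: something-else", path)
  expect_error(read_kbp_models(path), "version-1")
})

test_that("audit flags compare achieved metrics to the prediction band", {
  g <- grid_geometry(spacing = 1, dim = c(20, 20, 10))
  rectum <- box_mask(g, c(1, 5), c(1, 5), c(1, 4), "Rectum")
  ptv76 <- box_mask(g, c(3, 8), c(3, 8), c(1, 4), "PTV76")
  structures <- list(Rectum = rectum, PTV76 = ptv76)
  xov <- overlap_fraction(rectum, ptv76)

  spec <- kbp_default_models()$rectum_v60
  set.seed(9)
  xs <- runif(20, 0, 40); ys <- 1.0 * xs + 0 + rnorm(20, 0, 1)
  model <- fit_kbp_model(spec, xs, ys)
  band <- predict_with_interval(model, xov)

  make_plan <- function(v60_pct) {
    d <- array(0, g$dim)
    n_hot <- round(v60_pct / 100 * sum(rectum$occupancy))
    d[which(rectum$occupancy)[seq_len(n_hot)]] <- 65
    dose_grid(d, g)
  }
  achieved_at <- function(frac) band$predicted * frac
  # achieved right at the prediction -> within
  res_mid <- audit_plan(make_plan(band$predicted), structures, list(model))
  expect_equal(res_mid$status, "within")
  # achieved far above the upper bound -> suboptimal
  res_hi <- audit_plan(make_plan(min(99, band$upper * 1.8)), structures, list(model))
  expect_equal(res_hi$status, "above_upper")

  # a model whose structures are missing is reported, others still run
  models <- list(model, fit_kbp_model(kbp_default_models()$cavity_davg,
                                      c(4, 8, 12), c(25, 18, 12)))
  res <- audit_plan(make_plan(band$predicted), structures, models)
  expect_equal(res$status[1], "within")
  expect_true(is.na(res$status[2]) && grepl("cavity_davg", res$error[2]))
})

test_that("plans simulated on the model line are rarely flagged", {
  spec <- kbp_default_models()$bladder_v70
  A <- 1.1; B <- 0.3; s <- 1.2
  set.seed(55)
  flagged <- replicate(400, {
    x <- runif(25, 0, 30)
    m <- fit_kbp_model(spec, x, A * x + B + rnorm(25, 0, s))
    xn <- runif(1, 0, 30)
    yn <- A * xn + B + rnorm(1, 0, s)
    pr <- predict_with_interval(m, xn)
    yn > pr$upper
  })
  expect_lte(mean(flagged), 0.05)  # nominal above-upper rate is 2.5%
})
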