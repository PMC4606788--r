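# independent profile-likelihood oracle for the Box-Cox exponent
boxcox_grid_oracle <- function(y, grid = seq(-2, 2, 0.05)) {
  n <- length(y)
  ll <- vapply(grid, function(l) {
    z <- if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
    sse <- sum((z - mean(z))^2)
    -n / 2 * log(sse / n) + (l - 1) * sum(log(y))
  }, numeric(1))
  grid[which.max(ll)]
}

test_that("control pooling follows the minimum-count stratified sampling rule", {
  tabs <- lapply(c(a = 500, b = 800, c = 1200), function(n) {
    data.frame(fibre_id = seq_len(n), porin_T = rnorm(n))
  })
  pool <- sample_control_pool(tabs, seed = 1)
  expect_equal(nrow(pool$fibres), 3 * 500)
  expect_equal(unname(table(pool$fibres$subject)), rep(500L, 3),
               ignore_attr = TRUE)
  expect_equal(pool$n_per_subject, 500)
  # sampling without replacement: no duplicated fibre within a subject
  for (s in names(tabs)) {
    ids <- pool$fibres$fibre_id[pool$fibres$subject == s]
    expect_false(any(duplicated(ids)))
  }
  # single subject keeps every fibre
  single <- sample_control_pool(tabs["a"], seed = 2)
  expect_equal(nrow(single$fibres), 500)
  # determinism
  expect_identical(sample_control_pool(tabs, seed = 7)$fibres,
                   sample_control_pool(tabs, seed = 7)$fibres)
  expect_error(sample_control_pool(list(a = tabs$a[0, ])),
               class = "quadfibre_input_error")
})

test_that("Box-Cox diagnostic identifies the log transform for log-normal data", {
  y <- local({ set.seed(31); exp(rnorm(2000, 2, 0.4)) })
  lam <- check_boxcox_lambda(y)
  expect_lt(abs(as.numeric(lam)), 0.15)
  expect_equal(as.numeric(lam), boxcox_grid_oracle(y), tolerance = 0.051)

  # already-normal positive data prefer lambda near 1
  y2 <- local({ set.seed(32); rnorm(2000, 100, 5) })
  lam2 <- suppressWarnings(check_boxcox_lambda(y2))
  expect_lt(abs(as.numeric(lam2) - 1), 0.3)
  expect_equal(as.numeric(lam2), boxcox_grid_oracle(y2), tolerance = 0.051)

  # degenerate scale: flat profile, no warning
  y3 <- local({ set.seed(33); exp(rnorm(100, 5, 1e-9)) })
  expect_no_warning(check_boxcox_lambda(y3))

  expect_error(check_boxcox_lambda(c(-1, 2, 3)), class = "quadfibre_input_error")
  expect_error(check_boxcox_lambda(rep(1, 5)), class = "quadfibre_input_error")
})

test_that("normality tests are calibrated and powered", {
  calib <- vapply(1:30, function(s) {
    x <- local({ set.seed(400 + s); rnorm(500) })
    r <- suppressWarnings(test_normality(x))
    r$p_shapiro > 0.01 && r$p_dagostino > 0.01
  }, logical(1))
  expect_gte(mean(calib), 0.9)

  power <- vapply(1:20, function(s) {
    x <- local({ set.seed(500 + s); rexp(500) })
    suppressWarnings(test_normality(x))$p_shapiro < 0.001
  }, logical(1))
  expect_equal(mean(power), 1)

  expect_error(test_normality(rep(3, 100)), class = "quadfibre_input_error")
  expect_error(test_normality(rnorm(5)), class = "quadfibre_input_error")
  # n > 5000 path subsamples for Shapiro-Wilk but keeps full-n K2
  big <- local({ set.seed(9); rnorm(6000) })
  r <- suppressWarnings(test_normality(big))
  expect_equal(r$n, 6000)
  expect_true(is.finite(r$W))
})

test_that("D'Agostino-Pearson omnibus statistic matches an independent implementation", {
  # fixture and expected values frozen from an independent implementation
  # (scipy.stats.normaltest) on the same 60 numbers
  x <- c(7.152350, 12.527457, 8.258677, 9.481654, 9.849313, 8.518231,
         7.264415, 11.297786, 10.722116, 6.094274, 14.694819, 11.936994,
         8.481226, 11.804397, 9.066094, 9.878621, 11.577689, 7.486664,
         11.151715, 12.797958, 12.644596, 9.400603, 11.805839, 6.756835,
         9.683621, 10.898968, 7.312798, 9.836625, 13.449480, 15.236319,
         11.554723, 11.657266, 8.082023, 7.581223, 7.175416, 11.083094,
         11.503879, 8.682479, 7.542650, 10.515116, 10.625806, 9.738377,
         12.539966, 9.814075, 9.867698, 7.783571, 10.271914, 12.694156,
         10.122288, 10.141829, 10.867309, 10.554967, 11.060505, 11.073442,
         11.236700, 8.409965, 10.600062, 6.794597, 10.533598, 7.476752)
  r <- dagostino_pearson(x)
  expect_equal(r$K2, 0.2941912519, tolerance = 1e-9)
  expect_equal(r$p.value, 0.8632114281, tolerance = 1e-9)
})

test_that("protein regression matches hand least squares and recovers parameters", {
  # 5-point toy with an exact hand solution: slope 0.5, intercept 1, see 0
  toy <- data.frame(porin_T = 0:4, coxi_T = c(1, 1.5, 2, 2.5, 3),
                    ndufb8_T = 0:4)
  fit <- fit_protein_regression(toy, "coxi")
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$see, 0, tolerance = 1e-12)
  # identity line
  fit2 <- fit_protein_regression(toy, "ndufb8")
  expect_equal(fit2$slope, 1, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
  expect_equal(fit2$r2, 1, tolerance = 1e-12)

  # parameter recovery on simulated control truth (a=0.8, b=0.9, see=0.15)
  tr <- local({
    set.seed(55)
    x <- rnorm(3000, 9.2, 0.35)
    data.frame(porin_T = x, coxi_T = 0.8 + 0.9 * x + rnorm(3000, 0, 0.15),
               ndufb8_T = 0)
  })
  f3 <- fit_protein_regression(tr, "coxi")
  se_slope <- f3$see / (sqrt(3000) * sd(tr$porin_T))
  expect_lt(abs(f3$slope - 0.9), 3 * se_slope)
  expect_lt(abs(f3$see - 0.15), 3 * 0.15 / sqrt(2 * 3000))
  # residual invariants: mean 0, SD = see * sqrt((n-2)/n)
  res <- tr$coxi_T - (f3$intercept + f3$slope * tr$porin_T)
  expect_lt(abs(mean(res)), 1e-10)
  expect_equal(sd(res) * sqrt(2999 / 3000), f3$see * sqrt(2998 / 3000),
               tolerance = 1e-10)

  expect_error(fit_protein_regression(toy[1:2, ], "coxi"),
               class = "quadfibre_input_error")
  expect_error(
    fit_protein_regression(data.frame(porin_T = rep(1, 10), coxi_T = rnorm(10),
                                      ndufb8_T = 0), "coxi"),
    class = "quadfibre_input_error")
})

test_that("control model recovers generator moments and serialises losslessly", {
  model <- default_control_model()
  cfg <- simulation_config()
  expect_lt(abs(model$porin_mu_T - cfg$porin_mu_T), 3 * cfg$porin_sd_T / sqrt(3000) + 0.02)
  expect_lt(abs(model$porin_sd_T - cfg$porin_sd_T), 3 * cfg$porin_sd_T / sqrt(6000) + 0.02)
  # the corrected porin scale is slightly stretched by the global 546
  # subtraction of a mass-dependent background (see the methods vignette),
  # which attenuates the fitted slope relative to the latent truth
  expect_lt(abs(model$coxi_fit$slope - cfg$coxi_slope), 0.08)
  expect_lt(abs(model$coxi_fit$see - cfg$coxi_see), 0.02)

  path <- tempfile(fileext = ".json")
  write_control_model(model, path)
  back <- read_control_model(path)
  z1 <- score_protein_z(c(8.2, 8.9), c(9.0, 9.4), model$coxi_fit)
  z2 <- score_protein_z(c(8.2, 8.9), c(9.0, 9.4), back$coxi_fit)
  expect_equal(z1, z2, tolerance = 1e-12)
  expect_equal(score_porin_z(9.5, back), score_porin_z(9.5, model),
               tolerance = 1e-12)
})

test_that("independently seeded control models agree within sampling error", {
  m1 <- default_control_model()
  m2 <- make_control_model(seed0 = 700, pool_seed = 71)
  se_slope <- 2 * m1$coxi_fit$see / (sqrt(3000) * 0.35)
  expect_lt(abs(m1$coxi_fit$slope - m2$coxi_fit$slope), 3 * sqrt(2) * se_slope)
  expect_lt(abs(m1$porin_mu_T - m2$porin_mu_T), 6 * 0.35 / sqrt(3000) + 0.02)
})
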