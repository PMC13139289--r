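sim_cohort <- function(n = 400, beta_S = -0.14, beta_T = 0, seed = 1,
                       rho_s_t = 0.862) {
  synthesize_cohort(synthetic_cohort_spec(
    n = n,
    regions = tibble::tibble(region = "test", beta_S = beta_S, beta_T = beta_T),
    rho_s_t = rho_s_t, seed = seed))
}

test_that("a noiseless single-predictor fit gives a standardized beta of 1", {
  set.seed(9)
  x <- rlnorm(200)
  tab <- tibble::tibble(
    age = runif(200, 40, 90), sex = rbinom(200, 1, 0.5),
    population = rbinom(200, 1, 0.5), ticv_mm3 = rnorm(200, 1.4e6, 1e5),
    S_mm2 = x, T_mm = rlnorm(200), bv_pure = 2 * x)
  fit <- suppressWarnings(fit_bv_model(tab, "pure", model = 1))
  expect_equal(fit$terms$beta_std[fit$terms$term == "S_mm2"], 1,
               tolerance = 1e-10)
  # raw-scale coefficient recovers the generating slope
  expect_equal(fit$terms$beta[fit$terms$term == "S_mm2"], 2, tolerance = 1e-8)
})

test_that("with orthogonal S and T the joint model matches the single fits", {
  n <- 512
  set.seed(4)
  # a mutually orthogonal design: balanced patterns for the exposures and
  # indicators, covariates residualised against everything else
  s <- rep(c(-1, 1), n / 2)
  tt <- rep(c(-1, -1, 1, 1), n / 4)
  sex <- rep(c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L), n / 8)
  pop <- rep(c(1L, 0L, 0L, 1L), n / 4)
  age <- residuals(lm(rnorm(n) ~ s + tt + sex + pop))
  ticv <- residuals(lm(rnorm(n) ~ s + tt + sex + pop + age))
  tab <- tibble::tibble(
    age = age, sex = sex, population = pop,
    ticv_mm3 = ticv + 10, S_mm2 = s + 5, T_mm = tt + 5,
    bv_r = 0.3 * s - 0.2 * tt + rnorm(n, 0, 0.5))
  b1 <- fit_bv_model(tab, "r", 1)$terms
  b2 <- fit_bv_model(tab, "r", 2)$terms
  b3 <- fit_bv_model(tab, "r", 3)$terms
  expect_equal(b3$beta_std[b3$term == "S_mm2"],
               b1$beta_std[b1$term == "S_mm2"], tolerance = 1e-6)
  expect_equal(b3$beta_std[b3$term == "T_mm"],
               b2$beta_std[b2$term == "T_mm"], tolerance = 1e-6)
})

test_that("beta equals beta* when all variables are standardized", {
  tab <- sim_cohort(n = 600, seed = 3)
  tab2 <- tab
  tab2$S_mm2 <- zscore(tab$S_mm2); tab2$T_mm <- zscore(tab$T_mm)
  tab2$age <- zscore(tab$age); tab2$ticv_mm3 <- zscore(tab$ticv_mm3)
  tab2$bv_test <- zscore(tab$bv_test)
  fit <- fit_bv_model(tab2, "test", 3)
  cont <- fit$terms$term %in% c("S_mm2", "T_mm", "age", "ticv_mm3")
  expect_equal(fit$terms$beta[cont], fit$terms$beta_std[cont],
               tolerance = 1e-10)
})

test_that("VIF follows its closed form and flags exact collinearity", {
  set.seed(8)
  n <- 2000
  a <- rnorm(n); b <- rnorm(n)
  expect_lt(max(abs(vif(cbind(a = a, b = b)) - 1)), 0.01)
  # exact sample correlation 0.8 gives VIF = 1 / (1 - 0.64)
  x1 <- rnorm(n)
  e <- lm(rnorm(n) ~ x1)$residuals   # orthogonal to x1 by construction
  x2 <- 0.8 * zscore(x1) + sqrt(1 - 0.64) * zscore(e)
  v <- vif(cbind(x1 = zscore(x1), x2 = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  expect_error(vif(cbind(a = a, dup = a)), "collinearity")
  expect_error(vif(matrix(rnorm(10), ncol = 1)), "at least 2")
  # agrees with the standard regression diagnostic on a fitted model
  tab <- sim_cohort(n = 500, seed = 6)
  fit <- fit_bv_model(tab, "test", 3)
  vc <- car::vif(fit$fit)
  expect_equal(unname(fit$terms$vif[match(names(vc), fit$terms$term)]),
               unname(vc), tolerance = 1e-8)
})

test_that("BH adjustment matches the literal step-up oracle", {
  out <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$p_adj, rep(0.04, 4))
  expect_true(all(out$rejected))
  expect_equal(bh_adjust(0.03)$p_adj, 0.03)
  expect_false(any(bh_adjust(rep(1, 6))$rejected))
  set.seed(13)
  for (i in 1:6) {
    p <- runif(sample(1:12, 1))^2
    expect_equal(bh_adjust(p)$p_adj, oracle_bh(p), tolerance = 1e-12)
    # monotone non-decreasing in raw-p order
    o <- order(p)
    expect_true(all(diff(bh_adjust(p)$p_adj[o]) >= -1e-15))
    expect_true(all(bh_adjust(p)$p_adj >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("adding S attenuates the spurious T effect (model 2 vs model 3)", {
  # S drives the outcome, T only correlates with S
  tab <- sim_cohort(n = 1232, beta_S = -0.15, beta_T = 0, seed = 21)
  m2 <- fit_bv_model(tab, "test", 2)$terms
  m3 <- fit_bv_model(tab, "test", 3)$terms
  bT2 <- m2$beta_std[m2$term == "T_mm"]
  bT3 <- m3$beta_std[m3$term == "T_mm"]
  expect_lt(abs(bT3), abs(bT2))
  expect_lt(bT2, -0.05)  # the marginal T effect is visibly non-zero
})

test_that("fit_bv_models applies FDR per model across regions", {
  spec <- synthetic_cohort_spec(
    n = 800,
    regions = tibble::tibble(region = c("a", "b", "c"),
                             beta_S = c(-0.2, -0.1, 0),
                             beta_T = c(0, 0, 0)),
    seed = 31)
  tab <- synthesize_cohort(spec)
  fits <- fit_bv_models(tab, c("a", "b", "c"), models = 1:3)
  expect_true(all(is.na(fits$p_adj[!fits$term %in% c("S_mm2", "T_mm")])))
  for (m in 1:3) {
    sel <- fits$model == m & fits$term %in% c("S_mm2", "T_mm")
    expect_equal(fits$p_adj[sel], oracle_bh(fits$p_value[sel]),
                 tolerance = 1e-12)
  }
  expect_true(all(fits$p_adj >= fits$p_value, na.rm = TRUE))
  expect_true(all(fits$vif >= 1))
})

test_that("tidy and glance expose broom-style summaries", {
  tab <- sim_cohort(n = 300, seed = 41)
  fit <- fit_bv_model(tab, "test", 3)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value", "vif") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 300)
  expect_gte(gl$max.vif, 1)
  expect_s3_class(tidy(morphometry_result_stub <- structure(
    list(summary = tibble::tibble(id = "x"), faces = NULL),
    class = "morphometry_result")), "tbl_df")
})

test_that("autoplot builds coefficient and thickness displays", {
  tab <- sim_cohort(n = 300, seed = 43)
  fits <- fit_bv_models(tab, "test", models = 1:2)
  p <- ggplot2::autoplot(fits)
  expect_s3_class(p, "ggplot")
  ph <- make_annulus(phantom_spec(shape = "annulus", r1 = 2, r2 = 3,
                                  height = 3, arc = 360, spacing = 0.5))
  res <- morphometry(ph$ct, ph$artery)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
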