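# Simulates per-plant metric tables directly from the model families (not
# through the ecological generator) so the fitting machinery is tested
# against a known truth.
sim_glmm_data <- function(n_groups = 20, n_per = 30, beta_pi = -0.5,
                          beta_po = 0.2, beta_int = 0, sd_group = 0.5,
                          family = "poisson") {
  n <- n_groups * n_per
  g <- rep(seq_len(n_groups), each = n_per)
  pi_raw <- rnorm(n, 50, 10)
  pi_std <- (pi_raw - mean(pi_raw)) / sd(pi_raw)
  po <- rbinom(n, 1, 0.6)
  u <- rep(rnorm(n_groups, 0, sd_group), each = n_per)
  total <- rep(sample(20:80, n_groups, TRUE), each = n_per)
  eta <- beta_pi * pi_std + beta_po * po + beta_int * pi_std * po + u
  df <- data.frame(assemblage_id = paste0("A", g), origin = ifelse(po == 1,
                   "native", "exotic"), phylo_isolation = pi_raw,
                   total_richness = total, n_native_comparators = 10L)
  if (family == "poisson") {
    df$richness <- rpois(n, exp(-3 + eta + log(total)))
  } else if (family == "binomial") {
    pr <- plogis(0.5 + eta)
    df$mean_jaccard <- rbinom(n, 10, pr) / 10
  } else {
    df$mean_dprime <- 0.5 + 0.1 * eta + rnorm(n, 0, 0.1)
  }
  df
}

test_that("offset algebra: doubling totals shifts only the intercept", {
  set.seed(101)
  df <- sim_glmm_data()
  fit1 <- fit_model(df, model_spec("richness"))
  df2 <- df
  df2$total_richness <- 2 * df$total_richness
  fit2 <- fit_model(df2, model_spec("richness"))
  co1 <- setNames(fit1$coefficients$estimate, fit1$coefficients$term)
  co2 <- setNames(fit2$coefficients$estimate, fit2$coefficients$term)
  expect_equal(co2[["PI"]], co1[["PI"]], tolerance = 1e-4)
  expect_equal(co2[["PO"]], co1[["PO"]], tolerance = 1e-4)
  expect_equal(co2[["(Intercept)"]], co1[["(Intercept)"]] - log(2),
               tolerance = 1e-4)
})

test_that("fits are reproducible and recover known coefficients", {
  set.seed(77)
  df <- sim_glmm_data(beta_pi = -0.5)
  fit_a <- fit_model(df, model_spec("richness"))
  fit_b <- fit_model(df, model_spec("richness"))
  expect_equal(fit_a$coefficients$estimate, fit_b$coefficients$estimate,
               tolerance = 1e-6)
  # parameter recovery across small replicate set (scaled from the
  # 100-replicate design; the acceptance suite exercises the full pipeline)
  set.seed(500)
  hits <- 0L
  for (r in 1:10) {
    df <- sim_glmm_data(beta_pi = -0.5)
    est <- fit_model(df, model_spec("richness"))$coefficients
    b <- est$estimate[est$term == "PI"]
    hits <- hits + (abs(b - (-0.5)) < 0.15)
  }
  expect_gte(hits, 8L)
})

test_that("binomial encoding matches an explicit successes/failures fit", {
  set.seed(33)
  df <- sim_glmm_data(family = "binomial")
  fit <- fit_model(df, model_spec("mean_jaccard"))
  succ <- round(df$mean_jaccard * df$n_native_comparators)
  raw <- lme4::glmer(
    cbind(succ, n_native_comparators - succ) ~ PI + PO + (1 | assemblage_id),
    data = transform(df,
                     PI = (phylo_isolation - mean(phylo_isolation)) /
                       sd(phylo_isolation),
                     PO = as.numeric(origin == "native"),
                     succ = succ),
    family = stats::binomial())
  expect_equal(fit$logLik, as.numeric(logLik(raw)), tolerance = 1e-6)
  expect_equal(sort(fit$coefficients$estimate), sort(unname(lme4::fixef(raw))),
               tolerance = 1e-5)
})

test_that("the interaction LRT is a valid nested comparison", {
  set.seed(11)
  df <- sim_glmm_data(beta_int = 0)
  res <- lrt_interaction(df, model_spec("richness"))
  expect_gte(res$lrt$chi_squared, 0)
  expect_equal(res$lrt$df, 1L)
  expect_true(res$lrt$p_value >= 0 && res$lrt$p_value <= 1)
  expect_identical(res$lrt$keep_interaction, res$lrt$p_value < 0.05)
  # strong interaction is detected and the full model kept
  set.seed(12)
  df2 <- sim_glmm_data(beta_int = 0.6, n_groups = 20, n_per = 30)
  res2 <- lrt_interaction(df2, model_spec("richness"))
  expect_true(res2$lrt$keep_interaction)
  expect_true(res2$fit$spec$interaction)
  # log-likelihood monotonicity across families
  for (fam in c("binomial", "gaussian")) {
    set.seed(100 + nchar(fam))
    resp <- if (fam == "binomial") "mean_jaccard" else "mean_dprime"
    dfx <- sim_glmm_data(family = fam)
    resx <- lrt_interaction(dfx, model_spec(resp))
    expect_gte(resx$lrt$chi_squared, 0)
  }
})

test_that("singular fits fall back to fixed effects with McFadden R2", {
  set.seed(41)
  df <- sim_glmm_data(sd_group = 0)
  fit <- fit_model(df, model_spec("richness"))
  fb <- fallback_if_singular(fit)
  if (fit$re_variance < 1e-8) {
    expect_true(fb$fallback_used)
    expect_true(is.finite(fb$mcfadden))
    expect_gte(fb$mcfadden, 0)
    expect_error(r2_nakagawa(fb), "McFadden")
  } else {
    expect_false(fb$fallback_used)
  }
  # large variance: never a fallback
  set.seed(42)
  df2 <- sim_glmm_data(sd_group = 1.5)
  fit2 <- fit_model(df2, model_spec("richness"))
  expect_false(fallback_if_singular(fit2)$fallback_used)
  expect_gt(fit2$re_variance, 0.5)
  # null-only truth: McFadden pseudo-R2 near zero
  set.seed(43)
  df3 <- sim_glmm_data(beta_pi = 0, beta_po = 0, sd_group = 0)
  fit3 <- fallback_if_singular(fit_model(df3, model_spec("richness")),
                               threshold = Inf)  # force the fixed-effect route
  expect_true(fit3$fallback_used)
  expect_lt(fit3$mcfadden, 0.01)
})

test_that("Nakagawa R2 recovers a known Gaussian variance partition", {
  # var_fixed = 1, var_random = 1, var_resid = 2 -> marginal 0.25, cond. 0.50
  set.seed(7)
  n_groups <- 200
  n_per <- 10
  g <- rep(seq_len(n_groups), each = n_per)
  x <- rnorm(n_groups * n_per)
  u <- rep(rnorm(n_groups, 0, 1), each = n_per)
  y <- x + u + rnorm(n_groups * n_per, 0, sqrt(2))
  df <- data.frame(assemblage_id = paste0("A", g),
                   origin = rep(c("native", "exotic"), length.out = length(g)),
                   phylo_isolation = x, mean_dprime = y,
                   total_richness = 10, n_native_comparators = 5)
  fit <- fit_model(df, model_spec("mean_dprime"))
  r2 <- r2_nakagawa(fit)
  expect_equal(unname(r2[["marginal"]]), 0.25, tolerance = 0.05)
  expect_equal(unname(r2[["conditional"]]), 0.50, tolerance = 0.05)
  expect_lte(r2[["marginal"]], r2[["conditional"]])
  # ordering holds on the other families too
  set.seed(8)
  for (resp in c("richness", "mean_jaccard")) {
    dfx <- sim_glmm_data(family = if (resp == "richness") "poisson" else
      "binomial")
    r2x <- r2_nakagawa(fit_model(dfx, model_spec(resp)))
    expect_lte(r2x[["marginal"]], r2x[["conditional"]] + 1e-12)
    expect_gte(r2x[["marginal"]], 0)
    expect_lte(r2x[["conditional"]], 1)
  }
})

test_that("degenerate designs raise contract errors", {
  set.seed(9)
  df <- sim_glmm_data(n_groups = 4, n_per = 10)
  df$origin <- "native"
  expect_error(fit_model(df, model_spec("richness")), "rank-deficient")
  df2 <- sim_glmm_data(n_groups = 4, n_per = 10)
  df2$phylo_isolation <- 5
  expect_error(fit_model(df2, model_spec("richness")), "rank-deficient")
  df3 <- sim_glmm_data(n_groups = 1, n_per = 30)
  expect_error(fit_model(df3, model_spec("richness")), ">= 2 assemblages")
})
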