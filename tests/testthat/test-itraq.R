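itq <- function(id, pep, r1, r2, contaminant = FALSE, reverse = FALSE) {
  tibble::tibble(protein_id = id, unique_quantified_peptides = as.integer(pep),
                 ratios_116_114 = list(r1), ratios_117_115 = list(r2),
                 is_contaminant = contaminant, is_reverse = reverse)
}

test_that("iTRAQ detection needs two peptides and two ratios in each channel", {
  rec <- dplyr::bind_rows(
    itq("short", 3, c(1, 2), c(1)),          # one 117/115 ratio only
    itq("ok", 2, c(1, 2), c(1, 2)),          # boundary passes
    itq("rev", 5, c(1, 2), c(1, 2), reverse = TRUE),
    itq("onepep", 1, c(1, 2), c(1, 2)))
  expect_identical(filter_itraq(rec)$protein_id, "ok")
})

test_that("channel median normalization centers and is scale-equivariant", {
  rec <- dplyr::bind_rows(itq("a", 2, c(2, 2), c(4, 1)),
                          itq("b", 2, c(2, 2), c(2, 2)))
  norm <- median_normalize_itraq(rec)
  expect_equal(unlist(norm$log2_116_114), rep(0, 4))  # all ratios equal the median

  set.seed(21)
  rec <- dplyr::bind_rows(purrr::map(1:30, function(i) {
    itq(sprintf("p%02d", i), 3, 2^rnorm(3), 2^rnorm(2))
  }))
  n1 <- median_normalize_itraq(rec)
  rec10 <- dplyr::mutate(rec, ratios_116_114 = purrr::map(ratios_116_114, ~ .x * 10))
  n2 <- median_normalize_itraq(rec10)
  expect_equal(unlist(n1$log2_116_114), unlist(n2$log2_116_114), tolerance = 1e-12)

  # pool-median-divide-log2 oracle
  pooled <- unlist(rec$ratios_116_114)
  expect_equal(unlist(n1$log2_116_114), log2(pooled / median(pooled)),
               tolerance = 1e-12)
})

test_that("the variance prior collapses to a point when dispersion vanishes", {
  # at large df the log-scale bias correction vanishes and s0^2 -> the
  # common variance
  pr <- fit_eb_prior(rep(0.25, 50), dfs = 10000)
  expect_true(is.infinite(pr$d0))
  expect_equal(pr$s0_sq, 0.25, tolerance = 1e-3)
  # two equal-variance proteins: finite or infinite, but never a crash
  expect_s3_class(fit_eb_prior(c(0.1, 0.1), dfs = 3), "eb_prior")
  expect_error(fit_eb_prior(c(0, 0), dfs = 3), "positive variance")
})

test_that("the prior fit recovers known hyperparameters from simulated variances", {
  set.seed(101)
  d0 <- 4
  s0 <- 0.1
  n <- 5000
  df <- 3
  true_var <- d0 * s0 / rchisq(n, d0)
  s2 <- true_var * rchisq(n, df) / df
  pr <- fit_eb_prior(s2, dfs = df)
  expect_lt(abs(pr$d0 - d0) / d0, 0.20)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.10)
})

test_that("the prior fit agrees with an established variance-shrinkage implementation", {
  set.seed(55)
  s2 <- 0.1 * rchisq(300, 6) / 6 * (4 * 0.1 / rchisq(300, 4)) / 0.1
  fit <- limma::fitFDist(s2, df1 = 6)
  pr <- fit_eb_prior(s2, dfs = 6)
  expect_equal(pr$d0, fit$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, fit$scale, tolerance = 1e-6)
})

test_that("the moderated t reduces to the ordinary t and to the z-form at the d0 limits", {
  set.seed(8)
  for (i in 1:25) {
    obs <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1), sd = runif(1, 0.1, 1))
    plain <- moderated_t(obs, list(d0 = 0, s0_sq = 0.5))
    tt <- t.test(obs)
    expect_equal(plain$t_mod, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(plain$p, tt$p.value, tolerance = 1e-10)

    zform <- moderated_t(obs, list(d0 = Inf, s0_sq = 0.5))
    expect_equal(zform$t_mod, mean(obs) / sqrt(0.5 / length(obs)),
                 tolerance = 1e-12)
    expect_equal(zform$p, 2 * pnorm(-abs(zform$t_mod)), tolerance = 1e-10)

    mod <- moderated_t(obs, list(d0 = 4, s0_sq = 0.1))
    ora <- oracle_moderated_t(obs, 4, 0.1)
    expect_equal(mod$t_mod, ora$t, tolerance = 1e-10)
    expect_equal(mod$p, ora$p, tolerance = 1e-10)
    # posterior variance is a convex combination of sample and prior variance
    expect_gte(mod$moderated_var, min(mod$sample_var, 0.1) - 1e-15)
    expect_lte(mod$moderated_var, max(mod$sample_var, 0.1) + 1e-15)
  }
  expect_error(moderated_t(1.5, list(d0 = 4, s0_sq = 0.1)), "2 observations")
})

test_that("moderated statistics match limma's squeeze on shared data", {
  set.seed(77)
  sim <- simulate_itraq(n_proteins = 300, frac_true = 0.1, seed = 77)
  rec <- median_normalize_itraq(filter_itraq(sim$records))
  obs <- purrr::map2(rec$log2_116_114, rec$log2_117_115, c)
  sv <- vapply(obs, var, numeric(1))
  df <- lengths(obs) - 1
  pr <- fit_eb_prior(sv, df)
  sq <- limma::squeezeVar(sv, df)
  res <- itraq_moderated_test(rec, prior = pr)
  expect_equal(res$moderated_var, sq$var.post, tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:60, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # non-decreasing in sorted order
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("enrichment calls use a strict threshold and a positive direction", {
  res <- tibble::tibble(protein_id = c("a", "b", "c", "d"),
                        mean_log2 = c(1, 1, -1, 1),
                        q = c(0.019, 0.02, 0.001, 0.5))
  expect_identical(call_enriched(res), "a")  # q = 0.02 exactly is not enriched
})

test_that("null simulations keep enriched calls within the FDR budget", {
  sim <- simulate_itraq(n_proteins = 2000, frac_true = 0, seed = 12)
  rec <- median_normalize_itraq(filter_itraq(sim$records))
  res <- itraq_moderated_test(rec)
  n_enr <- length(call_enriched(res))
  alpha <- 0.02
  m <- nrow(res)
  expect_lte(n_enr, m * alpha + 3 * sqrt(m * alpha * (1 - alpha)))
})

test_that("strong spike-ins are recovered with high recall and controlled FDR", {
  sim <- simulate_itraq(n_proteins = 2000, frac_true = 0.05, true_shift = 2.0,
                        n_obs_per_channel = 2, d0 = 4, s0_sq = 0.1, seed = 42)
  rec <- median_normalize_itraq(filter_itraq(sim$records))
  res <- itraq_moderated_test(rec)
  enr <- call_enriched(res)
  truth <- sim$truth
  shifted <- truth$protein_id[truth$is_true]
  expect_gte(mean(shifted %in% enr), 0.90)
  fdr <- mean(!(enr %in% shifted))
  expect_lte(fdr, 0.02 + 3 * sqrt(0.02 * 0.98 / max(length(enr), 1)))
})

test_that("with d0 = 0 the whole pipeline reduces to ordinary one-sample t-tests", {
  sim <- simulate_itraq(n_proteins = 100, frac_true = 0.2,
                        n_obs_per_channel = 3, seed = 6)
  rec <- median_normalize_itraq(filter_itraq(sim$records))
  res <- itraq_moderated_test(rec, prior = list(d0 = 0, s0_sq = 1))
  obs <- purrr::map2(rec$log2_116_114, rec$log2_117_115, c)
  plain_p <- vapply(obs, function(o) t.test(o)$p.value, numeric(1))
  expect_equal(res$p, plain_p, tolerance = 1e-10)
  expect_equal(res$q, p.adjust(plain_p, "BH"), tolerance = 1e-10)
})
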