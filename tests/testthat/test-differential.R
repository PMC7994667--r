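test_that("moderated t matches its closed forms", {
  # infinite prior: z-test against s0
  r <- matrix(rep(1, 4), 1, dimnames = list("f1", NULL))
  prior <- structure(list(d0 = Inf, s0_sq = 0.25), class = "VariancePrior")
  res <- moderated_ttest(r, prior)
  expect_equal(res$t, 4)
  expect_equal(res$p, 2 * pnorm(-4), tolerance = 1e-12)

  # finite prior: posterior variance (d0 s0^2 + d s^2) / (d0 + d)
  v <- c(1, 1, 1, 1) + c(-1.5, -0.5, 0.5, 1.5) * sqrt(2 / var(c(-1.5, -0.5, 0.5, 1.5)))
  v <- v - mean(v) + 1   # mean 1, sample variance 2, n = 4
  r2 <- matrix(v, 1, dimnames = list("f1", NULL))
  prior2 <- structure(list(d0 = 4, s0_sq = 1), class = "VariancePrior")
  res2 <- moderated_ttest(r2, prior2)
  s2_post <- (4 * 1 + 3 * 2) / (4 + 3)
  expect_equal(res2$s2_post, s2_post, tolerance = 1e-12)
  expect_equal(res2$t, 1 / sqrt(s2_post / 4), tolerance = 1e-12)
  expect_equal(res2$df_total, 7)
})

test_that("moderated t reduces to the ordinary t (d0 = 0) and z (d0 = Inf) limits", {
  set.seed(1)
  x <- matrix(rnorm(200 * 4, 0.2, 0.5), 200,
              dimnames = list(sprintf("f%03d", 1:200), NULL))
  # d0 -> 0: ordinary one-sample t
  tiny <- structure(list(d0 = 1e-9, s0_sq = 1), class = "VariancePrior")
  res <- moderated_ttest(x, tiny)
  ref_t <- apply(x, 1, function(r) t.test(r)$statistic)
  expect_equal(unname(res$t), unname(ref_t), tolerance = 1e-5)
  # d0 = Inf: z-test with fixed s0
  infp <- structure(list(d0 = Inf, s0_sq = 0.25), class = "VariancePrior")
  resz <- moderated_ttest(x, infp)
  expect_equal(unname(resz$t), unname(rowMeans(x) / (0.5 / 2)),
               tolerance = 1e-12)
  expect_equal(resz$p, 2 * pnorm(-abs(resz$t)), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(7)
  x <- matrix(rnorm(500 * 4, 0, 1) * sqrt(rep(2 * 5 / rchisq(500, 5), 4)),
              500, dimnames = list(sprintf("f%03d", 1:500), NULL))
  x[1:50, ] <- x[1:50, ] + 1
  fit <- limma::lmFit(x, cbind(rep(1, 4)))
  fit <- limma::eBayes(fit)
  prior <- estimate_variance_prior(apply(x, 1, var), 3)
  expect_equal(prior$d0, fit$df.prior, tolerance = 0.02)
  expect_equal(prior$s0_sq, fit$s2.prior, tolerance = 0.02)
  res <- moderated_ttest(x, prior)
  expect_equal(unname(res$t), unname(fit$t[, 1]), tolerance = 1e-6)
  expect_equal(unname(res$p), unname(fit$p.value[, 1]), tolerance = 1e-6)
})

test_that("variance-prior estimation recovers known hyperparameters", {
  # scaled inverse-chi-square prior (d0 = 5, s0^2 = 2), d = 3 residual df
  errs <- t(sapply(1:5, function(seed) {
    set.seed(seed)
    true_var <- 2 * 5 / rchisq(10000, 5)
    s2 <- true_var * rchisq(10000, 3) / 3
    pr <- estimate_variance_prior(s2, 3)
    c(d0 = pr$d0 / 5, s0 = pr$s0_sq / 2)
  }))
  expect_true(all(abs(errs - 1) < 0.2))
  # constant observed variances: d0 = Inf and s0^2 equal to that value
  prc <- estimate_variance_prior(rep(1.7, 100), 3)
  expect_identical(prc$d0, Inf)
  expect_equal(prc$s0_sq, 1.7)
  # constant true variance: very large estimated d0 (median over seeds)
  d0s <- sapply(1:10, function(seed) {
    set.seed(seed)
    estimate_variance_prior(2 * rchisq(10000, 3) / 3, 3)$d0
  })
  expect_gt(median(d0s), 100)
  expect_error(estimate_variance_prior(rep(0, 100), 3), "zero")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.73), 0.73)
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(50)^2
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("regulated calls gate on both q and fold change", {
  tab <- data.frame(log2FC = c(0.09, 0.5, -0.5, -0.09, 0.2),
                    q = c(0.001, 0.04, 0.06, 0.01, NA))
  out <- call_regulated(tab)
  expect_equal(as.character(out$regulated),
               c("none", "up", "none", "none", "none"))
})

test_that("paired shift test handles identity, power and degenerate inputs", {
  x <- rnorm(10)
  res <- paired_shift_test(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # planted +0.5 shift at the scale of the mitochondrial subset
  hits <- sapply(1:20, function(seed) {
    set.seed(seed)
    d <- rnorm(515, 0.5, 1)
    paired_shift_test(d, rep(0, 515))$p < 1e-10
  })
  expect_gte(mean(hits), 0.95)
  expect_warning(res0 <- paired_shift_test(rep(1, 5), rep(0, 5)), "constant")
  expect_equal(res0$p, 0)
  expect_error(paired_shift_test(1:2, 2:3), "n >= 3")
})

test_that("Pearson test matches the t-transform and rejects degenerate input", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson_cor_test(a, a)$r, 1)
  # r = 0.97, n = 7: t = r sqrt(n-2)/sqrt(1-r^2), p approx 3e-4
  set.seed(3)
  for (i in 1:50) {
    b <- rnorm(7); cc <- rnorm(7)
    res <- pearson_cor_test(b, cc)
    tt <- res$r * sqrt(5) / sqrt(1 - res$r^2)
    expect_equal(res$p, 2 * pt(-abs(tt), 5), tolerance = 1e-12)
  }
  expect_error(pearson_cor_test(rep(1, 5), rnorm(5)), "zero variance")
  # orthogonalized vectors: r = 0 to machine precision
  x <- rnorm(20)
  y_perp <- residuals(lm(rnorm(20) ~ x))
  expect_lt(abs(pearson_cor_test(x, y_perp)$r), 1e-12)
})

test_that("fit_differential runs one prior and one BH family per contrast", {
  cfg <- sim_config(seed = 5, n_proteins = 300)
  study <- simulate_study(cfg)
  diff <- fit_differential(ratios_vs_reference(study$proteome))
  expect_setequal(unique(diff$treatment), c("2i", "Cdk8i"))
  expect_equal(sort(unique(diff$timepoint)), c(1, 2, 4, 7, 10, 14))
  one <- diff[diff$treatment == "2i" & diff$timepoint == 7, ]
  expect_equal(nrow(one), 300)
  expect_equal(one$q, bh_adjust(one$p), tolerance = 1e-12)
  expect_true(all(one$q >= one$p - 1e-15))
  expect_equal(one$n, rep(4, 300))
})
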