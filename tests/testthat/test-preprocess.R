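test_that("cyclic loess removes constant offsets and leaves identical samples alone", {
  d <- tiny_design(n_treated = 1)[1:2, ]
  set.seed(1)
  base <- rnorm(2000, 25, 2)
  v <- cbind(base, base)
  dimnames(v) <- list(sprintf("f%04d", 1:2000), d$sample_id)
  m <- expression_matrix(v, d, "protein")
  out <- cyclic_loess_normalize(m)
  expect_lt(max(abs(out$values - v)), 1e-9)

  v2 <- v
  v2[, 2] <- base + 0.8 + rnorm(2000, 0, 0.05)
  m2 <- expression_matrix(v2, d, "protein")
  out2 <- cyclic_loess_normalize(m2)
  expect_lt(abs(median(out2$values[, 2] - out2$values[, 1])), 0.01)
  # grand mean of the plex preserved
  expect_lt(abs(mean(out2$values) - mean(v2)), 1e-6)
})

test_that("cyclic loess flattens a smooth intensity-dependent bias", {
  d <- tiny_design(n_treated = 1)[1:2, ]
  set.seed(2)
  a <- rnorm(4000, 25, 2)
  bias <- 0.5 * sin((a - 25) / 4)
  v <- cbind(a - bias / 2, a + bias / 2)
  dimnames(v) <- list(sprintf("f%04d", 1:4000), d$sample_id)
  out <- cyclic_loess_normalize(expression_matrix(v, d, "protein"))
  mm <- out$values[, 2] - out$values[, 1]
  aa <- rowMeans(out$values)
  decile <- cut(aa, quantile(aa, 0:10 / 10), include.lowest = TRUE)
  expect_true(all(abs(tapply(mm, decile, median)) < 0.05))
})

test_that("cyclic loess agrees with limma's implementation on complete data", {
  skip_if_not_installed("limma")
  d <- tiny_design(n_treated = 2)[1:3, ]
  d$treatment[2:3] <- "2i"; d$timepoint[2:3] <- 1:2; d$plex <- "px1"
  set.seed(3)
  v <- matrix(rnorm(3000 * 3, 25, 2), 3000,
              dimnames = list(sprintf("f%04d", 1:3000), d$sample_id))
  v[, 2] <- v[, 2] + 0.6
  ours <- cyclic_loess_normalize(expression_matrix(v, d, "protein"))
  theirs <- limma::normalizeCyclicLoess(v, span = 0.7, iterations = 3,
                                        method = "pairs")
  # same normalization target: residual offsets of both outputs agree
  expect_lt(max(abs(apply(ours$values - theirs, 2, median))), 0.02)
})

test_that("single-sample plexes are left unchanged with a warning", {
  d <- tiny_design(n_treated = 1)[1, , drop = FALSE]
  v <- matrix(rnorm(100, 25), 100,
              dimnames = list(sprintf("f%03d", 1:100), d$sample_id))
  m <- expression_matrix(v, d, "protein")
  expect_warning(out <- cyclic_loess_normalize(m), "single sample")
  expect_identical(out$values, v)
})

test_that("EB batch adjustment removes planted location shifts, keeps treatment effects", {
  d <- do.call(rbind, lapply(1:2, function(b) {
    data.frame(sample_id = paste0("b", b, "_", 1:8),
               cell_line = paste0("CL", b),
               treatment = rep(c("SL", "2i"), 4),
               timepoint = rep(c(0, 1), 4), plex = paste0("px", b),
               replicate = rep(1:4, each = 2), stringsAsFactors = FALSE)
  }))
  set.seed(4)
  base <- rnorm(600, 25, 2)
  mk <- function(batch_shift, treat_shift) {
    v <- sapply(seq_len(16), function(s) {
      base + rnorm(600, 0, 0.2) +
        ifelse(d$plex[s] == "px2", batch_shift, 0) +
        ifelse(d$treatment[s] == "2i", treat_shift, 0)
    })
    dimnames(v) <- list(sprintf("f%03d", 1:600), d$sample_id)
    expression_matrix(v, d, "protein")
  }
  # pure batch shift vanishes
  adj <- batch_adjust_eb(mk(2, 0))
  per_feature_diff <- rowMeans(adj$values[, d$plex == "px2"]) -
    rowMeans(adj$values[, d$plex == "px1"])
  expect_lt(mean(abs(per_feature_diff)), 0.05)
  # treatment effect of +1 survives within 10%
  adj2 <- batch_adjust_eb(mk(2, 1))
  eff <- mean(adj2$values[, d$treatment == "2i"]) -
    mean(adj2$values[, d$treatment == "SL"])
  expect_lt(abs(eff - 1), 0.1)
  # single batch: identity
  m1 <- subset_matrix(mk(0, 1), samples = which(d$plex == "px1"))
  expect_lt(max(abs(batch_adjust_eb(m1)$values - m1$values)), 1e-9)
})

test_that("EB batch adjustment is near-idempotent and matches ComBat closely", {
  d <- do.call(rbind, lapply(1:2, function(b) {
    data.frame(sample_id = paste0("b", b, "_", 1:8),
               cell_line = paste0("CL", b),
               treatment = rep(c("SL", "2i"), 4),
               timepoint = rep(c(0, 1), 4), plex = paste0("px", b),
               replicate = rep(1:4, each = 2), stringsAsFactors = FALSE)
  }))
  set.seed(5)
  v <- matrix(rnorm(500 * 16, 25, 2), 500,
              dimnames = list(sprintf("f%03d", 1:500), d$sample_id))
  v[, d$plex == "px2"] <- v[, d$plex == "px2"] + rnorm(500, 1.5, 0.3)
  v[, d$treatment == "2i"] <- v[, d$treatment == "2i"] + 0.5
  m <- expression_matrix(v, d, "protein")
  once <- batch_adjust_eb(m)
  twice <- batch_adjust_eb(once)
  # no systematic drift on re-running (the EB scale shrinkage perturbs
  # individual values symmetrically, as reference implementations also do)
  expect_lt(abs(mean(twice$values - once$values)), 1e-3)

  skip_if_not_installed("sva")
  mod <- model.matrix(~ factor(paste(d$treatment, d$timepoint)))
  ref <- suppressMessages(sva::ComBat(v, batch = factor(d$plex), mod = mod))
  expect_lt(mean(abs(once$values - ref)), 0.05)
  # the second-run perturbation magnitude matches ComBat's
  ref2 <- suppressMessages(sva::ComBat(ref, batch = factor(d$plex),
                                       mod = mod))
  expect_equal(mean(abs(twice$values - once$values)),
               mean(abs(ref2 - ref)), tolerance = 0.2)
})

test_that("batch confounded 1:1 with a covariate level is refused by name", {
  d <- do.call(rbind, lapply(1:2, function(b) {
    data.frame(sample_id = paste0("b", b, "_", 1:4),
               cell_line = paste0("CL", b),
               treatment = if (b == 1) "SL" else "2i",
               timepoint = if (b == 1) 0 else 1, plex = paste0("px", b),
               replicate = 1:4, stringsAsFactors = FALSE)
  }))
  v <- matrix(rnorm(100 * 8, 25), 100,
              dimnames = list(sprintf("f%03d", 1:100), d$sample_id))
  expect_error(batch_adjust_eb(expression_matrix(v, d, "protein")),
               "confounded")
})

test_that("ratios subtract the mean of the same-plex SL reference channels", {
  d <- tiny_design(n_treated = 1, treatments = "2i")
  d <- rbind(d, within(d[1, ], {
    sample_id <- "px1_ref2"; replicate <- 2
  }))
  v <- matrix(c(24, 26, 26), 1,
              dimnames = list("f1", c("px1_ref", "px1_t1", "px1_ref2")))
  m <- expression_matrix(v, d[match(colnames(v), d$sample_id), ], "protein")
  r <- ratios_vs_reference(m)
  expect_equal(unname(r$values["f1", "px1_t1"]), 1)    # 26 - mean(24, 26)
  expect_equal(unname(r$values["f1", "px1_ref"]), -1)
  # plex without a reference errors
  d2 <- tiny_design()[2:4, ]
  v2 <- matrix(rnorm(3), 1, dimnames = list("f1", d2$sample_id))
  expect_error(ratios_vs_reference(expression_matrix(v2, d2, "protein")),
               "lacks an SL reference")
})

test_that("collapse_and_zscore averages replicates then z-scores with n-1 sd", {
  # two cell lines, one treatment, three timepoints; replicates (1, 3) at t1
  d <- do.call(rbind, lapply(1:2, function(cl) {
    data.frame(sample_id = paste0("CL", cl, "_t", 1:3),
               cell_line = paste0("CL", cl), treatment = "2i",
               timepoint = 1:3, plex = paste0("CL", cl), replicate = 1,
               stringsAsFactors = FALSE)
  }))
  v <- rbind(f1 = c(1, 2, 3, 3, 2, 1),   # means (2, 2, 2): degenerate
             f2 = c(1, 1, 2, 1, 3, 5))   # means (1, 2, 3.5)
  colnames(v) <- d$sample_id
  m <- expression_matrix(v, d, "protein")
  attr(m, "ratio") <- TRUE
  tj <- collapse_and_zscore(m, mode = "per_treatment", treatments = "2i")
  expect_equal(unname(tj$z[["2i"]]["f1", ]), c(0, 0, 0))
  mu <- mean(c(1, 2, 3.5)); s <- sd(c(1, 2, 3.5))
  expect_equal(unname(tj$z[["2i"]]["f2", ]), (c(1, 2, 3.5) - mu) / s,
               tolerance = 1e-12)
  # (1, 2, 3) z-scores to (-1, 0, 1)
  expect_equal(unname((c(1, 2, 3) - 2) / sd(1:3)), c(-1, 0, 1))
})

test_that("z-scored trajectories satisfy the mean-0 sd-1 invariant per mode", {
  cfg <- sim_config(seed = 6, n_proteins = 120, n_posttx = 5)
  ratios <- ratios_vs_reference(simulate_study(cfg)$proteome)
  per <- collapse_and_zscore(ratios, mode = "per_treatment")
  for (tr in names(per$z)) {
    z <- per$z[[tr]]
    live <- apply(z, 1, function(r) any(r != 0))
    expect_lt(max(abs(rowMeans(z[live, ]))), 1e-12)
    expect_lt(max(abs(apply(z[live, ], 1, sd) - 1)), 1e-12)
  }
  conc <- collapse_and_zscore(ratios, mode = "concatenated")
  rows <- trajectory_rows(conc)
  live <- apply(rows, 1, function(r) any(r != 0))
  expect_lt(max(abs(rowMeans(rows[live, ]))), 1e-12)
  expect_lt(max(abs(apply(rows[live, ], 1, sd) - 1)), 1e-12)
})

test_that("PCA scores are deterministic, sign-fixed, and separate planted groups", {
  d <- tiny_design(n_treated = 3)
  set.seed(8)
  v <- matrix(rnorm(200 * 8, 25, 1), 200,
              dimnames = list(sprintf("f%03d", 1:200), d$sample_id))
  v[1:50, d$treatment == "2i"] <- v[1:50, d$treatment == "2i"] + 3
  m <- expression_matrix(v, d, "protein")
  pc <- pca_scores(m, 2)
  grp <- d$treatment == "2i"
  # PC1 separates the shifted group: score signs split the two groups
  expect_equal(length(unique(sign(pc$scores[grp, 1]))), 1)
  expect_equal(length(unique(sign(pc$scores[!grp, 1]))), 1)
  expect_true(sign(pc$scores[grp, 1][1]) != sign(pc$scores[!grp, 1][1]))
  # rank-1 matrix: PC1 carries all variance
  v1 <- outer(rnorm(100), seq(-1, 1, length.out = 8)) + 25
  dimnames(v1) <- list(sprintf("g%03d", 1:100), d$sample_id)
  p1 <- pca_scores(expression_matrix(v1, d, "protein"), 2)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-10)
  # duplicate samples get identical scores; missing values are refused
  vdup <- v; vdup[, 2] <- vdup[, 1]
  pd <- pca_scores(expression_matrix(vdup, d, "protein"), 2)
  expect_equal(pd$scores[1, ], pd$scores[2, ], tolerance = 1e-9)
  vna <- v; vna[1, 1] <- NA
  expect_error(pca_scores(expression_matrix(vna, d, "protein"), 2), "impute")
})
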