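test_that("fixed seed gives bit-identical simulations; layers are independent streams", {
  cfg <- sim_config(seed = 1, n_proteins = 100, n_posttx = 5,
                    n_gsk3_substrates = 5, n_phosphosites = 60,
                    n_metabolites = 40)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$proteome$values, b$proteome$values)
  expect_identical(a$mrna$values, b$mrna$values)
  expect_identical(a$truth$features, b$truth$features)
  # the metabolome stream does not depend on whether other layers ran
  m1 <- simulate_metabolome(cfg)
  simulate_study(cfg)
  m2 <- simulate_metabolome(cfg)
  expect_identical(m1$metabolome$values, m2$metabolome$values)
})

test_that("zero planted fractions give a pure baseline + batch + noise matrix", {
  cfg <- sim_config(seed = 2, n_proteins = 200, frac_shared_up = 0,
                    frac_shared_down = 0, frac_specific = 0, n_posttx = 0)
  study <- simulate_study(cfg)
  expect_true(all(study$truth$features$label == "null"))
  expect_true(all(study$truth$effects$effect == 0))
  # values decompose exactly: baseline + plex offset + channel noise
  # (treated channels at noise_sd; SL references at half, being
  # doubled-input controls)
  resid <- study$proteome$values -
    study$truth$batch_offsets[, study$proteome$design$plex]
  centered <- resid - rowMeans(resid)
  treated <- study$proteome$design$treatment != "SL"
  expect_lt(abs(sd(centered[, treated]) - cfg$noise_sd), 0.02)
  expect_lt(sd(centered[, !treated]), cfg$noise_sd)
})

test_that("planted effects are realized at the stated magnitude before noise", {
  cfg <- sim_config(seed = 3, n_proteins = 400)
  study <- simulate_study(cfg)
  tf <- study$truth$features
  eff <- study$truth$effects
  planted <- tf$feature[tf$label != "null"]
  peak <- tapply(abs(eff$effect), eff$feature, max)
  expect_true(all(peak[planted] >= 4 * cfg$noise_sd - 1e-12))
  expect_true(all(peak[setdiff(tf$feature, planted)] == 0))
  # truth labels cover exactly the generated features
  expect_setequal(tf$feature, rownames(study$proteome$values))
  # posttx features have zero mRNA effect: check the realized matrices
  mr <- study$mrna
  px <- tf$feature[tf$posttx]
  expect_lt(max(abs(rowMeans(mr$values[px, , drop = FALSE]))), 0.15)
})

test_that("a planted shared-up effect is detectable by a one-sample t at day 7", {
  # direct Monte-Carlo power check of the generator's effect-to-noise
  # contract: peak effect +1 log2, noise 0.2, 4 cell lines
  rejections <- sapply(1:500, function(seed) {
    set.seed(seed)
    ratios <- 1 + rnorm(4, 0, 0.2)
    t.test(ratios)$p.value < 0.05
  })
  expect_gte(mean(rejections), 0.95)
})

test_that("phospho layer plants coordinated substrate pairs with fitting windows", {
  cfg <- sim_config(seed = 4, n_phosphosites = 500, n_gsk3_substrates = 10)
  ph <- simulate_phospho_layer(cfg)
  gsk <- ph$truth$gsk3
  t <- ph$phospho
  sub <- gsk[gsk$class == "substrate", ]
  di <- t[match(sub$di_id, t$site_id), ]
  mono <- t[match(sub$mono_id, t$site_id), ]
  # construction invariants: S/T at center and center+4, priming = site + 4
  expect_true(all(substr(di$sequence_window, 8, 8) %in% c("S", "T")))
  expect_true(all(substr(di$sequence_window, 12, 12) %in% c("S", "T")))
  expect_true(all(mono$position == di$position + 4))
  expect_true(all(annotate_gsk3_motif(di)))
  # di-form declines by at least 1 log2 by 2 h in 2i (before noise: check
  # the realized mean across cell lines at 2 h vs the SL reference)
  design <- attr(t, "design")
  ratios <- ratios_vs_reference(phospho_values(t))
  at2h <- ratios$values[sub$di_id,
                        design$treatment == "2i" & design$timepoint == 2,
                        drop = FALSE]
  expect_true(all(rowMeans(at2h) <= -1 + 4 * cfg$noise_sd))
  mono2h <- ratios$values[sub$mono_id,
                          design$treatment == "2i" & design$timepoint == 2,
                          drop = FALSE]
  expect_true(all(rowMeans(mono2h) > -0.3))
  # localization probabilities: configured fraction below class I among
  # singletons
  singles <- t[!t$site_id %in% c(gsk$di_id, gsk$mono_id), ]
  expect_equal(mean(singles$localization_prob < 0.75), cfg$frac_lowloc,
               tolerance = 0.08)
})

test_that("zero planted substrates leave no coordinated pairs beyond chance", {
  cfg <- sim_config(seed = 5, n_phosphosites = 400, n_gsk3_substrates = 0)
  ph <- simulate_phospho_layer(cfg)
  expect_equal(nrow(ph$truth$gsk3), 0)
  diff <- fit_differential(ratios_vs_reference(phospho_values(ph$phospho)))
  calls <- call_gsk3_substrates(ph$phospho, diff)
  expect_lte(nrow(calls[calls$verdict == "substrate", ]), 1)
})

test_that("metabolome missingness: MEC blocks are whole treatments, MAR rate calibrated", {
  cfg <- sim_config(seed = 6, n_metabolites = 120, mar_rate = 0,
                    mec_rate = 0.1)
  met <- simulate_metabolome(cfg)
  mt <- met$truth$metabolites
  mec <- mt[!is.na(mt$mec_treatment), ]
  expect_gt(nrow(mec), 0)
  for (i in seq_len(nrow(mec))) {
    block <- met$metabolome$values[
      mec$feature[i], met$metabolome$design$treatment == mec$mec_treatment[i]]
    expect_equal(length(block), 16)
    expect_true(all(is.na(block)))
  }
  other <- met$metabolome$values[
    mec$feature[1], met$metabolome$design$treatment != mec$mec_treatment[1]]
  expect_true(all(!is.na(other)))
  # complete when both rates are zero
  cfg0 <- sim_config(seed = 6, n_metabolites = 60, mar_rate = 0, mec_rate = 0)
  expect_false(anyNA(simulate_metabolome(cfg0)$metabolome$values))
  # observed MAR fraction matches the nominal rate (binomial check)
  fracs <- sapply(1:30, function(seed) {
    c2 <- sim_config(seed = seed, n_metabolites = 80, mar_rate = 0.07,
                     mec_rate = 0)
    mean(is.na(simulate_metabolome(c2)$metabolome$values))
  })
  expect_lt(abs(mean(fracs) - 0.07), 0.02)
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(frac_shared_up = 0.6, frac_shared_down = 0.5),
               "sum to at most 1")
  expect_error(sim_config(mar_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_proteins = 0), ">= 1")
  expect_error(sim_config(timepoints_protein = c(1, 2)), "reference 0")
  expect_error(simulate_study(sim_config(n_proteins = 20, n_posttx = 19)),
               "n_posttx")
})
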