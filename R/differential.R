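# Empirical-Bayes moderated one-sample t-tests on log2 ratios versus the
# serum/LIF reference, with BH-FDR control and fold-change gating, plus the
# paired and correlation tests used for cross-layer comparisons.

# Solve trigamma(y) = x by Newton iteration on the decreasing convex
# function, following the standard empirical-Bayes construction.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Estimate the variance prior for moderated t-tests
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior to observed
#' per-feature sample variances: the mean and variance of log(s^2) are
#' matched to the theoretical scaled-F distribution implied by the prior
#' (d0, s0^2) and the residual degrees of freedom. When the observed
#' dispersion of log(s^2) does not exceed the pure sampling contribution,
#' the prior degrees of freedom are infinite and the moderated t becomes a
#' z-test against s0.
#'
#' @param s_sq per-feature sample variances (log2^2 units); zeros/NAs are
#'   ignored for the fit.
#' @param d residual degrees of freedom, scalar or per-feature.
#' @return object of class `VariancePrior`: list with `d0` (possibly `Inf`)
#'   and `s0_sq`.
#' @export
estimate_variance_prior <- function(s_sq, d) {
  d <- rep_len(d, length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0 & d >= 1
  if (all(!is.finite(s_sq) | s_sq == 0)) stop("all sample variances are zero")
  if (sum(ok) < 30) stop("need >= 30 features with positive variance and d >= 1")
  s_sq <- s_sq[ok]; d <- d[ok]

  z <- log(s_sq)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(d / 2))

  if (evar <= 0 || var(z) < 1e-15) {
    # No excess dispersion beyond sampling: infinite prior df. With exactly
    # constant s^2 the only consistent scale is that common value.
    s0 <- if (var(z) < 1e-15) s_sq[1] else exp(emean)
    prior <- list(d0 = Inf, s0_sq = s0)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    prior <- list(d0 = d0,
                  s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
  structure(prior, class = "VariancePrior")
}

#' Moderated one-sample t-test on log2 ratios
#'
#' For each feature, tests whether the mean log2 ratio across replicates
#' (cell lines) differs from zero, using the posterior variance
#' s~^2 = (d0 s0^2 + d s^2) / (d0 + d) and t = mean / (s~ / sqrt(n)) with
#' d0 + d degrees of freedom (standard normal when d0 is infinite).
#' Features with fewer than 2 observations get `NA` statistics.
#'
#' @param ratios numeric matrix, features x replicates, of log2 ratios; NAs
#'   allowed.
#' @param prior `VariancePrior`; if `NULL`, estimated from the data via
#'   [estimate_variance_prior()].
#' @return data.frame with `feature`, `log2FC`, `t`, `df_total`, `p`, plus
#'   `n` and the moderated variance `s2_post`.
#' @export
moderated_ttest <- function(ratios, prior = NULL) {
  ratios <- as.matrix(ratios)
  n <- rowSums(!is.na(ratios))
  fc <- rowMeans(ratios, na.rm = TRUE)
  s2 <- apply(ratios, 1, var, na.rm = TRUE)
  d <- pmax(n - 1, 0)
  if (is.null(prior)) prior <- estimate_variance_prior(s2, d)

  if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s0_sq, length(fc))
    df_total <- rep(Inf, length(fc))
  } else {
    s2_post <- (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
    df_total <- prior$d0 + d
  }
  t_stat <- fc / sqrt(s2_post / n)
  p <- ifelse(is.infinite(df_total),
              2 * pnorm(-abs(t_stat)),
              2 * pt(-abs(t_stat), df_total))
  low_n <- n < 2
  t_stat[low_n] <- NA_real_
  p[low_n] <- NA_real_
  fc[n < 1] <- NA_real_
  data.frame(feature = rownames(ratios), log2FC = fc, t = t_stat,
             df_total = df_total, p = p, n = n, s2_post = s2_post,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (q-values), monotone and capped at 1; NAs are
#' excluded from the family and propagated.
#'
#' @param p p-value vector in [0, 1].
#' @return q-value vector.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag regulated features
#'
#' A feature is called `up` (`down`) at a contrast when its q-value is
#' below `q_max` and its log2 fold change is at least `fc_min` in magnitude
#' with the corresponding sign; otherwise `none`.
#'
#' @param table data.frame with `log2FC` and `q` columns.
#' @param q_max FDR threshold (default 0.05).
#' @param fc_min minimum absolute log2 fold change (default 0.1).
#' @return the table with a `regulated` factor column.
#' @export
call_regulated <- function(table, q_max = 0.05, fc_min = 0.1) {
  reg <- rep("none", nrow(table))
  ok <- !is.na(table$q) & !is.na(table$log2FC) & table$q < q_max
  reg[ok & table$log2FC >= fc_min] <- "up"
  reg[ok & table$log2FC <= -fc_min] <- "down"
  table$regulated <- factor(reg, levels = c("up", "down", "none"))
  table
}

#' Per-contrast moderated differential analysis
#'
#' Runs the moderated one-sample t-test separately for every
#' (treatment, timepoint) contrast present in a log2-ratio matrix, with one
#' variance prior and one BH family per contrast, then applies the
#' regulated-call gate. Replicates are the cell lines: each contrast column
#' set is averaged within cell line before testing, so n equals the number
#' of cell lines.
#'
#' @param ratios ExpressionMatrix of log2 ratios versus the reference
#'   (see [ratios_vs_reference()]); SL reference columns are ignored.
#' @param q_max,fc_min thresholds passed to [call_regulated()].
#' @return `DifferentialTable` data.frame: `feature`, `treatment`,
#'   `timepoint`, `log2FC`, `t`, `df_total`, `p`, `q`, `regulated`.
#' @export
fit_differential <- function(ratios, q_max = 0.05, fc_min = 0.1) {
  d <- ratios$design
  contrasts <- unique(d[d$treatment != "SL", c("treatment", "timepoint")])
  contrasts <- contrasts[order(contrasts$treatment, contrasts$timepoint), ]
  out <- vector("list", nrow(contrasts))
  for (ci in seq_len(nrow(contrasts))) {
    tr <- contrasts$treatment[ci]; tp <- contrasts$timepoint[ci]
    cols <- which(d$treatment == tr & d$timepoint == tp)
    lines <- d$cell_line[cols]
    # one value per cell line: average technical duplicates if present
    reps <- vapply(unique(lines), function(cl) {
      rowMeans(ratios$values[, cols[lines == cl], drop = FALSE], na.rm = TRUE)
    }, numeric(n_features(ratios)))
    res <- moderated_ttest(reps)
    res$q <- bh_adjust(res$p)
    res <- call_regulated(res, q_max = q_max, fc_min = fc_min)
    res$treatment <- tr
    res$timepoint <- tp
    out[[ci]] <- res[, c("feature", "treatment", "timepoint", "log2FC", "t",
                         "df_total", "p", "q", "regulated", "n")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("DifferentialTable", "data.frame")
  res
}

#' Paired shift test between matched protein and mRNA ratios
#'
#' One-sample two-sided t-test on the paired differences x - y.
#'
#' @param x,y equal-length matched numeric vectors (n >= 3).
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_shift_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3) {
    stop("need matched vectors with n >= 3")
  }
  dd <- x - y
  if (sd(dd) == 0) {
    if (all(dd == 0)) return(list(t = 0, df = length(dd) - 1, p = 1,
                                  mean_diff = 0, n = length(dd)))
    warning("constant nonzero differences: zero variance, reporting p = 0")
    return(list(t = sign(dd[1]) * Inf, df = length(dd) - 1, p = 0,
                mean_diff = mean(dd), n = length(dd)))
  }
  tt <- t.test(dd)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(dd), n = length(dd))
}

#' Two-tailed Pearson correlation test
#'
#' @param a,b finite numeric vectors of equal length, n >= 3.
#' @return list of class `CorrelationResult`: `r`, `n`, `p`.
#' @export
pearson_cor_test <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need n >= 3 finite paired values")
  if (sd(a) == 0 || sd(b) == 0) {
    stop("correlation undefined: zero variance in one of the vectors")
  }
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(a), p = ct$p.value),
            class = "CorrelationResult")
}
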