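# Within-plex normalization, cross-plex batch adjustment, ratio formation
# against the serum/LIF reference, trajectory collapsing/z-scoring, and PCA.

#' Cyclic loess normalization within each plex
#'
#' For every pair of samples in a plex, the log-ratio M = x_i - x_j is
#' smoothed against the average intensity A = (x_i + x_j) / 2 with a local
#' regression of span `span`; half of the fitted trend is subtracted from
#' one member and added to the other. All pairs are visited `iterations`
#' times. Missing values are ignored pairwise; single-sample plexes are
#' returned unchanged with a warning.
#'
#' @param m ExpressionMatrix of log2 abundances.
#' @param span local-regression span (default 0.7).
#' @param iterations number of cyclic passes (default 3).
#' @return normalized ExpressionMatrix.
#' @export
cyclic_loess_normalize <- function(m, span = 0.7, iterations = 3) {
  v <- m$values
  for (px in unique(m$design$plex)) {
    cols <- which(m$design$plex == px)
    if (length(cols) < 2) {
      warning("plex '", px, "' has a single sample; left unchanged")
      next
    }
    v[, cols] <- cyclic_loess_core(v[, cols, drop = FALSE], span, iterations)
  }
  expression_matrix(v, m$design, m$layer, row_flags = attr(m, "row_flags"))
}

cyclic_loess_core <- function(x, span, iterations) {
  ns <- ncol(x)
  for (it in seq_len(iterations)) {
    for (i in seq_len(ns - 1)) {
      for (j in (i + 1):ns) {
        ok <- is.finite(x[, i]) & is.finite(x[, j])
        if (sum(ok) < 10) next
        a <- (x[ok, i] + x[ok, j]) / 2
        mm <- x[ok, i] - x[ok, j]
        fit <- lowess(a, mm, f = span)
        trend <- approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
        x[ok, i] <- x[ok, i] - trend / 2
        x[ok, j] <- x[ok, j] + trend / 2
      }
    }
  }
  x
}

#' Empirical-Bayes batch adjustment across plexes
#'
#' Parametric location/scale adjustment in the ComBat style: features are
#' standardized under a model retaining the biological covariates
#' (treatment x timepoint), per-batch per-feature location and scale are
#' shrunk toward method-of-moments hyperpriors (normal prior on locations,
#' inverse-gamma on scales), batch terms are removed, and the data are
#' restored to the original scale with covariate effects intact.
#'
#' @param m ExpressionMatrix of log2 abundances (complete; NAs not
#'   supported in the adjustment).
#' @param mean_only logical; skip the scale adjustment (used automatically
#'   for batches with < 3 samples).
#' @return adjusted ExpressionMatrix.
#' @export
batch_adjust_eb <- function(m, mean_only = FALSE) {
  d <- m$design
  batch <- factor(d$plex)
  if (nlevels(batch) < 2) return(m)
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples")

  group <- factor(paste(d$treatment, d$timepoint, sep = "_"))
  # a batch holding exactly one covariate level that occurs nowhere else
  # cannot be separated from it
  if (nlevels(group) > 1) {
    tab <- table(batch, group) > 0
    lone <- rownames(tab)[vapply(seq_len(nrow(tab)), function(b) {
      gl <- which(tab[b, ])
      length(gl) == 1 && sum(tab[, gl]) == 1
    }, TRUE)]
    if (length(lone) > 0) {
      stop("batch confounded 1:1 with a covariate level: batch ",
           paste(lone, collapse = ", "))
    }
  }

  y <- m$values
  if (anyNA(y)) stop("batch adjustment requires a complete matrix")
  nb <- nlevels(batch)
  batch_design <- model.matrix(~ 0 + batch)
  mod <- if (nlevels(group) > 1) model.matrix(~ group)[, -1, drop = FALSE]
         else NULL
  X <- cbind(batch_design, mod)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient: batch confounded with covariates")
  }

  beta <- t(solve(crossprod(X), crossprod(X, t(y))))
  n_batches <- colSums(batch_design)
  grand <- beta[, seq_len(nb), drop = FALSE] %*% (n_batches / sum(n_batches))
  stand_mean <- matrix(grand, nrow(y), ncol(y))
  if (!is.null(mod)) {
    stand_mean <- stand_mean + beta[, -(1:nb), drop = FALSE] %*% t(mod)
  }
  resid <- y - t(X %*% t(beta))
  var_pooled <- rowSums(resid^2) / ncol(y)
  var_pooled[var_pooled < 1e-12] <- 1e-12
  z <- (y - stand_mean) / sqrt(var_pooled)

  for (b in levels(batch)) {
    cols <- which(batch == b)
    gamma_hat <- rowMeans(z[, cols, drop = FALSE])
    if (length(cols) < 3 || mean_only) {
      delta_star <- rep(1, nrow(z))
      gamma_star <- shrink_location(gamma_hat, rep(1, nrow(z)), length(cols))
    } else {
      delta_hat <- apply(z[, cols, drop = FALSE], 1, var)
      eb <- eb_location_scale(z[, cols, drop = FALSE], gamma_hat, delta_hat)
      gamma_star <- eb$gamma; delta_star <- eb$delta
    }
    z[, cols] <- (z[, cols, drop = FALSE] - gamma_star) / sqrt(delta_star)
  }
  out <- z * sqrt(var_pooled) + stand_mean
  expression_matrix(out, d, m$layer, row_flags = attr(m, "row_flags"))
}

# Normal-prior shrinkage of batch locations when scales are held at 1.
shrink_location <- function(gamma_hat, delta_star, n) {
  g_bar <- mean(gamma_hat); t2 <- var(gamma_hat)
  if (!is.finite(t2) || t2 <= 0) return(rep(g_bar, length(gamma_hat)))
  (t2 * n * gamma_hat + delta_star * g_bar) / (t2 * n + delta_star)
}

# Joint EB location/scale estimation for one batch (parametric fixed-point
# iteration; normal prior on location, inverse-gamma on scale, hyperpriors
# by method of moments).
eb_location_scale <- function(zb, gamma_hat, delta_hat, tol = 1e-4) {
  n <- ncol(zb)
  g_bar <- mean(gamma_hat); t2 <- var(gamma_hat)
  m_d <- mean(delta_hat); v_d <- var(delta_hat)
  a_prior <- (2 * v_d + m_d^2) / v_d
  b_prior <- (m_d * v_d + m_d^3) / v_d
  if (!is.finite(a_prior) || !is.finite(b_prior) || v_d <= 0) {
    return(list(gamma = shrink_location(gamma_hat, delta_hat, n),
                delta = delta_hat))
  }
  gamma <- gamma_hat; delta <- delta_hat
  for (iter in 1:100) {
    gamma_new <- (t2 * n * gamma_hat + delta * g_bar) / (t2 * n + delta)
    sse <- rowSums((zb - gamma_new)^2)
    delta_new <- (0.5 * sse + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(gamma_new - gamma) / pmax(abs(gamma), 1e-8),
                  abs(delta_new - delta) / pmax(delta, 1e-8))
    gamma <- gamma_new; delta <- delta_new
    if (change < tol) break
  }
  list(gamma = gamma, delta = delta)
}

#' Log2 ratios against the within-plex serum/LIF reference
#'
#' Per plex, subtracts the mean of that plex's SL reference channel(s) from
#' every channel; the layer becomes a log2-ratio layer. The doubled-input
#' control channels are ordinary references after normalization.
#'
#' @param m ExpressionMatrix of log2 abundances with >= 1 SL channel per
#'   plex.
#' @return ExpressionMatrix of log2 ratios.
#' @export
ratios_vs_reference <- function(m) {
  v <- m$values
  for (px in unique(m$design$plex)) {
    cols <- which(m$design$plex == px)
    ref <- cols[m$design$treatment[cols] == "SL"]
    if (length(ref) == 0) stop("plex '", px, "' lacks an SL reference channel")
    ref_mean <- rowMeans(v[, ref, drop = FALSE], na.rm = TRUE)
    v[, cols] <- v[, cols, drop = FALSE] - ref_mean
  }
  out <- expression_matrix(v, m$design, m$layer,
                           row_flags = attr(m, "row_flags"))
  attr(out, "ratio") <- TRUE
  out
}

#' Collapse replicates and z-score temporal trajectories
#'
#' Averages log2 ratios over replicates (cell lines) per treatment and
#' timepoint, then z-scores each feature's trajectory using the sample
#' (n - 1) standard deviation. With `mode = "concatenated"` (default) the
#' 2i and Cdk8/19i trajectories are concatenated before z-scoring, so both
#' treatments share one scale per feature; `mode = "per_treatment"` scales
#' each treatment separately. Constant trajectories map to all zeros. The
#' timepoint-0 reference (ratio 0 by construction) is excluded.
#'
#' @param ratios ExpressionMatrix of log2 ratios.
#' @param mode `"concatenated"` or `"per_treatment"`.
#' @param treatments treatments to include (default the non-SL ones
#'   present).
#' @return object of class `TrajectoryMatrix`: list with `z` (named list of
#'   feature x timepoint matrices per treatment), `timepoints`, `mode`.
#' @export
collapse_and_zscore <- function(ratios, mode = c("concatenated",
                                                 "per_treatment"),
                                treatments = NULL) {
  mode <- match.arg(mode)
  d <- ratios$design
  if (is.null(treatments)) {
    treatments <- setdiff(unique(d$treatment), "SL")
  }
  tps <- sort(unique(d$timepoint[d$treatment %in% treatments & d$timepoint > 0]))
  if (length(tps) < 2) stop("need >= 2 timepoints per treatment")

  means <- lapply(treatments, function(tr) {
    sapply(tps, function(tp) {
      cols <- which(d$treatment == tr & d$timepoint == tp)
      if (length(cols) == 0) {
        stop("no samples for treatment ", tr, " at timepoint ", tp)
      }
      rowMeans(ratios$values[, cols, drop = FALSE], na.rm = TRUE)
    })
  })
  names(means) <- treatments
  for (tr in treatments) colnames(means[[tr]]) <- as.character(tps)

  z <- means
  if (mode == "concatenated") {
    cat_mat <- do.call(cbind, means)
    mu <- rowMeans(cat_mat)
    s <- apply(cat_mat, 1, sd)
    for (tr in treatments) {
      z[[tr]] <- (means[[tr]] - mu) / ifelse(s > 0, s, Inf)
    }
  } else {
    for (tr in treatments) {
      mu <- rowMeans(means[[tr]])
      s <- apply(means[[tr]], 1, sd)
      z[[tr]] <- (means[[tr]] - mu) / ifelse(s > 0, s, Inf)
    }
  }
  structure(list(z = z, timepoints = tps, mode = mode,
                 feature_ids = rownames(ratios$values)),
            class = "TrajectoryMatrix")
}

#' Concatenate the per-treatment z-trajectories into one matrix
#'
#' @param t TrajectoryMatrix.
#' @return features x (treatments * timepoints) matrix.
#' @export
trajectory_rows <- function(t) {
  out <- do.call(cbind, t$z)
  colnames(out) <- unlist(lapply(names(t$z), function(tr) {
    paste(tr, colnames(t$z[[tr]]), sep = "_")
  }))
  out
}

#' PCA sample scores
#'
#' Feature-centered singular value decomposition; component signs are fixed
#' so that each component's largest-magnitude loading is positive, making
#' scores deterministic.
#'
#' @param m ExpressionMatrix (complete; impute metabolites first).
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `variance_fraction`.
#' @export
pca_scores <- function(m, n_components = 2) {
  if (anyNA(m$values)) {
    stop("matrix contains missing values; impute before PCA")
  }
  pc <- prcomp(t(m$values), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    j <- which.max(abs(pc$rotation[, i]))
    if (pc$rotation[j, i] < 0) scores[, i] <- -scores[, i]
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, variance_fraction = vf[seq_len(k)])
}
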