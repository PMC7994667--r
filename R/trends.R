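# Temporal module discovery: per-feature trend correlation between
# treatments, gap-statistic selection of the cluster number, k-means
# clustering of z-scored trajectories, and centroid correlations.

#' Per-feature correlation between the 2i and Cdk8/19i trajectories
#'
#' @param t TrajectoryMatrix with both treatments on the same timepoint
#'   grid.
#' @param r_min retention threshold for the correlated subset (default
#'   0.6).
#' @param treatments the two treatments to compare.
#' @return data.frame `feature`, `r`, `n`, `p`, `retained`; features with a
#'   constant trajectory in either treatment are reported with NA and a
#'   `skipped` reason. The retained feature ids are also in
#'   `attr(, "retained")`.
#' @export
trend_correlation <- function(t, r_min = 0.6, treatments = c("2i", "Cdk8i")) {
  stopifnot(all(treatments %in% names(t$z)))
  a <- t$z[[treatments[1]]]
  b <- t$z[[treatments[2]]]
  if (!identical(dim(a), dim(b))) stop("treatments must share a timepoint grid")
  out <- data.frame(feature = t$feature_ids, r = NA_real_,
                    n = ncol(a), p = NA_real_, retained = FALSE,
                    skipped = NA_character_, stringsAsFactors = FALSE)
  for (f in seq_len(nrow(a))) {
    if (sd(a[f, ]) == 0 || sd(b[f, ]) == 0) {
      out$skipped[f] <- "constant trajectory"
      next
    }
    ct <- pearson_cor_test(a[f, ], b[f, ])
    out$r[f] <- ct$r; out$p[f] <- ct$p
  }
  out$retained <- !is.na(out$r) & out$r > r_min
  attr(out, "retained") <- out$feature[out$retained]
  out
}

# Within-cluster dispersion: sum over clusters of (1/(2 n_r)) x the sum of
# pairwise squared Euclidean distances, which equals the within-cluster sum
# of squares around centroids.
within_dispersion <- function(x, cluster) {
  sum(vapply(split(seq_len(nrow(x)), cluster), function(rows) {
    xc <- x[rows, , drop = FALSE]
    sum(sweep(xc, 2, colMeans(xc))^2)
  }, numeric(1)))
}

#' Gap statistic for choosing the number of clusters
#'
#' Compares log within-cluster dispersion of k-means solutions against B
#' reference datasets drawn uniformly over each dimension's observed range:
#' Gap(k) = mean_b log W*_kb - log W_k with simulation spread
#' s_k = sd_b(log W*_kb) sqrt(1 + 1/B). The chosen K is the smallest k with
#' Gap(k) >= Gap(k+1) - s_{k+1}.
#'
#' @param x numeric matrix of trajectory rows.
#' @param k_max largest k scanned (default 20).
#' @param B reference datasets (default 50).
#' @param seed RNG seed.
#' @param restarts k-means restarts per fit (default 25).
#' @return object of class `GapProfile`: data.frame `k`, `W`, `logW`,
#'   `E_logW`, `gap`, `s`, plus `chosen_K` attribute (also `$chosen_K`).
#' @export
gap_statistic <- function(x, k_max = 20, B = 50, seed = 1, restarts = 25) {
  x <- as.matrix(x)
  if (k_max >= nrow(x)) stop("k_max must be smaller than the number of rows")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  ks <- seq_len(k_max)
  logW <- vapply(ks, function(k) log(kmeans_W(x, k, restarts)), numeric(1))
  rng <- apply(x, 2, range)
  logWstar <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    ref <- sapply(seq_len(ncol(x)), function(j) {
      runif(nrow(x), rng[1, j], rng[2, j])
    })
    logWstar[b, ] <- vapply(ks, function(k) log(kmeans_W(ref, k, restarts)),
                            numeric(1))
  }
  gap <- colMeans(logWstar) - logW
  s <- apply(logWstar, 2, sd) * sqrt(1 + 1 / B)
  chosen <- k_max
  for (k in seq_len(k_max - 1)) {
    if (gap[k] >= gap[k + 1] - s[k + 1]) { chosen <- k; break }
  }
  out <- data.frame(k = ks, W = exp(logW), logW = logW,
                    E_logW = colMeans(logWstar), gap = gap, s = s)
  attr(out, "chosen_K") <- chosen
  class(out) <- c("GapProfile", "data.frame")
  out
}

#' Chosen cluster number from a gap profile
#'
#' @param gap `GapProfile` from [gap_statistic()].
#' @return the selected K.
#' @export
chosen_K <- function(gap) attr(gap, "chosen_K")

kmeans_W <- function(x, k, restarts) {
  if (k == 1) return(within_dispersion(x, rep(1, nrow(x))))
  fit <- suppressWarnings(kmeans(x, k, nstart = restarts, iter.max = 50))
  fit$tot.withinss
}

#' K-means clustering of z-scored trajectories
#'
#' Lloyd-style k-means (Hartigan-Wong refinement, best of `restarts`
#' initializations by within-cluster dispersion), deterministic given the
#' seed. Cluster labels are relabelled by decreasing cluster size so the
#' output is stable across platforms.
#'
#' @param t TrajectoryMatrix (or a plain matrix of trajectory rows).
#' @param K number of clusters.
#' @param seed RNG seed.
#' @param restarts initializations (default 25).
#' @return object of class `TrendClusterModel`: list with `assignments`
#'   (named integer vector), `centroids` (per treatment, cluster x
#'   timepoint matrices; for plain-matrix input a single `all` matrix),
#'   `W` (within-cluster dispersion), `K`.
#' @export
kmeans_trajectories <- function(t, K, seed = 1, restarts = 25) {
  x <- if (inherits(t, "TrajectoryMatrix")) trajectory_rows(t) else as.matrix(t)
  if (K > nrow(x)) stop("K cannot exceed the number of rows")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  if (K == nrow(x)) {
    # one point per cluster: zero dispersion, identity assignment
    fit <- list(cluster = seq_len(K), centers = x, size = rep(1L, K),
                tot.withinss = 0)
  } else {
    fit <- suppressWarnings(kmeans(x, K, nstart = restarts, iter.max = 100))
  }
  # relabel by decreasing size, ties by first occurrence
  sizes <- fit$size
  relabel <- order(order(-sizes, seq_along(sizes)))
  assignments <- setNames(relabel[fit$cluster], rownames(x))
  centers <- fit$centers[order(-sizes, seq_along(sizes)), , drop = FALSE]
  rownames(centers) <- seq_len(K)

  centroids <- if (inherits(t, "TrajectoryMatrix")) {
    ntp <- length(t$timepoints)
    trs <- names(t$z)
    setNames(lapply(seq_along(trs), function(i) {
      cm <- centers[, (i - 1) * ntp + seq_len(ntp), drop = FALSE]
      colnames(cm) <- as.character(t$timepoints)
      cm
    }), trs)
  } else list(all = centers)

  structure(list(assignments = assignments, centroids = centroids,
                 W = fit$tot.withinss, K = K),
            class = "TrendClusterModel")
}

#' Per-cluster correlation between treatment centroids
#'
#' @param model TrendClusterModel with centroids for both treatments.
#' @param treatments the two treatments to compare.
#' @return data.frame `cluster`, `r`, `n`, `p`; degenerate (constant)
#'   centroids are reported as NA with `note = "degenerate"`.
#' @export
centroid_correlation <- function(model, treatments = c("2i", "Cdk8i")) {
  stopifnot(all(treatments %in% names(model$centroids)))
  a <- model$centroids[[treatments[1]]]
  b <- model$centroids[[treatments[2]]]
  out <- data.frame(cluster = seq_len(nrow(a)), r = NA_real_,
                    n = ncol(a), p = NA_real_, note = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(a))) {
    if (sd(a[k, ]) == 0 || sd(b[k, ]) == 0) {
      out$note[k] <- "degenerate"
      next
    }
    ct <- pearson_cor_test(a[k, ], b[k, ])
    out$r[k] <- ct$r; out$p[k] <- ct$p
  }
  out
}
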