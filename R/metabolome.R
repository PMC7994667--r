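# Metabolite-specific preprocessing: presence filtering, classification of
# missingness into missing-at-random (MAR) versus missing-in-an-entire-
# condition (MEC, treated as left-censored), imputation, and quantile
# centering to the median.

#' Drop samples dominated by missing values
#'
#' Samples with more than `max_missing` missing fraction are removed before
#' analysis, mirroring the occasional whole-sample failure in metabolomics
#' runs; removals are reported via a message.
#'
#' @param m ExpressionMatrix.
#' @param max_missing maximum tolerated missing fraction per sample
#'   (default 0.5).
#' @return ExpressionMatrix without the failing samples.
#' @export
drop_failed_samples <- function(m, max_missing = 0.5) {
  frac <- colMeans(is.na(m$values))
  bad <- frac > max_missing
  if (any(bad)) {
    message("dropping sample(s) with >", max_missing * 100, "% missing: ",
            paste(m$design$sample_id[bad], collapse = ", "))
    m <- subset_matrix(m, samples = which(!bad))
  }
  m
}

#' Filter metabolites by within-treatment presence
#'
#' Keeps a feature when its observed fraction reaches `min_fraction` in at
#' least one treatment group.
#'
#' @param m ExpressionMatrix.
#' @param min_fraction required observed fraction (default 0.75).
#' @return filtered ExpressionMatrix.
#' @export
filter_by_presence <- function(m, min_fraction = 0.75) {
  treatments <- unique(m$design$treatment)
  if (length(treatments) < 1) stop("design has no treatment groups")
  ok <- Reduce(`|`, lapply(treatments, function(tr) {
    cols <- m$design$treatment == tr
    rowMeans(!is.na(m$values[, cols, drop = FALSE])) >= min_fraction
  }))
  subset_matrix(m, features = ok)
}

#' Classify missing cells as MAR or MEC
#'
#' A missing cell is MEC when every sample of its (feature, treatment)
#' block is missing; every other missing cell is MAR.
#'
#' @param m ExpressionMatrix.
#' @return object of class `MissingnessMap`: list with `class` (character
#'   matrix `observed`/`MAR`/`MEC` aligned with the values) and
#'   `observed_count` (feature x treatment observed counts).
#' @export
classify_missingness <- function(m) {
  cls <- matrix("observed", nrow(m$values), ncol(m$values),
                dimnames = dimnames(m$values))
  cls[is.na(m$values)] <- "MAR"
  treatments <- unique(m$design$treatment)
  counts <- sapply(treatments, function(tr) {
    cols <- m$design$treatment == tr
    rowSums(!is.na(m$values[, cols, drop = FALSE]))
  })
  rownames(counts) <- rownames(m$values)
  for (tr in treatments) {
    cols <- m$design$treatment == tr
    mec_rows <- counts[, tr] == 0
    cls[mec_rows, cols] <- "MEC"
  }
  structure(list(class = cls, observed_count = counts),
            class = "MissingnessMap")
}

#' Imputation configuration
#'
#' @param mec_quantile_bound percentile (0-50, exclusive) of the receiving
#'   sample's observed values bounding MEC draws from above; default 2.5.
#' @param mar_method `"condition_normal"` (draw from the feature's observed
#'   Normal within the same treatment) — the only method currently
#'   implemented.
#' @param seed RNG seed for reproducible draws.
#' @return `ImputeConfig` list.
#' @export
impute_config <- function(mec_quantile_bound = 2.5,
                          mar_method = "condition_normal", seed = 1L) {
  if (mec_quantile_bound <= 0 || mec_quantile_bound >= 50) {
    stop("mec_quantile_bound must lie strictly between 0 and 50")
  }
  mar_method <- match.arg(mar_method, "condition_normal")
  structure(list(mec_quantile_bound = mec_quantile_bound,
                 mar_method = mar_method, seed = as.integer(seed)),
            class = "ImputeConfig")
}

#' Impute missing metabolite values
#'
#' MAR cells are drawn from Normal(mean, sd) of the feature's observed
#' values within the same treatment (falling back to all treatments when
#' fewer than two observations are available there; an sd of zero yields
#' the deterministic mean). MEC cells are treated as left-censored: each is
#' drawn uniformly from (q - 0.5, q], where q is the configured percentile
#' of the receiving sample's observed values, so MEC imputations never
#' exceed that per-sample bound. Observed cells are never altered.
#'
#' @param m ExpressionMatrix with missing values.
#' @param map [classify_missingness()] output.
#' @param cfg [impute_config()].
#' @return complete ExpressionMatrix.
#' @export
impute <- function(m, map, cfg = impute_config()) {
  if (any(rowSums(!is.na(m$values)) == 0)) {
    stop("feature(s) with zero observations cannot be imputed")
  }
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  v <- m$values
  d <- m$design
  # per-sample left-tail bounds from observed values only
  q_bound <- apply(v, 2, function(col) {
    quantile(col, cfg$mec_quantile_bound / 100, na.rm = TRUE, names = FALSE)
  })

  for (f in seq_len(nrow(v))) {
    miss <- which(is.na(v[f, ]))
    for (s in miss) {
      if (map$class[f, s] == "MEC") {
        v[f, s] <- runif(1, q_bound[s] - 0.5, q_bound[s])
      } else {
        tr <- d$treatment[s]
        obs <- m$values[f, d$treatment == tr]
        obs <- obs[!is.na(obs)]
        if (length(obs) < 2) {
          obs <- m$values[f, !is.na(m$values[f, ])]
        }
        mu <- mean(obs)
        sdv <- if (length(obs) > 1) sd(obs) else 0
        v[f, s] <- if (sdv == 0) mu else rnorm(1, mu, sdv)
      }
    }
  }
  expression_matrix(v, d, m$layer)
}

#' Quantile centering to the median
#'
#' Subtracts each sample's median and adds back the grand median of the
#' pre-centering sample medians, so that afterwards every sample median
#' equals the grand median.
#'
#' @param m complete ExpressionMatrix.
#' @return centered ExpressionMatrix.
#' @export
quantile_center_median <- function(m) {
  med <- apply(m$values, 2, median, na.rm = TRUE)
  grand <- median(med)
  v <- sweep(m$values, 2, med - grand)
  expression_matrix(v, m$design, m$layer)
}
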