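# Shared fixtures and independent oracles, built in code at test time.

# Minimal two-plex design: each plex has one SL reference and `n_treated`
# treated channels for one treatment.
tiny_design <- function(n_treated = 3, treatments = c("2i", "Cdk8i"),
                        timepoints = seq_len(n_treated)) {
  do.call(rbind, lapply(seq_along(treatments), function(i) {
    tr <- treatments[i]
    px <- paste0("px", i)
    rbind(
      data.frame(sample_id = paste0(px, "_ref"), cell_line = paste0("CL", i),
                 treatment = "SL", timepoint = 0, plex = px, replicate = 1,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = paste0(px, "_t", timepoints),
                 cell_line = paste0("CL", i), treatment = tr,
                 timepoint = timepoints, plex = px, replicate = 1,
                 stringsAsFactors = FALSE))
  }))
}

random_expression <- function(n_features, design, seed = 1, mean = 25,
                              sd = 2) {
  set.seed(seed)
  v <- matrix(rnorm(n_features * nrow(design), mean, sd), n_features,
              dimnames = list(sprintf("f%04d", seq_len(n_features)),
                              design$sample_id))
  expression_matrix(v, design, "protein")
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail: draw all
# C(N, n) subsets of the universe and count overlaps >= k with a fixed
# K-subset.
enumerate_overlap_tail <- function(k, K, n, N) {
  universe <- seq_len(N)
  set1 <- seq_len(K)
  draws <- utils::combn(universe, n)
  mean(colSums(matrix(draws %in% set1, nrow = n)) >= k)
}

# Brute-force BH step-up: q_i = min over j with p_(j) >= p_(i)-rank of
# p_(j) * m / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(p[o][r:m] * m / (r:m)))
  }
  q
}

# One-sample-per-cell-line ratio matrix from an ExpressionMatrix, for one
# treatment and timepoint (used to probe moderated tests directly).
ratios_for_contrast <- function(ratios, treatment, timepoint) {
  d <- ratios$design
  cols <- which(d$treatment == treatment & d$timepoint == timepoint)
  out <- ratios$values[, cols, drop = FALSE]
  colnames(out) <- d$cell_line[cols]
  out
}

# (feature, treatment) pairs with planted protein effect, for divergence
# recovery scoring.
posttx_truth_pairs <- function(truth) {
  px <- truth$features[truth$features$posttx, ]
  unlist(lapply(seq_len(nrow(px)), function(i) {
    trs <- if (px$label[i] == "specific") px$specific_treatment[i]
           else c("2i", "Cdk8i")
    paste(px$feature[i], trs)
  }))
}

# Features eligible for a post-transcriptional verdict: protein regulated
# at >= 2 timepoints within one treatment.
eligible_features <- function(diff_table, min_timepoints = 2) {
  regtab <- stats::aggregate(regulated != "none" ~ feature + treatment,
                             data = diff_table, FUN = sum)
  names(regtab)[3] <- "k"
  unique(regtab$feature[regtab$k >= min_timepoints])
}
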