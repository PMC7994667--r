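# Cross-layer protein-versus-mRNA comparison: post-transcriptional
# divergence classification and paired subset shift reporting.

#' Classify protein/mRNA divergence per feature and contrast
#'
#' Joins the protein and mRNA differential tables on
#' (feature, treatment, timepoint) and assigns one class per joined row:
#' `protein_up_mrna_flat` when the protein is regulated up (per the
#' [call_regulated()] gate) while the mRNA shows no change (q >= `q_max`
#' AND |log2FC| < `fc_min` — both conditions, stricter than either alone);
#' `protein_down_mrna_flat` symmetrically; `concordant` when both layers
#' are regulated in the same direction; `none` otherwise. Features present
#' in only one layer are excluded and counted in the coverage attribute.
#'
#' @param protein,mrna `DifferentialTable`s sharing feature ids and a
#'   (treatment, timepoint) grid.
#' @param fc_min,q_max thresholds (defaults 0.1 and 0.05).
#' @return data.frame of class `DivergenceCall`: `feature`, `treatment`,
#'   `timepoint`, `protein_log2FC`, `protein_q`, `mrna_log2FC`, `mrna_q`,
#'   `class`; `attr(, "coverage")` reports joined/protein-only/mrna-only
#'   feature counts.
#' @export
classify_posttranscriptional <- function(protein, mrna, fc_min = 0.1,
                                         q_max = 0.05) {
  key <- function(t) paste(t$feature, t$treatment, t$timepoint, sep = "\r")
  pk <- key(protein); mk <- key(mrna)
  common <- intersect(pk, mk)
  coverage <- c(joined = length(common),
                protein_only = length(setdiff(unique(protein$feature),
                                              unique(mrna$feature))),
                mrna_only = length(setdiff(unique(mrna$feature),
                                           unique(protein$feature))))
  p <- protein[match(common, pk), ]
  m <- mrna[match(common, mk), ]

  p_reg <- call_regulated(p, q_max = q_max, fc_min = fc_min)$regulated
  m_reg <- call_regulated(m, q_max = q_max, fc_min = fc_min)$regulated
  m_flat <- (is.na(m$q) | m$q >= q_max) & abs(m$log2FC) < fc_min

  cls <- rep("none", length(common))
  cls[p_reg == "up" & m_flat] <- "protein_up_mrna_flat"
  cls[p_reg == "down" & m_flat] <- "protein_down_mrna_flat"
  cls[p_reg != "none" & p_reg == m_reg] <- "concordant"

  out <- data.frame(feature = p$feature, treatment = p$treatment,
                    timepoint = p$timepoint,
                    protein_log2FC = p$log2FC, protein_q = p$q,
                    mrna_log2FC = m$log2FC, mrna_q = m$q,
                    protein_regulated = as.character(p_reg),
                    class = factor(cls, levels = c("protein_up_mrna_flat",
                                                   "protein_down_mrna_flat",
                                                   "concordant", "none")),
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- coverage
  class(out) <- c("DivergenceCall", "data.frame")
  out
}

#' Summarize divergent features across contrasts
#'
#' Collapses per-contrast divergence calls to one verdict per feature and
#' treatment. A feature is post-transcriptional when it is divergent
#' (protein regulated, mRNA flat) at `min_divergent` or more timepoints and
#' its mRNA shows no significant change, in either direction, at any
#' timepoint where the protein is regulated. Requiring two divergent
#' timepoints protects against single-timepoint protein false positives
#' pairing with quiet mRNAs; blocking on any significant mRNA movement
#' (not just same-direction concordance) ensures the verdict means "the
#' transcript did not move while the protein did".
#'
#' @param calls `DivergenceCall` table.
#' @param min_divergent minimum number of divergent timepoints (default 2).
#' @param q_max mRNA significance threshold used for within-treatment
#'   blocking at protein-regulated timepoints (default 0.05).
#' @param q_block mRNA significance threshold for the across-course block
#'   (default 0.01): a transcript this clearly regulated anywhere in the
#'   course is not "unresponsive".
#' @return data.frame `feature`, `treatment`, `posttx` (logical),
#'   `n_divergent`, `n_concordant`, `n_mrna_moving`, `mrna_quiet`.
#' @export
summarize_divergence <- function(calls, min_divergent = 2, q_max = 0.05,
                                 q_block = 0.01) {
  quiet <- !tapply(!is.na(calls$mrna_q) & calls$mrna_q < q_block,
                   calls$feature, any)
  sp <- split(seq_len(nrow(calls)),
              list(calls$feature, calls$treatment), drop = TRUE)
  rows <- lapply(sp, function(idx) {
    f <- calls$feature[idx[1]]
    nd <- sum(calls$class[idx] %in% c("protein_up_mrna_flat",
                                      "protein_down_mrna_flat"))
    nc <- sum(calls$class[idx] == "concordant")
    moving <- sum(calls$protein_regulated[idx] != "none" &
                    !is.na(calls$mrna_q[idx]) & calls$mrna_q[idx] < q_max)
    data.frame(feature = f,
               treatment = calls$treatment[idx[1]],
               posttx = nd >= min_divergent && moving == 0 && quiet[[f]],
               n_divergent = nd, n_concordant = nc, n_mrna_moving = moving,
               mrna_quiet = quiet[[f]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$feature, out$treatment), ]
}

#' Paired shift report for a feature subset
#'
#' Restricts matched protein and mRNA log2 ratios to a subset (e.g.
#' mitochondrially annotated proteins), runs the paired two-sided t-test on
#' the differences, and reports per-layer distribution summaries using the
#' boxplot convention (median, quartiles, whiskers at 1.5 IQR).
#'
#' @param protein_ratios,mrna_ratios named numeric vectors of log2 ratios
#'   sharing feature ids.
#' @param subset character vector of feature ids, length >= 3, all present
#'   in both layers.
#' @return list with `test` ([paired_shift_test()] result) and `summary`
#'   (per-layer data.frame: median, q1, q3, whisker_low, whisker_high, n).
#' @export
subset_shift_report <- function(protein_ratios, mrna_ratios, subset) {
  shared <- intersect(names(protein_ratios), names(mrna_ratios))
  missing_ids <- setdiff(subset, shared)
  if (length(missing_ids) > 0) {
    stop("subset ids absent from the shared features: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  if (length(subset) < 3) stop("subset must contain >= 3 features")
  x <- protein_ratios[subset]
  y <- mrna_ratios[subset]
  box <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[3] - q[1]
    inside <- v[v >= q[1] - 1.5 * iqr & v <= q[3] + 1.5 * iqr]
    data.frame(median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = min(inside, na.rm = TRUE),
               whisker_high = max(inside, na.rm = TRUE),
               n = sum(is.finite(v)))
  }
  summ <- rbind(protein = box(x), mrna = box(y))
  list(test = paired_shift_test(x, y), summary = summ)
}
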