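# Class-I phosphosite filtering, Gsk3 motif annotation (S/T-X-X-X-pS/pT:
# the kinase targets S/T four residues N-terminal of a pre-phosphorylated
# priming site), and substrate inference from coordinated behavior of the
# di-phosphorylated peptidoform and its priming-only mono form.

#' Filter to class-I phosphosites
#'
#' Keeps rows whose localization probability is at least `min_prob`
#' (inclusive); 0.75 is the conventional class-I cutoff.
#'
#' @param t PhosphoSiteTable.
#' @param min_prob probability threshold (default 0.75).
#' @return filtered PhosphoSiteTable.
#' @export
filter_class1 <- function(t, min_prob = 0.75) {
  out <- t[t$localization_prob >= min_prob, , drop = FALSE]
  attr(out, "design") <- attr(t, "design")
  class(out) <- class(t)
  out
}

#' Annotate the Gsk3 consensus motif
#'
#' Flags a site when the window center residue is S or T and the residue
#' four positions C-terminal of the center is S or T (the candidate
#' pre-phosphorylated priming position).
#'
#' @param t PhosphoSiteTable (or a character vector of odd-length
#'   sequence windows).
#' @return logical vector, one flag per row/window.
#' @export
annotate_gsk3_motif <- function(t) {
  win <- if (is.character(t)) t else as.character(t$sequence_window)
  len <- nchar(win)
  center <- (len + 1) %/% 2
  ok_len <- center + 4 <= len
  if (any(!ok_len)) {
    warning(sum(!ok_len), " window(s) too short for the +4 priming ",
            "position; flagged FALSE")
  }
  cr <- substr(win, center, center)
  pr <- substr(win, center + 4, center + 4)
  ok_len & cr %in% c("S", "T") & pr %in% c("S", "T")
}

#' Infer Gsk3 substrates from priming-pair peptidoform behavior
#'
#' A class-I, motif-matching di-phosphorylated site is called a substrate
#' when its di-phospho peptidoform is significantly down-regulated in 2i
#' (log2FC <= `fc_down`, q < `q_max`) at one or more early timepoints while
#' the priming-only mono-phosphorylated form at position +4 is not
#' down-regulated there (log2FC >= 0 or not significant): loss of the
#' kinase's activity removes the second phosphate but spares the priming
#' one. Pairs where the mono form collapses together with the di form are
#' `rejected` (whole-site loss, not kinase-specific); motif sites without
#' the pattern, or without a paired mono form, are `motif_only`.
#'
#' @param t PhosphoSiteTable (unfiltered; class-I filtering is applied
#'   internally via `min_prob`).
#' @param diff_2i `DifferentialTable` over peptidoforms (feature =
#'   `site_id`) containing 2i contrasts.
#' @param q_max significance threshold (default 0.05).
#' @param fc_down maximum di-form log2FC counted as a decline (default
#'   -0.5).
#' @param min_prob class-I cutoff (default 0.75).
#' @param early_timepoints 2i evidence window in hours (default
#'   c(0.5, 1, 2, 6)).
#' @return data.frame of class `GskCall`: `protein`, `site_pos`,
#'   `priming_pos`, `di_id`, `mono_id`, `di_log2FC`, `di_q`,
#'   `mono_log2FC`, `mono_q`, `verdict`, `reason`.
#' @export
call_gsk3_substrates <- function(t, diff_2i, q_max = 0.05, fc_down = -0.5,
                                 min_prob = 0.75,
                                 early_timepoints = c(0.5, 1, 2, 6)) {
  t1 <- filter_class1(t, min_prob)
  motif <- annotate_gsk3_motif(t1)
  di <- t1[t1$multiplicity == 2 & motif, , drop = FALSE]
  if (nrow(di) == 0) {
    return(empty_gsk_calls())
  }
  d2 <- diff_2i[diff_2i$treatment == "2i" &
                  diff_2i$timepoint %in% early_timepoints, , drop = FALSE]

  calls <- lapply(seq_len(nrow(di)), function(i) {
    prot <- di$protein[i]; pos <- di$position[i]
    di_id <- di$site_id[i]
    mono <- t1[t1$protein == prot & t1$position == pos + 4 &
                 t1$multiplicity == 1, , drop = FALSE]
    di_stats <- d2[d2$feature == di_id, , drop = FALSE]
    base <- data.frame(protein = prot, site_pos = pos,
                       priming_pos = pos + 4L, di_id = di_id,
                       mono_id = NA_character_, di_log2FC = NA_real_,
                       di_q = NA_real_, mono_log2FC = NA_real_,
                       mono_q = NA_real_, verdict = "motif_only",
                       reason = NA_character_, stringsAsFactors = FALSE)
    if (nrow(di_stats) == 0) {
      base$reason <- "no differential result for di form"
      return(base)
    }
    down <- !is.na(di_stats$q) & di_stats$q < q_max &
      di_stats$log2FC <= fc_down
    j <- if (any(down)) which(down)[which.min(di_stats$log2FC[down])]
         else which.min(di_stats$log2FC)
    base$di_log2FC <- min(di_stats$log2FC[if (any(down)) down else TRUE],
                          na.rm = TRUE)
    base$di_q <- min(di_stats$q[if (any(down)) down else TRUE], na.rm = TRUE)
    if (!any(down)) {
      base$reason <- "di form not down-regulated in the early 2i window"
      return(base)
    }
    if (nrow(mono) == 0) {
      base$reason <- "unpaired"
      return(base)
    }
    mono_id <- mono$site_id[1]
    base$mono_id <- mono_id
    ok_tp <- vapply(di_stats$timepoint[down], function(tp) {
      ms <- d2[d2$feature == mono_id & d2$timepoint == tp, , drop = FALSE]
      if (nrow(ms) == 0) return(NA)
      ms$log2FC[1] >= 0 | is.na(ms$q[1]) | ms$q[1] >= q_max
    }, logical(1))
    mono_stats <- d2[d2$feature == mono_id, , drop = FALSE]
    if (nrow(mono_stats) > 0) {
      base$mono_log2FC <- mono_stats$log2FC[which.min(mono_stats$q)]
      base$mono_q <- min(mono_stats$q, na.rm = TRUE)
    }
    if (any(ok_tp, na.rm = TRUE)) {
      base$verdict <- "substrate"
    } else {
      base$verdict <- "rejected"
      base$reason <- "priming mono form also down-regulated (whole-site loss)"
    }
    base
  })
  out <- do.call(rbind, calls)
  class(out) <- c("GskCall", "data.frame")
  out
}

empty_gsk_calls <- function() {
  out <- data.frame(protein = character(), site_pos = integer(),
                    priming_pos = integer(), di_id = character(),
                    mono_id = character(), di_log2FC = numeric(),
                    di_q = numeric(), mono_log2FC = numeric(),
                    mono_q = numeric(), verdict = character(),
                    reason = character(), stringsAsFactors = FALSE)
  class(out) <- c("GskCall", "data.frame")
  out
}

#' Motif enrichment within a trend cluster
#'
#' Fisher/hypergeometric enrichment of motif-positive sites in a cluster
#' against the class-I background.
#'
#' @param cluster_sites character vector of site ids in the cluster.
#' @param background character vector of class-I site ids (the universe).
#' @param motif_flags named logical vector over the background.
#' @return [fisher_enrichment()] result.
#' @export
motif_cluster_enrichment <- function(cluster_sites, background, motif_flags) {
  if (length(cluster_sites) == 0) stop("empty cluster")
  if (!all(cluster_sites %in% background)) {
    stop("cluster sites must be a subset of the background")
  }
  fisher_enrichment(a = sum(motif_flags[cluster_sites]),
                    n = length(cluster_sites),
                    K = sum(motif_flags[background]),
                    N = length(background))
}
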