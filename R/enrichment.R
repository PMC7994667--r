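# Preranked gene-set enrichment (weighted Kolmogorov-Smirnov-style running
# sum with gene-set permutation null) and Fisher's exact category
# enrichment against a declared background.

# Running-sum enrichment score evaluated only at hit positions.
# pos: sorted 1-based positions of the set members in the ranked list;
# w: |score|^p at those positions; N: list length.
es_from_positions <- function(pos, w, N, details = FALSE) {
  nh <- length(pos)
  if (nh == 0) return(if (details) list(es = 0, at_hit = NA) else 0)
  if (nh == N) return(if (details) list(es = 1, at_hit = nh) else 1)
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  nr <- sum(w)
  cw <- cumsum(w) / if (nr > 0) nr else 1
  miss_step <- 1 / (N - nh)
  peaks <- cw - (pos - seq_len(nh)) * miss_step
  troughs <- c(0, cw[-nh]) - (pos - seq_len(nh)) * miss_step
  hi <- max(peaks); lo <- min(troughs, 0)
  es <- if (hi >= -lo) hi else lo
  if (!details) return(es)
  at_hit <- if (es >= 0) which.max(peaks) else which.min(troughs)
  list(es = es, at_hit = at_hit)
}

#' Preranked gene-set enrichment with NES and permutation FDR
#'
#' Walks the list sorted by decreasing score; set members increment the
#' running sum by |score|^p / sum(|score|^p over members) and non-members
#' decrement it by 1/(N - N_hits); ES is the signed maximum deviation. The
#' null is built from `n_perm` random same-size member sets; NES divides ES
#' by the mean |null ES| of matching sign, the nominal p compares against
#' same-sign nulls, and the FDR q follows the standard NES-ratio
#' construction over the pooled normalized null, clipped to [0, 1].
#' Score ties are broken by stable input order.
#'
#' @param ranked named numeric vector: feature -> score (e.g. log2 ratio).
#' @param sets `GeneSetCollection` (named list of member id vectors).
#' @param n_perm permutations (default 1000).
#' @param weight_p score weight exponent (default 1, the classic weighted
#'   statistic).
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked list (defaults 5 and 500).
#' @param seed RNG seed.
#' @return data.frame of class `GseaResult`: `set`, `size`, `ES`, `NES`,
#'   `p`, `q`, `leading_edge` (comma-separated ids); skipped sets appear
#'   with NA statistics and a `skipped` reason.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight_p = 1,
                           min_size = 5, max_size = 500, seed = 1) {
  if (any(!is.finite(ranked))) stop("scores must be finite")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  ord <- order(-ranked)   # stable: ties keep input order
  ids <- names(ranked)[ord]
  scores <- ranked[ord]
  N <- length(scores)
  w_all <- abs(scores)^weight_p

  out <- data.frame(set = names(sets), size = NA_integer_, ES = NA_real_,
                    NES = NA_real_, p = NA_real_, q = NA_real_,
                    leading_edge = NA_character_, skipped = NA_character_,
                    stringsAsFactors = FALSE)
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    pos <- which(ids %in% sets[[i]])
    nh <- length(pos)
    out$size[i] <- nh
    if (nh < min_size || nh > max_size) {
      out$skipped[i] <- sprintf("size %d outside [%d, %d] after intersection",
                                nh, min_size, max_size)
      next
    }
    es_det <- es_from_positions(pos, w_all[pos], N, details = TRUE)
    es <- es_det$es
    null_es <- vapply(seq_len(n_perm), function(b) {
      rpos <- sample.int(N, nh)
      es_from_positions(rpos, w_all[rpos], N)
    }, numeric(1))
    mean_pos <- mean(null_es[null_es >= 0])
    mean_neg <- mean(abs(null_es[null_es < 0]))
    nes <- if (es >= 0) es / mean_pos else -abs(es) / mean_neg
    same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    out$ES[i] <- es; out$NES[i] <- nes; out$p[i] <- p
    null_nes[[i]] <- ifelse(null_es >= 0, null_es / mean_pos,
                            null_es / mean_neg)
    # leading edge: members at/before the peak for positive ES, at/after
    # the trough for negative ES
    o <- sort(pos)
    le <- if (es >= 0) ids[o[seq_len(es_det$at_hit)]]
          else ids[o[es_det$at_hit:length(o)]]
    out$leading_edge[i] <- paste(le, collapse = ",")
  }

  pooled <- unlist(null_nes)
  scored <- which(!is.na(out$NES))
  for (i in scored) {
    nes <- out$NES[i]
    if (nes >= 0) {
      num <- mean(pooled >= nes)
      den_pool <- mean(pooled >= 0)
      den_obs <- mean(out$NES[scored] >= nes) / mean(out$NES[scored] >= 0)
    } else {
      num <- mean(pooled <= nes)
      den_pool <- mean(pooled < 0)
      den_obs <- mean(out$NES[scored] <= nes) / mean(out$NES[scored] < 0)
    }
    q <- (num / den_pool) / den_obs
    out$q[i] <- min(max(q, 0), 1)
  }
  class(out) <- c("GseaResult", "data.frame")
  out
}

#' One-sided Fisher (hypergeometric) category enrichment
#'
#' Tests whether a category is over-represented in a group of size `n`
#' containing `a` category members, against a background of `N` features of
#' which `K` belong to the category. The enrichment p-value is the exact
#' upper tail P(X >= a); the odds ratio is the conditional maximum
#' likelihood estimate.
#'
#' @param a category members inside the group.
#' @param n group size.
#' @param K category members in the background.
#' @param N background size.
#' @return list with `p`, `odds_ratio` and the 2x2 counts.
#' @export
fisher_enrichment <- function(a, n, K, N) {
  if (a > n || a > K || n > N || K > N || (n - a) > (N - K)) {
    stop("inconsistent counts: require a <= min(n, K), n <= N, K <= N, ",
         "n - a <= N - K")
  }
  p <- hypergeom_overlap(a, K, n, N)$p
  tab <- matrix(c(a, n - a, K - a, N - K - (n - a)), 2)
  or <- unname(stats::fisher.test(tab, alternative = "greater")$estimate)
  list(p = p, odds_ratio = or, a = a, n = n, K = K, N = N)
}
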