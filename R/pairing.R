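#' Per-position pairing states between a small RNA and a target window
#'
#' Small RNA position `i` (5'->3') pairs antiparallel with window base
#' `L - i + 1` (the window is given in transcript sense, 5'->3').  Pairing
#' states are `"WC"` (Watson-Crick: A:T, T:A, G:C, C:G), `"GU"` (wobble on
#' the RNA sense: small RNA G opposite target T, or small RNA T opposite
#' target G) and `"MM"` (anything else, including N).
#'
#' @param srna_seq small RNA sequence (DNA alphabet, T for U).
#' @param window_seq target window sequence of the same length.
#' @return character vector of states over small RNA positions 1..L.
#' @export
pairing_states <- function(srna_seq, window_seq) {
  if (nchar(srna_seq) != nchar(window_seq))
    stop_ctx("small RNA and window must have equal length")
  pairing_states_chars(seq_chars(srna_seq), seq_chars(window_seq))
}

pairing_states_chars <- function(s, w) {
  t <- rev(w)  # t[i] faces small RNA position i
  st <- rep("MM", length(s))
  st[t == COMP[s]] <- "WC"
  st[(s == "G" & t == "T") | (s == "T" & t == "G")] <- "GU"
  st[is.na(COMP[s]) | !t %in% names(COMP)] <- "MM"
  st
}

#' Built-in pairing score
#'
#' +2 per Watson-Crick pair in the seed (positions 2-7 by default), +1 per
#' Watson-Crick pair outside the seed, +0.5 per GU wobble anywhere, 0 for a
#' mismatch.  An intentionally simple stand-in for external target scorers;
#' per-site scores from external tools can be supplied instead wherever a
#' score is consumed.
#'
#' @param states pairing state vector ([pairing_states()]).
#' @param seed_range seed positions (default `2:7`).
#' @return numeric score.
#' @export
pairing_score <- function(states, seed_range = 2:7) {
  pos <- seq_along(states)
  seed <- pos %in% seed_range
  sum(2 * (states == "WC" & seed) + (states == "WC" & !seed) +
        0.5 * (states == "GU"))
}

#' Extend a target region and pick the best-pairing window
#'
#' Hybrid mRNA regions shorter than the small RNA are extended with
#' transcript context on both sides by the length deficit, then all windows
#' of the small RNA length within the extended region are scored and the
#' best-scoring window is returned (ties: smallest start).  Regions at least
#' as long as the small RNA are scanned the same way without extension.
#' Transcripts shorter than the small RNA yield the whole transcript with
#' `MM`-padded states and `padded = TRUE`.
#'
#' @param refs a [reference_set()].
#' @param transcript_id transcript holding the region.
#' @param region_start,region_end 1-based closed region interval.
#' @param srna_seq the small RNA sequence.
#' @param scorer function(states) -> numeric (default [pairing_score()]).
#' @return list: `window_start`, `window_end`, `states`, `score`, `padded`.
#' @export
extend_site <- function(refs, transcript_id, region_start, region_end,
                        srna_seq, scorer = pairing_score) {
  tx <- refs$transcripts[[transcript_id]]
  if (is.null(tx)) stop_ctx("unknown transcript: ", transcript_id)
  tlen <- nchar(tx)
  L <- nchar(srna_seq)
  s <- seq_chars(srna_seq)
  if (tlen < L) {
    w <- c(seq_chars(tx), rep("N", L - tlen))
    st <- pairing_states_chars(s, w)
    return(list(window_start = 1L, window_end = tlen, states = st,
                score = scorer(st), padded = TRUE))
  }
  m <- region_end - region_start + 1L
  ext <- max(0L, L - m)
  lo <- max(1L, region_start - ext)
  hi <- min(tlen, region_end + ext)
  first <- min(lo, tlen - L + 1L)
  last <- max(first, min(hi, tlen) - L + 1L)
  starts <- first:last
  tchars <- seq_chars(substr(tx, first, last + L - 1L))
  best <- NULL
  for (w0 in starts) {
    off <- w0 - first
    st <- pairing_states_chars(s, tchars[(off + 1L):(off + L)])
    sc <- scorer(st)
    if (is.null(best) || sc > best$score)
      best <- list(window_start = w0, window_end = w0 + L - 1L, states = st,
                   score = sc, padded = FALSE)
  }
  best
}

#' Map a mutation to its small-RNA-relative position
#'
#' Returns the 1-based small RNA position opposite the mutated mRNA base
#' under the antiparallel mapping; `NA` when the base lies outside the
#' pairing window.
#'
#' @param ref_pos 1-based transcript coordinate(s) of the mutation.
#' @param window_start window start coordinate.
#' @param L small RNA length.
#' @return integer vector of small RNA positions (`NA` = outside).
#' @export
map_cim_position <- function(ref_pos, window_start, L) {
  p <- L - (ref_pos - window_start)
  p[p < 1L | p > L] <- NA_integer_
  as.integer(p)
}

#' Positional distribution of mutations along the small RNA
#'
#' Weighted histogram of small-RNA-relative mutation positions, separately
#' for deletions and substitutions.  Optionally restricted to reads in the
#' top third of targeting scores.
#'
#' @param cims mutation table carrying `srna_rel_pos`.
#' @param l_max histogram length (default: max observed position).
#' @param scores optional named numeric vector of per-read targeting scores;
#'   when given together with `top_third = TRUE`, only reads in the top
#'   third of scores contribute.
#' @param top_third apply the top-third score restriction.
#' @return data.frame `position`, `deletion`, `substitution` (weights).
#' @export
positional_distribution <- function(cims, l_max = NULL, scores = NULL,
                                    top_third = FALSE) {
  k <- cims[cims$kind %in% c("deletion", "substitution") &
              !is.na(cims$srna_rel_pos), , drop = FALSE]
  if (top_third) {
    if (is.null(scores)) stop_ctx("top_third requires per-read scores")
    n_top <- ceiling(length(scores) / 3)
    top_ids <- names(sort(scores, decreasing = TRUE))[seq_len(n_top)]
    k <- k[k$read_id %in% top_ids, , drop = FALSE]
  }
  if (is.null(l_max)) l_max <- if (nrow(k)) max(k$srna_rel_pos) else 0L
  out <- data.frame(position = seq_len(l_max),
                    deletion = numeric(l_max),
                    substitution = numeric(l_max))
  for (kind in c("deletion", "substitution")) {
    kk <- k[k$kind == kind, , drop = FALSE]
    if (nrow(kk)) {
      agg <- rowsum(kk$weight, kk$srna_rel_pos)
      pos <- as.integer(rownames(agg))
      out[[kind]][pos] <- agg[, 1]
    }
  }
  out
}

#' Per-position pairing ratio of a set of hybrids
#'
#' For every small RNA position, the weight fraction of hybrids paired at
#' that position.  "Paired" counts Watson-Crick pairs only by default; GU
#' wobbles count as paired with `count_gu = TRUE`.
#'
#' @param states_list list of pairing state vectors (equal length).
#' @param weights per-hybrid weights (default 1).
#' @param count_gu treat GU wobble as paired.
#' @return data.frame `position`, `ratio`, `total_weight`; ratios are `NA`
#'   when the set is empty.
#' @export
pairing_ratio_profile <- function(states_list, weights = NULL,
                                  count_gu = FALSE) {
  if (!length(states_list)) {
    return(data.frame(position = integer(0), ratio = numeric(0),
                      total_weight = numeric(0)))
  }
  L <- length(states_list[[1]])
  if (is.null(weights)) weights <- rep(1, length(states_list))
  tot <- sum(weights)
  mat <- do.call(rbind, states_list)
  paired <- mat == "WC"
  if (count_gu) paired <- paired | mat == "GU"
  num <- colSums(paired * weights)
  data.frame(position = seq_len(L),
             ratio = if (tot > 0) num / tot else rep(NA_real_, L),
             total_weight = tot)
}

#' Pairing-ratio differences centered on the mutation
#'
#' Hybrids carrying a mutation are grouped by the small-RNA-relative
#' mutation position k; for each group and each offset in `-flank..flank`
#' the difference `ratio(all hybrids) - ratio(group)` is evaluated at
#' position `k + offset` (all-hybrids minus mutation subset, so a local
#' pairing dip in the subset appears as a positive difference).  Offsets
#' falling outside `1..L` are skipped for that group.  The per-offset
#' distribution across groups is summarized by median, quartiles and
#' 5th/95th percentiles.
#'
#' @param cim_states list of pairing state vectors of mutation-carrying
#'   hybrids.
#' @param cim_positions small-RNA-relative mutation position per hybrid.
#' @param all_states,all_weights pairing states (and weights) of the
#'   baseline set (all hybrids).
#' @param cim_weights weights of the mutation-carrying hybrids (default 1).
#' @param flank number of offsets on each side (default 5).
#' @param count_gu treat GU wobble as paired.
#' @return list: `per_group` (data.frame `cim_position`, `offset`, `diff`)
#'   and `summary` (per-offset median/quartiles/percentiles).
#' @export
ratio_diff_around_cim <- function(cim_states, cim_positions, all_states,
                                  all_weights = NULL, cim_weights = NULL,
                                  flank = 5L, count_gu = FALSE) {
  stopifnot(flank >= 1L)
  if (is.null(cim_weights)) cim_weights <- rep(1, length(cim_states))
  base <- pairing_ratio_profile(all_states, all_weights, count_gu = count_gu)
  L <- nrow(base)
  rows <- list()
  for (k in sort(unique(cim_positions))) {
    idx <- which(cim_positions == k)
    prof <- pairing_ratio_profile(cim_states[idx], cim_weights[idx],
                                  count_gu = count_gu)
    for (off in seq(-flank, flank)) {
      p <- k + off
      if (p < 1L || p > L) next
      rows[[length(rows) + 1L]] <- data.frame(
        cim_position = k, offset = off,
        diff = base$ratio[p] - prof$ratio[p])
    }
  }
  per_group <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cim_position = integer(0), offset = integer(0),
               diff = numeric(0))
  offs <- seq(-flank, flank)
  summ <- data.frame(offset = offs, median = NA_real_, q1 = NA_real_,
                     q3 = NA_real_, p5 = NA_real_, p95 = NA_real_,
                     n_groups = 0L)
  for (i in seq_along(offs)) {
    d <- per_group$diff[per_group$offset == offs[i]]
    if (length(d)) {
      qs <- stats::quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
      summ[i, c("p5", "q1", "median", "q3", "p95")] <-
        qs[c(1, 2, 3, 4, 5)]
      summ$n_groups[i] <- length(d)
    }
  }
  list(per_group = per_group, summary = summ)
}

#' Pairing ratio within the seed or non-seed region
#'
#' Seed = small RNA positions 2-7; non-seed = positions 8-21, clipped to the
#' small RNA length.
#'
#' @param states pairing state vector.
#' @param region `"seed"` or `"nonseed"`.
#' @param seed_range seed positions (default `2:7`).
#' @param nonseed_max last non-seed position before clipping (default 21).
#' @param count_gu treat GU wobble as paired.
#' @return fraction of region positions paired, in `[0, 1]`.
#' @export
region_pairing_ratio <- function(states, region = c("seed", "nonseed"),
                                 seed_range = 2:7, nonseed_max = 21L,
                                 count_gu = FALSE) {
  region <- match.arg(region)
  L <- length(states)
  pos <- if (region == "seed") seed_range else
    seq(max(seed_range) + 1L, min(nonseed_max, L))
  pos <- pos[pos >= 1L & pos <= L]
  st <- states[pos]
  paired <- st == "WC"
  if (count_gu) paired <- paired | st == "GU"
  mean(paired)
}

#' Offset between co-occurring deletions and substitutions
#'
#' Restricted to target sites carrying at least one deletion and one
#' substitution; within each site every deletion x substitution pair
#' contributes `substitution position - deletion position` (small RNA
#' coordinates) with weight `min(deletion weight, substitution weight)`.
#'
#' @param cims mutation table with `srna_rel_pos` and a `site_id` column
#'   (e.g. added by the pipeline after site aggregation).
#' @return data.frame `offset`, `weight` (weighted histogram).
#' @export
deletion_substitution_offset <- function(cims) {
  k <- cims[cims$kind %in% c("deletion", "substitution") &
              !is.na(cims$srna_rel_pos), , drop = FALSE]
  out <- list()
  for (site in unique(k$site_id)) {
    s <- k[k$site_id == site, , drop = FALSE]
    del <- s[s$kind == "deletion", , drop = FALSE]
    sub <- s[s$kind == "substitution", , drop = FALSE]
    if (nrow(del) == 0 || nrow(sub) == 0) next
    for (i in seq_len(nrow(del))) {
      off <- sub$srna_rel_pos - del$srna_rel_pos[i]
      w <- pmin(sub$weight, del$weight[i])
      out[[length(out) + 1L]] <- data.frame(offset = off, weight = w)
    }
  }
  if (!length(out)) return(data.frame(offset = integer(0), weight = numeric(0)))
  all <- do.call(rbind, out)
  agg <- stats::aggregate(weight ~ offset, data = all, sum)
  agg[order(agg$offset), , drop = FALSE]
}
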