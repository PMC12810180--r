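#' Per-position mutation map from non-hybrid reads
#'
#' Sums mutation weights per transcript position, with separate deletion and
#' substitution tracks.  Deletions are the default downstream enrichment
#' signal (they mark crosslink sites more faithfully than substitutions,
#' whose sequencing background is higher).
#'
#' @param cims mutation table from non-hybrid (mRNA-only) alignments,
#'   already ambiguity-filtered.
#' @param refs a [reference_set()].
#' @return object of class `cim_map`: named list per transcript with
#'   numeric vectors `deletion` and `substitution` of transcript length.
#' @export
build_nonhybrid_cim_map <- function(cims, refs) {
  lens <- nchar(refs$transcripts)
  out <- lapply(lens, function(l)
    list(deletion = numeric(l), substitution = numeric(l)))
  names(out) <- names(refs$transcripts)
  k <- cims[cims$kind %in% c("deletion", "substitution"), , drop = FALSE]
  for (i in seq_len(nrow(k))) {
    tid <- k$transcript_id[i]
    if (is.null(out[[tid]])) next
    p <- k$ref_pos[i]
    out[[tid]][[k$kind[i]]][p] <- out[[tid]][[k$kind[i]]][p] + k$weight[i]
  }
  structure(out, class = "cim_map")
}

#' Test a target region for mutation enrichment
#'
#' One-sided Mann-Whitney U test comparing per-position mutation counts
#' inside the region against all positions of the transcript outside it
#' (region greater); enrichment is called at `p <= 0.01`.  A region spanning
#' the whole transcript leaves the test undefined (`NA`).
#'
#' @param cmap a `cim_map` ([build_nonhybrid_cim_map()]).
#' @param transcript_id transcript to test.
#' @param region_start,region_end 1-based closed region interval.
#' @param kind `"deletion"` (default) or `"substitution"`.
#' @param alpha significance level (default 0.01).
#' @return list: `p`, `enriched`.
#' @export
region_enrichment_test <- function(cmap, transcript_id, region_start,
                                   region_end, kind = "deletion",
                                   alpha = 0.01) {
  track <- cmap[[transcript_id]][[kind]]
  if (is.null(track)) stop_ctx("transcript not in map: ", transcript_id)
  n <- length(track)
  region_start <- max(1L, region_start)
  region_end <- min(n, region_end)
  idx <- seq(region_start, region_end)
  if (length(idx) >= n) return(list(p = NA_real_, enriched = NA))
  x <- track[idx]
  y <- track[-idx]
  if (max(c(x, y)) == min(c(x, y)))
    return(list(p = 1, enriched = FALSE))
  p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                           exact = FALSE)$p.value)
  list(p = p, enriched = p <= alpha)
}

#' Count reads in a window centered on the site
#'
#' The window (default 50 nt) is centered at the transcript coordinate
#' opposite the 10th nucleotide of the small RNA in the site's pairing
#' window; reads whose 5' end lies within the half-open window
#' `[c - w/2, c + w/2)` are counted with their weights.  The window is
#' clipped at transcript ends implicitly (positions outside the transcript
#' hold no reads).
#'
#' @param window_start,window_end site pairing window (1-based closed).
#' @param read_positions data.frame with transcript-space 5'-end `pos` and
#'   `weight` of the reads (e.g. 22G-RNA reads on this transcript).
#' @param window window width in nt (default 50).
#' @return weighted read count.
#' @export
window_count <- function(window_start, window_end, read_positions,
                         window = 50L) {
  L <- window_end - window_start + 1L
  center <- window_start + (L - 10L)  # coordinate opposite small RNA pos 10
  half <- window %/% 2L
  lo <- center - half
  hi <- center + half - 1L
  sel <- read_positions$pos >= lo & read_positions$pos <= hi
  sum(read_positions$weight[sel])
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM_i = count_i * 1e6 / ((length_i / 1000) * total)` where `total` is
#' the number of reads mapping to protein-coding genes.
#'
#' @param counts per-feature read counts.
#' @param lengths_nt per-feature lengths in nucleotides.
#' @param total_protein_coding_reads normalization total.
#' @return numeric RPKM values.
#' @export
rpkm <- function(counts, lengths_nt, total_protein_coding_reads) {
  if (any(lengths_nt <= 0)) stop_ctx("feature lengths must be positive")
  if (total_protein_coding_reads <= 0) stop_ctx("total must be positive")
  counts * 1e6 / ((lengths_nt / 1000) * total_protein_coding_reads)
}

#' Per-site mutant/wild-type ratios
#'
#' `ratio_i = (mut_i + pseudocount) / (wt_i + pseudocount)`; sites where
#' both values are zero are dropped (their indices are attached as attribute
#' `"dropped"`).
#'
#' @param values_mut,values_wt matched per-site values.
#' @param pseudocount added to both numerator and denominator (default 1).
#' @return numeric ratios for the retained sites.
#' @export
ratio_mutant_over_wt <- function(values_mut, values_wt, pseudocount = 1) {
  if (length(values_mut) != length(values_wt))
    stop_ctx("mutant and wild-type site lists differ in length")
  both_zero <- values_mut == 0 & values_wt == 0
  r <- (values_mut[!both_zero] + pseudocount) /
    (values_wt[!both_zero] + pseudocount)
  attr(r, "dropped") <- which(both_zero)
  r
}

#' Flag WAGO targets from IP vs input 22G counts
#'
#' A transcript is a WAGO target when its 22G-RNA count in the WAGO-1 IP
#' exceeds twice the input count (strict), after adding a pseudocount of 1
#' to both.
#'
#' @param ip_counts,input_counts matched normalized transcript counts.
#' @param fold enrichment threshold (default 2).
#' @param pseudocount added to both counts (default 1).
#' @return logical vector of target flags.
#' @export
classify_wago_targets <- function(ip_counts, input_counts, fold = 2,
                                  pseudocount = 1) {
  if (length(ip_counts) != length(input_counts))
    stop_ctx("IP and input tables differ in length")
  (ip_counts + pseudocount) / (input_counts + pseudocount) > fold
}
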