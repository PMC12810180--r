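#' Align read segments to the reference set
#'
#' Local alignments of read substrings against every small RNA and
#' transcript reference, found by exact k-mer anchoring (`min_anchor`-mers
#' select candidate references) followed by a local gapped extension
#' (match +1, mismatch -1, gap open -6, gap extend -1).  One best local
#' alignment is reported per (read, reference) pair; alignments with more
#' than `max_mismatch` mismatches are suppressed, transcript segments must
#' span at least `min_segment` read bases and small RNA segments at least
#' `min_anchor`.
#'
#' All coordinates are 1-based closed intervals.  Deletions and
#' substitutions are encoded in the returned CIGAR/MD strings.
#'
#' @param reads read table ([read_fastq()]).
#' @param refs a [reference_set()].
#' @param min_anchor anchor k-mer length and minimum small RNA segment
#'   length (default 12).
#' @param max_mismatch maximum mismatches per segment (default 4).
#' @param min_segment minimum aligned read length for transcript segments
#'   (default 18).
#' @param match,mismatch,gap_open,gap_ext alignment scores (a 1-nt gap costs
#'   `gap_open + gap_ext`).
#' @return data.frame of segments: `read_id`, `ref_id`, `namespace`
#'   (`"small_rna"` or `"transcript"`), read/ref intervals, `cigar`, `md`,
#'   `n_mismatch`, `score`.
#' @export
align_segments <- function(reads, refs, min_anchor = 12L, max_mismatch = 4L,
                           min_segment = 18L, match = 1L, mismatch = -1L,
                           gap_open = 6L, gap_ext = 1L) {
  ref_ids <- c(names(refs$small_rnas), names(refs$transcripts))
  ref_seqs <- c(unname(refs$small_rnas), unname(refs$transcripts))
  ns <- c(rep("small_rna", length(refs$small_rnas)),
          rep("transcript", length(refs$transcripts)))
  min_len <- ifelse(ns == "small_rna", min_anchor, min_segment)
  res <- cpp_align_segments(reads$id, reads$seq, ref_ids, ref_seqs,
                            as.integer(min_len), as.integer(min_anchor),
                            as.integer(max_mismatch), as.integer(match),
                            as.integer(mismatch), as.integer(gap_open),
                            as.integer(gap_ext))
  out <- as.data.frame(res, stringsAsFactors = FALSE)
  out$namespace <- ns[base::match(out$ref_id, ref_ids)]
  out
}

#' Resolve one read into a small RNA arm plus an mRNA arm
#'
#' Chooses the (small RNA segment, transcript segment) pair maximizing total
#' aligned read bases minus arm overlap, subject to: read-coordinate arm
#' overlap of at most `max_overlap` bases, at most `max_flank` unaligned
#' bases at each read end, at most `max_gap` unaligned bases between the
#' arms, and (unless `any_order`) the small RNA arm 5' of the mRNA arm.
#' Ties are broken by longer small RNA arm, then lexicographic small RNA id,
#' then lexicographic transcript id, making the decomposition deterministic.
#'
#' @param segments alignment rows of a single read ([align_segments()]).
#' @param read_len read length.
#' @param max_overlap maximum junction overlap (default 4).
#' @param max_flank maximum unaligned bases at each read end (default 4).
#' @param max_gap maximum unaligned bases between the arms (default 4).
#' @param any_order allow the mRNA arm 5' of the small RNA arm.
#' @return list with `class` (`"hybrid"`, `"mrna_only"`, `"srna_only"` or
#'   `"unmapped"`), and for hybrids `srna`/`mrna` segment rows plus the
#'   junction overlap interval (`overlap_start`, `overlap_end`; both 0 when
#'   empty).
#' @export
decompose_chimera <- function(segments, read_len, max_overlap = 4L,
                              max_flank = 4L, max_gap = 4L, any_order = FALSE) {
  sr <- segments[segments$namespace == "small_rna", , drop = FALSE]
  mr <- segments[segments$namespace == "transcript", , drop = FALSE]
  best <- NULL
  if (nrow(sr) && nrow(mr)) {
    for (i in seq_len(nrow(sr))) {
      for (j in seq_len(nrow(mr))) {
        a <- sr[i, ]; b <- mr[j, ]
        if (!any_order && a$read_start > b$read_start) next
        os <- max(a$read_start, b$read_start)
        oe <- min(a$read_end, b$read_end)
        olen <- max(0L, oe - os + 1L)
        if (olen > max_overlap) next
        lflank <- min(a$read_start, b$read_start) - 1L
        rflank <- read_len - max(a$read_end, b$read_end)
        if (lflank > max_flank || rflank > max_flank) next
        gap <- if (olen > 0L) 0L else os - oe - 1L
        if (gap > max_gap) next
        alen <- a$read_end - a$read_start + 1L
        blen <- b$read_end - b$read_start + 1L
        cand <- list(obj = alen + blen - olen, srna_len = alen,
                     srna = a, mrna = b,
                     overlap_start = if (olen > 0L) os else 0L,
                     overlap_end = if (olen > 0L) oe else 0L)
        if (is.null(best) || better_pair(cand, best)) best <- cand
      }
    }
  }
  if (!is.null(best)) {
    return(list(class = "hybrid", srna = best$srna, mrna = best$mrna,
                overlap_start = best$overlap_start,
                overlap_end = best$overlap_end))
  }
  if (nrow(mr)) {
    mr <- mr[order(-mr$score, mr$ref_id), , drop = FALSE]
    return(list(class = "mrna_only", mrna = mr[1, ]))
  }
  if (nrow(sr)) {
    sr <- sr[order(-sr$score, sr$ref_id), , drop = FALSE]
    return(list(class = "srna_only", srna = sr[1, ]))
  }
  list(class = "unmapped")
}

better_pair <- function(a, b) {
  if (a$obj != b$obj) return(a$obj > b$obj)
  sa <- a$srna$score + a$mrna$score
  sb <- b$srna$score + b$mrna$score
  if (sa != sb) return(sa > sb)
  if (a$srna_len != b$srna_len) return(a$srna_len > b$srna_len)
  if (a$srna$ref_id != b$srna$ref_id) return(a$srna$ref_id < b$srna$ref_id)
  a$mrna$ref_id < b$mrna$ref_id
}

#' Detect hybrids in a read table
#'
#' Runs [align_segments()] on all reads and [decompose_chimera()] per read.
#'
#' @inheritParams align_segments
#' @inheritParams decompose_chimera
#' @param segments optional precomputed segment table (e.g. from
#'   [ingest_sam()]); when supplied the alignment step is skipped.
#' @param ... passed to [align_segments()].
#' @return list with `hybrids` (one row per hybrid read: arm coordinates,
#'   CIGAR/MD of both arms, junction overlap, weight) and `classification`
#'   (one row per read: `read_id`, `class`, `weight`, best reference where
#'   applicable).
#' @export
detect_hybrids <- function(reads, refs, segments = NULL, max_overlap = 4L,
                           max_flank = 4L, max_gap = 4L, any_order = FALSE,
                           ...) {
  if (is.null(segments)) segments <- align_segments(reads, refs, ...)
  seg_split <- split(segments, factor(segments$read_id, levels = reads$id))
  n <- nrow(reads)
  cls <- character(n)
  best_ref <- rep(NA_character_, n)
  hyb <- vector("list", n)
  for (i in seq_len(n)) {
    d <- decompose_chimera(seg_split[[i]], nchar(reads$seq[i]),
                           max_overlap = max_overlap, max_flank = max_flank,
                           max_gap = max_gap, any_order = any_order)
    cls[i] <- d$class
    if (d$class == "hybrid") {
      a <- d$srna; b <- d$mrna
      hyb[[i]] <- data.frame(
        read_id = reads$id[i], weight = reads$weight[i],
        srna_id = a$ref_id, srna_read_start = a$read_start,
        srna_read_end = a$read_end, srna_ref_start = a$ref_start,
        srna_ref_end = a$ref_end, srna_cigar = a$cigar, srna_md = a$md,
        srna_n_mismatch = a$n_mismatch,
        transcript_id = b$ref_id, mrna_read_start = b$read_start,
        mrna_read_end = b$read_end, mrna_ref_start = b$ref_start,
        mrna_ref_end = b$ref_end, mrna_cigar = b$cigar, mrna_md = b$md,
        mrna_n_mismatch = b$n_mismatch,
        overlap_start = d$overlap_start, overlap_end = d$overlap_end,
        stringsAsFactors = FALSE)
      best_ref[i] <- b$ref_id
    } else if (d$class == "mrna_only") {
      best_ref[i] <- d$mrna$ref_id
    } else if (d$class == "srna_only") {
      best_ref[i] <- d$srna$ref_id
    }
  }
  hybrids <- do.call(rbind, hyb[!vapply(hyb, is.null, logical(1))])
  if (is.null(hybrids)) {
    hybrids <- empty_df(list(
      read_id = character(), weight = numeric(), srna_id = character(),
      srna_read_start = integer(), srna_read_end = integer(),
      srna_ref_start = integer(), srna_ref_end = integer(),
      srna_cigar = character(), srna_md = character(),
      srna_n_mismatch = integer(), transcript_id = character(),
      mrna_read_start = integer(), mrna_read_end = integer(),
      mrna_ref_start = integer(), mrna_ref_end = integer(),
      mrna_cigar = character(), mrna_md = character(),
      mrna_n_mismatch = integer(), overlap_start = integer(),
      overlap_end = integer()))
  }
  rownames(hybrids) <- NULL
  classification <- data.frame(read_id = reads$id, class = cls,
                               weight = reads$weight, best_ref = best_ref,
                               stringsAsFactors = FALSE)
  list(hybrids = hybrids, classification = classification,
       segments = segments)
}
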