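#' Extract candidate mutations from alignments
#'
#' Walks CIGAR and MD jointly and emits one row per deleted reference base
#' (kind `"deletion"`), per mismatch (kind `"substitution"`) and per
#' inserted read base (kind `"insertion"`).  Insertions are parsed but
#' excluded from all crosslink-induced mutation (CIM) tallies downstream.
#' MD/CIGAR inconsistencies raise an error naming the alignment.
#'
#' `ref_pos` is the 1-based reference coordinate of the mutated base;
#' `read_pos` is the 1-based read coordinate (for deletions, the first read
#' base after the deleted reference base, since deletions consume no read
#' bases).  When `refs` is supplied, MD-derived reference bases are
#' validated against the reference sequence.
#'
#' @param segments segment table ([align_segments()] / [ingest_sam()]).
#' @param reads read table supplying sequences and weights.
#' @param refs optional [reference_set()] for reference-base validation.
#' @return data.frame: `read_id`, `kind`, `transcript_id`, `ref_pos`,
#'   `ref_base`, `read_base`, `read_pos`, `weight`.
#' @export
extract_mutations <- function(segments, reads, refs = NULL) {
  seqs <- reads$seq
  ws <- reads$weight
  names(seqs) <- names(ws) <- reads$id
  all_refs <- if (!is.null(refs)) c(refs$small_rnas, refs$transcripts)
  out <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    out[[i]] <- extract_mutations_one(
      s$read_id, seqs[[s$read_id]], s$ref_id, s$read_start, s$ref_start,
      s$cigar, s$md, ws[[s$read_id]],
      if (!is.null(all_refs)) all_refs[[s$ref_id]])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_cim_df())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_cim_df <- function() {
  empty_df(list(read_id = character(), kind = character(),
                transcript_id = character(), ref_pos = integer(),
                ref_base = character(), read_base = character(),
                read_pos = integer(), weight = numeric()))
}

extract_mutations_one <- function(read_id, seq, ref_id, read_start, ref_start,
                                  cigar, md, weight, ref_seq = NULL) {
  ops <- parse_cigar(cigar)
  ev <- parse_md_events(md)
  need <- sum(ops$len[ops$op %in% c("M", "=", "X", "D")])
  if (nrow(ev) != need)
    stop_ctx("MD/CIGAR inconsistency for alignment of ", read_id, " on ",
             ref_id, " (", cigar, " vs MD:", md, ")")
  read_pos <- read_start
  ref_pos <- ref_start
  ei <- 1L
  rows <- list()
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      sl <- ev[ei:(ei + len - 1L), , drop = FALSE]
      if (any(sl$type == "d"))
        stop_ctx("MD deletion inside CIGAR match for ", read_id, " on ", ref_id)
      subs <- which(sl$type == "s")
      for (p in subs) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = read_id, kind = "substitution", transcript_id = ref_id,
          ref_pos = ref_pos + p - 1L, ref_base = sl$base[p],
          read_base = substr(seq, read_pos + p - 1L, read_pos + p - 1L),
          read_pos = read_pos + p - 1L, weight = weight,
          stringsAsFactors = FALSE)
      }
      read_pos <- read_pos + len
      ref_pos <- ref_pos + len
      ei <- ei + len
    } else if (op == "D") {
      sl <- ev[ei:(ei + len - 1L), , drop = FALSE]
      if (any(sl$type != "d"))
        stop_ctx("CIGAR deletion without MD deletion for ", read_id, " on ",
                 ref_id)
      for (p in seq_len(len)) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = read_id, kind = "deletion", transcript_id = ref_id,
          ref_pos = ref_pos + p - 1L, ref_base = sl$base[p],
          read_base = NA_character_, read_pos = read_pos, weight = weight,
          stringsAsFactors = FALSE)
      }
      ref_pos <- ref_pos + len
      ei <- ei + len
    } else if (op == "I") {
      for (p in seq_len(len)) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = read_id, kind = "insertion", transcript_id = ref_id,
          ref_pos = ref_pos, ref_base = NA_character_,
          read_base = substr(seq, read_pos + p - 1L, read_pos + p - 1L),
          read_pos = read_pos + p - 1L, weight = weight,
          stringsAsFactors = FALSE)
      }
      read_pos <- read_pos + len
    } else if (op %in% c("S", "H")) {
      stop_ctx("clipped CIGAR op inside core alignment for ", read_id)
    } else {
      stop_ctx("unsupported CIGAR op ", op, " for ", read_id)
    }
  }
  if (ei != nrow(ev) + 1L)
    stop_ctx("MD not fully consumed for ", read_id, " on ", ref_id)
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, rows)
  if (!is.null(ref_seq)) {
    chk <- res$kind != "insertion"
    ok <- substr(rep(ref_seq, sum(chk)), res$ref_pos[chk], res$ref_pos[chk]) ==
      res$ref_base[chk]
    if (!all(ok))
      stop_ctx("MD reference base disagrees with reference for ", read_id,
               " on ", ref_id)
  }
  res
}

#' Remove mutations in the junction overlap
#'
#' Mutations whose read coordinate falls inside the junction overlap of
#' their hybrid are removed (they could derive from either the small RNA or
#' the mRNA).  Substitutions and insertions are inside when their read base
#' lies in the overlap; a deletion is inside when both flanking read bases
#' are.
#'
#' @param cims mutation table ([extract_mutations()]).
#' @param hybrids hybrid table ([detect_hybrids()]).
#' @return filtered mutation table, input order preserved.
#' @export
filter_junction_overlap <- function(cims, hybrids) {
  if (nrow(cims) == 0) return(cims)
  idx <- base::match(cims$read_id, hybrids$read_id)
  os <- hybrids$overlap_start[idx]
  oe <- hybrids$overlap_end[idx]
  has <- !is.na(os) & os > 0L
  inside <- rep(FALSE, nrow(cims))
  del <- cims$kind == "deletion"
  inside[has & !del] <- cims$read_pos[has & !del] >= os[has & !del] &
    cims$read_pos[has & !del] <= oe[has & !del]
  inside[has & del] <- (cims$read_pos[has & del] - 1L) >= os[has & del] &
    cims$read_pos[has & del] <= oe[has & del]
  out <- cims[!inside, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop mutation annotations with ambiguous alternative placements
#'
#' For each read carrying mutations, the read-derived mRNA-arm sequence
#' (mutations included) is searched against every reference transcript.  If
#' it occurs exactly (up to `max_alt_mismatch` mismatches) anywhere other
#' than at the called locus -- e.g. in a sister transposon-family copy --
#' all of the read's mutation annotations are dropped; the read itself is
#' retained.
#'
#' @param cims mutation table.
#' @param arms data.frame with one row per read: `read_id`,
#'   `transcript_id`, `ref_start` (called locus) and `arm_seq` (read-derived
#'   arm sequence).  See [hybrid_arms()].
#' @param refs a [reference_set()].
#' @param max_alt_mismatch mismatches tolerated in the alternative match
#'   (default 0 = exact).
#' @return filtered mutation table; dropped read ids are attached as
#'   attribute `"ambiguous_reads"`.
#' @export
filter_ambiguous <- function(cims, arms, refs, max_alt_mismatch = 0L) {
  if (nrow(cims) == 0) {
    attr(cims, "ambiguous_reads") <- character(0)
    return(cims)
  }
  txset <- Biostrings::DNAStringSet(refs$transcripts)
  tids <- names(refs$transcripts)
  check <- arms[arms$read_id %in% unique(cims$read_id), , drop = FALSE]
  dropped <- character(0)
  for (i in seq_len(nrow(check))) {
    a <- check[i, ]
    hits <- Biostrings::vmatchPattern(a$arm_seq, txset,
                                      max.mismatch = max_alt_mismatch)
    counts <- S4Vectors::elementNROWS(hits)
    ambiguous <- FALSE
    for (t in which(counts > 0)) {
      starts <- BiocGenerics::start(hits[[t]])
      if (tids[t] != a$transcript_id) {
        ambiguous <- TRUE
      } else if (any(starts != a$ref_start)) {
        ambiguous <- TRUE
      }
      if (ambiguous) break
    }
    if (ambiguous) dropped <- c(dropped, a$read_id)
  }
  out <- cims[!cims$read_id %in% dropped, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ambiguous_reads") <- dropped
  out
}

#' Extract mRNA-arm sequences from a hybrid table
#'
#' @param hybrids hybrid table.
#' @param reads read table.
#' @return data.frame `read_id`, `transcript_id`, `ref_start`, `arm_seq`,
#'   suitable for [filter_ambiguous()].
#' @export
hybrid_arms <- function(hybrids, reads) {
  seqs <- reads$seq
  names(seqs) <- reads$id
  data.frame(read_id = hybrids$read_id, transcript_id = hybrids$transcript_id,
             ref_start = hybrids$mrna_ref_start,
             arm_seq = substr(seqs[hybrids$read_id], hybrids$mrna_read_start,
                              hybrids$mrna_read_end),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentage of reads carrying a mutation
#'
#' @param n_reads_with_mut (possibly fractional) read count carrying at
#'   least one mutation of a kind.
#' @param n_total total read count.
#' @return `100 * n_reads_with_mut / n_total`.
#' @export
mutation_frequency <- function(n_reads_with_mut, n_total) {
  if (any(n_total <= 0)) stop_ctx("n_total must be positive")
  if (any(n_reads_with_mut < 0) || any(n_reads_with_mut > n_total))
    stop_ctx("n_reads_with_mut must lie in [0, n_total]")
  100 * n_reads_with_mut / n_total
}

#' Weight of reads carrying at least one mutation of a kind
#'
#' A read counts once (with its full weight) per mutation kind it carries,
#' so deletion and substitution tallies are independent.
#'
#' @param cims mutation table.
#' @param kind `"deletion"` or `"substitution"`.
#' @return summed weight of distinct carrier reads.
#' @export
mutation_carrier_weight <- function(cims, kind) {
  k <- cims[cims$kind == kind, , drop = FALSE]
  if (nrow(k) == 0) return(0)
  sum(k$weight[!duplicated(k$read_id)])
}

#' Mutation spectrum by origin base
#'
#' Weight-summed counts and percentages by origin (reference) base for
#' deletions and substitutions, plus the 4x4 substitution matrix with
#' per-origin percentages (e.g. the share of T substitutions that are T->C;
#' T plays the role of uridine).  Insertions are excluded.
#'
#' @param cims mutation table.
#' @return list with `origin` (data.frame base x kind weights and
#'   percentages) and `substitution_matrix` (list of `weight` and `percent`
#'   4x4 matrices, rows = origin base).
#' @export
mutation_spectrum <- function(cims) {
  bases <- c("A", "C", "G", "T")
  origin <- data.frame(base = bases,
                       deletion_weight = 0, substitution_weight = 0,
                       deletion_pct = 0, substitution_pct = 0,
                       stringsAsFactors = FALSE)
  m <- matrix(0, 4, 4, dimnames = list(from = bases, to = bases))
  for (kind in c("deletion", "substitution")) {
    k <- cims[cims$kind == kind & cims$ref_base %in% bases, , drop = FALSE]
    if (nrow(k)) {
      w <- vapply(bases, function(b) sum(k$weight[k$ref_base == b]),
                  numeric(1))
      col <- paste0(kind, "_weight")
      origin[[col]] <- unname(w)
      tot <- sum(w)
      if (tot > 0) origin[[paste0(kind, "_pct")]] <- unname(100 * w / tot)
    }
  }
  subs <- cims[cims$kind == "substitution" & cims$ref_base %in% bases &
                 cims$read_base %in% bases, , drop = FALSE]
  if (nrow(subs)) {
    agg <- stats::aggregate(weight ~ ref_base + read_base, data = subs, sum)
    for (i in seq_len(nrow(agg)))
      m[agg$ref_base[i], agg$read_base[i]] <- agg$weight[i]
  }
  rs <- rowSums(m)
  pct <- m
  nz <- rs > 0
  pct[nz, ] <- 100 * m[nz, , drop = FALSE] / rs[nz]
  pct[!nz, ] <- 0
  list(origin = origin, substitution_matrix = list(weight = m, percent = pct))
}
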