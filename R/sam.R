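#' Ingest alignments from a SAM file
#'
#' One segment per mapped record; secondary and supplementary alignments are
#' retained.  Records must carry an MD tag unless `recompute_md = TRUE`, in
#' which case MD is rebuilt from the reference.  Reference names must
#' resolve in `refs`.
#'
#' @param path path to a (plain-text) SAM file.
#' @param refs a [reference_set()].
#' @param recompute_md rebuild missing MD tags from the reference.
#' @return segment table in the [align_segments()] layout.
#' @export
ingest_sam <- function(path, refs, recompute_md = FALSE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  ref_ids <- c(names(refs$small_rnas), names(refs$transcripts))
  ref_seqs <- c(refs$small_rnas, refs$transcripts)
  ns <- c(rep("small_rna", length(refs$small_rnas)),
          rep("transcript", length(refs$transcripts)))
  names(ns) <- ref_ids
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop_ctx("malformed SAM record at line ", i)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next
    rname <- f[3]
    if (!rname %in% ref_ids)
      stop_ctx("unknown reference name in SAM: ", rname)
    cigar <- f[6]
    ops <- parse_cigar(cigar)
    seq <- f[10]
    lead_s <- if (ops$op[1] == "S") ops$len[1] else 0L
    read_consumed <- sum(ops$len[ops$op %in% c("M", "I", "=", "X")])
    ref_consumed <- sum(ops$len[ops$op %in% c("M", "D", "=", "X")])
    pos <- as.integer(f[4])
    tags <- if (length(f) > 11) f[12:length(f)] else character()
    md <- sub("^MD:Z:", "", grep("^MD:Z:", tags, value = TRUE))
    if (length(md) == 0) {
      if (!recompute_md)
        stop_ctx("SAM record ", f[1], " lacks an MD tag ",
                 "(use recompute_md = TRUE to rebuild it)")
      if (seq == "*")
        stop_ctx("cannot recompute MD for ", f[1], ": no SEQ field")
      md <- build_md(ops, substr(seq, lead_s + 1L, lead_s + read_consumed),
                     substr(ref_seqs[[rname]], pos, pos + ref_consumed - 1L))
    }
    core <- ops[!ops$op %in% c("S", "H"), , drop = FALSE]
    core_cigar <- paste0(core$len, core$op, collapse = "")
    nmm <- md_mismatch_count(md)
    n_gap <- sum(core$op %in% c("I", "D"))
    gap_bases <- sum(core$len[core$op %in% c("I", "D")])
    matches <- sum(core$len[core$op %in% c("M", "=", "X")]) - nmm
    score <- matches - nmm - (6L * n_gap + gap_bases)
    out[[i]] <- data.frame(
      read_id = f[1], ref_id = rname, read_start = lead_s + 1L,
      read_end = lead_s + read_consumed, ref_start = pos,
      ref_end = pos + ref_consumed - 1L, cigar = core_cigar, md = md,
      n_mismatch = nmm, score = score, namespace = unname(ns[rname]),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(empty_df(list(read_id = character(), ref_id = character(),
                         read_start = integer(), read_end = integer(),
                         ref_start = integer(), ref_end = integer(),
                         cigar = character(), md = character(),
                         n_mismatch = integer(), score = integer(),
                         namespace = character())))
  do.call(rbind, out)
}

#' Write segment alignments as SAM
#'
#' @param segments segment table ([align_segments()]).
#' @param reads read table providing full read sequences and qualities.
#' @param refs a [reference_set()].
#' @param path output path.
#' @export
write_sam <- function(segments, reads, refs, path) {
  ref_ids <- c(names(refs$small_rnas), names(refs$transcripts))
  ref_len <- nchar(c(refs$small_rnas, refs$transcripts))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", ref_ids, "\tLN:", ref_len))
  seqs <- reads$seq
  quals <- reads$qual
  names(seqs) <- names(quals) <- reads$id
  recs <- character(nrow(segments))
  seen <- character(0)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    full <- seqs[[s$read_id]]
    lead <- s$read_start - 1L
    trail <- nchar(full) - s$read_end
    cig <- paste0(if (lead > 0L) paste0(lead, "S"), s$cigar,
                  if (trail > 0L) paste0(trail, "S"))
    flag <- if (s$read_id %in% seen) 256L else 0L
    seen <- c(seen, s$read_id)
    recs[i] <- paste(s$read_id, flag, s$ref_id, s$ref_start, 60L, cig, "*",
                     0L, 0L, full, quals[[s$read_id]],
                     paste0("NM:i:", s$n_mismatch),
                     paste0("MD:Z:", s$md), paste0("AS:i:", s$score),
                     sep = "\t")
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(m) || nchar(paste(m, collapse = "")) != nchar(cigar))
    stop_ctx("malformed CIGAR: ", cigar)
  data.frame(len = as.integer(sub("[A-Z=]$", "", m)),
             op = sub("^[0-9]+", "", m), stringsAsFactors = FALSE)
}

# expand an MD tag into per-reference-base events within aligned M/D ops:
# "m" match, "s" substitution (with ref base), "d" deleted base
parse_md_events <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  if (nchar(paste(toks, collapse = "")) != nchar(md))
    stop_ctx("malformed MD tag: ", md)
  type <- character(0)
  base <- character(0)
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      n <- as.integer(t)
      if (n > 0L) {
        type <- c(type, rep("m", n))
        base <- c(base, rep(NA_character_, n))
      }
    } else if (startsWith(t, "^")) {
      b <- seq_chars(substr(t, 2L, nchar(t)))
      type <- c(type, rep("d", length(b)))
      base <- c(base, b)
    } else {
      type <- c(type, "s")
      base <- c(base, t)
    }
  }
  data.frame(type = type, base = base, stringsAsFactors = FALSE)
}

md_mismatch_count <- function(md) {
  ev <- parse_md_events(md)
  sum(ev$type == "s")
}

# rebuild an MD string from CIGAR ops plus the aligned read/ref substrings
build_md <- function(ops, read_aln, ref_aln) {
  ri <- 1L; rj <- 1L
  run <- 0L
  md <- ""
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      for (p in seq_len(len)) {
        if (substr(read_aln, ri, ri) == substr(ref_aln, rj, rj)) {
          run <- run + 1L
        } else {
          md <- paste0(md, run, substr(ref_aln, rj, rj))
          run <- 0L
        }
        ri <- ri + 1L; rj <- rj + 1L
      }
    } else if (op == "D") {
      md <- paste0(md, run, "^", substr(ref_aln, rj, rj + len - 1L))
      run <- 0L
      rj <- rj + len
    } else if (op == "I") {
      ri <- ri + len
    }
  }
  paste0(md, run)
}
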