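#' Read a FASTQ file into a read table
#'
#' Reads are returned as a data.frame with columns `id`, `seq`, `qual`
#' (Phred+33 string) and `weight`.  Weights encoded in the read name as
#' `name|count=N` (the convention used by [write_fastq()] after
#' deduplication) are decoded; all other reads get weight 1.
#'
#' @param path path to a FASTQ file (Phred+33).
#' @return data.frame with one row per read.
#' @export
read_fastq <- function(path) {
  idx <- locate_bad_fastq_record(path)
  if (!is.na(idx))
    stop_ctx("malformed FASTQ record ", idx, " in ", path)
  x <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) {
      stop_ctx("failed to parse FASTQ ", path, ": ", conditionMessage(e))
    })
  ids <- names(x)
  weight <- rep(1, length(ids))
  has_count <- grepl("\\|count=[0-9.]+$", ids)
  weight[has_count] <- as.numeric(sub("^.*\\|count=", "", ids[has_count]))
  ids[has_count] <- sub("\\|count=[0-9.]+$", "", ids[has_count])
  data.frame(id = ids, seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             weight = weight, stringsAsFactors = FALSE, row.names = NULL)
}

# best-effort diagnostic: index of the first structurally bad 4-line record
locate_bad_fastq_record <- function(path) {
  lines <- tryCatch(readLines(path), error = function(e) NULL)
  if (is.null(lines)) return(NA_integer_)
  n <- length(lines)
  nrec <- ceiling(n / 4)
  for (i in seq_len(nrec)) {
    j <- (i - 1) * 4
    if (j + 4 > n) return(i)
    if (!startsWith(lines[j + 1], "@") || !startsWith(lines[j + 3], "+") ||
        nchar(lines[j + 2]) != nchar(lines[j + 4]))
      return(i)
  }
  NA_integer_
}

#' Write a read table to FASTQ
#'
#' Non-unit weights are encoded in the read name as `name|count=N`.
#'
#' @param reads read table as returned by [read_fastq()].
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  ids <- ifelse(reads$weight != 1,
                paste0(reads$id, "|count=", reads$weight), reads$id)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Adapter- and quality-trim reads, then length-filter
#'
#' The 3' adapter is removed at the first position where the read matches a
#' prefix of the adapter over at least `min_overlap` bases (a full internal
#' adapter occurrence, or a read-suffix/adapter-prefix match).  Low-quality
#' 3' tails are then removed with the standard partial-sum (BWA-style)
#' algorithm at threshold `min_qual`.  Reads whose trimmed length falls
#' outside `[min_len, max_len]` are discarded; input order is preserved.
#'
#' @param reads read table ([read_fastq()]).
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len retained length range (defaults 17 and 70).
#' @param min_qual 3' quality-trim threshold (default 30).
#' @param min_overlap minimum adapter overlap for a match (default 5).
#' @param pre_trimmed if `TRUE` skip adapter and quality trimming and only
#'   apply the length filter (for libraries trimmed upstream).
#' @return trimmed read table; the number of length-filtered reads is
#'   attached as attribute `"dropped"`.
#' @export
trim_reads <- function(reads, adapter, min_len = 17L, max_len = 70L,
                       min_qual = 30L, min_overlap = 5L, pre_trimmed = FALSE) {
  stopifnot(min_len > 0, min_len <= max_len)
  if (!pre_trimmed && (missing(adapter) || !nzchar(adapter)))
    stop_ctx("adapter must be a non-empty sequence")
  n <- nrow(reads)
  if (n == 0) {
    out <- reads
    attr(out, "dropped") <- 0
    return(out)
  }
  seqs <- reads$seq
  quals <- reads$qual
  if (!pre_trimmed) {
    adapter <- toupper(adapter)
    alen <- nchar(adapter)
    for (i in seq_len(n)) {
      s <- seqs[i]
      len <- nchar(s)
      cut <- find_adapter_start(s, len, adapter, alen, min_overlap)
      if (cut > 0L) {
        s <- substr(s, 1L, cut - 1L)
        quals[i] <- substr(quals[i], 1L, cut - 1L)
        len <- cut - 1L
      }
      keep <- quality_trim_length(qual_to_int(quals[i]), min_qual)
      if (keep < len) {
        s <- substr(s, 1L, keep)
        quals[i] <- substr(quals[i], 1L, keep)
      }
      seqs[i] <- s
    }
  }
  lens <- nchar(seqs)
  keep <- lens >= min_len & lens <= max_len
  out <- data.frame(id = reads$id[keep], seq = seqs[keep], qual = quals[keep],
                    weight = reads$weight[keep], stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "dropped") <- sum(!keep)
  out
}

# 1-based read position where the adapter match begins; 0 if none.
# First (leftmost) occurrence wins: a full internal occurrence precedes any
# read-suffix partial match, and among suffix matches the longest overlap is
# the leftmost.
find_adapter_start <- function(s, len, adapter, alen, min_overlap) {
  if (len >= alen) {
    f <- regexpr(adapter, s, fixed = TRUE)[1]
    if (f > 0L) return(f)
  }
  kmax <- min(alen - 1L, len)
  if (kmax >= min_overlap) {
    for (k in seq(kmax, min_overlap)) {
      if (substr(s, len - k + 1L, len) == substr(adapter, 1L, k))
        return(len - k + 1L)
    }
  }
  0L
}

# retained length after BWA-style 3' quality trimming: trim the suffix
# maximizing sum(threshold - q); no trim when the maximum is not positive
quality_trim_length <- function(q, threshold) {
  len <- length(q)
  if (len == 0L) return(0L)
  cs <- cumsum(rev(threshold - q))
  m <- max(cs)
  if (m > 0L) len - which.max(cs) else len
}

#' Collapse identical read sequences
#'
#' One output read per distinct sequence; the output weight is the summed
#' input weight (= copy count for raw reads) and the representative id is
#' the lexicographically smallest input id among the copies.  Total weight
#' is conserved.
#'
#' @param reads read table (already trimmed).
#' @return deduplicated read table, ordered by representative id.
#' @export
deduplicate_reads <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  ord <- order(reads$seq, reads$id, method = "radix")
  r <- reads[ord, , drop = FALSE]
  first <- !duplicated(r$seq)
  grp <- cumsum(first)
  w <- as.vector(rowsum(r$weight, grp))
  out <- r[first, , drop = FALSE]
  out$weight <- w
  out <- out[order(out$id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
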