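#' Construct a reference set
#'
#' A reference set holds the small RNA sequences (the guides: piRNAs,
#' miRNAs) and the transcript sequences (the potential targets:
#' protein-coding mRNAs, pseudogenes, transposon-family variants) that reads
#' are aligned against.  Sequences are stored uppercase in the DNA alphabet;
#' uracil is converted to thymine on construction.
#'
#' @param small_rnas named character vector of small RNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param srna_class per-small-RNA class label (`"miRNA"`, `"piRNA"` or
#'   `"other"`); recycled if length 1.
#' @param biotype per-transcript biotype (`"protein-coding"`, `"pseudogene"`
#'   or `"transposon"`); recycled if length 1.
#' @param family optional per-transcript family id (used for transposon
#'   variants); `NA` where not applicable.
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(small_rnas, transcripts, srna_class = "piRNA",
                          biotype = "protein-coding", family = NULL) {
  small_rnas <- normalize_seqs(small_rnas, "small RNA")
  transcripts <- normalize_seqs(transcripts, "transcript")
  srna_class <- rep_len(srna_class, length(small_rnas))
  biotype <- rep_len(biotype, length(transcripts))
  if (is.null(family)) family <- rep(NA_character_, length(transcripts))
  family <- rep_len(family, length(transcripts))
  names(srna_class) <- names(small_rnas)
  names(biotype) <- names(transcripts)
  names(family) <- names(transcripts)
  structure(list(small_rnas = small_rnas, transcripts = transcripts,
                 srna_class = srna_class, biotype = biotype, family = family),
            class = "reference_set")
}

normalize_seqs <- function(x, what) {
  if (length(x) == 0) stop_ctx("empty ", what, " reference")
  ids <- names(x)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop_ctx(what, " references must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_ctx("duplicated ", what, " id(s): ", paste(unique(dup), collapse = ", "))
  x <- toupper(x)
  x <- chartr("U", "T", x)
  if (any(nchar(x) == 0)) stop_ctx("empty ", what, " sequence present")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop_ctx("non-nucleotide characters in ", what, " record(s): ",
             paste(ids[bad], collapse = ", "))
  x
}

#' Load small RNA and transcript references from FASTA
#'
#' @param small_rna_fasta path to the small RNA FASTA file.
#' @param transcript_fasta path to the transcript FASTA file.
#' @inheritParams reference_set
#' @return a [reference_set()].
#' @export
load_references <- function(small_rna_fasta, transcript_fasta,
                            srna_class = "piRNA", biotype = "protein-coding",
                            family = NULL) {
  reference_set(read_fasta(small_rna_fasta), read_fasta(transcript_fasta),
                srna_class = srna_class, biotype = biotype, family = family)
}

read_fasta <- function(path) {
  # read as BString so RNA (U) records survive; normalization happens in
  # reference_set()
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x$small_rnas), "small RNAs,",
      length(x$transcripts), "transcripts\n")
  invisible(x)
}
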