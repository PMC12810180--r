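#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement lookup for single characters
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_chars <- function(x) unname(COMP[x])

# Phred+33 quality string -> integer scores
qual_to_int <- function(q) as.integer(charToRaw(q)) - 33L

int_to_qual <- function(q) rawToChar(as.raw(q + 33L))

# split a sequence into single characters
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw one element of v (safe for length-1 vectors, unlike sample())
sample1 <- function(v) v[sample.int(length(v), 1L)]

# build an empty data.frame with the given column types (prototypes)
empty_df <- function(proto) {
  as.data.frame(lapply(proto, function(x) x[0]), stringsAsFactors = FALSE)
}

stop_ctx <- function(...) stop(..., call. = FALSE)
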