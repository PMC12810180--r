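test_that("exact small RNA copies align full length without mismatch", {
  refs <- tiny_refs()
  r <- reads_df(refs$small_rnas[["sr1"]])
  seg <- align_segments(r, refs)
  sr <- seg[seg$namespace == "small_rna", ]
  expect_equal(nrow(sr), 1)
  expect_equal(sr$read_start, 1)
  expect_equal(sr$read_end, 21)
  expect_equal(sr$ref_start, 1)
  expect_equal(sr$ref_end, 21)
  expect_equal(sr$n_mismatch, 0)
  expect_equal(sr$cigar, "21M")
  expect_equal(sr$md, "21")
})

test_that("an internal substitution is encoded in the MD tag", {
  refs <- tiny_refs()
  tx <- refs$transcripts[["tx1"]]
  frag <- substr(tx, 20, 49)  # 30-nt transcript substring
  ch <- strsplit(frag, "")[[1]]
  ch[15] <- setdiff(c("A", "C", "G", "T"), ch[15])[1]
  seg <- align_segments(reads_df(paste(ch, collapse = "")), refs)
  seg <- seg[seg$namespace == "transcript", ]
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_mismatch, 1)
  expect_equal(seg$cigar, "30M")
  expect_equal(seg$md, paste0(14, substr(tx, 34, 34), 15))
})

test_that("alignment scores equal the Biostrings local-alignment oracle and
           coordinates equal simulator truth", {
  cfg <- sim_config(n_transcripts = 6, transcript_length = 200, n_srnas = 5,
                    n_hybrid_reads = 40, n_nonhybrid_reads = 5, seed = 13)
  sim <- simulate_library(cfg)
  dd <- deduplicate_reads(trim_reads(sim$reads, cfg$adapter))
  seg <- align_segments(dd, sim$refs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  all_refs <- c(sim$refs$small_rnas, sim$refs$transcripts)
  for (i in seq_len(nrow(seg))) {
    pa <- Biostrings::pairwiseAlignment(
      dd$seq[dd$id == seg$read_id[i]], all_refs[[seg$ref_id[i]]],
      type = "local", substitutionMatrix = mat, gapOpening = 6,
      gapExtension = 1)
    expect_equal(seg$score[i], Biostrings::score(pa))
  }
  # arm coordinates recover the planted fragment; the 5' end may gain up to
  # 4 nt of junction context when the transcript happens to continue the
  # small RNA (resolved downstream by the junction-overlap filter)
  tr <- sim$truth$reads
  tr <- tr[tr$class == "hybrid", ]
  for (j in seq_len(nrow(tr))) {
    ids <- dd$id[dd$seq == tr$insert_seq[j]]
    s <- seg[seg$read_id %in% ids & seg$ref_id == tr$transcript_id[j], ]
    expect_true(all(s$ref_end == tr$frag_end[j]))
    ext <- tr$frag_start[j] - s$ref_start
    expect_true(all(ext >= 0 & ext <= 4))
  }
})

test_that("deletions produce the expected CIGAR/MD and survive alignment", {
  refs <- tiny_refs()
  tx <- refs$transcripts[["tx1"]]
  frag <- substr(tx, 15, 54)  # 40 nt
  ch <- strsplit(frag, "")[[1]]
  # delete an interior base whose neighbours differ
  del_at <- which(ch[2:39] != ch[1:38] & ch[2:39] != ch[3:40])[10] + 1
  seg <- align_segments(reads_df(paste(ch[-del_at], collapse = "")), refs)
  seg <- seg[seg$namespace == "transcript", ]
  expect_equal(nrow(seg), 1)
  expect_equal(seg$cigar, sprintf("%dM1D%dM", del_at - 1, 40 - del_at))
  expect_equal(seg$md, sprintf("%d^%s%d", del_at - 1, ch[del_at],
                               40 - del_at))
  expect_equal(seg$ref_start, 15)
  expect_equal(seg$ref_end, 54)
})

test_that("SAM round-trip preserves segment alignments", {
  cfg <- sim_config(n_transcripts = 6, transcript_length = 200, n_srnas = 5,
                    n_hybrid_reads = 25, n_nonhybrid_reads = 5, seed = 14)
  sim <- simulate_library(cfg)
  dd <- deduplicate_reads(trim_reads(sim$reads, cfg$adapter))
  seg <- align_segments(dd, sim$refs)
  tmp <- tempfile(fileext = ".sam")
  write_sam(seg, dd, sim$refs, tmp)
  back <- ingest_sam(tmp, sim$refs)
  ord <- function(d) {
    d <- d[order(d$read_id, d$ref_id), c("read_id", "ref_id", "read_start",
                                         "read_end", "ref_start", "ref_end",
                                         "cigar", "md", "n_mismatch")]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(back), ord(seg))
})

test_that("SAM ingestion parses format semantics and errors cleanly", {
  refs <- tiny_refs()
  tx <- refs$transcripts[["tx1"]]
  hdr <- c("@HD\tVN:1.6", paste0("@SQ\tSN:tx1\tLN:", nchar(tx)))
  rec <- paste("q1", 0, "tx1", 5, 60, "25M", "*", 0, 0,
               substr(tx, 5, 29), strrep("I", 25), "MD:Z:25", sep = "\t")
  f <- tempfile(fileext = ".sam")
  writeLines(c(hdr, rec), f)
  seg <- ingest_sam(f, refs)
  expect_equal(seg$ref_start, 5)
  expect_equal(seg$ref_end, 29)
  expect_equal(seg$n_mismatch, 0)
  # 10M1D15M with MD 10^X15: one deleted reference base at offset 10
  frag <- paste0(substr(tx, 5, 14), substr(tx, 16, 30))
  rec2 <- paste("q2", 0, "tx1", 5, 60, "10M1D15M", "*", 0, 0, frag,
                strrep("I", 25), paste0("MD:Z:10^", substr(tx, 15, 15), "15"),
                sep = "\t")
  writeLines(c(hdr, rec2), f)
  seg2 <- ingest_sam(f, refs)
  expect_equal(seg2$ref_end - seg2$ref_start + 1L, 26L)
  muts <- extract_mutations(seg2, reads_df(frag, ids = "q2"), refs)
  expect_equal(muts$kind, "deletion")
  expect_equal(muts$ref_pos, 15)
  # missing MD tag fails unless recomputation is requested
  rec3 <- paste("q3", 0, "tx1", 5, 60, "25M", "*", 0, 0,
                substr(tx, 5, 29), strrep("I", 25), sep = "\t")
  writeLines(c(hdr, rec3), f)
  expect_error(ingest_sam(f, refs), "MD")
  seg3 <- ingest_sam(f, refs, recompute_md = TRUE)
  expect_equal(seg3$md, "25")
  # unknown reference name
  rec4 <- paste("q4", 0, "nope", 5, 60, "25M", "*", 0, 0,
                substr(tx, 5, 29), strrep("I", 25), "MD:Z:25", sep = "\t")
  writeLines(c(hdr, rec4), f)
  expect_error(ingest_sam(f, refs), "nope")
})
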