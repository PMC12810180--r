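#' Run the full CLASH CIM pipeline
#'
#' Executes preprocess -> hybrid detection -> mutation calling (junction and
#' ambiguity filters) -> pairing-window extension and small-RNA-relative
#' mapping -> site aggregation and tiering -> non-hybrid mutation map and
#' per-site deletion-enrichment annotation.  Read weight is conserved at
#' every stage (reads are only classified or dropped with a counted reason);
#' the accounting is returned in the manifest.
#'
#' @param reads read table ([read_fastq()]) or path to a FASTQ file.
#' @param refs a [reference_set()].
#' @param adapter 3' adapter sequence (required unless `pre_trimmed`).
#' @param pre_trimmed input reads are already adapter/quality trimmed.
#' @param min_len,max_len,min_qual trimming parameters ([trim_reads()]).
#' @param min_anchor,max_mismatch,min_segment aligner parameters
#'   ([align_segments()]).
#' @param max_overlap,max_flank,max_gap,any_order decomposition parameters
#'   ([decompose_chimera()]).
#' @param max_alt_mismatch ambiguity filter tolerance ([filter_ambiguous()]).
#' @param enrich_alpha significance level for the non-hybrid deletion
#'   enrichment annotation.
#' @param outdir optional directory: when given, all tables are written as
#'   TSV (1-based coordinates), sites additionally as BED (0-based
#'   half-open), the non-hybrid deletion map as bedGraph, plus a manifest.
#' @return list: `reads` (deduplicated), `classification`, `hybrids` (with
#'   pairing window, score, states and enrichment annotation), `cims`
#'   (filtered, with `srna_rel_pos` and `site_id`), `cims_prefilter`,
#'   `sites`, `nonhybrid_cims`, `cim_map`, `profile`, `spectrum`,
#'   `frequencies`, `manifest`.
#' @export
run_pipeline <- function(reads, refs, adapter = NULL, pre_trimmed = FALSE,
                         min_len = 17L, max_len = 70L, min_qual = 30L,
                         min_anchor = 12L, max_mismatch = 4L,
                         min_segment = 18L, max_overlap = 4L, max_flank = 4L,
                         max_gap = 4L, any_order = FALSE,
                         max_alt_mismatch = 0L, enrich_alpha = 0.01,
                         outdir = NULL) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  manifest <- list(n_raw_reads = nrow(reads),
                   raw_weight = sum(reads$weight))

  trimmed <- if (pre_trimmed) {
    trim_reads(reads, adapter = "X", min_len = min_len, max_len = max_len,
               pre_trimmed = TRUE)
  } else {
    if (is.null(adapter)) stop_ctx("adapter required unless pre_trimmed")
    trim_reads(reads, adapter, min_len = min_len, max_len = max_len,
               min_qual = min_qual)
  }
  manifest$n_trimmed <- nrow(trimmed)
  manifest$n_length_filtered <- attr(trimmed, "dropped")

  dedup <- deduplicate_reads(trimmed)
  manifest$n_unique <- nrow(dedup)
  manifest$dedup_weight <- sum(dedup$weight)

  det <- detect_hybrids(dedup, refs, min_anchor = min_anchor,
                        max_mismatch = max_mismatch,
                        min_segment = min_segment, max_overlap = max_overlap,
                        max_flank = max_flank, max_gap = max_gap,
                        any_order = any_order)
  hybrids <- det$hybrids
  classification <- det$classification
  cw <- tapply(classification$weight, classification$class, sum)
  manifest$class_weight <- as.list(cw)

  # mutation calling on hybrid mRNA arms
  mseg <- data.frame(read_id = hybrids$read_id, ref_id = hybrids$transcript_id,
                     read_start = hybrids$mrna_read_start,
                     read_end = hybrids$mrna_read_end,
                     ref_start = hybrids$mrna_ref_start,
                     ref_end = hybrids$mrna_ref_end,
                     cigar = hybrids$mrna_cigar, md = hybrids$mrna_md,
                     stringsAsFactors = FALSE)
  cims_raw <- extract_mutations(mseg, dedup, refs)
  manifest$n_mutations_raw <- nrow(cims_raw)
  cims <- filter_junction_overlap(cims_raw, hybrids)
  manifest$n_mutations_junction_removed <- nrow(cims_raw) - nrow(cims)
  arms <- hybrid_arms(hybrids, dedup)
  cims <- filter_ambiguous(cims, arms, refs,
                           max_alt_mismatch = max_alt_mismatch)
  manifest$n_ambiguous_reads <- length(attr(cims, "ambiguous_reads"))

  # pairing window per hybrid + small-RNA-relative mutation coordinates
  hybrids <- extend_hybrid_windows(hybrids, refs)
  idx <- base::match(cims$read_id, hybrids$read_id)
  L_of <- nchar(refs$small_rnas)[hybrids$srna_id[idx]]
  cims$srna_id <- hybrids$srna_id[idx]
  cims$srna_rel_pos <- map_cim_position(cims$ref_pos,
                                        hybrids$window_start[idx],
                                        L_of)
  cims$site_id <- paste(hybrids$srna_id[idx], hybrids$transcript_id[idx],
                        hybrids$window_start[idx], hybrids$window_end[idx],
                        sep = "|")
  cim_tally <- cims[cims$kind != "insertion", , drop = FALSE]

  sites <- aggregate_sites(hybrids, cim_tally)
  if (nrow(sites)) sites$abundance_tier <- classify_abundance(sites$total_weight)
  sites <- classify_score_tertiles(sites)
  manifest$site_weight <- sum(sites$total_weight)
  manifest$hybrid_weight <- sum(hybrids$weight)

  # non-hybrid (mRNA-only) mutation map
  nh <- nonhybrid_segments(det$segments, classification)
  nh_cims <- extract_mutations(nh, dedup, refs)
  if (nrow(nh)) {
    seqs <- dedup$seq
    names(seqs) <- dedup$id
    nh_arms <- data.frame(read_id = nh$read_id, transcript_id = nh$ref_id,
                          ref_start = nh$ref_start,
                          arm_seq = substr(seqs[nh$read_id], nh$read_start,
                                           nh$read_end),
                          stringsAsFactors = FALSE)
    nh_cims <- filter_ambiguous(nh_cims, nh_arms, refs,
                                max_alt_mismatch = max_alt_mismatch)
  }
  cmap <- build_nonhybrid_cim_map(
    nh_cims[nh_cims$kind != "insertion", , drop = FALSE], refs)

  # annotate sites (and hybrids) with non-hybrid deletion enrichment
  if (nrow(sites)) {
    enr <- lapply(seq_len(nrow(sites)), function(i)
      region_enrichment_test(cmap, sites$transcript_id[i],
                             sites$window_start[i], sites$window_end[i],
                             kind = "deletion", alpha = enrich_alpha))
    sites$nonhybrid_del_p <- vapply(enr, function(e) e$p, numeric(1))
    sites$nonhybrid_del_enriched <- vapply(enr, function(e)
      isTRUE(e$enriched), logical(1))
    hyb_key <- paste(hybrids$srna_id, hybrids$transcript_id,
                     hybrids$window_start, hybrids$window_end, sep = "|")
    hybrids$nonhybrid_del_enriched <-
      sites$nonhybrid_del_enriched[base::match(hyb_key, sites$site_id)]
  } else {
    sites$nonhybrid_del_p <- numeric(0)
    sites$nonhybrid_del_enriched <- logical(0)
  }

  profile <- positional_distribution(cim_tally)
  spectrum <- mutation_spectrum(cim_tally)
  hw <- sum(hybrids$weight)
  nw <- sum(classification$weight[classification$class == "mrna_only"])
  frequencies <- data.frame(
    read_type = c("hybrid", "hybrid", "nonhybrid", "nonhybrid"),
    kind = c("deletion", "substitution", "deletion", "substitution"),
    carrier_weight = c(mutation_carrier_weight(cim_tally, "deletion"),
                       mutation_carrier_weight(cim_tally, "substitution"),
                       mutation_carrier_weight(nh_cims, "deletion"),
                       mutation_carrier_weight(nh_cims, "substitution")),
    total_weight = c(hw, hw, nw, nw), stringsAsFactors = FALSE)
  frequencies$percent <- ifelse(frequencies$total_weight > 0,
                                100 * frequencies$carrier_weight /
                                  frequencies$total_weight, NA_real_)

  res <- list(reads = dedup, classification = classification,
              hybrids = hybrids, cims = cim_tally, cims_prefilter = cims_raw,
              sites = sites, nonhybrid_cims = nh_cims, cim_map = cmap,
              profile = profile, spectrum = spectrum,
              frequencies = frequencies, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(res, refs, outdir)
  res
}

# pairing window, score and states per hybrid
extend_hybrid_windows <- function(hybrids, refs) {
  n <- nrow(hybrids)
  ws <- we <- integer(n)
  sc <- numeric(n)
  st <- character(n)
  code <- c(WC = "W", GU = "G", MM = "M")
  for (i in seq_len(n)) {
    ext <- extend_site(refs, hybrids$transcript_id[i],
                       hybrids$mrna_ref_start[i], hybrids$mrna_ref_end[i],
                       refs$small_rnas[[hybrids$srna_id[i]]])
    ws[i] <- ext$window_start
    we[i] <- ext$window_end
    sc[i] <- ext$score
    st[i] <- paste(code[ext$states], collapse = "")
  }
  hybrids$window_start <- ws
  hybrids$window_end <- we
  hybrids$score <- sc
  hybrids$states <- st
  hybrids
}

# best transcript segment of each mRNA-only read
nonhybrid_segments <- function(segments, classification) {
  nh <- classification[classification$class == "mrna_only", , drop = FALSE]
  keep <- segments[segments$read_id %in% nh$read_id &
                     segments$namespace == "transcript" &
                     paste(segments$read_id, segments$ref_id) %in%
                     paste(nh$read_id, nh$best_ref), , drop = FALSE]
  if (!nrow(keep)) return(keep)
  keep <- keep[order(keep$read_id, -keep$score), , drop = FALSE]
  keep <- keep[!duplicated(keep$read_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

# decode a pipeline "states" string back to a state vector
states_vector <- function(s) {
  map <- c(W = "WC", G = "GU", M = "MM")
  unname(map[seq_chars(s)])
}

write_pipeline_outputs <- function(res, refs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, name) {
    utils::write.table(d, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(res$classification, "classification.tsv")
  tsv(res$hybrids, "hybrids.tsv")
  tsv(res$cims, "cims.tsv")
  tsv(res$sites, "sites.tsv")
  tsv(res$nonhybrid_cims, "nonhybrid_cims.tsv")
  tsv(res$profile, "positional_profile.tsv")
  tsv(res$frequencies, "mutation_frequencies.tsv")
  tsv(res$spectrum$origin, "mutation_spectrum.tsv")
  if (nrow(res$sites)) {
    bed <- data.frame(chrom = res$sites$transcript_id,
                      start = res$sites$window_start - 1L,
                      end = res$sites$window_end,
                      name = res$sites$site_id,
                      score = res$sites$total_weight, strand = "+")
    utils::write.table(bed, file.path(outdir, "sites.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  bg <- list()
  for (tid in names(res$cim_map)) {
    v <- res$cim_map[[tid]]$deletion
    nz <- which(v > 0)
    if (length(nz))
      bg[[tid]] <- data.frame(chrom = tid, start = nz - 1L, end = nz,
                              value = v[nz])
  }
  if (length(bg)) {
    utils::write.table(do.call(rbind, bg),
                       file.path(outdir, "nonhybrid_deletions.bedGraph"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  mf <- res$manifest
  mf$class_weight <- NULL
  lines <- c(paste0("package_version\t", as.character(
    utils::packageVersion("cimclash"))),
    vapply(names(mf), function(k) paste0(k, "\t", mf[[k]]), character(1)),
    vapply(names(res$manifest$class_weight), function(k)
      paste0("class_weight_", k, "\t", res$manifest$class_weight[[k]]),
      character(1)))
  writeLines(lines, file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}
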