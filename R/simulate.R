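#' Configuration for the synthetic CLASH simulator
#'
#' The simulator emits a CLASH-like library with full ground truth: hybrid
#' reads (small RNA 5' arm ligated to an mRNA fragment whose transcript
#' context carries a planted pairing architecture), non-hybrid mRNA
#' fragments, PCR duplicates, crosslink-induced deletions/substitutions with
#' uridine origin preference and U->C / C->U substitution spectra, uniform
#' sequencing error, and a 3' adapter.
#'
#' Crosslink positions are drawn once per target site and mutation kind (a
#' crosslink reflects the bound complex, not the individual read):
#' deletions from `round(Normal(del_pos_mean, del_pos_sd))` in
#' small-RNA-relative coordinates, substitutions `sub_offset` (+/- jitter)
#' positions away from the deletion-side crosslink, modelling reverse
#' transcriptase stalling at the crosslink (deletion) versus bypassing it
#' and misincorporating slightly further along (substitution).  Deletions
#' are only placed at bases whose
#' neighbours differ from the deleted base (indel placement inside a
#' homopolymer is undefined).  Fragments carrying a mutation keep at least
#' `cim_flank` intact bases on both sides so the mutation is always inside
#' the reported alignment, and chimeric junctions are emitted clean (no
#' positive-scoring extension of the mRNA arm into the small RNA arm).
#'
#' @param n_transcripts,transcript_length reference transcript count/length.
#' @param n_srnas,srna_length small RNA count/length (21 = piRNA-like).
#' @param n_hybrid_reads,n_nonhybrid_reads template counts before duplicate
#'   expansion.
#' @param dup_prob PCR duplicate multiplicity is `1 + rgeom(dup_prob)`.
#' @param perfect_seed_frac fraction of sites with perfect seed pairing; the
#'   rest carry one seed mismatch compensated by full non-seed pairing.
#' @param bg_mismatch per-position background mismatch probability outside
#'   the seed.
#' @param cim_prob per-read probability of carrying a mutation.
#' @param cim_del_frac fraction of mutations that are deletions.
#' @param del_pos_mean,del_pos_sd small-RNA-relative crosslink (deletion)
#'   position distribution.
#' @param sub_offset,sub_offset_jitter substitutions sit `sub_offset`
#'   positions from the deletion-side crosslink (the reverse transcriptase
#'   incorporates aberrant bases ~2 nt after bypassing the crosslink), with
#'   a +/-1 jitter of probability `sub_offset_jitter` on each side.
#' @param t_origin_frac fraction of mutations with T (uridine) origin.
#' @param t_to_c share of T substitutions that become C.
#' @param c_to_t share of C substitutions that become T.
#' @param seq_error uniform per-base sequencing error rate.
#' @param adapter 3' adapter sequence appended to every read.
#' @param frag_min,frag_max mRNA fragment length range (nt).
#' @param cim_frag_min minimum fragment length when a mutation is carried.
#' @param cim_flank minimum intact fragment flank around a mutation.
#' @param nonhybrid_frag_min,nonhybrid_frag_max non-hybrid fragment lengths.
#' @param nonhybrid_at_sites fraction of non-hybrid reads drawn from planted
#'   target sites (crosslinked there) rather than uniformly.
#' @param transposon_family optional `list(copies =, distance =)`: adds a
#'   family of near-identical transcripts at the given Hamming distance (to
#'   exercise the ambiguity filter).
#' @param cim_pairing_dip extra mismatch probability planted at crosslink
#'   position +/- 1 in the site's pairing architecture.
#' @param seed integer seed; the seed fully determines the output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 30L, transcript_length = 300L,
                       n_srnas = 25L, srna_length = 21L,
                       n_hybrid_reads = 1000L, n_nonhybrid_reads = 100L,
                       dup_prob = 0.7, perfect_seed_frac = 0.7,
                       bg_mismatch = 0.1, cim_prob = 0.6,
                       cim_del_frac = 0.5, del_pos_mean = 11.5,
                       del_pos_sd = 1, sub_offset = -2L,
                       sub_offset_jitter = 0.2,
                       t_origin_frac = 0.6, t_to_c = 0.85, c_to_t = 0.84,
                       seq_error = 0, adapter = "AGATCGGAAGAGC",
                       frag_min = 18L, frag_max = 35L, cim_frag_min = 25L,
                       cim_flank = 12L, nonhybrid_frag_min = 18L,
                       nonhybrid_frag_max = 40L, nonhybrid_at_sites = 0.5,
                       transposon_family = NULL, cim_pairing_dip = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(perfect_seed_frac, bg_mismatch, cim_prob, cim_del_frac,
             t_origin_frac, t_to_c, c_to_t, seq_error, nonhybrid_at_sites,
             cim_pairing_dip, dup_prob)
  if (any(fracs < 0 | fracs > 1)) stop_ctx("fractions must lie in [0, 1]")
  if (sub_offset_jitter > 0.5) stop_ctx("sub_offset_jitter must be <= 0.5")
  if (frag_min > frag_max || cim_frag_min > frag_max)
    stop_ctx("infeasible fragment length range")
  if (cim_frag_min < 2 * cim_flank + 1)
    stop_ctx("cim_frag_min must allow cim_flank on both sides")
  if (transcript_length < srna_length + 2L * (40L + frag_max))
    stop_ctx("transcripts too short for site planting margins")
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Simulate the reference set and plant target sites
#'
#' Generates random small RNAs and transcripts (uniform base composition),
#' plants one pairing window per small RNA into a transcript (architecture
#' per `perfect_seed_frac`), draws the per-site crosslink positions, and
#' optionally adds a transposon family of near-identical transcript copies.
#'
#' @param cfg a [sim_config()].
#' @return list: `refs` (a [reference_set()]), `sites` (data.frame of
#'   planted sites: ids, window, architecture, per-kind crosslink
#'   positions), `config`.
#' @export
simulate_references <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$srna_length
  # exclude homopolymer runs >= 5 nt: a run in the guide puts a run in the
  # target window, where deletion placement is inherently ambiguous
  srnas <- vapply(seq_len(cfg$n_srnas), function(i) {
    repeat {
      s <- rand_seq(L)
      if (!grepl("AAAAA|CCCCC|GGGGG|TTTTT", s)) return(s)
    }
  }, character(1))
  names(srnas) <- sprintf("sr%03d", seq_len(cfg$n_srnas))
  txs <- vapply(seq_len(cfg$n_transcripts), function(i)
    rand_seq(cfg$transcript_length), character(1))
  names(txs) <- sprintf("tx%03d", seq_len(cfg$n_transcripts))
  txs_chars <- lapply(txs, seq_chars)

  margin <- 40L
  occupied <- lapply(txs, function(x) integer(0))
  sites <- vector("list", cfg$n_srnas)
  # discretized Normal mass over small RNA positions for the deletion-side
  # crosslink
  mu <- cfg$del_pos_mean
  psd <- max(cfg$del_pos_sd, 1e-9)
  kmass <- stats::pnorm(seq_len(L) + 0.5, mu, psd) -
    stats::pnorm(seq_len(L) - 0.5, mu, psd)
  draw_origin <- function() {
    sample(BASES, 1L, prob = c((1 - cfg$t_origin_frac) / 3,
                               (1 - cfg$t_origin_frac) / 3,
                               (1 - cfg$t_origin_frac) / 3,
                               cfg$t_origin_frac))
  }
  pj <- c(cfg$sub_offset_jitter, 1 - 2 * cfg$sub_offset_jitter,
          cfg$sub_offset_jitter)
  for (i in seq_len(cfg$n_srnas)) {
    sid <- names(srnas)[i]
    attempt <- 0L
    ok <- FALSE
    while (!ok && attempt < 80L) {
      attempt <- attempt + 1L
      repeat {
        ti <- sample.int(cfg$n_transcripts, 1L)
        ws <- sample1(seq(margin + 1L, cfg$transcript_length - L - margin))
        slots <- seq(ws - L, ws + 2L * L)
        if (!any(slots %in% occupied[[ti]])) break
      }
      # crosslink positions first: deletion from the positional law,
      # substitution a fixed (jittered) offset away
      k_del <- if (sum(kmass) > 0) wsample1(seq_len(L), kmass) else
        max(1L, min(L, as.integer(round(mu))))
      k_sub <- k_del + cfg$sub_offset + wsample1(c(-1L, 0L, 1L), pj)
      if (k_sub < 1L || k_sub > L) k_sub <- max(1L, min(L, k_del +
                                                          cfg$sub_offset))
      # uridine preference: the guide base opposite the crosslink is chosen
      # so its Watson-Crick partner on the mRNA is the drawn origin base
      s <- seq_chars(srnas[[i]])
      s[k_del] <- COMP[[draw_origin()]]
      if (k_sub != k_del) s[k_sub] <- COMP[[draw_origin()]]
      arch <- if (runif(1) < cfg$perfect_seed_frac) "perfect" else "seed_mm"
      w <- rev(unname(COMP[s]))  # perfect complement window, transcript sense
      spare <- setdiff(2:7, c(k_del, k_sub))
      if (arch == "seed_mm") {
        i0 <- sample1(spare)
        w[L - i0 + 1L] <- sample1(setdiff(BASES, COMP[[s[i0]]]))
      }
      for (p in setdiff(c(1L, seq(8L, L)), c(k_del, k_sub))) {
        if (runif(1) < cfg$bg_mismatch)
          w[L - p + 1L] <- sample1(setdiff(BASES, COMP[[s[p]]]))
      }
      tmp <- txs_chars[[ti]]
      tmp[seq(ws, ws + L - 1L)] <- w
      if (cfg$cim_pairing_dip > 0) {
        dip_at <- c(if (cfg$cim_del_frac > 0) k_del,
                    if (cfg$cim_del_frac < 1) k_sub)
        for (k in dip_at) tmp <- plant_dip(cfg, tmp, s, ws, L, k)
      }
      # deletion placement must be unambiguous and strictly favour the
      # gapped alignment; otherwise replant the site
      tpos <- ws + (L - k_del)
      b <- tmp[tpos]
      ok <- tmp[tpos - 1L] != b && tmp[tpos + 1L] != b &&
        del_frame_safe(tmp, tpos, cfg$cim_flank)
      if (ok) {
        srnas[i] <- paste(s, collapse = "")
        occupied[[ti]] <- c(occupied[[ti]], seq(ws, ws + L - 1L))
        txs_chars[[ti]] <- tmp
      }
    }
    if (!ok) stop_ctx("could not place a deletion crosslink for ", sid)
    sites[[i]] <- data.frame(
      srna_id = sid, transcript_id = names(txs)[ti], window_start = ws,
      window_end = ws + L - 1L, arch = arch, k_del = k_del, k_sub = k_sub,
      stringsAsFactors = FALSE)
  }
  txs <- vapply(txs_chars, paste, character(1), collapse = "")
  biotype <- rep("protein-coding", length(txs))
  family <- rep(NA_character_, length(txs))
  if (!is.null(cfg$transposon_family)) {
    fam <- cfg$transposon_family
    base <- rand_seq(cfg$transcript_length)
    copies <- character(fam$copies)
    copies[1] <- base
    for (j in seq(2L, fam$copies)) {
      ch <- seq_chars(base)
      pos <- sample(seq(20L, cfg$transcript_length - 20L), fam$distance)
      for (p in pos) ch[p] <- sample1(setdiff(BASES, ch[p]))
      copies[j] <- paste(ch, collapse = "")
    }
    names(copies) <- sprintf("tn001_%d", seq_len(fam$copies))
    txs <- c(txs, copies)
    biotype <- c(biotype, rep("transposon", fam$copies))
    family <- c(family, rep("tn001", fam$copies))
  }
  refs <- reference_set(srnas, txs, srna_class = "piRNA", biotype = biotype,
                        family = family)
  sites <- do.call(rbind, sites)
  sites$site_id <- paste(sites$srna_id, sites$transcript_id,
                         sites$window_start, sites$window_end, sep = "|")
  list(refs = refs, sites = sites, config = cfg)
}

# weighted draw of one element (safe for length-1 vectors)
wsample1 <- function(v, w) v[sample.int(length(v), 1L, prob = w)]

# TRUE when a deletion at tpos yields a strictly optimal gapped alignment
# for every fragment honouring the flank guarantee: an ungapped competitor
# reads one arm segment in a +/-1 shifted frame, paying 1 per trimmed base
# (j) plus 2 per shifted-frame mismatch; it must always pay more than the
# 7-point gap cost
del_frame_safe <- function(tc, tpos, flank, gap_cost = 7L) {
  idx <- seq(tpos - flank, tpos - 1L)
  v <- tc[idx] != tc[idx + 1L]
  mm_left <- c(rev(cumsum(rev(v))), 0L)   # mismatches kept after trimming j
  if (min(seq(0L, flank) + 2L * mm_left) <= gap_cost) return(FALSE)
  idx2 <- seq(tpos + 1L, tpos + flank)
  w <- tc[idx2] != tc[idx2 - 1L]
  mm_right <- c(rev(cumsum(w)), 0L)
  min(seq(0L, flank) + 2L * mm_right) > gap_cost
}


# plant extra mismatches at crosslink position +/- 1 (pairing dip); the
# replacement base must mismatch the small RNA and not create homopolymers
plant_dip <- function(cfg, tx_chars, s, ws, L, k) {
  for (j in seq(max(1L, k - 1L), min(L, k + 1L))) {
    if (runif(1) >= cfg$cim_pairing_dip) next
    tpos <- ws + (L - j)
    cand <- setdiff(BASES, c(COMP[[s[j]]], tx_chars[tpos - 1L],
                             tx_chars[tpos + 1L]))
    if (length(cand)) tx_chars[tpos] <- sample1(cand)
  }
  tx_chars
}

draw_sub_base <- function(cfg, origin) {
  if (origin == "T") {
    if (runif(1) < cfg$t_to_c) return("C")
    return(sample(c("A", "G"), 1L))
  }
  if (origin == "C") {
    if (runif(1) < cfg$c_to_t) return("T")
    return(sample(c("A", "G"), 1L))
  }
  sample1(setdiff(BASES, origin))
}

# TRUE when the transcript context 5' of the fragment start cannot extend
# the mRNA-arm alignment into the small RNA arm.  Checks the ungapped
# diagonal (every prefix of the leftward extension must score <= 0 under
# match +1 / mismatch -1) and, conservatively, nearby diagonals reachable
# through a gap: a single-gap extension only pays off if some diagonal
# carries a contiguous segment scoring more than the gap cost (7), so all
# diagonal maximum-subarray scores must stay below 8.
junction_clean <- function(tx_chars, fs, srna_chars, max_ext = 0L,
                           max_diag = 3L, gap_gain = 8L) {
  L <- length(srna_chars)
  n <- min(L, fs - 1L)
  if (n <= 0L) return(TRUE)
  rd <- srna_chars[seq(L, L - n + 1L)]  # read bases walking leftwards
  for (d in seq(-max_diag, max_diag)) {
    ref_pos <- fs - seq_len(n) - d
    ok <- which(ref_pos >= 1L)
    if (!length(ok)) next
    sc <- ifelse(tx_chars[ref_pos[ok]] == rd[ok], 1L, -1L)
    if (d == 0L) {
      cs <- cumsum(sc)
      # the ungapped extension may not reach beyond max_ext bases
      if (length(cs) > max_ext && any(cs[seq(max_ext + 1L, length(cs))] > 0L))
        return(FALSE)
    }
    best <- cur <- 0L
    for (v in sc) {
      cur <- max(0L, cur + v)
      if (cur > best) best <- cur
    }
    if (best >= gap_gain) return(FALSE)
  }
  TRUE
}

#' Simulate a CLASH library with ground truth
#'
#' @param cfg a [sim_config()].
#' @param simref output of [simulate_references()] (regenerated from `cfg`
#'   when omitted).
#' @return list: `reads` (FASTQ-style read table, one row per emitted copy),
#'   `truth` (list of `reads` -- one row per template, `cims`, `errors`),
#'   `refs`, `sites`, `config`.
#' @export
simulate_library <- function(cfg, simref = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(simref)) simref <- simulate_references(cfg)
  refs <- simref$refs
  sites <- simref$sites
  set.seed(cfg$seed + 500000L)
  L <- cfg$srna_length
  tx_chars <- lapply(refs$transcripts, seq_chars)
  srna_chars <- lapply(refs$small_rnas, seq_chars)

  n_h <- cfg$n_hybrid_reads
  n_n <- cfg$n_nonhybrid_reads
  n_t <- n_h + n_n
  t_reads <- vector("list", n_t)
  t_cims <- vector("list", n_t)

  for (i in seq_len(n_h)) {
    si <- sample.int(nrow(sites), 1L)
    st <- sites[si, ]
    tid <- st$transcript_id
    tc <- tx_chars[[tid]]
    tlen <- length(tc)
    sc <- srna_chars[[st$srna_id]]
    has_cim <- runif(1) < cfg$cim_prob
    kind <- if (has_cim && runif(1) < cfg$cim_del_frac) "deletion" else
      if (has_cim) "substitution" else NA_character_
    k <- if (has_cim) {
      if (kind == "deletion") st$k_del else st$k_sub
    } else NA_integer_
    tpos <- if (has_cim) st$window_start + (L - k) else NA_integer_

    frag <- sample_fragment(cfg, tc, sc, st$window_start, st$window_end,
                            tpos, tlen, L)
    fs <- frag[1]; fe <- frag[2]
    fchars <- tc[fs:fe]
    ref_base <- read_base <- NA_character_
    read_pos <- NA_integer_
    if (has_cim) {
      c0 <- tpos - fs + 1L
      ref_base <- fchars[c0]
      if (kind == "deletion") {
        fchars <- fchars[-c0]
        read_pos <- L + c0
      } else {
        read_base <- draw_sub_base(cfg, ref_base)
        fchars[c0] <- read_base
        read_pos <- L + c0
      }
    }
    insert <- paste0(paste(sc, collapse = ""), paste(fchars, collapse = ""))
    t_reads[[i]] <- data.frame(
      template_id = sprintf("h%05d", i), class = "hybrid",
      srna_id = st$srna_id, transcript_id = tid, site_id = st$site_id,
      frag_start = fs, frag_end = fe, window_start = st$window_start,
      window_end = st$window_end, arch = st$arch, insert_seq = insert,
      multiplicity = NA_integer_, stringsAsFactors = FALSE)
    if (has_cim) {
      t_cims[[i]] <- data.frame(
        template_id = sprintf("h%05d", i), kind = kind, transcript_id = tid,
        ref_pos = tpos, ref_base = ref_base, read_base = read_base,
        srna_rel_pos = k, read_pos = read_pos, stringsAsFactors = FALSE)
    }
  }

  tx_with_sites <- unique(sites$transcript_id)
  for (j in seq_len(n_n)) {
    i <- n_h + j
    at_site <- runif(1) < cfg$nonhybrid_at_sites
    has_cim <- runif(1) < cfg$cim_prob
    kind <- if (has_cim && runif(1) < cfg$cim_del_frac) "deletion" else
      if (has_cim) "substitution" else NA_character_
    if (at_site) {
      st <- sites[sample.int(nrow(sites), 1L), ]
      tid <- st$transcript_id
      tc <- tx_chars[[tid]]
      tpos <- if (has_cim) {
        st$window_start + (L - (if (kind == "deletion") st$k_del else
          st$k_sub))
      } else NA_integer_
      frag <- sample_fragment(cfg, tc, NULL, st$window_start, st$window_end,
                              tpos, length(tc), L,
                              lmin = cfg$nonhybrid_frag_min,
                              lmax = cfg$nonhybrid_frag_max)
    } else {
      tid <- sample1(names(refs$transcripts)[refs$biotype ==
                                               "protein-coding"])
      tc <- tx_chars[[tid]]
      tlen <- length(tc)
      lmin <- if (has_cim) max(cfg$cim_frag_min, cfg$nonhybrid_frag_min) else
        cfg$nonhybrid_frag_min
      l <- sample1(seq(lmin, cfg$nonhybrid_frag_max))
      if (has_cim) {
        tpos <- draw_nonhybrid_cim_pos(cfg, tc, kind)
        fs <- sample1(seq(max(1L, tpos + cfg$cim_flank - l + 1L),
                          min(tpos - cfg$cim_flank, tlen - l + 1L)))
      } else {
        tpos <- NA_integer_
        fs <- sample.int(tlen - l + 1L, 1L)
      }
      frag <- c(fs, fs + l - 1L)
    }
    fs <- frag[1]; fe <- frag[2]
    fchars <- tc[fs:fe]
    ref_base <- read_base <- NA_character_
    read_pos <- NA_integer_
    if (has_cim) {
      c0 <- tpos - fs + 1L
      ref_base <- fchars[c0]
      if (kind == "deletion") {
        fchars <- fchars[-c0]
        read_pos <- c0
      } else {
        read_base <- draw_sub_base(cfg, ref_base)
        fchars[c0] <- read_base
        read_pos <- c0
      }
    }
    insert <- paste(fchars, collapse = "")
    t_reads[[i]] <- data.frame(
      template_id = sprintf("n%05d", j), class = "nonhybrid",
      srna_id = NA_character_, transcript_id = tid, site_id = NA_character_,
      frag_start = fs, frag_end = fe, window_start = NA_integer_,
      window_end = NA_integer_, arch = NA_character_, insert_seq = insert,
      multiplicity = NA_integer_, stringsAsFactors = FALSE)
    if (has_cim) {
      t_cims[[i]] <- data.frame(
        template_id = sprintf("n%05d", j), kind = kind, transcript_id = tid,
        ref_pos = tpos, ref_base = ref_base, read_base = read_base,
        srna_rel_pos = NA_integer_, read_pos = read_pos,
        stringsAsFactors = FALSE)
    }
  }

  truth_reads <- do.call(rbind, t_reads)
  truth_cims <- do.call(rbind, t_cims[!vapply(t_cims, is.null, logical(1))])
  if (is.null(truth_cims)) {
    truth_cims <- empty_df(list(template_id = character(), kind = character(),
                                transcript_id = character(),
                                ref_pos = integer(), ref_base = character(),
                                read_base = character(),
                                srna_rel_pos = integer(),
                                read_pos = integer()))
  }

  # duplicate expansion, sequencing error, adapter
  mult <- 1L + rgeom(n_t, cfg$dup_prob)
  truth_reads$multiplicity <- mult
  ids <- seqs <- vector("list", n_t)
  errs <- list()
  for (i in seq_len(n_t)) {
    full <- paste0(truth_reads$insert_seq[i], cfg$adapter)
    copies <- character(mult[i])
    cid <- sprintf("%s.%02d", truth_reads$template_id[i], seq_len(mult[i]))
    for (m in seq_len(mult[i])) {
      s <- full
      if (cfg$seq_error > 0) {
        ch <- seq_chars(s)
        hit <- which(runif(length(ch)) < cfg$seq_error)
        for (p in hit) {
          to <- sample1(setdiff(BASES, ch[p]))
          errs[[length(errs) + 1L]] <- data.frame(
            copy_id = cid[m], read_pos = p, from = ch[p], to = to,
            stringsAsFactors = FALSE)
          ch[p] <- to
        }
        if (length(hit)) s <- paste(ch, collapse = "")
      }
      copies[m] <- s
    }
    ids[[i]] <- cid
    seqs[[i]] <- copies
  }
  ids <- unlist(ids)
  seqs <- unlist(seqs)
  reads <- data.frame(id = ids, seq = seqs,
                      qual = strrep("I", nchar(seqs)), weight = 1,
                      stringsAsFactors = FALSE)
  errors <- if (length(errs)) do.call(rbind, errs) else
    empty_df(list(copy_id = character(), read_pos = integer(),
                  from = character(), to = character()))
  list(reads = reads,
       truth = list(reads = truth_reads, cims = truth_cims, errors = errors),
       refs = refs, sites = sites, config = cfg)
}

# fragment interval for a hybrid (or site-attached non-hybrid) read:
# shorter-than-small-RNA fragments sit inside the pairing window, longer
# ones contain it; mutation flanks and (for hybrids) a clean junction are
# enforced by resampling
sample_fragment <- function(cfg, tc, sc, ws, we, tpos, tlen, L,
                            lmin = cfg$frag_min, lmax = cfg$frag_max) {
  has_cim <- !is.na(tpos)
  if (has_cim) {
    ri <- c(min(ws, tpos - cfg$cim_flank), max(we, tpos + cfg$cim_flank))
    lmin <- max(cfg$cim_frag_min, ri[2] - ri[1] + 1L)
  }
  for (try in seq_len(200L)) {
    l <- sample1(seq(lmin, max(lmin, lmax)))
    if (has_cim) {
      lo <- max(1L, ri[2] - l + 1L)
      hi <- min(ri[1], tlen - l + 1L)
    } else if (l < L) {
      lo <- ws
      hi <- we - l + 1L
    } else {
      lo <- max(1L, we - l + 1L)
      hi <- min(ws, tlen - l + 1L)
    }
    if (lo > hi) next
    fs <- sample1(seq(lo, hi))
    # fragments containing the full pairing window tolerate a short (<= 4 nt)
    # accidental junction extension: the window stays inside the scanned
    # region and the junction filter handles overlap mutations
    max_ext <- if (has_cim || l >= L) 4L else 0L
    if (is.null(sc) || junction_clean(tc, fs, sc, max_ext = max_ext))
      return(c(fs, fs + l - 1L))
  }
  # deterministic fallback: scan all (length, start) combinations
  for (l in seq(lmin, max(lmin, lmax))) {
    if (has_cim) {
      lo <- max(1L, ri[2] - l + 1L); hi <- min(ri[1], tlen - l + 1L)
    } else if (l < L) {
      lo <- ws; hi <- we - l + 1L
    } else {
      lo <- max(1L, we - l + 1L); hi <- min(ws, tlen - l + 1L)
    }
    if (lo > hi) next
    max_ext <- if (has_cim || l >= L) 4L else 0L
    for (fs in seq(lo, hi)) {
      if (is.null(sc) || junction_clean(tc, fs, sc, max_ext = max_ext))
        return(c(fs, fs + l - 1L))
    }
  }
  stop_ctx("no feasible fragment placement at window ", ws)
}

# transcript position for a background (non-site) non-hybrid mutation
draw_nonhybrid_cim_pos <- function(cfg, tc, kind) {
  tlen <- length(tc)
  lo <- cfg$cim_flank + 1L
  hi <- tlen - cfg$cim_flank
  for (try in seq_len(400L)) {
    b_star <- sample(BASES, 1L, prob = c((1 - cfg$t_origin_frac) / 3,
                                         (1 - cfg$t_origin_frac) / 3,
                                         (1 - cfg$t_origin_frac) / 3,
                                         cfg$t_origin_frac))
    p <- sample1(seq(lo, hi))
    if (tc[p] != b_star) next
    if (kind == "deletion" &&
        (tc[p - 1L] == tc[p] || tc[p + 1L] == tc[p] ||
         !del_frame_safe(tc, p, cfg$cim_flank))) next
    return(p)
  }
  for (try in seq_len(400L)) {
    p <- sample1(seq(lo, hi))
    if (kind == "deletion" &&
        (tc[p - 1L] == tc[p] || tc[p + 1L] == tc[p] ||
         !del_frame_safe(tc, p, cfg$cim_flank))) next
    return(p)
  }
  stop_ctx("could not place a non-hybrid mutation")
}

#' Compare called mutations against simulator ground truth
#'
#' Calls are matched to truth records by read sequence (error-free copies
#' retain the template insert sequence) with a fallback on the template id
#' encoded in the read name.  Precision is the fraction of called
#' (read, kind, position, base) records that are true; recall is the
#' fraction of truth records (over distinct insert sequences) that were
#' called.
#'
#' @param cims called mutation table (deletions/substitutions;
#'   insertions are ignored).
#' @param reads the deduplicated read table the calls were made from.
#' @param truth simulator truth (`$truth` of [simulate_library()]).
#' @param classes truth read classes to evaluate against (default
#'   `"hybrid"`).
#' @return list: `precision`, `recall` (over distinct call/truth records),
#'   `weighted_precision`, `weighted_recall` (weighted by read count --
#'   the pipeline's accounting unit, where a duplicated genuine crosslink
#'   counts with its full read weight while a one-off sequencing-error
#'   artifact counts once), `tp`, `fp`, `fn`.
#' @export
evaluate_cim_calls <- function(cims, reads, truth, classes = "hybrid") {
  k <- cims[cims$kind %in% c("deletion", "substitution"), , drop = FALSE]
  tr <- truth$reads[truth$reads$class %in% classes, , drop = FALSE]
  tc <- truth$cims[truth$cims$template_id %in% tr$template_id, , drop = FALSE]
  cim_key <- function(d) paste(d$kind, d$transcript_id, d$ref_pos,
                               d$ref_base, ifelse(is.na(d$read_base), "-",
                                                  d$read_base), sep = ":")
  seq_of_template <- tr$insert_seq
  names(seq_of_template) <- tr$template_id
  truth_keys_by_seq <- split(cim_key(tc),
                             unname(seq_of_template[tc$template_id]))
  truth_keys_by_tpl <- split(cim_key(tc), tc$template_id)
  read_seq <- reads$seq
  names(read_seq) <- reads$id

  call_keys_by_seq <- split(cim_key(k), unname(read_seq[k$read_id]))

  read_weight <- reads$weight
  names(read_weight) <- reads$id
  mult_by_seq <- tapply(truth$reads$multiplicity, truth$reads$insert_seq, sum)

  tp <- fp <- 0L
  tp_w <- fp_w <- 0
  for (i in seq_len(nrow(k))) {
    s <- read_seq[[k$read_id[i]]]
    keys <- truth_keys_by_seq[[s]]
    if (is.null(keys)) {
      tpl <- sub("\\.[0-9]+$", "", k$read_id[i])
      keys <- truth_keys_by_tpl[[tpl]]
    }
    w <- read_weight[[k$read_id[i]]]
    if (!is.null(keys) && cim_key(k[i, ]) %in% keys) {
      tp <- tp + 1L
      tp_w <- tp_w + w
    } else {
      fp <- fp + 1L
      fp_w <- fp_w + w
    }
  }
  fn <- 0L
  total_truth <- 0L
  hit_w <- tot_w <- 0
  for (s in names(truth_keys_by_seq)) {
    keys <- unique(truth_keys_by_seq[[s]])
    total_truth <- total_truth + length(keys)
    w <- unname(mult_by_seq[[s]])
    tot_w <- tot_w + w * length(keys)
    called <- call_keys_by_seq[[s]]
    miss <- sum(!keys %in% called)
    fn <- fn + miss
    hit_w <- hit_w + w * (length(keys) - miss)
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (total_truth > 0) (total_truth - fn) / total_truth
       else NA_real_,
       weighted_precision = if (tp_w + fp_w > 0) tp_w / (tp_w + fp_w)
       else NA_real_,
       weighted_recall = if (tot_w > 0) hit_w / tot_w else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' Classification accuracy against simulator truth
#'
#' @param classification per-read classification ([detect_hybrids()]).
#' @param reads deduplicated read table.
#' @param truth simulator truth.
#' @return fraction of deduplicated reads whose hybrid/non-hybrid call
#'   matches the truth class of their template.
#' @export
evaluate_classification <- function(classification, reads, truth) {
  tr <- truth$reads
  class_of_seq <- tr$class
  names(class_of_seq) <- tr$insert_seq
  class_of_tpl <- tr$class
  names(class_of_tpl) <- tr$template_id
  read_seq <- reads$seq
  names(read_seq) <- reads$id
  truth_class <- class_of_seq[read_seq[classification$read_id]]
  miss <- is.na(truth_class)
  truth_class[miss] <-
    class_of_tpl[sub("\\.[0-9]+$", "", classification$read_id[miss])]
  called <- ifelse(classification$class == "hybrid", "hybrid", "nonhybrid")
  mean(called == truth_class, na.rm = TRUE)
}
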