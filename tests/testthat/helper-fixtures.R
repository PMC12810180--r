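# Shared fixtures and independent oracles used across the suite.

# deterministic tiny reference set with one planted perfect site
tiny_refs <- function() {
  srna <- c(sr1 = "GGACTCTACAGATGTGCTCAA")  # 21 nt
  win <- revcomp(srna)
  set.seed(99)
  left <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
  tx <- paste0(left, win, right)
  reference_set(srna, c(tx1 = tx))
}

# build a read table from bare sequences (all high quality)
reads_df <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                     weight = 1) {
  data.frame(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
             weight = weight, stringsAsFactors = FALSE)
}

# independent exhaustive substring oracle for the ambiguity filter: does
# `arm` occur in any transcript other than at (tid, start)?
oracle_has_alternative <- function(arm, refs, tid, start) {
  for (t in names(refs$transcripts)) {
    hits <- gregexpr(arm, refs$transcripts[[t]], fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    for (h in hits) {
      if (t != tid || h != start) return(TRUE)
    }
  }
  FALSE
}

# independent exact Mann-Whitney oracle: enumerate group assignments and
# compare midrank rank sums (a different formulation than the package's
# pair-counting U)
oracle_mw_exact <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pool) + 1) / 2
  idx <- utils::combn(length(pool), n1)
  dev <- abs(w_obs - mu)
  hits <- 0L
  for (j in seq_len(ncol(idx))) {
    w <- sum(r[idx[, j]])
    if (abs(w - mu) >= dev - 1e-9) hits <- hits + 1L
  }
  hits / ncol(idx)
}

# per-position pairing state oracle (independent of pairing_states)
oracle_pair_state <- function(s_base, t_base) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  if (!s_base %in% names(wc) || !t_base %in% names(wc)) return("MM")
  if (t_base == wc[[s_base]]) return("WC")
  if ((s_base == "G" && t_base == "T") || (s_base == "T" && t_base == "G"))
    return("GU")
  "MM"
}

run_default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_hybrid_reads = 400, n_nonhybrid_reads = 60,
                        seed = 21)
      sim <- simulate_library(cfg)
      res <- run_pipeline(sim$reads, sim$refs, adapter = cfg$adapter)
      cache <<- list(cfg = cfg, sim = sim, res = res)
    }
    cache
  }
})
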