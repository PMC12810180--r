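test_that("pairing states follow the antiparallel WC/GU rules", {
  srna <- "GGACTT"
  expect_equal(pairing_states(srna, revcomp(srna)), rep("WC", 6))
  # small RNA G opposite target T is a GU wobble
  w <- strsplit(revcomp(srna), "")[[1]]
  w[6] <- "T"  # faces small RNA position 1 (G)
  st <- pairing_states(srna, paste(w, collapse = ""))
  expect_equal(st[1], "GU")
  expect_equal(st[-1], rep("WC", 5))
  expect_error(pairing_states("ACGT", "ACG"), "equal length")
})

test_that("pairing states equal a per-position oracle on random pairs", {
  set.seed(31)
  for (i in 1:200) {
    L <- sample(15:22, 1)
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    w <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    got <- pairing_states(paste(s, collapse = ""), paste(w, collapse = ""))
    want <- vapply(seq_len(L), function(p)
      oracle_pair_state(s[p], w[L - p + 1]), character(1))
    expect_equal(got, want)
  }
})

test_that("site extension finds the planted best-pairing window", {
  refs <- tiny_refs()
  srna <- refs$small_rnas[["sr1"]]
  # region exactly the window and perfectly complementary
  ext <- extend_site(refs, "tx1", 61, 81, srna)
  expect_equal(ext$window_start, 61)
  expect_equal(ext$states, rep("WC", 21))
  expect_false(ext$padded)
  # a 15-nt sub-region: extension recovers the planted 21-nt window
  ext2 <- extend_site(refs, "tx1", 64, 78, srna)
  expect_equal(ext2$window_start, 61)
  expect_equal(ext2$score, pairing_score(rep("WC", 21)))
  # region at the transcript 5' end: extension clips at position 1
  refs3 <- reference_set(refs$small_rnas,
                         c(tx1 = paste0(revcomp(srna),
                                        substr(refs$transcripts[["tx1"]], 1,
                                               60))))
  ext3 <- extend_site(refs3, "tx1", 1, 15, srna)
  expect_equal(ext3$window_start, 1)
  # transcript shorter than the small RNA: padded, flagged
  refs4 <- reference_set(refs$small_rnas, c(s = "ACGTACGTACGTACG"))
  ext4 <- extend_site(refs4, "s", 2, 10, srna)
  expect_true(ext4$padded)
  expect_equal(length(ext4$states), 21)
})

test_that("exhaustive window scoring oracle agrees with extend_site", {
  refs <- tiny_refs()
  srna <- refs$small_rnas[["sr1"]]
  tx <- refs$transcripts[["tx1"]]
  region <- c(55, 70)
  ext <- extend_site(refs, "tx1", region[1], region[2], srna)
  # oracle: score every window of length 21 in the extended region directly
  L <- 21
  m <- region[2] - region[1] + 1
  lo <- max(1, region[1] - (L - m))
  hi <- min(nchar(tx), region[2] + (L - m))
  best <- -Inf; best_start <- NA
  for (s0 in lo:(hi - L + 1)) {
    st <- pairing_states(srna, substr(tx, s0, s0 + L - 1))
    sc <- pairing_score(st)
    if (sc > best) { best <- sc; best_start <- s0 }
  }
  expect_equal(ext$window_start, best_start)
  expect_equal(ext$score, best)
})

test_that("mutations map to the antiparallel small RNA position", {
  # window 61..81, L = 21: transcript base 61 faces position 21, base 81
  # faces position 1
  expect_equal(map_cim_position(61, 61, 21), 21L)
  expect_equal(map_cim_position(81, 61, 21), 1L)
  expect_equal(map_cim_position(71, 61, 21), 11L)
  expect_true(is.na(map_cim_position(60, 61, 21)))
  expect_true(is.na(map_cim_position(82, 61, 21)))
  # bijection over the window
  expect_equal(sort(map_cim_position(61:81, 61, 21)), 1:21)
})

test_that("positional distributions aggregate weights by kind", {
  cims <- data.frame(read_id = c("a", "b"), kind = c("deletion", "deletion"),
                     srna_rel_pos = c(11L, 11L), weight = c(2, 3),
                     stringsAsFactors = FALSE)
  p <- positional_distribution(cims, l_max = 21)
  expect_equal(p$deletion[11], 5)
  expect_equal(sum(p$deletion), sum(cims$weight))
  expect_equal(sum(p$substitution), 0)
  p0 <- positional_distribution(cims[0, ], l_max = 21)
  expect_true(all(p0$deletion == 0))
  # top-third restriction keeps the highest-scoring reads only
  scores <- c(a = 10, b = 1, c = 5)
  p_top <- positional_distribution(cims, l_max = 21, scores = scores,
                                   top_third = TRUE)
  expect_equal(p_top$deletion[11], 2)
})

test_that("pairing ratios and region ratios count paired positions", {
  wc <- rep("WC", 21)
  mm <- rep("MM", 21)
  prof <- pairing_ratio_profile(list(wc, wc), weights = c(1, 1))
  expect_equal(prof$ratio, rep(1, 21))
  prof2 <- pairing_ratio_profile(list(wc, mm), weights = c(1, 1))
  expect_equal(prof2$ratio, rep(0.5, 21))
  gu <- rep("GU", 21)
  expect_equal(pairing_ratio_profile(list(gu))$ratio, rep(0, 21))
  expect_equal(pairing_ratio_profile(list(gu), count_gu = TRUE)$ratio,
               rep(1, 21))
  st <- c(rep("MM", 7), rep("WC", 14))
  expect_equal(region_pairing_ratio(st, "seed"), 0)
  expect_equal(region_pairing_ratio(st, "nonseed"), 1)
  expect_equal(region_pairing_ratio(rep("WC", 21), "seed"), 1)
  # random vectors equal a direct count oracle
  set.seed(7)
  for (i in 1:50) {
    st <- sample(c("WC", "GU", "MM"), 21, replace = TRUE)
    expect_equal(region_pairing_ratio(st, "seed"), mean(st[2:7] == "WC"))
    expect_equal(region_pairing_ratio(st, "nonseed"), mean(st[8:21] == "WC"))
  }
})

test_that("ratio differences centered on the mutation behave at boundaries", {
  wc <- rep("WC", 21)
  # subset identical to baseline -> all differences zero
  rd <- ratio_diff_around_cim(list(wc, wc), c(5L, 5L), list(wc, wc),
                              flank = 3)
  expect_true(all(rd$per_group$diff == 0))
  # single group at position 1: negative offsets are skipped
  rd2 <- ratio_diff_around_cim(list(wc), 1L, list(wc), flank = 3)
  expect_true(all(rd2$per_group$offset >= 0))
  expect_equal(rd2$summary$n_groups[rd2$summary$offset == -1], 0)
})

test_that("deletion/substitution offsets pair mutations within a site", {
  cims <- data.frame(read_id = c("a", "b", "c"),
                     kind = c("deletion", "substitution", "deletion"),
                     srna_rel_pos = c(11L, 9L, 12L), weight = c(1, 2, 1),
                     site_id = c("s1", "s1", "s2"), stringsAsFactors = FALSE)
  off <- deletion_substitution_offset(cims)
  # only site s1 has both kinds; pair weight = min(del, sub) = 1
  expect_equal(off$offset, -2)
  expect_equal(off$weight, 1)
  # a deletion-only site contributes nothing
  expect_equal(nrow(deletion_substitution_offset(cims[cims$site_id == "s2", ])),
               0)
})
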