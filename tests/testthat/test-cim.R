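test_that("mutation extraction follows CIGAR/MD semantics", {
  refs <- tiny_refs()
  tx <- refs$transcripts[["tx1"]]
  seg <- data.frame(read_id = "r1", ref_id = "tx1", read_start = 1,
                    read_end = 25, ref_start = 5, ref_end = 29,
                    cigar = "25M", md = "25", stringsAsFactors = FALSE)
  out <- extract_mutations(seg, reads_df(substr(tx, 5, 29), ids = "r1"), refs)
  expect_equal(nrow(out), 0)

  frag <- paste0(substr(tx, 5, 14), substr(tx, 16, 30))
  seg2 <- data.frame(read_id = "r2", ref_id = "tx1", read_start = 1,
                     read_end = 25, ref_start = 5, ref_end = 30,
                     cigar = "10M1D15M",
                     md = paste0("10^", substr(tx, 15, 15), "15"),
                     stringsAsFactors = FALSE)
  out2 <- extract_mutations(seg2, reads_df(frag, ids = "r2"), refs)
  expect_equal(out2$kind, "deletion")
  expect_equal(out2$ref_pos, 5 + 10)
  expect_equal(out2$ref_base, substr(tx, 15, 15))
  expect_true(is.na(out2$read_base))
  expect_equal(out2$read_pos, 11)  # first read base after the deletion

  # inconsistent MD (wrong match total) raises an error naming the read
  seg3 <- seg2
  seg3$md <- "9^A15"
  expect_error(extract_mutations(seg3, reads_df(frag, ids = "r2"), refs),
               "r2")
})

test_that("simulated mutations are extracted exactly", {
  cfg <- sim_config(n_hybrid_reads = 250, n_nonhybrid_reads = 0, seed = 19)
  sim <- simulate_library(cfg)
  res <- run_pipeline(sim$reads, sim$refs, adapter = cfg$adapter)
  ev <- evaluate_cim_calls(res$cims, res$reads, sim$truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})

test_that("junction-overlap mutations are removed", {
  cims <- data.frame(read_id = c("a", "a", "a"),
                     kind = c("substitution", "substitution", "deletion"),
                     transcript_id = "t", ref_pos = c(100, 110, 105),
                     ref_base = "T", read_base = c("C", "C", NA),
                     read_pos = c(21, 30, 25), weight = 1,
                     stringsAsFactors = FALSE)
  hybrids <- data.frame(read_id = "a", overlap_start = 20, overlap_end = 21,
                        stringsAsFactors = FALSE)
  out <- filter_junction_overlap(cims, hybrids)
  expect_equal(out$read_pos, c(30, 25))
  # empty overlap -> identity
  hybrids0 <- data.frame(read_id = "a", overlap_start = 0, overlap_end = 0,
                         stringsAsFactors = FALSE)
  expect_equal(nrow(filter_junction_overlap(cims, hybrids0)), 3)
  # a deletion flanked by overlap bases is removed too
  cims_del <- cims[3, ]
  cims_del$read_pos <- 21
  hyb2 <- data.frame(read_id = "a", overlap_start = 20, overlap_end = 21,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(filter_junction_overlap(cims_del, hyb2)), 0)
})

test_that("ambiguous arm placements drop mutation annotations", {
  set.seed(4)
  base <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  ch <- strsplit(base, "")[[1]]
  pos <- 60
  sister <- ch
  sister[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
  refs <- reference_set(c(sr1 = paste(sample(c("A","C","G","T"), 21,
                                             replace = TRUE), collapse = "")),
                        c(fam1 = base, fam2 = paste(sister, collapse = "")),
                        biotype = "transposon", family = "fam")
  # a read arm from fam1 whose substitution converts the divergent base to
  # the fam2 variant: exactly matches fam2 -> annotation dropped
  arm <- ch[41:80]
  arm_mut <- arm
  arm_mut[20] <- sister[pos]
  cims <- data.frame(read_id = "r1", kind = "substitution",
                     transcript_id = "fam1", ref_pos = pos,
                     ref_base = ch[pos], read_base = sister[pos],
                     read_pos = 20, weight = 1, stringsAsFactors = FALSE)
  arms <- data.frame(read_id = "r1", transcript_id = "fam1", ref_start = 41,
                     arm_seq = paste(arm_mut, collapse = ""),
                     stringsAsFactors = FALSE)
  out <- filter_ambiguous(cims, arms, refs)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "ambiguous_reads"), "r1")
  expect_true(oracle_has_alternative(arms$arm_seq, refs, "fam1", 41))
  # a substitution to a base present in neither copy stays unique
  other <- setdiff(c("A", "C", "G", "T"), c(ch[pos], sister[pos]))[1]
  arm_u <- arm
  arm_u[20] <- other
  arms2 <- arms
  arms2$arm_seq <- paste(arm_u, collapse = "")
  out2 <- filter_ambiguous(cims, arms2, refs)
  expect_equal(nrow(out2), 1)
  expect_false(oracle_has_alternative(arms2$arm_seq, refs, "fam1", 41))
})

test_that("mutation frequency reproduces published percentage arithmetic", {
  expect_equal(round(mutation_frequency(5166.5, 20038571), 3), 0.026)
  expect_equal(round(mutation_frequency(281215, 20038571), 2), 1.40)
  expect_equal(round(mutation_frequency(875559.5, 15107177), 1), 5.8)
  expect_equal(round(mutation_frequency(1120123, 15107177), 2), 7.41)
  expect_equal(mutation_frequency(0, 100), 0)
  expect_error(mutation_frequency(1, 0), "positive")
  expect_error(mutation_frequency(5, 4), "n_total")
})

test_that("mutation spectrum tallies origins and substitution types", {
  cims <- data.frame(read_id = "r", kind = "substitution",
                     transcript_id = "t", ref_pos = 1, ref_base = "T",
                     read_base = "C", read_pos = 1, weight = 1,
                     stringsAsFactors = FALSE)
  sp <- mutation_spectrum(cims)
  expect_equal(sp$origin$substitution_pct[sp$origin$base == "T"], 100)
  expect_equal(sp$substitution_matrix$percent["T", "C"], 100)
  sp0 <- mutation_spectrum(cims[0, ])
  expect_true(all(sp0$origin$deletion_weight == 0))
  expect_true(all(sp0$substitution_matrix$weight == 0))
  # per-origin substitution percentages sum to 100 where non-zero
  cims2 <- rbind(cims, within(cims, read_base <- "A"))
  sp2 <- mutation_spectrum(cims2)
  expect_equal(sum(sp2$substitution_matrix$percent["T", ]), 100)
})

test_that("simulated spectrum parameters are recovered", {
  cfg <- sim_config(n_hybrid_reads = 2000, n_nonhybrid_reads = 0, seed = 23)
  sim <- simulate_library(cfg)
  res <- run_pipeline(sim$reads, sim$refs, adapter = cfg$adapter)
  sp <- mutation_spectrum(res$cims)
  # deletions carry the uridine preference most faithfully (substitutions
  # inherit the crosslink context, which constrains their origin base)
  t_del <- sp$origin$deletion_pct[sp$origin$base == "T"] / 100
  expect_gt(t_del, 0.42)
  t_to_c <- sp$substitution_matrix$percent["T", "C"] / 100
  expect_lt(abs(t_to_c - cfg$t_to_c), 0.08)
  c_to_t <- sp$substitution_matrix$percent["C", "T"] / 100
  expect_lt(abs(c_to_t - cfg$c_to_t), 0.10)
})
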