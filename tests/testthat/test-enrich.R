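test_that("non-hybrid mutation maps accumulate per-position weights", {
  refs <- tiny_refs()
  cims <- data.frame(read_id = c("a", "b"), kind = c("deletion", "deletion"),
                     transcript_id = "tx1", ref_pos = c(10L, 10L),
                     ref_base = "T", read_base = NA, read_pos = 1,
                     weight = c(2, 1), stringsAsFactors = FALSE)
  m <- build_nonhybrid_cim_map(cims, refs)
  expect_equal(m[["tx1"]]$deletion[10], 3)
  expect_equal(sum(m[["tx1"]]$deletion), 3)
  expect_equal(sum(m[["tx1"]]$substitution), 0)
  m0 <- build_nonhybrid_cim_map(cims[0, ], refs)
  expect_true(all(m0[["tx1"]]$deletion == 0))
  # simulator map equals per-position truth sums
  x <- run_default_sim()
  tc <- x$sim$truth$cims
  tr <- x$sim$truth$reads
  nh <- tc[tc$template_id %in% tr$template_id[tr$class == "nonhybrid"] &
             tc$kind == "deletion", ]
  nh$mult <- tr$multiplicity[match(nh$template_id, tr$template_id)]
  truth_sum <- tapply(nh$mult, paste(nh$transcript_id, nh$ref_pos), sum)
  got <- x$res$cim_map
  for (k in names(truth_sum)) {
    parts <- strsplit(k, " ")[[1]]
    expect_equal(got[[parts[1]]]$deletion[as.integer(parts[2])],
                 unname(truth_sum[[k]]))
  }
})

test_that("region enrichment testing is one-sided and bounded", {
  refs <- tiny_refs()
  tx_len <- nchar(refs$transcripts[["tx1"]])
  mk_map <- function(track) {
    m <- list(tx1 = list(deletion = track, substitution = numeric(tx_len)))
    class(m) <- "cim_map"
    m
  }
  # all-zero transcript: maximal p, not enriched
  r0 <- region_enrichment_test(mk_map(numeric(tx_len)), "tx1", 61, 81)
  expect_equal(r0$p, 1)
  expect_false(r0$enriched)
  # strong in-region signal against a zero background is enriched, and the
  # normal-approximation p is conservative relative to the exact extreme tail
  tr <- numeric(tx_len)
  tr[61:81] <- 5
  r1 <- region_enrichment_test(mk_map(tr), "tx1", 61, 81)
  expect_true(r1$enriched)
  expect_lte(r1$p, 0.01)
  # identical in/out distributions: not enriched
  r2 <- region_enrichment_test(mk_map(rep(2, tx_len)), "tx1", 61, 81)
  expect_false(r2$enriched)
  # region == whole transcript -> undefined
  r3 <- region_enrichment_test(mk_map(tr), "tx1", 1, tx_len)
  expect_true(is.na(r3$p))
})

test_that("adding in-region weight never increases the enrichment p", {
  refs <- tiny_refs()
  tx_len <- nchar(refs$transcripts[["tx1"]])
  set.seed(13)
  base <- rpois(tx_len, 0.2)
  last <- Inf
  for (add in c(0, 2, 5, 10)) {
    tr <- base
    tr[61:81] <- tr[61:81] + add
    m <- list(tx1 = list(deletion = tr, substitution = numeric(tx_len)))
    class(m) <- "cim_map"
    p <- region_enrichment_test(m, "tx1", 61, 81)$p
    expect_lte(p, last + 1e-12)
    last <- p
  }
})

test_that("window counts cover a half-open window opposite position 10", {
  # window 101..121 (L = 21): center is opposite small RNA position 10,
  # i.e. transcript coordinate 101 + 11 = 112; window = [87, 136]
  rp <- data.frame(pos = c(112, 87, 136, 86, 137), weight = 1)
  expect_equal(window_count(101, 121, rp), 3)
  rp2 <- data.frame(pos = 112 + 30, weight = 2)
  expect_equal(window_count(101, 121, rp2), 0)
  # translation equivariance
  set.seed(2)
  pos <- sample(1:500, 100, replace = TRUE)
  rp3 <- data.frame(pos = pos, weight = runif(100))
  shift <- 37
  rp3s <- data.frame(pos = pos + shift, weight = rp3$weight)
  expect_equal(window_count(101, 121, rp3),
               window_count(101 + shift, 121 + shift, rp3s))
  # interval-membership oracle on uniformly placed reads
  c0 <- 101 + 11
  expect_equal(window_count(101, 121, rp3),
               sum(rp3$weight[rp3$pos >= c0 - 25 & rp3$pos <= c0 + 24]))
})

test_that("RPKM follows the definition", {
  expect_equal(rpkm(10, 2000, 1e6), 5)
  expect_equal(rpkm(0, 500, 1e6), 0)
  set.seed(8)
  counts <- rpois(20, 50)
  lens <- sample(200:5000, 20)
  tot <- 2.5e6
  expect_equal(rpkm(counts, lens, tot), counts * 1e6 / ((lens / 1000) * tot))
  expect_error(rpkm(1, 0, 100), "positive")
  expect_error(rpkm(1, 100, 0), "positive")
})

test_that("mutant/wild-type ratios apply pseudocounts and drop double zeros", {
  expect_equal(as.numeric(ratio_mutant_over_wt(2, 2, 0)), 1)
  expect_equal(as.numeric(ratio_mutant_over_wt(0, 4, 1)), 0.2)
  r <- ratio_mutant_over_wt(c(0, 3), c(0, 1), 1)
  expect_equal(length(r), 1)
  expect_equal(attr(r, "dropped"), 1)
  expect_error(ratio_mutant_over_wt(1:3, 1:2), "length")
})

test_that("WAGO target flags require strict two-fold IP enrichment", {
  expect_true(classify_wago_targets(9, 3))    # (9+1)/(3+1) = 2.5
  expect_false(classify_wago_targets(3, 3))
  expect_false(classify_wago_targets(7, 3))   # exactly 2 is not > 2
  set.seed(10)
  ip <- rpois(50, 20)
  inp <- rpois(50, 10)
  expect_equal(classify_wago_targets(ip, inp),
               (ip + 1) / (inp + 1) > 2)
})

test_that("grouped fold-change comparison detects a planted depletion", {
  # mutant 22G levels halved at mutation-carrying sites
  set.seed(99)
  n <- 40
  wt_cim <- rpois(n, 40)
  wt_nocim <- rpois(n, 40)
  mut_cim <- rbinom(n, wt_cim, 0.5)   # 2-fold depletion
  mut_nocim <- wt_nocim
  r_cim <- ratio_mutant_over_wt(mut_cim, wt_cim, 1)
  r_nocim <- ratio_mutant_over_wt(mut_nocim, wt_nocim, 1)
  g <- group_compare(as.numeric(r_cim), as.numeric(r_nocim),
                     n_perm = 2000, seed = 5)
  expect_lt(g$mw_p, 0.01)
  expect_lt(g$perm_p, 0.01)
  expect_lt(g$median_a, g$median_b)
})
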