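test_that("depth counts M-segment overlap and matches an interval oracle", {
  ref <- tiny_reference()
  idx <- build_index(ref, k = 21)
  r <- substr(ref$contigs[["chr1"]], 1001, 1101)
  rec <- align_batch(c(r, r, r), idx)
  d <- compute_depth(rec, ref)
  expect_identical(unname(d[["chr1"]][1050]), 3)
  expect_identical(unname(d[["chr1"]][999]), 0)
  expect_identical(sum(d[["chr1"]]), 3 * 101)       # depth conservation
  # empty alignment set -> all-zero track
  d0 <- compute_depth(rec[0, ], ref)
  expect_true(all(d0[["chr1"]] == 0) && all(d0[["transgene"]] == 0))
  # random mini-scenario records vs IRanges::coverage oracle
  aln <- mini_alignments()$e2e
  sub <- aln[aln$mapped & aln$unique & aln$cigar == "101M", ][1:2000, ]
  d1 <- compute_depth(sub, mini_scenario()$reference, require_unique = FALSE)
  for (ctg in unique(sub$contig)) {
    s <- sub[sub$contig == ctg, ]
    orc <- as.numeric(IRanges::coverage(
      IRanges::IRanges(start = s$pos, width = 101L),
      width = nchar(mini_scenario()$reference$contigs[[ctg]])))
    expect_identical(unname(d1[[ctg]]), orc)
  }
  bad <- sub[1, ]; bad$contig <- "chrZ"
  expect_error(compute_depth(bad, ref), "not in reference")
})

test_that("GC model is near-identity without bias and removes a planted bias", {
  sc <- mini_scenario()
  ref <- sc$reference
  d <- compute_depth(mini_alignments()$e2e, ref)
  mask <- rbind(ref$homology[, c("contig", "start", "end")],
                data.frame(contig = "transgene", start = 1L,
                           end = nchar(ref$contigs[["transgene"]])),
                data.frame(contig = "chr1", start = sc$locus_base,
                           end = sc$locus_base + 1000L))
  m <- fit_gc_bias(d, ref, bin_size = 1000L, mask = mask)
  expect_true(all(m$ratio > 0.9 & m$ratio < 1.1))
  dc <- correct_gc(d, m)
  expect_lt(abs(mean(dc[["chr1"]]) / mean(d[["chr1"]]) - 1), 0.02)
  # plant a 2x multiplicative bias in high-GC bins, then remove it
  bins <- m$bins[m$bins$contig == "chr1", ]
  d2 <- d
  hi <- bins[!is.na(bins$gc) & bins$gc >= stats::median(bins$gc), ]
  for (k in seq_len(nrow(hi)))
    d2[["chr1"]][hi$start[k]:hi$end[k]] <- 2 * d2[["chr1"]][hi$start[k]:hi$end[k]]
  m2 <- fit_gc_bias(d2, ref, bin_size = 1000L, mask = mask)
  dc2 <- correct_gc(d2, m2)
  binned <- isceimap:::binned_depth(dc2["chr1"], 1000L)
  binned <- binned[!isceimap:::mask_bins(binned, mask), ]
  doubled <- binned$start %in% hi$start
  # before correction the biased group sits at ~2x; after correction the two
  # groups agree within 10% (per-bin Poisson noise remains, the systematic
  # bias is gone)
  raw_binned <- isceimap:::binned_depth(d2["chr1"], 1000L)
  raw_binned <- raw_binned[!isceimap:::mask_bins(raw_binned, mask), ]
  expect_gt(mean(raw_binned$depth[doubled]) /
              mean(raw_binned$depth[!doubled]), 1.8)
  expect_lt(abs(mean(binned$depth[doubled]) /
                  mean(binned$depth[!doubled]) - 1), 0.10)
  expect_error(fit_gc_bias(d, ref, bin_size = 10^7), "bin_size")
})

test_that("background depth is robust and close to the simulated depth", {
  sc <- mini_scenario()
  ref <- sc$reference
  d0 <- compute_depth(mini_alignments()$e2e, ref)
  mask <- rbind(ref$homology[, c("contig", "start", "end")],
                data.frame(contig = "chr1", start = sc$locus_base,
                           end = sc$locus_base + 1000L))
  bg <- background_depth(d0, ref, mask = mask)
  expect_lt(abs(bg - 20) / 20, 0.05)
  # robust to one strongly amplified bin
  d1 <- d0
  d1[["chr1"]][30001:31000] <- 10 * d1[["chr1"]][30001:31000]
  expect_lt(abs(background_depth(d1, ref, mask = mask) - bg) / bg, 0.02)
  # median-based background agrees with the mean on unbiased data
  binned <- isceimap:::binned_depth(d0["chr1"], 1000L)
  binned <- binned[!isceimap:::mask_bins(binned, mask), ]
  expect_lt(abs(bg - mean(binned$depth)) / bg, 0.05)
})

test_that("copy-number arithmetic reproduces the coverage-ratio worked examples", {
  # shared promoter: 80x over a 20x diploid background, 2 endogenous copies
  expect_identical(estimate_copy_number(80, 20, endogenous_copies = 2,
                                        ploidy = 2)$copies, 6L)
  # cassette-only reporter CDS: 60x, no endogenous copy
  expect_identical(estimate_copy_number(60, 20, endogenous_copies = 0,
                                        ploidy = 2)$copies, 6L)
  # one haploid copy
  expect_identical(estimate_copy_number(10, 20, 0, 2)$copies, 1L)
  # scale invariance
  e1 <- estimate_copy_number(80, 20, 2, 2)
  e2 <- estimate_copy_number(800, 200, 2, 2)
  expect_identical(e1$copies, e2$copies)
  expect_equal(e1$copies_frac, e2$copies_frac)
  # Poisson interval brackets the point estimate and tightens with length
  es <- estimate_copy_number(60, 20, 0, 2, region_length = 700)
  el <- estimate_copy_number(60, 20, 0, 2, region_length = 7000)
  expect_true(es$ci[1] < 6 && es$ci[2] > 6)
  expect_lt(diff(el$ci), diff(es$ci))
  expect_error(estimate_copy_number(-5, 20, 0, 2), "nonnegative")
  expect_error(estimate_copy_number(80, 0, 0, 2), "positive")
})
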