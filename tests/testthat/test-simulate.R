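test_that("simulated host genome has requested length, GC and plantings", {
  h <- simulate_host_genome(100000, gc_fraction = 0.40, seed = 1)
  expect_identical(nchar(h[["chr1"]]), 100000L)
  gc <- sum(strsplit(h[["chr1"]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.40), 0.01)
  expect_identical(simulate_host_genome(100000, 0.40, seed = 1), h)
  prom <- strrep("ACGTT", 20)
  h2 <- simulate_host_genome(20000, 0.4,
                             planted_promoter = list(sequence = prom,
                                                     start = 5001), seed = 2)
  hit <- gregexpr(prom, h2[["chr1"]], fixed = TRUE)[[1]]
  expect_true(5001L %in% as.integer(hit))
  expect_error(simulate_host_genome(1000, 0.4,
                                    planted_promoter = list(sequence = prom,
                                                            start = 990)),
               "bounds")
})

test_that("insertion splicing follows the deletion/duplication arithmetic", {
  set.seed(3)
  host <- c(chrT = paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                         collapse = ""))
  cons <- tiny_construct(50)
  del <- insertion_event("chrT", 200, 212, cons)   # 11 bp deletion
  a1 <- apply_insertion_events(host, list(del))
  expect_identical(nchar(a1$allele[["chrT_tg"]]), 1000L - 11L + 50L)
  dup <- insertion_event("chrT", 334, 320, cons)   # 15 bp duplication
  a2 <- apply_insertion_events(host, list(dup))
  expect_identical(nchar(a2$allele[["chrT_tg"]]), 1000L + 15L + 50L)
  # duplicated host bases flank the payload on both sides
  expect_identical(substr(a2$allele[["chrT_tg"]], 320, 334),
                   substr(host[["chrT"]], 320, 334))
  expect_identical(substr(a2$allele[["chrT_tg"]], 334 + 50 + 1, 334 + 50 + 15),
                   substr(host[["chrT"]], 320, 334))
  expect_error(apply_insertion_events(host,
                                      list(insertion_event("chrT", 999, 1200,
                                                           cons))),
               "outside")
})

test_that("lesion classification inverts event generation over the offset range", {
  set.seed(4)
  host <- c(chrT = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                         collapse = ""))
  cons <- tiny_construct(40)
  for (d in -30:30) {
    L <- 600L; R <- L + 1L + d      # d<0: duplication; d=0: blunt; d>0: deletion
    ev <- insertion_event("chrT", L, R, cons)
    les <- classify_target_site(L, R)
    tr <- apply_insertion_events(host, list(ev))
    expected_len <- 2000L - max(0L, R - L - 1L) + max(0L, L - R + 1L) + 40L
    expect_identical(nchar(tr$allele[["chrT_tg"]]), expected_len)
    if (d == 0) expect_identical(les$class, "blunt")
    else if (d > 0) {
      expect_identical(les$class, "deletion")
      expect_identical(les$length, d)
    } else {
      # R = L+1+d with d < 0 duplicates host bases R..L, i.e. -d of them
      expect_identical(les$class, "duplication")
      expect_identical(les$length, -d)
    }
  }
})

test_that("read simulation hits the requested depth and is reproducible", {
  set.seed(5)
  al <- c(a = paste(sample(c("A", "C", "G", "T"), 500000, TRUE), collapse = ""),
          b = paste(sample(c("A", "C", "G", "T"), 500000, TRUE), collapse = ""))
  p <- sim_params(depth = 20, error_rate = 0, seed = 9)
  rd <- simulate_reads(al, p)
  expect_equal(length(rd$qname), round(20 * 1e6 / 202), tolerance = 0.001)
  # error-free reads are exact substrings of their allele (or revcomp)
  i <- sample(length(rd$qname), 50)
  tr <- rd$truth[i, ]
  expect_true(all(substring(al[tr$allele], tr$frag_start,
                            tr$frag_start + 100) == rd$read1[i]))
  expect_true(all(vapply(seq_along(i), function(k) {
    frag_end <- tr$frag_start[k] + tr$frag_len[k] - 1L
    revcomp_chr(substring(al[[tr$allele[k]]], frag_end - 100L, frag_end)) ==
      rd$read2[i[k]]
  }, logical(1))))
  # observed depth in a 10 kb window within 3 Poisson standard errors
  win <- 200001:210000
  cov <- integer(10000)
  sel <- rd$truth$allele == "a"
  for (k in which(sel)) {
    s1 <- rd$truth$frag_start[k]
    s2 <- rd$truth$frag_start[k] + rd$truth$frag_len[k] - 101L
    for (s in c(s1, s2)) {
      lo <- max(s, 200001L); hi <- min(s + 100L, 210000L)
      if (lo <= hi) cov[(lo:hi) - 200000L] <- cov[(lo:hi) - 200000L] + 1L
    }
  }
  md <- mean(cov)
  se <- 20 / sqrt(20 * 10000 / 101)
  expect_lt(abs(md - 20), 3 * se)
  # same seed, byte-identical FASTQ
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_fastq(simulate_reads(al, p), f1, f2)
  write_fastq(simulate_reads(al, p), g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
  rt <- read_fastq_pair(f1, f2)
  expect_identical(rt$read1, rd$read1)
  unlink(c(f1, f2, g1, g2))
  expect_error(sim_params(depth = -1), "positive")
  expect_error(sim_params(read_length = 500, fragment_mean = 350),
               "must not exceed")
})

test_that("truth SAM places interior reads unclipped and junction reads soft-clipped", {
  sc <- errorfree_scenario()
  path <- tempfile(fileext = ".sam")
  rec <- emit_truth_sam(sc$reads, sc$truth, sc$reference, path)
  expect_identical(nrow(rec), 2L * length(sc$reads$qname))
  back <- read_sam(path)
  expect_identical(nrow(back), nrow(rec))        # count oracle via SAM reader
  expect_identical(back$pos, rec$pos)
  expect_identical(back$cigar, rec$cigar)
  expect_identical(back$unique, rec$unique)
  # reads fully inside an unmodified host region are unclipped at true position
  tr <- sc$reads$truth
  B <- sc$locus_base
  far <- which(tr$allele == "wt" & tr$frag_start > 1000 &
                 tr$frag_start + tr$frag_len < 60000)[1:50]
  r1rows <- rec[rec$read1 %in% TRUE, ][far, ]
  expect_true(all(r1rows$cigar == "101M"))
  expect_identical(r1rows$pos, tr$frag_start[far])
  # junction-spanning read1s carry a soft clip at the true breakpoint
  segs <- sc$truth$segments
  j <- which(tr$allele == "tg" &
               tr$frag_start < segs$a_end[1] - 54 &
               tr$frag_start > segs$a_end[1] - 70)
  expect_gt(length(j), 0)
  jrows <- rec[rec$read1 %in% TRUE, ][j, ]
  expect_true(all(grepl("S", jrows$cigar)))
  expect_true(all(jrows$pos + isceimap:::cigar_ref_len(jrows$cigar) - 1L ==
                    B + 200L))
})

test_that("the study scenario encodes the characterized locus geometry", {
  sc <- mini_scenario()
  expect_identical(nrow(sc$sites_truth), 2L)
  expect_identical(sum(sc$sites_truth$copies), 6L)
  les1 <- classify_target_site(sc$sites_truth$left[1], sc$sites_truth$right[1])
  les2 <- classify_target_site(sc$sites_truth$left[2], sc$sites_truth$right[2])
  expect_identical(les1$class, "deletion"); expect_identical(les1$length, 11L)
  expect_identical(les2$class, "duplication"); expect_identical(les2$length, 15L)
  expect_identical(min(sc$sites_truth$right[2]) - sc$sites_truth$right[1],
                   108L)
  # every simulated fragment lies within its allele
  al <- sc$truth$allele
  tr <- sc$reads$truth
  lens <- c(tg = nchar(al[["chr1_tg"]]),
            wt = nchar(sc$reference$contigs[["chr1"]]))
  expect_true(all(tr$frag_start >= 1))
  expect_true(all(tr$frag_start + tr$frag_len - 1L <= lens[tr$allele]))
})
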