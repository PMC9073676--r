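test_that("index construction validates k and indexes every position", {
  ref <- tiny_reference()
  expect_error(build_index(ref, k = 5000), "shortest contig")
  idx <- build_index(ref, k = 21)
  # a random planted 31-mer is recovered at its planting position
  set.seed(21)
  probe <- substr(ref$contigs[["chr1"]], 2345, 2375)
  a <- align_local(probe, idx)
  expect_true(a$mapped)
  expect_identical(as.integer(a$pos), 2345L)
  expect_identical(a$cigar, "31M")
})

test_that("end-to-end alignment recovers exact substrings on both strands", {
  ref <- tiny_reference()
  idx <- build_index(ref, k = 21)
  r <- substr(ref$contigs[["chr1"]], 1501, 1601)
  a <- align_end_to_end(r, idx)
  expect_identical(a[, c("contig", "pos", "strand", "cigar")],
                   data.frame(contig = "chr1", pos = 1501L, strand = "+",
                              cigar = "101M"))
  expect_identical(a$score, 101L)
  expect_true(a$unique)
  b <- align_end_to_end(revcomp_chr(r), idx)
  expect_identical(as.integer(b$pos), 1501L)
  expect_identical(b$strand, "-")
  # an unalignable read returns unmapped, not an error
  junk <- strrep("ACGT", 26)
  expect_false(align_end_to_end(substr(junk, 1, 101), idx)$mapped ||
                 FALSE)
})

test_that("reads from a repeated region are flagged non-unique", {
  set.seed(31)
  unit <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  host <- c(chr1 = paste0(pad(1000), unit, pad(800), unit, pad(1000)))
  idx <- build_index(host, k = 21)
  rd <- substr(unit, 101, 201)
  a <- align_end_to_end(rd, idx)
  expect_true(a$mapped)
  expect_false(a$unique)
  expect_identical(a$score, a$second)
  # lexicographic tie-break: first occurrence wins
  expect_identical(as.integer(a$pos), 1101L)
  # brute-force oracle confirms two equal-score placements
  sc1 <- oracle_score(rd, substr(host[["chr1"]], 1, 2200))
  sc2 <- oracle_score(rd, substr(host[["chr1"]], 2201, nchar(host[["chr1"]])))
  expect_identical(sc1, sc2)
})

test_that("local mode soft-clips chimeric reads and equals end-to-end on clean reads", {
  ref <- tiny_reference()
  host <- ref$contigs[["chr1"]]; tg <- ref$contigs[["transgene"]]
  idx <- build_index(ref, k = 21)
  # pick a host cut with no chance microhomology into the construct start,
  # so the breakpoint representation is unambiguous by construction
  st <- 3001L
  while (substr(host, st + 60L, st + 60L) == substr(tg, 1L, 1L))
    st <- st + 1L
  chim <- paste0(substr(host, st, st + 59L), substr(tg, 1, 41))
  a <- align_local(chim, idx)
  expect_identical(a$cigar, "60M41S")
  expect_identical(as.integer(a$pos), st)
  clip <- substr(chim, 61, 101)
  b <- align_local(clip, build_index(ref$contigs["transgene"], k = 11))
  expect_identical(as.integer(b$pos), 1L)
  expect_identical(b$cigar, "41M")
  r <- substr(host, 2001, 2101)
  expect_identical(align_local(r, idx)[, c("pos", "cigar", "score")],
                   align_end_to_end(r, idx)[, c("pos", "cigar", "score")])
})

test_that("alignment scores match the dynamic-programming oracle", {
  ref <- tiny_reference(seed = 41, host_len = 8000, construct_len = 500)
  idx <- build_index(ref, k = 21)
  whole <- paste0(ref$contigs[["chr1"]], ref$contigs[["transgene"]])
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (t in 1:60) {
    st <- sample(7800, 1)
    rd <- substr(ref$contigs[["chr1"]], st, st + 100)
    nmut <- sample(0:4, 1)
    for (m in seq_len(nmut)) {
      p <- sample(101, 1); substr(rd, p, p) <- sample(bases, 1)
    }
    if (runif(1) < 0.3) {  # small indel
      p <- sample(30:70, 1)
      rd <- if (runif(1) < 0.5)
        paste0(substr(rd, 1, p), sample(bases, 1), substr(rd, p + 1, 101))
      else paste0(substr(rd, 1, p), substr(rd, p + 2, 101))
    }
    if (runif(1) < 0.3) rd <- revcomp_chr(rd)
    loc <- align_local(rd, idx)
    e2e <- align_end_to_end(rd, idx)
    expect_identical(as.numeric(loc$score),
                     as.numeric(oracle_score(rd, whole, "local")))
    if (e2e$mapped) {
      expect_identical(as.numeric(e2e$score),
                       as.numeric(oracle_score(rd, whole, "global-local")))
      # clipping can only help: local score >= end-to-end score
      expect_gte(loc$score, e2e$score)
    }
    # CIGAR accounts for every read base
    tb <- isceimap:::cigar_table(loc$cigar)
    expect_identical(sum(tb$len[tb$op %in% c("M", "S", "I")]), nchar(rd))
  }
})

test_that("pairing flags concordant and discordant pairs correctly", {
  sc <- mini_scenario()
  aln <- mini_alignments()$e2e
  tr <- sc$reads$truth
  # wild-type fragments map as proper pairs at high rate
  wt1 <- aln[aln$read1 %in% TRUE, ][tr$allele == "wt", ]
  expect_gt(mean(wt1$proper, na.rm = TRUE), 0.95)
  # a pair with read 1 inside the payload's vector backbone (construct-only
  # sequence) and read 2 in the downstream host flank is discordant, mates on
  # different contigs
  segs <- sc$truth$segments
  last_pay <- max(which(segs$src == "transgene"))
  vec_lo <- segs$a_start[last_pay] + 4613L   # vector portion of the copy
  pay <- which(tr$allele == "tg" &
                 tr$frag_start >= vec_lo &
                 tr$frag_start + 100L <= segs$a_end[last_pay] &
                 tr$frag_start + tr$frag_len - 1L >=
                   segs$a_end[last_pay] + 101L)
  expect_gt(length(pay), 2)
  pay1 <- aln[aln$read1 %in% TRUE, ][pay, ]
  pay2 <- aln[!(aln$read1 %in% TRUE), ][pay, ]
  ok <- pay1$mapped & pay2$mapped
  expect_true(all(!pay1$proper[ok]))
  expect_true(all(pay1$contig[ok] == "transgene"))
  expect_true(all(pay2$contig[ok] == "chr1"))
  expect_error(align_pairs(c("ACGT"), character(0),
                           build_index(tiny_reference(), 21)),
               "out of sync")
})

test_that("SAM round trip preserves the fields downstream modules use", {
  aln <- mini_alignments()$local
  sub <- aln[1:400, ]
  ref <- mini_scenario()$reference
  p <- tempfile(fileext = ".sam")
  write_sam(sub, ref, p)
  back <- read_sam(p)
  for (f in c("qname", "read1", "mapped", "contig", "pos", "strand", "cigar",
              "score", "second", "unique", "seq", "mate_contig", "mate_pos",
              "mate_strand", "proper"))
    expect_identical(back[[f]], sub[[f]], label = paste("field", f))
  expect_identical(isceimap:::cigar_table("60M41S"),
                   data.frame(op = c("M", "S"), len = c(60L, 41L)))
  unlink(p)
})
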