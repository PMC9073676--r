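test_that("lesion classification reproduces the characterized line's boundary arithmetic", {
  les1 <- classify_target_site(86757200, 86757212)
  expect_identical(les1$class, "deletion")
  expect_identical(les1$length, 11L)
  expect_equal(les1$interval, c(86757201, 86757211))
  les2 <- classify_target_site(86757334, 86757320)
  expect_identical(les2$class, "duplication")
  expect_identical(les2$length, 15L)
  expect_equal(les2$interval, c(86757320, 86757334))
  les3 <- classify_target_site(100, 101)
  expect_identical(les3$class, "blunt")
  expect_identical(les3$length, 0L)
  expect_error(classify_target_site(0, 5), "positive")
})

test_that("site distance uses the closest-boundary gap and is translation invariant", {
  mkb <- function(pos, side) {
    b <- isceimap:::boundary_frame()
    b[1, ] <- list("chr1", side, pos, 1L, "+", "start", 5L, 0L, 0L, "")
    b
  }
  mks <- function(l, r) isceimap:::make_site(mkb(l, "left"), mkb(r, "right"))
  s1 <- mks(200, 212); s2 <- mks(334, 320)
  expect_identical(site_distance(s1, s2), 108)
  expect_identical(site_distance(s2, s1), 108)
  expect_identical(site_distance(s1, s1), 0)
  expect_identical(site_distance(mks(1200, 1212), mks(1334, 1320)), 108)
})

test_that("junction pairs keep transgene/promoter x unique-host discordant pairs only", {
  sc <- mini_scenario()
  aln <- mini_alignments()$e2e
  jp <- find_junction_pairs(aln, sc$reference)
  expect_gt(nrow(jp), 10)
  # every retained pair's host mate lies within a fragment length of a truth
  # boundary or of the payload-bearing locus
  B <- sc$locus_base
  lim <- 350 + 4 * 35
  near <- (jp$host_end >= B + 200 - lim & jp$host_pos <= B + 334 + lim) |
    jp$tg_is_promoter
  expect_true(all(near[jp$host_contig == "chr1"]))
  # unpaired input errors
  single <- aln; single$read1 <- NA
  expect_error(find_junction_pairs(single, sc$reference), "not paired")
})

test_that("split reads pinpoint constructed chimeric junctions by construction", {
  ref <- tiny_reference()
  host <- ref$contigs[["chr1"]]; tg <- ref$contigs[["transgene"]]
  idx <- build_index(ref, k = 21)
  chim <- paste0(substr(host, 3001, 3060), substr(tg, 1, 41))
  plain <- substr(host, 2001, 2101)
  rec <- align_batch(c(chim, plain), idx, mode = "local")
  sr <- find_split_reads(rec, ref, min_clip = 20)
  expect_identical(nrow(sr), 1L)
  expect_identical(sr$side, "left")           # host ends, construct begins
  expect_identical(sr$host_pos, 3060L)        # last host base of the 60M
  expect_identical(sr$cpos, 1L)
  expect_identical(sr$orient, "+")
})

test_that("on the error-free scenario every split-read breakpoint equals a truth boundary", {
  sc <- errorfree_scenario()
  idx <- build_index(sc$reference, k = 21)
  loc <- align_pairs(sc$reads$read1, sc$reads$read2, idx,
                     qname = sc$reads$qname, mode = "local")
  sr <- find_split_reads(loc, sc$reference)
  expect_gt(nrow(sr), 8)
  truth_pos <- c(sc$sites_truth$left, sc$sites_truth$right)
  expect_true(all(sr$host_pos %in% truth_pos))
  # and all four boundaries are recovered
  jp <- find_junction_pairs(align_pairs(sc$reads$read1, sc$reads$read2, idx,
                                        qname = sc$reads$qname, mode = "e2e"),
                            sc$reference)
  bnd <- cluster_boundaries(sr, jp, sc$reference)
  expect_identical(nrow(bnd), 4L)
  expect_setequal(bnd$pos, truth_pos)
})

test_that("boundary clustering merges within the window and applies support thresholds", {
  sr <- isceimap:::split_read_frame()
  for (i in 1:8) sr[nrow(sr) + 1, ] <-
    list(paste0("r", i), "host", "chr1", "left", 5000L, 1L, "+", "start",
         30L, 30L)
  sr[nrow(sr) + 1, ] <- list("stray", "host", "chr1", "left", 5200L, 1L, "+",
                             "start", 30L, 30L)
  bnd <- cluster_boundaries(sr, NULL, NULL, window = 10L, min_support = 3L)
  expect_identical(nrow(bnd), 1L)
  expect_identical(bnd$pos, 5000L)
  expect_identical(bnd$split_support, 8L)
  dropped <- attr(bnd, "dropped")
  expect_identical(nrow(dropped), 1L)
  expect_identical(dropped$pos, 5200L)
  expect_identical(dropped$split_support, 1L)
  # a 1-split boundary is rescued by junction-pair corroboration
  jp <- data.frame(qname = c("p1", "p2"), host_contig = "chr1",
                   host_pos = c(4800L, 4820L), host_end = c(4900L, 4920L),
                   host_strand = "+", tg_contig = "transgene",
                   tg_pos = 1L, tg_strand = "+", tg_is_promoter = FALSE,
                   stringsAsFactors = FALSE)
  bnd2 <- cluster_boundaries(sr[9, ], jp, NULL, min_support = 3L,
                             min_pair_support = 2L)
  expect_identical(nrow(bnd2), 1L)
  expect_identical(bnd2$pair_support, 2L)
})

test_that("boundary pairing yields the two lesioned sites and handles half-sites", {
  rep <- mini_report()
  sites <- rep$sites
  expect_length(sites, 2L)
  sc <- mini_scenario()
  expect_identical(sites[[1]]$left$pos, sc$sites_truth$left[1])
  expect_identical(sites[[1]]$right$pos, sc$sites_truth$right[1])
  expect_identical(sites[[2]]$left$pos, sc$sites_truth$left[2])
  expect_identical(sites[[2]]$right$pos, sc$sites_truth$right[2])
  expect_identical(sites[[1]]$lesion$class, "deletion")
  expect_identical(sites[[1]]$lesion$length, 11L)
  expect_identical(sites[[2]]$lesion$class, "duplication")
  expect_identical(sites[[2]]$lesion$length, 15L)
  expect_identical(site_distance(sites[[1]], sites[[2]]), 108)
  # the duplication case has right < left and still pairs correctly
  expect_lt(sites[[2]]$right$pos, sites[[2]]$left$pos)
  # a lone left boundary gives one half-site and no full site
  lone <- rep$boundaries[rep$boundaries$side == "left", ][1, , drop = FALSE]
  hs <- pair_boundaries_into_sites(lone)
  expect_length(hs, 0L)
  expect_identical(nrow(attr(hs, "half_sites")), 1L)
  # every reported boundary satisfies the evidence rule
  bnd <- rep$boundaries
  expect_true(all(bnd$split_support >= 3 |
                    (bnd$split_support >= 1 & bnd$pair_support >= 2)))
})

test_that("concatemer junctions are typed by construct termini and orientation", {
  set.seed(77)
  host <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 60000, TRUE),
                         collapse = ""))
  cons <- tiny_construct(2000)
  ref <- build_combined_reference(host, cons)
  mk_reads <- function(events) {
    tr <- apply_insertion_events(host, events)
    al <- c(tg = unname(tr$allele[["chr1_tg"]]), wt = unname(host[["chr1"]]))
    simulate_reads(al, sim_params(depth = 15, error_rate = 0, seed = 3))
  }
  idx <- build_index(ref, k = 21)
  aln_of <- function(rd) align_pairs(rd$read1, rd$read2, idx,
                                     qname = rd$qname, mode = "local")
  # head-to-tail trimer: the two internal copy-copy joins are sequence
  # identical, so they collapse to ONE distinct junction record
  tri <- mk_reads(list(insertion_event("chr1", 30000, 30001, cons,
                                       copies = 3, orientations = "+")))
  cj <- find_concatemer_junctions(aln_of(tri), ref)
  ht <- cj[cj$orientation == "head-to-tail", ]
  expect_identical(nrow(ht), 1L)
  expect_gte(ht$support[1], 2L)
  expect_identical(ht$pos_a, 1L)
  expect_identical(ht$pos_b, 2000L)
  # single-copy insertion: no construct-construct junction
  single <- mk_reads(list(insertion_event("chr1", 30000, 30001, cons)))
  expect_identical(nrow(find_concatemer_junctions(aln_of(single), ref)), 0L)
  # head-to-head dimer
  hh <- mk_reads(list(insertion_event("chr1", 30000, 30001, cons, copies = 2,
                                      orientations = c("+", "-"))))
  cjh <- find_concatemer_junctions(aln_of(hh), ref)
  expect_true(any(cjh$orientation == "head-to-head"))
  expect_false(any(cjh$orientation == "head-to-tail"))
})

test_that("allele reconstruction and in-silico PCR recover the simulated truth", {
  sc <- mini_scenario()
  rep <- mini_report()
  host <- sc$reference$contigs[["chr1"]]
  allele <- reconstruct_allele(rep$sites, host, sc$construct,
                               copies_per_site = sc$sites_truth$copies)
  expect_identical(allele, unname(sc$truth$allele[["chr1_tg"]]))
  # empty site list leaves the host unchanged
  expect_identical(reconstruct_allele(list(), host, sc$construct), host)
  # blunt single-copy site: length is host + construct
  b <- isceimap:::boundary_frame()
  b[1, ] <- list("chr1", "left", 5000L, 1L, "+", "start", 5L, 0L, 0L, "")
  r <- isceimap:::boundary_frame()
  r[1, ] <- list("chr1", "right", 5001L, 7622L, "+", "end", 5L, 0L, 0L, "")
  blunt <- isceimap:::make_site(b[1, ], r[1, ])
  expect_identical(nchar(reconstruct_allele(list(blunt), host, sc$construct)),
                   nchar(host) + nchar(sc$construct$sequence))
  # primers across a junction amplify the transgenic allele, not wild type
  B <- sc$locus_base
  fwd <- substr(host, B + 120, B + 144)
  rev <- revcomp_chr(substr(sc$construct$sequence, 200, 224))
  amp_tg <- in_silico_pcr(allele, fwd, rev, max_len = 2000)
  amp_wt <- in_silico_pcr(host, fwd, rev, max_len = 2000)
  expect_identical(nrow(amp_tg), 1L)
  expect_identical(nrow(amp_wt), 0L)
  # expected product: (B+120 .. B+200) host + 224 construct bases
  expect_identical(amp_tg$length, (B + 200L - (B + 120L) + 1L) + 224L)
  # a plain genomic product of known span
  f2 <- substr(host, 1001, 1020); r2 <- revcomp_chr(substr(host, 1481, 1500))
  amp <- in_silico_pcr(host, f2, r2, max_len = 5000)
  expect_identical(amp$length, 500L)
  # no reverse-primer hit -> no product
  expect_identical(nrow(in_silico_pcr(host, f2, strrep("ACGTT", 5))), 0L)
})
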