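test_that("the cleavage model emits the 4-nt 3' overhang from the 18-bp site", {
  m <- cleavage_model()
  expect_identical(nchar(m$recognition_sequence), 18L)
  ov <- cleavage_overhang(m)
  expect_identical(ov$sequence, "ATAA")
  expect_identical(ov$length, 4L)
  # overhang is a substring of the site at the cut offsets (slicing oracle)
  expect_identical(ov$sequence,
                   substr(m$recognition_sequence,
                          min(m$top_cut, m$bottom_cut) + 1L,
                          max(m$top_cut, m$bottom_cut)))
  blunt <- cleavage_model(top_cut = 9, bottom_cut = 9)
  expect_identical(blunt$overhang_kind, "blunt")
  expect_identical(cleavage_overhang(blunt)$length, 0L)
  expect_error(cleavage_model(top_cut = 99), "within")
})

test_that("microhomology scanner finds planted matches and respects min_len", {
  flank <- paste0(strrep("C", 10), "ATAA", strrep("G", 10))
  term <- paste0(strrep("T", 8), "ATAA")
  hits <- scan_microhomology(flank, term, min_len = 3)
  expect_gte(nrow(hits), 1L)
  top <- hits[hits$strand == "+", ][1, ]
  expect_identical(top$seq, "ATAA")
  expect_identical(top$flank_offset, 11L)
  expect_identical(top$terminal_offset, 9L)
  # disjoint alphabets share nothing
  expect_identical(nrow(scan_microhomology(strrep("A", 30), strrep("C", 30),
                                           min_len = 3)), 0L)
  expect_error(scan_microhomology("", "ACGT"), "nonempty")
  expect_error(scan_microhomology("ACGT", "ACGT", min_len = 1), "min_len")
})

test_that("scanner agrees with the brute-force all-substring-pairs oracle", {
  set.seed(123)
  bases <- c("A", "C", "G", "T")
  for (t in 1:100) {
    a <- paste(sample(bases, sample(15:40, 1), TRUE), collapse = "")
    b <- paste(sample(bases, sample(15:40, 1), TRUE), collapse = "")
    got <- scan_microhomology(a, b, min_len = 3)
    got_fwd <- got[got$strand == "+", c("flank_offset", "terminal_offset",
                                        "length")]
    want <- brute_maximal_matches(a, b, 3L)
    if (is.null(want)) {
      expect_identical(nrow(got_fwd), 0L)
    } else {
      names(want) <- c("flank_offset", "terminal_offset", "length")
      o1 <- got_fwd[order(got_fwd$flank_offset, got_fwd$terminal_offset), ]
      o2 <- want[order(want$flank_offset, want$terminal_offset), ]
      rownames(o1) <- rownames(o2) <- NULL
      expect_identical(o1, o2)
    }
    # reverse-complement symmetry: scanning the revcomp flank flips strands
    rcg <- scan_microhomology(revcomp_chr(a), b, min_len = 3)
    expect_identical(sort(rcg$length[rcg$strand == "-"]),
                     sort(got$length[got$strand == "+"]))
    # every hit is verifiable by direct substring extraction
    for (k in seq_len(nrow(got))) {
      h <- got[k, ]
      fl <- if (h$strand == "+") a else revcomp_chr(a)
      off <- if (h$strand == "+") h$flank_offset else
        nchar(a) - (h$flank_offset + h$length - 1L) + 1L
      expect_identical(substr(fl, off, off + h$length - 1L), h$seq)
      expect_identical(substr(b, h$terminal_offset,
                              h$terminal_offset + h$length - 1L), h$seq)
    }
  }
})

test_that("flank-flank homology scan handles identical and disjoint flanks", {
  f <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
  hh <- scan_flank_homology(f, f, min_len = 4)
  expect_identical(max(hh$length), 25L)
  expect_identical(nrow(scan_flank_homology(strrep("A", 20), strrep("C", 20),
                                            min_len = 4)), 0L)
})

test_that("the MMEJ report flags the planted overhang, recognition and duplication signatures", {
  rep <- mini_report()
  mh <- rep$microhomology
  b <- mh$boundaries
  expect_identical(nrow(b), 4L)
  # the overhang (ATAA) sits immediately downstream of the downstream site's
  # right boundary and matches the construct's right terminus
  dn <- b[b$site == 2 & b$side == "right", ]
  expect_true(dn$overhang_match)
  expect_identical(dn$overhang_len, 4L)
  # recognition-site homology upstream of the upstream site's left boundary
  up <- b[b$site == 1 & b$side == "left", ]
  expect_gte(up$recognition_len, 5L)
  # tandem-duplication signature: site 2 duplication + inter-site flank homology
  expect_identical(nrow(mh$site_pairs), 1L)
  expect_true(mh$site_pairs$duplication_signature)
  expect_gte(mh$site_pairs$flank_homology_len, 8L)
  # empty site list -> empty report
  mh0 <- mmej_report(list(), "ACGTACGT", mini_scenario()$construct)
  expect_identical(nrow(mh0$boundaries), 0L)
  expect_identical(nrow(mh0$site_pairs), 0L)
})
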