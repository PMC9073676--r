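# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

# a small but complete study fixture (same locus geometry as the full-size
# scenario, on a 150 kb toy chromosome)
mini_scenario <- function() {
  if (is.null(.fix$sc))
    .fix$sc <- study_scenario(seed = 1, host_length = 150000, depth = 20)
  .fix$sc
}

mini_alignments <- function() {
  if (is.null(.fix$aln)) {
    sc <- mini_scenario()
    idx <- build_index(sc$reference, k = 21)
    .fix$aln <- list(
      e2e = align_pairs(sc$reads$read1, sc$reads$read2, idx,
                        qname = sc$reads$qname, mode = "e2e"),
      local = align_pairs(sc$reads$read1, sc$reads$read2, idx,
                          qname = sc$reads$qname, mode = "local"))
  }
  .fix$aln
}

mini_report <- function() {
  if (is.null(.fix$rep)) {
    sc <- mini_scenario()
    .fix$rep <- run_pipeline(sc$reference, sc$reads, sc$features,
                             sc$endogenous, alignments = mini_alignments())
  }
  .fix$rep
}

# error-free variant: split-read breakpoints must be exact
errorfree_scenario <- function() {
  if (is.null(.fix$sc0))
    .fix$sc0 <- study_scenario(seed = 2, host_length = 150000, depth = 20,
                               error_rate = 0)
  .fix$sc0
}

# wild-type negative control
wt_report <- function() {
  if (is.null(.fix$wt)) {
    sc <- wildtype_scenario(seed = 5, host_length = 120000, depth = 20)
    .fix$wt <- run_pipeline(sc$reference, sc$reads, sc$features,
                            sc$endogenous)
  }
  .fix$wt
}

# tiny random assembly for alignment unit tests
tiny_reference <- function(seed = 11, host_len = 6000, construct_len = 800) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  host <- setNames(paste(sample(bases, host_len, TRUE), collapse = ""), "chr1")
  cons <- tiny_construct(construct_len)
  build_combined_reference(host, cons)
}

tiny_construct <- function(len = 800) {
  transgene_construct(paste(sample(c("A", "C", "G", "T"), len, TRUE),
                            collapse = ""),
                      data.frame(label = character(0), start = integer(0),
                                 end = integer(0)))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# independent quadratic oracle: all maximal common substrings >= min_len
brute_maximal_matches <- function(a, b, min_len) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  hits <- list()
  for (i in seq_along(av)) for (j in seq_along(bv)) {
    # must not be extendable left
    if (i > 1 && j > 1 && av[i - 1] == bv[j - 1]) next
    L <- 0L
    while (i + L <= length(av) && j + L <= length(bv) &&
           av[i + L] == bv[j + L]) L <- L + 1L
    if (L >= min_len)
      hits[[length(hits) + 1L]] <- data.frame(a_offset = i, b_offset = j,
                                              length = L)
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# Smith-Waterman / glocal score oracle via Biostrings
oracle_score <- function(read, subject_seq, type = c("local", "global-local")) {
  type <- match.arg(type)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = TRUE)
  s <- Biostrings::DNAString(subject_seq)
  max(Biostrings::pairwiseAlignment(read, s, type = type,
                                    substitutionMatrix = mat,
                                    gapOpening = 6, gapExtension = 1,
                                    scoreOnly = TRUE),
      Biostrings::pairwiseAlignment(revcomp_chr(read), s, type = type,
                                    substitutionMatrix = mat,
                                    gapOpening = 6, gapExtension = 1,
                                    scoreOnly = TRUE))
}
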