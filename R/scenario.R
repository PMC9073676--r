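# One-call study fixture: a toy chromosome carrying the full geometry of an
# I-SceI transgenic line — two adjacent concatemeric insertions (target-site
# deletion at one, target-site duplication at the other, 108 bp of host
# sequence between the closest boundaries), an endogenous copy of the
# cassette promoter elsewhere on the chromosome, and junction microhomology
# to the meganuclease recognition site and its cleavage overhang — plus
# paired-end reads from the hemizygous diploid at ~20x.

# Remnants of the 18-bp I-SceI recognition site left at the construct ends by
# cleavage: the downstream fragment (left end of the cassette) begins with
# the overhang plus the right half of the site; the upstream fragment (right
# end) terminates in the left half of the site ending in the overhang.
ISCEI_LEFT_REMNANT <- "ATAACAGGGTAAT"
ISCEI_RIGHT_REMNANT <- "TAGGGATAA"

#' Build the study-mimicking transgene construct fixture
#'
#' ~7.6 kb cassette: meganuclease-site remnant, ~3.9 kb promoter, ~0.7 kb
#' eGFP CDS, ~3 kb vector backbone, remnant. Internal sequences are drawn
#' from the current RNG stream (call [set.seed()] first for reproducibility).
#'
#' @param promoter_len,egfp_len,vector_len feature lengths, bp.
#' @param gc GC fraction of the random feature sequences.
#' @return A [transgene_construct()].
#' @export
make_study_construct <- function(promoter_len = 3900L, egfp_len = 700L,
                                 vector_len = 3000L, gc = 0.45) {
  promoter <- random_dna(promoter_len, gc)
  egfp <- random_dna(egfp_len, gc)
  vector <- random_dna(vector_len, gc)
  lr <- nchar(ISCEI_LEFT_REMNANT); rr <- nchar(ISCEI_RIGHT_REMNANT)
  seqs <- paste0(ISCEI_LEFT_REMNANT, promoter, egfp, vector,
                 ISCEI_RIGHT_REMNANT)
  s1 <- lr + 1L
  features <- data.frame(
    label = c("isce1_site_left", "promoter", "egfp", "vector",
              "isce1_site_right"),
    start = c(1L, s1, s1 + promoter_len, s1 + promoter_len + egfp_len,
              s1 + promoter_len + egfp_len + vector_len),
    end = c(lr, s1 + promoter_len - 1L, s1 + promoter_len + egfp_len - 1L,
            s1 + promoter_len + egfp_len + vector_len - 1L,
            lr + promoter_len + egfp_len + vector_len + rr),
    stringsAsFactors = FALSE)
  transgene_construct(seqs, features)
}

#' The reference study-geometry simulation scenario
#'
#' Builds the complete study fixture and simulates reads from the hemizygous
#' diploid. Locus geometry (relative to a locus base position `B`):
#' site 1 boundaries `B+200` / `B+212` (11-bp target-site deletion of
#' `B+201..B+211`), site 2 boundaries `B+334` / `B+320` (15-bp target-site
#' duplication of `B+320..B+334`), closest-boundary distance 108 bp. Six
#' construct copies are split across the two sites (default 3 + 3,
#' head-to-tail). Microhomology is planted at the junctions: a
#' recognition-site-homologous motif upstream of site 1, the 4-nt cleavage
#' overhang (ATAA) as genomic sequence immediately downstream of site 2, and
#' a shared 8-bp motif upstream of both sites (the realignment homology of a
#' tandem duplication). The endogenous promoter is planted far from the
#' locus so the promoter copy-number arithmetic (2 endogenous + inserted
#' copies on one haplotype) holds.
#'
#' @param seed RNG seed; the whole fixture is reproducible from it.
#' @param host_length toy chromosome length (>= 100 kb; the default 1 Mb
#'   mirrors the desk-scale study conditions, smaller values give quick
#'   fixtures with identical locus geometry).
#' @param depth sequencing depth as pile-up coverage on the reference (both
#'   haplotypes combined, the scale coverage plots use): a hemizygous diploid
#'   at 20x shows a 20x background, the shared promoter at 80x
#'   (2 endogenous + 6 inserted copies, each at 10x), the reporter at 60x.
#' @param copies construct copies at the two sites.
#' @param error_rate per-base substitution error rate.
#' @param read_length,fragment_mean,fragment_sd read/fragment geometry.
#' @return List of class `study_scenario`: `reference` (combined reference
#'   with homology annotation), `reads`, `truth` (allele + segment map),
#'   `construct`, `features` (intervals used for copy number), `sites_truth`,
#'   `expected_copies`, `params`.
#' @export
study_scenario <- function(seed = 1L, host_length = 1e6, depth = 20,
                           copies = c(3L, 3L), error_rate = 0.001,
                           read_length = 101L, fragment_mean = 350,
                           fragment_sd = 35) {
  if (host_length < 1e5) stop("host_length must be >= 100 kb")
  set.seed(seed)
  construct <- make_study_construct()
  prom <- construct_feature(construct, "promoter")
  prom_seq <- substr(construct$sequence, prom$start, prom$end)
  prom_host_start <- as.integer(host_length * 0.5) + 1L
  host <- simulate_host_genome(host_length, gc_fraction = 0.4,
                               planted_promoter = list(sequence = prom_seq,
                                                       start = prom_host_start),
                               name = "chr1")
  B <- as.integer(host_length * 0.7)
  plant <- function(seqs, at, what) {
    substr(seqs, at, at + nchar(what) - 1L) <- what
    seqs
  }
  hseq <- host[["chr1"]]
  hseq <- plant(hseq, B + 180L, "GTACCGAT")          # shared upstream motif, site 1
  hseq <- plant(hseq, B + 190L, "GGGTAAT")           # recognition-site homology
  hseq <- plant(hseq, B + 201L, "CCTGACTGGTC")       # the 11 bp lost at site 1
  hseq <- plant(hseq, B + 306L, "GTACCGAT")          # shared upstream motif, site 2
  hseq <- plant(hseq, B + 314L, "CTTCAC")
  hseq <- plant(hseq, B + 320L, "ATAA")              # overhang homology downstream of site 2
  hseq <- plant(hseq, B + 335L, "C")
  host[["chr1"]] <- hseq
  events <- list(
    insertion_event("chr1", B + 200L, B + 212L, construct,
                    copies = copies[1], orientations = "+"),
    insertion_event("chr1", B + 334L, B + 320L, construct,
                    copies = copies[2], orientations = "+"))
  truth <- apply_insertion_events(host, events)
  alleles <- c(truth$allele["chr1_tg"], wt = unname(host["chr1"]))
  names(alleles) <- c("tg", "wt")
  # segment map under the read-simulation allele names (tg + wild-type
  # identity), so truth-derived SAM can be emitted for any read
  truth$segments$allele <- "tg"
  truth$segments <- rbind(
    truth$segments,
    data.frame(allele = "wt", a_start = 1L, a_end = nchar(host[["chr1"]]),
               src = "chr1", s_start = 1L, s_end = nchar(host[["chr1"]]),
               strand = "+", stringsAsFactors = FALSE))
  # `depth` is the pile-up coverage on the haploid reference (the convention
  # coverage tracks and the copy-number arithmetic use): both haplotypes map
  # onto one reference copy, so each allele is sequenced at depth/2
  params <- sim_params(read_length = read_length,
                       fragment_mean = fragment_mean,
                       fragment_sd = fragment_sd, depth = depth / 2,
                       error_rate = error_rate, seed = NULL)
  reads <- simulate_reads(alleles, params)
  homology <- data.frame(
    contig = c("chr1", "transgene"),
    start = c(prom_host_start, prom$start),
    end = c(prom_host_start + nchar(prom_seq) - 1L, prom$end),
    stringsAsFactors = FALSE)
  reference <- build_combined_reference(host, construct,
                                        transgene_name = "transgene",
                                        homology = homology)
  egfp <- construct_feature(construct, "egfp")
  vec <- construct_feature(construct, "vector")
  features <- list(
    promoter = genomic_interval("chr1", prom_host_start,
                                prom_host_start + nchar(prom_seq) - 1L),
    egfp = genomic_interval("transgene", egfp$start, egfp$end),
    vector = genomic_interval("transgene", vec$start, vec$end))
  clen <- nchar(construct$sequence)
  sites_truth <- data.frame(
    site = 1:2, contig = "chr1",
    left = c(B + 200L, B + 334L), right = c(B + 212L, B + 320L),
    lesion = c("deletion", "duplication"), lesion_len = c(11L, 15L),
    copies = copies, stringsAsFactors = FALSE)
  structure(list(reference = reference, reads = reads, truth = truth,
                 construct = construct, features = features,
                 sites_truth = sites_truth,
                 expected_copies = c(promoter = sum(copies), egfp = sum(copies),
                                     vector = sum(copies)),
                 endogenous = c(promoter = 2L, egfp = 0L, vector = 0L),
                 locus_base = B, params = params, seed = seed),
            class = "study_scenario")
}

#' A wild-type (no-insertion) negative-control scenario
#'
#' Same host and construct fixture, but both haplotypes are wild type. The
#' pipeline should call zero integration sites and zero transgene copies.
#'
#' @inheritParams study_scenario
#' @return List of class `study_scenario` (with empty `sites_truth`).
#' @export
wildtype_scenario <- function(seed = 1L, host_length = 1e6, depth = 20,
                              error_rate = 0.001) {
  sc <- study_scenario(seed = seed, host_length = host_length, depth = depth,
                       error_rate = error_rate)
  set.seed(seed + 104729L)
  host <- setNames(sc$reference$contigs[["chr1"]], "chr1")
  alleles <- c(a = unname(host), b = unname(host))
  reads <- simulate_reads(alleles, sc$params)
  sc$reads <- reads
  sc$sites_truth <- sc$sites_truth[0, , drop = FALSE]
  sc$expected_copies[] <- 0L
  sc
}
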