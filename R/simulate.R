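# Synthetic transgenic-genome and paired-end read simulator.
#
# The generator models a hemizygous transgenic animal: one haplotype carries
# one or more concatemeric insertions of the construct (with target-site
# deletion/duplication lesions at the boundaries), the sister haplotype is
# wild type. Reads are drawn as short-insert paired-end fragments so the
# downstream junction-pair / split-read / coverage machinery sees the same
# evidence classes as real whole-genome sequencing.

#' Read-simulation parameters
#'
#' Defaults mirror a typical short-insert Illumina whole-genome run:
#' 2x101 bp pairs from ~350 bp fragments at 19x diploid coverage with a
#' substitution-only error model.
#'
#' @param read_length read length in bp.
#' @param fragment_mean,fragment_sd fragment (insert) length distribution, bp.
#' @param depth target fold-coverage of the diploid genome.
#' @param error_rate per-base substitution probability.
#' @param seed optional RNG seed; when set, output is byte-reproducible.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(read_length = 101L, fragment_mean = 350, fragment_sd = 35,
                       depth = 19, error_rate = 0.001, seed = NULL) {
  if (depth <= 0 || read_length <= 0 || fragment_mean <= 0)
    stop("depth, read_length and fragment_mean must be positive")
  if (read_length > fragment_mean)
    stop("read_length must not exceed fragment_mean")
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 depth = depth, error_rate = error_rate, seed = seed),
            class = "sim_params")
}

#' Simulate a host contig
#'
#' I.i.d. random sequence at a requested GC content, optionally with a given
#' sequence (e.g. the construct's promoter, to emulate an endogenous locus
#' shared with the cassette) planted at a fixed interval.
#'
#' @param length contig length (>= 10 kb recommended for meaningful tests).
#' @param gc_fraction target GC fraction.
#' @param planted_promoter optional `list(sequence=, start=)` to embed.
#' @param seed optional RNG seed.
#' @param name contig name.
#' @return Named character vector of length 1 (a one-contig assembly).
#' @export
simulate_host_genome <- function(length, gc_fraction = 0.4,
                                 planted_promoter = NULL, seed = NULL,
                                 name = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  seq <- random_dna(length, gc_fraction)
  if (!is.null(planted_promoter)) {
    ps <- toupper(planted_promoter$sequence)
    st <- as.integer(planted_promoter$start)
    if (st < 1L || st + nchar(ps) - 1L > length)
      stop("planted interval exceeds contig bounds")
    substr(seq, st, st + nchar(ps) - 1L) <- ps
  }
  setNames(seq, name)
}

#' Describe one transgene insertion event
#'
#' Boundary convention: `left` is the last host base before the inserted DNA,
#' `right` the first host base after it. The lesion class follows from the
#' pair: `right == left + 1` is a blunt join, `right > left + 1` deletes host
#' bases `left+1 .. right-1`, and `right <= left` tandem-duplicates host bases
#' `right .. left` (the duplicated stretch flanks the payload on both sides).
#'
#' @param contig host contig name.
#' @param left,right 1-based boundary positions (see above).
#' @param construct a [transgene_construct()].
#' @param copies number of construct copies in the inserted concatemer.
#' @param orientations `+`/`-` per copy (recycled); head-to-tail is all `+`.
#' @return List of class `insertion_event` with the payload sequence attached.
#' @export
insertion_event <- function(contig, left, right, construct, copies = 1L,
                            orientations = "+") {
  left <- as.integer(left); right <- as.integer(right)
  copies <- as.integer(copies)
  if (copies < 1L) stop("copies must be >= 1")
  orientations <- rep_len(orientations, copies)
  if (!all(orientations %in% c("+", "-"))) stop("orientations must be +/-")
  clen <- nchar(construct$sequence)
  parts <- vapply(orientations, function(o) {
    if (o == "+") construct$sequence else rc_seq(construct$sequence)
  }, character(1))
  payload <- paste(parts, collapse = "")
  payload_segments <- data.frame(
    p_start = (seq_len(copies) - 1L) * clen + 1L,
    p_end = seq_len(copies) * clen,
    strand = orientations, stringsAsFactors = FALSE)
  structure(list(contig = contig, left = left, right = right,
                 payload = payload, copies = copies,
                 orientations = orientations,
                 payload_segments = payload_segments),
            class = "insertion_event")
}

lesion_of_event <- function(event) classify_target_site(event$left, event$right)

#' Apply insertion events to one haplotype
#'
#' Splices each event's payload into the host sequence honouring the
#' boundary convention of [insertion_event()], producing the transgenic
#' allele plus a segment map (allele interval -> source contig interval)
#' used for truth alignments.
#'
#' @param assembly named character vector of host contigs.
#' @param events list of [insertion_event()]s (non-overlapping).
#' @param transgene_name source name recorded for payload segments.
#' @param allele_suffix appended to contig names for the transgenic allele.
#' @return List of class `sim_truth`: `allele` (named character vector),
#'   `segments` (data.frame), `events`.
#' @export
apply_insertion_events <- function(assembly, events,
                                   transgene_name = "transgene",
                                   allele_suffix = "_tg") {
  segs <- list(); out <- assembly
  names(out) <- paste0(names(assembly), allele_suffix)
  by_contig <- split(events, vapply(events, `[[`, "", "contig"))
  for (ctg in names(by_contig)) {
    if (!ctg %in% names(assembly)) stop("event contig '", ctg, "' not in assembly")
    host <- assembly[[ctg]]
    hlen <- nchar(host)
    evs <- by_contig[[ctg]]
    ord <- order(vapply(evs, function(e) min(e$left, e$right), 0))
    evs <- evs[ord]
    aname <- paste0(ctg, allele_suffix)
    cur <- 1L; apos <- 0L; parts <- character(0)
    for (e in evs) {
      if (e$left < 0L || e$right < 1L || e$left > hlen || e$right > hlen + 1L)
        stop("event boundaries outside contig")
      if (min(e$left, e$right) < cur - 1L)
        stop("overlapping insertion events")
      if (e$left >= cur) {
        seg <- substr(host, cur, e$left)
        parts <- c(parts, seg)
        segs[[length(segs) + 1L]] <- data.frame(
          allele = aname, a_start = apos + 1L, a_end = apos + nchar(seg),
          src = ctg, s_start = cur, s_end = e$left, strand = "+",
          stringsAsFactors = FALSE)
        apos <- apos + nchar(seg)
      }
      ps <- e$payload_segments
      for (ci in seq_len(nrow(ps))) {
        cseg <- substr(e$payload, ps$p_start[ci], ps$p_end[ci])
        parts <- c(parts, cseg)
        segs[[length(segs) + 1L]] <- data.frame(
          allele = aname, a_start = apos + 1L, a_end = apos + nchar(cseg),
          src = transgene_name, s_start = 1L, s_end = nchar(cseg),
          strand = ps$strand[ci], stringsAsFactors = FALSE)
        apos <- apos + nchar(cseg)
      }
      cur <- e$right
    }
    seg <- substr(host, cur, hlen)
    parts <- c(parts, seg)
    segs[[length(segs) + 1L]] <- data.frame(
      allele = aname, a_start = apos + 1L, a_end = apos + nchar(seg),
      src = ctg, s_start = cur, s_end = hlen, strand = "+",
      stringsAsFactors = FALSE)
    out[[aname]] <- paste(parts, collapse = "")
  }
  # wild-type identity segments for untouched contigs keep truth SAM simple
  for (ctg in setdiff(names(assembly), names(by_contig))) {
    aname <- paste0(ctg, allele_suffix)
    segs[[length(segs) + 1L]] <- data.frame(
      allele = aname, a_start = 1L, a_end = nchar(assembly[[ctg]]),
      src = ctg, s_start = 1L, s_end = nchar(assembly[[ctg]]), strand = "+",
      stringsAsFactors = FALSE)
  }
  structure(list(allele = out, segments = do.call(rbind, segs),
                 events = events),
            class = "sim_truth")
}

apply_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n <- nchar(reads)
  nerr <- rbinom(length(reads), n, rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(n[i], nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  reads
}

#' Simulate paired-end reads from a set of alleles
#'
#' Fragment starts are uniform over each allele; fragment lengths are
#' Normal(`fragment_mean`, `fragment_sd`) truncated below at the read length.
#' Read 1 is the fragment prefix, read 2 the reverse complement of the
#' fragment suffix. The fragment count is chosen so total read bases divided
#' by the summed allele length equals `depth`.
#'
#' @param alleles named character vector (typically a diploid pair:
#'   transgenic and wild-type haplotypes).
#' @param params a [sim_params()].
#' @return List of class `sim_reads`: `qname`, `read1`, `read2`, `truth`
#'   (data.frame of per-fragment origin: allele, start, length).
#' @export
simulate_reads <- function(alleles, params = sim_params()) {
  if (length(alleles) < 1L || any(nchar(alleles) < params$read_length))
    stop("alleles must be nonempty and at least one read long")
  if (!is.null(params$seed)) set.seed(params$seed)
  rl <- params$read_length
  total <- sum(nchar(alleles))
  nfrag_total <- round(params$depth * total / (2 * rl))
  n_per <- round(nfrag_total * nchar(alleles) / total)
  qname <- read1 <- read2 <- character(0)
  truth <- list()
  for (ai in seq_along(alleles)) {
    n <- n_per[ai]
    if (n == 0L) next
    alen <- nchar(alleles[[ai]])
    flen <- pmin(pmax(rl, round(rnorm(n, params$fragment_mean,
                                      params$fragment_sd))), alen)
    fstart <- 1L + floor(runif(n) * (alen - flen + 1))
    r1 <- substring(alleles[[ai]], fstart, fstart + rl - 1L)
    r2 <- rc_seq(substring(alleles[[ai]], fstart + flen - rl, fstart + flen - 1L))
    r1 <- apply_errors(r1, params$error_rate)
    r2 <- apply_errors(r2, params$error_rate)
    qn <- sprintf("frag_%s_%07d", names(alleles)[ai], seq_len(n))
    qname <- c(qname, qn); read1 <- c(read1, r1); read2 <- c(read2, r2)
    truth[[ai]] <- data.frame(qname = qn, allele = names(alleles)[ai],
                              frag_start = as.integer(fstart),
                              frag_len = as.integer(flen),
                              stringsAsFactors = FALSE)
  }
  structure(list(qname = qname, read1 = read1, read2 = read2,
                 truth = do.call(rbind, truth), params = params),
            class = "sim_reads")
}

#' Write simulated reads as a FASTQ pair
#'
#' @param reads a [simulate_reads()] result.
#' @param path1,path2 output paths for mate 1 / mate 2.
#' @param quality_char fixed Phred+33 quality character.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq <- function(reads, path1, path2, quality_char = "I") {
  emit <- function(seqs, qn, path) {
    qual <- strrep(quality_char, nchar(seqs))
    writeLines(paste0("@", qn, "\n", seqs, "\n+\n", qual), path)
  }
  emit(reads$read1, paste0(reads$qname, "/1"), path1)
  emit(reads$read2, paste0(reads$qname, "/2"), path2)
  invisible(c(path1, path2))
}

#' Read a FASTQ pair back into a `sim_reads`-like list
#'
#' @param path1,path2 FASTQ paths (mate 1 / mate 2, in sync).
#' @return List with `qname`, `read1`, `read2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  parse1 <- function(path) {
    x <- readLines(path)
    if (length(x) %% 4L != 0L) stop("truncated FASTQ: ", path)
    list(qname = sub("/[12]$", "", sub("^@", "", x[seq(1, length(x), 4)])),
         seq = toupper(x[seq(2, length(x), 4)]))
  }
  a <- parse1(path1); b <- parse1(path2)
  if (!identical(a$qname, b$qname)) stop("FASTQ mates out of sync")
  list(qname = a$qname, read1 = a$seq, read2 = b$seq)
}
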