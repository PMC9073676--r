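# Minimal SAM text interop. Only the fields the downstream modules consume
# are round-tripped: the 11 mandatory columns plus AS (alignment score) and
# XS (second-best score, from which the unique flag is reconstructed). This
# lets an externally produced SAM stand in for the built-in aligner, and
# lets truth-derived SAM drive the junction/coverage modules in tests.

FLAG_PAIRED <- 1L; FLAG_PROPER <- 2L; FLAG_UNMAPPED <- 4L
FLAG_MATE_UNMAPPED <- 8L; FLAG_REVERSE <- 16L; FLAG_MATE_REVERSE <- 32L
FLAG_READ1 <- 64L; FLAG_READ2 <- 128L

#' Write alignment records as SAM
#'
#' @param records alignment-record data.frame (see [align_pairs()]).
#' @param reference a `combined_reference` (for `@SQ` header lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference$contigs),
                   nchar(reference$contigs)))
  paired <- !is.na(records$read1)
  flag <- ifelse(paired, FLAG_PAIRED, 0L) +
    ifelse(paired & !is.na(records$proper) & records$proper, FLAG_PROPER, 0L) +
    ifelse(!records$mapped, FLAG_UNMAPPED, 0L) +
    ifelse(paired & is.na(records$mate_contig), FLAG_MATE_UNMAPPED, 0L) +
    ifelse(records$mapped & records$strand == "-", FLAG_REVERSE, 0L) +
    ifelse(paired & !is.na(records$mate_strand) & records$mate_strand == "-",
           FLAG_MATE_REVERSE, 0L) +
    ifelse(paired & records$read1, FLAG_READ1, 0L) +
    ifelse(paired & !records$read1, FLAG_READ2, 0L)
  rname <- ifelse(records$mapped, records$contig, "*")
  pos <- ifelse(records$mapped, records$pos, 0L)
  mapq <- ifelse(records$mapped & !is.na(records$unique) & records$unique,
                 60L, 0L)
  cig <- ifelse(records$mapped, records$cigar, "*")
  rnext <- ifelse(is.na(records$mate_contig), "*",
                  ifelse(!is.na(records$contig) &
                           records$mate_contig == records$contig, "=",
                         records$mate_contig))
  pnext <- ifelse(is.na(records$mate_pos), 0L, records$mate_pos)
  seqf <- ifelse(is.na(records$seq), "*", records$seq)
  tags <- ifelse(records$mapped, sprintf("AS:i:%d", records$score), "")
  tags <- ifelse(records$mapped & !is.na(records$second),
                 sprintf("%s\tXS:i:%d", tags, records$second), tags)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*", records$qname,
                  flag, rname, pos, mapq, cig, rnext, pnext, seqf)
  body <- ifelse(nzchar(tags), paste0(body, "\t", tags), body)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Accepts SAM produced by [write_sam()], [emit_truth_sam()] or an external
#' aligner; only M/S/I/D CIGAR operations are supported. The unique flag is
#' reconstructed from AS/XS when present, else from MAPQ > 0.
#'
#' @param path SAM path.
#' @param uniq_margin AS-vs-XS margin used to reconstruct uniqueness.
#' @return Alignment-record data.frame.
#' @export
read_sam <- function(path, uniq_margin = 2L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(empty_records(0L))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("malformed SAM record (fewer than 11 fields)")
  getf <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(getf(2))
  rec <- empty_records(length(lines))
  rec$qname <- getf(1)
  paired <- bitwAnd(flag, FLAG_PAIRED) > 0L
  rec$read1 <- ifelse(paired, bitwAnd(flag, FLAG_READ1) > 0L, NA)
  rec$mapped <- bitwAnd(flag, FLAG_UNMAPPED) == 0L
  rec$contig <- ifelse(rec$mapped, getf(3), NA_character_)
  rec$pos <- ifelse(rec$mapped, as.integer(getf(4)), NA_integer_)
  rec$strand <- ifelse(rec$mapped,
                       ifelse(bitwAnd(flag, FLAG_REVERSE) > 0L, "-", "+"),
                       NA_character_)
  cig <- getf(6)
  if (any(rec$mapped & grepl("[^0-9MSID]", cig)))
    stop("unsupported CIGAR operation (only M/S/I/D handled)")
  rec$cigar <- ifelse(rec$mapped, cig, NA_character_)
  rnext <- getf(7); pnext <- as.integer(getf(8))
  rec$mate_contig <- ifelse(rnext == "*", NA_character_,
                            ifelse(rnext == "=", rec$contig, rnext))
  rec$mate_pos <- ifelse(rnext == "*", NA_integer_, pnext)
  rec$mate_strand <- ifelse(paired & bitwAnd(flag, FLAG_MATE_UNMAPPED) == 0L,
                            ifelse(bitwAnd(flag, FLAG_MATE_REVERSE) > 0L,
                                   "-", "+"), NA_character_)
  sq <- getf(10)
  rec$seq <- ifelse(sq == "*", NA_character_, toupper(sq))
  rec$proper <- ifelse(paired, bitwAnd(flag, FLAG_PROPER) > 0L, NA)
  tagmat <- vapply(f, function(x) {
    tg <- x[-(1:11)]
    a <- tg[startsWith(tg, "AS:i:")]
    s <- tg[startsWith(tg, "XS:i:")]
    c(if (length(a)) sub("AS:i:", "", a[1]) else NA_character_,
      if (length(s)) sub("XS:i:", "", s[1]) else NA_character_)
  }, character(2))
  rec$score <- as.integer(tagmat[1, ])
  rec$second <- as.integer(tagmat[2, ])
  mapq <- as.integer(getf(5))
  rec$unique <- ifelse(rec$mapped,
                       ifelse(!is.na(rec$score),
                              is.na(rec$second) |
                                rec$score >= rec$second + uniq_margin,
                              mapq > 0L),
                       NA)
  rec
}

#' Emit the truth alignment of simulated reads as SAM records
#'
#' Writes each simulated read with the placement it would receive from a
#' perfect local aligner against the combined reference: reads wholly inside
#' one source segment map contiguously; junction-spanning reads are anchored
#' on the segment with the largest overlap and soft-clipped at the true
#' breakpoint. Reads falling entirely within a promoter-homology region are
#' flagged non-unique and (for construct-origin reads) placed on the host
#' copy, mirroring a lexicographic equal-best tie-break.
#'
#' @param reads a [simulate_reads()] result.
#' @param truth the [apply_insertion_events()] truth used to build the alleles
#'   (its `segments` table maps allele coordinates to reference coordinates).
#' @param reference the `combined_reference` the reads are to be placed on.
#' @param path optional SAM output path.
#' @return Alignment-record data.frame (invisibly if `path` given).
#' @export
emit_truth_sam <- function(reads, truth, reference, path = NULL) {
  segs <- truth$segments
  tr <- reads$truth
  rl <- reads$params$read_length
  n <- nrow(tr)
  rec <- empty_records(2L * n)
  hom <- reference$homology
  if (is.null(hom))
    hom <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  hom_tg <- hom[hom$contig == reference$transgene, , drop = FALSE]
  hom_host <- hom[hom$contig != reference$transgene, , drop = FALSE]
  frag_lim <- reads$params$fragment_mean + 4 * reads$params$fragment_sd
  place <- function(allele, a_start, a_end, read_fwd) {
    ss <- segs[segs$allele == allele & segs$a_start <= a_end &
                 segs$a_end >= a_start, , drop = FALSE]
    if (nrow(ss) == 0L) return(NULL)
    ov <- pmin(ss$a_end, a_end) - pmax(ss$a_start, a_start) + 1L
    s <- ss[which.max(ov), ]
    o_start <- max(s$a_start, a_start); o_end <- min(s$a_end, a_end)
    clip_l <- o_start - a_start; clip_r <- a_end - o_end
    if (s$strand == "+") {
      rpos <- s$s_start + (o_start - s$a_start)
      strand <- if (read_fwd) "+" else "-"
      cl <- clip_l; cr <- clip_r
    } else {
      rpos <- s$s_start + (s$a_end - o_end)
      strand <- if (read_fwd) "-" else "+"
      cl <- clip_r; cr <- clip_l
    }
    mlen <- o_end - o_start + 1L
    cigar <- paste0(if (cl > 0L) paste0(cl, "S") else "", mlen, "M",
                    if (cr > 0L) paste0(cr, "S") else "")
    list(contig = s$src, pos = rpos, strand = strand, cigar = cigar,
         score = mlen, mlen = mlen)
  }
  in_region <- function(region, pos, end) {
    nrow(region) > 0L && any(pos >= region$start & end <= region$end)
  }
  for (i in seq_len(n)) {
    for (mate in 1:2) {
      a_start <- if (mate == 1L) tr$frag_start[i] else
        tr$frag_start[i] + tr$frag_len[i] - rl
      a_end <- a_start + rl - 1L
      p <- place(tr$allele[i], a_start, a_end, mate == 1L)
      j <- 2L * (i - 1L) + mate
      rec$qname[j] <- tr$qname[i]; rec$read1[j] <- mate == 1L
      if (is.null(p)) next
      uniq <- TRUE
      endp <- p$pos + p$mlen - 1L
      if (p$contig == reference$transgene &&
          in_region(hom_tg, p$pos, endp) && nrow(hom_host) > 0L) {
        # equal-best between construct copy and host copy: host wins the
        # lexicographic tie-break
        p$contig <- hom_host$contig[1]
        p$pos <- hom_host$start[1] + (p$pos - hom_tg$start[1])
        uniq <- FALSE
      } else if (p$contig != reference$transgene &&
                 in_region(hom_host[hom_host$contig == p$contig, , drop = FALSE],
                           p$pos, endp)) {
        uniq <- FALSE
      }
      rec$mapped[j] <- TRUE
      rec$contig[j] <- p$contig; rec$pos[j] <- p$pos
      rec$strand[j] <- p$strand; rec$cigar[j] <- p$cigar
      rec$score[j] <- p$score
      rec$second[j] <- if (uniq) NA_integer_ else p$score
      rec$unique[j] <- uniq
      sq <- if (mate == 1L) reads$read1[i] else reads$read2[i]
      rec$seq[j] <- if (p$strand == "-") rc_seq(sq) else sq
    }
    a <- 2L * i - 1L; b <- 2L * i
    rec$mate_contig[a] <- rec$contig[b]; rec$mate_pos[a] <- rec$pos[b]
    rec$mate_strand[a] <- rec$strand[b]
    rec$mate_contig[b] <- rec$contig[a]; rec$mate_pos[b] <- rec$pos[a]
    rec$mate_strand[b] <- rec$strand[a]
    prop <- !is.na(rec$contig[a]) && !is.na(rec$contig[b]) &&
      rec$contig[a] == rec$contig[b] && rec$strand[a] != rec$strand[b]
    if (prop) {
      plus <- if (rec$strand[a] == "+") a else b
      minus <- if (plus == a) b else a
      fr <- (rec$pos[minus] + rl - 1L) - rec$pos[plus] + 1L
      prop <- fr > 0 && fr <= frag_lim
    }
    rec$proper[a] <- prop; rec$proper[b] <- prop
  }
  if (!is.null(path)) {
    write_sam(rec, reference, path)
    return(invisible(rec))
  }
  rec
}
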