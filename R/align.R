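# Desk-scale paired-end aligner: exact k-mer seeding plus affine-gap DP
# extension (compiled in src/aligner.cpp), run in the two modes the analysis
# needs — end-to-end (whole read must align; junction-spanning reads fail and
# surface as discordant pairs) and local (read ends may be soft-clipped;
# junction-spanning reads become split reads).

#' Alignment scoring scheme
#'
#' A gap of length g costs `|gap_open| + g * |gap_extend|`. `min_score` is the
#' reporting threshold in both modes; an alignment is flagged unique when its
#' score beats the best alternative locus by at least `uniq_margin`.
#'
#' @param match,mismatch,gap_open,gap_extend match bonus and penalties.
#' @param min_score minimum reported score.
#' @param uniq_margin best-vs-second-best margin for the unique flag.
#' @return List of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -4L, gap_open = -6L,
                           gap_extend = -1L, min_score = 20L,
                           uniq_margin = 2L) {
  if (match <= 0) stop("match bonus must be positive")
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0)
    stop("penalties must be <= 0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score),
                 uniq_margin = as.integer(uniq_margin)),
            class = "scoring_scheme")
}

#' Build an exact k-mer seed index over a reference
#'
#' @param reference a `combined_reference` or named character vector.
#' @param k seed length (11..31); must not exceed the shortest contig.
#' @return List of class `seed_index` (holds an external pointer; rebuild
#'   rather than serialize).
#' @export
build_index <- function(reference, k = 21L) {
  contigs <- if (inherits(reference, "combined_reference"))
    reference$contigs else reference
  if (any(nchar(contigs) < k))
    stop("k exceeds the shortest contig length")
  ptr <- .tg_build_index(names(contigs), unname(contigs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), contigs = names(contigs)),
            class = "seed_index")
}

empty_records <- function(n) {
  data.frame(qname = character(n), read1 = NA, mapped = logical(n),
             contig = NA_character_, pos = NA_integer_,
             strand = NA_character_, cigar = NA_character_,
             score = NA_integer_, second = NA_integer_, unique = NA,
             seq = NA_character_, mate_contig = NA_character_,
             mate_pos = NA_integer_, mate_strand = NA_character_,
             proper = NA, stringsAsFactors = FALSE)
}

#' Align a batch of reads
#'
#' @param reads character vector of read sequences.
#' @param index a [build_index()] result.
#' @param scoring a [scoring_scheme()].
#' @param mode `"e2e"` (end-to-end, no soft clips) or `"local"`.
#' @param qname optional read names.
#' @return Alignment-record data.frame; `seq` is stored in reference
#'   orientation (reverse-complemented for `-` strand records), as in SAM.
#' @export
align_batch <- function(reads, index, scoring = scoring_scheme(),
                        mode = c("e2e", "local"), qname = NULL) {
  mode <- match.arg(mode)
  if (is.null(qname)) qname <- sprintf("read_%06d", seq_along(reads))
  raw <- .tg_align_batch(index$ptr, toupper(reads), mode,
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, scoring$min_score,
                         scoring$uniq_margin,
                         5L, 8L, 12L)
  rec <- empty_records(length(reads))
  rec$qname <- qname
  rec$mapped <- raw$mapped
  rec$contig <- ifelse(raw$mapped, index$contigs[raw$contig_idx], NA_character_)
  rec$pos <- as.integer(raw$pos)
  rec$strand <- raw$strand
  rec$cigar <- raw$cigar
  rec$score <- raw$score
  rec$second <- raw$second
  rec$unique <- rec$mapped &
    (is.na(rec$second) | rec$score >= rec$second + scoring$uniq_margin)
  rec$seq <- toupper(reads)
  neg <- which(rec$mapped & rec$strand == "-")
  if (length(neg)) rec$seq[neg] <- rc_seq(rec$seq[neg])
  rec
}

#' Align a single read end-to-end or locally
#'
#' @param read one read sequence.
#' @inheritParams align_batch
#' @return One-row alignment-record data.frame (`mapped = FALSE` when no
#'   alignment reaches `min_score`).
#' @export
align_end_to_end <- function(read, index, scoring = scoring_scheme()) {
  align_batch(read, index, scoring, mode = "e2e")
}

#' @rdname align_end_to_end
#' @export
align_local <- function(read, index, scoring = scoring_scheme()) {
  align_batch(read, index, scoring, mode = "local")
}

# CIGAR helpers ---------------------------------------------------------------

cigar_table <- function(cigar) {
  if (is.na(cigar)) return(data.frame(op = character(0), len = integer(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MSID]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# reference bases consumed (M + D), vectorized with a fast path for pure nM
cigar_ref_len <- function(cigars) {
  out <- integer(length(cigars))
  simple <- grepl("^[0-9]+M$", cigars)
  out[simple] <- as.integer(sub("M$", "", cigars[simple]))
  for (i in which(!simple & !is.na(cigars))) {
    tb <- cigar_table(cigars[i])
    out[i] <- sum(tb$len[tb$op %in% c("M", "D")])
  }
  out[is.na(cigars)] <- NA_integer_
  out
}

# terminal soft-clip lengths, vectorized
cigar_clips <- function(cigars) {
  cz <- ifelse(is.na(cigars), "", cigars)
  left <- integer(length(cz)); right <- integer(length(cz))
  lm <- regexpr("^[0-9]+S", cz)
  rm_ <- regexpr("[0-9]+S$", cz)
  left[lm > 0] <- as.integer(sub("S$", "", regmatches(cz, lm)))
  right[rm_ > 0] <- as.integer(sub("S$", "", regmatches(cz, rm_)))
  right[grepl("^[0-9]+S$", cz)] <- 0L  # clip-only cigar: count once
  left[is.na(cigars)] <- NA_integer_; right[is.na(cigars)] <- NA_integer_
  list(left = left, right = right)
}

#' Align a paired-end read set
#'
#' Both mates are aligned independently; a pair is flagged proper when the
#' mates map to the same contig on opposite strands in forward/reverse
#' orientation with an implied fragment length within
#' `mean +/- 4 sd` of the insert model. Everything else is discordant — the
#' raw material for junction-pair detection.
#'
#' @param reads1,reads2 mate sequences, in sync.
#' @param index a [build_index()] result.
#' @param scoring a [scoring_scheme()].
#' @param insert_model `list(mean=, sd=)` insert-size model.
#' @param mode alignment mode for both mates.
#' @param qname optional fragment names.
#' @return Alignment-record data.frame with two rows per pair.
#' @export
align_pairs <- function(reads1, reads2, index, scoring = scoring_scheme(),
                        insert_model = list(mean = 350, sd = 35),
                        mode = c("e2e", "local"), qname = NULL) {
  mode <- match.arg(mode)
  if (length(reads1) != length(reads2))
    stop("mate files out of sync: unequal read counts")
  if (is.null(qname)) qname <- sprintf("frag_%07d", seq_along(reads1))
  r1 <- align_batch(reads1, index, scoring, mode, qname = qname)
  r2 <- align_batch(reads2, index, scoring, mode, qname = qname)
  r1$read1 <- TRUE; r2$read1 <- FALSE
  r1$mate_contig <- r2$contig; r1$mate_pos <- r2$pos; r1$mate_strand <- r2$strand
  r2$mate_contig <- r1$contig; r2$mate_pos <- r1$pos; r2$mate_strand <- r1$strand
  end1 <- r1$pos + cigar_ref_len(r1$cigar) - 1L
  end2 <- r2$pos + cigar_ref_len(r2$cigar) - 1L
  both <- r1$mapped & r2$mapped
  same <- both & r1$contig == r2$contig & r1$strand != r2$strand
  plus_start <- ifelse(r1$strand == "+", r1$pos, r2$pos)
  minus_end <- ifelse(r1$strand == "+", end2, end1)
  frag <- minus_end - plus_start + 1L
  lim <- c(insert_model$mean - 4 * insert_model$sd,
           insert_model$mean + 4 * insert_model$sd)
  proper <- same & !is.na(frag) & frag >= max(0, lim[1]) & frag <= lim[2] &
    frag > 0
  r1$proper <- proper; r2$proper <- proper
  out <- rbind(r1, r2)
  out[order(rep(seq_along(qname), 2L), rep(1:2, each = length(qname))), ,
      drop = FALSE]
}
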