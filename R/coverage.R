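# Depth, GC-bias correction and coverage-ratio copy-number estimation.
#
# Under a Poisson sequencing model the read depth of a region is proportional
# to how many times that region is present in the sample. For a hemizygous
# transgenic diploid, a region present at `c` copies per diploid genome shows
# `c/2 x` the haploid background, so
#   copies_from_transgene = ploidy * region_depth / background_depth
#                           - endogenous_copies.
# The same formula serves a promoter shared with the host genome
# (endogenous_copies = 2) and cassette-only features such as the reporter
# CDS (endogenous_copies = 0).

#' Compute a per-base depth track from alignment records
#'
#' Depth counts reads whose aligned (M) segments overlap each base.
#' Non-unique alignments are excluded when `require_unique`, EXCEPT inside
#' the reference's promoter-homology regions: reads shared between an
#' endogenous locus and the construct's copy of it are inherently
#' multi-mapping, and dropping them would carve a spurious coverage hole in
#' exactly the region whose depth carries the copy-number signal.
#'
#' @param records alignment-record data.frame.
#' @param reference a `combined_reference`.
#' @param require_unique drop non-unique alignments (outside homology regions).
#' @return List of class `depth_track`: one numeric vector per contig.
#' @export
compute_depth <- function(records, reference, require_unique = TRUE) {
  rec <- records[records$mapped, , drop = FALSE]
  bad <- setdiff(unique(rec$contig), names(reference$contigs))
  if (length(bad))
    stop("alignment contig(s) not in reference: ", paste(bad, collapse = ", "))
  if (require_unique) {
    keep <- rec$unique
    hom <- reference$homology
    if (!is.null(hom) && nrow(hom)) {
      ends <- rec$pos + cigar_ref_len(rec$cigar) - 1L
      for (k in seq_len(nrow(hom))) {
        keep <- keep | (rec$contig == hom$contig[k] &
                          rec$pos >= hom$start[k] - 200L &
                          ends <= hom$end[k] + 200L)
      }
    }
    rec <- rec[keep, , drop = FALSE]
  }
  track <- lapply(reference$contigs, function(s) numeric(nchar(s)))
  simple <- grepl("^[0-9]+M$", rec$cigar)
  for (ctg in unique(rec$contig)) {
    len <- nchar(reference$contigs[[ctg]])
    starts <- integer(0); ends <- integer(0)
    sel <- rec$contig == ctg & simple
    if (any(sel)) {
      starts <- rec$pos[sel]
      ends <- starts + as.integer(sub("M$", "", rec$cigar[sel])) - 1L
    }
    for (i in which(rec$contig == ctg & !simple)) {
      tb <- cigar_table(rec$cigar[i])
      rp <- rec$pos[i]
      for (j in seq_len(nrow(tb))) {
        if (tb$op[j] == "M") {
          starts <- c(starts, rp); ends <- c(ends, rp + tb$len[j] - 1L)
          rp <- rp + tb$len[j]
        } else if (tb$op[j] == "D") rp <- rp + tb$len[j]
      }
    }
    if (!length(starts)) next
    ends <- pmin(ends, len); starts <- pmax(starts, 1L)
    ok <- starts <= ends
    d <- cumsum(as.numeric(tabulate(starts[ok], len) -
                             tabulate(ends[ok] + 1L, len + 1L)[seq_len(len)]))
    track[[ctg]] <- d
  }
  structure(track, class = "depth_track")
}

bin_starts <- function(len, bin_size) seq.int(1L, len, by = bin_size)

binned_depth <- function(depth, bin_size) {
  out <- list()
  for (ctg in names(depth)) {
    len <- length(depth[[ctg]])
    bs <- bin_starts(len, bin_size)
    be <- pmin(bs + bin_size - 1L, len)
    grp <- rep(seq_along(bs), times = be - bs + 1L)
    mean_d <- as.numeric(tapply(depth[[ctg]], grp, mean))
    out[[ctg]] <- data.frame(contig = ctg, start = bs, end = be,
                             depth = mean_d, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

bin_gc <- function(reference, bins) {
  gc <- numeric(nrow(bins))
  for (ctg in unique(bins$contig)) {
    sel <- bins$contig == ctg
    v <- Biostrings::Views(Biostrings::DNAString(reference$contigs[[ctg]]),
                           start = bins$start[sel], end = bins$end[sel])
    gcc <- Biostrings::letterFrequency(v, letters = "GC")[, 1]
    acgt <- Biostrings::letterFrequency(v, letters = "ACGT")[, 1]
    gc[sel] <- ifelse(acgt > 0, gcc / acgt, NA_real_)
  }
  gc
}

mask_bins <- function(bins, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, nrow(bins)))
  m <- rep(FALSE, nrow(bins))
  for (k in seq_len(nrow(mask))) {
    m <- m | (bins$contig == mask$contig[k] & bins$start <= mask$end[k] &
                bins$end >= mask$start[k])
  }
  m
}

#' Fit a binned GC-bias model
#'
#' Bins the genome, computes mean depth per GC class (fixed-width tenths of
#' GC fraction), and expresses each class as a ratio to the global mean
#' binned depth. Classes with fewer than 3 bins inherit ratio 1. This is a
#' deliberately simplified binned-ratio analogue of fragment-level GC
#' correction tools.
#'
#' @param depth a `depth_track`.
#' @param reference the `combined_reference` the depth was computed on.
#' @param bin_size bin width in bp (default 1000).
#' @param mask optional data.frame (`contig`, `start`, `end`) of regions
#'   excluded from model FITTING (multi-copy regions such as the transgene
#'   contig or a shared promoter would otherwise drag their GC class up);
#'   masked bins are still corrected.
#' @return List of class `gc_bias_model`.
#' @export
fit_gc_bias <- function(depth, reference, bin_size = 1000L, mask = NULL) {
  if (bin_size > max(nchar(reference$contigs)))
    stop("bin_size exceeds the longest contig")
  bins <- binned_depth(depth, bin_size)
  if (nrow(bins) < 50L)
    stop("need at least 50 bins to fit a GC model; decrease bin_size")
  bins$gc <- bin_gc(reference, bins)
  bins$gc_class <- pmin(floor(bins$gc * 10), 9)
  bins$masked <- mask_bins(bins, mask)
  fitbins <- bins[!bins$masked & !is.na(bins$gc_class), , drop = FALSE]
  global <- mean(fitbins$depth)
  ratio <- rep(1, 10)
  for (g in 0:9) {
    sel <- fitbins$gc_class == g
    if (sum(sel) >= 3L && global > 0) {
      r <- mean(fitbins$depth[sel]) / global
      if (r > 0) ratio[g + 1L] <- r
    }
  }
  structure(list(bin_size = as.integer(bin_size), ratio = ratio,
                 bins = bins, global_mean = global),
            class = "gc_bias_model")
}

#' Apply a GC-bias correction to a depth track
#'
#' Each base's depth is divided by the observed/expected ratio of its bin's
#' GC class.
#'
#' @param depth a `depth_track`.
#' @param model a [fit_gc_bias()] model (carries its own binning).
#' @return Corrected `depth_track`.
#' @export
correct_gc <- function(depth, model) {
  out <- depth
  for (ctg in names(depth)) {
    sel <- model$bins$contig == ctg
    if (!any(sel)) next
    b <- model$bins[sel, , drop = FALSE]
    cls <- ifelse(is.na(b$gc_class), -1L, b$gc_class)
    r <- ifelse(cls >= 0L, model$ratio[cls + 1L], 1)
    per_base <- rep(r, times = b$end - b$start + 1L)
    out[[ctg]] <- depth[[ctg]] / per_base
  }
  structure(out, class = "depth_track")
}

#' Robust background depth
#'
#' Median of binned (corrected) depth over host bins, excluding masked
#' regions (construct-homologous and insertion-adjacent intervals) and the
#' transgene contig.
#'
#' @param depth a `depth_track` (typically GC-corrected).
#' @param reference the `combined_reference`.
#' @param mask optional data.frame (`contig`, `start`, `end`) to exclude.
#' @param bin_size bin width.
#' @return Scalar background depth.
#' @export
background_depth <- function(depth, reference, mask = NULL, bin_size = 1000L) {
  bins <- binned_depth(depth[names(depth) != reference$transgene], bin_size)
  bins <- bins[!mask_bins(bins, mask), , drop = FALSE]
  stats::median(bins$depth)
}

#' Mean depth over an interval
#'
#' @param depth a `depth_track`.
#' @param interval a [genomic_interval()].
#' @return Named list with mean and median depth over the interval.
#' @export
region_depth <- function(depth, interval) {
  v <- depth[[interval$contig]][interval$start:interval$end]
  list(mean = mean(v), median = stats::median(v))
}

#' Coverage-ratio copy-number estimate
#'
#' `copies = round(ploidy * region_depth / background_depth -
#' endogenous_copies)`, clamped at zero. With diploid background 20x, a
#' shared promoter at 80x gives `2*80/20 - 2 = 6` cassette copies and a
#' cassette-only reporter at 60x gives `2*60/20 - 0 = 6`. A Poisson interval
#' on the region's read count is propagated to the copy estimate when the
#' region's effective read count can be derived.
#'
#' @param region_depth mean (corrected) depth over the region.
#' @param background_depth genome-wide robust depth (> 0).
#' @param endogenous_copies copies of the region already present per diploid
#'   host genome (2 for a shared promoter, 0 for cassette-only features).
#' @param ploidy host ploidy (default 2).
#' @param region_length optional region length (bp) for Poisson bounds.
#' @param read_length read length used to convert depth to a read count.
#' @return List of class `copy_number_estimate`: `copies` (integer),
#'   `copies_frac`, `ci` (95% bounds, or NULL), inputs echoed.
#' @export
estimate_copy_number <- function(region_depth, background_depth,
                                 endogenous_copies = 0L, ploidy = 2L,
                                 region_length = NULL, read_length = 101L) {
  if (region_depth < 0 || background_depth <= 0 || endogenous_copies < 0 ||
      ploidy <= 0)
    stop("depths must be nonnegative, background and ploidy positive")
  frac <- ploidy * region_depth / background_depth - endogenous_copies
  copies <- max(0L, as.integer(round(frac)))
  ci <- NULL
  if (!is.null(region_length) && region_length > 0) {
    n_eff <- region_depth * region_length / read_length
    lo <- stats::qchisq(0.025, 2 * n_eff) / 2
    hi <- stats::qchisq(0.975, 2 * (n_eff + 1)) / 2
    d_ci <- c(lo, hi) * read_length / region_length
    ci <- pmax(0, ploidy * d_ci / background_depth - endogenous_copies)
  }
  structure(list(copies = copies, copies_frac = frac, ci = ci,
                 region_depth = region_depth,
                 background_depth = background_depth,
                 endogenous_copies = as.integer(endogenous_copies),
                 ploidy = as.integer(ploidy)),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "copy number: %d (fractional %.2f; region %.1fx vs background %.1fx, endogenous %d, ploidy %d)\n",
    x$copies, x$copies_frac, x$region_depth, x$background_depth,
    x$endogenous_copies, x$ploidy))
  if (!is.null(x$ci))
    cat(sprintf("  95%% Poisson interval on copies: [%.2f, %.2f]\n",
                x$ci[1], x$ci[2]))
  invisible(x)
}

#' Export a depth track as bedGraph
#'
#' @param depth a `depth_track`.
#' @param path output path.
#' @param bin_size summarising bin width.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, path, bin_size = 100L) {
  bins <- binned_depth(depth, bin_size)
  writeLines(sprintf("%s\t%d\t%d\t%.3f", bins$contig, bins$start - 1L,
                     bins$end, bins$depth), path)
  invisible(path)
}
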