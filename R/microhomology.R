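# Junction microhomology annotation. Meganuclease-mediated transgenesis can
# proceed through microhomology-mediated end joining (MMEJ): short exact
# homologies between resected genomic ends and the construct termini (the
# recognition-site remnants and the 4-nt 3' overhang left by cleavage) seed
# the join, and homology between the two genomic flanks can mediate a
# subsequent tandem duplication of the whole insertion. Matching here is
# exact-only: the motifs involved are a handful of bases.

#' Describe a meganuclease cleavage model
#'
#' Cut offsets are counted in top-strand coordinates of the recognition
#' sequence: the top strand is cut after `top_cut`, the bottom strand
#' (in top-strand coordinates) after `bottom_cut`. The canonical default is
#' the I-SceI homing endonuclease: an 18-bp nonpalindromic site cut to leave
#' a 4-nt 3' overhang.
#'
#' @param recognition_sequence recognition site, top strand.
#' @param top_cut,bottom_cut cut offsets (0..site length).
#' @param overhang_kind `"3prime"`, `"5prime"` or `"blunt"`.
#' @return List of class `cleavage_model`.
#' @export
cleavage_model <- function(recognition_sequence = "TAGGGATAACAGGGTAAT",
                           top_cut = 9L, bottom_cut = 5L,
                           overhang_kind = c("3prime", "5prime", "blunt")) {
  recognition_sequence <- check_dna(recognition_sequence, "recognition site")
  overhang_kind <- match.arg(overhang_kind)
  len <- nchar(recognition_sequence)
  if (top_cut < 0L || top_cut > len || bottom_cut < 0L || bottom_cut > len)
    stop("cut offsets must lie within the recognition site")
  if (top_cut == bottom_cut) overhang_kind <- "blunt"
  structure(list(recognition_sequence = recognition_sequence,
                 top_cut = as.integer(top_cut),
                 bottom_cut = as.integer(bottom_cut),
                 overhang_kind = overhang_kind),
            class = "cleavage_model")
}

#' Single-stranded overhang left by cleavage
#'
#' The overhang is the stretch of the recognition sequence between the two
#' cut offsets; its length is `|top_cut - bottom_cut|`. The I-SceI default
#' yields the 4-nt 3' overhang 5'-ATAA-3'.
#'
#' @param model a [cleavage_model()].
#' @return List with `sequence` and `length`.
#' @export
cleavage_overhang <- function(model) {
  a <- min(model$top_cut, model$bottom_cut)
  b <- max(model$top_cut, model$bottom_cut)
  list(sequence = substr(model$recognition_sequence, a + 1L, b),
       length = b - a)
}

# All maximal exact matches >= min_len between two sequences; a match is
# maximal when it cannot be extended on either side.
maximal_matches <- function(a, b, min_len) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  na <- length(av); nb <- length(bv)
  if (na == 0L || nb == 0L) return(NULL)
  hits <- list()
  prev <- integer(nb)
  for (i in seq_len(na)) {
    run <- integer(nb)
    eq <- av[i] == bv
    run[eq] <- c(0L, prev)[seq_len(nb)][eq] + 1L
    # a run ending at (i, j) is maximal if (i+1, j+1) does not match
    for (j in which(run >= min_len)) {
      ended <- i == na || j == nb || av[i + 1L] != bv[j + 1L]
      if (ended) {
        L <- run[j]
        hits[[length(hits) + 1L]] <- c(i - L + 1L, j - L + 1L, L)
      }
    }
    prev <- run
  }
  if (!length(hits)) return(NULL)
  m <- do.call(rbind, hits)
  data.frame(a_offset = m[, 1], b_offset = m[, 2], length = m[, 3])
}

#' Scan a genomic flank for microhomology to a construct terminus
#'
#' Reports all maximal exact matches of at least `min_len` bases between the
#' flank (both strands) and the construct-terminal window, sorted by length
#' then offset. Every hit is self-evidencing: the matched substring occurs at
#' both reported offsets.
#'
#' @param flank_seq genomic flank window.
#' @param construct_terminal_seq construct terminal window.
#' @param min_len minimum match length (>= 2).
#' @param max_shift optional cap on the flank offset (distance from the
#'   window's start) of reported hits; `Inf` reports all.
#' @return data.frame of hits: `flank_offset`, `terminal_offset`, `length`,
#'   `strand`, `seq`.
#' @export
scan_microhomology <- function(flank_seq, construct_terminal_seq, min_len = 3L,
                               max_shift = Inf) {
  if (!nzchar(flank_seq) || !nzchar(construct_terminal_seq))
    stop("both sequences must be nonempty")
  if (min_len < 2L) stop("min_len must be >= 2")
  out <- list()
  for (strand in c("+", "-")) {
    f <- if (strand == "+") toupper(flank_seq) else rc_seq(flank_seq)
    mm <- maximal_matches(f, construct_terminal_seq, min_len)
    if (is.null(mm)) next
    # report flank offsets on the forward strand of the flank
    fo <- if (strand == "+") mm$a_offset else
      nchar(flank_seq) - (mm$a_offset + mm$length - 1L) + 1L
    out[[length(out) + 1L]] <- data.frame(
      flank_offset = fo, terminal_offset = mm$b_offset, length = mm$length,
      strand = strand,
      seq = substring(f, mm$a_offset, mm$a_offset + mm$length - 1L),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(flank_offset = integer(0), terminal_offset = integer(0),
                      length = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  d <- do.call(rbind, out)
  d <- d[d$flank_offset <= max_shift, , drop = FALSE]
  d <- d[order(-d$length, d$flank_offset, d$terminal_offset), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Scan two genomic flanks for shared homology
#'
#' Maximal exact matches between the flanks upstream of two nearby
#' integration sites; such direct homology can mediate realignment and
#' tandem duplication of an initial insertion.
#'
#' @param upstream_flank,downstream_flank the two flank windows.
#' @param min_len minimum match length.
#' @return data.frame of hits (forward-strand matches, plus reverse-strand
#'   matches of the first flank flagged in `strand`).
#' @export
scan_flank_homology <- function(upstream_flank, downstream_flank,
                                min_len = 4L) {
  scan_microhomology(upstream_flank, downstream_flank, min_len = min_len)
}

#' MMEJ evidence report for called integration sites
#'
#' For each boundary of each site: the junction-proximal genomic flank is
#' scanned against the construct-terminal window joined there; matches that
#' cover the cleavage overhang at a terminus are labelled `overhang`, matches
#' overlapping a recognition-site remnant feature `recognition`, anything
#' else `other`. For each pair of sites the upstream flanks are compared, and
#' a tandem-duplication signature is flagged when one site carries a
#' target-site duplication and the inter-site flank homology reaches
#' `dup_min_len`.
#'
#' @param sites an `integration_site_list`.
#' @param host host contig sequence.
#' @param construct a [transgene_construct()].
#' @param model a [cleavage_model()].
#' @param flank_len flank window, bp.
#' @param min_len minimum microhomology length.
#' @param dup_min_len minimum flank-flank homology for the duplication flag.
#' @param max_shift how close to the junction (bp) an overhang match must sit.
#' @return List of class `mmej_report`: `boundaries` and `site_pairs`
#'   data.frames plus the per-hit tables.
#' @export
mmej_report <- function(sites, host, construct, model = cleavage_model(),
                        flank_len = 30L, min_len = 3L, dup_min_len = 4L,
                        max_shift = 5L) {
  host <- toupper(host)
  cseq <- construct$sequence
  clen <- nchar(cseq)
  ov <- cleavage_overhang(model)
  olen <- ov$length
  brows <- list(); hit_tables <- list()
  for (si in seq_along(sites)) {
    s <- sites[[si]]
    for (bside in c("left", "right")) {
      b <- s[[bside]]
      # junction-proximal flank: upstream of a left boundary, downstream of a
      # right boundary (the side that was genomic before the join)
      if (bside == "left") {
        fl <- substr(host, max(1L, b$pos - flank_len + 1L), b$pos)
        proximal_is_end <- TRUE   # junction at the flank's right end
      } else {
        fl <- substr(host, b$pos, min(nchar(host), b$pos + flank_len - 1L))
        proximal_is_end <- FALSE  # junction at the flank's left end
      }
      # construct terminal window joined at this boundary
      joined_start <- (b$orient == "+" && bside == "left") ||
        (b$orient == "-" && bside == "right")
      if (joined_start) {
        tw <- substr(cseq, 1L, flank_len); toff <- 0L
        ov_rng <- c(1L, olen)
        rec_feats <- construct$features[
          construct$features$label == "isce1_site_left", , drop = FALSE]
      } else {
        tw <- substr(cseq, clen - flank_len + 1L, clen)
        toff <- clen - flank_len
        ov_rng <- c(clen - olen + 1L, clen)
        rec_feats <- construct$features[
          construct$features$label == "isce1_site_right", , drop = FALSE]
      }
      hits <- scan_microhomology(fl, tw, min_len = min_len)
      if (nrow(hits)) {
        hits$construct_start <- hits$terminal_offset + toff
        hits$construct_end <- hits$construct_start + hits$length - 1L
        covers_ov <- hits$construct_start <= ov_rng[1] &
          hits$construct_end >= ov_rng[2]
        prox_dist <- if (proximal_is_end)
          nchar(fl) - (hits$flank_offset + hits$length - 1L) else
            hits$flank_offset - 1L
        hits$element <- "other"
        if (nrow(rec_feats)) {
          in_rec <- hits$construct_start <= rec_feats$end[1] &
            hits$construct_end >= rec_feats$start[1]
          hits$element[in_rec] <- "recognition"
        }
        hits$element[covers_ov & prox_dist <= max_shift] <- "overhang"
        hits$prox_dist <- prox_dist
      }
      ov_len_best <- if (nrow(hits) && any(hits$element == "overhang"))
        max(hits$length[hits$element == "overhang"]) else 0L
      rec_len_best <- if (nrow(hits) && any(hits$element == "recognition"))
        max(hits$length[hits$element == "recognition"]) else 0L
      bid <- sprintf("site%d_%s", si, bside)
      hit_tables[[bid]] <- hits
      brows[[length(brows) + 1L]] <- data.frame(
        boundary = bid, site = si, side = bside, pos = b$pos,
        orient = b$orient, joined_terminus = if (joined_start) "start" else "end",
        overhang_match = ov_len_best >= olen & olen > 0L,
        overhang_len = ov_len_best, recognition_len = rec_len_best,
        junction_seq = fl, stringsAsFactors = FALSE)
    }
  }
  boundaries <- if (length(brows)) do.call(rbind, brows) else
    data.frame(boundary = character(0), site = integer(0), side = character(0),
               pos = integer(0), orient = character(0),
               joined_terminus = character(0), overhang_match = logical(0),
               overhang_len = integer(0), recognition_len = integer(0),
               junction_seq = character(0), stringsAsFactors = FALSE)
  prows <- list()
  if (length(sites) >= 2L) {
    for (i in seq_len(length(sites) - 1L)) for (j in (i + 1L):length(sites)) {
      up <- function(s) substr(host, max(1L, s$left$pos - flank_len + 1L),
                               s$left$pos)
      hh <- scan_flank_homology(up(sites[[i]]), up(sites[[j]]),
                                min_len = min_len)
      best <- if (nrow(hh)) max(hh$length) else 0L
      has_dup <- sites[[i]]$lesion$class == "duplication" ||
        sites[[j]]$lesion$class == "duplication"
      prows[[length(prows) + 1L]] <- data.frame(
        site_a = i, site_b = j, flank_homology_len = best,
        duplication_signature = has_dup && best >= dup_min_len,
        stringsAsFactors = FALSE)
    }
  }
  site_pairs <- if (length(prows)) do.call(rbind, prows) else
    data.frame(site_a = integer(0), site_b = integer(0),
               flank_homology_len = integer(0),
               duplication_signature = logical(0), stringsAsFactors = FALSE)
  structure(list(boundaries = boundaries, site_pairs = site_pairs,
                 hits = hit_tables, overhang = ov),
            class = "mmej_report")
}

#' @export
print.mmej_report <- function(x, ...) {
  cat("MMEJ junction report —", nrow(x$boundaries), "boundaries\n")
  if (nrow(x$boundaries))
    print(x$boundaries[, c("boundary", "pos", "joined_terminus",
                           "overhang_match", "overhang_len",
                           "recognition_len")], row.names = FALSE)
  if (nrow(x$site_pairs)) {
    cat("site pairs:\n")
    print(x$site_pairs, row.names = FALSE)
  }
  invisible(x)
}
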