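# End-to-end orchestration: align in both modes, compute GC-corrected depth
# and coverage-ratio copy numbers, call integration sites from junction pairs
# plus split reads, and annotate junction microhomology. Each stage is an
# exported function; run_pipeline() is the glue and the analysis/ scripts are
# thin narrative drivers over it.

#' Pipeline configuration
#'
#' All thresholds in one place. Defaults: 21-mer seeds; match +1 / mismatch
#' -4 / gap open -6 / gap extend -1, minimum score 20, uniqueness margin 2;
#' split reads need a >= 20 bp clip remapping with score >= 15; boundaries
#' cluster within 10 bp and need 3 split reads (or 1 split + 2 junction
#' pairs); boundary pairing spans up to 10 kb; GC model bins of 1000 bp;
#' microhomology scanning over 30 bp flanks at minimum match 3 (4 for the
#' duplication signature).
#'
#' @param k seed length.
#' @param scoring a [scoring_scheme()].
#' @param insert_model `list(mean=, sd=)` insert-size model.
#' @param bin_size GC/background bin width, bp.
#' @param min_clip,min_remap_score split-read thresholds.
#' @param window boundary clustering window, bp.
#' @param min_support,min_pair_support boundary support thresholds.
#' @param max_span boundary pairing span, bp.
#' @param flank_len,mh_min_len,dup_min_len microhomology parameters.
#' @param ploidy host ploidy.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 21L, scoring = scoring_scheme(),
                            insert_model = list(mean = 350, sd = 35),
                            bin_size = 1000L, min_clip = 20L,
                            min_remap_score = 15L, window = 10L,
                            min_support = 3L, min_pair_support = 2L,
                            max_span = 10000L, flank_len = 30L,
                            mh_min_len = 3L, dup_min_len = 4L, ploidy = 2L) {
  structure(list(k = k, scoring = scoring, insert_model = insert_model,
                 bin_size = bin_size, min_clip = min_clip,
                 min_remap_score = min_remap_score, window = window,
                 min_support = min_support,
                 min_pair_support = min_pair_support, max_span = max_span,
                 flank_len = flank_len, mh_min_len = mh_min_len,
                 dup_min_len = dup_min_len, ploidy = ploidy),
            class = "pipeline_config")
}

#' Run the full integration-site analysis
#'
#' Reads are mapped to the combined reference twice — end-to-end (junction
#' pairs, depth) and locally (split reads) — then depth is GC-corrected,
#' copy numbers estimated per feature, boundaries clustered and paired into
#' sites, concatemer junctions collected, and junction microhomology
#' annotated.
#'
#' @param reference a `combined_reference`.
#' @param reads a [simulate_reads()] result, or
#'   `list(read1=, read2=, qname=)`.
#' @param features named list of [genomic_interval()]s to estimate copy
#'   number for (e.g. promoter on the host, reporter CDS on the transgene).
#' @param endogenous named integer vector: copies of each feature already in
#'   the diploid host genome (promoter 2, cassette-only features 0).
#' @param config a [pipeline_config()].
#' @param alignments optional precomputed alignments
#'   (`list(e2e = records, local = records)`, e.g. from [read_sam()] or
#'   [emit_truth_sam()]), bypassing the built-in aligner.
#' @param outdir optional directory for intermediate artifacts (SAM,
#'   bedGraph, TSV/JSON reports).
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(reference, reads, features, endogenous,
                         config = pipeline_config(), alignments = NULL,
                         outdir = NULL) {
  read_len <- if (!is.null(reads)) max(nchar(reads$read1[1]), 1L) else 101L
  if (is.null(alignments)) {
    idx <- build_index(reference, k = config$k)
    e2e <- align_pairs(reads$read1, reads$read2, idx, config$scoring,
                       config$insert_model, mode = "e2e",
                       qname = reads$qname)
    loc <- align_pairs(reads$read1, reads$read2, idx, config$scoring,
                       config$insert_model, mode = "local",
                       qname = reads$qname)
  } else {
    e2e <- if (!is.null(alignments$e2e)) alignments$e2e else alignments$local
    loc <- if (!is.null(alignments$local)) alignments$local else alignments$e2e
  }
  n_reads <- nrow(e2e)
  mapped_fraction <- mean(e2e$mapped)

  # depth + GC correction + background (multi-copy regions masked from the
  # model fit and the background median)
  depth_raw <- compute_depth(e2e, reference)
  mask <- reference$homology
  tg_mask <- data.frame(contig = reference$transgene, start = 1L,
                        end = nchar(reference$contigs[[reference$transgene]]),
                        stringsAsFactors = FALSE)
  mask <- if (is.null(mask)) tg_mask else
    rbind(mask[, c("contig", "start", "end")], tg_mask)
  gc_model <- fit_gc_bias(depth_raw, reference, bin_size = config$bin_size,
                          mask = mask)
  depth <- correct_gc(depth_raw, gc_model)
  bg <- background_depth(depth, reference, mask = mask,
                         bin_size = config$bin_size)

  cn <- lapply(names(features), function(f) {
    rd <- region_depth(depth, features[[f]])
    est <- estimate_copy_number(rd$mean, bg,
                                endogenous_copies = endogenous[[f]],
                                ploidy = config$ploidy,
                                region_length = features[[f]]$end -
                                  features[[f]]$start + 1L,
                                read_length = read_len)
    data.frame(feature = f, contig = features[[f]]$contig,
               start = features[[f]]$start, end = features[[f]]$end,
               mean_depth = rd$mean, median_depth = rd$median,
               background = bg, endogenous = endogenous[[f]],
               copies_frac = est$copies_frac, copies = est$copies,
               ci_lo = if (is.null(est$ci)) NA_real_ else est$ci[1],
               ci_hi = if (is.null(est$ci)) NA_real_ else est$ci[2],
               stringsAsFactors = FALSE)
  })
  cn <- do.call(rbind, cn)

  jp <- find_junction_pairs(e2e, reference)
  sr <- find_split_reads(loc, reference, min_clip = config$min_clip,
                         min_remap_score = config$min_remap_score)
  bnd <- cluster_boundaries(sr, jp, reference, window = config$window,
                            min_support = config$min_support,
                            min_pair_support = config$min_pair_support,
                            frag_limit = config$insert_model$mean +
                              4 * config$insert_model$sd)
  sites <- pair_boundaries_into_sites(bnd, max_span = config$max_span)
  conc <- find_concatemer_junctions(loc, reference,
                                    min_clip = config$min_clip,
                                    min_remap_score = config$min_remap_score)
  mh <- if (length(sites)) {
    ctg <- sites[[1]]$left$contig
    mmej_report(sites, reference$contigs[[ctg]], reference$construct,
                flank_len = config$flank_len, min_len = config$mh_min_len,
                dup_min_len = config$dup_min_len)
  } else mmej_report(list(), "A", reference$construct)

  host_depth <- unlist(depth[names(depth) != reference$transgene],
                       use.names = FALSE)
  report <- structure(list(
    n_reads = n_reads, n_pairs = n_reads %/% 2L,
    mapped_fraction = mapped_fraction,
    mean_coverage = mean(host_depth),
    background_depth = bg,
    copy_number = cn,
    junction_pairs = nrow(jp), split_reads = nrow(sr),
    boundaries = bnd, sites = sites, concatemer_junctions = conc,
    microhomology = mh,
    dropped_boundaries = attr(bnd, "dropped"),
    config = config,
    version = as.character(utils::packageVersion("isceimap"))),
    class = "run_report")

  if (!is.null(outdir)) write_report_artifacts(report, depth, e2e, loc,
                                               reference, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d reads, %.2f%% mapped, host coverage %.1fx (background %.1fx)\n",
              x$n_reads, 100 * x$mapped_fraction, x$mean_coverage,
              x$background_depth))
  cat("copy number:\n")
  print(x$copy_number[, c("feature", "mean_depth", "background", "endogenous",
                          "copies_frac", "copies")], row.names = FALSE)
  cat(sprintf("%d junction pairs, %d split reads\n", x$junction_pairs,
              x$split_reads))
  print(x$sites)
  if (nrow(x$concatemer_junctions)) {
    cat("concatemer junctions:\n")
    print(x$concatemer_junctions, row.names = FALSE)
  }
  print(x$microhomology)
  invisible(x)
}

#' Export integration sites as BED
#'
#' One BED line per site spanning its boundary pair (0-based half-open).
#'
#' @param sites an `integration_site_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  lines <- vapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    lo <- min(s$left$pos, s$right$pos); hi <- max(s$left$pos, s$right$pos)
    sprintf("%s\t%d\t%d\tsite%d_%s_%d\t%d\t.", s$left$contig, lo - 1L, hi,
            i, s$lesion$class, s$lesion$length, s$support)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialise a run report to JSON
#'
#' Printed coordinates are 1-based inclusive.
#'
#' @param report a [run_pipeline()] report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  sites <- lapply(seq_along(report$sites), function(i) {
    s <- report$sites[[i]]
    list(site = i, contig = s$left$contig, left = s$left$pos,
         right = s$right$pos, lesion = s$lesion$class,
         lesion_length = s$lesion$length,
         lesion_interval = s$lesion$interval,
         split_support = s$left$split_support + s$right$split_support,
         pair_support = s$left$pair_support + s$right$pair_support)
  })
  x <- list(n_reads = report$n_reads,
            mapped_fraction = report$mapped_fraction,
            mean_coverage = report$mean_coverage,
            background_depth = report$background_depth,
            copy_number = report$copy_number,
            junction_pairs = report$junction_pairs,
            split_reads = report$split_reads,
            sites = sites,
            concatemer_junctions = report$concatemer_junctions,
            microhomology = list(
              boundaries = report$microhomology$boundaries,
              site_pairs = report$microhomology$site_pairs),
            version = report$version)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

write_report_artifacts <- function(report, depth, e2e, loc, reference,
                                   outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_sam(e2e, reference, file.path(outdir, "aligned_e2e.sam"))
  write_sam(loc, reference, file.path(outdir, "aligned_local.sam"))
  write_bedgraph(depth, file.path(outdir, "depth_corrected.bedgraph"),
                 bin_size = 100L)
  write.table(report$copy_number, file.path(outdir, "copy_number.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$boundaries, file.path(outdir, "boundaries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dropped <- report$dropped_boundaries
  if (!is.null(dropped))
    write.table(dropped, file.path(outdir, "dropped_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(report$sites))
    write_sites_bed(report$sites, file.path(outdir, "sites.bed"))
  write_report_json(report, file.path(outdir, "report.json"))
  invisible(outdir)
}
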