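#' @useDynLib isceimap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rnorm runif setNames quantile
#' @importFrom utils head tail write.table
NULL

# Internal sequence helpers ---------------------------------------------------

rc_seq <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(length, gc_fraction = 0.4) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
        collapse = "")
}

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || nchar(x) < 1L)
    stop(what, " must be a single nonempty DNA string")
  if (grepl("[^ACGTNacgtn]", x))
    stop(what, " contains characters outside {A,C,G,T,N}")
  toupper(x)
}

#' Construct a transgene construct description
#'
#' Bundles the construct sequence (the injected cassette: promoter, reporter,
#' vector backbone, flanked by meganuclease-site remnants) with its feature
#' annotation in 1-based inclusive construct coordinates.
#'
#' @param sequence DNA string of the linearized construct.
#' @param features data.frame with columns `label`, `start`, `end` (1-based
#'   inclusive). Recognised labels include `promoter`, `egfp`, `vector`,
#'   `isce1_site_left`, `isce1_site_right`.
#' @return An object of class `transgene_construct`.
#' @export
transgene_construct <- function(sequence, features) {
  sequence <- check_dna(sequence, "construct sequence")
  stopifnot(is.data.frame(features),
            all(c("label", "start", "end") %in% names(features)))
  len <- nchar(sequence)
  if (any(features$start < 1L) || any(features$end > len) ||
      any(features$start > features$end))
    stop("feature intervals must lie within [1, construct length]")
  core <- features[features$label %in% c("promoter", "egfp", "vector"), ]
  if (nrow(core) > 1L) {
    o <- order(core$start)
    if (any(core$start[o][-1L] <= core$end[o][-nrow(core)]))
      stop("promoter/egfp/vector features must not overlap")
  }
  structure(list(sequence = sequence, features = features),
            class = "transgene_construct")
}

construct_feature <- function(construct, label) {
  f <- construct$features[construct$features$label == label, , drop = FALSE]
  if (nrow(f) == 0L) stop("construct has no feature labelled '", label, "'")
  f[1L, ]
}

#' @export
print.transgene_construct <- function(x, ...) {
  cat("transgene_construct:", nchar(x$sequence), "bp,",
      nrow(x$features), "features\n")
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' Build a combined host + transgene reference
#'
#' Appends the transgene construct to the host assembly as an extra contig, the
#' standard trick that lets one aligner pass place reads on either the genome
#' or the cassette and makes host/transgene chimeric fragments visible as
#' discordant pairs and soft-clipped reads.
#'
#' @param host named character vector (or `DNAStringSet`) of host contigs.
#' @param construct a [transgene_construct()].
#' @param transgene_name contig name given to the construct.
#' @param homology optional data.frame (`contig`, `start`, `end`) of regions
#'   where the host genome and the construct share sequence (e.g. an
#'   endogenous promoter also carried by the cassette); depth computation
#'   retains non-uniquely mapped reads inside these.
#' @return Object of class `combined_reference`.
#' @export
build_combined_reference <- function(host, construct,
                                     transgene_name = "transgene",
                                     homology = NULL) {
  if (methods::is(host, "DNAStringSet")) host <- as.character(host)
  if (!is.character(host) || length(host) < 1L)
    stop("host assembly must contain at least one contig")
  if (is.null(names(host)) || any(!nzchar(names(host))) ||
      anyDuplicated(names(host)))
    stop("host contigs must have nonempty unique names")
  if (transgene_name %in% names(host))
    stop("name collision: host already has a contig named '",
         transgene_name, "'")
  host <- toupper(host)
  contigs <- c(host, setNames(construct$sequence, transgene_name))
  structure(list(contigs = contigs,
                 host_names = names(host),
                 transgene = transgene_name,
                 construct = construct,
                 homology = homology),
            class = "combined_reference")
}

#' @export
print.combined_reference <- function(x, ...) {
  cat("combined_reference:", length(x$contigs), "contigs (",
      sum(nchar(x$contigs)), "bp ), transgene contig '", x$transgene, "'\n",
      sep = "")
  invisible(x)
}

ref_seq <- function(reference, contig) {
  s <- reference$contigs[[contig]]
  if (is.null(s)) stop("contig '", contig, "' not in reference")
  s
}

#' Extract the sequence of a genomic interval
#'
#' @param reference a `combined_reference`.
#' @param interval a [genomic_interval()].
#' @return DNA string (reverse-complemented for `-` strand intervals).
#' @export
interval_seq <- function(reference, interval) {
  s <- ref_seq(reference, interval$contig)
  if (interval$start < 1L || interval$end > nchar(s))
    stop("interval outside contig bounds")
  out <- substr(s, interval$start, interval$end)
  if (identical(interval$strand, "-")) out <- rc_seq(out)
  out
}

# FASTA I/O -------------------------------------------------------------------

#' Read a (possibly wrapped) FASTA file into a named character vector
#'
#' Sequences are upper-cased on read so downstream exact-match logic is
#' case-insensitive.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  if (any(!nzchar(names(x)))) stop("malformed FASTA: empty record name")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write an assembly to FASTA
#'
#' @param assembly named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(assembly), path,
                              width = width)
  invisible(path)
}

# Coordinates -----------------------------------------------------------------

#' Create a 1-based inclusive genomic interval
#'
#' All user-facing coordinates in this package are 1-based inclusive (the
#' convention used when printing positions such as boundary base pairs);
#' internal arithmetic uses 0-based half-open intervals via [to_zero_based()].
#'
#' @param contig contig name.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @return Object of class `genomic_interval`.
#' @export
genomic_interval <- function(contig, start, end, strand = ".") {
  stopifnot(length(contig) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("require 1 <= start <= end")
  if (!strand %in% c("+", "-", ".")) stop("strand must be '+', '-' or '.'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' @param interval a [genomic_interval()] (for `to_zero_based`) or a list with
#'   `contig`, `start`, `end` in 0-based half-open coordinates (for
#'   `from_zero_based`).
#' @return The converted interval; the mapping is a bijection that preserves
#'   interval length (`end - start` half-open equals the inclusive width).
#' @export
to_zero_based <- function(interval) {
  list(contig = interval$contig,
       start = interval$start - 1L,
       end = interval$end,
       strand = interval$strand)
}

#' @rdname to_zero_based
#' @export
from_zero_based <- function(interval) {
  genomic_interval(interval$contig, interval$start + 1L, interval$end,
                   strand = if (is.null(interval$strand)) "." else interval$strand)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s)\n", x$contig, x$start, x$end, x$strand))
  invisible(x)
}
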