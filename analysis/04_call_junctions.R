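#!/usr/bin/env Rscript
# Step 4 — call integration sites: discordant junction pairs bracket the
# loci, soft-clipped split reads give base-pair boundaries, boundaries are
# clustered, paired into sites, and the left/right order classifies the
# target-site lesion. Construct-construct (concatemer) junctions are typed
# by the joined termini.

suppressPackageStartupMessages(library(isceimap))

if (!file.exists("results/data/alignments.rds"))
  stop("run analysis/02_align.R first")
sc <- readRDS("results/data/scenario.rds")
aln <- readRDS("results/data/alignments.rds")
ref <- sc$reference

jp <- find_junction_pairs(aln$e2e, ref)
sr <- find_split_reads(aln$local, ref, min_clip = 20, min_remap_score = 15)
bnd <- cluster_boundaries(sr, jp, ref, window = 10, min_support = 3,
                          min_pair_support = 2)
sites <- pair_boundaries_into_sites(bnd, max_span = 10000)
conc <- find_concatemer_junctions(aln$local, ref)

write.table(bnd, "results/boundaries.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(attr(bnd, "dropped"), "results/dropped_candidates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
if (length(sites)) write_sites_bed(sites, "results/sites.bed")
write.table(conc, "results/concatemer_junctions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(sites, "results/data/sites.rds")

cat(sprintf("%d junction pairs, %d split reads -> %d boundaries (%d dropped)\n",
            nrow(jp), nrow(sr), nrow(bnd), nrow(attr(bnd, "dropped"))))
print(sites)
if (length(sites) >= 2)
  cat(sprintf("distance between sites: %d bp\n",
              site_distance(sites[[1]], sites[[2]])))
cat("concatemer junctions:\n")
print(conc, row.names = FALSE)
cat("truth boundaries for comparison:\n")
print(sc$sites_truth, row.names = FALSE)
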