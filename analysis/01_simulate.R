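#!/usr/bin/env Rscript
# Step 1 — build the study fixture: a 1 Mb toy chromosome carrying two
# adjacent concatemeric transgene insertions (11-bp target-site deletion at
# site 1, 15-bp target-site duplication at site 2, closest boundaries 108 bp
# apart, 3+3 construct copies head-to-tail), an endogenous promoter copy
# elsewhere, junction microhomology to the I-SceI site, and 2x101 bp
# paired-end reads at 20x from the hemizygous diploid.

suppressPackageStartupMessages(library(isceimap))

seed <- 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

message("simulating (seed ", seed, ") ...")
sc <- study_scenario(seed = seed)

write_fasta(sc$reference$contigs, "results/data/combined_reference.fa")
write_fastq(sc$reads, "results/data/reads_R1.fastq", "results/data/reads_R2.fastq")
write.table(sc$sites_truth, "results/data/truth_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, read_pairs = length(sc$reads$qname),
       depth = 20, read_length = 101, fragment_mean = 350,
       expected_copies = as.list(sc$expected_copies),
       features = lapply(sc$features, function(f)
         list(contig = f$contig, start = f$start, end = f$end))),
  "results/data/truth_summary.json", auto_unbox = TRUE)
saveRDS(sc, "results/data/scenario.rds")

cat(sprintf("wrote %d read pairs; transgenic allele %d bp vs wild type %d bp\n",
            length(sc$reads$qname), nchar(sc$truth$allele[["chr1_tg"]]),
            nchar(sc$reference$contigs[["chr1"]])))
cat("truth sites:\n")
print(sc$sites_truth, row.names = FALSE)
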