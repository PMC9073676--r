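#!/usr/bin/env Rscript
# Step 3 — depth, GC-bias correction and coverage-ratio copy number.
# A region present c times per diploid genome shows c/2 x the haploid
# background, so copies = 2 * depth/background - endogenous (2 endogenous
# copies for the shared promoter, 0 for cassette-only features).

suppressPackageStartupMessages(library(isceimap))

if (!file.exists("results/data/alignments.rds"))
  stop("run analysis/02_align.R first")
sc <- readRDS("results/data/scenario.rds")
aln <- readRDS("results/data/alignments.rds")
ref <- sc$reference

depth_raw <- compute_depth(aln$e2e, ref)
mask <- rbind(ref$homology[, c("contig", "start", "end")],
              data.frame(contig = ref$transgene, start = 1L,
                         end = nchar(ref$contigs[[ref$transgene]])))
gc_model <- fit_gc_bias(depth_raw, ref, bin_size = 1000, mask = mask)
depth <- correct_gc(depth_raw, gc_model)
bg <- background_depth(depth, ref, mask = mask)
write_bedgraph(depth, "results/depth_corrected.bedgraph", bin_size = 100)

cn <- do.call(rbind, lapply(names(sc$features), function(f) {
  rd <- region_depth(depth, sc$features[[f]])
  est <- estimate_copy_number(rd$mean, bg,
                              endogenous_copies = sc$endogenous[[f]],
                              region_length = sc$features[[f]]$end -
                                sc$features[[f]]$start + 1L)
  data.frame(feature = f, mean_depth = rd$mean, median_depth = rd$median,
             background = bg, endogenous = sc$endogenous[[f]],
             copies_frac = est$copies_frac, copies = est$copies,
             ci_lo = est$ci[1], ci_hi = est$ci[2])
}))
write.table(cn, "results/copy_number.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(depth = depth, gc_model = gc_model, background = bg),
        "results/data/depth.rds")

cat(sprintf("GC decile ratios: %s\n",
            paste(sprintf("%.2f", gc_model$ratio), collapse = " ")))
cat(sprintf("background depth: %.2fx\n", bg))
print(cn, row.names = FALSE, digits = 4)
cat("expected copies (truth):",
    paste(names(sc$expected_copies), sc$expected_copies, collapse = ", "),
    "\n")
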