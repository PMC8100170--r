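#!/usr/bin/env Rscript
# Stage 3: expression specificity of osteocyte genes across tissues.
#
# Median log2 FPKM per tissue (the osteocyte pseudo-tissue pools all its
# samples), quantile-normalised across tissues, then the Tau index per
# gene with the low (< 0.15) / moderate / high (> 0.85) bins.

suppressMessages(library(osteosig))
data_dir <- "results/data"
out <- "results/specificity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fpkm <- read_expression_matrix(file.path(data_dir, "panel_fpkm.tsv"), "FPKM")
samples <- read_sample_table(file.path(data_dir, "panel_samples.tsv"))
truth <- utils::read.delim(file.path(data_dir, "panel_truth.tsv"))

groups <- split(samples$sample_id, samples$tissue)
med <- tissue_medians(fpkm, groups)
tau <- compute_tau(quantile_normalize(med))
utils::write.table(tau, file.path(out, "tau.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("specificity classes:\n")
print(table(tau$spec_class))
planted <- !is.na(truth$specific_tissue)
cat(sprintf("planted tissue-specific genes classified high: %d / %d\n",
            sum(tau$spec_class[planted] == "high"), sum(planted)))
osteo <- truth$specific_tissue == "osteocyte" & planted
cat(sprintf("of which osteocyte-specific: %d\n", sum(osteo, na.rm = TRUE)))

write_run_manifest(file.path(out, "manifest.json"), "tau",
                   inputs = list(fpkm = file.path(data_dir, "panel_fpkm.tsv")),
                   params = list(pseudocount = 1,
                                 bins = c(low = 0.15, high = 0.85)))
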