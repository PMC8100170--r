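#!/usr/bin/env Rscript
# Stage 2: define the genes actively expressed in osteocytes.
#
# Per sample, fit the bimodal log2-FPKM density, place mu at the KDE
# peak, estimate the half-normal spread above it, and call a gene active
# in a skeletal site when zFPKM > -2.6 in every replicate. Pearson
# correlation between samples is computed over the active genes.

suppressMessages(library(osteosig))
data_dir <- "results/data"
out <- "results/activity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fpkm <- read_expression_matrix(file.path(data_dir, "cohort_fpkm.tsv"), "FPKM")
samples <- read_sample_table(file.path(data_dir, "cohort_samples.tsv"))
truth <- utils::read.delim(file.path(data_dir, "cohort_truth.tsv"))

models <- fit_activity_models(fpkm)
model_tab <- do.call(rbind, lapply(models, function(m)
  data.frame(sample_id = m$sample_id, mu = m$mu, sd = m$sd,
             z_cutoff = m$z_cutoff, fpkm_threshold = m$fpkm_threshold)))
utils::write.table(model_tab, file.path(out, "activity_models.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

z <- zfpkm_transform(fpkm, models)
groups <- split(samples$sample_id, samples$tissue)
calls <- call_activity(z, groups)
status <- data.frame(gene_id = rownames(calls),
                     unclass(calls)[, , drop = FALSE], row.names = NULL)
utils::write.table(status, file.path(out, "activity_status.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

active <- active_union(calls)
write_gene_list(active, file.path(out, "active_any_site.txt"))

for (g in colnames(calls)) {
  tab <- table(unclass(calls)[, g])
  cat(sprintf("%-8s active %4d  variable %4d  inactive %4d\n",
              g, tab[["active"]], tab[["variable"]], tab[["inactive"]]))
}
planted <- truth$gene_id[truth$is_active]
tp <- length(intersect(active, planted))
cat(sprintf("active in any site: %d (planted %d; recall %.3f, precision %.3f)\n",
            length(active), length(planted),
            tp / length(planted), tp / length(active)))

corr <- sample_correlation(fpkm, active, groups)
utils::write.table(round(corr$group_means, 4),
                   file.path(out, "between_site_correlation.tsv"),
                   sep = "\t", quote = FALSE)
cat("mean between-site Pearson r:\n")
print(round(corr$group_means, 3))

write_run_manifest(file.path(out, "manifest.json"), "activity",
                   inputs = list(fpkm = file.path(data_dir, "cohort_fpkm.tsv")),
                   params = list(z_cutoff = -2.6, groups_by = "tissue"))
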