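#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Four seeded datasets with the statistical structure each downstream
# stage assumes: a three-site bone cohort with bimodal FPKM (activity
# calling), a 13-tissue panel with planted tissue-specific genes (Tau),
# a paired osteocyte-enriched vs whole-bone count experiment with a
# planted LFC mixture (enrichment), and a differential-expression
# exclusion table marking contaminant-tissue genes (signature filter).

suppressMessages(library(osteosig))
seed <- 20260927L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(seed = seed)
write_expression_matrix(cohort$fpkm, file.path(out, "cohort_fpkm.tsv"))
write_sample_table(cohort$samples, file.path(out, "cohort_samples.tsv"))
utils::write.table(cohort$truth, file.path(out, "cohort_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("cohort: %d genes x %d samples, %d planted active\n",
            nrow(cohort$fpkm), ncol(cohort$fpkm),
            sum(cohort$truth$is_active)))

panel <- simulate_tissue_panel(seed = seed)
write_expression_matrix(panel$fpkm, file.path(out, "panel_fpkm.tsv"))
write_sample_table(panel$samples, file.path(out, "panel_samples.tsv"))
utils::write.table(panel$truth, file.path(out, "panel_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("panel: %d genes, %d tissues, %d planted tissue-specific\n",
            nrow(panel$fpkm), length(unique(panel$samples$tissue)),
            sum(!is.na(panel$truth$specific_tissue))))

enr <- simulate_enrichment_experiment(seed = seed)
write_expression_matrix(enr$counts, file.path(out, "enrichment_counts.tsv"))
write_sample_table(enr$samples, file.path(out, "enrichment_samples.tsv"))
utils::write.table(enr$truth, file.path(out, "enrichment_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("enrichment: %d genes, %d paired animals, %d planted enriched\n",
            nrow(enr$counts), length(unique(enr$samples$animal_id)),
            sum(enr$truth$is_enriched)))

# Contaminant differential-expression table: a slice of genes flagged as
# significantly higher in blood, bone marrow or muscle than bone. Planted
# over the same gene namespace as the enrichment experiment.
set.seed(seed)
n_flag <- 400L
flagged <- sample(enr$truth$gene_id, n_flag)
dge <- data.frame(
  gene = flagged,
  contrast_tissue = sample(c("blood", "bone_marrow", "muscle"), n_flag,
                           replace = TRUE),
  lfc = round(stats::rlnorm(n_flag, log(2), 0.4), 3),
  p_value = signif(stats::runif(n_flag, 1e-6, 0.04), 3),
  stringsAsFactors = FALSE)
utils::write.table(dge, file.path(out, "contaminant_dge.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("exclusion table: %d genes flagged in contaminant tissues\n",
            n_flag))

write_run_manifest(file.path(out, "manifest.json"), "simulate",
                   params = list(cohort = "defaults", panel = "defaults",
                                 enrichment = "defaults",
                                 n_contaminant_flags = n_flag),
                   seed = seed)
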