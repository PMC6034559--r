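#!/usr/bin/env Rscript
# Generate every synthetic input the workflow consumes, with planted
# ground truth: pan-genome (inclusion + exclusion clades), proteomes with
# the 18 published SFB-unique peptides embedded, a qPCR run, the sIgA
# cohort, and a two-group taxon abundance table.

library(raretaxa)

cfg <- sim_config(seed = 1)
outdir <- "results/analysis/inputs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

pg <- generate_pangenome(cfg)
write_genome_set(pg$reference, file.path(outdir, "reference.fasta"))
write_genome_set(pg$inclusion, file.path(outdir, "inclusion.fasta"))
write_genome_set(pg$exclusion, file.path(outdir, "exclusion.fasta"))
write_planted_truth(pg$truth, file.path(outdir, "planted_truth.json"))

prot <- generate_proteomes(cfg)
write_fasta(prot$inclusion, file.path(outdir, "inclusion_proteome.fasta"))
write_fasta(prot$background, file.path(outdir, "background_proteome.fasta"))

cohort <- generate_siga_cohort(cfg)
write.csv(cohort, file.path(outdir, "cohort.csv"), row.names = FALSE)

abund <- generate_abundance_table(cfg)
write.csv(abund, file.path(outdir, "abundance.csv"), row.names = FALSE)

set.seed(cfg$seed + 505L)
loads <- setNames(10^runif(8, 2, 7), sprintf("LF%02d", 1:8))
run <- generate_qpcr_run(cfg, loads)
write.csv(run$curve, file.path(outdir, "qpcr_curve.csv"), row.names = FALSE)
write.csv(run$samples, file.path(outdir, "qpcr_samples.csv"), row.names = FALSE)
write.csv(data.frame(sample_id = names(loads), true_load = loads),
          file.path(outdir, "qpcr_true_loads.csv"), row.names = FALSE)

cat("Planted truth:\n")
cat("  conserved genes:   ", paste(pg$truth$conserved_gene_ids, collapse = ", "), "\n")
cat("  exclusion-shared:  ", paste(pg$truth$exclusion_shared_gene_ids, collapse = ", "), "\n")
cat("  marker genes:      ", paste(pg$truth$marker_gene_ids, collapse = ", "), "\n")
cat("  planted peptides:  ", length(prot$truth$planted_unique_peptides), "\n")
cat("  cohort:            ", nrow(cohort), "subjects (",
    sum(cohort$sfb_status == "positive"), "SFB-positive )\n")
cat("Inputs written to", outdir, "\n")
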