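#!/usr/bin/env Rscript
# Step 1 — generate the synthetic two-strain brainstem study.
#
# Emulated design: 4 treatment (DBA/1-like, seizure-susceptible) vs 4
# control (C57BL/6-like) arrays; log-normal intensities; planted 4-fold
# shifts in both directions; a toy genome carrying all six lncRNA
# positional categories and 115 lincRNA-neighbor pairs with a planted
# direction concordance of 0.685 (the fraction the published study reports).
# Everything downstream (steps 02-06) starts from the files written here.

suppressMessages(library(lncarray))

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg_yaml <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                        package = "lncarray"))
cfg <- do.call(sim_config, utils::modifyList(cfg_yaml$simulate,
                                             list(seed = cfg_yaml$seed)))
print(cfg)

study <- simulate_study(cfg)
write_expression_tsv(study$matrix, file.path(out, "expression_raw.tsv"))
write_groups_tsv(study$groups, file.path(out, "groups.tsv"))
write_gtf(study$annotation, file.path(out, "annotation.gtf"))
write_bed12(study$annotation, file.path(out, "annotation.bed"))

# persist the ground truth so later steps can score their recoveries
truth <- study$truth
utils::write.table(
  data.frame(transcript_id = names(truth$de_status),
             biotype = unname(truth$biotype[names(truth$de_status)]),
             de_status = unname(truth$de_status),
             log2fc = unname(truth$log2fc[names(truth$de_status)])),
  file.path(out, "truth_de_status.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(
  data.frame(lncrna_id = names(truth$true_category),
             category = unname(truth$true_category)),
  file.path(out, "truth_categories.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(truth$true_pairs, file.path(out, "truth_pairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d transcripts x %d samples; %d annotated transcripts\n",
            nrow(study$matrix), ncol(study$matrix),
            nrow(study$annotation$transcripts)))
cat(sprintf("planted DE: %d up, %d down; planted pairs: %d (%d concordant)\n",
            sum(truth$de_status == "up"), sum(truth$de_status == "down"),
            nrow(truth$true_pairs), sum(truth$true_pairs$concordant)))
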