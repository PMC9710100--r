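#!/usr/bin/env Rscript
# Step 6 — descriptive summaries of the DE set.
#
# Length-bin and chromosome distributions of the DE lncRNAs, positional
# category fractions, volcano coordinates, and the hierarchical-clustering
# leaf orders behind the expression heatmap.

suppressMessages(library(lncarray))
out <- "results/analysis"

annotation <- read_gtf(file.path(out, "annotation.gtf"))
norm <- read_expression_tsv(file.path(out, "expression_normalized.tsv"))
de <- utils::read.delim(file.path(out, "de_all.tsv"))
class(de) <- c("de_result", "data.frame")
classes <- utils::read.delim(file.path(out, "classification.tsv"))

bundle <- summarize_de(de, classes = classes, annotation = annotation)
for (comp in c("length_histogram", "chrom_distribution", "category_fractions")) {
  rows <- do.call(rbind, lapply(names(bundle[[comp]]), function(arm) {
    v <- bundle[[comp]][[arm]]
    if (length(v) == 0) return(NULL)
    data.frame(arm = arm, bin = names(v), fraction = unname(v))
  }))
  utils::write.table(rows, file.path(out, paste0("summary_", comp, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
utils::write.table(bundle$volcano_table, file.path(out, "volcano.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

lh <- bundle$length_histogram$all
cat("DE lncRNA length distribution:\n")
for (b in names(lh)) cat(sprintf("  %-10s %.1f%%\n", b, 100 * lh[[b]]))
cf <- bundle$category_fractions$all
cat("DE lncRNA positional categories:\n")
for (b in names(cf)) cat(sprintf("  %-26s %.1f%%\n", b, 100 * cf[[b]]))

de_ids <- de$transcript_id[de$passes_primary]
ord <- suppressWarnings(cluster_order(norm[de_ids, , drop = FALSE]))
writeLines(ord$transcript_order, file.path(out, "cluster_transcript_order.txt"))
writeLines(ord$sample_order, file.path(out, "cluster_sample_order.txt"))
cat(sprintf("clustered %d DE transcripts; sample leaf order: %s\n",
            length(ord$transcript_order), paste(ord$sample_order, collapse = " ")))
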