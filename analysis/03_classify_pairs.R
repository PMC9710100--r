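#!/usr/bin/env Rscript
# Step 3 — positional classification and cis-pairing.
#
# Classifies every annotated lncRNA into one of the six positional
# categories, then builds the two published pair types among primary-filter
# passes: antisense lncRNA / sense mRNA pairs, and intergenic lincRNA /
# nearest coding neighbor pairs within 300 kb (nearest upstream and
# nearest downstream each count), with the direction-concordance summary.

suppressMessages(library(lncarray))
out <- "results/analysis"

annotation <- read_gtf(file.path(out, "annotation.gtf"))
de <- utils::read.delim(file.path(out, "de_all.tsv"))
class(de) <- c("de_result", "data.frame")

classes <- classify_all(annotation)
write_classification(classes, file.path(out, "classification.tsv"))
truth_cat <- utils::read.delim(file.path(out, "truth_categories.tsv"))
hit <- classes$category[match(truth_cat$lncrna_id, classes$lncrna_id)] ==
  truth_cat$category
cat(sprintf("classified %d lncRNAs; planted categories recovered: %.1f%%\n",
            nrow(classes), 100 * mean(hit)))
print(table(classes$category))

as_pairs <- antisense_pairs(classes, de, annotation)
write_pairs_tsv(as_pairs, de, file.path(out, "antisense_pairs.tsv"))
cat(sprintf("antisense pairs: %d rows over %d distinct DE antisense lncRNAs\n",
            nrow(as_pairs), length(unique(as_pairs$lncrna_id))))

linc_pairs <- lincrna_neighbors(annotation, classes, de)
write_pairs_tsv(linc_pairs, de, file.path(out, "lincrna_pairs.tsv"))
cs <- concordance_summary(linc_pairs)
print(cs)
utils::write.table(data.frame(statistic = names(unclass(cs)),
                              value = unlist(unclass(cs))),
                   file.path(out, "lincrna_concordance.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

truth_pairs <- utils::read.delim(file.path(out, "truth_pairs.tsv"))
key <- paste(linc_pairs$lncrna_id, linc_pairs$mrna_id)
cat(sprintf("planted pairs recovered: %d/%d\n",
            sum(paste(truth_pairs$lncrna_id, truth_pairs$mrna_id) %in% key),
            nrow(truth_pairs)))
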