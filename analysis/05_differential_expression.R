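#!/usr/bin/env Rscript
# Multi-criteria differential expression, concordance and overlap.
#
# Three selection rules on the full gene set: fold change > |2| with BH FDR
# Q < 1e-4 for patient-vs-control contrasts; p < 0.001 for direct CCI-vs-RAP
# contrasts; FDR Q < 0.001 for disposition contrasts. The day-1 common gene
# set is checked for direction concordance between trajectories, and the
# day-1/day-14 direct signatures for overlap (both the DE-selected sets and
# the generator's planted truth sets).

suppressPackageStartupMessages(library(septraj))

expr <- read_expression("scratch/cohort/expression.tsv")
meta <- read_metadata("scratch/cohort/metadata.tsv")

de <- lapply(default_comparisons(), function(cmp) {
  records <- de_records(expr, meta, cmp$a, cmp$b)
  list(records = records, selected = select_genes(records, cmp$criteria))
})

counts <- data.frame(
  comparison = names(de),
  n_selected = vapply(de, function(d) length(d$selected), integer(1)),
  row.names = NULL
)
write.table(counts, "results/de_counts.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

conc <- concordance(
  de$cci_day1_vs_control$records, de$rap_day1_vs_control$records,
  de$cci_day1_vs_control$selected, de$rap_day1_vs_control$selected
)
ov_sel <- overlap_report(
  de$cci_vs_rap_day1$selected, de$cci_vs_rap_day14$selected
)
truth <- utils::read.delim("scratch/cohort/truth.tsv", stringsAsFactors = FALSE)
d1_truth <- unique(truth$gene_id[truth$role %in% c("cci_specific", "rap_specific") &
  truth$timepoint == "day1"])
d14_truth <- unique(truth$gene_id[truth$role == "day14_signature"])
ov_truth <- overlap_report(d1_truth, d14_truth)

write.table(
  data.frame(
    quantity = c("day1_common_genes", "day1_percent_same_direction",
      "direct_selected_overlap", "direct_truth_overlap"),
    value = c(conc$n_common, conc$percent_same_direction,
      ov_sel$n_common, ov_truth$n_common)
  ),
  "results/de_set_analysis.tsv", sep = "\t", quote = FALSE, row.names = FALSE
)

print(counts, row.names = FALSE)
cat(sprintf(
  "day-1 sets share %d genes; %.0f%% change in the same direction in both trajectories\n",
  conc$n_common, conc$percent_same_direction
))
cat(sprintf(
  "planted day-1 vs day-14 direct signatures share %d genes (disjoint by design)\n",
  ov_truth$n_common
))
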