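#!/usr/bin/env Rscript
# Load the two packaged hydrolysis datasets, summarise their factor spans,
# and audit every row against the declared applicable ranges. The acid
# table is known to contain two catalyst concentrations outside its own
# stated 9-20 g/kg range; they are reported, not dropped.

suppressMessages(library(sludgekin))
dir.create("results", showWarnings = FALSE)

for (name in c("acid", "alkali")) {
  ds <- if (name == "acid") load_acid_dataset() else load_alkali_dataset()
  message(sprintf("== %s-thermal dataset: %d runs ==", name, nrow(ds$data)))
  for (col in names(ds$ranges)) {
    message(sprintf("  %-14s observed [%g, %g], applicable [%g, %g]",
                    col, min(ds$data[[col]]), max(ds$data[[col]]),
                    ds$ranges[[col]][1], ds$ranges[[col]][2]))
  }
  viol <- validate_ranges(ds, warn = FALSE)
  if (nrow(viol) == 0) {
    message("  all rows inside the applicable ranges")
  } else {
    message(sprintf("  %d out-of-range value(s):", nrow(viol)))
    for (i in seq_len(nrow(viol)))
      message(sprintf("    row %d: %s = %g outside [%g, %g]",
                      viol$row[i], viol$factor[i], viol$value[i],
                      viol$lower[i], viol$upper[i]))
  }
  write.csv(viol, sprintf("results/range_violations_%s.csv", name),
            row.names = FALSE, quote = FALSE)
}
message("wrote results/range_violations_{acid,alkali}.csv")
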