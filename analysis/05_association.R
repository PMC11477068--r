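#!/usr/bin/env Rscript
# Association models on the pooled per-gene feature table: logistic
# regression of the methylation indicator on the six transmit-type counts
# (all genes), and ordinary least squares of 6mA density on the same
# counts (methylated genes only). Uses the high-confidence consistent
# sites and transmissions from both samples.

source("analysis/00_common.R")

pair <- suppressWarnings(suppressMessages(
  run_two_sample(sample_config("sample_a"), sample_config("sample_b"),
                 write = FALSE)))

out_tsv(pair$fit_logistic$terms, "regression_logistic.tsv")
out_tsv(pair$fit_linear$terms, "regression_linear.tsv")
if (nrow(pair$fit_logistic$dropped_terms))
  out_tsv(pair$fit_logistic$dropped_terms, "regression_logistic_dropped.tsv")
write_feature_table(pair$feature_rows,
                    file.path(OUT_DIR, "pair_gene_features.tsv"))

message("logistic model (methylated ~ transmit-type counts):")
print(pair$fit_logistic)
message("linear model (6mA density ~ transmit-type counts, methylated genes):")
print(pair$fit_linear)
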