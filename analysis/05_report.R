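#!/usr/bin/env Rscript
# Stage 5 — the full bound-vs-apo comparison in one reproducible pipeline.
#
# Runs the end-to-end study design with the default configuration: build,
# paired equilibrium runs, the d+theta steered suite against the
# orientation-only control (10 seed-paired replicas per condition), all
# analyses, and the comparison report with the three headline verdicts.

suppressPackageStartupMessages(library(rockbundle))

report <- run_pipeline(run_config(list(
  output = list(dir = "results/analysis/pipeline", write_trajectories = FALSE)
)))

print(report)
message("\nFull artifacts under results/analysis/pipeline/ ",
        "(report.json, report.md, suite and network CSVs).")
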