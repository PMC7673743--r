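#!/usr/bin/env Rscript
# Stage 7 — run the whole pipeline through the orchestrator and write the
# consolidated machine-readable report (this re-executes stages 1-6 inside
# run_pipeline; the numbered scripts above expose the same computations
# stage by stage).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                  value = TRUE)[1])), "_settings.R"))

run <- run_pipeline(study_config())
write_report(run, file.path(RESULTS, "run_report.json"))
print(run)
message("report written to ", file.path(RESULTS, "run_report.json"))
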