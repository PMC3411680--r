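#!/usr/bin/env Rscript
# Stage 2: annotation refinement. Reads the truth annotation produced by
# stage 1 as if it were a raw annotation, joins interrupted fragments
# (gap >80% covered by other TE insertions), filters out annotations whose
# length outside simple repeats is below 20 bp, and classifies copies as
# full-length or incomplete. Writes the refined GFF3 under results/.

suppressPackageStartupMessages(library(telandscape))

copies <- read_te_gff3("results/sim/truth.gff3")
fs <- default_family_specs()
families <- te_families(fs$family_id, fs$order_label, fs$consensus_length)

refined <- refine_annotation(copies, families)

write_te_gff3(refined, "results/refined.gff3")

cat("input copies:", nrow(copies), "-> refined:", nrow(refined), "\n")
cat("full-length:", sum(refined$full_length),
    "| incomplete:", sum(!refined$full_length), "\n")
cat("wrote: results/refined.gff3\n")
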