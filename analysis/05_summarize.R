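#!/usr/bin/env Rscript
# Stage 5: genome census. Builds the six-column TE summary (per order:
# families, copies, full-length/incomplete, DNA amount, percent of genome)
# for the simulated genome, and reruns the same bookkeeping on the
# transcribed per-order rows of the published Laccaria bicolor census to
# reproduce its subtotal, total, composition and density figures.

suppressPackageStartupMessages(library(telandscape))

## simulated genome
copies <- read_te_gff3("results/refined.gff3")
sim <- simulate_te_genome(sim_config(seed = 2026L))
fs <- default_family_specs()
families <- te_families(fs$family_id, fs$order_label, fs$consensus_length)
gsize <- sum(assembly_lengths(sim$assembly))

s <- summarize_te_landscape(copies, families, gsize)
write_census_tsv(s$table, "results/sim_census.tsv")
tot <- s$table[s$table$row_type == "total", ]
cat(sprintf("simulated genome: %d copies, %.2f Mb of TE (%.1f%% of %0.1f Mb;
  %.2f Mb after overlap deduplication)\n",
            tot$n_copies, tot$dna_mb, tot$composition_pct, gsize / 1e6,
            s$masked_bp / 1e6))
cat("density:", density_summary(tot$n_copies, gsize)$rounded,
    "copies/Mb\n\n")

## published census bookkeeping (60 Mb genome)
cen <- summarize_rows(laccaria_census_orders(), 60e6)
write_census_tsv(cen, "results/laccaria_census.tsv")
ctot <- cen[cen$order_label == "Total TE", ]
cat(sprintf("L. bicolor census: %d families, %d copies (%d/%d
  full-length/incomplete), %.2f Mb, %.1f%% of the genome, %d copies/Mb\n",
            ctot$n_families, ctot$n_copies, ctot$n_full_length,
            ctot$n_incomplete, ctot$dna_mb, ctot$composition_pct,
            density_summary(ctot$n_copies, 60e6)$rounded))
cat("wrote: results/sim_census.tsv, results/laccaria_census.tsv\n")
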