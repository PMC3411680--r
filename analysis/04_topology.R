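#!/usr/bin/env Rscript
# Stage 4: genomic topology. Detects nests (TEs inside TEs) and clusters
# (chains within 10 kb), profiles copy density in 10 kb windows, and counts
# nests/clusters in the terminal regions of each chromosome. Writes the
# nest/cluster/density tables under results/.

suppressPackageStartupMessages(library(telandscape))

copies <- read_te_gff3("results/refined.gff3")
sim <- simulate_te_genome(sim_config(seed = 2026L))
lens <- assembly_lengths(sim$assembly)
fs <- default_family_specs()
order_of <- setNames(fs$order_label, fs$family_id)[copies$family_id]
names(order_of) <- copies$copy_id

rep <- topology_report(copies)
write_tsv_table(rep$nests, "results/nests.tsv",
                sort_by = c("chrom", "host_id"))
write_clusters_bed(rep$clusters, "results/clusters.bed")

prof <- density_profile(copies, lens, by_order = unname(order_of))
write_tsv_table(prof, "results/density_10kb.tsv")

# terminal enrichment of cluster spans (1 Mb termini; these 1 Mb
# chromosomes are entirely terminal, so also report a 100 kb scan)
te1 <- suppressMessages(terminal_enrichment(rep$clusters, lens))
te2 <- terminal_enrichment(rep$clusters, lens,
                           topology_params(terminal_region_bp = 100000L))
frac <- nested_or_clustered_fraction(copies, rep, order_of)

cat("nests:", rep$n_nests, "| clusters:", rep$n_clusters,
    "| deduplicated union:", rep$n_features, "\n")
cat(sprintf("nested and/or clustered copies: %.1f%%\n",
            100 * frac$fraction))
if (!is.null(frac$order_share)) {
  print(round(100 * frac$order_share, 1))
}
cat(sprintf("clusters in terminal 100 kb: %d of %d (%.0f%%)\n",
            te2$n_terminal, te2$n_total, 100 * te2$fraction))
cat("wrote: results/nests.tsv, results/clusters.bed,",
    "results/density_10kb.tsv\n")
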