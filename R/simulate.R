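# Synthetic TE landscape generator: genomes with planted copies of known
# family, age, truncation, nesting and clustering, so every pipeline stage
# can be checked against ground truth.

.DNA <- c("A", "C", "G", "T")

#' Default family specifications for the simulator
#'
#' A fungal-genome-like mix: Copia and Gypsy LTR retrotransposons dominate,
#' with TIR elements next and minor LARD, MITE, LINE and Helitron families
#' (about 300 copies across 10 families).
#'
#' @return data.frame: family_id, order_label, consensus_length,
#'   ltr_length (NA for non-LTR orders), copy_count.
#' @export
default_family_specs <- function() {
  data.frame(
    family_id = c("Copia1", "Copia2", "Gypsy1", "Gypsy2", "LARD1",
                  "TIR1", "TIR2", "MITE1", "LINE1", "Helitron1"),
    order_label = c("Copia", "Copia", "Gypsy", "Gypsy", "LARD",
                    "TIR", "TIR", "MITE", "LINE", "Helitron"),
    consensus_length = c(5000L, 4500L, 6000L, 5500L, 4000L,
                         2500L, 2000L, 400L, 5000L, 3500L),
    ltr_length = c(300L, 250L, 350L, 300L, 400L,
                   NA, NA, NA, NA, NA),
    copy_count = c(50L, 40L, 40L, 30L, 10L, 50L, 30L, 20L, 25L, 5L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' The defaults define a desk-scale study system: 3 chromosomes of 1 Mb
#' background carrying ~300 copies, insertion ages drawn from three
#' expansion bursts (0--0.5, 1--5 and 10--57 Mya, equal weights, ages
#' Beta(2,2)-shaped within each burst so episodes peak mid-period), a
#' molecular clock of 1.3e-8 substitutions/site/year and a 2:1
#' transition:transversion bias.
#'
#' @param seed integer RNG seed; equal configs give byte-identical output.
#' @param n_chroms,chrom_length_bp background genome dimensions.
#' @param family_specs as \code{default_family_specs()}.
#' @param age_bins list of c(lo, hi) year ranges of the expansion bursts.
#' @param age_weights mixture weights over the bursts.
#' @param rate_r substitutions/site/year.
#' @param kappa expected transition:transversion count ratio.
#' @param truncation_prob probability a planted copy is 5'- or 3'-truncated.
#' @param truncation_extent range (fractions of length removed) for
#'   truncated copies.
#' @param nest_prob probability a copy is inserted inside an earlier copy.
#' @param cluster_prob probability a (non-nested) copy is placed within
#'   \code{cluster_max_gap_bp} of an earlier copy.
#' @param cluster_max_gap_bp upper bound of the planted cluster gap.
#' @param gc background and consensus GC content.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_chroms = 3L, chrom_length_bp = 1e6,
                       family_specs = default_family_specs(),
                       age_bins = list(c(0, 0.5e6), c(1e6, 5e6),
                                       c(10e6, 57e6)),
                       age_weights = c(1, 1, 1) / 3,
                       rate_r = 1.3e-8, kappa = 2,
                       truncation_prob = 0.7,
                       truncation_extent = c(0.05, 0.8),
                       nest_prob = 0.3, cluster_prob = 0.4,
                       cluster_max_gap_bp = 9000L, gc = 0.5) {
  stopifnot(truncation_prob >= 0, truncation_prob <= 1,
            nest_prob >= 0, nest_prob <= 1,
            cluster_prob >= 0, cluster_prob <= 1,
            nest_prob + cluster_prob <= 1,
            rate_r > 0, kappa > 0, chrom_length_bp > 0)
  structure(as.list(environment()), class = "sim_config")
}

.random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.DNA, n, replace = TRUE, prob = p), collapse = "")
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate a family consensus sequence
#'
#' LTR orders get exactly identical terminal repeats of \code{ltr_length};
#' TIR/MITE orders get reverse-complement terminal inverted repeats (30 bp
#' or \code{ltr_length} when given); other orders are plain random
#' sequence.
#'
#' @param order_label TE order.
#' @param consensus_length total consensus length in bp.
#' @param ltr_length terminal repeat length for LTR orders (must be smaller
#'   than half the consensus).
#' @param gc GC content.
#' @return Character consensus sequence.
#' @export
make_consensus <- function(order_label, consensus_length, ltr_length = NA,
                           gc = 0.5) {
  if (has_ltr(order_label)) {
    stopifnot(!is.na(ltr_length))
    if (ltr_length >= consensus_length / 2) {
      stop("ltr_length must be below half the consensus length")
    }
    ltr <- .random_dna(ltr_length, gc)
    internal <- .random_dna(consensus_length - 2 * ltr_length, gc)
    return(paste0(ltr, internal, ltr))
  }
  if (order_label %in% c("TIR", "MITE")) {
    tir_len <- if (!is.na(ltr_length)) ltr_length
               else min(30L, floor(consensus_length / 3))
    tir <- .random_dna(tir_len, gc)
    internal <- .random_dna(consensus_length - 2 * tir_len, gc)
    return(paste0(tir, internal, .revcomp(tir)))
  }
  .random_dna(consensus_length, gc)
}

# K2P per-site transition probabilities after time t at total rate r and
# ts:tv count ratio kappa (alpha = transition rate, beta = each
# transversion rate; r = alpha + 2 beta, kappa = alpha / (2 beta))
.k2p_site_probs <- function(rt, kappa) {
  beta <- rt / (2 * kappa + 2)
  alpha <- 2 * kappa * beta
  e1 <- exp(-4 * beta)
  e2 <- exp(-2 * (alpha + beta))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1  # each of the two transversion targets
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

#' Mutate a sequence according to its age
#'
#' Applies the Kimura two-parameter substitution process site-by-site for a
#' divergence of \code{r * age_years} expected substitutions per site, with
#' transitions favoured by \code{kappa}. Applied independently to each LTR
#' copy of an element, the expected pairwise K2P distance between the two
#' LTRs is ~ 2 r age. No indels are introduced.
#'
#' @param seq nucleotide string.
#' @param age_years elapsed time in years (>= 0).
#' @param rate_r substitutions per site per year.
#' @param kappa expected transition:transversion count ratio.
#' @return Mutated sequence string.
#' @export
mutate_by_age <- function(seq, age_years, rate_r = 1.3e-8, kappa = 2) {
  stopifnot(age_years >= 0)
  if (age_years == 0) return(seq)
  pr <- .k2p_site_probs(rate_r * age_years, kappa)
  x <- strsplit(seq, "")[[1]]
  is_base <- x %in% .DNA
  ev <- sample(c("same", "ts", "tv"), length(x), replace = TRUE,
               prob = c(pr[["same"]], pr[["ts"]], 2 * pr[["tv"]]))
  ts_idx <- which(ev == "ts" & is_base)
  x[ts_idx] <- .TS_PARTNER[x[ts_idx]]
  tv_idx <- which(ev == "tv" & is_base)
  for (i in tv_idx) x[i] <- sample(.TV_PARTNERS[[x[i]]], 1)
  paste(x, collapse = "")
}

#' Simulate one LTR pair of known age
#'
#' Builds a random LTR and mutates two copies independently for
#' \code{age_years} each, emulating the divergence of the 5' and 3' LTRs of
#' an element inserted \code{age_years} ago.
#'
#' @param age_years true insertion age.
#' @param ltr_length LTR length in bp (default 300).
#' @param rate_r,kappa,gc as in \code{sim_config}.
#' @return List with \code{ltr5}, \code{ltr3}, \code{age_years}.
#' @export
sim_ltr_pair <- function(age_years, ltr_length = 300L, rate_r = 1.3e-8,
                         kappa = 2, gc = 0.5) {
  anc <- .random_dna(ltr_length, gc)
  list(ltr5 = mutate_by_age(anc, age_years, rate_r, kappa),
       ltr3 = mutate_by_age(anc, age_years, rate_r, kappa),
       age_years = age_years)
}

.draw_age <- function(config) {
  k <- sample.int(length(config$age_bins), 1, prob = config$age_weights)
  b <- config$age_bins[[k]]
  b[1] + (b[2] - b[1]) * rbeta(1, 2, 2)
}

#' Simulate a genome with a planted TE landscape
#'
#' Generates background chromosomes, consensus sequences per family, and
#' plants copies one by one: with \code{nest_prob} a copy is inserted
#' strictly inside an earlier copy (the host's ground-truth span is
#' extended across the interruption, matching the representation fragment
#' joining reconstructs); with \code{cluster_prob} it lands within the
#' cluster gap of an earlier copy; otherwise at a uniform position outside
#' existing copies. Truncated copies lose a random prefix or suffix. All
#' coordinates in the returned truth are 0-based half-open on the final
#' assembly.
#'
#' @param config a \code{sim_config()}.
#' @return List with \code{assembly} (DNAStringSet), \code{copies} (truth
#'   as a TE copy table with extra columns true_age_years, truncated,
#'   nest_parent, cluster_id), \code{families}, \code{consensus} (named
#'   character vector), \code{config}.
#' @export
simulate_te_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  fs <- config$family_specs
  consensus <- setNames(
    vapply(seq_len(nrow(fs)), function(i)
      make_consensus(fs$order_label[i], fs$consensus_length[i],
                     fs$ltr_length[i], config$gc), character(1)),
    fs$family_id)
  families <- te_families(fs$family_id, fs$order_label, fs$consensus_length)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- setNames(
    vapply(chroms, function(ch)
      .random_dna(config$chrom_length_bp, config$gc), character(1)),
    chroms)

  truth <- data.frame(
    copy_id = character(), family_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    cons_start = integer(), cons_end = integer(),
    identity_pct = numeric(), full_length = logical(),
    true_age_years = numeric(), truncated = logical(),
    nest_parent = character(), stringsAsFactors = FALSE)

  plan <- fs[rep(seq_len(nrow(fs)), fs$copy_count),
             c("family_id", "order_label"), drop = FALSE]
  plan <- plan[sample.int(nrow(plan)), , drop = FALSE]

  n_skipped <- 0L
  for (i in seq_len(nrow(plan))) {
    fam <- plan$family_id[i]
    cons <- consensus[[fam]]
    age <- .draw_age(config)
    elem <- mutate_by_age(cons, age, config$rate_r, config$kappa)
    mism <- mapply(function(a, b) sum(a != b),
                   strsplit(elem, ""), strsplit(cons, ""))
    identity <- 100 * (1 - mism / nchar(cons))
    cons_start <- 0L; cons_end <- nchar(cons)
    truncated <- runif(1) < config$truncation_prob
    if (truncated) {
      cut <- round(nchar(elem) *
                     runif(1, config$truncation_extent[1],
                           config$truncation_extent[2]))
      cut <- min(cut, nchar(elem) - 50L)  # keep a usable stub
      if (cut > 0) {
        if (runif(1) < 0.5) {
          elem <- substr(elem, cut + 1L, nchar(elem))
          cons_start <- cons_start + cut
        } else {
          elem <- substr(elem, 1L, nchar(elem) - cut)
          cons_end <- cons_end - cut
        }
      } else truncated <- FALSE
    }
    strand <- sample(c("+", "-"), 1)
    ins_seq <- if (strand == "-") .revcomp(elem) else elem
    L <- nchar(ins_seq)

    u <- runif(1)
    mode <- if (u < config$nest_prob && nrow(truth) > 0) "nest"
            else if (u < config$nest_prob + config$cluster_prob &&
                     nrow(truth) > 0) "cluster"
            else "random"
    placed <- FALSE
    nest_parent <- NA_character_
    for (try in 1:50) {
      if (mode == "nest") {
        host <- truth[sample.int(nrow(truth), 1), ]
        if (host$end - host$start < 3) next
        p <- host$start + sample.int(host$end - host$start - 1L, 1)
        ch <- host$chrom
        # ground truth records the innermost element containing the
        # insertion point (the chosen host may itself hold earlier inserts)
        enc <- truth[truth$chrom == ch & truth$start < p & p < truth$end, ,
                     drop = FALSE]
        nest_parent <- enc$copy_id[which.min(enc$end - enc$start)]
      } else if (mode == "cluster") {
        anchor <- truth[sample.int(nrow(truth), 1), ]
        gap <- sample.int(config$cluster_max_gap_bp, 1)
        p <- if (runif(1) < 0.5) anchor$end + gap else anchor$start - gap
        ch <- anchor$chrom
        if (p < 0 || p > nchar(seqs[[ch]])) next
        tr <- truth[truth$chrom == ch, , drop = FALSE]
        if (any(tr$start < p & p < tr$end)) next  # would nest accidentally
        nest_parent <- NA_character_
      } else {
        ch <- sample(chroms, 1)
        p <- sample.int(nchar(seqs[[ch]]) + 1L, 1) - 1L
        tr <- truth[truth$chrom == ch, , drop = FALSE]
        if (any(tr$start < p & p < tr$end)) next
        nest_parent <- NA_character_
      }
      # insert and shift existing truth coordinates
      seqs[[ch]] <- paste0(substr(seqs[[ch]], 1, p),
                           ins_seq,
                           substr(seqs[[ch]], p + 1L, nchar(seqs[[ch]])))
      on_ch <- truth$chrom == ch
      spans <- on_ch & truth$start < p & p < truth$end
      after <- on_ch & truth$start >= p
      truth$end[spans] <- truth$end[spans] + L
      truth$start[after] <- truth$start[after] + L
      truth$end[after] <- truth$end[after] + L
      truth <- rbind(truth, data.frame(
        copy_id = sprintf("sim_%04d", i), family_id = fam, chrom = ch,
        start = p, end = p + L, strand = strand,
        cons_start = cons_start, cons_end = cons_end,
        identity_pct = identity, full_length = !truncated,
        true_age_years = age, truncated = truncated,
        nest_parent = nest_parent, stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed) {
      n_skipped <- n_skipped + 1L
      message("placement failed for copy ", i, " (", fam, "); skipped")
    }
  }
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  truth$cluster_id <- .truth_cluster_ids(truth)
  assembly <- Biostrings::DNAStringSet(seqs)
  validate_copies(truth, assembly_lengths(assembly))
  list(assembly = assembly, copies = truth, families = families,
       consensus = consensus, config = config, n_skipped = n_skipped)
}

# single-linkage labelling of the planted copies (<= 10 kb end-to-start
# gaps chain; singletons get NA)
.truth_cluster_ids <- function(truth, gap_bp = 10000L) {
  ids <- rep(NA_integer_, nrow(truth))
  cid <- 0L
  for (ch in unique(truth$chrom)) {
    idx <- which(truth$chrom == ch)
    open <- idx[1]; max_end <- truth$end[idx[1]]
    for (i in idx[-1]) {
      if (truth$start[i] - max_end <= gap_bp) {
        open <- c(open, i)
      } else {
        if (length(open) >= 2) {
          cid <- cid + 1L; ids[open] <- cid
        }
        open <- i
      }
      max_end <- max(max_end, truth$end[i])
    }
    if (length(open) >= 2) {
      cid <- cid + 1L; ids[open] <- cid
    }
  }
  ids
}

#' Write simulator output to disk
#'
#' Emits the genome FASTA, the truth annotation as GFF3 and TSV, and a
#' config echo (key = value lines).
#'
#' @param sim output of \code{simulate_te_genome}.
#' @param dir output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(sim$assembly, fa)
  gff <- file.path(dir, "truth.gff3")
  write_te_gff3(sim$copies, gff, source = "telandscape_sim")
  tsv <- file.path(dir, "truth.tsv")
  write_tsv_table(sim$copies, tsv, sort_by = c("chrom", "start"))
  cfgf <- file.path(dir, "config.txt")
  cfg <- sim$config
  simple <- vapply(cfg, function(x) is.atomic(x) && length(x) <= 3,
                   logical(1))
  writeLines(paste0(names(cfg)[simple], " = ",
                    vapply(cfg[simple], function(x)
                      paste(format(x), collapse = ","), character(1))),
             cfgf)
  invisible(c(fasta = fa, gff3 = gff, tsv = tsv, config = cfgf))
}
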