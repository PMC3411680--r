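# Genome summary bookkeeping: per-order copy numbers, full-length /
# incomplete split, DNA amount and percent composition, with class
# subtotals and a grand total, in the layout of a genome TE census table.

.ORDER_ROW_ORDER <- c("ERV", "Copia", "Gypsy", "LARD", "DIRS",
                      "Tad", "Deceiver", "L1", "LINE",
                      "TIR", "Helitron", "MITE", "unclassified")

#' Summary arithmetic over per-order rows
#'
#' Takes leaf rows (one per TE order) and computes composition percentages,
#' the LTR and non-LTR sub-subtotals, class I / class II / fragment
#' subtotals and the grand total. This is the bookkeeping layer used both
#' on counted copies (\code{summarize_te_landscape}) and on externally
#' transcribed census rows.
#'
#' @param order_rows data.frame with columns order_label, n_families,
#'   n_copies, n_full_length, n_incomplete, dna_mb (full/incomplete may be
#'   NA for fragment rows).
#' @param genome_size_bp genome size in bp (> 0).
#' @return data.frame of leaf rows plus subtotal/total rows, with
#'   \code{row_type} in \{order, subtotal, total\} and
#'   \code{composition_pct} = 100 * dna_mb / genome Mb.
#' @export
summarize_rows <- function(order_rows, genome_size_bp) {
  if (genome_size_bp <= 0) stop("genome size must be positive")
  genome_mb <- genome_size_bp / 1e6
  r <- order_rows
  r$class_label <- te_class_of(r$order_label)
  r <- r[order(match(r$order_label, .ORDER_ROW_ORDER)), , drop = FALSE]
  agg <- function(label, rows, class_label) {
    data.frame(
      order_label = label,
      n_families = sum(rows$n_families),
      n_copies = sum(rows$n_copies),
      n_full_length = if (all(is.na(rows$n_full_length))) NA_integer_
                      else sum(rows$n_full_length, na.rm = TRUE),
      n_incomplete = if (all(is.na(rows$n_incomplete))) NA_integer_
                     else sum(rows$n_incomplete, na.rm = TRUE),
      dna_mb = sum(rows$dna_mb),
      class_label = class_label,
      stringsAsFactors = FALSE
    )
  }
  ltr <- r[r$order_label %in% .LTR_ORDERS, , drop = FALSE]
  nonltr <- r[r$class_label == "I" & !r$order_label %in% .LTR_ORDERS, ,
              drop = FALSE]
  cls1 <- r[r$class_label == "I", , drop = FALSE]
  cls2 <- r[r$class_label == "II", , drop = FALSE]
  frag <- r[r$class_label == "fragment", , drop = FALSE]
  out <- rbind(
    if (nrow(ltr)) cbind(agg("LTR", ltr, "I"), row_type = "subtotal"),
    if (nrow(ltr)) cbind(ltr, row_type = "order"),
    if (nrow(nonltr)) cbind(agg("Non-LTR", nonltr, "I"),
                            row_type = "subtotal"),
    if (nrow(nonltr)) cbind(nonltr, row_type = "order"),
    cbind(agg("Total Class I", cls1, "I"), row_type = "subtotal"),
    if (nrow(cls2)) cbind(cls2, row_type = "order"),
    cbind(agg("Total Class II", cls2, "II"), row_type = "subtotal"),
    if (nrow(frag)) cbind(cbind(frag, row_type = "order")),
    cbind(agg("Total TE", r, "all"), row_type = "total")
  )
  out$composition_pct <- 100 * out$dna_mb / genome_mb
  rownames(out) <- NULL
  out[, c("order_label", "class_label", "row_type", "n_families",
          "n_copies", "n_full_length", "n_incomplete", "dna_mb",
          "composition_pct")]
}

#' Summarize a refined annotation into a genome TE census
#'
#' Per order: number of families with at least one copy, copy number,
#' full-length / incomplete split, DNA amount (each copy contributes its
#' full genomic span -- overlapping copies are not merged, matching
#' per-row census conventions) and percent of genome. Fragment
#' (unclassified) rows carry NA for the full/incomplete split. A
#' deduplicated masked-bp figure is also returned for transparency.
#'
#' @param copies refined, flagged copy table.
#' @param families family table.
#' @param genome_size_bp genome size in bp (a parameter, not inferred from
#'   the FASTA, so summaries over subsets stay comparable).
#' @return List with \code{table} (see \code{summarize_rows}) and
#'   \code{masked_bp} (bp covered by at least one copy).
#' @export
summarize_te_landscape <- function(copies, families, genome_size_bp) {
  if (genome_size_bp <= 0) stop("genome size must be positive")
  ord_of <- setNames(families$order_label, families$family_id)
  ords <- ord_of[copies$family_id]
  ords[is.na(ords)] <- "unclassified"
  rows <- lapply(unique(families$order_label), function(o) {
    idx <- which(ords == o)
    fams <- unique(copies$family_id[idx])
    fl <- copies$full_length[idx]
    is_frag <- te_class_of(o) == "fragment"
    data.frame(
      order_label = o,
      n_families = length(fams),
      n_copies = length(idx),
      n_full_length = if (is_frag) NA_integer_ else sum(fl, na.rm = TRUE),
      n_incomplete = if (is_frag) NA_integer_
                     else sum(!fl, na.rm = TRUE) + sum(is.na(fl)),
      dna_mb = sum(copies$end[idx] - copies$start[idx]) / 1e6,
      stringsAsFactors = FALSE
    )
  })
  order_rows <- do.call(rbind, rows)
  masked <- 0L
  for (ch in unique(copies$chrom)) {
    d <- copies[copies$chrom == ch, , drop = FALSE]
    masked <- masked + sum(IRanges::width(
      IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))))
  }
  list(table = summarize_rows(order_rows, genome_size_bp),
       masked_bp = masked)
}

#' Genome-wide TE copy density
#'
#' @param n_copies total copy count (or a copy table).
#' @param genome_size_bp genome size in bp (> 0).
#' @return List with \code{copies_per_mb} (exact) and \code{rounded}
#'   (nearest integer, the reporting convention).
#' @export
density_summary <- function(n_copies, genome_size_bp) {
  stopifnot(genome_size_bp > 0)
  if (is.data.frame(n_copies)) n_copies <- nrow(n_copies)
  d <- n_copies / (genome_size_bp / 1e6)
  list(copies_per_mb = d, rounded = round(d))
}

#' Write a census table in the six-column layout
#'
#' Columns: TE type, Family, Copy number, Full length/incomplete, DNA
#' amount (Mb), TE composition in genome (\%); Mb and percentages at two
#' decimals; byte-identical across runs on equal input.
#'
#' @param summary_table output \code{table} of \code{summarize_rows} /
#'   \code{summarize_te_landscape}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_census_tsv <- function(summary_table, path) {
  s <- summary_table
  df <- data.frame(
    `TE type` = s$order_label,
    Family = s$n_families,
    `Copy number` = s$n_copies,
    `Full length/incomplete` = ifelse(
      is.na(s$n_full_length), "-",
      paste0(s$n_full_length, "/", s$n_incomplete)),
    `DNA amount (Mb)` = sprintf("%.2f", s$dna_mb),
    `TE composition in genome (%)` = sprintf("%.2f", s$composition_pct),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
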