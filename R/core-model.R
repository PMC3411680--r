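#' @importFrom stats setNames na.omit runif rbeta
#' @importFrom utils read.table write.table
NULL

#' Per-order rows of the published Laccaria bicolor TE census
#'
#' The leaf rows (one per TE order) of the genome-wide TE census of the
#' 60 Mb *Laccaria bicolor* S238N-H82 assembly: family counts, copy
#' numbers, full-length/incomplete splits and DNA amounts. Fragment rows
#' carry NA for the full/incomplete split (fragments are excluded from that
#' bookkeeping). Input for \code{summarize_rows()}, which recomputes the
#' subtotal, total, composition and density figures.
#'
#' @return data.frame with columns order_label, n_families, n_copies,
#'   n_full_length, n_incomplete, dna_mb.
#' @export
laccaria_census_orders <- function() {
  path <- system.file("extdata", "laccaria_bicolor_te_census_orders.tsv",
                      package = "telandscape", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Fixed order -> class mapping (class I retroelements, class II DNA
# transposons, unclassified fragments).
.TE_ORDERS <- c(
  ERV = "I", Copia = "I", Gypsy = "I", LARD = "I", DIRS = "I",
  Tad = "I", Deceiver = "I", L1 = "I", LINE = "I",
  TIR = "II", Helitron = "II", MITE = "II",
  unclassified = "fragment"
)

.LTR_ORDERS <- c("ERV", "Copia", "Gypsy", "LARD", "DIRS")

#' Known TE order labels
#'
#' @return Character vector of the recognised TE order labels.
#' @export
te_orders <- function() names(.TE_ORDERS)

#' Map a TE order label to its class
#'
#' Class I elements transpose through an RNA intermediate (LTR
#' retrotransposons and LINE-like elements), class II through a DNA
#' intermediate (TIR elements, Helitrons, MITEs); unclassified repeats are
#' carried as "fragment".
#'
#' @param order_label character vector of order labels.
#' @return Character vector with elements in \code{c("I","II","fragment")}.
#' @export
te_class_of <- function(order_label) {
  cls <- unname(.TE_ORDERS[order_label])
  if (anyNA(cls)) {
    stop("unknown TE order label(s): ",
         paste(unique(order_label[is.na(cls)]), collapse = ", "))
  }
  cls
}

#' Does a TE order carry long terminal repeats?
#'
#' @param order_label character vector of order labels.
#' @return Logical vector, TRUE for the LTR retrotransposon orders.
#' @export
has_ltr <- function(order_label) order_label %in% .LTR_ORDERS

#' Construct a TE family table
#'
#' @param family_id character vector of unique family names.
#' @param order_label order label per family (see \code{te_orders()}).
#' @param consensus_length consensus sequence length in bp (> 0).
#' @return data.frame with columns family_id, order_label, class_label,
#'   consensus_length, has_ltr.
#' @export
te_families <- function(family_id, order_label, consensus_length) {
  stopifnot(!anyDuplicated(family_id), all(consensus_length > 0))
  data.frame(
    family_id = as.character(family_id),
    order_label = as.character(order_label),
    class_label = te_class_of(order_label),
    consensus_length = as.integer(consensus_length),
    has_ltr = has_ltr(order_label),
    stringsAsFactors = FALSE
  )
}

#' Construct a TE copy table
#'
#' Genomic and consensus coordinates use the internal 0-based half-open
#' convention; converters from GFF3 and RepeatMasker own the +/-1 arithmetic.
#' Minus-strand copies keep unflipped genomic coordinates; sequence
#' extraction reverse-complements on demand.
#'
#' @param copy_id unique copy identifiers.
#' @param family_id family of each copy.
#' @param chrom chromosome / linkage-group name.
#' @param start,end 0-based half-open genomic interval, start < end.
#' @param strand "+" or "-".
#' @param cons_start,cons_end 0-based half-open span on the family consensus
#'   (NA when unknown).
#' @param identity_pct percent identity to the consensus in [0, 100].
#' @param full_length logical flag (default NA until classified).
#' @return data.frame with one row per copy.
#' @export
te_copies <- function(copy_id, family_id, chrom, start, end,
                      strand = "+", cons_start = NA_integer_,
                      cons_end = NA_integer_, identity_pct = NA_real_,
                      full_length = NA) {
  n <- length(copy_id)
  df <- data.frame(
    copy_id = as.character(copy_id),
    family_id = rep_len(as.character(family_id), n),
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    cons_start = rep_len(as.integer(cons_start), n),
    cons_end = rep_len(as.integer(cons_end), n),
    identity_pct = rep_len(as.numeric(identity_pct), n),
    full_length = rep_len(as.logical(full_length), n),
    stringsAsFactors = FALSE
  )
  validate_copies(df)
  df
}

#' Validate a TE copy table
#'
#' Checks the interval, strand and identity invariants; optionally checks
#' intervals against chromosome lengths.
#'
#' @param copies copy table as from \code{te_copies()}.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @return The input, invisibly; errors on violation.
#' @export
validate_copies <- function(copies, chrom_lengths = NULL) {
  stopifnot(is.data.frame(copies))
  if (nrow(copies) == 0) return(invisible(copies))
  if (anyDuplicated(copies$copy_id)) stop("duplicate copy_id")
  if (any(copies$start < 0) || any(copies$start >= copies$end)) {
    stop("invalid interval: require 0 <= start < end")
  }
  if (!all(copies$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ok_id <- is.na(copies$identity_pct) |
    (copies$identity_pct >= 0 & copies$identity_pct <= 100)
  if (!all(ok_id)) stop("identity_pct outside [0, 100]")
  have_cons <- !is.na(copies$cons_start) & !is.na(copies$cons_end)
  if (any(have_cons & copies$cons_start >= copies$cons_end)) {
    stop("invalid consensus span: require cons_start < cons_end")
  }
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[copies$chrom]
    if (anyNA(len)) stop("copy on unknown chromosome")
    if (any(copies$end > len)) stop("copy extends past chromosome end")
  }
  invisible(copies)
}

#' Chromosome lengths of an assembly
#'
#' @param assembly a \code{Biostrings::DNAStringSet} (or named character
#'   vector of sequences).
#' @return Named integer vector of lengths in bp.
#' @export
assembly_lengths <- function(assembly) {
  if (is.character(assembly)) return(setNames(nchar(assembly), names(assembly)))
  setNames(Biostrings::width(assembly), names(assembly))
}

#' Extract the genomic sequence of a copy
#'
#' Reverse-complements for minus-strand copies so the returned sequence
#' reads in element orientation.
#'
#' @param assembly \code{DNAStringSet} genome.
#' @param copy one-row slice of a copy table.
#' @return Character scalar (A/C/G/T/N).
#' @export
copy_sequence <- function(assembly, copy) {
  s <- Biostrings::subseq(assembly[[copy$chrom]], copy$start + 1L, copy$end)
  if (copy$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Merge simple-repeat intervals into a clean track
#'
#' @param intervals data.frame with columns chrom, start, end
#'   (0-based half-open).
#' @return data.frame of merged, sorted, non-overlapping intervals.
#' @export
simple_repeat_track <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  stopifnot(all(intervals$start >= 0), all(intervals$start < intervals$end))
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
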