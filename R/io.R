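# Readers/writers for the standard annotation formats the pipeline touches.
# All converters translate 1-based inclusive file coordinates to the
# internal 0-based half-open convention on the way in, and back on the way
# out.

.parse_order_label <- function(class_family) {
  known <- te_orders()
  parts <- strsplit(class_family, "/", fixed = TRUE)[[1]]
  # prefer the most specific token; RepeatMasker writes e.g. LTR/Copia,
  # LINE/Tad, DNA/TIR, RC/Helitron
  for (tok in rev(parts)) {
    hit <- known[tolower(known) == tolower(tok)]
    if (length(hit)) return(hit[1])
    if (tolower(tok) %in% c("line", "l1")) return("LINE")
  }
  "unclassified"
}

#' Read a RepeatMasker .out annotation file
#'
#' Parses the standard RepeatMasker column layout (three header lines, then
#' score, divergence, deletion and insertion percentages, query name and
#' 1-based inclusive coordinates, strand, repeat name, class/family, repeat
#' coordinates, ID). Query coordinates are converted to 0-based half-open;
#' strand "C" maps to "-"; percent identity is 100 minus the divergence.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return List with elements \code{copies} (TE copy table) and
#'   \code{families} (family table deduplicated by repeat name, consensus
#'   length inferred from repeat end + remaining bases).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character()
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) {
    return(list(
      copies = te_copies(character(), character(), character(),
                         integer(), integer()),
      families = te_families(character(), character(), integer())
    ))
  }
  rows <- vector("list", n)
  fam_name <- character(n); fam_order <- character(n); fam_len <- integer(n)
  strip_paren <- function(x) as.integer(gsub("[()]", "", x))
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 14) {
      stop("malformed RepeatMasker row at line ", i + 3L, ": ", lines[i])
    }
    qbeg <- suppressWarnings(as.integer(f[6]))
    qend <- suppressWarnings(as.integer(f[7]))
    div <- suppressWarnings(as.numeric(f[2]))
    if (anyNA(c(qbeg, qend, div)) || qbeg < 1 || qend < qbeg) {
      stop("malformed RepeatMasker row at line ", i + 3L, ": ", lines[i])
    }
    strand <- if (f[9] %in% c("C", "-")) "-" else "+"
    ord <- .parse_order_label(f[11])
    if (ord == "unclassified" && f[11] != "Unknown") {
      message("line ", i + 3L, ": unknown class string '", f[11],
              "' -> unclassified")
    }
    # repeat coords: '+' rows are begin end (left); 'C' rows (left) end begin
    if (strand == "+") {
      rbeg <- strip_paren(f[12]); rend <- strip_paren(f[13])
      rleft <- strip_paren(f[14])
    } else {
      rleft <- strip_paren(f[12]); rend <- strip_paren(f[13])
      rbeg <- strip_paren(f[14])
    }
    rows[[i]] <- data.frame(
      copy_id = if (length(f) >= 15) paste0("rm_", f[15], "_", i)
                else paste0("rm_", i),
      family_id = f[10], chrom = f[5],
      start = qbeg - 1L, end = qend,
      strand = strand,
      cons_start = rbeg - 1L, cons_end = rend,
      identity_pct = 100 - div,
      full_length = NA,
      stringsAsFactors = FALSE
    )
    fam_name[i] <- f[10]; fam_order[i] <- ord
    fam_len[i] <- rend + rleft
  }
  copies <- do.call(rbind, rows)
  validate_copies(copies)
  keep <- !duplicated(fam_name)
  cons_len <- tapply(fam_len, fam_name, max)
  families <- te_families(fam_name[keep], fam_order[keep],
                          as.integer(cons_len[fam_name[keep]]))
  list(copies = copies, families = families)
}

#' Read TE copies from a GFF3 file
#'
#' Expects one feature per copy with a \code{family_id} attribute; optional
#' attributes \code{identity}, \code{cons_start}/\code{cons_end} (0-based
#' half-open on the consensus) and \code{full_length}. Records lacking
#' \code{family_id} are rejected with a message. Features with strand "."
#' are stored as "+" (logged).
#'
#' @param path path to a GFF3 file.
#' @return TE copy table (0-based half-open coordinates).
#' @export
read_te_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr))
  getattr <- function(nm, default) {
    if (nm %in% names(mc)) mc[[nm]] else rep(default, length(gr))
  }
  fam <- as.character(getattr("family_id", NA_character_))
  drop <- is.na(fam)
  if (any(drop)) {
    message(sum(drop), " GFF3 record(s) without family_id attribute rejected")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*" & !drop)) {
    message(sum(strand == "*" & !drop),
            " feature(s) with strand '.' stored as '+'")
  }
  strand[strand == "*"] <- "+"
  id <- as.character(getattr("ID", NA_character_))
  if (anyNA(id[!drop])) id[is.na(id)] <- paste0("gff_", seq_along(id)[is.na(id)])
  copies <- data.frame(
    copy_id = id,
    family_id = fam,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    cons_start = as.integer(getattr("cons_start", NA_integer_)),
    cons_end = as.integer(getattr("cons_end", NA_integer_)),
    identity_pct = as.numeric(getattr("identity", NA_real_)),
    full_length = as.logical(getattr("full_length", NA)),
    stringsAsFactors = FALSE
  )
  copies <- copies[!drop, , drop = FALSE]
  rownames(copies) <- NULL
  validate_copies(copies)
  copies
}

#' Write TE copies to a GFF3 file
#'
#' Inverse of \code{read_te_gff3}: internal 0-based half-open coordinates
#' become 1-based inclusive; attributes carry copy and family identifiers,
#' identity, consensus span and the full-length flag. Reading the file back
#' reproduces (chrom, start, end, strand, family) exactly.
#'
#' @param copies TE copy table.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return \code{path}, invisibly.
#' @export
write_te_gff3 <- function(copies, path, source = "telandscape") {
  gr <- GenomicRanges::GRanges(
    seqnames = copies$chrom,
    ranges = IRanges::IRanges(copies$start + 1L, copies$end),
    strand = copies$strand
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- "dispersed_repeat"
  S4Vectors::mcols(gr)$ID <- copies$copy_id
  S4Vectors::mcols(gr)$family_id <- copies$family_id
  if (!all(is.na(copies$identity_pct)))
    S4Vectors::mcols(gr)$identity <- copies$identity_pct
  if (!all(is.na(copies$cons_start))) {
    S4Vectors::mcols(gr)$cons_start <- copies$cons_start
    S4Vectors::mcols(gr)$cons_end <- copies$cons_end
  }
  if (!all(is.na(copies$full_length)))
    S4Vectors::mcols(gr)$full_length <- copies$full_length
  if ("joined_from" %in% names(copies) && !all(is.na(copies$joined_from)))
    S4Vectors::mcols(gr)$joined_from <- copies$joined_from
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read simple-repeat intervals from a 3-column BED file
#'
#' BED is already 0-based half-open; intervals are merged per chromosome.
#'
#' @param path path to a BED file.
#' @return Merged simple-repeat track data.frame (chrom, start, end).
#' @export
read_simple_repeats_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  simple_repeat_track(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  ))
}

#' Write a stage output table as TSV
#'
#' Deterministic: fixed column order as given, rows sorted by the supplied
#' keys, numeric columns named in \code{fixed2} printed with two decimals
#' (the convention used for Mb and percent columns).
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param sort_by optional character vector of column names to sort rows by.
#' @param fixed2 character vector of numeric columns to format at 2 decimals.
#' @return \code{path}, invisibly.
#' @export
write_tsv_table <- function(df, path, sort_by = NULL, fixed2 = character()) {
  if (!is.null(sort_by) && nrow(df) > 0) {
    df <- df[do.call(order, df[sort_by]), , drop = FALSE]
  }
  for (cl in intersect(fixed2, names(df))) {
    df[[cl]] <- sprintf("%.2f", df[[cl]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write cluster spans as a BED file
#'
#' @param clusters cluster table from \code{find_clusters}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  bed <- data.frame(chrom = clusters$chrom, start = clusters$start,
                    end = clusters$end,
                    name = paste0("cluster_", clusters$cluster_id))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
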