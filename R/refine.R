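# Annotation refinement: fragment joining, simple-repeat subtraction,
# minimum-length elimination, full-length classification.

#' Fragment-joining policy
#'
#' Two consecutive fragments of the same family are joined when the genomic
#' gap between them consists of more than \code{min_other_te_fraction} of
#' other TE insertions (nested elements interrupting the host).
#'
#' @param min_other_te_fraction fraction of the gap that must be covered by
#'   other TE annotations (default 0.80, strict greater-than).
#' @param require_same_family join only fragments of one family.
#' @param require_colinear require the fragments to be colinear on the
#'   family consensus.
#' @param colinear_tol_bp allowed consensus overlap between colinear
#'   fragments, in bp. RepeatMasker fragment pairs commonly overlap a little
#'   on the consensus, so a 50 bp tolerance is the default.
#' @return A list of class \code{join_policy}.
#' @export
join_policy <- function(min_other_te_fraction = 0.80,
                        require_same_family = TRUE,
                        require_colinear = TRUE,
                        colinear_tol_bp = 50L) {
  stopifnot(min_other_te_fraction >= 0, min_other_te_fraction <= 1)
  structure(list(min_other_te_fraction = min_other_te_fraction,
                 require_same_family = require_same_family,
                 require_colinear = require_colinear,
                 colinear_tol_bp = as.integer(colinear_tol_bp)),
            class = "join_policy")
}

#' Minimum-length filter policy
#'
#' @param min_length_bp minimum residual copy length in bp (default 20):
#'   annotations whose length outside simple repeats falls below this are
#'   eliminated.
#' @return A list of class \code{filter_policy}.
#' @export
filter_policy <- function(min_length_bp = 20L) {
  stopifnot(min_length_bp >= 1)
  structure(list(min_length_bp = as.integer(min_length_bp)),
            class = "filter_policy")
}

# fraction of [gap_start, gap_end) covered by intervals (start,end matrix);
# empty gap counts as fully covered
.gap_coverage <- function(gap_start, gap_end, other_start, other_end) {
  if (gap_end <= gap_start) return(1)
  if (length(other_start) == 0) return(0)
  ir <- IRanges::intersect(
    IRanges::IRanges(gap_start + 1L, gap_end),
    IRanges::reduce(IRanges::IRanges(other_start + 1L, other_end))
  )
  sum(IRanges::width(ir)) / (gap_end - gap_start)
}

.colinear <- function(prev, nxt, tol) {
  if (is.na(prev$cons_start) || is.na(nxt$cons_start)) return(FALSE)
  if (prev$strand == "+") {
    nxt$cons_start >= prev$cons_end - tol
  } else {
    # minus-strand fragments ascending on the genome descend on the consensus
    prev$cons_start >= nxt$cons_end - tol
  }
}

#' Join interrupted TE fragments
#'
#' Consecutive same-family, same-strand fragments that are colinear on the
#' family consensus are merged into one copy whenever the genomic gap
#' between them is covered by other TE annotations beyond the policy
#' threshold (strictly more than 80\% by default). Merging proceeds
#' transitively left-to-right; overlapping same-family fragments (gap <= 0)
#' merge unconditionally. The merged copy spans both fragments, its
#' consensus span is the union, and its identity is the length-weighted
#' mean. A \code{joined_from} column records provenance.
#'
#' @param copies TE copy table, consensus coordinates populated.
#' @param policy a \code{join_policy()}.
#' @return Copy table with joined fragments merged; idempotent.
#' @export
join_fragments <- function(copies, policy = join_policy()) {
  if (nrow(copies) < 2) {
    copies$joined_from <- rep(NA_character_, nrow(copies))
    return(copies)
  }
  copies <- copies[order(copies$chrom, copies$start, copies$end), ,
                   drop = FALSE]
  rownames(copies) <- NULL
  if (!"joined_from" %in% names(copies)) {
    copies$joined_from <- NA_character_
  }
  grp_key <- if (policy$require_same_family) {
    paste(copies$chrom, copies$family_id, copies$strand)
  } else {
    paste(copies$chrom, copies$strand)
  }
  out <- list()
  for (key in unique(grp_key)) {
    idx <- which(grp_key == key)
    grp <- copies[idx, , drop = FALSE]
    others <- copies[-idx, , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    for (j in seq_len(nrow(grp))[-1]) {
      nxt <- grp[j, , drop = FALSE]
      gap <- nxt$start - cur$end
      join <- FALSE
      if (gap <= 0) {
        join <- TRUE  # overlapping fragments: merged unconditionally
        if (gap < 0) message("overlapping fragments ", cur$copy_id, " / ",
                             nxt$copy_id, " merged")
      } else {
        colin <- !policy$require_colinear ||
          .colinear(cur, nxt, policy$colinear_tol_bp)
        if (colin) {
          # exclude the two fragments themselves from the covering set
          oth <- others[others$chrom == cur$chrom, , drop = FALSE]
          cov <- .gap_coverage(cur$end, nxt$start, oth$start, oth$end)
          join <- cov > policy$min_other_te_fraction
        }
      }
      if (join) {
        w1 <- cur$end - cur$start; w2 <- nxt$end - nxt$start
        cur$joined_from <- paste(na.omit(c(
          if (is.na(cur$joined_from)) cur$copy_id else cur$joined_from,
          nxt$copy_id)), collapse = ",")
        cur$end <- nxt$end
        cur$cons_start <- min(cur$cons_start, nxt$cons_start)
        cur$cons_end <- max(cur$cons_end, nxt$cons_end)
        cur$identity_pct <- (cur$identity_pct * w1 + nxt$identity_pct * w2) /
          (w1 + w2)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Remove annotations shorter than the threshold after simple-repeat overlap
#'
#' For each copy the residual length is its genomic length minus its overlap
#' with the (merged) simple-repeat track; copies whose residual falls below
#' the policy minimum (20 bp by default) are eliminated. The subtraction is
#' a filter criterion only: surviving copies keep their original
#' coordinates.
#'
#' @param copies TE copy table.
#' @param simple_repeats merged track from \code{simple_repeat_track()} /
#'   \code{read_simple_repeats_bed()}; may be empty.
#' @param policy a \code{filter_policy()}.
#' @return Filtered copy table.
#' @export
subtract_and_filter <- function(copies, simple_repeats = NULL,
                                policy = filter_policy()) {
  if (nrow(copies) == 0) return(copies)
  residual <- copies$end - copies$start
  if (!is.null(simple_repeats) && nrow(simple_repeats) > 0) {
    for (ch in unique(copies$chrom)) {
      sr <- simple_repeats[simple_repeats$chrom == ch, , drop = FALSE]
      if (nrow(sr) == 0) next
      ci <- which(copies$chrom == ch)
      ir_c <- IRanges::IRanges(copies$start[ci] + 1L, copies$end[ci])
      ir_s <- IRanges::IRanges(sr$start + 1L, sr$end)
      ov <- IRanges::findOverlaps(ir_c, ir_s)
      if (length(ov)) {
        w <- IRanges::width(IRanges::pintersect(
          ir_c[S4Vectors::queryHits(ov)], ir_s[S4Vectors::subjectHits(ov)]))
        overlap <- tapply(w, S4Vectors::queryHits(ov), sum)
        residual[ci[as.integer(names(overlap))]] <-
          residual[ci[as.integer(names(overlap))]] - as.integer(overlap)
      }
    }
  }
  out <- copies[residual >= policy$min_length_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify copies as full-length or incomplete
#'
#' A copy is full-length when it covers at least \code{min_coverage} of its
#' family consensus and both consensus termini lie within
#' \code{terminus_tol_bp} of the consensus ends. Copies without a consensus
#' span are incomplete (logged).
#'
#' @param copies TE copy table.
#' @param families family table with \code{consensus_length}.
#' @param min_coverage minimum consensus coverage fraction (default 0.95).
#' @param terminus_tol_bp allowed missing bp at each terminus (default 10).
#' @return Copy table with \code{full_length} set for every row.
#' @export
flag_full_length <- function(copies, families, min_coverage = 0.95,
                             terminus_tol_bp = 10L) {
  if (nrow(copies) == 0) return(copies)
  cl <- setNames(families$consensus_length, families$family_id)[copies$family_id]
  missing <- is.na(copies$cons_start) | is.na(copies$cons_end) | is.na(cl)
  if (any(missing)) {
    message(sum(missing), " cop(ies) without consensus span -> incomplete")
  }
  cov <- (copies$cons_end - copies$cons_start) / cl
  fl <- !missing & cov >= min_coverage &
    copies$cons_start <= terminus_tol_bp &
    copies$cons_end >= cl - terminus_tol_bp
  copies$full_length <- fl & !is.na(fl)
  copies
}

#' Refine an annotation set in one call
#'
#' Chains \code{join_fragments}, \code{subtract_and_filter} and
#' \code{flag_full_length} with the supplied policies.
#'
#' @param copies raw TE copy table.
#' @param families family table.
#' @param simple_repeats simple-repeat track or NULL.
#' @param join a \code{join_policy()}.
#' @param filter a \code{filter_policy()}.
#' @return Refined, flagged copy table.
#' @export
refine_annotation <- function(copies, families, simple_repeats = NULL,
                              join = join_policy(),
                              filter = filter_policy()) {
  out <- join_fragments(copies, join)
  out <- subtract_and_filter(out, simple_repeats, filter)
  flag_full_length(out, families)
}
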