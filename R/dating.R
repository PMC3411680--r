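# LTR insertion dating. The two long terminal repeats of an element are
# identical at insertion time; substitutions accumulate independently on
# both, so the Kimura two-parameter distance K between them converts to an
# insertion age T = K / (2 r) under a molecular clock with per-site,
# per-year rate r.

#' Molecular-clock parameters for LTR dating
#'
#' @param rate_r substitutions per site per year (default 1.3e-8, the
#'   average rate commonly adopted for fungal LTR retrotransposons).
#' @param bins ordered, non-overlapping list of c(lo, hi) age bins in years.
#'   Defaults to the three expansion periods resolved in the *Laccaria
#'   bicolor* landscape: 0--0.5 Mya, 1--5 Mya, 10--57 Mya.
#' @return A list of class \code{clock_params}.
#' @export
clock_params <- function(rate_r = 1.3e-8,
                         bins = list(c(0, 0.5e6), c(1e6, 5e6),
                                     c(10e6, 57e6))) {
  stopifnot(rate_r > 0)
  lo <- vapply(bins, `[`, numeric(1), 1)
  hi <- vapply(bins, `[`, numeric(1), 2)
  stopifnot(all(lo < hi), !is.unsorted(lo),
            all(hi[-length(hi)] <= lo[-1]))
  structure(list(rate_r = rate_r, bins = bins), class = "clock_params")
}

#' Activity-calling policy
#'
#' @param identity_threshold_pct families whose full-length copies exceed
#'   this percent identity (strict greater-than; default 95) are flagged
#'   potentially active.
#' @return A list of class \code{activity_policy}.
#' @export
activity_policy <- function(identity_threshold_pct = 95) {
  stopifnot(identity_threshold_pct > 0, identity_threshold_pct < 100)
  structure(list(identity_threshold_pct = identity_threshold_pct),
            class = "activity_policy")
}

#' Globally align the two LTRs of an element
#'
#' Needleman-Wunsch global alignment with affine gaps (match +1,
#' mismatch -1, gap open 10, gap extend 0.5 by default), via
#' \code{Biostrings::pairwiseAlignment}. Callers must orient the sequences;
#' a reverse-complemented partner simply scores poorly.
#'
#' @param ltr5,ltr3 nucleotide strings, each at least \code{min_len} bp.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param min_len minimum LTR length accepted for dating (default 30 bp).
#' @return List with aligned strings \code{a5}, \code{a3} and \code{score}.
#' @export
align_ltrs <- function(ltr5, ltr3, match = 1, mismatch = -1,
                       gap_open = 10, gap_extend = 0.5, min_len = 30L) {
  if (nchar(ltr5) < min_len || nchar(ltr3) < min_len) {
    stop("LTR shorter than ", min_len, " bp: too short to date")
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    ltr5, ltr3, type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a5 = as.character(Biostrings::alignedPattern(pa)),
       a3 = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Count transition and transversion fractions in an alignment
#'
#' Columns where either symbol is a gap or not in \{A,C,G,T\} are excluded.
#' Transitions are A<->G and C<->T; every other mismatch is a transversion.
#'
#' @param alignment list with \code{a5}, \code{a3} as from
#'   \code{align_ltrs}, or any two equal-length strings.
#' @return List with \code{P} (transition fraction), \code{Q} (transversion
#'   fraction) and \code{n} (comparable columns). Errors when n = 0.
#' @export
count_pq <- function(alignment) {
  x <- strsplit(toupper(alignment$a5), "")[[1]]
  y <- strsplit(toupper(alignment$a3), "")[[1]]
  stopifnot(length(x) == length(y))
  acgt <- c("A", "C", "G", "T")
  ok <- x %in% acgt & y %in% acgt
  n <- sum(ok)
  if (n == 0) stop("no comparable columns: undatable pair")
  x <- x[ok]; y <- y[ok]
  mism <- x != y
  purine <- c("A", "G")
  ts <- mism & ((x %in% purine) == (y %in% purine))
  list(P = sum(ts) / n, Q = sum(mism & !ts) / n, n = n)
}

#' Kimura two-parameter distance
#'
#' K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q), the substitution-corrected
#' distance distinguishing transition (P) and transversion (Q) fractions.
#' The pair is saturated (K undefined) when 1 - 2P - Q <= 0 or
#' 1 - 2Q <= 0.
#'
#' @param P transition fraction in [0, 1].
#' @param Q transversion fraction in [0, 1].
#' @return List with \code{K} (NA when saturated) and \code{saturated}.
#' @export
kimura2p <- function(P, Q) {
  stopifnot(P >= 0, P <= 1, Q >= 0, Q <= 1)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(K = NA_real_, saturated = TRUE))
  }
  list(K = -0.5 * log(w1) - 0.25 * log(w2), saturated = FALSE)
}

#' Convert a K2P distance to an insertion age
#'
#' T = K / (2 r): the divergence between the two LTRs accrues on both
#' copies, hence the factor 2 in the denominator.
#'
#' @param K K2P distance (non-saturated).
#' @param clock \code{clock_params()}.
#' @return Age in years.
#' @export
age_from_k <- function(K, clock = clock_params()) {
  if (is.na(K)) stop("saturated pair has no defined age")
  stopifnot(K >= 0)
  K / (2 * clock$rate_r)
}

#' Extract 5'/3' LTR pairs from genomic copies
#'
#' Takes the terminal \code{ltr_lengths[family]} bases of each copy's
#' element-oriented sequence (minus-strand copies are reverse-complemented
#' first). Callers should restrict to full-length, uninterrupted copies:
#' a nested insert sitting inside a host places foreign sequence between
#' the host's LTRs.
#'
#' @param assembly \code{DNAStringSet} genome.
#' @param copies copy table (only families named in \code{ltr_lengths} are
#'   used).
#' @param ltr_lengths named vector: family_id -> LTR length in bp.
#' @return data.frame with copy_id, family_id, ltr5, ltr3.
#' @export
extract_ltr_pairs <- function(assembly, copies, ltr_lengths) {
  copies <- copies[copies$family_id %in% names(ltr_lengths), , drop = FALSE]
  rows <- lapply(seq_len(nrow(copies)), function(i) {
    cp <- copies[i, ]
    L <- ltr_lengths[[cp$family_id]]
    s <- copy_sequence(assembly, cp)
    if (nchar(s) < 2 * L) return(NULL)
    data.frame(copy_id = cp$copy_id, family_id = cp$family_id,
               ltr5 = substr(s, 1, L),
               ltr3 = substr(s, nchar(s) - L + 1, nchar(s)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(copy_id = character(), family_id = character(),
                      ltr5 = character(), ltr3 = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Date a set of LTR pairs
#'
#' Aligns, counts substitutions and converts to ages per copy.
#'
#' @param pairs data.frame with columns copy_id, family_id, ltr5, ltr3.
#' @param clock \code{clock_params()}.
#' @param ... passed to \code{align_ltrs}.
#' @return data.frame: copy_id, family_id, n, P, Q, K, age_years, saturated.
#' @export
date_ltr_pairs <- function(pairs, clock = clock_params(), ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    al <- align_ltrs(pairs$ltr5[i], pairs$ltr3[i], ...)
    pq <- count_pq(al)
    k <- kimura2p(pq$P, pq$Q)
    data.frame(
      copy_id = pairs$copy_id[i], family_id = pairs$family_id[i],
      n = pq$n, P = pq$P, Q = pq$Q, K = k$K,
      age_years = if (k$saturated) NA_real_ else age_from_k(k$K, clock),
      saturated = k$saturated, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram of families per expansion period
#'
#' A family is counted once in every age bin (closed-lower, open-upper)
#' holding at least one of its dated copies. Copies outside all bins are
#' tallied under "other"; saturated copies are excluded from the bins and
#' tallied separately (silently dropping them would bias the landscape).
#'
#' @param dated output of \code{date_ltr_pairs}.
#' @param clock \code{clock_params()} supplying the bins.
#' @return List with \code{family_counts} (one per bin, named
#'   "lo-hi years"), \code{other_families}, \code{n_saturated_copies}, and
#'   the per-copy bin assignment \code{copy_bin} (NA = saturated,
#'   0 = outside all bins).
#' @export
bin_expansions <- function(dated, clock = clock_params()) {
  bins <- clock$bins
  labs <- vapply(bins, function(b)
    sprintf("%g-%g", b[1], b[2]), character(1))
  copy_bin <- rep(NA_integer_, nrow(dated))
  unsat <- !dated$saturated
  copy_bin[unsat] <- 0L
  for (k in seq_along(bins)) {
    inb <- unsat & dated$age_years >= bins[[k]][1] &
      dated$age_years < bins[[k]][2]
    copy_bin[inb] <- k
  }
  fam_counts <- integer(length(bins))
  for (k in seq_along(bins)) {
    fam_counts[k] <- length(unique(dated$family_id[!is.na(copy_bin) &
                                                     copy_bin == k]))
  }
  other <- length(unique(dated$family_id[!is.na(copy_bin) & copy_bin == 0L]))
  list(family_counts = setNames(fam_counts, labs),
       other_families = other,
       n_saturated_copies = sum(dated$saturated),
       copy_bin = copy_bin)
}

#' Flag potentially active families
#'
#' A family is potentially still active when it has at least two
#' full-length copies whose identity to the consensus exceeds the policy
#' threshold (strictly more than 95 percent by default) -- i.e. it contains
#' nearly identical members.
#'
#' @param families family table.
#' @param copies refined copy table with \code{full_length} and
#'   \code{identity_pct}.
#' @param policy \code{activity_policy()}.
#' @return Named logical vector over \code{families$family_id}.
#' @export
flag_active <- function(families, copies, policy = activity_policy()) {
  hits <- copies[!is.na(copies$full_length) & copies$full_length &
                   !is.na(copies$identity_pct) &
                   copies$identity_pct > policy$identity_threshold_pct, ,
                 drop = FALSE]
  cnt <- table(hits$family_id)
  out <- setNames(rep(FALSE, nrow(families)), families$family_id)
  act <- names(cnt)[cnt >= 2]
  out[intersect(act, names(out))] <- TRUE
  out
}
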