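# Genomic topology of TE copies: nests (strict containment), clusters
# (chains of copies within 10 kb), windowed density, terminal-region
# enrichment.

#' Topology parameters
#'
#' @param cluster_gap_bp maximum inter-copy gap joining a cluster
#'   (default 10,000 bp).
#' @param terminal_region_bp length of each chromosome terminus treated as
#'   terminal (default 1 Mb).
#' @param window_bp density window size (default 10 kb).
#' @param step_bp window step; defaults to \code{window_bp} (tiling
#'   windows, which make the count-conservation invariant exact). Set
#'   smaller for a true sliding profile.
#' @return A list of class \code{topology_params}.
#' @export
topology_params <- function(cluster_gap_bp = 10000L,
                            terminal_region_bp = 1000000L,
                            window_bp = 10000L,
                            step_bp = window_bp) {
  stopifnot(cluster_gap_bp > 0, terminal_region_bp > 0, window_bp > 0,
            step_bp > 0)
  structure(list(cluster_gap_bp = as.integer(cluster_gap_bp),
                 terminal_region_bp = as.integer(terminal_region_bp),
                 window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp)),
            class = "topology_params")
}

#' Detect nested TE copies
#'
#' A copy B is nested in host A when A strictly contains B with at least
#' 1 bp flank on both sides (A.start < B.start and B.end < A.end). Each
#' insert is reported with its smallest enclosing host. Host spans should
#' come from refined (joined) annotations so interrupted elements span
#' their inserts.
#'
#' @param copies refined TE copy table.
#' @return data.frame with columns host_id, insert_id, chrom, depth (1 =
#'   host is not itself nested, etc.).
#' @export
find_nests <- function(copies) {
  empty <- data.frame(host_id = character(), insert_id = character(),
                      chrom = character(), depth = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(copies) < 2) return(empty)
  res <- list()
  for (ch in unique(copies$chrom)) {
    d <- copies[copies$chrom == ch, , drop = FALSE]
    if (nrow(d) < 2) next
    ir <- IRanges::IRanges(d$start + 1L, d$end)
    ov <- IRanges::findOverlaps(ir, ir, type = "within")
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    strict <- q != s & d$start[s] < d$start[q] & d$end[q] < d$end[s]
    q <- q[strict]; s <- s[strict]
    if (!length(q)) next
    # smallest enclosing host per insert
    w <- d$end[s] - d$start[s]
    best <- vapply(split(seq_along(q), q), function(ii)
      ii[which.min(w[ii])], integer(1))
    res[[ch]] <- data.frame(
      host_id = d$copy_id[s[best]],
      insert_id = d$copy_id[q[best]],
      chrom = ch, depth = NA_integer_, stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  # nesting depth: chain length of host links above each insert
  parent <- setNames(out$host_id, out$insert_id)
  out$depth <- vapply(out$insert_id, function(id) {
    dpt <- 0L
    while (!is.na(parent[id])) {
      dpt <- dpt + 1L
      id <- parent[[id]]
      if (!id %in% names(parent)) break
    }
    dpt
  }, integer(1))
  out
}

#' Detect TE clusters
#'
#' Single-linkage chaining of copies sorted by position: a copy joins the
#' open cluster while the gap between its start and the running maximum end
#' so far is at most \code{cluster_gap_bp} (overlapping copies have gap
#' <= 0 and always chain). Only groups of two or more copies are clusters
#' -- equivalent to the transitive closure of the pairwise "within 10 kb"
#' relation.
#'
#' @param copies TE copy table.
#' @param params \code{topology_params()}.
#' @return data.frame: cluster_id, chrom, start, end, n_members,
#'   member_ids (comma-separated).
#' @export
find_clusters <- function(copies, params = topology_params()) {
  empty <- data.frame(cluster_id = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), member_ids = character(),
                      stringsAsFactors = FALSE)
  if (nrow(copies) < 2) return(empty)
  copies <- copies[order(copies$chrom, copies$start, copies$end), ,
                   drop = FALSE]
  res <- list(); cid <- 0L
  for (ch in unique(copies$chrom)) {
    d <- copies[copies$chrom == ch, , drop = FALSE]
    members <- 1L
    max_end <- d$end[1]
    flush <- function(members, max_end) {
      if (length(members) >= 2) {
        cid <<- cid + 1L
        res[[length(res) + 1L]] <<- data.frame(
          cluster_id = cid, chrom = ch,
          start = min(d$start[members]), end = max_end,
          n_members = length(members),
          member_ids = paste(d$copy_id[members], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] - max_end <= params$cluster_gap_bp) {
        members <- c(members, i)
      } else {
        flush(members, max_end)
        members <- i
      }
      max_end <- max(max_end, d$end[i])
    }
    flush(members, max_end)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Windowed TE density profile
#'
#' Counts copies per consecutive non-overlapping window (default 10 kb);
#' a copy belongs to the window containing its start, so window counts sum
#' to the copy count on every chromosome. The final partial window is
#' retained. With \code{step_bp < window_bp} a sliding profile is produced
#' (counts then overlap and no longer sum to the copy number).
#'
#' @param copies TE copy table.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param params \code{topology_params()}.
#' @param by_order optional copy -> order_label vector (same length as
#'   \code{nrow(copies)}) adding per-order count columns.
#' @return data.frame: chrom, window_index (0-based), start, end, count
#'   (+ one column per order when requested).
#' @export
density_profile <- function(copies, chrom_lengths,
                            params = topology_params(), by_order = NULL) {
  res <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    w <- params$window_bp; s <- params$step_bp
    starts <- seq(0L, max(0L, L - 1L), by = s)
    starts <- starts[starts < L]
    ends <- pmin(starts + w, L)
    ci <- which(copies$chrom == ch)
    cnt <- integer(length(starts))
    ord_counts <- NULL
    if (!is.null(by_order)) {
      ords <- sort(unique(by_order))
      ord_counts <- matrix(0L, length(starts), length(ords),
                           dimnames = list(NULL, ords))
    }
    if (length(ci)) {
      if (s == w) {
        win <- floor(copies$start[ci] / w) + 1L
        tab <- table(win)
        cnt[as.integer(names(tab))] <- as.integer(tab)
        if (!is.null(ord_counts)) {
          for (o in colnames(ord_counts)) {
            tab_o <- table(win[by_order[ci] == o])
            ord_counts[as.integer(names(tab_o)), o] <- as.integer(tab_o)
          }
        }
      } else {
        for (k in seq_along(starts)) {
          inw <- copies$start[ci] >= starts[k] & copies$start[ci] < ends[k]
          cnt[k] <- sum(inw)
          if (!is.null(ord_counts)) {
            for (o in colnames(ord_counts))
              ord_counts[k, o] <- sum(inw & by_order[ci] == o)
          }
        }
      }
    }
    df <- data.frame(chrom = ch, window_index = seq_along(starts) - 1L,
                     start = starts, end = ends, count = cnt,
                     stringsAsFactors = FALSE)
    if (!is.null(ord_counts)) df <- cbind(df, as.data.frame(ord_counts))
    res[[ch]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count nests/clusters within terminal chromosome regions
#'
#' A feature is terminal when its span overlaps the first or last
#' \code{terminal_region_bp} (default 1 Mb) of its chromosome. Chromosomes
#' shorter than twice the terminal region are entirely terminal (logged).
#'
#' @param features data.frame with chrom, start, end (e.g. cluster spans or
#'   nest host spans).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param params \code{topology_params()}.
#' @return List with \code{n_terminal}, \code{n_total}, \code{fraction} and
#'   logical vector \code{terminal}.
#' @export
terminal_enrichment <- function(features, chrom_lengths,
                                params = topology_params()) {
  t_bp <- params$terminal_region_bp
  L <- chrom_lengths[features$chrom]
  short <- L < 2 * t_bp
  if (any(short[!duplicated(features$chrom)])) {
    message("chromosome(s) shorter than ", 2 * t_bp,
            " bp are entirely terminal")
  }
  term <- features$start < t_bp | features$end > L - t_bp
  list(n_terminal = sum(term), n_total = nrow(features),
       fraction = if (nrow(features)) sum(term) / nrow(features) else NA_real_,
       terminal = unname(term))
}

#' Full topology report for a refined annotation
#'
#' @param copies refined TE copy table.
#' @param params \code{topology_params()}.
#' @return List of class \code{topology_report}: \code{nests},
#'   \code{clusters}, and \code{n_features} (deduplicated union count of
#'   nests and clusters, nests inside a cluster counted once).
#' @export
topology_report <- function(copies, params = topology_params()) {
  nests <- find_nests(copies)
  clusters <- find_clusters(copies, params)
  # deduplicated union: a nest whose host is a cluster member adds nothing
  in_cluster <- unlist(strsplit(clusters$member_ids, ","))
  extra_nests <- sum(!(nests$host_id %in% in_cluster))
  structure(list(nests = nests, clusters = clusters,
                 n_nests = nrow(nests), n_clusters = nrow(clusters),
                 n_features = nrow(clusters) + extra_nests),
            class = "topology_report")
}

#' Fraction of copies that are nested and/or clustered
#'
#' @param copies TE copy table.
#' @param report \code{topology_report()} for the same copies.
#' @param order_of optional named vector copy_id -> order label for the
#'   per-order breakdown (Gypsy+Copia pooled, TIR, LINE).
#' @return List with \code{fraction}, \code{n_involved}, and
#'   \code{order_share} (share of the involved copies per order group).
#' @export
nested_or_clustered_fraction <- function(copies, report, order_of = NULL) {
  involved <- unique(c(report$nests$host_id, report$nests$insert_id,
                       unlist(strsplit(report$clusters$member_ids, ","))))
  involved <- intersect(involved, copies$copy_id)
  frac <- length(involved) / max(1L, nrow(copies))
  share <- NULL
  if (!is.null(order_of) && length(involved)) {
    ord <- order_of[involved]
    grp <- ifelse(ord %in% c("Gypsy", "Copia"), "Gypsy+Copia", ord)
    share <- table(grp) / length(involved)
  }
  list(fraction = frac, n_involved = length(involved), order_share = share)
}
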