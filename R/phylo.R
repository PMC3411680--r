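# Distance-based phylogeny of reverse transcriptase / ribonuclease H
# domain alignments: p-distance, neighbor joining with deterministic
# tie-breaking, column-bootstrap support, newick I/O.

#' Pairwise distances from an amino-acid alignment
#'
#' Uncorrected p-distance (mismatches over columns where both sequences
#' are non-gap) by default; the Poisson correction -ln(1 - p) is available
#' for comparison.
#'
#' @param msa named character vector of aligned sequences (equal lengths)
#'   or a character matrix with one row per taxon.
#' @param model "p" (default) or "poisson".
#' @return Symmetric numeric matrix with taxa as dimnames.
#' @export
pdistance <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- .msa_matrix(msa)
  taxa <- rownames(m)
  n <- nrow(m)
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) stop("no comparable columns between ", taxa[i],
                         " and ", taxa[j])
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      if (model == "poisson") {
        if (p >= 1) stop("saturated pair ", taxa[i], "/", taxa[j],
                         " under Poisson correction")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

.msa_matrix <- function(msa) {
  if (is.matrix(msa)) {
    stopifnot(!is.null(rownames(msa)))
    return(toupper(msa))
  }
  stopifnot(!is.null(names(msa)))
  lens <- nchar(msa)
  if (length(unique(lens)) != 1) stop("ragged alignment rejected")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Neighbor-joining tree
#'
#' Standard agglomerative NJ (Saitou & Nei): repeatedly join the pair
#' minimizing Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k), ties
#' broken by the lexicographically smallest index pair; branch lengths by
#' the two-point formula, negative estimates clamped to zero (count kept in
#' \code{attr(tree, "n_clamped")}). Consistent on additive matrices: the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param d symmetric distance matrix with >= 3 labelled taxa.
#' @return An unrooted \code{ape::phylo} tree.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  stopifnot(max(abs(d - t(d))) < 1e-12, all(diag(d) == 0), all(is.finite(d)))
  labels <- rownames(d)
  sub <- labels  # newick fragment per active node
  active <- seq_len(n)
  D <- d
  clamped <- 0L
  cl <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(D)
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- cl(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- cl(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_sub <- paste0("(", sub[i], ":", fmt(bi), ",", sub[j], ":",
                      fmt(bj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    newd <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd),
               c(newd, 0))
    sub <- c(sub[keep], new_sub)
    active <- seq_len(m - 1)
  }
  b1 <- cl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- cl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- cl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", sub[1], ":", fmt(b1), ",", sub[2], ":", fmt(b2),
                ",", sub[3], ":", fmt(b3), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "n_clamped") <- clamped
  tree
}

# canonical leaf-set labels of every internal bipartition of an unrooted
# tree; the side not containing the alphabetically first taxon is kept
.bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  anchor <- sort(labels)[1]
  out <- character(0)
  nodes <- integer(0)
  for (k in seq_along(pp)) {
    set <- labels[pp[[k]]]
    if (length(set) == length(labels)) next  # root: trivial split
    if (length(set) < 2 || length(set) > length(labels) - 2) next
    if (anchor %in% set) set <- setdiff(labels, set)
    out <- c(out, paste(sort(set), collapse = "|"))
    nodes <- c(nodes, length(labels) + k)
  }
  names(out) <- nodes
  out
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' percentage of replicates containing the same bipartition. Seeded and
#' reproducible; supports are stored as node labels.
#'
#' @param msa alignment as for \code{pdistance}.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param model distance model passed to \code{pdistance}.
#' @return The full-data NJ tree with \code{node.label} carrying percent
#'   support (root label empty) and \code{attr(, "support")}, the named
#'   support vector keyed by bipartition.
#' @export
nj_bootstrap <- function(msa, n_reps = 1000L, seed = 1L,
                         model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- .msa_matrix(msa)
  full <- nj_tree(pdistance(m, model))
  bips <- .bipartitions(full)
  counts <- setNames(numeric(length(bips)), bips)
  set.seed(seed)
  ncol_m <- ncol(m)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol_m, ncol_m, replace = TRUE)
    rep_tree <- nj_tree(pdistance(m[, cols, drop = FALSE], model))
    rb <- .bipartitions(rep_tree)
    hit <- bips %in% rb
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  n_tip <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  node_ids <- as.integer(names(bips))
  labs[node_ids - n_tip] <- sprintf("%g", unname(support))
  full$node.label <- labs
  attr(full, "support") <- support
  full
}

#' Write a tree to a newick file
#'
#' Bootstrap supports, when present, are emitted as internal node labels.
#' \code{read_newick(write_newick(t))} is isomorphic to \code{t} with equal
#' branch lengths to 1e-9.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree file
#'
#' @param path path to a newick file.
#' @return An \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
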