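# Brute-force oracles and small generators shared across tests. Each
# oracle re-derives the quantity by direct enumeration, independently of
# the package implementation it checks.

ACGT <- c("A", "C", "G", "T")

# per-column substitution classifier (transitions A<->G, C<->T)
oracle_pq <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  ts_pairs <- c("AG", "GA", "CT", "TC")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(x)) {
    if (x[i] %in% ACGT && y[i] %in% ACGT) {
      n <- n + 1L
      if (x[i] != y[i]) {
        if (paste0(x[i], y[i]) %in% ts_pairs) ts <- ts + 1L else tv <- tv + 1L
      }
    }
  }
  list(P = ts / n, Q = tv / n, n = n)
}

rand_aligned_pair <- function(len = 60) {
  alpha <- c(ACGT, "-", "N")
  pr <- c(rep(0.22, 4), 0.06, 0.06)
  list(a5 = paste(sample(alpha, len, TRUE, prob = pr), collapse = ""),
       a3 = paste(sample(alpha, len, TRUE, prob = pr), collapse = ""))
}

# end-to-end age estimate for one simulated LTR pair
est_age_pair <- function(p, clock = clock_params()) {
  al <- align_ltrs(p$ltr5, p$ltr3)
  pq <- count_pq(al)
  k <- kimura2p(pq$P, pq$Q)
  if (k$saturated) NA_real_ else age_from_k(k$K, clock)
}

rand_copy_table <- function(n, chroms = c("c1", "c2"), L = 200000,
                            max_len = 8000) {
  start <- sample.int(L - max_len, n)
  len <- sample.int(max_len, n)
  te_copies(sprintf("r%03d", seq_len(n)), "FAMX",
            sample(chroms, n, replace = TRUE), start, start + len)
}

# all-pairs strict-containment oracle; smallest enclosing host per insert
oracle_nests <- function(copies) {
  out <- list()
  for (i in seq_len(nrow(copies))) {
    best <- NA_integer_; bw <- Inf
    for (j in seq_len(nrow(copies))) {
      if (i == j) next
      if (copies$chrom[j] == copies$chrom[i] &&
          copies$start[j] < copies$start[i] &&
          copies$end[i] < copies$end[j]) {
        w <- copies$end[j] - copies$start[j]
        if (w < bw) { bw <- w; best <- j }
      }
    }
    if (!is.na(best)) {
      out[[length(out) + 1L]] <- c(host = copies$copy_id[best],
                                   insert = copies$copy_id[i])
    }
  }
  if (!length(out)) {
    return(data.frame(host_id = character(), insert_id = character()))
  }
  m <- do.call(rbind, out)
  data.frame(host_id = m[, "host"], insert_id = m[, "insert"],
             stringsAsFactors = FALSE)
}

# transitive closure of the pairwise "gap <= gap_bp" relation; returns a
# list of sorted member-id vectors, groups of >= 2 only
oracle_cluster_sets <- function(copies, gap_bp = 10000) {
  n <- nrow(copies)
  if (n < 2) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || copies$chrom[i] != copies$chrom[j]) next
      gap <- max(copies$start[i], copies$start[j]) -
        min(copies$end[i], copies$end[j])
      adj[i, j] <- gap <= gap_bp
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sets <- split(copies$copy_id, comp)
  sets <- Filter(function(s) length(s) >= 2, sets)
  unname(lapply(sets, sort))
}

cluster_sets_of <- function(clusters) {
  unname(lapply(strsplit(clusters$member_ids, ","), sort))
}

same_set_of_sets <- function(a, b) {
  key <- function(s) paste(s, collapse = "|")
  setequal(vapply(a, key, character(1)), vapply(b, key, character(1)))
}

# K2P distance via an independent implementation: build a sequence pair
# with exact transition/transversion counts and hand it to
# ape::dist.dna(model = "K80")
oracle_k2p_ape <- function(P, Q, n = 1200) {
  nts <- round(P * n); ntv <- round(Q * n)
  s1 <- rep("a", n)
  s2 <- c(rep("g", nts), rep("c", ntv), rep("a", n - nts - ntv))
  db <- ape::as.DNAbin(rbind(x = s1, y = s2))
  as.numeric(ape::dist.dna(db, model = "K80"))
}

# OLS minimum-evolution search over all 15 unrooted 5-taxon topologies
oracle_me5 <- function(d) {
  taxa <- rownames(d)
  stopifnot(length(taxa) == 5)
  pairs <- t(combn(5, 2))
  best <- NULL; best_len <- Inf
  cherries <- combn(5, 2, simplify = FALSE)
  for (c1 in cherries) {
    rest <- setdiff(1:5, c1)
    for (c2 in combn(rest, 2, simplify = FALSE)) {
      if (min(c1) > min(c2)) next  # each split pair once
      e <- setdiff(rest, c2)
      # edges: 5 pendant + u-w + v-w  (u joins c1, v joins c2, e at w)
      A <- matrix(0, nrow(pairs), 7)
      onpath <- function(i, j) {
        path <- rep(0, 7)
        path[i] <- 1; path[j] <- 1
        side <- function(k) if (k %in% c1) "u" else if (k %in% c2) "v" else "w"
        si <- side(i); sj <- side(j)
        if (si != sj) {
          if ("u" %in% c(si, sj)) path[6] <- 1
          if ("v" %in% c(si, sj)) path[7] <- 1
        }
        path
      }
      dv <- numeric(nrow(pairs))
      for (r in seq_len(nrow(pairs))) {
        A[r, ] <- onpath(pairs[r, 1], pairs[r, 2])
        dv[r] <- d[pairs[r, 1], pairs[r, 2]]
      }
      fit <- qr.solve(A, dv)
      len <- sum(fit)
      if (len < best_len - 1e-12) {
        best_len <- len
        nwk <- sprintf("((%s,%s),(%s,%s),%s);",
                       taxa[c1[1]], taxa[c1[2]], taxa[c2[1]],
                       taxa[c2[2]], taxa[e])
        best <- ape::read.tree(text = nwk)
      }
    }
  }
  best
}

# brute-force restatement of the full-length rule
oracle_full_length <- function(cons_start, cons_end, cons_len,
                               min_cov = 0.95, tol = 10) {
  if (is.na(cons_start) || is.na(cons_end)) return(FALSE)
  (cons_end - cons_start) / cons_len >= min_cov &&
    cons_start <= tol && cons_end >= cons_len - tol
}
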