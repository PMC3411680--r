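test_that("nests require strict containment; overlap is not nesting", {
  cp <- te_copies(c("host", "ins", "ovl"), c("A", "B", "C"), "c1",
                  c(1000L, 2000L, 7500L), c(8000L, 3000L, 9000L))
  n <- find_nests(cp)
  expect_equal(nrow(n), 1L)
  expect_equal(n$host_id, "host")
  expect_equal(n$insert_id, "ins")
  # identical-boundary copies do not nest (need >= 1 bp flank)
  cp2 <- te_copies(c("a", "b"), c("A", "B"), "c1", c(100L, 100L),
                   c(500L, 400L))
  expect_equal(nrow(find_nests(cp2)), 0L)
})

test_that("triple nesting reports smallest enclosing hosts and depths", {
  cp <- te_copies(c("A", "B", "C"), c("fA", "fB", "fC"), "c1",
                  c(0L, 1000L, 2000L), c(10000L, 9000L, 3000L))
  n <- find_nests(cp)
  n <- n[order(n$insert_id), ]
  expect_equal(n$insert_id, c("B", "C"))
  expect_equal(n$host_id, c("A", "B"))
  expect_equal(n$depth, c(1L, 2L))
})

test_that("nest relation matches the all-pairs containment oracle", {
  set.seed(31)
  for (i in 1:25) {
    cp <- rand_copy_table(40)
    got <- find_nests(cp)
    want <- oracle_nests(cp)
    got <- got[order(got$insert_id), c("host_id", "insert_id")]
    want <- want[order(want$insert_id), c("host_id", "insert_id")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    # irreflexive and antisymmetric
    expect_false(any(got$host_id == got$insert_id))
    expect_false(any(paste(got$host_id, got$insert_id) %in%
                       paste(got$insert_id, got$host_id)))
  }
})

test_that("clusters chain copies within 10 kb and need two members", {
  cp <- te_copies(c("a", "b", "c"), "F", "c1",
                  c(100L, 5000L, 20000L), c(500L, 6000L, 21000L))
  cl <- find_clusters(cp)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$member_ids, "a,b")   # gap 4500 chains; gap 14000 breaks
  expect_equal(c(cl$start, cl$end), c(100L, 6000L))
  # 5 copies 1 bp apart form one 5-member cluster
  s <- cumsum(c(100L, rep(1001L, 4)))
  cp5 <- te_copies(sprintf("m%d", 1:5), "F", "c1", s, s + 1000L)
  cl5 <- find_clusters(cp5)
  expect_equal(cl5$n_members, 5L)
})

test_that("find_clusters equals the brute-force transitive closure", {
  set.seed(77)
  for (i in 1:25) {
    cp <- rand_copy_table(sample(10:60, 1))
    got <- cluster_sets_of(find_clusters(cp))
    want <- oracle_cluster_sets(cp)
    expect_true(same_set_of_sets(got, want))
  }
})

test_that("density windows partition copies by start coordinate", {
  cp <- te_copies(sprintf("c%d", 1:4), "F", "c1",
                  c(1L, 5000L, 9999L, 10000L),
                  c(400L, 5400L, 10399L, 10400L))
  prof <- density_profile(cp, c(c1 = 20000L))
  expect_equal(prof$count, c(3L, 1L))          # 9999 -> window 0; 10000 -> 1
  expect_equal(prof$start, c(0L, 10000L))
  # final partial window retained, counts conserved
  prof2 <- density_profile(cp, c(c1 = 25000L))
  expect_equal(nrow(prof2), 3L)
  expect_equal(sum(prof2$count), nrow(cp))
})

test_that("window counts are conserved on random instances", {
  set.seed(5)
  for (i in 1:10) {
    cp <- rand_copy_table(80)
    lens <- c(c1 = 200000L, c2 = 200000L)
    prof <- density_profile(cp, lens)
    for (ch in names(lens)) {
      expect_equal(sum(prof$count[prof$chrom == ch]),
                   sum(cp$chrom == ch))
    }
  }
})

test_that("per-order density lanes sum to the total", {
  set.seed(6)
  cp <- rand_copy_table(50)
  ords <- sample(c("Copia", "TIR", "LINE"), 50, replace = TRUE)
  prof <- density_profile(cp, c(c1 = 200000L, c2 = 200000L),
                          by_order = ords)
  expect_equal(prof$Copia + prof$TIR + prof$LINE, prof$count)
})

test_that("terminal regions are the first and last megabase", {
  feats <- data.frame(chrom = "LG1",
                      start = c(200000, 2000000, 900000),
                      end = c(400000, 2100000, 1200000))
  te <- terminal_enrichment(feats, c(LG1 = 5000000))
  expect_equal(te$terminal, c(TRUE, FALSE, TRUE))  # straddling counts
  expect_equal(te$n_terminal, 2L)
  expect_equal(te$fraction, 2 / 3)
  # short chromosome: everything terminal, logged
  expect_message(
    te2 <- terminal_enrichment(data.frame(chrom = "s", start = 500000,
                                          end = 600000), c(s = 1500000)),
    "entirely terminal")
  expect_true(te2$terminal)
})

test_that("nested-or-clustered fraction covers hosts, inserts and members", {
  far <- te_copies(c("a", "b"), "F", "c1", c(0L, 50000L),
                   c(1000L, 51000L))
  rep0 <- topology_report(far)
  expect_equal(nested_or_clustered_fraction(far, rep0)$fraction, 0)

  near <- te_copies(c("a", "b"), "F", "c1", c(0L, 1001L),
                    c(1000L, 2000L))
  rep1 <- topology_report(near)
  expect_equal(nested_or_clustered_fraction(near, rep1)$fraction, 1)

  # per-order shares pool Gypsy with Copia
  cp <- te_copies(c("g", "c", "t", "x"), c("G", "C", "T", "X"), "c1",
                  c(0L, 2000L, 4000L, 100000L),
                  c(1000L, 3000L, 5000L, 101000L))
  repc <- topology_report(cp)
  ord <- c(g = "Gypsy", c = "Copia", t = "TIR", x = "LINE")
  f <- nested_or_clustered_fraction(cp, repc, order_of = ord)
  expect_equal(f$fraction, 0.75)
  expect_equal(unname(f$order_share[["Gypsy+Copia"]]), 2 / 3)
})

test_that("the nest/cluster union deduplicates nests inside clusters", {
  # host+insert pair that is also within 10 kb of a third copy
  cp <- te_copies(c("h", "i", "n"), c("A", "B", "C"), "c1",
                  c(1000L, 2000L, 9000L), c(8000L, 3000L, 9500L))
  rep <- topology_report(cp)
  expect_equal(rep$n_nests, 1L)
  expect_equal(rep$n_clusters, 1L)
  expect_equal(rep$n_features, 1L)   # nest's host is a cluster member
})
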