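test_that("consensus construction honours terminal repeat structure", {
  set.seed(1)
  cons <- make_consensus("Copia", 5000L, 300L)
  expect_equal(nchar(cons), 5000L)
  expect_equal(substr(cons, 1, 300), substr(cons, 4701, 5000))
  tir <- make_consensus("TIR", 2000L, 40L)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(substr(tir, 1, 40), rc(substr(tir, 1961, 2000)))
  expect_error(make_consensus("Copia", 500L, 260L), "half")
  set.seed(123); c1 <- make_consensus("Gypsy", 3000L, 200L)
  set.seed(123); c2 <- make_consensus("Gypsy", 3000L, 200L)
  expect_identical(c1, c2)
})

test_that("mutate_by_age matches the per-site substitution expectation", {
  set.seed(8)
  seq0 <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  expect_identical(mutate_by_age(seq0, 0), seq0)
  # observed divergence within 3 sigma of the binomial expectation
  r <- 1.3e-8; age <- 5e6
  mut <- mutate_by_age(seq0, age, r, 2)
  diff <- mapply(function(a, b) mean(a != b),
                 strsplit(seq0, ""), strsplit(mut, ""))
  p_exp <- 1 - exp(-r * age)
  sigma <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(diff - p_exp), 3 * sigma)
})

test_that("transition bias follows kappa", {
  set.seed(9)
  P <- 0; Q <- 0
  for (i in 1:100) {
    p <- sim_ltr_pair(5e6, ltr_length = 500L, kappa = 2)
    pq <- count_pq(list(a5 = p$ltr5, a3 = p$ltr3))
    P <- P + pq$P; Q <- Q + pq$Q
  }
  # analytic expectation of the OBSERVED ts:tv ratio at this divergence
  # (back-substitutions erode the instantaneous 2:1 towards equality)
  rt <- 2 * 1.3e-8 * 5e6
  beta <- rt / 6; alpha <- 4 * beta
  e1 <- exp(-4 * beta); e2 <- exp(-2 * (alpha + beta))
  want <- (0.25 + 0.25 * e1 - 0.5 * e2) / (0.5 * (1 - e1))
  expect_equal(P / Q, want, tolerance = 0.1)
})

test_that("equal configs give byte-identical genomes and truth", {
  cfg <- sim_config(seed = 77, n_chroms = 2, chrom_length_bp = 5e4,
                    family_specs = {
                      fs <- default_family_specs()
                      fs$copy_count <- rep(2L, nrow(fs)); fs
                    })
  s1 <- simulate_te_genome(cfg)
  s2 <- simulate_te_genome(cfg)
  expect_identical(as.character(s1$assembly), as.character(s2$assembly))
  expect_identical(s1$copies, s2$copies)
  d <- withr::local_tempdir()
  write_sim_output(s1, d)
  expect_true(all(file.exists(file.path(d, c("genome.fasta", "truth.gff3",
                                             "truth.tsv", "config.txt")))))
})

test_that("planted copies land where the truth says they do", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length_bp = 1e5,
                    truncation_prob = 0,
                    family_specs = {
                      fs <- default_family_specs()[c(1, 6), ]
                      fs$copy_count <- c(4L, 4L); fs
                    })
  sim <- simulate_te_genome(cfg)
  lens <- assembly_lengths(sim$assembly)
  expect_equal(unname(lens[["chr1"]]),
               1e5 + sum(sim$copies$end - sim$copies$start) -
                 sum(vapply(sim$copies$copy_id, function(id) {
                   # nested inserts inflate host spans; subtract them back
                   kids <- sim$copies[!is.na(sim$copies$nest_parent) &
                                        sim$copies$nest_parent == id, ]
                   sum(kids$end - kids$start)
                 }, numeric(1))))
  # an untruncated, un-nested copy's sequence matches its mutated element
  solo <- sim$copies[is.na(sim$copies$nest_parent) &
                       !(sim$copies$copy_id %in% sim$copies$nest_parent), ]
  solo <- solo[!vapply(solo$copy_id, function(id)
    any(!is.na(sim$copies$nest_parent) & sim$copies$nest_parent == id),
    logical(1)), ]
  cp <- solo[1, ]
  seqs <- copy_sequence(sim$assembly, cp)
  cons <- sim$consensus[[cp$family_id]]
  expect_equal(nchar(seqs), nchar(cons))
  expect_gt(mean(strsplit(seqs, "")[[1]] == strsplit(cons, "")[[1]]), 0.5)
})

test_that("forced nesting nests and forced clustering clusters", {
  fs <- default_family_specs()[1, ]; fs$copy_count <- 2L
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length_bp = 1e5,
                    nest_prob = 1, cluster_prob = 0, truncation_prob = 0,
                    family_specs = fs)
  sim <- simulate_te_genome(cfg)
  expect_equal(nrow(sim$copies), 2L)
  inner <- sim$copies[!is.na(sim$copies$nest_parent), ]
  outer <- sim$copies[is.na(sim$copies$nest_parent), ]
  expect_equal(nrow(inner), 1L)
  expect_lt(outer$start, inner$start)
  expect_gt(outer$end, inner$end)
  nst <- find_nests(sim$copies)
  expect_equal(nst$host_id, outer$copy_id)
  expect_equal(nst$insert_id, inner$copy_id)

  fs2 <- default_family_specs()[c(1, 6), ]; fs2$copy_count <- c(5L, 5L)
  cfg2 <- sim_config(seed = 4, n_chroms = 1, chrom_length_bp = 2e5,
                     nest_prob = 0, cluster_prob = 1, truncation_prob = 0,
                     family_specs = fs2)
  sim2 <- simulate_te_genome(cfg2)
  cl <- find_clusters(sim2$copies)
  got <- cluster_sets_of(cl)
  want <- lapply(split(sim2$copies$copy_id, sim2$copies$cluster_id),
                 sort)
  expect_true(same_set_of_sets(got, unname(want)))
  expect_true(all(!is.na(sim2$copies$cluster_id)))
})

test_that("without truncation every planted copy is full length", {
  fs <- default_family_specs()
  fs$copy_count <- rep(3L, nrow(fs))
  cfg <- sim_config(seed = 21, n_chroms = 2, chrom_length_bp = 2e5,
                    truncation_prob = 0, family_specs = fs)
  sim <- simulate_te_genome(cfg)
  fl <- flag_full_length(sim$copies, sim$families)
  expect_true(all(fl$full_length))
})
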