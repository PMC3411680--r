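test_that("LTR alignment handles the documented cases", {
  a <- align_ltrs(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_equal(a$a5, a$a3)
  expect_equal(nchar(a$a5), 100L)

  # single 1-bp gap for an 8 vs 7 bp pair, 7 matched columns
  b <- align_ltrs("ACGTACGT", "ACGACGT", min_len = 5L)
  expect_equal(sum(strsplit(b$a3, "")[[1]] == "-"), 1L)
  pq <- count_pq(b)
  expect_equal(pq$n, 7L)
  expect_equal(pq$P + pq$Q, 0)

  expect_error(align_ltrs("ACGT", "ACGT"), "too short")
})

test_that("count_pq classifies transitions and transversions correctly", {
  expect_equal(count_pq(list(a5 = "ACGT", a3 = "ACGT")),
               list(P = 0, Q = 0, n = 4L))
  # A->G is a transition
  expect_equal(count_pq(list(a5 = "ACGT", a3 = "GCGT")),
               list(P = 0.25, Q = 0, n = 4L))
  # gap columns dropped
  expect_equal(count_pq(list(a5 = "A-CT", a3 = "AGCT"))$n, 3L)
  # N columns dropped
  expect_equal(count_pq(list(a5 = "ANCT", a3 = "AGCT"))$n, 3L)
  expect_error(count_pq(list(a5 = "----", a3 = "ACGT")), "undatable")
})

test_that("count_pq matches the brute-force column classifier", {
  set.seed(101)
  for (i in 1:300) {
    p <- rand_aligned_pair(40)
    want <- tryCatch(oracle_pq(p$a5, p$a3), error = function(e) NULL)
    if (is.null(want) || want$n == 0) {
      expect_error(count_pq(p))
    } else {
      got <- count_pq(p)
      expect_equal(got$P, want$P)
      expect_equal(got$Q, want$Q)
      expect_equal(got$n, want$n)
    }
  }
})

test_that("kimura2p matches an independent K80 evaluation on a (P,Q) grid", {
  for (P in c(0, 0.05, 0.1, 0.2)) {
    for (Q in c(0, 0.05, 0.1, 0.15)) {
      if (P + Q == 0) next
      want <- oracle_k2p_ape(P, Q)
      got <- kimura2p(P, Q)
      expect_false(got$saturated)
      expect_equal(got$K, want, tolerance = 1e-9)
    }
  }
  expect_equal(kimura2p(0, 0)$K, 0)
  expect_equal(kimura2p(0.1, 0.05)$K, 0.1701812, tolerance = 1e-6)
})

test_that("kimura2p flags saturation on both log branches", {
  expect_true(kimura2p(0.5, 0.1)$saturated)   # 1 - 2P - Q = -0.1
  expect_true(kimura2p(0.1, 0.5)$saturated)   # 1 - 2Q = 0
  expect_true(is.na(kimura2p(0.5, 0.1)$K))
})

test_that("K is monotone in P and Q and approaches P+Q near zero", {
  grid <- seq(0, 0.2, by = 0.02)
  for (Q in c(0, 0.05, 0.1)) {
    ks <- vapply(grid, function(P) kimura2p(P, Q)$K, numeric(1))
    expect_true(all(diff(ks) > 0))
  }
  for (P in c(0, 0.05, 0.1)) {
    ks <- vapply(grid, function(Q) kimura2p(P, Q)$K, numeric(1))
    expect_true(all(diff(ks) > 0))
  }
  for (P in c(1e-4, 5e-4)) {
    for (Q in c(1e-4, 4e-4)) {
      expect_lt(abs(kimura2p(P, Q)$K - (P + Q)), 1e-6)
    }
  }
})

test_that("the molecular clock converts K to years as T = K / (2r)", {
  expect_equal(age_from_k(0), 0)
  expect_equal(age_from_k(0.026), 1.0e6)
  expect_equal(age_from_k(1.482), 5.7e7)
  ck <- clock_params(rate_r = 1e-9)
  expect_equal(age_from_k(0.002, ck), 1e6)
  expect_error(age_from_k(NA_real_), "saturated")
})

test_that("expansion binning counts families once per occupied period", {
  dated <- data.frame(
    copy_id = sprintf("c%d", 1:5),
    family_id = c("famA", "famA", "famB", "famB", "famC"),
    age_years = c(0.2e6, 3e6, 0.7e6, 20e6, NA),
    saturated = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  h <- bin_expansions(dated)
  expect_equal(unname(h$family_counts), c(1L, 1L, 1L))
  expect_equal(h$other_families, 1L)        # famB's 0.7 My copy: gap
  expect_equal(h$n_saturated_copies, 1L)
  expect_equal(h$copy_bin, c(1L, 2L, 0L, 3L, NA))
  # closed-lower, open-upper boundaries
  b <- bin_expansions(data.frame(copy_id = "x", family_id = "f",
                                 age_years = 0.5e6, saturated = FALSE))
  expect_equal(unname(b$family_counts), c(0L, 0L, 0L))
  e <- bin_expansions(data.frame(copy_id = character(),
                                 family_id = character(),
                                 age_years = numeric(),
                                 saturated = logical()))
  expect_equal(sum(e$family_counts), 0L)
})

test_that("activity flagging needs two >95% full-length copies", {
  fams <- te_families(c("A", "B", "C"), "Copia", 5000L)
  cp <- te_copies(sprintf("c%d", 1:5), c("A", "A", "B", "C", "C"),
                  "c1", c(0L, 10000L, 20000L, 30000L, 40000L),
                  c(5000L, 15000L, 25000L, 35000L, 45000L),
                  identity_pct = c(97, 98, 95, 99, 80),
                  full_length = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  act <- flag_active(fams, cp)
  expect_equal(unname(act), c(TRUE, FALSE, FALSE))
  # 95.0 exactly fails the strict > threshold even with two copies
  cp$identity_pct <- c(95, 95, 95, 95, 95)
  expect_false(any(flag_active(fams, cp)))
  # full-length requirement: two 97% incomplete copies do not qualify
  cp$identity_pct <- c(97, 97, 97, 97, 97)
  cp$full_length <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(unname(flag_active(fams, cp)), c(FALSE, FALSE, TRUE))
})

test_that("simulated LTR pairs date back to their true age", {
  set.seed(2024)
  for (tau in c(0.5e6, 5e6)) {
    est <- replicate(60, est_age_pair(sim_ltr_pair(tau)))
    est <- est[!is.na(est)]
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - tau), 3 * se + 0.02 * tau)
  }
})
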