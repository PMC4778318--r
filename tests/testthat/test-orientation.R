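test_that("expected forward fraction follows the composition product rule", {
  uni <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  expect_equal(expected_forward_fraction("GGATC", uni)$F_expected, 0.5)
  # composition of the full 500-nt interval (A 33.9%, T 33.4%):
  # F(AAA) = .339^3 / (.339^3 + .334^3)
  tab1 <- c(A = 0.339, C = 0.168, G = 0.158, T = 0.334)
  ef <- expected_forward_fraction("AAA", tab1)
  expect_equal(ef$P_fw, 0.339^3, tolerance = 1e-12)
  expect_equal(ef$P_rc, 0.334^3, tolerance = 1e-12)
  expect_equal(ef$F_expected, 0.339^3 / (0.339^3 + 0.334^3),
               tolerance = 1e-12)
  expect_equal(round(ef$F_expected, 3), 0.511)
  # palindromes are composition-invariant
  skewed <- c(A = 0.5, C = 0.2, G = 0.2, T = 0.1)
  expect_equal(expected_forward_fraction("ACGT", skewed)$F_expected, 0.5)
  # ambiguity codes sum the allowed base probabilities
  ef_r <- expected_forward_fraction("R", skewed)
  expect_equal(ef_r$P_fw, 0.7)
  expect_equal(ef_r$P_rc, 0.3)
  expect_error(expected_forward_fraction("AC", c(A = 1, C = 0, G = 0, T = 0)),
               "positive")
})

test_that("F(m) + F(rc(m)) = 1 for any motif and composition", {
  set.seed(41)
  for (i in 1:30) {
    p <- as.numeric(rmultinom(1, 1000, c(0.3, 0.2, 0.2, 0.3))) + 1
    comp <- setNames(p / sum(p), c("A", "C", "G", "T"))
    m <- random_iupac(sample(4:10, 1L))
    f1 <- expected_forward_fraction(m, comp)$F_expected
    f2 <- expected_forward_fraction(reverse_complement(m), comp)$F_expected
    expect_equal(f1 + f2, 1, tolerance = 1e-12)
  }
})

test_that("orientation test matches exact binomial tails and signs", {
  res <- orientation_test(10L, 0L, 0.5)
  expect_equal(res$p_value, 2 * 0.5^10, tolerance = 1e-12)
  expect_identical(res$preferred, "fw")
  res2 <- orientation_test(6L, 6L, 0.5)
  expect_equal(res2$p_value, 1)
  expect_identical(res2$preferred, "none")
  expect_identical(orientation_test(5L, 5L, 0.9)$preferred, "rc")
  # below min_hits: not assessable
  res3 <- orientation_test(4L, 4L, 0.5)
  expect_false(res3$assessable)
  expect_true(is.na(res3$p_value))
})

test_that("orientation test equals the enumeration oracle for n <= 20", {
  for (n in c(10L, 15L, 20L)) {
    for (F0 in c(0.3, 0.5, 0.62)) {
      for (k in seq(0L, n, by = 2L)) {
        got <- orientation_test(k, n - k, F0)$p_value
        expect_equal(got, oracle_binom_two_sided(k, n, F0),
                     tolerance = 1e-10, info = sprintf("k=%d n=%d F=%g", k, n, F0))
      }
    }
  }
})

test_that("positional entropy reproduces closed forms", {
  # one hit in each 50-nt bin
  uniform <- seq(-500L, -50L, by = 50L)
  expect_equal(positional_entropy(uniform)$PE, log(10), tolerance = 1e-12)
  expect_equal(positional_entropy(rep(-25L, 40L))$PE, 0)
  two_bins <- c(rep(-480L, 5L), rep(-20L, 5L))
  expect_equal(positional_entropy(two_bins)$PE, log(2), tolerance = 1e-12)
  expect_error(positional_entropy(integer(0L)), "at least one")
  expect_error(positional_entropy(-1L, n_bins = 3L), "divisible")
})

test_that("positional entropy is invariant under bin relabeling", {
  set.seed(42)
  starts <- sample(seq(-500L, -1L), 200L, replace = TRUE)
  pe <- positional_entropy(starts)
  # move every hit to the mirrored bin (bin b -> 11 - b), keeping counts
  mirrored <- -501L - starts
  pe_m <- positional_entropy(mirrored)
  expect_equal(pe_m$PE, pe$PE, tolerance = 1e-12)
  expect_equal(sort(pe_m$bin_probs), sort(pe$bin_probs), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  set.seed(43)
  p <- runif(50L)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(numeric(0L)), "no p-values")
})

make_verdict_inputs <- function(n = 6L, seed = 44L) {
  set.seed(seed)
  list(
    orient = data.frame(
      motif_id = paste0("m", 1:n), n_fw = 30L, n_rc = 20L,
      P_fw = 0.1, P_rc = 0.1, F_expected = 0.5,
      p_orient = runif(n), q_orient = NA_real_,
      preferred = sample(c("fw", "rc"), n, replace = TRUE),
      assessable = TRUE, stringsAsFactors = FALSE),
    presence = data.frame(motif_id = paste0("m", 1:n), p = runif(n),
                          d = runif(n, -0.1, 0.4)),
    oc = data.frame(motif_id = paste0("m", 1:n), p = runif(n),
                    d = runif(n, -0.5, 0.5)),
    pe = data.frame(motif_id = paste0("m", 1:n), PE_fw = runif(n, 0, log(10)),
                    PE_rc = runif(n, 0, log(10))))
}

test_that("verdict flags honor the nesting invariants on arbitrary inputs", {
  for (seed in 44:53) {
    x <- make_verdict_inputs(12L, seed)
    v <- classify_motifs(x$orient, x$presence, x$oc, x$pe)
    cc <- v$complete
    expect_true(all(!v$D2[cc] | v$D1[cc]))  # D2 => D1
    expect_true(all(!v$D3[cc] | v$D2[cc]))  # D3 => D2
    expect_true(all(!v$E[cc] | v$C[cc]))    # E => C
    expect_true(all(!v$F[cc] | v$E[cc]))    # F => E
  }
})

test_that("verdicts respond to constructed component statistics", {
  # strong presence effect, no orientation preference -> C without D1
  orient <- data.frame(motif_id = c("a", "b"), n_fw = c(25L, 60L),
                       n_rc = c(25L, 10L), P_fw = 0.1, P_rc = 0.1,
                       F_expected = 0.5,
                       p_orient = c(0.9, 1e-8), q_orient = NA_real_,
                       preferred = c("none", "fw"), assessable = TRUE,
                       stringsAsFactors = FALSE)
  presence <- data.frame(motif_id = c("a", "b"), p = c(1e-10, 1e-9),
                         d = c(0.5, 0.4))
  oc <- data.frame(motif_id = c("a", "b"), p = c(0.8, 1e-6),
                   d = c(0.0, 0.4))
  pe <- data.frame(motif_id = c("a", "b"), PE_fw = c(2.3, 0.9),
                   PE_rc = c(2.3, 2.2))
  v <- classify_motifs(orient, presence, oc, pe)
  expect_identical(v$C, c(TRUE, TRUE))
  expect_identical(v$D1, c(FALSE, TRUE))
  expect_identical(v$D2, c(FALSE, TRUE))
  expect_identical(v$D3, c(FALSE, TRUE))
  expect_identical(v$E, c(FALSE, TRUE))
  expect_identical(v$F, c(FALSE, TRUE))
})

test_that("motifs with missing component statistics are set aside", {
  x <- make_verdict_inputs(5L)
  x$presence$p[2L] <- NA_real_
  x$orient$assessable[3L] <- FALSE
  x$orient$p_orient[3L] <- NA_real_
  v <- classify_motifs(x$orient, x$presence, x$oc, x$pe)
  expect_identical(v$complete, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(v$C[!v$complete])))
})
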