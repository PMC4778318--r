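test_that("expression matrices round-trip and are validated", {
  set.seed(61)
  m <- matrix(rnorm(20), 4L, 5L,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path)
  expect_equal(back, m, tolerance = 1e-12)
  writeLines(c("gene_id\ts1\ts2\ts3", "g1\t1\t2\tNA", "g2\t1\t2\t3"), path)
  expect_error(read_expression_matrix(path), "missing")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t1\t2"), path)
  expect_error(read_expression_matrix(path), "samples")
})

test_that("pairwise correlations match the textbook formula", {
  expr <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 4, 6, 8, 10),
                g3 = c(5, 4, 3, 2, 1))
  expect_equal(pairwise_correlations(c("g1", "g2"), expr)[1L], 1)
  expect_equal(pairwise_correlations(c("g1", "g3"), expr)[1L], -1)
  set.seed(62)
  expr4 <- matrix(rnorm(20), 4L, 5L, dimnames = list(paste0("g", 1:4), NULL))
  r <- sort(pairwise_correlations(paste0("g", 1:4), expr4))
  hand <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  want <- sort(apply(combn(4L, 2L), 2L,
                     function(ij) hand(expr4[ij[1L], ], expr4[ij[2L], ])))
  expect_equal(as.numeric(r), want, tolerance = 1e-12)
  expect_error(pairwise_correlations("g1", expr4), "at least 2")
  # absent genes are dropped
  expect_length(pairwise_correlations(c("g1", "g2", "nope"), expr4), 1L)
})

test_that("pair subsampling is seeded and unbiased", {
  set.seed(63)
  expr <- matrix(rnorm(60 * 30), 60L, 30L,
                 dimnames = list(sprintf("g%02d", 1:60), NULL))
  genes <- rownames(expr)
  full <- pairwise_correlations(genes, expr)
  sub1 <- pairwise_correlations(genes, expr, pair_cap = 400L, seed = 9L)
  sub2 <- pairwise_correlations(genes, expr, pair_cap = 400L, seed = 9L)
  expect_identical(as.numeric(sub1), as.numeric(sub2))
  expect_length(sub1, 400L)
  expect_true(all(round(sub1, 12) %in% round(full, 12)))
  se <- sd(full) / sqrt(400L)
  expect_lt(abs(mean(sub1) - mean(full)), 3 * se)
})

test_that("Cohen's d is the standardized mean difference", {
  a <- c(0.1, 0.3, 0.5); b <- c(0.1, 0.3, 0.5)
  expect_equal(cohens_d(a, b), 0)
  a2 <- c(0.1, 0.3, 0.5) + 0.2
  expect_equal(cohens_d(a2, b), 0.2 / 0.2)
  set.seed(64)
  x <- rnorm(50L); y <- rnorm(40L)
  expect_equal(cohens_d(x, y), -cohens_d(y, x), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("set comparison detects a shared latent factor", {
  set.seed(65)
  n_samples <- 200L
  z <- rnorm(n_samples)
  module <- t(replicate(60L, 0.5 * z + rnorm(n_samples)))
  noise <- matrix(rnorm(60L * n_samples), 60L)
  expr <- rbind(module, noise)
  rownames(expr) <- sprintf("g%03d", 1:120)
  cmp <- compare_sets(rownames(expr)[1:60], rownames(expr)[61:120], expr)
  expect_lt(cmp$p_r_diff, 1e-6)
  expect_gt(cmp$cohens_d, 0.1)
  # identical sets: no difference
  same <- compare_sets(rownames(expr)[1:30], rownames(expr)[1:30], expr)
  expect_equal(same$cohens_d, 0, tolerance = 1e-12)
  expect_gt(same$p_r_diff, 0.9)
})

test_that("Wilcoxon p agrees with the rank-enumeration oracle at small n", {
  set.seed(66)
  for (i in 1:20) {
    a <- rnorm(4L); b <- rnorm(4L)
    got <- wilcox.test(a, b)$p.value
    expect_equal(got, oracle_wilcoxon_two_sided(a, b), tolerance = 1e-10)
  }
})

test_that("estimated effect size grows with the factor loading", {
  set.seed(67)
  d_of_lambda <- vapply(c(0, 0.25, 0.5), function(lambda) {
    mean(replicate(20L, {
      ns <- 120L
      z <- rnorm(ns)
      module <- t(replicate(30L, lambda * z + rnorm(ns)))
      noise <- matrix(rnorm(30L * ns), 30L)
      expr <- rbind(module, noise)
      rownames(expr) <- sprintf("g%02d", 1:60)
      compare_sets(rownames(expr)[1:30], rownames(expr)[31:60], expr)$cohens_d
    }))
  }, numeric(1L))
  expect_true(all(diff(d_of_lambda) > 0))
})

test_that("shuffled set labels give uniform p-values", {
  set.seed(68)
  expr <- matrix(rnorm(40L * 60L), 40L, 60L,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  ps <- replicate(200L, {
    idx <- sample(40L)
    compare_sets(rownames(expr)[idx[1:20]], rownames(expr)[idx[21:40]],
                 expr)$p_r_diff
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("presence/absence sets follow the sizing rules", {
  w <- small_oriented_world()
  ms <- curate_catalog(w$catalog)
  mt <- map_catalog(ms, w$regions, c(-500, -1))
  universe <- rownames(w$expr)
  sets <- build_presence_absence_sets("oriented_confined", mt, universe,
                                      min_neg = 100L, seed = 3L)
  expect_gt(length(sets$positive), 100L)
  expect_identical(length(sets$negative), length(sets$positive))
  expect_length(intersect(sets$negative,
                          gene_sets(mt, "oriented_confined")$any), 0L)
  # small positive set -> negative set floored at min_neg
  tiny_mt <- mt
  keep <- mt$hits$motif_id == "oriented_confined" &
    mt$hits$gene_id %in% gene_sets(mt, "oriented_confined")$any[1:20]
  tiny_mt$hits <- mt$hits[keep, ]
  tiny <- build_presence_absence_sets("oriented_confined", tiny_mt, universe,
                                      min_neg = 100L, seed = 3L)
  expect_lte(length(tiny$positive), 20L)
  expect_identical(length(tiny$negative), 100L)
  # motif everywhere -> no negatives -> error naming the motif
  all_mt <- mt
  all_mt$hits <- data.frame(gene_id = mt$gene_ids, motif_id = "everywhere",
                            orientation = "fw", start = -10L, end = -5L)
  all_mt$motif_ids <- "everywhere"
  expect_error(build_presence_absence_sets("everywhere", all_mt, universe),
               "everywhere")
})

test_that("orientation sets are exclusive and disjoint", {
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    motif_id = "m",
    orientation = c("fw", "rc", "fw", "rc"),
    start = c(-50L, -80L, -50L, -50L), end = c(-45L, -75L, -45L, -45L))
  mt <- structure(list(hits = hits, interval = interval_spec(-100, -1),
                       region_length = 100L,
                       gene_ids = c("g1", "g2", "g3", "g4"),
                       motif_ids = "m"), class = "mapping_table")
  sets <- build_orientation_sets("m", mt)
  expect_identical(sets$fw_only, "g2")
  expect_identical(sets$rc_only, "g3")
  expect_false(sets$assessable)
  expect_length(intersect(sets$fw_only, sets$rc_only), 0L)
})
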