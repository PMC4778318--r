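make_mt <- function(hits, genes, motifs, interval = c(-500L, -51L),
                    L = 500L) {
  structure(list(hits = hits, interval = interval_spec(interval[1L],
                                                       interval[2L]),
                 region_length = L, gene_ids = genes, motif_ids = motifs),
            class = "mapping_table")
}

test_that("pair instances respect order, orientation and overlap rules", {
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2"),
    motif_id = c("A", "B", "A", "B"),
    orientation = c("fw", "rc", "fw", "rc"),
    start = c(-300L, -100L, -200L, -203L),
    end = c(-295L, -95L, -195L, -198L))
  mt <- make_mt(hits, c("g1", "g2"), c("A", "B"))
  inst <- find_pair_instances(mt, "A", "B")
  # g2's hits overlap (-203..-198 vs -200..-195) -> only g1 contributes
  expect_identical(nrow(inst), 1L)
  expect_identical(inst$gene_id, "g1")
  expect_identical(inst$order, "1_then_2")
  expect_identical(inst$ori_1, "fw")
  expect_identical(inst$ori_2, "rc")
  # max_gap: g1's gap is -100 - (-295) - 1 = 194
  expect_identical(nrow(find_pair_instances(mt, "A", "B", max_gap = 100L)),
                   0L)
  expect_identical(nrow(find_pair_instances(mt, "A", "B", max_gap = 200L)),
                   1L)
  # swapping the motif labels flips the order deterministically
  inst_sw <- find_pair_instances(mt, "B", "A")
  expect_identical(inst_sw$order, "2_then_1")
  expect_identical(inst_sw$ori_1, "rc")
})

test_that("same-motif pairs use unordered distinct hits and 4 cells", {
  hits <- data.frame(
    gene_id = "g1", motif_id = "A",
    orientation = c("fw", "rc", "fw"),
    start = c(-400L, -300L, -100L), end = c(-395L, -295L, -95L))
  mt <- make_mt(hits, "g1", "A")
  inst <- find_pair_instances(mt, "A", "A")
  expect_identical(nrow(inst), 3L)  # C(3,2) unordered pairs
  expect_true(all(inst$start_1 < inst$start_2))
  cnt <- pair_arrangement_counts(inst, "A", "A")
  expect_length(cnt$counts, 4L)
  expect_identical(sum(cnt$counts), 3L)
  expect_identical(cnt$counts[["fw:rc"]], 1L)  # -400fw then -300rc
  expect_error(order_test(cnt), "same-motif")
  expect_error(order_conditional_tests(cnt), "same-motif")
})

test_that("arrangement counts are equivariant under motif relabeling", {
  set.seed(81)
  hits_list <- lapply(1:30, function(g) {
    s1 <- sample(seq(-480L, -260L, by = 20L), 1L)
    s2 <- sample(seq(-240L, -60L, by = 20L), 1L)
    data.frame(gene_id = paste0("g", g), motif_id = c("A", "B"),
               orientation = sample(c("fw", "rc"), 2L, replace = TRUE),
               start = c(s1, s2), end = c(s1, s2) + 5L)
  })
  hits <- do.call(rbind, hits_list)
  mt <- make_mt(hits, paste0("g", 1:30), c("A", "B"))
  c_ab <- pair_arrangement_counts(find_pair_instances(mt, "A", "B"), "A", "B")
  c_ba <- pair_arrangement_counts(find_pair_instances(mt, "B", "A"), "B", "A")
  # cell (order o, ori1, ori2) maps to (other order, ori2, ori1)
  map_cell <- function(cell) {
    parts <- strsplit(cell, ":")[[1L]]
    paste(if (parts[1L] == "1_then_2") "2_then_1" else "1_then_2",
          parts[3L], parts[2L], sep = ":")
  }
  for (cell in names(c_ab$counts)) {
    expect_identical(c_ba$counts[[map_cell(cell)]], c_ab$counts[[cell]])
  }
  expect_equal(arrangement_entropy_test(c_ab, 1000L, seed = 1L)$entropy_H,
               arrangement_entropy_test(c_ba, 1000L, seed = 1L)$entropy_H,
               tolerance = 1e-12)
})

test_that("co-occurrence enrichment matches hypergeometric enumeration", {
  expect_equal(cooccurrence_enrichment(5L, 5L, 5L, 20L), 1 / choose(20L, 5L),
               tolerance = 1e-12)
  expect_equal(cooccurrence_enrichment(10L, 10L, 0L, 10L), 1)
  set.seed(82)
  for (i in 1:30) {
    N <- sample(10:30, 1L)
    n1 <- sample(1:N, 1L); n2 <- sample(1:N, 1L)
    k <- sample(max(0L, n1 + n2 - N):min(n1, n2), 1L)
    expect_equal(cooccurrence_enrichment(n1, n2, k, N),
                 oracle_hyper_upper(n1, n2, k, N), tolerance = 1e-10,
                 info = sprintf("N=%d n1=%d n2=%d k=%d", N, n1, n2, k))
  }
  expect_error(cooccurrence_enrichment(5L, 5L, 6L, 20L))
})

test_that("the order test is an exact 50:50 binomial", {
  cnt <- structure(list(motif_1 = "A", motif_2 = "B", same_motif = FALSE,
                        counts = setNames(c(25L, 25L, rep(0L, 6L)),
                                          motifOrient:::ARRANGEMENT_CELLS_8),
                        n_total = 50L, genes_with_pair = 50L),
                   class = "pair_arrangement_counts")
  expect_equal(order_test(cnt)$p_value, 1)
  cnt$counts <- setNames(c(50L, rep(0L, 7L)),
                         motifOrient:::ARRANGEMENT_CELLS_8)
  expect_lt(abs(order_test(cnt)$p_value / (2 * 0.5^50) - 1), 1e-9)
  expect_identical(order_test(cnt)$n_order_1, 25L + 25L - 0L)
  cnt$n_total <- 40L
  expect_false(order_test(cnt)$assessable)
})

test_that("arrangement entropy is maximal for balanced counts, minimal when concentrated", {
  cells <- motifOrient:::ARRANGEMENT_CELLS_8
  balanced <- arrangement_entropy_test(setNames(rep(10L, 8L), cells),
                                       n_shuffles = 5000L, seed = 2L)
  expect_equal(balanced$entropy_H, log(8), tolerance = 1e-12)
  expect_gt(balanced$p_empirical, 0.5)
  concentrated <- arrangement_entropy_test(setNames(c(80L, rep(0L, 7L)),
                                                    cells),
                                           n_shuffles = 10000L, seed = 2L)
  expect_lt(concentrated$p_empirical, 1e-3)
  expect_lt(concentrated$entropy_H, balanced$entropy_H)
  # reproducibility under seed
  again <- arrangement_entropy_test(setNames(c(80L, rep(0L, 7L)), cells),
                                    n_shuffles = 10000L, seed = 2L)
  expect_identical(again$p_empirical, concentrated$p_empirical)
})

test_that("order-conditional tests separate order from arrangement preference", {
  cells <- motifOrient:::ARRANGEMENT_CELLS_8
  ord1 <- startsWith(cells, "1_then_2")
  # pure order imbalance: orientations uniform within the favored order
  counts <- setNames(integer(8L), cells)
  counts[ord1] <- 30L
  cnt <- structure(list(motif_1 = "A", motif_2 = "B", same_motif = FALSE,
                        counts = counts, n_total = 120L,
                        genes_with_pair = 100L),
                   class = "pair_arrangement_counts")
  eight <- arrangement_entropy_test(cnt, 20000L, seed = 3L)
  expect_lt(eight$p_empirical, 0.05)
  cond <- order_conditional_tests(cnt, 20000L, seed = 3L)
  expect_gt(cond$order_1$p_empirical, 0.2)
  expect_false(cond$order_2$assessable)  # zero instances in that order
  # one dominant cell within each order: all three tests significant
  counts2 <- setNames(integer(8L), cells)
  counts2[ord1] <- c(60L, 5L, 5L, 5L)
  counts2[!ord1] <- c(45L, 4L, 4L, 4L)
  cnt2 <- structure(list(motif_1 = "A", motif_2 = "B", same_motif = FALSE,
                         counts = counts2, n_total = sum(counts2),
                         genes_with_pair = 90L),
                    class = "pair_arrangement_counts")
  cond2 <- order_conditional_tests(cnt2, 20000L, seed = 4L)
  expect_lt(arrangement_entropy_test(cnt2, 20000L, 4L)$p_empirical, 0.01)
  expect_lt(cond2$order_1$p_empirical, 0.01)
  expect_lt(cond2$order_2$p_empirical, 0.01)
})

test_that("empirical p-values are uniform under the multinomial null", {
  set.seed(83)
  ps <- vapply(1:300, function(i) {
    cnt <- as.integer(rmultinom(1L, 100L, rep(1 / 8, 8L)))
    arrangement_entropy_test(setNames(cnt, motifOrient:::ARRANGEMENT_CELLS_8),
                             n_shuffles = 1500L, seed = 1000L + i)$p_empirical
  }, numeric(1L))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("pair co-expression modes build the documented gene sets", {
  set.seed(84)
  n_genes <- 80L
  genes <- sprintf("g%02d", 1:n_genes)
  # genes 1..30 carry A and B (non-overlapping), 31..50 only A, 51..70 only B
  hits <- rbind(
    data.frame(gene_id = genes[1:30], motif_id = "A", orientation = "fw",
               start = -400L, end = -395L),
    data.frame(gene_id = genes[1:30], motif_id = "B", orientation = "rc",
               start = -200L, end = -195L),
    data.frame(gene_id = genes[31:50], motif_id = "A", orientation = "fw",
               start = -400L, end = -395L),
    data.frame(gene_id = genes[51:70], motif_id = "B", orientation = "fw",
               start = -200L, end = -195L))
  mt <- make_mt(hits, genes, c("A", "B"))
  inst <- find_pair_instances(mt, "A", "B")
  ns <- 100L
  z <- rnorm(ns)
  expr <- matrix(rnorm(n_genes * ns), n_genes, ns,
                 dimnames = list(genes, NULL))
  expr[1:30, ] <- expr[1:30, ] + 0.6 * matrix(z, 30L, ns, byrow = TRUE)
  cmp <- pair_coexpression(inst, mt, "A", "B", "both_vs_one", expr)
  expect_lt(cmp$p_r_diff, 1e-4)
  expect_gt(cmp$cohens_d, 0)
  expect_identical(cmp$n_genes_a, 30L)
  expect_identical(cmp$n_genes_b, 40L)
  # all instances share one order here -> order comparison not assessable
  expect_message(
    expect_null(pair_coexpression(inst, mt, "A", "B", "order_1_vs_order_2",
                                  expr)),
    "not assessable")
  top <- pair_coexpression(inst, mt, "A", "B", "top_arrangement_vs_rest",
                           expr)
  expect_null(top)  # every instance falls in the single top cell
})

test_that("pair analysis flags implanted co-occurrence and applies thresholds", {
  w <- small_oriented_world()
  ms <- curate_catalog(w$catalog)
  tab <- run_pair_analysis(ms, w$regions, expr = w$expr,
                           interval = c(-500L, -51L),
                           n_shuffles = 5000L, seed = 9L)
  expect_true(nrow(tab) >= 1L)
  expect_true(all(c("p_hypergeom", "q_hypergeom", "entropy_H",
                    "p_entropy") %in% names(tab)))
  expect_true(all(tab$genes_with_both > 5L))
  # same-motif rows, when present, carry no order statistics
  if (any(tab$same_motif))
    expect_true(all(is.na(tab$p_order[tab$same_motif])))
})
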