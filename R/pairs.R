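## Motif-pair co-occurrence, order and arrangement statistics. A pair
## instance is one non-overlapping combination of one hit of each motif in
## the same upstream interval of one gene. For distinct motifs each
## instance falls into one of eight arrangement cells (2 motif orders x 4
## orientation combinations); same-motif pairs have four cells (orientation
## of the upstream hit x orientation of the downstream hit; order carries
## no meaning). Arrangement preference is tested with an entropy statistic
## against an empirical multinomial-uniform null.

#' Enumerate non-overlapping pair instances
#'
#' @param mt A `mapping_table` (typically of the interval excluding the
#'   core promoter, e.g. `(-500, -51)`).
#' @param motif_1,motif_2 Motif identifiers (may be equal for same-motif
#'   pairs). Both must be among the mapped motifs.
#' @param max_gap Optional: keep only instances whose inter-hit gap (bases
#'   strictly between the two hits) is less than `max_gap`.
#' @return Data frame with one row per instance: `gene_id`, `start_1`,
#'   `end_1`, `ori_1`, `start_2`, `end_2`, `ori_2`, `order`
#'   (`"1_then_2"` when motif 1 is the more upstream, i.e. 5'-most hit).
#'   For same-motif pairs, instances are unordered distinct hit pairs and
#'   slot 1 holds the upstream hit.
#' @export
find_pair_instances <- function(mt, motif_1, motif_2, max_gap = NULL) {
  if (!(motif_1 %in% mt$motif_ids) || !(motif_2 %in% mt$motif_ids))
    stop("motif(s) not present in mapping table")
  same <- motif_1 == motif_2
  h <- mt$hits
  h1 <- h[h$motif_id == motif_1, ]
  h2 <- h[h$motif_id == motif_2, ]
  genes <- intersect(unique(h1$gene_id), unique(h2$gene_id))
  rows <- list()
  for (g in genes) {
    a <- h1[h1$gene_id == g, ]
    b <- h2[h2$gene_id == g, ]
    if (same) {
      n <- nrow(a)
      if (n < 2L) next
      combs <- utils::combn(n, 2L)
      for (k in seq_len(ncol(combs))) {
        i <- combs[1L, k]; j <- combs[2L, k]
        ## slot 1 = upstream (5'-most) hit
        if (a$start[j] < a$start[i]) { tmp <- i; i <- j; j <- tmp }
        if (a$start[j] <= a$end[i]) next  # overlap (or identical span)
        gap <- a$start[j] - a$end[i] - 1L
        if (!is.null(max_gap) && gap >= max_gap) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, start_1 = a$start[i], end_1 = a$end[i],
          ori_1 = a$orientation[i], start_2 = a$start[j],
          end_2 = a$end[j], ori_2 = a$orientation[j],
          order = "1_then_2", stringsAsFactors = FALSE)
      }
    } else {
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        if (a$start[i] <= b$end[j] && b$start[j] <= a$end[i]) next
        up_first <- a$start[i] < b$start[j]
        gap <- if (up_first) b$start[j] - a$end[i] - 1L
               else a$start[i] - b$end[j] - 1L
        if (!is.null(max_gap) && gap >= max_gap) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, start_1 = a$start[i], end_1 = a$end[i],
          ori_1 = a$orientation[i], start_2 = b$start[j],
          end_2 = b$end[j], ori_2 = b$orientation[j],
          order = if (up_first) "1_then_2" else "2_then_1",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0L), start_1 = integer(0L),
                      end_1 = integer(0L), ori_1 = character(0L),
                      start_2 = integer(0L), end_2 = integer(0L),
                      ori_2 = character(0L), order = character(0L))
  out
}

ARRANGEMENT_CELLS_8 <- as.vector(outer(
  c("1_then_2", "2_then_1"),
  as.vector(outer(c("fw", "rc"), c("fw", "rc"),
                  function(a, b) paste(a, b, sep = ":"))),
  function(o, or) paste(o, or, sep = ":")))

ARRANGEMENT_CELLS_4 <- as.vector(outer(c("fw", "rc"), c("fw", "rc"),
                                       function(a, b) paste(a, b, sep = ":")))

#' Tabulate arrangement counts of a motif pair
#'
#' @param instances Output of [find_pair_instances()].
#' @param motif_1,motif_2 Motif identifiers (for labeling; equal for
#'   same-motif pairs).
#' @return A `pair_arrangement_counts`: list with `motif_1`, `motif_2`,
#'   `same_motif`, `counts` (named integer vector over 8 cells
#'   `order:ori1:ori2`, or 4 cells `ori_up:ori_down` for same-motif
#'   pairs), `n_total`, and gene-level counts `genes_with_pair`.
#' @export
pair_arrangement_counts <- function(instances, motif_1, motif_2) {
  same <- motif_1 == motif_2
  if (same) {
    cells <- ARRANGEMENT_CELLS_4
    lab <- paste(instances$ori_1, instances$ori_2, sep = ":")
  } else {
    cells <- ARRANGEMENT_CELLS_8
    lab <- paste(instances$order, instances$ori_1, instances$ori_2,
                 sep = ":")
  }
  counts <- table(factor(lab, levels = cells))
  structure(list(motif_1 = motif_1, motif_2 = motif_2, same_motif = same,
                 counts = stats::setNames(as.integer(counts), cells),
                 n_total = nrow(instances),
                 genes_with_pair = length(unique(instances$gene_id))),
            class = "pair_arrangement_counts")
}

#' @export
print.pair_arrangement_counts <- function(x, ...) {
  cat(sprintf("pair %s / %s: %d instances in %d genes\n",
              x$motif_1, x$motif_2, x$n_total, x$genes_with_pair))
  print(x$counts)
  invisible(x)
}

#' Hypergeometric co-occurrence enrichment
#'
#' Upper-tail probability of observing at least `genes_with_both` genes
#' carrying both motifs, given `genes_with_1` and `genes_with_2` carriers
#' in a universe of `universe_n` genes.
#'
#' @param genes_with_1,genes_with_2 Carrier counts of the two motifs.
#' @param genes_with_both Genes with a valid (non-overlapping)
#'   co-occurrence.
#' @param universe_n Universe size.
#' @return Upper-tail hypergeometric p-value.
#' @export
cooccurrence_enrichment <- function(genes_with_1, genes_with_2,
                                    genes_with_both, universe_n) {
  stopifnot(genes_with_1 <= universe_n, genes_with_2 <= universe_n,
            genes_with_both <= min(genes_with_1, genes_with_2))
  stats::phyper(genes_with_both - 1L, genes_with_1,
                universe_n - genes_with_1, genes_with_2,
                lower.tail = FALSE)
}

#' Binomial motif-order test
#'
#' Exact two-sided binomial test of the order-1 instance count against an
#' expected 50% chance for both orders, summed over all four orientation
#' arrangements. Meaningless (and refused) for same-motif pairs.
#'
#' @param counts A `pair_arrangement_counts`.
#' @param min_n Minimum instances (default 50).
#' @return List with `p_value` (NA when below `min_n`), `n_order_1`,
#'   `n_order_2`, `assessable`.
#' @export
order_test <- function(counts, min_n = 50L) {
  if (counts$same_motif)
    stop("motif order is undefined for same-motif pairs")
  n1 <- sum(counts$counts[startsWith(names(counts$counts), "1_then_2")])
  n2 <- counts$n_total - n1
  if (counts$n_total < min_n)
    return(list(p_value = NA_real_, n_order_1 = n1, n_order_2 = n2,
                assessable = FALSE))
  list(p_value = stats::binom.test(n1, counts$n_total, 0.5)$p.value,
       n_order_1 = n1, n_order_2 = n2, assessable = TRUE)
}

## Entropy of counts after adding pseudocount 1 to each cell.
arrangement_entropy <- function(counts) {
  q <- (counts + 1) / sum(counts + 1)
  -sum(q * log(q))
}

#' Arrangement-entropy test with empirical null
#'
#' Computes the Shannon entropy (natural log) of the arrangement cell
#' frequencies after adding a pseudocount of 1 to every cell, and an
#' empirical p-value against `n_shuffles` multinomial draws of `n_total`
#' instances uniformly over the cells (same pseudocount): the fraction of
#' null entropies strictly smaller than the observed entropy. Small p
#' means the observed counts are more concentrated than random.
#'
#' @param counts A `pair_arrangement_counts`, or a bare named/unnamed
#'   integer vector of cell counts.
#' @param n_shuffles Null draws (default 100000).
#' @param seed Seed for the null draws.
#' @param min_n Minimum instances (default 50); below it the test is not
#'   assessable.
#' @param plus_one Use the `(r + 1) / (B + 1)` estimator instead of `r/B`
#'   (default FALSE).
#' @return List with `entropy_H`, `p_empirical` (0 is reported as 0 with
#'   `p_floor = 1/n_shuffles` attached), `assessable`.
#' @export
arrangement_entropy_test <- function(counts, n_shuffles = 100000L,
                                     seed = 1L, min_n = 50L,
                                     plus_one = FALSE) {
  cc <- if (inherits(counts, "pair_arrangement_counts")) counts$counts
        else counts
  n <- sum(cc)
  H <- arrangement_entropy(cc)
  if (n < min_n)
    return(list(entropy_H = H, p_empirical = NA_real_, assessable = FALSE,
                p_floor = 1 / n_shuffles))
  K <- length(cc)
  H_null <- with_seed(seed, {
    draws <- stats::rmultinom(n_shuffles, n, rep(1 / K, K)) + 1
    q <- draws / (n + K)
    -colSums(q * log(q))
  })
  r <- sum(H_null < H)
  p <- if (plus_one) (r + 1) / (n_shuffles + 1) else r / n_shuffles
  list(entropy_H = H, p_empirical = p, assessable = TRUE,
       p_floor = 1 / n_shuffles)
}

#' Order-conditional arrangement tests
#'
#' Applies the 4-cell arrangement-entropy test separately to the
#' orientation combinations within each motif order. A pair is
#' arrangement-preferring when the 8-cell test and both order-conditional
#' tests are significant; a pair significant on 8 cells solely through an
#' order imbalance fails the conditional tests.
#'
#' @param counts A `pair_arrangement_counts` of a distinct-motif pair.
#' @param n_shuffles,seed,min_n As in [arrangement_entropy_test()];
#'   `min_n` applies to each order's own instance total (default 50).
#' @return List with `order_1` and `order_2`, each an
#'   [arrangement_entropy_test()] result.
#' @export
order_conditional_tests <- function(counts, n_shuffles = 100000L,
                                    seed = 1L, min_n = 50L) {
  if (counts$same_motif)
    stop("order-conditional tests are undefined for same-motif pairs")
  cells <- names(counts$counts)
  c1 <- counts$counts[startsWith(cells, "1_then_2")]
  c2 <- counts$counts[startsWith(cells, "2_then_1")]
  list(order_1 = arrangement_entropy_test(c1, n_shuffles, seed, min_n),
       order_2 = arrangement_entropy_test(c2, n_shuffles, seed + 1L, min_n))
}

#' Pair-level co-expression comparison
#'
#' Builds the mode-specific gene sets and delegates to [compare_sets()]:
#'
#' * `both_vs_one`: genes carrying a valid co-occurrence of both motifs
#'   vs genes carrying exactly one of them (for same-motif pairs: the
#'   motif at least twice vs exactly once);
#' * `order_1_vs_order_2`: genes with instances of one motif order only
#'   vs the other order only (genes with both orders are excluded);
#' * `top_arrangement_vs_rest`: genes with an instance of the most
#'   frequent arrangement cell (ties broken by the lexicographically
#'   first label) vs genes whose instances all fall in other cells.
#'
#' @param instances Output of [find_pair_instances()].
#' @param mt The `mapping_table` the instances came from.
#' @param motif_1,motif_2 Motif identifiers.
#' @param mode Comparison mode (see above).
#' @param expr Expression matrix.
#' @param pair_cap,seed Passed to [compare_sets()].
#' @return A `coexpression_comparison`, or NULL with a message when a set
#'   has fewer than 2 measurable genes (not assessable).
#' @export
pair_coexpression <- function(instances, mt, motif_1, motif_2,
                              mode = c("both_vs_one", "order_1_vs_order_2",
                                       "top_arrangement_vs_rest"),
                              expr, pair_cap = 500000L, seed = 1L) {
  mode <- match.arg(mode)
  same <- motif_1 == motif_2
  if (mode == "both_vs_one") {
    if (same) {
      per_gene <- table(mt$hits$gene_id[mt$hits$motif_id == motif_1])
      set_a <- names(per_gene)[per_gene >= 2L]
      set_b <- names(per_gene)[per_gene == 1L]
    } else {
      set_a <- unique(instances$gene_id)
      g1 <- gene_sets(mt, motif_1)$any
      g2 <- gene_sets(mt, motif_2)$any
      set_b <- setdiff(union(g1, g2), intersect(g1, g2))
    }
  } else if (mode == "order_1_vs_order_2") {
    if (same) stop("motif order is undefined for same-motif pairs")
    g1 <- unique(instances$gene_id[instances$order == "1_then_2"])
    g2 <- unique(instances$gene_id[instances$order == "2_then_1"])
    both <- intersect(g1, g2)
    set_a <- setdiff(g1, both)
    set_b <- setdiff(g2, both)
  } else {
    cnt <- pair_arrangement_counts(instances, motif_1, motif_2)$counts
    top <- names(cnt)[order(-cnt, names(cnt))][1L]
    lab <- if (same) paste(instances$ori_1, instances$ori_2, sep = ":")
           else paste(instances$order, instances$ori_1, instances$ori_2,
                      sep = ":")
    set_a <- unique(instances$gene_id[lab == top])
    set_b <- setdiff(unique(instances$gene_id), set_a)
  }
  set_a <- intersect(set_a, rownames(expr))
  set_b <- intersect(set_b, rownames(expr))
  if (length(set_a) < 2L || length(set_b) < 2L) {
    message(sprintf("pair %s/%s mode %s: not assessable (set sizes %d, %d)",
                    motif_1, motif_2, mode, length(set_a), length(set_b)))
    return(NULL)
  }
  compare_sets(set_a, set_b, expr, pair_cap, seed)
}

#' Full pair analysis over a mapped catalog
#'
#' For every unordered pair (including same-motif pairs) of the supplied
#' motifs, counts valid co-occurrences and computes the hypergeometric
#' enrichment; pairs with more than `min_cooccurrences` co-occurring
#' genes are reported, and pairs with at least `min_instances` instances
#' additionally receive order, arrangement-entropy and order-conditional
#' tests. All p-value families are BH-corrected across the tested pairs.
#'
#' @param mt A `mapping_table` built from the uncontained pair subset
#'   (see [pair_motifs()]).
#' @param motif_ids Motifs to pair (default: all motifs of `mt`).
#' @param universe_n Hypergeometric universe size (default: number of
#'   mapped genes).
#' @param expr Optional expression matrix for `both_vs_one`
#'   co-expression columns.
#' @param min_cooccurrences Report pairs with more than this many
#'   co-occurring genes (default 5).
#' @param min_instances Minimum instances for arrangement/order tests
#'   (default 50).
#' @param n_shuffles Null draws for the entropy tests (default 100000).
#' @param max_gap Optional gap filter for instances.
#' @param seed Base seed.
#' @return Data frame, one row per reported pair, with co-occurrence,
#'   enrichment, order and arrangement statistics (NA where not
#'   assessable).
#' @export
pair_analysis <- function(mt, motif_ids = NULL, universe_n = NULL,
                          expr = NULL, min_cooccurrences = 5L,
                          min_instances = 50L, n_shuffles = 100000L,
                          max_gap = NULL, seed = 1L) {
  if (is.null(motif_ids)) motif_ids <- mt$motif_ids
  if (is.null(universe_n)) universe_n <- length(mt$gene_ids)
  pairs <- expand.grid(i = seq_along(motif_ids), j = seq_along(motif_ids))
  pairs <- pairs[pairs$i <= pairs$j, ]
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    m1 <- motif_ids[pairs$i[k]]; m2 <- motif_ids[pairs$j[k]]
    inst <- find_pair_instances(mt, m1, m2, max_gap = max_gap)
    cnt <- pair_arrangement_counts(inst, m1, m2)
    if (cnt$genes_with_pair <= min_cooccurrences) next
    n_g1 <- length(gene_sets(mt, m1)$any)
    n_g2 <- length(gene_sets(mt, m2)$any)
    p_hyper <- cooccurrence_enrichment(n_g1, n_g2, cnt$genes_with_pair,
                                       universe_n)
    seed_k <- seed + k
    ent <- arrangement_entropy_test(cnt, n_shuffles, seed_k,
                                    min_n = min_instances)
    p_order <- NA_real_
    p_ent_1 <- p_ent_2 <- NA_real_
    if (!cnt$same_motif) {
      ot <- order_test(cnt, min_n = min_instances)
      p_order <- ot$p_value
      oc <- order_conditional_tests(cnt, n_shuffles, seed_k + 1000L,
                                    min_n = min_instances)
      p_ent_1 <- oc$order_1$p_empirical
      p_ent_2 <- oc$order_2$p_empirical
    }
    p_expr <- d_expr <- NA_real_
    if (!is.null(expr)) {
      cmp <- pair_coexpression(inst, mt, m1, m2, "both_vs_one", expr,
                               seed = seed_k)
      if (!is.null(cmp)) { p_expr <- cmp$p_r_diff; d_expr <- cmp$cohens_d }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      motif_1 = m1, motif_2 = m2, same_motif = cnt$same_motif,
      genes_with_1 = n_g1, genes_with_2 = n_g2,
      genes_with_both = cnt$genes_with_pair, n_instances = cnt$n_total,
      p_hypergeom = p_hyper, entropy_H = ent$entropy_H,
      p_entropy = ent$p_empirical, p_order = p_order,
      p_entropy_order_1 = p_ent_1, p_entropy_order_2 = p_ent_2,
      p_expr = p_expr, d_expr = d_expr, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame())
  out <- do.call(rbind, rows)
  out$q_hypergeom <- bh_adjust(out$p_hypergeom)
  for (col in c("p_entropy", "p_order", "p_entropy_order_1",
                "p_entropy_order_2", "p_expr")) {
    qcol <- sub("^p_", "q_", col)
    out[[qcol]] <- NA_real_
    ok <- !is.na(out[[col]])
    if (any(ok)) out[[qcol]][ok] <- bh_adjust(out[[col]][ok])
  }
  ## arrangement-preferring: 8-cell and both order-conditional tests
  out$arrangement_preferring <- !out$same_motif &
    !is.na(out$q_entropy) & out$q_entropy < 0.05 &
    !is.na(out$q_entropy_order_1) & out$q_entropy_order_1 < 0.05 &
    !is.na(out$q_entropy_order_2) & out$q_entropy_order_2 < 0.05
  out[order(out$p_hypergeom), ]
}
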