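## Gene co-expression comparisons. A motif-defined gene set is judged
## co-expressed when the distribution of pairwise Pearson correlation
## coefficients within the set is shifted upward relative to a contrast
## set; the shift is tested with a two-sided Wilcoxon rank-sum test and
## sized with Cohen's d. Correlation pairs are treated as independent
## observations, faithfully reproducing the published protocol (not a
## statistical endorsement: pairs sharing a gene are dependent).

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Read a normalized expression matrix
#'
#' Tab-separated, first column gene ids, header row of sample ids; values
#' must be complete and numeric (normalized, log-scale expression).
#'
#' @param path File path.
#' @param min_samples Minimum number of samples (default 3).
#' @return Numeric matrix, genes in rows (rownames = gene ids).
#' @export
read_expression_matrix <- function(path, min_samples = 3L) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids in expression matrix")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values")
  if (anyNA(m)) stop("missing values in expression matrix")
  if (ncol(m) < min_samples)
    stop("expression matrix needs at least ", min_samples, " samples")
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix, genes in rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  tab <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise Pearson correlations within a gene set
#'
#' Computes the Pearson correlation coefficient for all `C(n, 2)` gene
#' pairs of the set (genes absent from the matrix are dropped), or a
#' seeded uniform subsample of `pair_cap` pairs when the full count
#' exceeds the cap.
#'
#' @param gene_set Character vector of gene ids.
#' @param expr Expression matrix, genes in rows.
#' @param pair_cap Maximum number of pairs (default 500000).
#' @param seed Seed for the subsampling draw (default 1).
#' @return Numeric vector of correlation coefficients; attribute
#'   `n_genes` gives the number of measurable genes used.
#' @export
pairwise_correlations <- function(gene_set, expr, pair_cap = 500000L,
                                  seed = 1L) {
  idx <- match(unique(gene_set), rownames(expr))
  idx <- idx[!is.na(idx)]
  n <- length(idx)
  if (n < 2L)
    stop("need at least 2 measurable genes (got ", n, ")")
  n_pairs <- n * (n - 1) / 2
  x <- expr[idx, , drop = FALSE]
  if (n_pairs <= pair_cap) {
    cm <- stats::cor(t(x))
    r <- cm[upper.tri(cm)]
  } else {
    k <- with_seed(seed, sample(n_pairs, pair_cap))
    ## linear upper-triangle index (column-major, i < j) -> (i, j)
    j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
    j <- ifelse(k <= (j - 1) * (j - 2) / 2, j - 1, j)  # float-safety
    i <- k - (j - 1) * (j - 2) / 2
    xs <- x - rowMeans(x)
    xs <- xs / sqrt(rowSums(xs^2))
    r <- rowSums(xs[i, , drop = FALSE] * xs[j, , drop = FALSE])
  }
  attr(r, "n_genes") <- n
  r
}

#' Cohen's d between two correlation samples
#'
#' Standardized mean difference: the difference of means over the square
#' root of the average variance, `(mean_a - mean_b) / sqrt((var_a +
#' var_b) / 2)`.
#'
#' @param r_a,r_b Numeric samples.
#' @return Scalar effect size (positive when `r_a` has the larger mean).
#' @export
cohens_d <- function(r_a, r_b) {
  if (length(r_a) < 2L || length(r_b) < 2L)
    stop("both samples need at least 2 values")
  pooled <- sqrt((stats::var(r_a) + stats::var(r_b)) / 2)
  if (pooled == 0) stop("zero pooled standard deviation")
  (mean(r_a) - mean(r_b)) / pooled
}

#' Compare co-expression of two gene sets
#'
#' Draws the pairwise-correlation samples of both sets and compares them
#' with a two-sided Wilcoxon rank-sum test (exact for small tie-free
#' samples, normal approximation with tie correction otherwise) plus
#' Cohen's d.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param expr Expression matrix, genes in rows.
#' @param pair_cap,seed Passed to [pairwise_correlations()].
#' @return A `coexpression_comparison`: list with `mean_r_a`, `mean_r_b`,
#'   `p_r_diff`, `cohens_d`, `n_pairs_a`, `n_pairs_b`, `n_genes_a`,
#'   `n_genes_b`.
#' @export
compare_sets <- function(set_a, set_b, expr, pair_cap = 500000L, seed = 1L) {
  r_a <- pairwise_correlations(set_a, expr, pair_cap, seed)
  r_b <- pairwise_correlations(set_b, expr, pair_cap, seed + 1L)
  p <- stats::wilcox.test(r_a, r_b)$p.value
  structure(list(mean_r_a = mean(r_a), mean_r_b = mean(r_b),
                 p_r_diff = p, cohens_d = cohens_d(r_a, r_b),
                 n_pairs_a = length(r_a), n_pairs_b = length(r_b),
                 n_genes_a = attr(r_a, "n_genes"),
                 n_genes_b = attr(r_b, "n_genes")),
            class = "coexpression_comparison")
}

#' @export
print.coexpression_comparison <- function(x, ...) {
  cat(sprintf(
    "co-expression comparison: mean r %.4f vs %.4f, p = %.3g, d = %.4f\n",
    x$mean_r_a, x$mean_r_b, x$p_r_diff, x$cohens_d))
  invisible(x)
}

#' Presence/absence gene sets for one motif
#'
#' The positive set holds the measurable genes with at least one hit of
#' the motif in the mapped interval, in either orientation. The negative
#' set is a seeded random sample of motif-free measurable genes, sized
#' `max(|positive|, min_neg)` (all motif-free genes when fewer are
#' available).
#'
#' @param motif_id Motif identifier.
#' @param mt A `mapping_table`.
#' @param universe Character vector of measurable gene ids (genes with
#'   expression data).
#' @param min_neg Minimum negative-set size (default 100).
#' @param seed Seed for the negative-set draw.
#' @return List with `positive`, `negative`.
#' @export
build_presence_absence_sets <- function(motif_id, mt, universe,
                                        min_neg = 100L, seed = 1L) {
  gs <- gene_sets(mt, motif_id)
  positive <- intersect(gs$any, universe)
  free <- intersect(gs$none, universe)
  if (length(free) == 0L)
    stop("no motif-free genes available for motif ", motif_id)
  target <- max(length(positive), min_neg)
  negative <- if (length(free) <= target) free
    else with_seed(seed, sample(free, target))
  list(positive = positive, negative = negative)
}

#' Exclusive orientation gene sets for one motif
#'
#' Genes whose interval carries the motif in the forward orientation only
#' versus genes carrying it in the reverse-complement orientation only;
#' genes with hits in both orientations belong to neither set.
#'
#' @param motif_id Motif identifier.
#' @param mt A `mapping_table`.
#' @param universe Measurable gene ids (defaults to all mapped genes).
#' @return List with `fw_only`, `rc_only`, `assessable` (both sets hold
#'   at least 2 measurable genes).
#' @export
build_orientation_sets <- function(motif_id, mt, universe = NULL) {
  gs <- gene_sets(mt, motif_id)
  fw_only <- gs$fw_only
  rc_only <- gs$rc_only
  if (!is.null(universe)) {
    fw_only <- intersect(fw_only, universe)
    rc_only <- intersect(rc_only, universe)
  }
  list(fw_only = fw_only, rc_only = rc_only,
       assessable = length(fw_only) >= 2L && length(rc_only) >= 2L)
}
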