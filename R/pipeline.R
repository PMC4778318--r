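## End-to-end orchestration: curate -> map -> orientation / positional /
## co-expression statistics -> filter cascade, per upstream interval, with
## optional TSV export; plus the randomized-control comparison and the
## interval-resolved orientation-preference profile.

DEFAULT_INTERVALS <- list(c(-500L, -1L), c(-250L, -1L), c(-100L, -1L),
                          c(-500L, -51L))

#' Single-motif analysis over upstream intervals
#'
#' Runs the full single-motif battery for every interval: catalog mapping,
#' composition-corrected orientation tests, presence/absence and
#' orientation-set co-expression comparisons, positional entropies (for
#' full-length intervals) and the C/D1/D2/D3/E/F filter cascade.
#'
#' @param motifs A `motif_set` (curated automatically when not yet
#'   curated).
#' @param regions An `upstream_set`.
#' @param expr Expression matrix, genes in rows.
#' @param intervals List of intervals (default `(-500,-1)`, `(-250,-1)`,
#'   `(-100,-1)`, `(-500,-51)`).
#' @param p_threshold,d_threshold Cascade thresholds (defaults 0.05,
#'   0.01).
#' @param min_hits Minimum mappings per motif for the orientation test
#'   (default 10).
#' @param min_neg Minimum negative-set size (default 100).
#' @param pair_cap Correlation-pair cap (default 500000).
#' @param n_bins Positional-entropy bins (default 10).
#' @param use_adjusted Apply thresholds to BH-adjusted p-values
#'   (default TRUE).
#' @param seed Base seed for negative-set draws and pair subsampling.
#' @param out_dir Optional directory for TSV export (per-interval detail
#'   files and a summary table).
#' @return List with `per_interval` (named by interval label: `mapping`,
#'   `orientation`, `presence`, `orientation_coexpr`, `pe`, `verdicts`)
#'   and `summary` (one row per interval with filter counts and
#'   percentages).
#' @export
run_single_motif_analysis <- function(motifs, regions, expr,
                                      intervals = DEFAULT_INTERVALS,
                                      p_threshold = 0.05,
                                      d_threshold = 0.01,
                                      min_hits = 10L, min_neg = 100L,
                                      pair_cap = 500000L, n_bins = 10L,
                                      use_adjusted = TRUE, seed = 1L,
                                      out_dir = NULL) {
  if (!isTRUE(attr(motifs, "curated"))) motifs <- curate_catalog(motifs)
  universe <- intersect(names(regions), rownames(expr))
  per_interval <- list()
  summary_rows <- list()
  for (iv in intervals) {
    iv <- as_interval(iv)
    lab <- interval_label(iv)
    mt <- map_catalog(motifs, regions, iv)
    orient <- orientation_stats(mt, motifs, regions = regions,
                                min_hits = min_hits)
    presence <- coexpr_table(mt, universe, expr, "presence",
                             min_neg = min_neg, pair_cap = pair_cap,
                             seed = seed)
    orient_cx <- coexpr_table(mt, universe, expr, "orientation",
                              pair_cap = pair_cap, seed = seed + 1L)
    pe <- NULL
    if (interval_width(iv) == mt$region_length &&
        mt$region_length %% n_bins == 0L)
      pe <- positional_entropy_stats(mt, n_bins)
    verdicts <- classify_motifs(orient, presence, orient_cx, pe,
                                p_threshold, d_threshold, use_adjusted)
    per_interval[[lab]] <- list(mapping = mt, orientation = orient,
                                presence = presence,
                                orientation_coexpr = orient_cx,
                                pe = pe, verdicts = verdicts)
    s <- summarize_verdicts(verdicts)
    s <- cbind(data.frame(interval = lab), s)
    summary_rows[[lab]] <- s
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  res <- list(per_interval = per_interval, summary = summary)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (lab in names(per_interval)) {
      tag <- gsub("[(),]", "", gsub(",", "_", lab))
      utils::write.table(per_interval[[lab]]$verdicts,
                         file.path(out_dir, paste0("verdicts_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      export_counts_tsv(per_interval[[lab]]$mapping,
                        file.path(out_dir, paste0("counts_", tag, ".tsv")))
    }
  }
  res
}

## Per-motif co-expression table: mode "presence" compares motif-carrying
## genes to a sampled motif-free negative set; mode "orientation" compares
## the exclusive forward-only and reverse-complement-only sets
## (d > 0 = higher correlations in the forward-only set).
coexpr_table <- function(mt, universe, expr, mode, min_neg = 100L,
                         pair_cap = 500000L, seed = 1L) {
  rows <- lapply(seq_along(mt$motif_ids), function(i) {
    mid <- mt$motif_ids[i]
    p <- d <- NA_real_
    if (mode == "presence") {
      sets <- tryCatch(
        build_presence_absence_sets(mid, mt, universe, min_neg,
                                    seed = seed + i),
        error = function(e) NULL)
      ok <- !is.null(sets) && length(sets$positive) >= 2L &&
        length(sets$negative) >= 2L
      if (ok) {
        # a 2-gene set yields a single correlation pair, leaving the
        # effect size undefined; such motifs stay not-assessable
        cmp <- tryCatch(
          compare_sets(sets$positive, sets$negative, expr, pair_cap,
                       seed = seed + i),
          error = function(e) NULL)
        if (!is.null(cmp)) { p <- cmp$p_r_diff; d <- cmp$cohens_d }
      }
    } else {
      sets <- build_orientation_sets(mid, mt, universe)
      if (sets$assessable) {
        cmp <- tryCatch(
          compare_sets(sets$fw_only, sets$rc_only, expr, pair_cap,
                       seed = seed + i),
          error = function(e) NULL)
        if (!is.null(cmp)) { p <- cmp$p_r_diff; d <- cmp$cohens_d }
      }
    }
    data.frame(motif_id = mid, p = p, d = d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pair analysis over the uncontained motif subset
#'
#' Maps the pair subset (see [pair_motifs()]) onto the core-promoter-free
#' interval and runs [pair_analysis()].
#'
#' @param motifs A `motif_set` (curated automatically).
#' @param regions An `upstream_set`.
#' @param expr Optional expression matrix.
#' @param interval Interval (default `(-500, -51)`).
#' @param ... Passed to [pair_analysis()].
#' @param out_dir Optional TSV export directory.
#' @return The [pair_analysis()] table.
#' @export
run_pair_analysis <- function(motifs, regions, expr = NULL,
                              interval = c(-500L, -51L), ...,
                              out_dir = NULL) {
  if (!isTRUE(attr(motifs, "curated"))) motifs <- curate_catalog(motifs)
  pm <- pair_motifs(motifs)
  mt <- map_catalog(pm, regions, as_interval(interval))
  tab <- pair_analysis(mt, expr = expr, ...)
  if (!is.null(out_dir) && nrow(tab) > 0L) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tab
}

#' Randomized-control comparison of filter pass rates
#'
#' Repeats the single-motif cascade for R1 (interval-composition) and R2
#' (motif-composition) randomized catalogs and Fisher-compares per-filter
#' pass rates against the true catalog, per interval.
#'
#' @param motifs A `motif_set` (curated automatically).
#' @param regions,expr As in [run_single_motif_analysis()].
#' @param intervals Intervals to compare (default the full set).
#' @param multiplier Random motifs per true motif (default 5).
#' @param seed Base seed.
#' @param ... Passed to [run_single_motif_analysis()].
#' @return Data frame: per interval, filter and background, pass
#'   fractions and Fisher p/q-values.
#' @export
run_control_comparison <- function(motifs, regions, expr,
                                   intervals = DEFAULT_INTERVALS,
                                   multiplier = 5L, seed = 1L, ...) {
  if (!isTRUE(attr(motifs, "curated"))) motifs <- curate_catalog(motifs)
  true_run <- run_single_motif_analysis(motifs, regions, expr,
                                        intervals = intervals,
                                        seed = seed, ...)
  rows <- list()
  for (iv in intervals) {
    iv <- as_interval(iv)
    lab <- interval_label(iv)
    comp <- base_composition(regions, iv)
    am <- analysis_motifs(motifs)
    r1 <- curate_catalog(generate_random_motifs(
      am, "R1_upstream", comp = comp, multiplier = multiplier,
      seed = seed + 101L))
    r2 <- curate_catalog(generate_random_motifs(
      am, "R2_motif", multiplier = multiplier, seed = seed + 202L))
    rand_verdicts <- list(
      R1 = run_single_motif_analysis(r1, regions, expr,
                                     intervals = list(iv),
                                     seed = seed + 1L,
                                     ...)$per_interval[[lab]]$verdicts,
      R2 = run_single_motif_analysis(r2, regions, expr,
                                     intervals = list(iv),
                                     seed = seed + 2L,
                                     ...)$per_interval[[lab]]$verdicts)
    cmp <- run_control_battery(true_run$per_interval[[lab]]$verdicts,
                               rand_verdicts)
    cmp <- cbind(data.frame(interval = lab), cmp)
    rows[[lab]] <- cmp
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interval-resolved orientation-preference profile
#'
#' For each non-overlapping 100-nt window, the percentage of motifs with
#' a significant (BH-corrected) orientation preference among motifs
#' mapping at least `min_hits` times to that window. With random
#' backgrounds, the profile is averaged over `repeats` freshly generated
#' random catalogs.
#'
#' @param motifs A curated `motif_set` or (for random backgrounds) the
#'   true catalog the random sets are derived from.
#' @param regions An `upstream_set`.
#' @param background `"true"`, `"R1_upstream"` or `"R2_motif"`.
#' @param repeats Random repeats to average (default 10; ignored for
#'   `"true"`).
#' @param min_hits Minimum mappings per window (default 10).
#' @param window Window width (default 100).
#' @param seed Base seed for random catalogs.
#' @return Data frame: `from_pos`, `to_pos`, `background`,
#'   `pct_oriented`, `n_motifs` (mean count of assessable motifs).
#' @export
orientation_profile <- function(motifs, regions,
                                background = c("true", "R1_upstream",
                                               "R2_motif"),
                                repeats = 10L, min_hits = 10L,
                                window = 100L, seed = 1L) {
  background <- match.arg(background)
  if (!isTRUE(attr(motifs, "curated"))) motifs <- curate_catalog(motifs)
  L <- attr(regions, "region_length")
  starts <- seq(-L, -1L, by = window)
  one_profile <- function(ms) {
    vapply(starts, function(s) {
      iv <- interval_spec(s, s + window - 1L)
      mt <- map_catalog(ms, regions, iv)
      ot <- orientation_stats(mt, ms, regions = regions,
                              min_hits = min_hits)
      n <- sum(ot$assessable)
      pct <- if (n == 0L) NA_real_ else
        100 * sum(ot$q_orient < 0.05, na.rm = TRUE) / n
      c(pct = pct, n = n)
    }, numeric(2L))
  }
  if (background == "true") {
    prof <- one_profile(motifs)
  } else {
    am <- analysis_motifs(motifs)
    comp <- base_composition(regions)
    mats <- lapply(seq_len(repeats), function(r) {
      rs <- generate_random_motifs(am, background, comp = comp,
                                   multiplier = 1L, seed = seed + r)
      one_profile(curate_catalog(rs))
    })
    prof <- Reduce(`+`, mats) / repeats
  }
  data.frame(from_pos = starts, to_pos = starts + window - 1L,
             background = background, pct_oriented = prof["pct", ],
             n_motifs = prof["n", ])
}
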