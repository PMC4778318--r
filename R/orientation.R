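## Composition-corrected orientation statistics. Under a zero-order
## background the chance that a mapped instance of motif m lies in forward
## rather than reverse-complement orientation is
##   F = P_fw / (P_fw + P_rc),  P_fw/rc = prod_i sum_{b in allowed(i)} p_b,
## with p_b the base frequencies of the scanned interval. Observed
## fw/rc counts are tested against F with an exact binomial test.

#' Expected forward-mapping fraction of a motif
#'
#' Computes the per-orientation background match probabilities `P_fw` and
#' `P_rc` (product over positions of the summed base frequencies allowed
#' at that position, for the consensus and its reverse complement) and the
#' expected forward fraction `F = P_fw / (P_fw + P_rc)`. Palindromic
#' motifs give `F = 0.5` under any composition.
#'
#' @param consensus IUPAC consensus string.
#' @param comp A `composition_profile` (or named numeric A/C/G/T
#'   frequencies), strictly positive.
#' @return List with `F_expected`, `P_fw`, `P_rc`.
#' @export
expected_forward_fraction <- function(consensus, comp) {
  freq <- if (inherits(comp, "composition_profile")) comp$freq else comp
  freq <- freq[c("A", "C", "G", "T")]
  if (any(is.na(freq)) || any(freq <= 0))
    stop("composition must be strictly positive for all four bases")
  prob_one <- function(seq) {
    chars <- strsplit(check_iupac(seq, "consensus"), "", fixed = TRUE)[[1L]]
    prod(vapply(IUPAC_SETS[chars], function(set) sum(freq[set]),
                numeric(1L)))
  }
  p_fw <- prob_one(consensus)
  p_rc <- prob_one(reverse_complement(consensus))
  list(F_expected = p_fw / (p_fw + p_rc), P_fw = p_fw, P_rc = p_rc)
}

#' Binomial orientation-preference test
#'
#' Exact two-sided binomial test of `n_fw` forward mappings among
#' `n_fw + n_rc` total mappings at success probability `F_expected`
#' (minimum-likelihood two-sided convention, as in [stats::binom.test()]).
#' The preferred orientation is the sign of
#' `log((n_fw/n_rc) / (F/(1-F)))`: `"fw"` when positive, `"rc"` when
#' negative, `"none"` when zero or undefined.
#'
#' @param n_fw,n_rc Observed forward / reverse-complement mapping counts.
#' @param F_expected Expected forward fraction from
#'   [expected_forward_fraction()].
#' @param min_hits Minimum total mappings for the test to be assessable
#'   (default 10).
#' @return List with `p_value` (NA when not assessable), `preferred`,
#'   `assessable`, `n_fw`, `n_rc`, `F_expected`.
#' @export
orientation_test <- function(n_fw, n_rc, F_expected, min_hits = 10L) {
  n <- n_fw + n_rc
  preferred <- if (n_fw == 0L && n_rc == 0L) "none"
    else if (n_rc == 0L) "fw"
    else if (n_fw == 0L) "rc"
    else {
      lr <- log((n_fw / n_rc) / (F_expected / (1 - F_expected)))
      if (lr > 0) "fw" else if (lr < 0) "rc" else "none"
    }
  if (n < min_hits) {
    return(list(p_value = NA_real_, preferred = preferred,
                assessable = FALSE, n_fw = n_fw, n_rc = n_rc,
                F_expected = F_expected))
  }
  p <- stats::binom.test(n_fw, n, p = F_expected)$p.value
  list(p_value = p, preferred = preferred, assessable = TRUE,
       n_fw = n_fw, n_rc = n_rc, F_expected = F_expected)
}

#' Positional entropy of motif hit locations
#'
#' Shannon entropy (natural log) of the distribution of hit start
#' positions over `n_bins` equal upstream bins: `PE = -sum p_i ln p_i`
#' with `0 ln 0 = 0`. Uniformly spread hits give `ln(n_bins)` (2.3026 for
#' 10 bins); hits confined to one bin give 0. Meaningful for the
#' full-length region only.
#'
#' @param starts Upstream start positions of the hits of one motif in one
#'   orientation (negative integers in `[-region_length, -1]`).
#' @param n_bins Number of equal bins (default 10).
#' @param region_length Region length, divisible by `n_bins` (default 500).
#' @return List with `bin_probs` (length `n_bins`, 5'-most bin first) and
#'   `PE` (nats).
#' @export
positional_entropy <- function(starts, n_bins = 10L, region_length = 500L) {
  if (length(starts) == 0L) stop("positional entropy needs at least one hit")
  if (region_length %% n_bins != 0L)
    stop("region_length must be divisible by n_bins")
  width <- region_length %/% n_bins
  if (any(starts < -region_length | starts > -1L))
    stop("start positions outside [-region_length, -1]")
  bin <- (starts + region_length) %/% width + 1L
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)
  nz <- p > 0
  list(bin_probs = p, PE = -sum(p[nz] * log(p[nz])))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values (monotone, capped at 1); thin wrapper over
#' [stats::p.adjust()] with `method = "BH"` that rejects empty input.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("no p-values to adjust")
  stats::p.adjust(p, method = "BH")
}

#' Per-motif orientation statistics for one mapped interval
#'
#' Runs [expected_forward_fraction()] and [orientation_test()] for every
#' motif of a mapping table, forming one BH family from the assessable
#' motifs of this interval.
#'
#' @param mt A `mapping_table`.
#' @param motifs The `motif_set` that was mapped (consensus lookup).
#' @param comp Composition profile of the mapped interval; computed from
#'   the interval itself when omitted requires `regions`.
#' @param regions Optional `upstream_set` used to compute `comp`.
#' @param min_hits Minimum mappings per motif (default 10).
#' @return Data frame with one row per motif: `motif_id`, `n_fw`, `n_rc`,
#'   `P_fw`, `P_rc`, `F_expected`, `p_orient`, `q_orient`, `preferred`,
#'   `assessable`.
#' @export
orientation_stats <- function(mt, motifs, comp = NULL, regions = NULL,
                              min_hits = 10L) {
  if (is.null(comp)) {
    if (is.null(regions)) stop("need comp or regions")
    comp <- base_composition(regions, mt$interval)
  }
  cnt <- hit_counts(mt)
  cons <- motifs$consensus[match(cnt$motif_id, motifs$id)]
  rows <- lapply(seq_len(nrow(cnt)), function(i) {
    ef <- expected_forward_fraction(cons[i], comp)
    ot <- orientation_test(cnt$n_fw[i], cnt$n_rc[i], ef$F_expected,
                           min_hits = min_hits)
    data.frame(motif_id = cnt$motif_id[i], n_fw = cnt$n_fw[i],
               n_rc = cnt$n_rc[i], P_fw = ef$P_fw, P_rc = ef$P_rc,
               F_expected = ef$F_expected, p_orient = ot$p_value,
               preferred = ot$preferred, assessable = ot$assessable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_orient <- NA_real_
  if (any(out$assessable))
    out$q_orient[out$assessable] <- bh_adjust(out$p_orient[out$assessable])
  out[, c("motif_id", "n_fw", "n_rc", "P_fw", "P_rc", "F_expected",
          "p_orient", "q_orient", "preferred", "assessable")]
}

#' Positional entropies for all motifs of a mapping table
#'
#' @param mt A `mapping_table` of a full-length scan.
#' @param n_bins Number of bins (default 10).
#' @return Data frame `motif_id`, `PE_fw`, `PE_rc` (NA when a motif has no
#'   hits in that orientation).
#' @export
positional_entropy_stats <- function(mt, n_bins = 10L) {
  L <- mt$region_length
  out <- data.frame(motif_id = mt$motif_ids, PE_fw = NA_real_,
                    PE_rc = NA_real_, stringsAsFactors = FALSE)
  for (ori in c("fw", "rc")) {
    col <- paste0("PE_", ori)
    sel <- mt$hits$orientation == ori
    sp <- split(mt$hits$start[sel], mt$hits$motif_id[sel])
    for (mid in names(sp)) {
      out[[col]][out$motif_id == mid] <-
        positional_entropy(sp[[mid]], n_bins, L)$PE
    }
  }
  out
}

#' Filter-cascade verdicts for all motifs of one interval
#'
#' Combines the orientation statistics, presence/absence co-expression
#' comparison, orientation-set co-expression comparison and (for
#' full-length scans) positional entropies into the nested filter flags:
#'
#' * `C` - significant presence/absence co-expression difference
#'   (`p_r_diff` below `p_threshold` and Cohen's d above `d_threshold`);
#' * `D1` - significant orientation preference;
#' * `D2` - `D1` and significantly higher intra-set correlation in the
#'   gene set of the preferred mapping orientation;
#' * `D3` - `D2` and lower positional entropy in the preferred
#'   orientation (full-length scans only, otherwise NA);
#' * `E` - the `D2` condition evaluated within the `C`-positive subset
#'   only, with the multiple-testing families re-formed over that subset;
#' * `F` - `E` and the `D3` entropy condition.
#'
#' Motifs missing any required component statistic are returned with
#' `complete = FALSE` and NA flags.
#'
#' @param orient Output of [orientation_stats()].
#' @param presence Data frame `motif_id`, `p`, `d` from presence/absence
#'   [compare_sets()] runs (raw p-values; BH is applied per family here).
#' @param orient_coexpr Data frame `motif_id`, `p`, `d` from forward-only
#'   vs reverse-complement-only comparisons; `d > 0` means higher
#'   correlations in the forward-only set.
#' @param pe Optional output of [positional_entropy_stats()].
#' @param p_threshold Significance threshold (default 0.05).
#' @param d_threshold Cohen's d threshold for filter C (default 0.01).
#' @param use_adjusted Apply thresholds to BH-adjusted values
#'   (default TRUE); set FALSE for raw p-values.
#' @return Data frame of per-motif flags `C`, `D1`, `D2`, `D3`, `E`, `F`
#'   plus the supporting statistics.
#' @export
classify_motifs <- function(orient, presence, orient_coexpr, pe = NULL,
                            p_threshold = 0.05, d_threshold = 0.01,
                            use_adjusted = TRUE) {
  v <- data.frame(motif_id = orient$motif_id, stringsAsFactors = FALSE)
  v$p_orient <- orient$p_orient
  v$q_orient <- orient$q_orient
  v$preferred <- orient$preferred
  i_pres <- match(v$motif_id, presence$motif_id)
  v$p_presence <- presence$p[i_pres]
  v$d_presence <- presence$d[i_pres]
  i_oc <- match(v$motif_id, orient_coexpr$motif_id)
  v$p_oc <- orient_coexpr$p[i_oc]
  v$d_oc <- orient_coexpr$d[i_oc]
  have_pe <- !is.null(pe)
  if (have_pe) {
    i_pe <- match(v$motif_id, pe$motif_id)
    v$PE_fw <- pe$PE_fw[i_pe]
    v$PE_rc <- pe$PE_rc[i_pe]
  } else {
    v$PE_fw <- NA_real_
    v$PE_rc <- NA_real_
  }

  ## completeness: every test must have been computable ("results of
  ## motifs with complete information across all tests")
  v$complete <- orient$assessable & !is.na(v$p_presence) & !is.na(v$p_oc)
  if (have_pe) v$complete <- v$complete & !is.na(v$PE_fw) & !is.na(v$PE_rc)

  cc <- v$complete
  v$C <- v$D1 <- v$D2 <- v$D3 <- v$E <- v$F <- NA
  if (!any(cc)) return(v)

  adj <- function(p) if (use_adjusted) bh_adjust(p) else p
  q_presence <- q_oc <- rep(NA_real_, nrow(v))
  q_presence[cc] <- adj(v$p_presence[cc])
  q_oc[cc] <- adj(v$p_oc[cc])
  q_or <- rep(NA_real_, nrow(v))
  q_or[cc] <- if (use_adjusted) bh_adjust(v$p_orient[cc]) else v$p_orient[cc]

  pref_gain <- (v$preferred == "fw" & v$d_oc > 0) |
               (v$preferred == "rc" & v$d_oc < 0)
  pe_lower <- ifelse(v$preferred == "fw", v$PE_fw < v$PE_rc,
              ifelse(v$preferred == "rc", v$PE_rc < v$PE_fw, FALSE))

  v$C[cc] <- q_presence[cc] < p_threshold & v$d_presence[cc] > d_threshold
  v$D1[cc] <- q_or[cc] < p_threshold
  v$D2[cc] <- v$D1[cc] & q_oc[cc] < p_threshold & pref_gain[cc]
  v$D3[cc] <- if (have_pe) v$D2[cc] & pe_lower[cc] else NA

  ## filter E: D2 condition within the C-positive subset, families re-formed
  v$E[cc] <- FALSE
  sub <- which(cc & v$C)
  if (length(sub) > 0L) {
    q_or_sub <- if (use_adjusted) bh_adjust(v$p_orient[sub]) else
      v$p_orient[sub]
    q_oc_sub <- if (use_adjusted) bh_adjust(v$p_oc[sub]) else v$p_oc[sub]
    v$E[sub] <- q_or_sub < p_threshold & q_oc_sub < p_threshold &
      pref_gain[sub]
  }
  v$F[cc] <- if (have_pe) v$E[cc] & pe_lower[cc] else NA
  v
}

#' Summarise a verdict table into filter counts
#'
#' @param verdicts Output of [classify_motifs()].
#' @return One-row data frame with the number of complete motifs and
#'   counts/percentages per filter.
#' @export
summarize_verdicts <- function(verdicts) {
  cc <- verdicts$complete
  n <- sum(cc)
  cnt <- function(col) sum(verdicts[[col]][cc], na.rm = TRUE)
  data.frame(n_motifs = n,
             C = cnt("C"), D1 = cnt("D1"), D2 = cnt("D2"), D3 = cnt("D3"),
             E = cnt("E"), F = cnt("F"),
             pct_C = 100 * cnt("C") / max(n, 1L),
             pct_D1 = 100 * cnt("D1") / max(n, 1L),
             pct_D2 = 100 * cnt("D2") / max(n, 1L),
             pct_E = 100 * cnt("E") / max(n, 1L))
}
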