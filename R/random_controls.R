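## Randomized-motif controls. Every true motif is replaced by `multiplier`
## random motifs of identical length, with positions drawn i.i.d. from one
## of two background distributions:
##   R1 ("upstream"): canonical bases A/C/G/T at the frequencies of the
##       analyzed upstream interval (no ambiguity codes);
##   R2 ("motif"):    characters (including ambiguity codes) at the
##       frequencies observed across the true motif consensus strings.

#' Generate a randomized motif catalog
#'
#' @param true_set A curated `motif_set` (lengths are taken from its
#'   analysis view).
#' @param background `"R1_upstream"` or `"R2_motif"`.
#' @param comp Interval `composition_profile` (required for R1).
#' @param multiplier Random motifs per true motif (default 5).
#' @param seed Seed for generation.
#' @return A `motif_set` with source `random_R1` / `random_R2` and
#'   `multiplier * n` motifs; the multiset of lengths equals `multiplier`
#'   copies of the true length multiset.
#' @export
generate_random_motifs <- function(true_set,
                                   background = c("R1_upstream", "R2_motif"),
                                   comp = NULL, multiplier = 5L, seed = 1L) {
  background <- match.arg(background)
  if (nrow(true_set) == 0L) stop("empty true motif set")
  if (background == "R1_upstream") {
    if (is.null(comp)) stop("R1 background needs an interval composition")
    freq <- if (inherits(comp, "composition_profile")) comp$freq else comp
    alphabet <- c("A", "C", "G", "T")
    probs <- as.numeric(freq[alphabet])
    src <- "random_R1"
  } else {
    chars <- strsplit(paste(true_set$consensus, collapse = ""), "",
                      fixed = TRUE)[[1L]]
    tab <- table(chars)
    alphabet <- names(tab)
    probs <- as.numeric(tab) / length(chars)
    src <- "random_R2"
  }
  lens <- nchar(true_set$consensus)
  with_seed(seed, {
    ids <- character(0L)
    cons <- character(0L)
    for (r in seq_len(multiplier)) {
      draw <- vapply(lens, function(l)
        paste(sample(alphabet, l, replace = TRUE, prob = probs),
              collapse = ""), character(1L))
      ids <- c(ids, sprintf("%s_%s_r%d", true_set$id,
                            sub("random_", "", src), r))
      cons <- c(cons, draw)
    }
    motif_set(ids, cons, src,
              provenance = sprintf("randomized (%s, x%d, seed %d)",
                                   background, multiplier, seed))
  })
}

#' Fisher comparison of filter pass rates
#'
#' Two-sided Fisher exact test on the 2x2 table of pass/fail counts for
#' true versus random motifs.
#'
#' @param k_true,n_true Passing / total true motifs.
#' @param k_rand,n_rand Passing / total random motifs.
#' @return Two-sided p-value.
#' @export
compare_pass_rates <- function(k_true, n_true, k_rand, n_rand) {
  stopifnot(k_true >= 0, k_true <= n_true, k_rand >= 0, k_rand <= n_rand,
            n_true > 0, n_rand > 0)
  tab <- matrix(c(k_true, n_true - k_true, k_rand, n_rand - k_rand), 2L)
  stats::fisher.test(tab)$p.value
}

#' Compare filter pass rates of true and random motif runs
#'
#' Given verdict tables (from [classify_motifs()]) of the true catalog and
#' one or more random catalogs under identical pipeline settings, tabulates
#' per-filter pass fractions and Fisher p-values, BH-corrected across the
#' comparison family.
#'
#' @param true_verdicts Verdict table of the true motifs.
#' @param random_verdicts Named list of verdict tables (e.g.
#'   `list(R1 = ..., R2 = ...)`).
#' @param filters Filter columns to compare (default C, D1, D2, E).
#' @return Data frame: `filter`, `background`, `k_true`, `n_true`,
#'   `frac_true`, `k_rand`, `n_rand`, `frac_rand`, `p_fisher`, `q_fisher`.
#' @export
run_control_battery <- function(true_verdicts, random_verdicts,
                                filters = c("C", "D1", "D2", "E")) {
  if (is.null(names(random_verdicts)))
    stop("random_verdicts must be a named list")
  count_pass <- function(v, f) {
    cc <- v$complete
    c(k = sum(v[[f]][cc], na.rm = TRUE), n = sum(cc))
  }
  rows <- list()
  for (f in filters) {
    kt <- count_pass(true_verdicts, f)
    for (bg in names(random_verdicts)) {
      kr <- count_pass(random_verdicts[[bg]], f)
      rows[[length(rows) + 1L]] <- data.frame(
        filter = f, background = bg,
        k_true = kt[["k"]], n_true = kt[["n"]],
        frac_true = kt[["k"]] / max(kt[["n"]], 1L),
        k_rand = kr[["k"]], n_rand = kr[["n"]],
        frac_rand = kr[["k"]] / max(kr[["n"]], 1L),
        p_fisher = compare_pass_rates(kt[["k"]], kt[["n"]],
                                      kr[["k"]], kr[["n"]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_fisher <- bh_adjust(out$p_fisher)
  out
}
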