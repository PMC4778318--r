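## Motif catalogs: a motif_set is a data.frame with columns
##   id        motif identifier (unique)
##   consensus IUPAC consensus string
##   source    one of "literature", "pbm", "core_promoter",
##             "random_R1", "random_R2"
##   flags     comma-joined curation flags ("" when unflagged)
## plus attributes provenance (free text) and curated (logical).

MOTIF_SOURCES <- c("literature", "pbm", "core_promoter",
                   "random_R1", "random_R2")

MOTIF_FLAGS <- c("palindromic", "contained_explicit", "contained_variant",
                 "dropped_short", "dropped_n_run", "duplicate")

#' Construct a motif set
#'
#' @param id Character vector of unique motif identifiers.
#' @param consensus IUPAC consensus strings.
#' @param source Source tags (recycled); see Details.
#' @param provenance Free-text provenance note.
#' @details Valid sources are `"literature"`, `"pbm"`, `"core_promoter"`,
#'   `"random_R1"` and `"random_R2"`.
#' @return A `motif_set` data.frame with columns `id`, `consensus`,
#'   `source`, `flags`.
#' @export
motif_set <- function(id, consensus, source = "literature",
                      provenance = "") {
  if (anyDuplicated(id))
    stop("motif ids must be unique")
  consensus <- vapply(consensus, check_iupac, character(1L),
                      what = "consensus", USE.NAMES = FALSE)
  source <- rep_len(as.character(source), length(id))
  if (!all(source %in% MOTIF_SOURCES))
    stop("unknown motif source: ",
         paste(setdiff(source, MOTIF_SOURCES), collapse = ", "))
  ms <- data.frame(id = as.character(id), consensus = consensus,
                   source = source, flags = "",
                   stringsAsFactors = FALSE)
  attr(ms, "provenance") <- provenance
  attr(ms, "curated") <- FALSE
  class(ms) <- c("motif_set", "data.frame")
  ms
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("motif_set: %d motifs (%scurated)\n", nrow(x),
              if (isTRUE(attr(x, "curated"))) "" else "not "))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}

has_flag <- function(ms, flag) {
  vapply(strsplit(ms$flags, ",", fixed = TRUE),
         function(f) any(f %in% flag), logical(1L))
}

add_flag <- function(flags, idx, flag) {
  flags[idx] <- ifelse(flags[idx] == "", flag,
                       paste(flags[idx], flag, sep = ","))
  flags
}

#' Read a motif catalog file
#'
#' Tab-separated with columns `motif_id`, `consensus`, `source` (and an
#' optional fourth `flags` column as written by [write_motif_catalog()]);
#' lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A `motif_set`.
#' @export
read_motif_catalog <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", fill = FALSE)
  if (ncol(raw) < 3L)
    stop("motif catalog needs columns motif_id<TAB>consensus<TAB>source")
  ms <- motif_set(raw[[1L]], raw[[2L]], raw[[3L]],
                  provenance = paste("read from", path))
  if (ncol(raw) >= 4L) {
    ms$flags <- raw[[4L]]
    ms$flags[is.na(ms$flags) | ms$flags == "."] <- ""
    attr(ms, "curated") <- TRUE
  }
  ms
}

#' Write a motif catalog file
#'
#' Emits `motif_id<TAB>consensus<TAB>source<TAB>flags` (flags comma-joined,
#' `.` when empty).
#'
#' @param ms A `motif_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_catalog <- function(ms, path) {
  out <- data.frame(ms$id, ms$consensus, ms$source,
                    ifelse(ms$flags == "", ".", ms$flags))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Trim terminal N characters (either end); may empty the string.
trim_terminal_n <- function(consensus) {
  sub("^N+", "", sub("N+$", "", consensus))
}

## Longest run of consecutive N in a consensus.
max_n_run <- function(consensus) {
  runs <- regmatches(consensus, gregexpr("N+", consensus))[[1L]]
  if (length(runs) == 0L) 0L else max(nchar(runs))
}

## TRUE iff motif `a` is contained in longer motif `b` at some offset with
## every position of `a` having a variant set that is a subset of the
## aligned position of `b`. Forward orientation only.
variant_contained_in <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la > lb) return(FALSE)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  for (off in 0:(lb - la)) {
    ok <- TRUE
    for (i in seq_len(la)) {
      if (!iupac_subset(ca[i], cb[off + i])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Curate a motif catalog
#'
#' Applies, in order: trimming of terminal `N` characters; dropping of
#' motifs with fewer than `min_unambiguous` unambiguous (A/C/G/T) bases;
#' dropping of motifs containing a run of `n_run_limit` or more consecutive
#' `N`; dropping of exact duplicate consensus strings (the first occurrence
#' is kept); flagging of palindromic motifs (excluded from orientation
#' analyses); and flagging of motifs contained in longer motifs, both by
#' explicit substring containment (`contained_explicit`) and, when
#' `variant_containment` is set, by per-position variant-set-subset
#' containment at any offset (`contained_variant`). Contained motifs are
#' kept (single-motif analyses) but excluded from pair analyses. Dropped
#' motifs remain in the returned set, carrying `dropped_*`/`duplicate`
#' flags; [analysis_motifs()] and [pair_motifs()] give the filtered views.
#'
#' Containment is evaluated in the forward orientation only; set
#' `rc_containment = TRUE` to additionally test against reverse-complemented
#' longer motifs.
#'
#' @param raw A `motif_set`.
#' @param min_unambiguous Minimum number of unambiguous bases (default 4).
#' @param n_run_limit Length of the disqualifying N run (default 4).
#' @param variant_containment Also flag containment under full variant
#'   expansion (default TRUE).
#' @param rc_containment Also test containment against reverse-complemented
#'   longer motifs (default FALSE).
#' @return The curated `motif_set` (flags populated, consensus trimmed).
#' @export
curate_catalog <- function(raw, min_unambiguous = 4L, n_run_limit = 4L,
                           variant_containment = TRUE,
                           rc_containment = FALSE) {
  ms <- raw
  ms$consensus <- trim_terminal_n(ms$consensus)
  if (any(ms$consensus == ""))
    stop("motif(s) empty after terminal-N trimming: ",
         paste(ms$id[ms$consensus == ""], collapse = ", "))
  flags <- rep("", nrow(ms))

  n_unamb <- vapply(strsplit(ms$consensus, "", fixed = TRUE),
                    function(ch) sum(ch %in% c("A", "C", "G", "T")),
                    integer(1L))
  flags <- add_flag(flags, n_unamb < min_unambiguous, "dropped_short")

  n_run <- vapply(ms$consensus, max_n_run, integer(1L), USE.NAMES = FALSE)
  flags <- add_flag(flags, n_run >= n_run_limit, "dropped_n_run")

  flags <- add_flag(flags, duplicated(ms$consensus), "duplicate")

  flags <- add_flag(flags, is_palindromic(ms$consensus), "palindromic")

  ## containment among surviving motifs only
  live <- !grepl("dropped_|duplicate", flags)
  live_idx <- which(live)
  for (i in live_idx) {
    others <- setdiff(live_idx, i)
    others <- others[nchar(ms$consensus[others]) >= nchar(ms$consensus[i])]
    ## an exact-duplicate pair never arises here (duplicates dropped), so
    ## equal-length containment means distinct codes with subset variants
    for (j in others) {
      targets <- ms$consensus[j]
      if (rc_containment) targets <- c(targets, reverse_complement(targets))
      expl <- any(vapply(targets, function(t)
        grepl(ms$consensus[i], t, fixed = TRUE), logical(1L)))
      if (expl && !has_single_flag(flags[i], "contained_explicit")) {
        flags[i] <- append_flag(flags[i], "contained_explicit")
      }
      if (variant_containment) {
        varc <- any(vapply(targets, function(t)
          variant_contained_in(ms$consensus[i], t), logical(1L)))
        if (varc && !has_single_flag(flags[i], "contained_variant"))
          flags[i] <- append_flag(flags[i], "contained_variant")
      }
    }
  }

  ms$flags <- flags
  live_after <- !grepl("dropped_|duplicate|palindromic", ms$flags)
  if (!any(live_after))
    stop("curation removed every motif")
  attr(ms, "curated") <- TRUE
  ms
}

has_single_flag <- function(flagstr, flag) {
  flag %in% strsplit(flagstr, ",", fixed = TRUE)[[1L]]
}

append_flag <- function(flagstr, flag) {
  if (flagstr == "") flag else paste(flagstr, flag, sep = ",")
}

#' Filtered views of a curated motif set
#'
#' `analysis_motifs()` returns the motifs used in single-motif analyses:
#' not dropped, not duplicates, not palindromic (contained motifs are kept,
#' merely flagged). `pair_motifs()` additionally excludes motifs contained
#' in longer motifs, yielding the truly uncontained subset used for the
#' pair analyses.
#'
#' @param ms A curated `motif_set`.
#' @return A `motif_set` subset.
#' @export
analysis_motifs <- function(ms) {
  if (!isTRUE(attr(ms, "curated"))) stop("motif set is not curated")
  keep <- !grepl("dropped_|duplicate|palindromic", ms$flags)
  subset_motifs(ms, keep)
}

#' @rdname analysis_motifs
#' @export
pair_motifs <- function(ms) {
  if (!isTRUE(attr(ms, "curated"))) stop("motif set is not curated")
  keep <- !grepl("dropped_|duplicate|palindromic|contained_", ms$flags)
  subset_motifs(ms, keep)
}

subset_motifs <- function(ms, keep) {
  out <- ms[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(ms, "provenance")
  attr(out, "curated") <- attr(ms, "curated")
  class(out) <- class(ms)
  out
}

#' Palindrome-enrichment binomial test
#'
#' Tests whether an observed number of palindromic motifs among `n` motifs
#' exceeds the rate expected of random motifs, using the exact binomial
#' upper tail: `P(X >= k)` with `X ~ Binomial(n, p0)`. The background rate
#' `p0` is typically estimated as the palindrome fraction of a large
#' random-motif sample with matched length distribution and composition.
#'
#' @param k Observed palindromic motifs.
#' @param n Total motifs.
#' @param p0 Background palindrome probability.
#' @return List with `p_value`, `k`, `n`, `p0`, `expected`.
#' @export
palindrome_enrichment_test <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  p <- stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
  list(p_value = p, k = k, n = n, p0 = p0, expected = n * p0)
}
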