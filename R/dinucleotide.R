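## First-order orientational asymmetry of upstream sequence. For each of
## the 16 dinucleotides B1B2:
##   R_B1B2   = f_B1B2 / (p_B1 * p_B2)   (occurrence ratio: observed vs
##              expected under zero-order independence)
##   DOR_B1B2 = R_B1B2 / R_rc(B1B2)      (dinucleotide orientation ratio)
## DOR departing from 1 signals that the forward dinucleotide is favoured
## over its reverse complement, i.e. intrinsic sequence directionality.
## Palindromic dinucleotides (AT, TA, CG, GC) have DOR = 1 identically.

DINUCLEOTIDES <- as.vector(outer(c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T"), paste0))

#' Pooled dinucleotide frequencies of an interval
#'
#' Counts overlapping (step 1) dinucleotides within the excised
#' subsequence of each region, never across gene boundaries. Positions
#' containing ambiguity codes are skipped. Frequencies are normalised by
#' the total number of counted dinucleotides.
#'
#' @param regions An `upstream_set`.
#' @param spec Interval of width >= 2 (default the full region).
#' @return Named numeric vector over the 16 dinucleotides, summing to 1.
#' @export
dinucleotide_frequencies <- function(regions, spec = NULL) {
  if (is.null(spec)) {
    L <- attr(regions, "region_length")
    spec <- interval_spec(-L, -1L)
  }
  spec <- as_interval(spec)
  if (interval_width(spec) < 2L) stop("interval width must be >= 2")
  sub <- excise(regions, spec)
  counts <- stats::setNames(numeric(16L), DINUCLEOTIDES)
  for (s in sub) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    if (n < 2L) next
    d1 <- ch[-n]; d2 <- ch[-1L]
    ok <- d1 %in% c("A", "C", "G", "T") & d2 %in% c("A", "C", "G", "T")
    if (!any(ok)) next
    tab <- table(factor(paste0(d1[ok], d2[ok]), levels = DINUCLEOTIDES))
    counts <- counts + as.numeric(tab)
  }
  total <- sum(counts)
  if (total == 0) stop("no countable dinucleotides in interval")
  counts / total
}

#' Occurrence ratios under zero-order expectation
#'
#' `R_B1B2 = f_B1B2 / (p_B1 * p_B2)` with single-base probabilities `p`
#' taken from the composition of the same interval. A dinucleotide whose
#' zero-order expectation is zero (a base absent from the interval) gets
#' `NA`.
#'
#' @param f Dinucleotide frequencies from [dinucleotide_frequencies()].
#' @param comp A `composition_profile` (or named A/C/G/T frequencies) of
#'   the same interval.
#' @return Named numeric vector of 16 occurrence ratios.
#' @export
occurrence_ratio <- function(f, comp) {
  freq <- if (inherits(comp, "composition_profile")) comp$freq else comp
  freq <- freq[c("A", "C", "G", "T")]
  if (any(is.na(freq)))
    stop("composition must provide all four base frequencies")
  b1 <- substr(DINUCLEOTIDES, 1L, 1L)
  b2 <- substr(DINUCLEOTIDES, 2L, 2L)
  expected <- as.numeric(freq[b1]) * as.numeric(freq[b2])
  r <- ifelse(expected > 0, as.numeric(f[DINUCLEOTIDES]) / expected,
              NA_real_)
  stats::setNames(r, DINUCLEOTIDES)
}

#' Dinucleotide orientation-ratio profile across windows
#'
#' For each window, computes dinucleotide frequencies, occurrence ratios
#' and orientation ratios `DOR = R_fw / R_rc` with their base-2
#' logarithms. Palindromic dinucleotides are reported as exactly 1
#' (log2 = 0). A reverse-complement ratio of zero leaves DOR as NA and is
#' flagged in the `defined` column.
#'
#' @param regions An `upstream_set`.
#' @param windows List of non-overlapping interval specifications
#'   (default: five 100-nt windows of a 500-nt region).
#' @return Long-format data frame: `from_pos`, `to_pos`, `dinucleotide`,
#'   `f`, `R`, `DOR`, `log2_DOR`, `defined`.
#' @export
dor_profile <- function(regions, windows = NULL) {
  L <- attr(regions, "region_length")
  if (is.null(windows)) {
    starts <- seq(-L, -1L, by = 100L)
    windows <- lapply(starts, function(s) interval_spec(s, s + 99L))
  }
  rc_d <- reverse_complement(DINUCLEOTIDES)
  palin <- DINUCLEOTIDES == rc_d
  rows <- lapply(windows, function(w) {
    w <- as_interval(w)
    f <- dinucleotide_frequencies(regions, w)
    comp <- base_composition(regions, w)
    R <- occurrence_ratio(f, comp)
    R_rc <- R[rc_d]
    dor <- ifelse(R_rc > 0, as.numeric(R) / as.numeric(R_rc), NA_real_)
    dor[palin] <- 1
    data.frame(from_pos = w[1L], to_pos = w[2L],
               dinucleotide = DINUCLEOTIDES,
               f = as.numeric(f), R = as.numeric(R), DOR = dor,
               log2_DOR = log2(dor), defined = !is.na(dor),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a DOR profile as TSV
#'
#' @param profile Output of [dor_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dor_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
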