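## Upstream regions: coding-strand sequences 5'->3' whose last base sits at
## upstream position -1, immediately 5' of the TSS. A region set is a named
## character vector (names = gene ids) with attribute region_length; all
## regions share one nominal length (default 500 nt).
##
## Coordinate convention: upstream positions are 1-based-negative closed
## intervals; position -L is the 5' end, -1 the 3' end. A sequence index j
## (1-based) corresponds to upstream position j - L - 1.

#' Construct an upstream region set
#'
#' @param seqs Named character vector of coding-strand sequences
#'   (names are gene ids).
#' @param region_length Nominal region length; defaults to the common
#'   sequence length.
#' @return An `upstream_set`: named uppercase character vector with
#'   attribute `region_length`.
#' @export
upstream_set <- function(seqs, region_length = NULL) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("every upstream region needs a gene id name")
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (is.null(region_length)) region_length <- lens[1L]
  if (any(lens != region_length))
    stop("region length mismatch for gene(s): ",
         paste(utils::head(names(seqs)[lens != region_length], 5L),
               collapse = ", "),
         " (expected ", region_length, ")")
  bad <- grepl(paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("non-IUPAC characters in gene(s): ",
         paste(utils::head(names(seqs)[bad], 5L), collapse = ", "))
  structure(seqs, region_length = as.integer(region_length),
            class = "upstream_set")
}

#' Read upstream regions from FASTA
#'
#' One record per gene; the first whitespace-delimited header token is the
#' gene id. All sequences must share one length unless `strict = FALSE`,
#' in which case longer sequences are truncated to their 3' (TSS-proximal)
#' end and shorter ones rejected.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @param strict Reject mixed lengths (default TRUE).
#' @param region_length Expected length; default taken from the first
#'   record.
#' @return An `upstream_set`.
#' @export
read_upstream_fasta <- function(path, strict = TRUE, region_length = NULL) {
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(dss), "\\s+"), `[[`, character(1L), 1L)
  seqs <- toupper(as.character(dss))
  names(seqs) <- ids
  if (is.null(region_length)) region_length <- nchar(seqs[1L])
  lens <- nchar(seqs)
  if (any(lens != region_length)) {
    if (strict)
      stop("sequence length != ", region_length, " for gene(s): ",
           paste(utils::head(ids[lens != region_length], 5L), collapse = ", "))
    if (any(lens < region_length))
      stop("sequence shorter than ", region_length, " for gene(s): ",
           paste(utils::head(ids[lens < region_length], 5L), collapse = ", "))
    seqs <- ifelse(lens > region_length,
                   substr(seqs, lens - region_length + 1L, lens), seqs)
  }
  upstream_set(seqs, region_length)
}

#' Write upstream regions to FASTA
#'
#' @param regions An `upstream_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_upstream_fasta <- function(regions, path) {
  dss <- Biostrings::BStringSet(unclass(regions))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' TSS-anchored interval specification
#'
#' Closed interval of upstream positions, e.g. `interval_spec(-500, -1)`
#' for the full region or `interval_spec(-100, -1)` for the 100 nt
#' immediately upstream of the TSS.
#'
#' @param from_pos,to_pos Negative inclusive bounds, `from_pos <= to_pos <= -1`.
#' @return An `interval_spec` (integer vector of length 2).
#' @export
interval_spec <- function(from_pos, to_pos) {
  from_pos <- as.integer(from_pos); to_pos <- as.integer(to_pos)
  if (is.na(from_pos) || is.na(to_pos) || from_pos > to_pos || to_pos > -1L)
    stop("need from_pos <= to_pos <= -1")
  structure(c(from_pos, to_pos), class = "interval_spec")
}

interval_width <- function(spec) spec[2L] - spec[1L] + 1L

interval_label <- function(spec) sprintf("(%d,%d)", spec[1L], spec[2L])

as_interval <- function(x) {
  if (inherits(x, "interval_spec")) x else interval_spec(x[1L], x[2L])
}

#' Excise a TSS-anchored interval
#'
#' Returns the subsequence at upstream positions `from_pos..to_pos`;
#' position -1 is the 3'-terminal base of each region.
#'
#' @param regions An `upstream_set` (or a plain named character vector of
#'   equal-length sequences).
#' @param spec An [interval_spec()] or length-2 numeric.
#' @return Named character vector of excised subsequences.
#' @export
excise <- function(regions, spec) {
  spec <- as_interval(spec)
  L <- attr(regions, "region_length")
  if (is.null(L)) L <- nchar(regions[1L])
  if (-spec[1L] > L)
    stop("interval ", interval_label(spec),
         " exceeds region length ", L)
  start <- spec[1L] + L + 1L
  end <- spec[2L] + L + 1L
  out <- as.vector(substr(unclass(regions), start, end))
  names(out) <- names(regions)
  out
}

#' Pooled base composition of an interval
#'
#' Counts bases over the excised subsequences of all regions, counting an
#' ambiguity code fractionally: a code allowing d bases contributes 1/d to
#' each. Frequencies are normalised by the total number of positions.
#'
#' @param regions An `upstream_set`.
#' @param spec Interval to profile (default the full region).
#' @return A `composition_profile`: list with `interval` and `freq`
#'   (named numeric A/C/G/T summing to 1).
#' @export
base_composition <- function(regions, spec = NULL) {
  if (is.null(spec)) {
    L <- attr(regions, "region_length")
    if (is.null(L)) L <- nchar(regions[1L])
    spec <- interval_spec(-L, -1L)
  }
  spec <- as_interval(spec)
  sub <- excise(regions, spec)
  chars <- strsplit(paste(sub, collapse = ""), "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop("no positions in interval")
  tab <- table(factor(chars, levels = IUPAC_CHARS))
  freq <- c(A = 0, C = 0, G = 0, T = 0)
  for (code in names(tab)) {
    n <- tab[[code]]
    if (n == 0) next
    set <- IUPAC_SETS[[code]]
    freq[set] <- freq[set] + n / length(set)
  }
  freq <- freq / length(chars)
  structure(list(interval = spec, freq = freq),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("base composition", interval_label(x$interval), ":",
      paste(sprintf("%s %.1f%%", names(x$freq), 100 * x$freq),
            collapse = "  "), "\n")
  invisible(x)
}

#' C/G skew profile across upstream windows
#'
#' For each non-overlapping window of `window` nt (5' to 3'), the ratio of
#' pooled C frequency to pooled G frequency (fractional ambiguity
#' counting). A window with zero G count reports `Inf`.
#'
#' @param regions An `upstream_set`.
#' @param window Window width in nt; must divide the region length.
#' @return Data frame with columns `from_pos`, `to_pos`, `ratio_cg`.
#' @export
cg_skew_profile <- function(regions, window = 100L) {
  L <- attr(regions, "region_length")
  if (L %% window != 0L) stop("window must divide region length")
  starts <- seq(-L, -1L, by = window)
  out <- lapply(starts, function(s) {
    comp <- base_composition(regions, interval_spec(s, s + window - 1L))
    data.frame(from_pos = s, to_pos = s + window - 1L,
               ratio_cg = if (comp$freq["G"] == 0) Inf
                          else unname(comp$freq["C"] / comp$freq["G"]))
  })
  do.call(rbind, out)
}

#' Write composition tables as TSV
#'
#' One row per interval with A/C/G/T percentages.
#'
#' @param regions An `upstream_set`.
#' @param specs List of interval specifications.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_composition_tsv <- function(regions, specs, path) {
  rows <- lapply(specs, function(sp) {
    sp <- as_interval(sp)
    comp <- base_composition(regions, sp)
    data.frame(interval = interval_label(sp),
               A = 100 * comp$freq[["A"]], C = 100 * comp$freq[["C"]],
               G = 100 * comp$freq[["G"]], T = 100 * comp$freq[["T"]])
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
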