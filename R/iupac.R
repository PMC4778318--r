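#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide ambiguity codes: per-code sets of allowed canonical bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CHARS <- names(IUPAC_SETS)

## Complement table: the complement of an ambiguity code is the code whose
## variant set is the base-wise complement of the original set
## (R<->Y, K<->M, B<->V, D<->H; S, W, N are self-complementary).
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B",
  D = "H", H = "D", N = "N"
)

#' Validate an IUPAC nucleotide string
#'
#' Checks that every character of `seq` is a valid IUPAC nucleotide code
#' (canonical bases A, C, G, T or the ambiguity codes R, Y, S, W, K, M, B,
#' D, H, V, N). Lowercase input is accepted and uppercased.
#'
#' @param seq A single character string.
#' @param what Label used in error messages.
#' @return The validated, uppercased string (invisibly usable).
#' @export
check_iupac <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% IUPAC_CHARS))
  if (length(bad) > 0L)
    stop(sprintf("invalid IUPAC character '%s' in %s at position %d",
                 chars[bad[1L]], what, bad[1L]))
  seq
}

#' Reverse complement of an IUPAC consensus
#'
#' Returns the reversed, base-wise complemented sequence. Ambiguity codes
#' map to the code whose allowed-base set is the complement of the original
#' set, e.g. `R` (A/G) maps to `Y` (C/T), `K` to `M`, `B` to `V`; `S`, `W`
#' and `N` are self-complementary.
#'
#' @param seq IUPAC nucleotide string (vectorised).
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("TATAAA")  # "TTTATA"
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- check_iupac(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Test whether a consensus is palindromic
#'
#' A motif is palindromic when it is identical, as an IUPAC string, to its
#' own reverse complement; such motifs present the same sequence on both
#' strands and are inherently orientation-invariant.
#'
#' @param seq IUPAC nucleotide string (vectorised).
#' @return Logical vector.
#' @examples
#' is_palindromic("ACGT")   # TRUE
#' is_palindromic("TATAAA") # FALSE
#' @export
is_palindromic <- function(seq) {
  reverse_complement(seq) == toupper(seq)
}

#' Per-position degeneracy of a consensus
#'
#' @param seq IUPAC string.
#' @return Integer vector, the number of allowed bases at each position.
#' @keywords internal
iupac_degeneracy <- function(seq) {
  seq <- check_iupac(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  vapply(IUPAC_SETS[chars], length, integer(1L))
}

#' Expand an IUPAC consensus into all unambiguous variants
#'
#' Enumerates every A/C/G/T string matching the consensus. The number of
#' variants is the product of per-position degeneracies; expansion refuses
#' when that product exceeds `cap` to protect against pathological motifs.
#'
#' @param seq IUPAC string.
#' @param cap Maximum number of variants (default 4096).
#' @return Character vector of unambiguous variants (unique, sorted by
#'   enumeration order with the first position varying slowest).
#' @examples
#' expand_variants("AR")  # "AA" "AG"
#' @export
expand_variants <- function(seq, cap = 4096L) {
  seq <- check_iupac(seq, "consensus")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sets <- IUPAC_SETS[chars]
  n <- prod(vapply(sets, length, integer(1L)))
  if (n > cap)
    stop(sprintf("consensus '%s' expands to %d variants, exceeding cap %d",
                 seq, n, cap))
  if (length(sets) == 0L) return(character(0L))
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

## Translate a consensus into a PCRE pattern of concrete-base character
## classes; ambiguity codes in the *scanned* sequence therefore never match
## (a genomic N is not any concrete base).
iupac_regex <- function(seq) {
  seq <- check_iupac(seq, "consensus")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

## Variant-set subset test per position: TRUE iff allowed(a) is a subset of
## allowed(b) for single characters a, b.
iupac_subset <- function(a, b) {
  all(IUPAC_SETS[[a]] %in% IUPAC_SETS[[b]])
}
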