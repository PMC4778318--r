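## Motif scanning. Both orientations of a motif are matched against the
## coding strand: "fw" matches the consensus as reported, "rc" matches its
## reverse complement. Matching is leftmost-greedy and non-overlapping
## (global-regex semantics: after a match the scan resumes at the position
## following the match's last base), reproducing classic global
## string-matching behaviour. The fw and rc scans are independent.

#' Scan sequences for non-overlapping motif matches
#'
#' @param consensus IUPAC consensus string (curated motif).
#' @param seqs Named character vector of sequences (e.g. excised upstream
#'   intervals); names are gene ids.
#' @param orientation `"fw"` to match the consensus, `"rc"` to match its
#'   reverse complement against the same strand.
#' @param from_pos Upstream position of the first base of each sequence
#'   (default `-nchar(seq)`, i.e. sequences ending at position -1).
#' @return Data frame with columns `gene_id`, `orientation`, `start`,
#'   `end`: upstream positions of the 5'-most and 3'-most matched base.
#'   Zero-row when nothing matches. Ambiguity codes in the scanned
#'   sequence are never matched.
#' @examples
#' scan_motif("TATAAA", c(g1 = "TATAAATATAAA"))
#' @export
scan_motif <- function(consensus, seqs, orientation = c("fw", "rc"),
                       from_pos = NULL) {
  orientation <- match.arg(orientation)
  pattern <- if (orientation == "fw") consensus
             else reverse_complement(consensus)
  len <- nchar(pattern)
  if (is.null(from_pos)) from_pos <- -nchar(seqs[[1L]])
  rx <- iupac_regex(pattern)
  m <- gregexpr(rx, seqs, perl = TRUE)
  ids <- names(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    st <- m[[i]]
    if (st[1L] == -1L) return(NULL)
    start <- from_pos + as.integer(st) - 1L
    data.frame(gene_id = ids[i], orientation = orientation,
               start = start, end = start + len - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0L), orientation = character(0L),
                      start = integer(0L), end = integer(0L))
  out
}

#' Map a motif catalog onto upstream intervals
#'
#' Scans every analysis motif (see [analysis_motifs()]) against the excised
#' interval of every region, in both orientations. Interval scans run on
#' the excised subsequence, so matches cannot straddle interval boundaries;
#' a hit belongs to the interval of its 5'-most base.
#'
#' @param motifs A curated `motif_set` (its [analysis_motifs()] view is
#'   scanned) or any `motif_set` when `filter = FALSE`.
#' @param regions An `upstream_set`.
#' @param interval [interval_spec()] to scan (default the full region).
#' @param filter Restrict to the analysis view of a curated set
#'   (default TRUE).
#' @return A `mapping_table`: list with `hits` (data frame `gene_id`,
#'   `motif_id`, `orientation`, `start`, `end`), `interval`,
#'   `region_length`, `gene_ids`, `motif_ids`.
#' @export
map_catalog <- function(motifs, regions, interval = NULL, filter = TRUE) {
  L <- attr(regions, "region_length")
  if (is.null(interval)) interval <- interval_spec(-L, -1L)
  interval <- as_interval(interval)
  ms <- if (filter && isTRUE(attr(motifs, "curated")))
    analysis_motifs(motifs) else motifs
  sub <- excise(regions, interval)
  hit_list <- vector("list", 2L * nrow(ms))
  k <- 0L
  for (i in seq_len(nrow(ms))) {
    for (ori in c("fw", "rc")) {
      h <- scan_motif(ms$consensus[i], sub, ori, from_pos = interval[1L])
      if (nrow(h) > 0L) {
        h$motif_id <- ms$id[i]
        k <- k + 1L
        hit_list[[k]] <- h
      }
    }
  }
  hits <- if (k > 0L) do.call(rbind, hit_list[seq_len(k)]) else
    data.frame(gene_id = character(0L), orientation = character(0L),
               start = integer(0L), end = integer(0L),
               motif_id = character(0L))
  hits <- hits[, c("gene_id", "motif_id", "orientation", "start", "end")]
  rownames(hits) <- NULL
  structure(list(hits = hits, interval = interval, region_length = L,
                 gene_ids = names(regions), motif_ids = ms$id),
            class = "mapping_table")
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("mapping_table: %d hits, %d motifs, %d genes, interval %s\n",
              nrow(x$hits), length(x$motif_ids), length(x$gene_ids),
              interval_label(x$interval)))
  invisible(x)
}

#' Per-motif, per-orientation hit counts
#'
#' @param mt A `mapping_table`.
#' @return Data frame `motif_id`, `n_fw`, `n_rc`, `n_genes_fw`,
#'   `n_genes_rc` (one row per mapped motif, including zero rows for
#'   motifs without hits).
#' @export
hit_counts <- function(mt) {
  h <- mt$hits
  out <- data.frame(motif_id = mt$motif_ids, n_fw = 0L, n_rc = 0L,
                    n_genes_fw = 0L, n_genes_rc = 0L,
                    stringsAsFactors = FALSE)
  for (ori in c("fw", "rc")) {
    sel <- h$orientation == ori
    cnt <- table(h$motif_id[sel])
    gn <- tapply(h$gene_id[sel], h$motif_id[sel],
                 function(g) length(unique(g)))
    idx <- match(names(cnt), out$motif_id)
    out[[paste0("n_", ori)]][idx] <- as.integer(cnt)
    out[[paste0("n_genes_", ori)]][match(names(gn), out$motif_id)] <-
      as.integer(gn)
  }
  out
}

#' Orientation-resolved gene sets of one motif
#'
#' @param mt A `mapping_table`.
#' @param motif_id Motif identifier.
#' @return List with `fw`, `rc` (genes with at least one hit in that
#'   orientation), `fw_only`, `rc_only`, `both`, `none`, `any`.
#' @export
gene_sets <- function(mt, motif_id) {
  h <- mt$hits[mt$hits$motif_id == motif_id, ]
  fw <- unique(h$gene_id[h$orientation == "fw"])
  rc <- unique(h$gene_id[h$orientation == "rc"])
  both <- intersect(fw, rc)
  any_g <- union(fw, rc)
  list(fw = fw, rc = rc,
       fw_only = setdiff(fw, both), rc_only = setdiff(rc, both),
       both = both, any = any_g,
       none = setdiff(mt$gene_ids, any_g))
}

#' Export hits as BED-like TSV
#'
#' Six columns: gene_id, 0-based start offset within the region, half-open
#' end offset, motif_id, score placeholder (0), strand (+ for fw, - for
#' rc). A header comment declares the upstream-coordinate mapping.
#'
#' @param mt A `mapping_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_hits_bed <- function(mt, path) {
  L <- mt$region_length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# offsets are 0-based within the %d-nt region; offset o = upstream position o - %d",
    L, L), con)
  h <- mt$hits
  if (nrow(h) > 0L) {
    bed <- data.frame(h$gene_id, h$start + L, h$end + L + 1L, h$motif_id,
                      0L, ifelse(h$orientation == "fw", "+", "-"))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Export hit counts as long-format TSV
#'
#' @param mt A `mapping_table`.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
export_counts_tsv <- function(mt, path) {
  cnt <- hit_counts(mt)
  long <- rbind(
    data.frame(motif_id = cnt$motif_id, interval = interval_label(mt$interval),
               orientation = "fw", n_hits = cnt$n_fw,
               n_genes = cnt$n_genes_fw),
    data.frame(motif_id = cnt$motif_id, interval = interval_label(mt$interval),
               orientation = "rc", n_hits = cnt$n_rc,
               n_genes = cnt$n_genes_rc))
  long <- long[order(long$motif_id, long$orientation), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(long)
}
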