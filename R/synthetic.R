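## Ground-truth synthetic worlds: promoter-like upstream sequence sets
## generated window-by-window from first-order Markov models (emulating
## TSS-proximal base skew and dinucleotide directional asymmetry), motif
## implants with configurable orientation bias and positional confinement,
## and expression matrices in which genes sharing an implanted motif load
## on a common latent factor.

BASES <- c("A", "C", "G", "T")

uniform_markov <- function() {
  m <- matrix(0.25, 4L, 4L, dimnames = list(BASES, BASES))
  m
}

#' First-order transition matrix with one inflated transition
#'
#' Starts from the uniform matrix and sets `P(to | from) = p`, spreading
#' the remainder of the row uniformly over the other three bases.
#'
#' @param from,to Bases of the inflated transition.
#' @param p Transition probability (default 0.30).
#' @return 4x4 row-stochastic matrix.
#' @export
biased_markov <- function(from, to, p = 0.30) {
  m <- uniform_markov()
  m[from, ] <- (1 - p) / 3
  m[from, to] <- p
  m
}

#' Synthetic world configuration
#'
#' @param n_genes Number of genes (default 2000).
#' @param region_length Upstream region length in nt (default 500).
#' @param window_models List of window models, each a list with
#'   `interval` (length-2 numeric, upstream positions), `init` (initial
#'   base distribution, default uniform) and `trans` (4x4 transition
#'   matrix, rows summing to 1). Default: one uniform i.i.d. window over
#'   the full region. Windows are generated 5' to 3'; the first base of a
#'   window after the first is conditioned on the last base of the
#'   previous window through the window's own transition matrix.
#' @param motif_implants List of implant specifications, each a list with
#'   `motif_id`, `consensus`, `prob` (per-gene implantation probability;
#'   0 registers the motif in the catalog without implanting), `fw_prob`
#'   (forward-orientation probability, default 0.5), `bins` (positional
#'   distribution over `n_bins` bins, 5'-most first; default uniform),
#'   `lambda` (latent-factor loading of the implanted-gene module,
#'   default 0), `module` (which implanted genes join the module:
#'   `"any"`, `"fw"`, `"rc"`; default `"any"`).
#' @param n_samples Expression samples (default 200).
#' @param noise_sd Expression noise SD (default 1).
#' @param n_bins Positional bins for implantation (default 10).
#' @param seed Master seed.
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(n_genes = 2000L, region_length = 500L,
                                   window_models = NULL,
                                   motif_implants = list(),
                                   n_samples = 200L, noise_sd = 1,
                                   n_bins = 10L, seed = 1L) {
  if (is.null(window_models))
    window_models <- list(list(interval = c(-region_length, -1L),
                               init = rep(0.25, 4L),
                               trans = uniform_markov()))
  for (wm in window_models) {
    tr <- wm$trans
    if (!all(abs(rowSums(tr) - 1) < 1e-9))
      stop("transition-matrix rows must sum to 1")
  }
  for (im in motif_implants) {
    if (!is.null(im$bins) && abs(sum(im$bins) - 1) > 1e-9)
      stop("positional distribution must sum to 1")
  }
  structure(list(n_genes = as.integer(n_genes),
                 region_length = as.integer(region_length),
                 window_models = window_models,
                 motif_implants = motif_implants,
                 n_samples = as.integer(n_samples), noise_sd = noise_sd,
                 n_bins = as.integer(n_bins), seed = as.integer(seed)),
            class = "synthetic_world_config")
}

## Markov sampling of one window for all genes at once.
sample_window <- function(n, width, init, trans, prev_base = NULL) {
  out <- matrix("", n, width)
  cum_t <- t(apply(trans, 1L, cumsum))
  if (is.null(prev_base)) {
    cur <- findInterval(stats::runif(n), cumsum(init),
                        rightmost.closed = TRUE) + 1L
    cur <- pmin(cur, 4L)
  } else {
    u <- stats::runif(n)
    cur <- 1L + (u > cum_t[prev_base, 1L]) + (u > cum_t[prev_base, 2L]) +
      (u > cum_t[prev_base, 3L])
  }
  out[, 1L] <- BASES[cur]
  if (width > 1L) for (j in 2:width) {
    u <- stats::runif(n)
    cur <- 1L + (u > cum_t[cur, 1L]) + (u > cum_t[cur, 2L]) +
      (u > cum_t[cur, 3L])
    out[, j] <- BASES[cur]
  }
  list(chars = out, last = cur)
}

#' Generate background upstream sequences
#'
#' Each region is generated window-by-window, 5' to 3', from the
#' configured first-order Markov models. Reproducible under the config
#' seed (offset 0).
#'
#' @param config A [synthetic_world_config()].
#' @return An `upstream_set` with gene ids `g0001`, `g0002`, ...
#' @export
synth_upstream <- function(config) {
  L <- config$region_length
  n <- config$n_genes
  wins <- config$window_models
  ## order windows 5' -> 3' and check they tile the region
  froms <- vapply(wins, function(w) w$interval[1L], numeric(1L))
  wins <- wins[order(froms)]
  covered <- sum(vapply(wins, function(w)
    w$interval[2L] - w$interval[1L] + 1, numeric(1L)))
  if (covered != L) stop("window models must tile the full region")
  with_seed(config$seed, {
    mat <- NULL
    last <- NULL
    for (w in wins) {
      width <- w$interval[2L] - w$interval[1L] + 1L
      init <- if (is.null(w$init)) rep(0.25, 4L) else w$init
      sw <- sample_window(n, width, init, w$trans, prev_base = last)
      mat <- if (is.null(mat)) sw$chars else cbind(mat, sw$chars)
      last <- sw$last
    }
    seqs <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
    names(seqs) <- sprintf("g%04d", seq_len(n))
    upstream_set(seqs, L)
  })
}

#' Implant motifs into synthetic regions
#'
#' For every implant specification, each gene is selected independently
#' with probability `prob`; a concrete variant of the consensus (uniform
#' over its expansions) is written over the background sequence (region
#' length preserved) at a start position drawn from the positional bin
#' distribution (uniform within the bin, the motif wholly inside it), in
#' forward orientation with probability `fw_prob`, else as its reverse
#' complement. Sites overlapping a previous implant are redrawn up to 20
#' times, then the gene is skipped. Reproducible under the config seed
#' (offset 1).
#'
#' @param regions Output of [synth_upstream()].
#' @param config The same [synthetic_world_config()].
#' @return List with `regions` (modified `upstream_set`) and `truth`
#'   (data frame `gene_id`, `motif_id`, `orientation`, `start`, `end`,
#'   `written`: the sequence as written on the coding strand).
#' @export
implant_motifs <- function(regions, config) {
  L <- config$region_length
  n_bins <- config$n_bins
  width <- L %/% n_bins
  seqs <- unclass(regions)
  occupied <- vector("list", length(seqs))
  truth <- list()
  with_seed(config$seed + 1L, {
    for (im in config$motif_implants) {
      if (is.null(im$prob) || im$prob <= 0) next
      variants <- expand_variants(im$consensus)
      m_len <- nchar(im$consensus)
      if (m_len > width)
        stop("motif ", im$motif_id, " does not fit in a positional bin")
      bins <- if (is.null(im$bins)) rep(1 / n_bins, n_bins) else im$bins
      fw_prob <- if (is.null(im$fw_prob)) 0.5 else im$fw_prob
      sel <- which(stats::runif(length(seqs)) < im$prob)
      for (g in sel) {
        placed <- FALSE
        for (try in seq_len(20L)) {
          b <- sample.int(n_bins, 1L, prob = bins)
          bin_start <- -L + (b - 1L) * width
          start <- bin_start + sample.int(width - m_len + 1L, 1L) - 1L
          end <- start + m_len - 1L
          occ <- occupied[[g]]
          clash <- !is.null(occ) &&
            any(start <= occ[, 2L] & occ[, 1L] <= end)
          if (clash) next
          variant <- variants[sample.int(length(variants), 1L)]
          fw <- stats::runif(1L) < fw_prob
          written <- if (fw) variant else reverse_complement(variant)
          j <- start + L + 1L
          substr(seqs[g], j, j + m_len - 1L) <- written
          occupied[[g]] <- rbind(occ, c(start, end))
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = names(seqs)[g], motif_id = im$motif_id,
            orientation = if (fw) "fw" else "rc",
            start = start, end = end, written = written,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          message("no non-overlapping site for ", im$motif_id,
                  " in gene ", names(seqs)[g], "; skipped")
      }
    }
  })
  truth_df <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(gene_id = character(0L), motif_id = character(0L),
               orientation = character(0L), start = integer(0L),
               end = integer(0L), written = character(0L))
  list(regions = upstream_set(seqs, L), truth = truth_df)
}

#' Synthesize a motif-linked expression matrix
#'
#' Each implanted motif with a positive loading defines a module: its
#' member genes share one standard-normal latent factor per sample,
#' `x_gs = sum_f lambda_f z_fs + e_gs` with Gaussian noise of SD
#' `noise_sd`; genes in no module are pure noise. With loading `lambda`
#' and unit noise, the expected within-module pairwise correlation is
#' `lambda^2 / (lambda^2 + 1)`. Reproducible under the config seed
#' (offset 2).
#'
#' @param truth Truth table from [implant_motifs()].
#' @param config The same [synthetic_world_config()].
#' @return Numeric matrix `n_genes x n_samples` (rownames = gene ids,
#'   colnames `s001`, ...), with attribute `modules`: named list of
#'   member gene ids per module motif.
#' @export
synth_expression <- function(truth, config) {
  n <- config$n_genes
  ns <- config$n_samples
  ids <- sprintf("g%04d", seq_len(n))
  with_seed(config$seed + 2L, {
    x <- matrix(stats::rnorm(n * ns, sd = config$noise_sd), n, ns,
                dimnames = list(ids, sprintf("s%03d", seq_len(ns))))
    modules <- list()
    for (im in config$motif_implants) {
      lambda <- if (is.null(im$lambda)) 0 else im$lambda
      if (lambda <= 0) next
      scope <- if (is.null(im$module)) "any" else im$module
      tt <- truth[truth$motif_id == im$motif_id, ]
      members <- switch(scope,
        any = unique(tt$gene_id),
        fw = unique(tt$gene_id[tt$orientation == "fw"]),
        rc = unique(tt$gene_id[tt$orientation == "rc"]),
        stop("unknown module scope: ", scope))
      if (length(members) == 0L) next
      z <- stats::rnorm(ns)
      x[members, ] <- x[members, , drop = FALSE] +
        lambda * matrix(z, length(members), ns, byrow = TRUE)
      modules[[im$motif_id]] <- members
    }
    attr(x, "modules") <- modules
    x
  })
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: background sequences, implants, expression.
#'
#' @param config A [synthetic_world_config()].
#' @return List with `regions`, `truth`, `expr`, `catalog` (a
#'   `motif_set` of all configured motifs, implanted or not) and
#'   `config`.
#' @export
synth_world <- function(config) {
  regions <- synth_upstream(config)
  imp <- implant_motifs(regions, config)
  expr <- synth_expression(imp$truth, config)
  catalog <- if (length(config$motif_implants) > 0L) {
    ids <- vapply(config$motif_implants, `[[`, character(1L), "motif_id")
    cons <- vapply(config$motif_implants, `[[`, character(1L), "consensus")
    keep <- !duplicated(ids)  # one motif may have several implant entries
    motif_set(ids[keep], cons[keep], "literature",
              provenance = "synthetic world catalog")
  } else NULL
  list(regions = imp$regions, truth = imp$truth, expr = expr,
       catalog = catalog, config = config)
}

#' Write a self-contained fixture directory
#'
#' Emits `upstream.fasta`, `motifs.tsv`, `expression.tsv`, `truth.json`
#' and `config.json`. Re-running with the same config reproduces the
#' files byte-identically.
#'
#' @param dir Target directory (created if needed).
#' @param config A [synthetic_world_config()].
#' @return The world (as from [synth_world()]), invisibly.
#' @export
make_fixture <- function(dir, config) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  world <- synth_world(config)
  write_upstream_fasta(world$regions, file.path(dir, "upstream.fasta"))
  if (!is.null(world$catalog))
    write_motif_catalog(world$catalog, file.path(dir, "motifs.tsv"))
  write_expression_matrix(world$expr, file.path(dir, "expression.tsv"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       digits = NA)
  snapshot <- unclass(config)
  snapshot$window_models <- lapply(snapshot$window_models, function(w)
    list(interval = w$interval, init = w$init,
         trans = as.vector(t(w$trans))))
  jsonlite::write_json(snapshot, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(world)
}

#' Read a fixture directory back
#'
#' @param dir Fixture directory written by [make_fixture()].
#' @return List with `regions`, `catalog` (NULL when absent), `expr`,
#'   `truth`.
#' @export
read_fixture <- function(dir) {
  catalog_path <- file.path(dir, "motifs.tsv")
  list(regions = read_upstream_fasta(file.path(dir, "upstream.fasta")),
       catalog = if (file.exists(catalog_path))
         read_motif_catalog(catalog_path) else NULL,
       expr = read_expression_matrix(file.path(dir, "expression.tsv")),
       truth = as.data.frame(jsonlite::read_json(file.path(dir, "truth.json"),
                                                 simplifyVector = TRUE)))
}

#' Preset world configurations
#'
#' `null_world_config()` describes a structureless world: uniform i.i.d.
#' sequence, a catalog of concrete random motifs that are never implanted
#' (chance occurrences only), and pure-noise expression. It is the
#' reference condition for false-positive calibration.
#'
#' `oriented_world_config()` describes the positive-control world: one
#' motif implanted with an 80:20 forward:reverse orientation bias in
#' which the forward instances are confined to the three bins nearest
#' the TSS and carry a latent-factor co-expression module with loading
#' 0.5, while the reverse-complement instances are uniformly placed and
#' module-free (orientation is therefore functionally distinguishable);
#' a second motif implanted without orientation or position bias; and a
#' TSS-proximal window with an inflated T-to-C transition
#' (`P(C|T) = 0.30`) giving a known positive log2 DOR(TC) near the TSS.
#'
#' @param n_genes,n_samples,seed World size and seed.
#' @param n_motifs Catalog size of the null world (default 15).
#' @param implant_prob Per-gene implantation probability of the oriented
#'   world's motifs (default 0.2).
#' @return A [synthetic_world_config()].
#' @export
null_world_config <- function(n_genes = 300L, n_samples = 50L, seed = 1L,
                              n_motifs = 15L) {
  motifs <- with_seed(seed + 7L, {
    vapply(seq_len(n_motifs), function(i)
      paste(sample(BASES, 7L, replace = TRUE), collapse = ""),
      character(1L))
  })
  implants <- lapply(seq_len(n_motifs), function(i)
    list(motif_id = sprintf("null_m%02d", i), consensus = motifs[i],
         prob = 0, lambda = 0))
  synthetic_world_config(n_genes = n_genes, n_samples = n_samples,
                         motif_implants = implants, seed = seed)
}

#' @rdname null_world_config
#' @export
oriented_world_config <- function(n_genes = 2000L, n_samples = 200L,
                                  seed = 1L, implant_prob = 0.2) {
  windows <- list(
    list(interval = c(-500L, -101L), init = rep(0.25, 4L),
         trans = uniform_markov()),
    list(interval = c(-100L, -1L), init = rep(0.25, 4L),
         trans = biased_markov("T", "C", 0.30)))
  implants <- list(
    list(motif_id = "oriented_confined", consensus = "GATCGGTACTGA",
         prob = 0.8 * implant_prob, fw_prob = 1,
         bins = c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1) / 3,
         lambda = 0.5, module = "fw"),
    list(motif_id = "oriented_confined", consensus = "GATCGGTACTGA",
         prob = 0.2 * implant_prob, fw_prob = 0, lambda = 0),
    list(motif_id = "unbiased_uniform", consensus = "CTAGCAATCGTG",
         prob = implant_prob, fw_prob = 0.5, lambda = 0))
  synthetic_world_config(n_genes = n_genes, region_length = 500L,
                         window_models = windows,
                         motif_implants = implants,
                         n_samples = n_samples, seed = seed)
}
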