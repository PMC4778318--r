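# Independent brute-force oracles. These deliberately re-derive results
# from first principles (enumeration, sliding windows, closed forms) and
# share no code with the implementation paths they check.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# All positions (1-based) where the consensus matches by per-position set
# membership, then reduced to the leftmost-greedy non-overlapping subset.
oracle_scan <- function(consensus, seq) {
  m <- nchar(consensus)
  L <- nchar(seq)
  if (m > L) return(integer(0L))
  cs <- strsplit(consensus, "")[[1L]]
  ss <- strsplit(seq, "")[[1L]]
  all_pos <- integer(0L)
  for (i in 1:(L - m + 1L)) {
    ok <- TRUE
    for (k in seq_len(m)) {
      if (!(ss[i + k - 1L] %in% ORACLE_SETS[[cs[k]]])) { ok <- FALSE; break }
    }
    if (ok) all_pos <- c(all_pos, i)
  }
  picked <- integer(0L)
  next_free <- 1L
  for (p in all_pos) {
    if (p >= next_free) {
      picked <- c(picked, p)
      next_free <- p + m
    }
  }
  picked
}

# Exact two-sided binomial p under the minimum-likelihood convention.
oracle_binom_two_sided <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

# Upper-tail hypergeometric by direct summation over overlap sizes.
oracle_hyper_upper <- function(n1, n2, k, N) {
  ks <- k:min(n1, n2)
  sum(choose(n1, ks) * choose(N - n1, n2 - ks)) / choose(N, n2)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all group
# assignments of the pooled (tie-free) sample.
oracle_wilcoxon_two_sided <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U
  combs <- combn(n + m, n)
  u_all <- apply(combs, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(u_all <= w_obs)
  p_ge <- mean(u_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Random IUPAC string with a configurable share of ambiguity codes.
random_iupac <- function(len, p_ambiguous = 0.3) {
  amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  vapply(len, function(l) {
    ch <- ifelse(runif(l) < p_ambiguous,
                 sample(amb, l, replace = TRUE),
                 sample(c("A", "C", "G", "T"), l, replace = TRUE))
    paste(ch, collapse = "")
  }, character(1L))
}

random_dna <- function(len) {
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1L))
}
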