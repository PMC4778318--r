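# motifOrient

Statistical toolkit for deciding whether the **orientation** of
transcription-factor binding-site (TFBS) motifs in gene promoter regions
carries regulatory information.

A cis-regulatory motif read 5'→3' on the coding strand and its reverse
complement present the same double-helix surface to the binding protein,
rotated 180° relative to the transcription start site (TSS). If that
rotation mattered, a motif should (i) map to upstream regions in one
orientation more often than sequence composition predicts, and (ii) the
genes carrying the favored orientation should be more strongly
co-expressed. motifOrient implements the full pipeline for testing both
claims on IUPAC consensus motif catalogs, TSS-anchored upstream FASTA
and an expression matrix:

* **Catalog curation** — terminal-N trimming, specificity and N-run
  filters, duplicate removal, palindrome flagging, explicit and
  variant-level containment detection (`curate_catalog()`).
* **Scanning** — leftmost-greedy, non-overlapping matching of each
  consensus and its reverse complement against the coding strand, per
  upstream interval (`scan_motif()`, `map_catalog()`).
* **Orientation tests** — exact binomial test of forward-mapping counts
  against the composition-corrected expectation
  `F = P_fw / (P_fw + P_rc)`, `P_fw/rc = prod_i sum_{b in allowed_i} p_b`,
  with Benjamini–Hochberg correction (`orientation_test()`).
* **Positional entropy** — Shannon entropy `PE = -sum p_i ln p_i` of hit
  locations over 10 upstream bins; low PE = positional confinement
  (`positional_entropy()`).
* **Dinucleotide orientation ratios** —
  `DOR = R(d) / R(rc(d))` with `R(B1B2) = f(B1B2) / (p_B1 p_B2)`;
  departures from 1 reveal intrinsic sequence directionality near the
  TSS (`dor_profile()`).
* **Co-expression comparisons** — Wilcoxon rank-sum + Cohen's d on
  pairwise Pearson correlation distributions of motif-defined gene sets
  (`compare_sets()`), feeding the nested C/D1/D2/D3/E/F filter cascade
  (`classify_motifs()`, `run_single_motif_analysis()`).
* **Randomized controls** — length-matched random motif catalogs under
  upstream-composition (R1) and motif-composition (R2) backgrounds,
  Fisher-compared per filter (`generate_random_motifs()`,
  `run_control_comparison()`).
* **Motif pairs** — hypergeometric co-occurrence, exact binomial order
  test, and an arrangement-entropy test over the 8 order × orientation
  cells with an empirical multinomial null (`pair_analysis()`).
* **Synthetic worlds** — ground-truth promoter sets with configurable
  Markov sequence asymmetry, motif implants (orientation bias,
  positional confinement) and latent-factor co-expression modules
  (`synth_world()`, `make_fixture()`).

## Worked example

Generate a positive-control world — one motif implanted 80:20
forward:reverse with its forward instances confined near the TSS and
co-expressed (factor loading 0.5), one unbiased motif, and an inflated
T→C transition in the proximal 100 nt — then run the single-motif
cascade:

```r
library(motifOrient)

world   <- synth_world(oriented_world_config(n_genes = 800, n_samples = 120, seed = 42))
catalog <- curate_catalog(world$catalog)
res     <- run_single_motif_analysis(catalog, world$regions, world$expr,
                                     intervals = list(c(-500, -1)), seed = 42)
res$per_interval[["(-500,-1)"]]$verdicts
#>            motif_id q_orient preferred d_presence PE_fw PE_rc     C    D1    D2    D3     E     F
#> 1 oriented_confined 2.47e-21        fw   1.252096  1.13  2.16  TRUE  TRUE  TRUE  TRUE  TRUE  TRUE
#> 2  unbiased_uniform 7.48e-01        fw  -0.000707  2.23  2.24 FALSE FALSE FALSE FALSE FALSE FALSE
```

The implanted motif is recovered at every stage: its orientation bias
survives composition correction and BH adjustment (`q_orient` ≈ 2e-21,
preferred `fw`), its carrier genes are strongly co-expressed
(`d_presence` = 1.25), and its forward hits are positionally confined
(`PE_fw` = 1.13 against `PE_rc` = 2.16; a uniform distribution over the
10 bins would give ln 10 ≈ 2.30). The unbiased motif passes nothing.
The implanted first-order sequence asymmetry is localized correctly:

```r
subset(dor_profile(world$regions), dinucleotide == "TC",
       c(from_pos, to_pos, log2_DOR))
#>    from_pos to_pos log2_DOR
#> 8      -500   -401  0.00286
#> 24     -400   -301 -0.00059
#> 40     -300   -201  0.02971
#> 56     -200   -101  0.00015
#> 72     -100     -1  0.14728
```

log2 DOR(TC) > 0 only in the (−100, −1) window carrying the implanted
T→C bias — the signature of TSS-proximal sequence directionality that
makes even composition-corrected random motifs map with apparent
orientation preference.

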