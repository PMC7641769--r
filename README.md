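# g4pombe

Stabilized G-quadruplexes (G4) — four-stranded structures formed by
guanine-rich DNA — act as replication obstacles in fission yeast
(*Schizosaccharomyces pombe*): when a G4-binding ligand such as PhenDC3
stabilizes them, replication forks slow, the leading-strand polymerase
(Pol&epsilon;/Cdc20) accumulates at G4 motifs, newly replicated tracts
shorten, and single-stranded DNA lesions accumulate. `g4pombe` implements
the computational methods of such a study as a tested, reusable R package
for genomicists and single-molecule microscopists:

* **G4 motif scanning** — the motif grammar (G≥3 N1–25)3 G≥3 on both
  strands of any FASTA, with maximal G-tracts, minimal loops, leftmost
  non-overlapping matches, a two-tetrad mode (G≥2) for weaker structures,
  interval masking, and annotation of the polymerase stall site one
  nucleotide 5′ of the first G-tract.
* **ChIP-seq peak/feature enrichment accounting** — union bp coverage,
  mean peak length, GC%, peaks-with-feature and features-within-peaks
  counts, treated/mock fold changes (rounded half-away-from-zero to 2
  decimals for reports), top-N peak selection, and the pseudo-replicate
  reliability ratio Np/Nt with the factor-of-2 rule (0.5 ≤ Np/Nt ≤ 2).
* **Single-molecule damage imaging** — tracing of stretched DNA backbones
  (noise-adaptive threshold, Guo–Hall thinning, longest skeleton path),
  diffraction-limited dot detection (difference of Gaussians + local
  maxima), dot-to-molecule assignment, and damage density in dots/µm and
  dots/Mbp via the 3000 bp/µm stretching constant, with a declumping
  correction for dots merged below the detector resolution.
* **Closed-form assay quantifications** — fiber tract statistics with
  Mann–Whitney tests (1 µm ≈ 2 kb), doubling time t/log2(x/x0), helicase
  unwinding 100·P/(P+S), CD molar ellipticity [θ] = m°·M/(10·L·C), and
  qPCR-stop relative amplification 2^(−ΔΔCq).
* **Synthetic data generators** — genomes with planted motifs, scored
  two-condition × two-replicate peak experiments with controlled feature
  enrichment, rendered two-channel fiber fields with Poisson-planted
  damage dots, and tract-length samples; every generator emits
  coordinate-level ground truth so the whole pipeline is testable offline.

## Worked example

Re-derive the fold-change columns of the published peak table from its
per-condition counts, then quantify damage on a rendered fiber field:

```r
library(g4pombe)

ledger_from_counts(
  n_peaks = c(344, 568), bp_covered = c(464876, 752369),
  feature_counts = list(g4 = c(50, 96), trna = c(44, 58), rrna5s = c(7, 16)))
#> Enrichment ledger (treated vs mock)
#> # A tibble: 2 x 8
#>   condition n_peaks total_bp_covered mean_peak_length ...
#> 1 mock          344           464876             1351
#> 2 treated       568           752369             1325
#>
#> Fold changes:
#>   bp_covered   1.62
#>   g4           1.92
#>   trna         1.32
#>   rrna5s       2.29

field <- gen_fiber_field(sim_config(seed = 13))   # 200 molecules, 30 dots/Mbp
traces <- trace_molecules(field)
dots   <- detect_dots(field)
assign_and_quantify(traces, dots, field$pixel_size)$pooled_dots_per_mbp_declumped
#> [1] 30.4
```

The fold changes are exactly the published cells (1.62× bp coverage, 1.92×
G4 motifs within peaks, 1.32× tRNA, 2.29× 5S rDNA), and the recovered
damage density matches the planted 30 dots/Mbp to within field-level
Poisson noise.

The numbered scripts under `analysis/` run the full workflow and write
tables under `results/`: `01_scan_motifs.R` (motif scan on a planted
genome; recall 1.00, precision 1.00 on 40 planted motifs),
`02_peak_enrichment.R` (published-count ledgers plus a synthetic 2×
enrichment experiment), `03_damage_imaging.R` (triplicate control vs
treated fields; with a 3× planted increase it reports, e.g., 29.4 ± 1.9 vs
91.6 ± 2.8 dots/Mbp, fold 3.12, p < 0.01), and `04_assay_quant.R` (tract
statistics at the n = 17 vs 50 design, doubling times, unwinding
titration, CD normalization, ΔΔCq table).

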