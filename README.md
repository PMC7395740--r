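# regmotif

Feedback motifs in transcription factor / microRNA regulatory networks.

## The problem

Autoregulation and reciprocal feedback between transcription factors
(TFs) and microRNAs are the circuit elements that give gene expression
its dynamical repertoire — oscillations, bistability, noise buffering.
`regmotif` is for computational biologists who want to ask, on genome-wide
binding and target data, *how common* these circuits are and *how
conserved* they are across tissues. It implements a complete, tested
pipeline:

1. **Network construction.** TF ChIP-seq binding peaks are filtered to
   cis-regulatory modules (CRMs), assigned to the closest transcription
   start site (TSS) within a strand-oriented promoter window (50 kb
   upstream, 10 kb downstream), copied onto intragenic miRNAs hosted in
   the target transcript, collapsed into weighted edges, and filtered so
   that each TF keeps only target regions with at least its
   outlier-trimmed mean number of binding sites. Curated miRNA→target
   edges are merged in as post-transcriptional regulation.
2. **Motif enumeration.** Four feedback motif classes on the trimmed
   regulator-only network:
   * **M1** — TF autoregulation: edge A→A;
   * **M2** — autoregulation with miRNA feedback: A→A, A→m, m⊣A;
   * **M3** — amplified feedback: A→A, A⇄B, B not autoregulatory;
   * **M4** — dual feedback: A→A, B→B, A⇄B.
3. **Enrichment statistics.** Degree-preserving edge rewiring
   (transcriptional and post-transcriptional edges randomised
   independently; a "locked" mode holds the self-loop set fixed) gives an
   empirical null. With `r` the number of null networks whose motif
   count reaches the observed count (inclusive `>=`) among `n`
   replicates,

   ```
   p = (r + 1) / (n + 1),    z = (observed − mean_null) / sd_null
   ```

4. **Tissue analysis.** Peaks are split by tissue via their dataset
   labels, the pipeline is rerun per tissue, and motif conservation is
   scored as the percentage of a TF's data-bearing tissues that contain
   the motif; tissue networks are compared by the Jaccard index of their
   transcriptional edge sets.
5. **Synthetic data.** A generator with planted ground truth emulates
   the structure of ReMap-style peak collections, Ensembl-style
   annotation, miRBase-style miRNA loci and miRTarBase-style target
   tables, so every stage is testable end to end without downloads.

## Worked example

```r
library(regmotif)

sim <- simulate_regulatory_data(sim_config(seed = 42))
bundle <- build_regulatory_network(sim$data$peaks, sim$data$crms,
                                   sim$data$genes, sim$data$mirnas,
                                   sim$data$mirna_targets)
bundle$report
#> <filter_report>
#>   input peaks       4385
#>   in CRMs           4324
#>   assigned to TSS   4243 (81 outside window)
#>   TFs mean-filtered 40 (edges 2061 -> 520)
bundle$network
#> <regnet> regulatory network
#>   nodes: 307 (40 TF, 59 miRNA, 208 other)
#>   edges: 688 (520 transcriptional, 168 posttranscriptional)

tidy(motif_census(bundle$trimmed))
#> # A tibble: 4 x 4
#>   motif_type count n_tfs n_mirnas
#> 1 M1            26    26        0
#> 2 M2            32    22       26
#> 3 M3            11    17        0
#> 4 M4            10    16        0

enrichment_test(bundle$trimmed, "M2",
                rewire_config(n_replicates = 500, seed = 42))
#> <motif_enrichment> M2 (locked null, n = 500)
#>   observed 32 | null mean 3.48 | r = 0 | p = 0.001996 | z = 17.3
```

Reading the output: 4,385 simulated peaks are reduced to 520
high-confidence transcriptional edges; 26 of 40 TFs autoregulate, and 22
of them sit in 32 distinct TF–miRNA dual-feedback (M2) loops. None of
500 degree-matched rewired networks (with the autoregulatory edges
locked) contains as many M2 loops, so the enrichment p-value takes its
smallest attainable value, (0+1)/(500+1) ≈ 0.002, with the observed
count 17 null standard deviations above the null mean.

Tissue-level summaries follow the same grammar:

```r
set <- split_by_tissue(sim$data$peaks, sim$data$tissue_map, sim$data$crms,
                       sim$data$genes, sim$data$mirnas,
                       sim$data$mirna_targets)
motif_conservation(set, "M1")   # % of data tissues with the self-loop
pairwise_jaccard(set)           # tissue x tissue edge-set similarity
loss_attribution(set)           # why M2 pairs disappear between tissues
```

Every result type has `tidy()`/`glance()` methods and an `autoplot()`
or `plot_*()` companion.

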