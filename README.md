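# scnanosim

Simulation of single-cell Oxford Nanopore long-read sequencing data with
complete ground truth.

Benchmarking single-cell long-read tools — cell-barcode demultiplexers,
UMI collapsers, isoform detection and quantification methods — requires
datasets where the truth is known: which read came from which cell, which
UMI, which transcript. Real experiments never expose this. scnanosim
builds such gold-standard datasets from the matrix level down to the
sequence level:

1. **Counts** — a Gamma–Poisson (negative binomial) model with log-normal
   per-cell library sizes, estimated from any real UMI count matrix
   (`estimate_count_params()`) and resimulated (`simulate_counts()`), or a
   user matrix used directly.
2. **Perfect reads** — one error-free library molecule per UMI with the
   10x/Nanopore construct `adapter + CB(16) + UMI(12) + dT(20) + cDNA + TSO`,
   transcript choice weighted $\propto e^{-L/\tau}$ toward short isoforms,
   optional intron retention, empirical cDNA truncation estimated from
   real-read alignments (PAF), and random strand orientation.
3. **PCR bias** — a branching process: each cycle every molecule
   duplicates with probability $P_{dup}$ (default 0.9) and each copy
   mutates at $P_{err}$ per base (default $3.5\times10^{-5}$), with
   heritable errors, so UMI families share mutations; expected pool
   $N(1+P_{dup})^{cycles}$.
4. **Sequencing errors** — a beta distribution fitted to per-read
   alignment identities (gap-included / gap-excluded / gap-compressed
   definitions) drives per-read error injection with per-base Phred
   qualities, written as FASTQ.
5. **QC** — streaming metrics (lengths, qualities, GC) with an HTML
   report and JSON sidecar.

Every function takes a data frame first and returns a tibble, so stages
chain with the pipe; fitted objects have `tidy()`/`glance()` and result
objects `autoplot()` methods. `run_pipeline()` chains everything from one
config with a single seed; all outputs are byte-reproducible.

## Worked example

A fully self-contained run (no external data): a toy reference and count
matrix are generated, then the five stages are chained.

```r
library(scnanosim)

cfg <- toy_config("demo", n_genes = 5, n_cells = 20, cycles = 4, seed = 42)
res <- run_pipeline(cfg)
#> [counts] using provided matrix demo/counts.csv
#> [templates] generating perfect reads
#> [templates] 191 molecules
#> [pcr] 4 cycles, p_dup 0.9
#> [pcr] 2485 molecules after amplification
#> [errors] injecting errors (mean identity 0.909)
#> [done] outputs in demo/out

glance(compute_qc(res$fastq))
#> # A tibble: 1 × 8
#>   n_reads min_length q25_length median_length q75_length max_length mean_quality
#>     <int>      <dbl>      <dbl>         <dbl>      <dbl>      <dbl>        <dbl>
#> 1    2485        319        408           454        577        653         11.3
```

The 191 molecules are exactly the 191 UMIs in the count matrix (count
conservation is exact); 4 PCR cycles at $P_{dup} = 0.9$ grow them to
2485 ≈ 191·1.9⁴ reads; mean identity 0.909 is the default Beta(30, 3)
model's mean, and the resulting mean Phred quality ≈ 11 corresponds to
that ~9% error rate. The ground truth travels alongside:

```r
res$molecules[1:3, c("read_id", "cell_barcode", "umi", "gene_id",
                     "transcript_id", "strand", "trunc_start", "trunc_end")]
#> # A tibble: 3 × 8
#>   read_id  cell_barcode umi   gene_id transcript_id strand trunc_start trunc_end
#>   <chr>    <chr>        <chr> <chr>   <chr>         <chr>        <int>     <int>
#> 1 mol_000… TTTACATCTGT… CGTT… gene01  gene01.t1     +                0       344
#> 2 mol_000… TTTACATCTGT… TGGA… gene01  gene01.t1     +                0       344
#> 3 mol_000… GTTGCACATTT… TCTG… gene01  gene01.t1     +                0       344
```

`demo/out/` contains the synthetic matrix, perfect-read FASTA, ground
truth TSVs, amplified pool, final FASTQ, the QC report and a manifest of
seeds and checksums. The same stages are scriptable from a shell via
`inst/scripts/scnanosim.R` (`all`, `counts`, `templates`, `pcr`,
`errors`, `qc` subcommands).

Real data slot in at three points: a real count matrix
(`counts$matrix` / `counts$reference_matrix`), real read-to-transcriptome
alignments for the truncation model (`templates$paf`), and real
read-to-genome alignments for the identity model (`errors$paf`).

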