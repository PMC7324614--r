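# sumiseq

Simulation and processing of UMI-barcoded DNA amplicon sequencing
(sUMI-seq): molecular barcoding of *DNA* templates during PCR, consensus
error correction, amplification-bias correction, and B-cell receptor
(BCR/IGH) repertoire analytics — plus a generative simulator of the whole
experiment so every stage is verifiable against ground truth.

## The problem and the method

Amplicon read counts are a poor proxy for molecule counts: per-molecule
differences in PCR efficiency compound exponentially (amplification
bias), and sequencing errors inflate apparent diversity and mutation
loads. UMIs solve this for RNA input, but a barcoded primer in a standard
exponential PCR fails for DNA — amplicons outcompete template, so one
molecule accumulates many barcodes. The method implemented here uses
primers with three regions — a gene-specific region, an 8 bp UMI, and a
MALBAC-style common tail — whose products self-anneal into loops and are
withdrawn from further priming. The first PCR is therefore near-linear:
each captured molecule gains a fresh (forward, reverse) UMI pair per
priming event. A second, exponential PCR on the common tails makes
sequencing material. Processing then:

1. filters read pairs (both mates median Phred > 32) and merges them only
   over an exactly identical overlap of > 50 bp;
2. identifies primers, orients reads, checks conserved bases, extracts
   the UMI pair, and excises primer segments;
3. groups reads by exact UMI pair and calls one consensus molecule per
   group — groups of ≤ 4 reads must agree completely, larger groups need
   every position's plurality fraction ≥ 0.8. Each retained consensus
   counts **once**: that single step removes both sequencing errors and
   amplification bias.

On top sit the method's statistics: the loop re-amplification rate
(reads whose internal synthetic DNA-UMI maps to more than one primer-UMI
pair, per 1000 reads), the subsampled amplification bias
`mean over 500 repeats of max_i n_i` at depth 3000 (n_i = reads carrying
synthetic UMI i), titration linearity, and repertoire analytics:
germline V/J annotation, Hamming-1 clone networks, Rényi clonal
diversification, matched-depth intraclonal diversity, and somatic
hypermutation summaries (proportion unmutated, silent/non-silent,
CDR/FWR, CDR3 lengths).

The simulator (`sim_config()`, `simulate_sumi_experiment()`,
`simulate_standard_experiment()`) generates truth-tagged paired FASTQ for
both the barcoded and the conventional experiment: clone-structured
templates with optional internal synthetic DNA-UMIs and region-weighted
somatic hypermutation, per-cycle Bernoulli priming and loop re-amplification
in PCR1, Beta-distributed per-molecule PCR2 efficiency, and per-base
substitution errors with a two-component quality model.

## Worked example

```r
library(sumiseq)
germ <- synthetic_germline()                 # bundled synthetic reference
cfg  <- sim_config(n_templates = 200, sequencing_depth = 8000,
                   seq_error_rate = 0.005, seed = 1)
sim  <- simulate_sumi_experiment(cfg, germ, out_dir = "sim_out")
run  <- run_sumi_pipeline("sim_out/reads_R1.fastq", "sim_out/reads_R2.fastq",
                          spec = sim$spec, germline = germ, seed = 1,
                          out_dir = "run_out")
str(run$manifest$counts, max.level = 1)
#> List of 9
#>  $ input            : int 8000
#>  $ quality_pass     : int 7609
#>  $ merged           : int 3845
#>  $ annotated        : int 3764
#>  $ primer_rejects   :List of 2
#>  $ umi_groups       : int 999
#>  $ consensus        : int 793
#>  $ consensus_rejects:List of 1
#>  $ bcr_retained     : int 754
```

8000 simulated pairs; 7609 survive the median-quality filter (the
simulator puts ~5% of pairs in a low-quality component); 3845 merge over
an exactly identical overlap (at 0.5% error a single mismatch in the
~60–90 bp overlap discards the pair); 3764 yield a valid primer/UMI
annotation (81 rejected for primer mismatches or barcode structure);
the reads collapse to 999 UMI groups, of which 793 pass the consensus
agreement rules — the pipeline's estimate of the number of captured
template molecules — and 754 molecules annotate as in-frame BCR
sequences against the bundled germline. `run_out/` contains
`consensus.fasta` (headers carry `umi_fwd`, `umi_rev`, `support`),
`rejections.tsv` and `manifest.json`.

A thin CLI over the same functions lives at
`inst/cli/sumi.R` (subcommands: `simulate`, `preprocess`, `run`,
`standard`, `bias`, `titrate`, `repertoire`, `compare`).

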