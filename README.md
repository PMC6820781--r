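# famex

Characterization of unstable TTTTA/TTTCA pentanucleotide repeat
expansions, the class of intronic expansions that causes familial adult
myoclonic epilepsy (FAME).

At such a locus the reference genome carries a short polymorphic TTTTA
microsatellite (12 units at the packaged example locus,
GRCh37 chr5:10,356,460–10,356,519). Affected chromosomes instead carry a
mixed expansion 5'-(TTTTA)<sub>exp</sub>(TTTCA)<sub>exp</sub>(TTTTA)<sub>opt</sub>-3',
kilobases long, somatically unstable in length and internal structure,
and — at the largest sizes — prone to micro-rearrangements. `famex` is
aimed at genome analysts who need the full measurement chain for such a
locus as reusable, tested components:

* **Long reads** — anchor a read via flanking alignment and decompose the
  expansion into exact motif runs: `locate_expansion()`, `decompose()`,
  `decompose_read()`, `summarize_reads()`, `dotplot()`.
* **Short reads** — screen 150-bp paired reads for expansion evidence and
  genotype up to two alleles: `classify_read()`, `genotype_locus()`.
* **Molecular combing (fiber FISH)** — classify fibers (N / U /
  P<sub>likely</sub> / P<sub>definite</sub> by the unstained length Y with
  thresholds 5.5 and 8.5 kb), size pathogenic alleles with
  *Y*<sub>p</sub> − *Y*<sub>n</sub> + Σ*R* + Σ*W*, assign configurations
  C1–C6 and account for micro-rearrangements: `call_alleles()`,
  `cohort_summary()`.
* **Haplotype dating** — generations to the most recent common ancestor
  from the genetic length *L* (Morgans) of a shared core haplotype, with
  *L* ~ Gamma(2, *n·g*), MLE *ĝ* = 2/(*n·L*) and an exact χ²₄ interval:
  `date_mrca()`, `haplotype_span_kb()`.
* **Phenotype statistics** — Pearson correlations with Fisher-z intervals
  per expansion part, and 2^(−ΔΔCt) expression comparison with an exact
  rank-sum test: `pearson_with_ci()`, `onset_correlation_report()`,
  `relative_expression_ddct()`.
* **Synthetic data** — seeded generators for mosaic allele populations,
  nanopore-like long reads, paired short reads, combing tables and
  phenotype cohorts, so every stage is testable offline:
  `simulate_allele_population()` and the `emit_*()` family.

A transcription of the published per-individual summary table ships as a
fixture (`fame3_cohort()`); the packaged locus flanks are synthetic
stand-ins (see `?fame3_locus`).

## Worked example

```r
library(famex)
cfg <- fame3_locus()

# the reference repeat tract implied by the printed coordinates
decompose(reference_tract(cfg))
#> <repeat_structure> (TTTTA)12  (12 units over 60 bases, 0 gaps)

# simulate a mosaic individual and decompose error-free long reads
model <- expansion_model(n_ttta5 = 560, n_tttca = 480, n_ttta3 = 120)
cells <- simulate_allele_population(model, n_cells = 50, seed = 1)
reads <- emit_long_reads(cells, cfg, error_model = read_error_model(0, 0, 0),
                         n_reads = 4, seed = 2, p_truncate = 0,
                         p_fusion_if_rearranged = 0)
dec <- decompose_reads(setNames(reads$sequence, reads$read_id), cfg)
decomposition_table(dec)[, c("read_id", "n_units_TTTCA", "size_kb_total",
                             "structure")]
#>       read_id n_units_TTTCA size_kb_total                      structure
#> 1 simread0001           442         5.290 (TTTTA)454(TTTCA)442(TTTTA)162
#> 2 simread0002           338         4.780 (TTTTA)482(TTTCA)338(TTTTA)136
#> 3 simread0003           578         6.985 (TTTTA)702(TTTCA)578(TTTTA)117
#> 4 simread0004           578         6.985 (TTTTA)702(TTTCA)578(TTTTA)117
round(summarize_reads(dec)$mean_size_kb, 3)
#> TTTTA_5p    TTTCA TTTTA_3p    total
#>    2.925    2.420    0.665    6.010
```

Each read is one sampled blood cell: per-cell unit counts differ because
the simulator jitters the germline (560/480/120 units) log-normally —
the somatic mosaicism the real locus shows. The mean expansion here is
6.0 kb, within the 3.3–14.1 kb range of published per-individual means.

```r
# combing analysis of the same cell population
comb <- emit_combing_table(cells, individual_id = "SIM1", seed = 3)
cohort_summary(call_alleles(comb))[, c("n_P", "mean_expansion_kb",
                                       "mean_tttca_kb")]
#>   n_P mean_expansion_kb mean_tttca_kb
#> 1  49              5.46          2.25

# dating a 0.35 cM core haplotype shared by two families
haplotype_span_kb(10301295, 10492095)
#> [1] 190.8
date_mrca(0.35, n_lineages = 2)
#> <dating_result> g_hat = 285.7 generations (95% CI 34.6-795.9)
#>   ~5714 years ago (CI 692-15919) at 20 years/generation

# genotype-phenotype correlation on the packaged cohort fixture
rep <- onset_correlation_report(fame3_cohort())
subset(rep, phenotype == "seizure", c(part, n, r, r2))
#>           part n      r     r2
#>          total 7 -0.747 0.5584
#>          ttta5 7  0.176 0.0308
#>          tttca 7 -0.776 0.6019
#>   ttta5_plus_3 7 -0.217 0.0470
```

The age at seizure onset correlates inversely with the mean TTTCA size
(r = −0.78) but not with the TTTTA parts — the signature that the TTTCA
stretch is the pathogenic component.

## Command line

An executable `famex` script is installed under the package's `exec/`
directory:

```sh
famex decompose --reads reads.fastq --locus locus.json --out decomp.tsv
famex screen    --reads R1.fq,R2.fq --locus locus.json --out screen.tsv
famex comb      --measurements comb.tsv --out-alleles a.tsv --out-summary s.tsv
famex date      --cm 0.35 --lineages 2
famex correlate --cohort cohort.tsv --out corr.tsv
famex simulate  --what combing --seed 1 --out sim.tsv
famex run       --seed 1 --outdir out/
```

## Vignette

`vignettes/famex-methods.Rmd` documents the models, conventions,
parameter defaults, the synthetic world the generators state, and known
limitations.
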