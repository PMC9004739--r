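# seedtox

Predicted **6mer seed toxicity** analysis of small RNA-seq data.

Any si-, sh- or miRNA that enters the RNA-induced silencing complex acts
through its 6mer seed (positions 2–7 from the 5' end). Seeds rich in G and C
target C-rich seed matches in the 3'UTRs of survival genes and kill cells;
an arrayed screen of all 4096 seeds measured the % cell viability each seed
leaves behind. `seedtox` turns raw small RNA-seq reads (or a pre-built
unique-read count table) into:

* annotated count tables — seed, % seed viability, miRNA and small-RNA
  ("RNA world") identity per unique read (**Output A**);
* seed-collapsed tables (**B**, plus a seed-keyed intermediary);
* 1%-viability-binned **Seed Tox** profiles, ready to plot (**C**);
* instance expansions for rank tests on toxicity (**D**), sequence logos
  (**E**, with a position-frequency-matrix helper) and per-position
  nucleotide rows (**F**);
* a native negative-binomial exact test for differential read abundance
  between coded groups (padj < 0.05, |log2FC| > 0.585), with delta-CPM
  Up/Down sub-branches;
* a **multinomial mixed-effects logit** of positional seed composition:
  log P(nuc = k)/P(nuc = A) = β₀ₖ + group + position + group×position +
  b_ik, b_ik ~ N(0, σ²ₖ), fitted by adaptive Gauss–Hermite marginal ML,
  with Tukey-adjusted odds ratios (OR* = 1/OR display convention) and a
  group×position likelihood-ratio test.

A seeded synthetic-data module (references, viability resource, reads with
planted composition shifts and differential effects) makes every stage
testable offline; it is first-class, documented code.

## Worked example

```r
library(seedtox)

spec <- sim_spec(seed = 7)                  # 2 groups x 3 samples, 8000 reads/sample
sim  <- simulate_reads(spec)
viab <- make_viability_table(spec)          # synthetic 4096-seed resource

ct   <- normalize_cpm(build_count_table(sim$samples))
flt  <- filter_rare_reads(ct)               # normCount < n removed
atab <- annotate_table(flt$kept, sim$refs$mirna, sim$refs$rnaworld, viab)
atab
#> annotated_count_table: 180 reads x 6 samples; 100 miRNA-assigned, 5 artifact rows dropped

round(mirna_content(atab), 1)
#> control_rep1 control_rep2 control_rep3 disease_rep1 disease_rep2 disease_rep3
#>         59.5         57.1         57.1         58.9         61.1         60.3

b    <- collapse_to_b(atab, "norm")         # Output B: (seed, name) keyed CPM
gavg <- collapse_group_average(b, sim$sample_groups)

# toxicity rank test on the Output D expansions (one value per rescaled instance)
toxicity_rank_test(list(control = expand_to_d(gavg, "control"),
                        disease = expand_to_d(gavg, "disease")))
#> Wilcoxon rank-sum: W = 669978, p = 5.27e-41

# positional composition model on the Output F expansions
fdat <- do.call(rbind, lapply(spec$groups, function(g) {
  f <- expand_to_f(gavg, g); f$group <- g; f
}))
m <- fit_seed_composition(fdat)
m
#> seed_composition_model: 2 groups ( control, disease ), 1954 seed instances
#>   reference category A; sigma2 (C, G, U): 0.0514, 0.0000, 0.0106

do.call(rbind, lapply(1:6, function(j)
  pairwise_or(m, "G", j, "disease", "control")))[, c("position","or","ci_lo","ci_hi","p_adj")]
#>   position    or ci_lo  ci_hi    p_adj
#> 1        1 4.869 3.796  6.246 1.30e-35
#> 2        2 8.736 5.813 13.129 1.85e-25
#> 3        3 1.927 1.508  2.463 1.56e-07
#> 4        4 0.507 0.380  0.676 3.83e-06
#> 5        5 1.475 1.130  1.925 4.28e-03
#> 6        6 0.607 0.478  0.771 4.40e-05

interaction_test(m)
#> interaction LRT: X2 = 435.7 on 15 df, p = 2.09e-83
```

Reading the output: the generator plants a per-position G-vs-A odds ratio
of 5 at seed positions 1–3 of the disease group (toxic seeds are G-rich
toward the 5' end). The fitted ORs recover the enrichment at the planted
positions (4.9, 8.7, 1.9 — the finite reference pool makes the realized
per-position shift vary around 5), stay near or below 1 at the unplanted
positions, and the highly significant interaction reflects exactly that
position dependence. The disease group's expansion also shifts toward lower
viability (more toxic seeds), hence the small Wilcoxon p.

## Whole pipeline in one call

```r
cfg <- pipeline_config(
  input = c(ctrl1 = "ctrl1.fastq", ctrl2 = "ctrl2.fastq",
            dis1 = "dis1.fastq",  dis2 = "dis2.fastq"),
  input_kind = "fastq", organism = "human", mode = "risc",
  mirna_fasta = "mirna.fasta", rnaworld_fasta = "rnaworld.fasta",
  viability_tsv = "viability.tsv", output_root = "out",
  analyses = c("totalCounts", "differential"),
  comparisons = "comparisons.csv",       # rows of 1 / -1 / 0 per sample
  groups = c(ctrl1 = "control", ctrl2 = "control",
             dis1 = "disease", dis2 = "disease"))
pipeline_plan(cfg)     # commented, ordered stage script (dry run)
pipeline_run(cfg)      # populates {totalCounts,differential}/{sRNA,miRNA}
```

`pipeline_run()` writes the keyed files (`A_rawCounts`, `A_normCounts`,
`A_diff`, `B_collapsed`, `Int_seedKeyed`, `C_binned`, `D_toxAnalysis_*`,
`E_seedAnalysis_*`, `F_seedExpand_*`, `Int_allReads`) plus a stage log with
row counts in/out. A command-line wrapper with `plan` / `run` / `simulate`
subcommands is installed at `exec/seedtox`.

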