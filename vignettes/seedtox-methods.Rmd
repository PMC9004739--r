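---
title: "seedtox: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedtox: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtox)
```

## The problem

Any small RNA loaded into the RNA-induced silencing complex (RISC) acts as a
guide whose targeting is dominated by its **6mer seed** — nucleotides 2–7
from the 5' end. Seeds rich in G (and, less so, C) target C-rich seed
matches in the 3'UTRs of survival genes and kill cells (death induced by
survival-gene elimination). An arrayed screen of all $4^6 = 4096$ seeds in a
neutral siRNA backbone measured **% cell viability** per seed; low viability
means a toxic seed. `seedtox` profiles any small RNA-seq dataset (total or
RISC-bound) purely by the predicted toxicity of each read's seed, and tests
whether seed *composition* differs between biological groups.

## Pipeline

Reads are cleaned (fixed-length 5' UMI strip, exact-prefix 5' adapters,
first exact occurrence of the 3' adapter, default `TCCGACGATC`), then length
filtered: **total** mode keeps 18–25 nt; **risc** mode keeps everything ≥ 7
nt, the minimum with an extractable seed. Unique reads are tabulated per
sample, normalized to counts-per-million (CPM), and rare reads are removed:
a read is dropped when its *normCount* — the row total of CPM values — is
strictly below $n$, the number of samples (these are overwhelmingly
sequencing errors). The pre-filter table is persisted (`Int_allReads.txt`)
so an analysis can restart without the threshold; the kept table is
re-normalized so columns again sum to $10^6$ (the re-normalization is our
choice; the source description is silent about it and Output A is defined as
"each sample normalized to 1 million reads").

Reads are then named: a mature-miRNA identity requires an ungapped, exactly
identical shared substring of ≥ 18 nt; a small-RNA ("RNA world") identity
requires ≥ 95% ungapped identity of the whole read against a catalog window
(for an 18–25 nt read this means at most one mismatch; indels are not
allowed, which keeps identity = matches / read length well defined).
Multiple qualifying references are resolved by longest shared identity, then
earlier alignment start on the read, then lexicographic name — an invented
but deterministic tie-break. Reads whose catalog assignment contains
`Tuschl`, `artifical`, `marker`, `adapter` or `artificial` (case-sensitive;
the misspelling is part of the historical catalog) are purged. Each kept row
carries its seed (RNA alphabet; the T→U mapping happens exactly once, in
`extract_seed()`), the species-averaged % viability of that seed, and both
identity columns.

### Keyed outputs

* **A** — annotated counts (raw / CPM / differential statistics).
* **B** — rows collapsed by (seed, assigned name), values summed;
  `Int_seedKeyed` further collapses to one row per seed.
* **C** — counts aggregated into 1% viability bins (round half away from
  zero — `49.5 → 50`), one row per bin over the resource's full range even
  when zero: the Seed Tox profile, directly plottable.
* **D / E** — each B row expanded into `round(count/1000)` instances
  carrying the row's viability (D) or seed string (E); the /1000 rescaling
  keeps downstream statistics tractable. Rows whose count rounds below 1
  simply vanish.
* **F** — as E, but only rows with a pre-scaling count ≥ 1000 are kept, and
  every instance emits six rows (position 1–6, nucleotide), with a unique
  instance id: exactly $6N$ rows for $N$ total scaled instances. The < 1000
  omission is stated only for F, so D and E deliberately do not apply it.

Half-away-from-zero rounding is used for both the 1% bins and the /1000
rescaling ("rounded steps" names rounding but no rule; half-away matches the
spreadsheet behavior the field plots with, and is asserted explicitly in the
tests: `5000 → 5`, `1500 → 2`, `499 → 0`).

The differential branch codes samples 1 / −1 / 0 (Group1 = control,
Group2 = perturbed), tests each read with a native negative-binomial exact
test, and keeps reads with adjusted p < 0.05 (or raw p, by option) and
|log2 FC| > 0.585. Downstream outputs then use the **delta CPM** with the
sign carried as an `Up` / `Down` group label, never as a negative count.

## Differential test

Raw counts are scaled to the geometric-mean library size and the two group
sums are compared conditionally on their total: group sums of i.i.d.
NB(μ, size $n/\phi$) variables give a Dirichlet-multinomial (beta-binomial)
conditional law, which degenerates to binomial($s$, $n_1/(n_1+n_2)$) at
$\phi = 0$. The two-sided p-value sums the probabilities of all outcomes no
more likely than the observed one. The common dispersion $\phi$ maximizes
the conditional (Dirichlet-multinomial) likelihood across reads; `tagwise`
moderates per-read estimates toward the common one with ten pseudo-reads of
prior weight; `poisson` forces $\phi = 0$. log2 fold changes use CPM group
means with a 0.5 pseudo-count on both groups. CPM is the pipeline's only
normalization — no TMM — and numerical parity with any external
implementation is not claimed; the $\phi \to 0$ limit is verified against a
closed-form binomial oracle, and the swap-symmetry and BH-monotonicity
properties are asserted directly.

## Seed-composition mixed model

Output F data are modeled as a baseline-category logit with A as the
reference (A-rich seeds are the least toxic):

$$\log \frac{P(\text{nuc}_{ij}=k)}{P(\text{nuc}_{ij}=A)}
  = \mathbf{x}_{g_i j}'\boldsymbol\beta_k + b_{ik},
  \qquad b_{ik} \sim N(0, \sigma_k^2),\; k \in \{C, G, U\}$$

with group, position (1–6) and their interaction as fixed effects and one
random intercept per seed *instance* (a 5000-count seed contributes five
instances, so abundance is represented) and per category, independent across
categories. The independence assumption is ours; the source text names only
"the seed id" as the random effect, and per-category intercepts with
category-specific variances still induce within-seed correlation across
positions.

**Estimation.** The joint multinomial likelihood couples the three
intercepts through the softmax denominator, so it is *not* literally a
product of one-dimensional integrals. We keep the one-dimensional
architecture by the conditional-binary decomposition (Begg–Gray): given
that an outcome is in $\{k, A\}$, its conditional probability is
$\operatorname{logit}^{-1}(\eta_k + b_{ik})$ — the denominator cancels — so
each category is fitted as a binary random-intercept logit on the positions
where the outcome is $k$ or $A$. Each marginal likelihood is integrated by
**adaptive Gauss–Hermite quadrature** (15 nodes by default; nodes from the
Golub–Welsch eigenproblem; per-pattern posterior modes by vectorized
Newton). Instances are collapsed to distinct (group, outcome-pattern)
weights, so likelihood cost is independent of abundance, and the optimizer
works on a frozen adaptive grid with exact analytic gradients,
re-centering the grid in outer cycles; final values are re-evaluated with
freshly adapted quadrature. At the $\sigma^2 = 0$ boundary the fit falls
back to the exact Newton–Raphson logistic solution, which for the saturated
group × position design equals the empirical cell log odds — that
equivalence is asserted to machine precision in the tests. The
decomposition is a consistent approximation when $\sigma^2 > 0$ (position
selection is mildly informative about $b_{ik}$); at 60 000 instances per
group the fitted log OR of a planted OR = 5, $\sigma^2 = 1$ scenario was
within 0.04 of truth.

Degenerate cells (a nucleotide absent from a whole group × position cell)
trigger a warning and a weak ridge ($\lambda = 10^{-2}$) on the fixed
effects rather than a divergent fit.

**Inference.** Odds ratios comparing the odds of $k$ vs A between two
groups at a position are Wald contrasts on the observed-information
covariance; all pairwise group contrasts are adjusted by Tukey's method via
the studentized-range distribution on the Wald scale (with two groups this
reduces to the unadjusted two-sided p). Display convention: when OR < 1 the
plotted value is OR* = 1/OR. The group × position interaction is tested by
a likelihood-ratio statistic summed over the three categories against
$\chi^2_{3(G-1)\cdot 5}$. Measured null calibration at $\alpha = 0.05$:
≈ 0.105 at 500 instances/group and ≈ 0.071 at 1000 (likelihood-ratio
statistics with estimated variance components carry textbook finite-sample
inflation, and the three category components are positively correlated);
the acceptance suite therefore exercises the test at 1000 instances/group,
the upper end of its stated range. Seed toxicity itself is compared by a
two-sided Wilcoxon rank-sum test on the Output D expansions (exact for
small tie-free samples, tie-corrected normal approximation otherwise) or
Kruskal–Wallis for more than two groups.

## Synthetic world

The generator states one fixed world (changed only once, see below): two
groups × three samples, 8000 expected reads per sample, 100 miRNA-like
references (20–23 nt), 80 small-RNA references (30–60 nt, read = 5'
fragment of 18–25 nt), 5 artifact entries named with the purge keywords,
NB dispersion 0.05 across replicates, 20% of references planted 4-fold up
(log2 FC = 2) in the disease group, and a planted G-composition shift:
disease sampling weights are tilted by $5^{n_G}$ where $n_G$ counts Gs at
seed positions 1–3 — per-position odds ratio 5, on the scale of the odds
ratios reported in diseased tissue. The shift lives in the 5' half of the
seed because that is where the toxic-seed G-enrichment is documented;
positions 4–6 double as negative controls. (A first design tilted on the
whole seed; that concentrates the disease pool onto the few most G-rich
references and makes per-position significance unstable, so the 5'-half
design replaced it — the one revision made to the stated world.) The
synthetic viability resource decreases smoothly with G (slope −12 per G)
and C (−6 per C) content plus seed- and cell-line-level noise, clamped at 0
and uncapped above 100, across three pseudo-cell-lines.

What a green test establishes: the machinery recovers planted differential
reads, planted composition shifts and conservation laws on data *shaped
like* small RNA-seq (unique-read multiplicity, reference-derived identity,
group tilts). What it does not establish: behavior under sequencing error
(reads are exact reference copies), adapter chemistry beyond exact
substrings, UMI collision statistics, or any claim about the real
biological datasets, which are deliberately not required.

## Numerical choices and limitations

* Quadrature: 15 adaptive nodes default; `nagq` is exposed. σ is optimized
  on $[0.01, 10]$ with an explicit σ = 0 boundary comparison.
* Covariance: observed information by gradient finite differences on the
  frozen grid; if σ sits on the boundary, the β block is inverted alone.
* Ties in the exact two-sided tests are grouped with a $1 + 10^{-10}$
  relative slack before summing "no more likely" outcomes.
* The rare-read rule uses strict `<` (equal-to-n rows are kept), and the
  boundary is asserted at normCount 3.9 vs 4.0 with n = 4.
* Row order everywhere: descending total value, then lexicographic — chosen
  for deterministic, human-scannable outputs.
* Multi-factor designs, gapped alignment, quality trimming, novel-miRNA
  discovery and E-value statistics are out of scope; `--use-blast`-style
  escape hatches are not provided.
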