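# trioburden

Two-stage burden analysis of rare predicted-pathogenic variants in
case-control **trio exome** cohorts, built for the study design in which an
affected child and both unaffected parents are sequenced together — the
setting used to ask whether a sporadic congenital disorder (here:
congenital hypopituitarism, compared against non-familial short stature)
has a major genetic component, and whether it is plausibly monogenic with
full penetrance.

The package is aimed at statistical-genetics analysts who have per-trio
annotated VCFs, a pedigree, and a gene panel, and who want the complete
chain — variant normalization, candidate filtering, trio transmission
classification, gene-level monogenic enumeration, and exact case-control
statistics — as tested, scriptable functions rather than a GUI workflow.

## What it computes

**Analysis 1 — panel burden.** A variant is a *rare, predicted-pathogenic
candidate* when all five criteria hold on the proband call: coverage
> 10 reads; genotype-score/coverage > 0.5; population allele frequency
< 1% (absent = not found = kept, and homozygote count < 2 for
homozygous/hemizygous probands); protein-altering consequence; and, for
missense, ≥ 2 of 3 damaging calls from SIFT / PolyPhen2 / MutationTaster
(truncating and indel classes bypass the predictor vote). Candidates in a
pituitary-development gene panel are counted per proband regardless of
inheritance.

**Analysis 2 — monogenic candidates.** Genome-wide, candidates are kept
only when their transmission could explain an affected child of unaffected
parents with full penetrance: de novo (child het, both parents confidently
non-carriers), autosomal recessive (homozygous, or compound-heterozygous
with ≥ 1 allele from each parent), or X-linked recessive (male proband
hemizygous, carrier mother, non-carrier father). Candidates are counted at
the gene level, one per (gene, mode, trio).

**Statistics.** For each analysis the per-proband counts are compared
between groups with exact tests implemented from first principles:

* mean counts — Mann-Whitney *U* from midranks with an exact-permutation
  two-sided *p* (full enumeration when C(n₁+n₂, n₁) ≤ 2×10⁶, else seeded
  Monte-Carlo with 10⁵ resamples);
* proportion of probands with ≥ 1 candidate — two-sided Fisher exact test
  by the point-probability method:
  *p* = Σ { P(T) : P(T) ≤ P(T_obs) } over all 2×2 tables T with the
  observed margins.

A synthetic trio-cohort generator (`simulate_cohort()`) produces cohorts
with Hardy-Weinberg parents, Mendelian transmission, and planted
de novo / compound-het / AR-homozygous / XLR / panel events of known
truth, so the whole pipeline is testable without controlled-access data.

## Worked example

The published results tables of the motivating cohort study (13
hypopituitarism trios vs 19 short-stature trios) ship as transcribed
fixtures; recomputing their statistics from scratch:

```r
library(trioburden)
s <- reported_burden_summary()
s$panel
#> Burden comparison (case vs control)
#>   probands:        13 vs 19
#>   mean/proband:    1 vs 0.21  (Mann-Whitney U = 179.5, P = 0.01, monte_carlo)
#>   % with >= 1:     62% vs 21%  (Fisher exact P = 0.03)
s$n_case_panel_genes        # 11 distinct panel genes hit in cases
s$monogenic_case_mean       # 1.3 gene-level monogenic candidates / proband
s$causative$p_fisher        # 0.0104: 0/13 vs 8/19 causative trios
```

62% of case probands vs 21% of controls carry at least one rare
predicted-pathogenic panel variant (Fisher exact P = 0.03) — a genetic
signal — while cases show *fewer* fully penetrant monogenic candidates
than controls and none in genes known to cause their phenotype
(P = 0.01), arguing against simple monogenic causation.

The same machinery runs end-to-end on simulated or real files:

```r
co <- simulate_cohort(study_scale_scenario())   # 13 vs 19 trios, known truth
run_analysis1(co)
#> Analysis: panel_burden
#> Burden comparison (case vs control)
#>   probands:        13 vs 19
#>   mean/proband:    0.92 vs 0.32  (Mann-Whitney U = 185.5, P = 0.01, monte_carlo)
#>   % with >= 1:     77% vs 32%  (Fisher exact P = 0.03)

dir <- tempfile(); write_cohort(co, dir)        # VCFs + PED + panel + truth
cfg <- run_config(pedigree = file.path(dir, "cohort.ped"),
                  cases = file.path(dir, "cases.txt"),
                  controls = file.path(dir, "controls.txt"),
                  panel = file.path(dir, "panel.txt"),
                  par = par_intervals("synthetic"),
                  out_dir = file.path(dir, "out"))
res <- run_pipeline(cfg)                        # TSV + JSON reports
```

A thin command-line wrapper ships at `inst/cli/trioburden.R`
(`simulate` and `run` subcommands).

## Caveats

The shipped panel (`trioburden_panel()`) is an incomplete 26-gene
reconstruction of the study's 42-gene panel (only individually named
genes are recoverable); supply the full panel for faithful screens. The
transcribed case variant table supports a case panel mean of 1.0 versus
the published 1.1 — one variant appears only in non-redistributable
supplementary material. See the methods vignette
(`vignettes/trioburden-methods.Rmd`) for the full model description,
design decisions and limitations.
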