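# fadesame

Does a cognitively enriched life leave a measurable trace in how the
aging brain encodes new memories? `fadesame` is an R package for
analyses that relate **environmental enrichment** — scored from the
Lifetime of Experiences Questionnaire (LEQ) — to the **preservation of
memory-network fMRI activity** in older adults, summarised by
single-value FADE and SAME scores computed against a young reference
cohort. It is aimed at researchers working with task-fMRI single-value
scores and questionnaire-based reserve proxies who need the whole
chain — task design, first-level contrasts, reference-based scoring,
and missing-data-aware regression — as tested, reusable code. Because
the cohort data such analyses run on are typically access-restricted,
the package ships a synthetic-cohort generator that emulates the study
design, so every stage runs, and is validated, without any data
download.

## The scores at the core

For a contrast map with voxel t-values $t_j$, a network mask $M$, and
young-cohort positive/negative-effect voxel sets $V^+, V^-$ with
per-voxel young mean $m_j$ and SD $s_j$:

- **FADE** (Functional Activity Deviation during Encoding):
  $\overline{t}_{M \setminus V^+} - \overline{t}_{V^+}$ — higher means
  more deviation from the young activation pattern.
- **SAME** (Similarity of Activations during Memory Encoding):
  $\frac{1}{|V^+|}\sum_{V^+}\frac{t_j - m_j}{s_j} +
   \frac{1}{|V^-|}\sum_{V^-}\frac{m_j - t_j}{s_j}$ — higher means more
  similarity; reduced activations *and* reduced deactivations lower
  it, and a map equal to the young mean scores exactly 0.

Both are computed for a **novelty** contrast (novel vs. familiarized
"master" images) and a **subsequent-memory** contrast (novel trials
parametrically modulated by later recognition confidence). The
**EE score** (0–60) sums 0–5 frequency points over six leisure
activities and two life stages. Incomplete LEQ profiles are not
imputed: Little's MCAR test checks the missingness, and regressions
use full-information maximum likelihood (FIML) over all partially
observed rows, with standardized betas.

## Worked example

```r
library(fadesame)

cfg <- sim_config(wire = "same_novelty", effect_beta = 0.13)
report <- full_run(cfg, analysis_config(), seed = 2)
report
#> End-to-end run (seed 2, config bf0894c24aa7da1c126f2bcc2b9b96fc)
#>   Little's MCAR test: chi-square = 180.11, df = 181, p = 0.505
#>   Primary regressions (standardized beta of EE):
#>     fade_novelty  beta = -0.080  p = 0.1392  (n = 372)
#>     same_novelty  beta =  0.182  p = 0.0006  (n = 372)
#>     fade_memory   beta = -0.061  p = 0.2577  (n = 372)
#>     same_memory   beta =  0.061  p = 0.2535  (n = 372)
#>   Focal outcome: same_novelty; interaction F(4, 330) = 0.14, p = 0.966
#>   Screened covariates: sex
```

Reading this: the generator wired a standardized enrichment effect of
0.13 into the novelty-SAME score only. The pipeline simulated 372
older adults (with 106 young reference maps), scored their LEQ
responses (30-ish participants have items missing completely at
random — Little's test agrees, p = 0.505), derived the four scores,
and recovered the wired effect where it was planted (β = 0.18 here;
single replicates scatter around 0.13 with SD ≈ 0.05) while the three
null outcomes stay near zero. Subgroup fits, the slope-heterogeneity
F-test, covariate screening and adjusted models follow the same
report:

```r
report$subgroup[, c("sample", "outcome", "n", "beta", "se", "p.value")]
#>   sample outcome          n  beta     se p.value
#> 1 OA     same_novelty   130 0.151 0.0903 0.0940
#> 2 SCD    same_novelty   205 0.196 0.0715 0.00608
#> 3 FH     same_novelty    37 0.221 0.164  0.177

tidy(report)                      # every fitted model, one row each
plot_enrichment_scatter(report)   # complete-case points, FIML line
```

Lower-level pieces are exported individually —
`simulate_session()`, `build_design_matrix()` / `fit_first_level()`
for the BOLD path, `derive_reference()` / `score_cohort()`,
`score_leq()`, `little_mcar_test()`, `fiml_regression()` — and a thin
command-line wrapper lives at `inst/cli/fadesame`
(`simulate`, `score-leq`, `fade-same`, `full-run`).

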