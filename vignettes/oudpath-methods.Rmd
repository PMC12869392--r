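---
title: "Modelling OUD transitions and ranking candidate therapies with oudpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling OUD transitions and ranking candidate therapies with oudpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oudpath)
```

# Overview

`oudpath` joins two analyses around one input format, a table of dated
coded-concept occurrences per person (`person_id`, `concept_id`,
`domain`, `day`):

1. a **multi-stage survival leg** that phenotypes three opioid-use-disorder
   transitions — onset, remission, relapse — and screens stage-specific
   predictors with stability-selected lasso-Cox models, and
2. a **therapy knowledge-graph leg** that assembles an evidence-weighted
   disease–gene–pathway–drug graph and ranks drugs by Personalized
   PageRank.

This vignette explains the models, the conventions the package fixes where
the underlying methodology leaves choices open, the parameters that matter,
and what the synthetic-data generator does and does not emulate.

# The survival leg

## Phenotyping

Three transition clocks are derived per person from two concept sets
(OUD-qualifying codes and remission codes), with end-of-data censoring:

* **onset** — day 0 to the first OUD-concept event; one record per person;
* **remission** — for persons with OUD, from the *last* OUD event
  preceding the remission code (or preceding censoring, for persons whose
  remission is never observed) to the first remission code;
* **relapse** — for persons with observed remission, from the remission
  day to the first OUD event strictly after it.

Two conventions are worth stating. First, the "last OUD event" origin is
well defined for censored persons too: it is the latest OUD event before
end of data. Second, start–stop risk intervals need strictly positive
length, so a remission code on the same day as an OUD event produces a
zero-length record, which is dropped with a warning rather than silently
kept; the same rule covers any degenerate record. Only the first
remission and first relapse are modelled — repeat cycles are out of
scope, which keeps the three transitions cleanly ordered and gives the
counting identity (#relapse records ≤ #remission events ≤ #onset events)
used as a standing invariant in the tests.

## Time-indexed features

For every concept, five transforms are evaluated at risk-set time $t$:
counts over the trailing 30/90/365-day windows, the cumulative count, and
days since the most recent occurrence. Windows are **half-open
$(t-w,\,t]$**: an occurrence exactly $w$ days before $t$ is outside the
$w$-day window, while an occurrence on day $t$ itself is inside. "Prior
to $t$" phrasing does not pin down the boundary, so one convention had to
be fixed, tested, and used identically by the simulator and the feature
builder.

Count transforms enter the model per unit of $\log(1+x)$, which keeps
zero counts at zero while taming the long right tail of utilization
counts; recency is left on its natural day scale (a log on a recency
would invert its interpretation). A concept never observed by time $t$
gets `days_since_last` equal to a finite sentinel — follow-up length + 1 —
paired with `cum` = 0; a finite sentinel keeps the design matrix dense
and preserves the "larger = longer ago" reading.

Rows are split **at event days only**. Between events every feature is a
step function (recency grows linearly but enters the partial likelihood
only where events occur, evaluated at row starts), so event-driven
splitting leaves the counting-process likelihood of the fitted
step-feature model unchanged while keeping row counts proportional to
event counts rather than follow-up days.

Static covariates (age, sex, socioeconomic indicators, genetic principal
components supplied as opaque numeric columns) are carried unchanged on
every row; categorical covariates expand to indicators against the most
frequent level.

## Penalized fitting and stability aggregation

Each shard is an L1-penalized Cox fit on the start–stop rows
(`glmnet::cv.glmnet`, `family = "cox"`, Breslow ties), with features
standardized internally and coefficients reported on the original scale.
Three conventions are fixed for reproducibility:

* the penalty is the **CV-deviance-minimizing** lambda, not the 1-SE rule;
* cross-validation folds are assigned **at the person level** (all rows of
  a person share a fold) by a seeded draw, so a shard fit is a pure
  function of (data, K, seed);
* shards partition **persons**, not rows, by a seeded draw.

Aggregation records, per feature, the number of shards selecting it and
the arithmetic mean of $\exp(\beta)$ over those shards (the mean of the
hazard ratios, not the exponential of the mean coefficient).
Prioritization keeps features above a selection-frequency threshold and
orders them by frequency, then by $|\ln \text{mean HR}|$, so strong
protective and strong adverse effects rank symmetrically.

Numerical choices: glmnet's start–stop Cox path is an R-level algorithm
and is the pipeline's dominant cost, so `fit_penalized_cox_shard()`
exposes the path controls with coarser-than-glmnet defaults
(`nlambda = 30`, `lambda.min.ratio = 0.05`, `thresh = 1e-5`,
`dfmax = 50`). The deepest, smallest-lambda region of the path is both
slow and prone to step-size failures when the selected set approaches the
event count; bounding the path with `dfmax` and a floor on lambda avoids
that region, which a stability screen has no use for anyway. Fits with
fewer than two events are refused; constant columns are dropped with a
note; coefficients with $|\beta| > 10$ trigger a separation warning but
are reported as estimated, since screening pipelines on sparse phenotype
data do encounter quasi-separated features and hiding them would be worse
than flagging them.

The unpenalized summary fit (`fit_summary_cox_with_fdr()`) is a single
`survival::coxph` counting-process model over a compact summary feature
set, with Wald 95% intervals and Benjamini–Hochberg q-values across the
set; non-convergence is reported per-feature as `NA` with a warning.

# The knowledge-graph leg

## Edge weights

Disease→gene weights come from an ordered piecewise rule over the
gene-evidence record; the **first matching branch wins**, in the order:
replication count ($0.5 + 0.3r$), cross-ancestry study flag ($1.0$),
OUD-only study flag ($0.8$), OUD-only MTAG flag ($0.5$), fine-mapping
posterior ($0.2 + p$), p-value rank ($\ln(3 + k/e)$), else the floor
$\varepsilon$. The result is capped into $[\varepsilon, c_{max}]$. The
ordering matters because a gene may carry several evidence types; a
piecewise list implies ordered cases, and replication evidence — the most
quantitative — is given precedence.

The p-rank branch deserves a caveat: the adopted literal form
$\ln(3 + k/e)$ exceeds 1 for every $k \ge 0$ (since $\ln 3 \approx 1.1$),
so under the default cap $c_{max} = 1$ it always saturates — every
p-rank-evidenced gene receives the full capped weight regardless of rank.
The reading is isolated in `gene_direct_weight()` so an alternative
(e.g. a decreasing-in-rank form) can be swapped in one place if a
different interpretation is preferred.

Pathway bridging: a pathway $p$ with member set $M_p$ containing at least
$m_{min}$ seed genes $S_p$ grants each non-seed member the bonus
$b_p = \gamma \sum_{g \in S_p} w^{direct}_g / |M_p|$. When several
pathways bridge one gene, the **maximum** bonus is kept (assignment, not
accumulation) and every supporting pathway is recorded for provenance;
the total number of bridged genes is capped at $B_{max}$, keeping the
highest bonuses (ties broken by gene id for determinism).

Gene→drug weights score potency and annotations:
$t = 1 + \mathrm{clip}((\mathrm{pChEMBL}-5)/4,\,0,\,1) + 0.2\,I_{ant} +
0.1\,I_{ago} + 0.3\,I_{ph3} + 0.7\,I_{app} + 0.2\,I_{bbb} -
0.5\,I_{res}$, with the potency term 0 when pChEMBL is missing, floored
at $\varepsilon$. Approval implies late phase ($I_{app}=1$ forces the
phase-3 term on), and the two mechanism indicators are additive if both
are set — the flattened printed form of the score supports the additive
reading, and this is taken as the defined behaviour.

## Ranking

Pathway nodes exist only to support bridging; before ranking they are
projected out and every remaining node's outgoing weights are normalized
to sum to one. Drug nodes have no outgoing edges; their random-walk mass
is redirected to the personalization vector (the standard dangling-node
treatment, required for the scores to remain a probability vector). The
personalization puts all restart mass on the disease node unless an
approved-drug prior is configured, in which case that mass is split
equally over approved drugs.

The ranking vector solves $r = \alpha P^\top r + (1-\alpha)s$ by power
iteration to an L1 tolerance. Defaults: $\alpha = 0.85$ (the conventional
damping), `tol` $= 10^{-10}$, `max_iter` $= 1000$. The iteration
contracts by a factor $\alpha$ per step, so reaching $10^{-10}$ needs on
the order of $\log(10^{-10})/\log(0.85) \approx 140$ iterations — a cap
of 100, sometimes seen as a PageRank default alongside looser tolerances,
would be self-inconsistent with this tolerance, hence the higher cap.
Non-convergence at the cap is an error carrying the residual, never a
silent partial result. Correctness of the iteration is pinned in the
tests against a dense linear solve of
$(I - \alpha \tilde P^\top) r = (1-\alpha) s$ on small graphs, and
cross-checked once against `igraph::page_rank`.

Ranked output is sorted by score with drug-id tie-breaks; each row carries
up to `why_top` supporting genes ordered by walk contribution
$r(g)\,P(g{\to}d)$, labelled direct / bridged / non-seed, with bridging
pathways named. An optional named vector of
additive per-drug score offsets (node-level priors, off by default) can
nudge the final ordering with external knowledge without touching the
walk itself. `alias_mode = "merge"` folds salt/ester forms
(lowercasing plus a fixed suffix list: hydrochloride, sulfate, tartrate,
…) into one ingredient row keeping the maximum score — duplicate entries
in drug databases are normalization artifacts, not distinct mechanisms.

Default parameters: $\varepsilon = 10^{-6}$, $c_{max} = 1$, $\gamma =
0.5$, $m_{min} = 2$, $B_{max} = 50$, approved prior 0. The floor and cap
bound every edge into a known range; $\gamma = 0.5$ halves bridged
evidence relative to direct; $m_{min} = 2$ demands at least two seed
genes before a pathway may vouch for its members; all are exposed in
`kg_params()` and on the command line.

# The synthetic-data generator

`simulate_cohort_events()` is first-class, tested code, not a fixture: it
defines the study conditions under which the pipeline's statistical
behaviour is demonstrated.

Concept events follow an inhomogeneous Poisson process per (person,
concept): a person-level log-normal frailty (sd 0.5 on the log scale,
mean-corrected) scales all of a person's intensities, and a Beta-shaped
per-(person, concept) intensity profile clusters occurrences in time, so
windowed counts genuinely vary within a person — all five transforms are
exercised, not just `cum`. Transition times are sampled exactly, by
inversion of the piecewise-constant cumulative hazard whose log-linear
predictor is the planted coefficient vector evaluated over the *same*
left-evaluated step features the feature builder computes. Sampling and
fitting therefore share one likelihood, which is what makes
planted-parameter recovery a meaningful test of the estimation pipeline
rather than of two approximations cancelling. Remission clocks start at
the sampled onset day and relapse clocks at the sampled remission day;
marker concepts (`oud1`, `rem1`) are written into the stream at the
sampled transition days so the phenotyping rules can be tested against
the latent truth. Days are integers from cohort entry; calendar dates and
vocabularies are deliberately not emulated.

Default conditions, chosen once: 2000 persons, 730 days of follow-up, 8
feature concepts across the four domains (4 condition + 2 drug + 1 survey
+ 1 procedure) plus 2 null condition concepts, 0.35 expected events per
concept-year — about 5–6 coded events per person-year, sparse and
irregular as EHR streams are — baseline hazards of $3\times10^{-4}$/day
(onset; ~20% two-year cumulative incidence), $10^{-3}$/day (remission)
and $8\times10^{-4}$/day (relapse), and one planted effect, $+1.0$ per
log1p-unit on the 30-day count of condition concept 1.

What the generator does **not** emulate — and therefore what passing
recovery tests do not establish about real data: informative observation
(visit frequency correlated with latent severity), measurement error and
phenotype misclassification, strongly correlated concept clusters,
missing-not-at-random survey responses, and calendar effects. Recovery
under the generator shows the estimation machinery is correct, not that
real-world confounding is overcome.

The knowledge-graph generator (`simulate_kg_tables()`) assigns each seed
gene exactly one evidence branch (proportions configurable), always
builds at least one bridgeable pathway ($\ge m_{min}$ seed genes plus a
non-seed member), and guarantees the drug table contains an approved
drug, a research-only drug and a missing-potency pair, so every weighting
branch downstream is reachable from simulated input.

# Validation harness sizes

The recovery harness in the test suite runs 20 replicate cohorts at the
default conditions (n = 2000), fitting each with person-level 3-fold CV
over a 15-value penalty path (`lambda.min.ratio = 0.15`,
`thresh = 1e-4`, `dfmax = 25`); the planted feature must carry the
correct sign in at least 90% of replicates and the highest selection
frequency overall. Mass-conservation and linear-solve equivalence of the
ranking walk run over 100 and 50 random graphs respectively. These sizes
are the package's validation conditions; larger cohorts simply sharpen
the same checks.

# Known limitations

* Only first remission and first relapse are modelled; recurrent-cycle
  extensions would need a different risk-set bookkeeping.
* The penalized screen reports selection frequencies and mean hazard
  ratios, not selection-corrected confidence intervals; the summary fit
  provides calibrated inference only for its prespecified low-dimensional
  feature set.
* Extreme hazard-ratio estimates from quasi-separated sparse features are
  flagged, not regularized away.
* The graph ranking reflects network proximity under the chosen evidence
  weights, not causal efficacy; opioid agonists and other
  abuse-liability candidates are not filtered by the package — that is a
  downstream, user-supplied filter by design.
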