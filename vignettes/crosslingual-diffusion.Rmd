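---
title: "Cross-lingual retweet influence and diffusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lingual retweet influence and diffusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retlang)
```

## The problem

When a piece of health misinformation circulates on a retweet network, it
does not stay inside one language community. This package implements an
analysis pipeline for a two-community setting (an English and a Japanese
collection stream) that asks four questions:

1. **Who is influential, month by month?** Influence is *unique-retweeter
   degree*: the number of distinct users who retweeted a given user within
   a calendar month. Raw retweet counts reward a handful of devoted
   amplifiers; distinct retweeters measure reach.
2. **How stable is the influencer set?** Month-over-month churn of the
   top-10 list is scored with Rank Biased Overlap (RBO).
3. **Who is for and who is against?** Stance labels (pro-use / anti-use of
   the treatment under discussion) are propagated from a small set of
   manually tagged influencers through the retweet graph.
4. **Which community finds shared content first?** For URLs retweeted by
   pro-use users of both communities, the lag between each community's
   first post is modelled with an asymmetric Laplace distribution.

Every stage takes and returns tibbles, so the pipeline composes with the
usual dplyr verbs; `run_pipeline()` wires all stages together and writes
CSV/JSON artifacts plus a manifest.

## Influence ranking

`build_degree_table()` counts, for each retweeted user, the number of
*distinct* retweeters, excluding self-retweets (being "retweeted by more
unique users" cannot include oneself). Duplicate retweets by the same user
count once. Self-retweets are retained in the event stream — they are
data — but contribute zero degree. Ties in `influence_ranking()` break
lexicographically by user identifier: the tie rule is arbitrary, but a
deterministic rule is required because the ranking feeds a rank-similarity
statistic where order matters.

## Rank Biased Overlap

For rankings $S$ and $T$, with $A_d$ the proportion of overlap between the
top-$d$ prefixes,

$$\mathrm{RBO}(S, T, p) = (1 - p)\sum_{d \ge 1} p^{d-1} A_d .$$

The geometric weights make disagreement near the top of the list expensive
and disagreement near the bottom cheap. Defaults are $p = 0.9$ and depth
10, the standard convention for top-10 lists (the top ten ranks then carry
about 86% of the total weight). Two variants are reported:

* **truncated** — the sum stops at the evaluation depth. Identical lists
  score $1 - p^{d}$ (0.651 at $p=0.9,\,d=10$), *not* 1; plots of truncated
  series must be read against that ceiling.
* **extrapolated** (default) — adds $p^{d} A_{d}$, the bounded extension
  under which identical lists score exactly 1.

Both are exposed so the choice is transparent; the churn *trend* is the
same under either.

## Stance propagation

Seeds are users with hand-assigned stances (hop 0). At hop $h$, every
still-unlabelled user who retweeted at least one determinately labelled
user is assigned the stance of the strict majority of those retweet events,
counted **with multiplicity** ("retweeted more times" is a statement about
events, not about distinct neighbours). An exact tie yields
`undetermined`. Three further rules close the semantics, each the
conservative reading of an otherwise open choice:

* labels are frozen once assigned — the rule is a one-pass frontier
  expansion, which makes the outcome independent of evaluation order
  within a hop;
* `undetermined` users do not transmit labels onward;
* propagation runs on the full-period graph, because the coverage numbers
  it feeds are population-wide, and stops at a per-language hop limit
  (reference configuration: 6 hops for English, 5 for Japanese).

`coverage_stats()` reports the share of the population with a determinate
label; on the reference population counts (280,713 pro + 206,428 anti of
698,484 English users; 118,474 + 95,685 of 259,151 Japanese users) it
prints 69.7% and 82.6%. The share of pro-use users *among labelled users*
is also reported but deliberately never asserted against a reference
value, because that figure's denominator is ambiguous in the source
material.

## Cross-lingual URL diffusion

URLs are canonicalised before any matching (`normalize_url()`): lowercased
scheme and host, fragments removed, `utm_*`/`fbclid`/`gclid` tracking
parameters stripped (identical articles circulate under varying tracking
decorations and must collide), other query parameters kept in order,
trailing slash removed, non-ASCII characters percent-encoded. The
operation is idempotent, which the test suite fuzzes.

URL content language is resolved by precedence: an explicit override
table, then a pluggable detector (a langdetect-style plug-in applied to
page content would slot in here), then a deterministic string heuristic —
any Hiragana/Katakana/CJK codepoint or a `.jp` host means Japanese,
otherwise English. The heuristic is deliberately simple and documented
rather than clever and opaque; real deployments should supply a detector
or overrides for high-volume URLs.

For each URL shared by pro-use users of both communities,
`timing_observations()` sets day 0 at the first post in the URL's own
language community and records two integer day differences: the other
community's first post, and the earliest day on which the other
community's daily retweet series attains its maximum (peak-day ties break
to the earliest day — the conservative choice given that peaks cluster
shortly after first posts). Negative values mean the non-native community
led. Days are UTC calendar days throughout; month boundaries are UTC too,
the only reproducible convention for API-collected timestamps. YouTube
URLs can be excluded by flag: YouTube localises its interface by viewer
location, so string-based language tagging is unreliable for them. The
pipeline writes the timing table both with and without YouTube URLs.

## The asymmetric Laplace model

Day-difference distributions are peaked at small lags with roughly
exponential tails on both sides, and the two tails differ — lead and lag
are not symmetric. The package therefore fits

$$f(x) = \frac{\lambda}{\kappa + 1/\kappa}
  \begin{cases} e^{-\lambda\kappa (x - m)} & x \ge m \\
                e^{-(\lambda/\kappa)(m - x)} & x < m \end{cases}$$

with location $m$ (days), rate $\lambda$ (1/days) and asymmetry $\kappa$;
$\kappa = 1$ recovers the symmetric Laplace, and the mass below the
location is $\kappa^2/(1+\kappa^2)$. This parameterisation was chosen for
its closed-form CDF (`pald()`), which makes the model-implied lead mass
$F(0)$ a one-liner; other parameterisations in the literature are simple
reparameterisations of this one.

Fitting (`fit_asymmetric_laplace()`) is exact maximum likelihood: the
likelihood is piecewise in $m$ and attains its maximum at a sample point,
so $m$ is profiled over the unique sample values; given $m$, with
$A = \sum (x_i - m)^+$ and $B = \sum (m - x_i)^+$, the conditional optima
are $\hat\kappa = (B/A)^{1/4}$ and
$\hat\lambda = n/(\hat\kappa A + B/\hat\kappa)$. Ties in log-likelihood
break toward the smallest candidate location, so the fit is fully
deterministic. Candidates at the sample extremes (where $A$ or $B$
vanishes) are excluded — the scale degenerates there — and an all-equal
sample is rejected outright. A `symmetric = TRUE` constraint ($\kappa$
fixed at 1) exists for likelihood comparisons; the unconstrained fit can
never score below it, which the tests assert. The tests also cross-check
the profile fit against an independent numerical optimiser.

## The synthetic corpus generator

`generate_corpus()` produces a bilingual corpus with recoverable ground
truth, so that every downstream stage has a known target. What it
emulates, and the defaults (all overridable in `synth_config()`):

* **Two unequal communities** — 2,000 English and 1,000 Japanese users
  (a 2:1 ratio scaled down from the study system's roughly 700k : 260k),
  over 6 months at a mean of 5 baseline retweets per user per month.
  These sizes keep a full test-suite run in minutes while leaving several
  thousand users per propagation experiment.
* **Heavy-tailed influence** — each user draws a Pareto($\alpha = 1.5$)
  attractiveness weight; retweet sources are drawn proportionally, so a
  few users dominate the degree rankings and influence decays steeply
  down the ranked list.
* **Stance homophily** — 60% of users are pro-use; with probability 0.9 a
  baseline retweet targets a same-stance source, otherwise any source.
  Homophily is what makes majority-retweet propagation recover the truth;
  0.9 models communities that occasionally retweet across stance lines.
* **A shared URL pool** — 500 URLs, 70% English (English content
  dominates the cross-lingual pool in this domain), 5% on YouTube hosts.
  Each URL has a native first-post day; with probability 0.3 the other
  community adopts it. Daily retweet counts decay geometrically (ratio
  0.6) after each community's first post, so the peak day is well defined
  and falls at the first-post day.
* **Cross-lingual offsets** — adoption-day offsets are asymmetric Laplace
  draws ($m = 0$, $\lambda = 0.5$/day, $\kappa = 1.5$ by default, putting
  ~69% of the mass on the lead side) rounded **away from zero** into
  whole days. Rounding away from zero preserves the sign of every draw,
  so the generated lead fraction equals the closed-form CDF mass below
  zero exactly in distribution — nearest-integer rounding would silently
  move mass from small leads and lags onto zero.

Seeds for stance propagation are the `n_seed_influencers_per_month` most
attractive users of each stance and community, replicated per month —
emulating monthly manual tagging of the top influencer list while staying
independent of the package's own degree computation.

What the generator does **not** emulate: real text (placeholder tokens
only — keyword counts are exercised structurally, not linguistically),
user arrival and churn, account suspension, retweet cascades with depth
(all retweets of a URL in a community target one poster), bursty
exogenous news events, or language detection errors. Passing tests on
synthetic corpora therefore validate the *computations*, not the
substantive conclusions one would draw from real collections.

## Numerical and degenerate-input choices

* Native-language assignment for users seen in both streams: majority of
  their event appearances (in either role), ties to the earliest
  appearance, a timestamp tie to English — deterministic, and documented
  as a package choice since dual-stream membership has no canonical
  rule.
* `smooth_series()` wraps a cubic smoothing spline
  (`stats::smooth.spline`, `lambda` = the smoothing argument);
  `smoothing = 0` and constant inputs return the input verbatim, and
  fewer than 4 points return the input with a warning.
* Rankings shorter than the requested `k` are returned whole and flagged
  (`short` attribute / column) rather than padded.
* Invalid URLs (no parseable host) are flagged and excluded from URL
  analyses, never fatal; malformed *event records*, by contrast, are
  hard errors with line numbers, because silently dropping events would
  bias every downstream count.
* All randomness in a pipeline run flows from one integer seed; reruns
  with the same configuration and seed are byte-identical, which the
  tests verify by file hash.

## Problem sizes

The bundled experiments run at deliberately moderate scale — corpora of a
few thousand users and a few hundred thousand events at most, 20,000-draw
parameter-recovery samples, exhaustive small-graph oracles up to 12 users
and list-pair enumerations up to length 5 over 6 symbols. These sizes are
the package's chosen trade-off between statistical resolution (sampling
error on a 30% mass at n ≈ 1,500 is about 1.2 points) and a test suite
that runs in minutes on one core.

## Known limitations

* The degree measure is per-month unique-retweeter in-degree; no other
  centrality, and no cumulative cross-month network, is computed.
* RBO here is the plain prefix-overlap form for duplicate-free lists; no
  weighted or tied-rank extensions.
* The stance rule is binary-majority with freezing; it cannot revise an
  early wrong label, which is the point (order independence) but also a
  limitation on graphs where later evidence contradicts hop-1 evidence.
* The URL language heuristic is script- and TLD-based; Japanese content
  on `.com` hosts with ASCII-only URLs will be tagged English unless a
  detector or override says otherwise.
* One ALD is fitted per observation series; no mixture across directions
  or first-vs-peak series is attempted.
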