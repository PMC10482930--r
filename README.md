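# retlang

Cross-lingual retweet influence and diffusion analysis for two-community
(English/Japanese) social-media collections, built for infodemiology: the
study of how health (mis)information spreads online. Given a stream of
retweet events — who retweeted whom, when, in which language stream, with
which URLs — the package answers:

* **Who is influential?** Monthly rankings by *unique-retweeter degree*
  (the number of distinct users who retweeted a given user that month).
* **How stable is the influencer set?** Month-over-month churn scored
  with Rank Biased Overlap,
  `RBO(S, T, p) = (1 − p) Σ_d p^(d−1) · A_d`,
  where `A_d` is the top-`d` prefix overlap of the two rankings —
  disagreement at the top of the list is penalised hardest.
* **Who is pro and who is anti?** Stance labels propagated from tagged
  seed influencers through the retweet graph by a majority-retweet rule
  (a user who retweeted pro-use users more times than anti-use users is
  pro-use, and vice versa; ties are undetermined), to a per-language hop
  limit, with population-coverage statistics.
* **Which community finds shared content first?** For every URL
  retweeted by pro-use users of both communities, first-post and
  peak-diffusion day differences (negative = the non-native community
  led), fitted with an asymmetric Laplace distribution
  `f(x) ∝ exp(−λκ(x−m))` for `x ≥ m`, `∝ exp(−(λ/κ)(m−x))` for `x < m`,
  whose closed-form CDF gives the model-implied lead mass `F(0)`.

A synthetic bilingual corpus generator with known ground truth (true
stances, true URL languages, true cross-lingual timing offsets) ships as a
first-class module, so the whole pipeline is testable end to end without
any platform data. Everything is tibble-in/tibble-out and pipe-friendly;
fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(retlang)

corpus <- generate_corpus(synth_config(n_users_en = 400, n_users_ja = 200,
                                       n_months = 4, n_urls = 300,
                                       rng_seed = 42))

# monthly influencer churn in the English stream
rankings <- monthly_rankings(corpus$events, k = 10, by_stream = TRUE)
monthly_rbo_series(dplyr::filter(rankings, stream_language == "en"),
                   p = 0.9, k = 10)
#> # A tibble: 5 × 6
#>   month   score short     p depth variant
#>   <chr>   <dbl> <lgl> <dbl> <int> <chr>
#> 1 2020-02 0.220 FALSE   0.9    10 extrapolated
#> 2 2020-03 0.755 FALSE   0.9    10 extrapolated
#> 3 2020-04 0.747 FALSE   0.9    10 extrapolated
#> 4 2020-05 0.695 FALSE   0.9    10 extrapolated
#> 5 2020-06 0.134 FALSE   0.9    10 extrapolated
```

Scores near 0.7 in the core months say the top-10 influencer set largely
persists month to month (1 = identical top-10, 0 = complete turnover).
The first and last rows compare against sparse boundary months — the
corpus runs February–May, and only adoption spillover lands in January
and June — so their low scores reflect thin rankings, not real churn.

```r
# stance propagation from the generator's seed influencers (English)
gt <- corpus$ground_truth
seeds <- dplyr::distinct(gt$seeds[gt$seeds$community == "en",
                                  c("user", "stance")])
labels <- propagate_stance(
  dplyr::filter(corpus$events, stream_language == "en"),
  seeds, max_hops = 6)
coverage_from_labels(labels, sum(gt$users$community == "en"))
#> # A tibble: 1 × 7
#>   total_users n_pro n_anti coverage_pct pro_share_pct ...
#> 1         400   246    154          100          61.5
```

All 400 users get a determinate label here (a small, densely homophilous
corpus); at realistic sparsity coverage drops below 100%.

```r
# cross-lingual diffusion timing, YouTube URLs excluded
langmap <- tibble::tibble(user = gt$users$user,
                          native_language = gt$users$community)
stances <- tibble::tibble(user = gt$users$user, stance = gt$users$stance)
records <- build_url_records(corpus$events, stances, langmap)
obs <- timing_observations(records, youtube_excluded = TRUE)
fit <- fit_asymmetric_laplace(obs$day_diff_first)
fit
#> Asymmetric Laplace fit (87 observations)
#>   location m       -2.0000
#>   scale lambda      0.4094
#>   asymmetry kappa   0.9608
#>   log-likelihood   -225.06
negative_mass(obs$day_diff_first, fit)
#> # A tibble: 1 × 3
#>       n empirical model
#> 1    87     0.690 0.763
```

69% of the shared URLs were posted in the non-native community *before*
their native one (`day_diff_first < 0`), and the fitted asymmetric
Laplace puts comparable mass below zero — the generator's default offset
law leads by design, and the pipeline recovers it.

`run_pipeline(config, out_dir)` runs every stage (rankings, keywords,
RBO, stance, cross-lingual timing) and writes CSV/JSON artifacts plus a
manifest; reruns with the same config and seed are byte-identical. A
shell wrapper lives at `inst/scripts/run_pipeline.R`.

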