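# Shared fixture builders: every fixture is generated in code, seeded.

# Constant-weather season: tmean/srad vectors recycled over n days.
toy_weather <- function(n = 61, tmean = 20, srad = 15, start = "2000-05-01",
                        site = "s1") {
  dates <- seq(as.Date(start), by = 1, length.out = n)
  weather_series(site, dates, rep_len(tmean, n), rep_len(srad, n))
}

toy_phenology <- function(start = "2000-05-01", head_day = 31, mat_day = 61) {
  d <- as.Date(start)
  phenology_record(d, d + head_day - 1, d + mat_day - 1)
}

# Independent OLS oracle via the explicit normal-equation sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       rmse = sqrt(mean(res^2)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       se_slope = sqrt(sum(res^2) / (n - 2) / sxx))
}

# Small pedigree-structured genotype panel reused by BLUP/GWAS tests.
family_panel <- function(n_founders = 40, n_per_gen = 80, generations = 2,
                         m_snps = 1000, h2_alpha = 0.33, h2_beta = 0.74,
                         seed = 11, ...) {
  gen_genotypes_pedigree(n_founders = n_founders, n_per_gen = n_per_gen,
                         generations = generations, m_snps = m_snps,
                         n_causal = min(80, m_snps %/% 4),
                         h2_alpha = h2_alpha,
                         h2_beta = h2_beta, seed = seed, ...)
}
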