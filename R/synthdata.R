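#' Generate synthetic daily weather series
#'
#' Produces a contiguous daily temperature/radiation series per site over a
#' span of calendar years: an annual sinusoid (temperature peaking in early
#' August, radiation in late June, the mid-latitude monsoon pattern the crop
#' model is used in) plus Gaussian day-to-day noise and a per-site mean
#' offset. An optional cold snap overwrites a block of summer days with a
#' fixed cool temperature to exercise the sterility path, which ordinary
#' synthetic summers rarely trigger.
#'
#' @param n_sites number of sites (ids `S1`, `S2`, ...).
#' @param years integer vector of calendar years to cover (full years).
#' @param seed integer seed; identical seeds give identical tables.
#' @param t_mean annual mean temperature, deg C.
#' @param t_amp annual temperature amplitude, deg C.
#' @param srad_mean annual mean solar radiation, MJ m-2 d-1.
#' @param srad_amp annual radiation amplitude.
#' @param t_sd,srad_sd day-to-day noise SDs.
#' @param site_t_sd SD of the per-site temperature offset.
#' @param cold_snap optional list with elements `site` (id), `year`,
#'   `start_doy`, `length`, `tmean`: those days get `tmean` exactly.
#' @return A row-bound [weather_series()] data frame for all sites.
#' @export
gen_weather <- function(n_sites = 1, years = 2000, seed = 1,
                        t_mean = 15, t_amp = 11,
                        srad_mean = 13, srad_amp = 7,
                        t_sd = 1.5, srad_sd = 3, site_t_sd = 1.0,
                        cold_snap = NULL) {
  if (n_sites < 1 || !length(years)) stop("need >= 1 site and >= 1 year")
  set.seed(seed)
  years <- sort(unique(as.integer(years)))
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = 1)
  doy <- as.integer(format(dates, "%j"))
  nd <- length(dates)
  out <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    off <- stats::rnorm(1, 0, site_t_sd)
    tmean <- t_mean + off + t_amp * sin(2 * pi * (doy - 127) / 365.25) +
      stats::rnorm(nd, 0, t_sd)
    srad <- pmax(0, srad_mean + srad_amp * sin(2 * pi * (doy - 81) / 365.25) +
                   stats::rnorm(nd, 0, srad_sd))
    out[[s]] <- weather_series(paste0("S", s), dates, tmean, srad)
  }
  w <- do.call(rbind, out)
  if (!is.null(cold_snap)) {
    yrs <- as.integer(format(w$date, "%Y"))
    dys <- as.integer(format(w$date, "%j"))
    sel <- w$site_id == cold_snap$site & yrs == cold_snap$year &
      dys >= cold_snap$start_doy &
      dys < cold_snap$start_doy + cold_snap$length
    w$tmean_c[sel] <- cold_snap$tmean
  }
  w
}

#' Generate per-cultivar genotypic truth
#'
#' Draws true plasticity/ability pairs within the ranges a temperate
#' japonica panel spans (plasticity roughly -0.2 to 0.95, ability 2.5 to
#' 7.3 t/ha), with optional linear genetic gain of ability over the release
#' years.
#'
#' @param n_cultivars number of cultivars.
#' @param seed integer seed.
#' @param beta_gain ability gain per year (t/ha/yr; 0.0102 matches a panel
#'   with a 10.2 kg/ha/yr trend), applied around the mean release year.
#' @param release_years range to draw release years from.
#' @return Data frame `cultivar_id`, `alpha`, `beta`, `release_year`.
#' @export
gen_truth <- function(n_cultivars = 50, seed = 1, beta_gain = 0,
                      release_years = c(1926, 2010)) {
  set.seed(seed)
  ry <- sample(release_years[1]:release_years[2], n_cultivars, replace = TRUE)
  alpha <- pmin(0.95, pmax(-0.23, stats::rnorm(n_cultivars, 0.35, 0.2)))
  beta <- pmin(7.3, pmax(2.5, stats::rnorm(n_cultivars, 5.5, 0.8) +
                           beta_gain * (ry - mean(ry))))
  data.frame(cultivar_id = sprintf("C%03d", seq_len(n_cultivars)),
             alpha = alpha, beta = beta, release_year = ry,
             stringsAsFactors = FALSE)
}

#' Generate synthetic yield-trial records
#'
#' Inverts the coefficient model: each trial's yield is
#' `alpha_i * (yp - spy) + beta_i + eps` with `eps ~ N(0, sd_resid)`. The
#' default residual SD of 0.84 t/ha is the typical per-cultivar regression
#' RMSE in large multi-environment rice panels. Potential yields are drawn
#' uniformly over the range such panels experience (0.1 to 9.8 t/ha, mean
#' ~5), or from a truncated normal when `yp_dist = "normal"`.
#'
#' @param truth a [gen_truth()] data frame (columns `cultivar_id`, `alpha`,
#'   `beta`).
#' @param env_count environments per cultivar.
#' @param seed integer seed.
#' @param sd_resid residual SD, t/ha.
#' @param spy standardized potential yield, t/ha.
#' @param yp_dist `"uniform"` over `yp_range`, or `"normal"` (truncated).
#' @param yp_mean,yp_sd truncated-normal parameters when
#'   `yp_dist = "normal"`.
#' @param yp_range potential-yield range, t/ha.
#' @param years calendar years environments are sampled from.
#' @param contamination_rate fraction of records replaced by gross outliers
#'   (yield shifted by `contamination_shift`), for exercising the cleaning
#'   rules; contaminated rows are flagged in `is_contaminated`.
#' @param contamination_shift outlier shift, t/ha.
#' @return Trial data frame: `cultivar_id`, `site_id`, `year`, `yp_t_ha`,
#'   `yield_t_ha`, `is_contaminated`.
#' @export
gen_trials <- function(truth, env_count = 300, seed = 1, sd_resid = 0.84,
                       spy = 8, yp_dist = c("uniform", "normal"),
                       yp_mean = 5, yp_sd = 1.8,
                       yp_range = c(0.1, 9.8), years = 1980:2017,
                       contamination_rate = 0, contamination_shift = 20) {
  if (env_count < 3) stop("env_count must be >= 3")
  yp_dist <- match.arg(yp_dist)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    yp <- if (yp_dist == "uniform")
      stats::runif(env_count, yp_range[1], yp_range[2])
    else pmin(yp_range[2], pmax(yp_range[1],
                                stats::rnorm(env_count, yp_mean, yp_sd)))
    yield <- truth$alpha[i] * (yp - spy) + truth$beta[i] +
      stats::rnorm(env_count, 0, sd_resid)
    contam <- stats::runif(env_count) < contamination_rate
    yield[contam] <- yield[contam] + contamination_shift
    data.frame(cultivar_id = truth$cultivar_id[i],
               site_id = sprintf("S%d", sample.int(20, env_count, TRUE)),
               year = sample(years, env_count, TRUE),
               yp_t_ha = yp, yield_t_ha = yield,
               is_contaminated = contam, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate genotypes and a pedigree by gene dropping
#'
#' Simulates founder SNP alleles at frequencies drawn from `maf_range`,
#' then drops genes through `generations` rounds of random mating (each
#' offspring samples two distinct parents from the previous generation and
#' inherits one allele per SNP from each, SNPs unlinked). Additive effects at
#' `n_causal` SNPs per trait produce true plasticity/ability genetic values;
#' effects are rescaled so the realized genetic variance fractions equal
#' `h2_alpha`/`h2_beta`, with a genetic correlation `rho_g` induced by
#' drawing the two traits' effects at shared causal SNPs from a correlated
#' normal.
#'
#' @param n_founders founder cultivars (generation 0).
#' @param n_per_gen offspring per subsequent generation.
#' @param generations number of offspring generations (>= 0).
#' @param m_snps number of SNPs.
#' @param maf_range founder allele-frequency range (minor allele).
#' @param n_causal causal SNPs per trait.
#' @param h2_alpha,h2_beta heritabilities of the two coefficients (in
#'   \[0, 1)).
#' @param rho_g genetic correlation of the two traits' causal effects.
#' @param mu_alpha,mu_beta trait means.
#' @param sd_alpha,sd_beta total phenotypic SDs (unit by default, the
#'   convenient scale for variance-component work; pass e.g. 0.25 and 1.0
#'   to put the coefficients on the scale trial panels show).
#' @param seed integer seed.
#' @return List: `genotypes` (dosage matrix, all individuals), `pedigree`
#'   (`id`, `parent1`, `parent2`), `truth` (data frame of true genetic
#'   values and phenotypes per individual; causal indices and effects in
#'   attributes `causal` and `effects`).
#' @export
gen_genotypes_pedigree <- function(n_founders = 40, n_per_gen = 80,
                                   generations = 3, m_snps = 1000,
                                   maf_range = c(0.05, 0.5), n_causal = 50,
                                   h2_alpha = 0.33, h2_beta = 0.74,
                                   rho_g = 0.3, mu_alpha = 0.35,
                                   mu_beta = 5.5, sd_alpha = 1, sd_beta = 1,
                                   seed = 1) {
  if (n_causal > m_snps) stop("n_causal must not exceed m_snps")
  if (h2_alpha >= 1 || h2_beta >= 1 || h2_alpha < 0 || h2_beta < 0)
    stop("heritabilities must lie in [0, 1)")
  set.seed(seed)
  p <- stats::runif(m_snps, maf_range[1], maf_range[2])
  flip <- stats::runif(m_snps) < 0.5
  p <- ifelse(flip, 1 - p, p)          # reference allele may be major or minor
  hap <- function(n) matrix(stats::rbinom(n * m_snps, 1, rep(p, each = n)),
                            n, m_snps)
  H1 <- hap(n_founders); H2 <- hap(n_founders)
  ids <- sprintf("G0_%03d", seq_len(n_founders))
  ped <- data.frame(id = ids, parent1 = NA_character_,
                    parent2 = NA_character_, stringsAsFactors = FALSE)
  prev <- seq_len(n_founders)
  for (g in seq_len(generations)) {
    nh1 <- matrix(0L, n_per_gen, m_snps); nh2 <- matrix(0L, n_per_gen, m_snps)
    p1 <- integer(n_per_gen); p2 <- integer(n_per_gen)
    for (i in seq_len(n_per_gen)) {
      pa <- sample(prev, 2)
      p1[i] <- pa[1]; p2[i] <- pa[2]
      pick1 <- stats::runif(m_snps) < 0.5
      pick2 <- stats::runif(m_snps) < 0.5
      nh1[i, ] <- ifelse(pick1, H1[pa[1], ], H2[pa[1], ])
      nh2[i, ] <- ifelse(pick2, H1[pa[2], ], H2[pa[2], ])
    }
    new_ids <- sprintf("G%d_%03d", g, seq_len(n_per_gen))
    ped <- rbind(ped, data.frame(id = new_ids, parent1 = ped$id[p1],
                                 parent2 = ped$id[p2],
                                 stringsAsFactors = FALSE))
    prev <- nrow(ped) - n_per_gen + seq_len(n_per_gen)
    H1 <- rbind(H1, nh1); H2 <- rbind(H2, nh2)
  }
  X <- H1 + H2
  rownames(X) <- ped$id
  colnames(X) <- sprintf("snp%05d", seq_len(m_snps))
  n <- nrow(X)
  causal <- sort(sample.int(m_snps, n_causal))
  z <- matrix(stats::rnorm(2 * n_causal), n_causal, 2)
  Lr <- chol(matrix(c(1, rho_g, rho_g, 1), 2))
  eff <- z %*% Lr                      # correlated raw effects
  scale_trait <- function(raw_g, h2, mu, sd_tot) {
    vg <- stats::var(raw_g)
    if (h2 == 0 || vg == 0) {
      g <- raw_g * 0
      return(list(g = g, y = mu + stats::rnorm(n, 0, sd_tot)))
    }
    g <- raw_g / sqrt(vg) * sd_tot * sqrt(h2)   # genetic variance h2 * sd^2
    ve <- sd_tot^2 * (1 - h2)
    list(g = g, y = mu + g + stats::rnorm(n, 0, sqrt(ve)))
  }
  ga <- scale_trait(as.vector(X[, causal] %*% eff[, 1]), h2_alpha, mu_alpha,
                    sd_alpha)
  gb <- scale_trait(as.vector(X[, causal] %*% eff[, 2]), h2_beta, mu_beta,
                    sd_beta)
  truth <- data.frame(id = ped$id, g_alpha = ga$g, g_beta = gb$g,
                      alpha = ga$y, beta = gb$y, stringsAsFactors = FALSE)
  attr(truth, "causal") <- causal
  attr(truth, "effects") <- eff
  list(genotypes = X, pedigree = ped, truth = truth)
}
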