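#' Read and write the package's CSV formats
#'
#' Weather CSV: `site_id,date,tmean_c,srad_mj_m2` (one row per day).
#' Trial CSV: `cultivar_id,site_id,year,transplanting_date,heading_date,
#' maturity_date,yield_t_ha` plus optional `panicle_number_m2`,
#' `panicle_length_cm`, `yp_t_ha`. Coefficient CSV:
#' `cultivar_id,n_trials,alpha,beta,b,rmse,r2_fit,r2_pred`.
#' Pedigree CSV: `id,parent1,parent2` (empty = unknown). All readers
#' validate the header and basic value constraints and name the offending
#' file and line on failure.
#'
#' @param path file path.
#' @return The validated data frame (weather additionally gains the
#'   `weather_series` class).
#' @name ypcgm_io
NULL

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

#' @rdname ypcgm_io
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("site_id", "date", "tmean_c", "srad_mj_m2"), path)
  out <- lapply(split(df, df$site_id), function(d)
    weather_series(d$site_id[1], d$date, d$tmean_c, d$srad_mj_m2))
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  w
}

#' @param weather,trials,coeffs,ped the table to write.
#' @rdname ypcgm_io
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(as.data.frame(weather), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname ypcgm_io
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("cultivar_id", "site_id", "year", "yield_t_ha"), path)
  bad <- which(!is.finite(df$yield_t_ha) | df$yield_t_ha < 0)
  if (length(bad))
    stop(sprintf("%s: line %d: yield_t_ha must be finite and >= 0 (got %s)",
                 path, bad[1] + 1L, df$yield_t_ha[bad[1]]))
  df
}

#' @rdname ypcgm_io
#' @export
write_trials_csv <- function(trials, path) {
  # the on-disk format promises yield_t_ha finite and >= 0 (readers enforce
  # it); rows violating the invariant - e.g. negative draws from the linear
  # generative model - are dropped with a warning
  bad <- !is.finite(trials$yield_t_ha) | trials$yield_t_ha < 0
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with negative or non-finite yield", sum(bad)))
    trials <- trials[!bad, , drop = FALSE]
  }
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ypcgm_io
#' @export
write_coefficients_csv <- function(coeffs, path) {
  utils::write.csv(as.data.frame(coeffs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname ypcgm_io
#' @export
read_coefficients_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("cultivar_id", "alpha", "beta"), path)
  class(df) <- c("cultivar_coefficients", "data.frame")
  df
}

#' @rdname ypcgm_io
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  require_cols(df, c("id", "parent1", "parent2"), path)
  df
}

#' Read a genotype dosage table
#'
#' TSV layout: first column `cultivar_id`, remaining columns one SNP each,
#' entries 0/1/2 or `NA`.
#'
#' @param path file path.
#' @return Dosage matrix with cultivar rownames.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "cultivar_id")
    stop(path, ": first column must be 'cultivar_id'")
  gm <- as.matrix(df[, -1, drop = FALSE])
  rownames(gm) <- df$cultivar_id
  storage.mode(gm) <- "double"
  check_dosages(gm)
  gm
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Uses the GT field of a VCF (via the vcfR package) and converts each
#' biallelic SNP record to an alternate-allele dosage (0 reference
#' homozygous, 1 heterozygous, 2 alternate homozygous, NA missing).
#' Multi-allelic records are dropped with a message.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return List: `genotypes` (samples x SNPs dosage matrix), `map`
#'   (`snp_id`, `chrom`, `pos`).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  bi <- !grepl(",", fix[, "ALT"])
  if (any(!bi)) message(sum(!bi), " multi-allelic record(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")[bi, , drop = FALSE]
  dose <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(g %in% c("0/0"), 0,
           ifelse(g %in% c("0/1", "1/0"), 1,
                  ifelse(g %in% c("1/1"), 2, NA_real_)))
  }
  gm <- t(apply(gt, 2, dose))
  if (is.null(dim(gm))) gm <- matrix(gm, ncol = 1)
  rownames(gm) <- colnames(gt)
  snp_id <- fix[bi, "ID"]
  noid <- is.na(snp_id) | snp_id == "."
  snp_id[noid] <- paste0(fix[bi, "CHROM"], "_", fix[bi, "POS"])[noid]
  colnames(gm) <- snp_id
  list(genotypes = gm,
       map = data.frame(snp_id = snp_id, chrom = fix[bi, "CHROM"],
                        pos = as.integer(fix[bi, "POS"]),
                        stringsAsFactors = FALSE))
}

#' Default run configuration
#'
#' The resolved defaults of every tunable the pipeline exposes, as a nested
#' list mirroring the YAML config file sections (`cgm`, `spy`, `scenarios`,
#' `quantgen`, `synth`, `io`, `seed`). `write_config()` emits it as YAML for
#' editing; `read_config()` loads and validates one, rejecting unknown keys.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    cgm = unclass(cgm_params()),
    spy = unclass(spy_config()),
    scenarios = list(alphas = seq(0, 0.6, length.out = 6), beta_fixed = 8),
    quantgen = list(model = "gBLUP", n_iter = 20000, burn_in = 5000,
                    k = 10, reps = 10, n_pcs = 4, maf_min = 0.05),
    synth = list(n_cultivars = 50, env_count = 100, sd_resid = 0.84,
                 n_founders = 40, n_per_gen = 80, generations = 2,
                 m_snps = 1000, n_causal = 50,
                 h2_alpha = 0.33, h2_beta = 0.74),
    io = list(weather = NULL, trials = NULL, genotypes = NULL,
              pedigree = NULL, out_dir = "ypcgm-out"))
}

#' @param config a configuration list.
#' @param path YAML file path.
#' @rdname default_config
#' @export
write_config <- function(config = default_config(), path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop(path, ": unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    if (is.list(defaults[[sec]]) && is.list(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
      if (length(bad))
        stop(path, ": unknown key(s) in [", sec, "]: ",
             paste(bad, collapse = ", "))
      defaults[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else defaults[[sec]] <- cfg[[sec]]
  }
  defaults
}
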