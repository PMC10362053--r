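#' Genome-wide Bonferroni significance threshold
#'
#' The family-wise threshold on the -log10(p) scale for m tests at
#' family-wise level q: `log10(m / q)`. For the conventional q = 0.05 and
#' m = 91,800 SNPs this evaluates to 6.264 (note that a printed threshold of
#' 6.191 corresponds to m = 77,625 tests at the same q).
#'
#' @param m number of SNPs tested.
#' @param q family-wise error level.
#' @return The threshold on the -log10(p) scale.
#' @examples
#' bonferroni_threshold(91800)  # 6.264
#' @export
bonferroni_threshold <- function(m, q = 0.05) {
  if (any(m < 1)) stop("m must be >= 1")
  log10(m / q)
}

#' Principal components of the standardized genotype matrix
#'
#' Computes sample scores on the leading principal components of the
#' column-standardized dosage matrix (the same X that defines G = XX'/m),
#' for use as fixed population-structure covariates in the mixed-model GWAS.
#'
#' @param gm dosage matrix (cultivars x SNPs).
#' @param n_pcs number of components.
#' @return n x n_pcs score matrix.
#' @export
genotype_pcs <- function(gm, n_pcs = 4) {
  G <- genomic_relationship(gm)
  eg <- eigen(unclass(G), symmetric = TRUE)
  npc <- min(n_pcs, sum(eg$values > 1e-8))
  scores <- eg$vectors[, seq_len(npc), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(npc)]), npc)
  rownames(scores) <- rownames(gm)
  colnames(scores) <- paste0("PC", seq_len(npc))
  scores
}

#' Mixed-linear-model GWAS
#'
#' Per-SNP association scan of one genotypic coefficient under the mixed
#' model `y = W b + x s + g + e`, with fixed covariates W (intercept plus
#' leading genotype principal components), a random polygenic term
#' `g ~ N(0, K sigma2_g)` on the kinship matrix K, and
#' `e ~ N(0, I sigma2_e)`. Variance components are estimated once by REML on
#' the null model (no SNP) via the eigendecomposition of K, then reused for
#' every SNP (the usual P3D/EMMAX approximation); each SNP is tested with a
#' Wald t-test under generalized least squares at those variances. Setting
#' `exact_reml = TRUE` re-estimates the variance components for every SNP
#' (slow, exact).
#'
#' @param y named numeric vector, one coefficient value per cultivar.
#' @param gm MAF-filtered dosage matrix aligned to `y` (rownames = ids).
#' @param K kinship matrix; defaults to [genomic_relationship()] of `gm`.
#' @param n_pcs number of principal-component covariates.
#' @param q family-wise level for the Bonferroni threshold.
#' @param map optional data frame `snp_id`, `chrom`, `pos` merged into the
#'   result.
#' @param exact_reml re-estimate variance components per SNP.
#' @return A data frame of class `gwas_result`: `snp_id`, `beta`, `se`, `p`,
#'   `neglog10p`, `maf` (plus `chrom`, `pos` when `map` is given), with
#'   attributes `threshold` (-log10 scale), `lambda` (genomic inflation
#'   factor), `h2_null`, `varcomp`.
#' @export
gwas_mlm <- function(y, gm, K = NULL, n_pcs = 4, q = 0.05, map = NULL,
                     exact_reml = FALSE) {
  gm <- as.matrix(gm)
  if (!is.null(names(y)) && !is.null(rownames(gm))) {
    common <- intersect(names(y), rownames(gm))
    if (!length(common)) stop("no shared ids between y and genotypes")
    y <- y[common]; gm <- gm[common, , drop = FALSE]
  }
  if (anyNA(y)) stop("y must be complete")
  n <- nrow(gm); m <- ncol(gm)
  if (length(y) != n) stop("length(y) must equal nrow(gm)")
  if (is.null(K)) K <- genomic_relationship(gm)
  K <- unclass(K)
  if (!is.null(rownames(K)) && !is.null(rownames(gm)))
    K <- K[rownames(gm), rownames(gm)]
  W <- cbind(`(Intercept)` = 1, genotype_pcs(gm, n_pcs))
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) stop("singular covariate matrix")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  S <- pmax(eg$values, 1e-10); U <- eg$vectors
  ys <- crossprod(U, y); Ws <- crossprod(U, W)
  vc <- reml_delta(ys, Ws, S)
  # transform to the whitened scale and residualize on covariates
  w <- 1 / sqrt(S + vc$delta)
  yt <- w * ys; Wt <- w * Ws
  Qw <- qr.Q(qr(Wt))
  yr <- yt - Qw %*% crossprod(Qw, yt)
  # SNP columns: rotate then whiten then residualize (column-wise)
  Xs <- w * crossprod(U, gm)
  Xr <- Xs - Qw %*% crossprod(Qw, Xs)
  xx <- colSums(Xr^2)
  xy <- as.vector(crossprod(Xr, yr))
  dfree <- n - ncol(W) - 1
  beta <- xy / xx
  rss <- sum(yr^2) - beta * xy
  rss[rss < 0] <- 0
  se <- sqrt(rss / dfree / xx)
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), dfree, lower.tail = FALSE)
  bad <- !is.finite(xx) | xx <= 1e-12
  beta[bad] <- NA; se[bad] <- NA; pval[bad] <- NA
  if (exact_reml) {
    for (j in which(!bad)) {
      vcj <- reml_delta(ys, cbind(Ws, Xs[, j] / w), S)
      wj <- 1 / sqrt(S + vcj$delta)
      Zj <- wj * cbind(Ws, Xs[, j] / w)
      yj <- wj * ys
      fit <- stats::lm.fit(Zj, yj)
      cf <- length(fit$coefficients)
      Rj <- chol2inv(qr.R(fit$qr))
      beta[j] <- fit$coefficients[cf]
      se[j] <- sqrt(sum(fit$residuals^2) / dfree * Rj[cf, cf])
      tj <- beta[j] / se[j]
      pval[j] <- 2 * stats::pt(abs(tj), dfree, lower.tail = FALSE)
    }
  }
  pfreq <- colMeans(gm, na.rm = TRUE) / 2
  res <- data.frame(snp_id = colnames(gm) %||% paste0("snp", seq_len(m)),
                    beta = beta, se = se, p = pval,
                    neglog10p = -log10(pval),
                    maf = pmin(pfreq, 1 - pfreq),
                    stringsAsFactors = FALSE)
  if (!is.null(map)) res <- merge(map, res, by = "snp_id", sort = FALSE)
  chi <- stats::qchisq(stats::median(res$p, na.rm = TRUE), df = 1,
                       lower.tail = FALSE)
  attr(res, "lambda") <- chi / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  attr(res, "threshold") <- bonferroni_threshold(sum(!bad), q)
  attr(res, "h2_null") <- 1 / (1 + vc$delta)
  attr(res, "varcomp") <- c(sigma2_g = vc$sg2, sigma2_e = vc$sg2 * vc$delta)
  class(res) <- c("gwas_result", "data.frame")
  res
}

# REML profile over delta = sigma2_e / sigma2_g for the rotated model
# ys = Ws b + eps, Var(eps) = sigma2_g * diag(S + delta).
reml_delta <- function(ys, Ws, S) {
  n <- length(ys); qn <- ncol(Ws)
  negll <- function(logd) {
    d <- S + exp(logd)
    Winv <- Ws / d
    WtW <- crossprod(Ws, Winv)
    b <- solve(WtW, crossprod(Winv, ys))
    r <- ys - Ws %*% b
    sg2 <- sum(r^2 / d) / (n - qn)
    0.5 * ((n - qn) * log(sg2) + sum(log(d)) +
             determinant(WtW, logarithm = TRUE)$modulus + (n - qn))
  }
  opt <- stats::optimize(negll, c(-12, 12))
  delta <- exp(opt$minimum)
  d <- S + delta
  Winv <- Ws / d
  b <- solve(crossprod(Ws, Winv), crossprod(Winv, ys))
  r <- ys - Ws %*% b
  sg2 <- sum(r^2 / d) / (n - qn)
  list(delta = delta, sg2 = sg2, b = b)
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of dosage columns over complete pairs of
#' observations, for a chosen set of SNPs.
#'
#' @param gm dosage matrix.
#' @param snp_ids column names (or indices) of the SNPs.
#' @return Symmetric r-squared matrix.
#' @export
ld_r2 <- function(gm, snp_ids = colnames(gm)) {
  X <- as.matrix(gm[, snp_ids, drop = FALSE])
  if (ncol(X) < 2) stop("need at least 2 SNPs")
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  mono <- !is.finite(v) | v == 0
  if (any(mono))
    stop("monomorphic SNP(s): ", paste(colnames(X)[mono], collapse = ", "))
  stats::cor(X, use = "pairwise.complete.obs")^2
}

#' Haplotype grouping and nonparametric comparison
#'
#' Classifies cultivars into haplotype groups by their homozygous dosage
#' vector at a chosen set of SNPs (cultivars with any heterozygous or
#' missing call at those SNPs are excluded), discards groups smaller than
#' `min_group`, and compares the coefficient values across the remaining
#' groups with a Kruskal-Wallis omnibus test followed by all-pairs
#' Steel-Dwass comparisons (pairwise midrank statistics referred to the
#' studentized-range null). Shapiro-Wilk normality and Levene (Brown-Forsythe,
#' median-centered) variance-homogeneity checks are reported as diagnostics.
#'
#' @param gm dosage matrix.
#' @param snp_ids the defining SNPs (column names or indices).
#' @param y named coefficient values per cultivar.
#' @param min_group smallest group size admitted to testing.
#' @return A list: `assignment` (data frame id, haplotype, y), `groups`
#'   (size table including excluded small groups), `kruskal`
#'   (`htest`), `pairwise` (data frame g1, g2, statistic, p), `diagnostics`.
#' @export
haplotype_compare <- function(gm, snp_ids, y, min_group = 4) {
  X <- as.matrix(gm[, snp_ids, drop = FALSE])
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    common <- intersect(names(y), rownames(X))
    y <- y[common]; X <- X[common, , drop = FALSE]
  }
  homo <- rowSums(is.na(X) | X == 1) == 0
  Xh <- X[homo, , drop = FALSE]; yh <- y[homo]
  hap <- apply(Xh, 1, paste, collapse = "")
  sizes <- sort(table(hap), decreasing = TRUE)
  lev <- paste0("Hap", seq_along(sizes))
  hapname <- stats::setNames(lev, names(sizes))
  assignment <- data.frame(id = rownames(Xh) %||% seq_along(hap),
                           haplotype = unname(hapname[hap]), y = unname(yh),
                           stringsAsFactors = FALSE)
  big <- names(sizes)[sizes >= min_group]
  keep <- hap %in% big
  if (length(unique(hap[keep])) < 2)
    stop("fewer than 2 haplotype groups of size >= ", min_group)
  g <- factor(unname(hapname[hap[keep]]))
  yk <- yh[keep]
  kw <- stats::kruskal.test(yk, g)
  pw <- steel_dwass(yk, g)
  diagnostics <- list(
    shapiro = lapply(split(yk, g), function(v)
      if (length(v) >= 3 && stats::sd(v) > 0) stats::shapiro.test(v)$p.value
      else NA_real_),
    levene_p = levene_median_p(yk, g))
  list(assignment = assignment,
       groups = data.frame(haplotype = unname(hapname[names(sizes)]),
                           pattern = names(sizes), n = as.integer(sizes),
                           tested = names(sizes) %in% big,
                           stringsAsFactors = FALSE),
       kruskal = kw, pairwise = pw, diagnostics = diagnostics)
}

# All-pairs Steel-Dwass comparisons: for each pair of groups, the two-sample
# midrank statistic (tie-corrected) is referred to the studentized-range
# distribution with k groups.
steel_dwass <- function(y, g) {
  g <- droplevels(factor(g))
  k <- nlevels(g)
  levs <- levels(g)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      yi <- y[g == levs[i]]; yj <- y[g == levs[j]]
      ni <- length(yi); nj <- length(yj); N <- ni + nj
      r <- rank(c(yi, yj))          # midranks
      Wi <- sum(r[seq_len(ni)])
      E <- ni * (N + 1) / 2
      V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
      tstat <- if (V > 0) (Wi - E) / sqrt(V) else 0
      p <- stats::ptukey(sqrt(2) * abs(tstat), nmeans = k, df = Inf,
                         lower.tail = FALSE)
      out[[length(out) + 1L]] <-
        data.frame(g1 = levs[i], g2 = levs[j], statistic = tstat, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Brown-Forsythe variant of Levene's test: one-way ANOVA of absolute
# deviations from the group medians.
levene_median_p <- function(y, g) {
  g <- droplevels(factor(g))
  med <- tapply(y, g, stats::median)
  z <- abs(y - med[g])
  if (stats::var(z) == 0) return(NA_real_)
  summary(stats::aov(z ~ g))[[1]][["Pr(>F)"]][1]
}
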