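#' Gibbs sampler configuration for the multi-trait BLUP models
#'
#' Defaults follow the usual practice for multi-trait animal-model fits:
#' 20,000 iterations with the first 5,000 discarded as burn-in, no thinning,
#' inverse-Wishart priors with identity scale and minimal degrees of freedom
#' (traits + 2). Reduce `n_iter`/`burn_in` for quick exploratory fits.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before averaging.
#' @param seed optional integer seed; identical seeds give identical fits.
#' @return An object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 20000, burn_in = 5000, seed = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = seed),
            class = "gibbs_config")
}

# Relationship structures for each model. All matrices are subset/reordered
# to `ids`.
blup_kernels <- function(model, G, A, ids) {
  model <- match.arg(model, c("gBLUP", "pBLUP", "gpBLUP", "gxpBLUP"))
  need_g <- model != "pBLUP"
  need_a <- model != "gBLUP"
  if (need_g && is.null(G)) stop(model, " requires the genomic matrix G")
  if (need_a && is.null(A)) stop(model, " requires the pedigree matrix A")
  sub <- function(K, what) {
    if (!is.null(rownames(K))) {
      if (!all(ids %in% rownames(K)))
        stop(what, " lacks ids: ",
             paste(utils::head(setdiff(ids, rownames(K)), 5), collapse = ", "))
      K <- K[ids, ids]
    } else if (!all(dim(K) == length(ids)))
      stop(what, " has no dimnames and the wrong size")
    unclass(K)
  }
  kl <- list()
  if (need_g) kl$g <- sub(G, "G")
  if (need_a) kl$p <- sub(A, "A")
  if (model == "gxpBLUP") kl$gxp <- kl$g * kl$p
  kl
}

# Symmetrize and, if needed, jitter a kernel so its Cholesky exists.
psd_prepare <- function(K, label) {
  K <- (K + t(K)) / 2
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    K <- K + diag(1e-8, nrow(K))
    ch <- tryCatch(chol(K), error = function(e)
      stop("relationship matrix '", label,
           "' is not positive semidefinite even after 1e-8 jitter"))
  }
  K
}

#' Multi-trait BLUP of the genotypic coefficients
#'
#' Fits the multi-trait mixed model `y = mu + sum_k u_k + e` over cultivars,
#' where each random term `u_k` (an n x p matrix of genetic values, p traits)
#' has covariance `Sigma_k (x) K_k` for its relationship matrix `K_k`
#' (genomic G, pedigree A, and/or their Hadamard product), and the residual
#' has covariance `R (x) I`. Four models are supported: `gBLUP` (G only),
#' `pBLUP` (A only), `gpBLUP` (G + A), and `gxpBLUP` (G + A + G*A).
#'
#' The reference backend is a Gibbs sampler with inverse-Wishart updates for
#' all covariance matrices; a fast EM-based REML point-estimate backend is
#' available for the single-kernel models (`gBLUP`, `pBLUP`). Cultivars whose
#' phenotype rows are entirely `NA` are treated as held out: their genetic
#' values are predicted from the relationship matrices as
#' `K[test, train] K[train, train]^-1 u_train`.
#'
#' @param y numeric matrix, cultivars x traits (typically 2 columns,
#'   plasticity and ability), rownames = cultivar ids; `NA` rows are
#'   predicted, partial missingness within a row is not supported.
#' @param model one of `"gBLUP"`, `"pBLUP"`, `"gpBLUP"`, `"gxpBLUP"`.
#' @param G,A genomic and pedigree relationship matrices (dimnames = ids).
#' @param sampler a [gibbs_config()].
#' @param backend `"gibbs"` (reference) or `"reml"` (EM point estimate,
#'   single-kernel models only).
#' @param fix_sigma,fix_R optional fixed covariance matrices (p x p; for
#'   `fix_sigma`, a named list per term): when supplied the corresponding
#'   update step is skipped, which turns the sampler into a known-variance
#'   BLUP.
#' @return A list of class `blup_fit`: `u` (named list of posterior-mean
#'   genetic-value matrices per term, including held-out cultivars),
#'   `fitted` (mu + sum of terms), `mu`, `Sigma` (list of p x p genetic
#'   covariances), `R`, `model`, `backend`, `train_ids`, `test_ids`.
#' @export
fit_multitrait_blup <- function(y, model = "gBLUP", G = NULL, A = NULL,
                                sampler = gibbs_config(),
                                backend = c("gibbs", "reml"),
                                fix_sigma = NULL, fix_R = NULL) {
  backend <- match.arg(backend)
  y <- as.matrix(y)
  if (is.null(rownames(y))) rownames(y) <- paste0("id", seq_len(nrow(y)))
  p <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("trait", seq_len(p))
  obs <- rowSums(is.na(y)) == 0
  partial <- rowSums(is.na(y)) %in% seq_len(p - 1)
  if (p > 1 && any(partial))
    stop("rows with partial trait missingness are not supported")
  train_ids <- rownames(y)[obs]
  test_ids <- rownames(y)[!obs]
  if (length(train_ids) < 3) stop("need at least 3 phenotyped cultivars")
  kernels_all <- blup_kernels(model, G, A, rownames(y))
  kernels <- lapply(kernels_all, function(K) {
    psd_prepare(K[train_ids, train_ids, drop = FALSE], "train kernel")
  })
  ytr <- y[train_ids, , drop = FALSE]
  fit <- if (backend == "reml") {
    if (length(kernels) != 1)
      stop("the REML backend supports single-kernel models only (gBLUP/pBLUP)")
    em_reml_fit(ytr, kernels[[1]], names(kernels))
  } else {
    gibbs_fit(ytr, kernels, sampler, fix_sigma = fix_sigma, fix_R = fix_R)
  }
  # extend genetic values to held-out cultivars via the conditional mean
  u_full <- lapply(names(kernels), function(nm) {
    utr <- fit$u[[nm]]
    uf <- matrix(NA_real_, nrow(y), p, dimnames = dimnames(y))
    uf[train_ids, ] <- utr
    if (length(test_ids)) {
      Kfull <- psd_prepare(kernels_all[[nm]], nm)
      Ktt <- Kfull[test_ids, train_ids, drop = FALSE]
      uf[test_ids, ] <- Ktt %*% stable_solve(kernels[[nm]], utr)
    }
    uf
  })
  names(u_full) <- names(kernels)
  fitted <- Reduce(`+`, u_full)
  fitted <- sweep(fitted, 2, fit$mu, "+")
  structure(list(u = u_full, fitted = fitted, mu = fit$mu,
                 Sigma = fit$Sigma, R = fit$R, model = model,
                 backend = backend, train_ids = train_ids,
                 test_ids = test_ids),
            class = "blup_fit")
}

# --- Gibbs backend -----------------------------------------------------------

gibbs_fit <- function(y, kernels, cfg, fix_sigma = NULL, fix_R = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.matrix(fix_sigma)) fix_sigma <- list(fix_sigma)
  n <- nrow(y); p <- ncol(y); nk <- length(kernels)
  nu0 <- p + 2
  S0 <- diag(p)
  # eigen-based inverses with a relative floor: kernels built from dense SNP
  # panels or deep pedigrees are routinely near-singular
  edec <- lapply(kernels, function(K) {
    eg <- eigen(K, symmetric = TRUE)
    list(d = pmax(eg$values, max(eg$values) * 1e-8), U = eg$vectors)
  })
  Kinv <- lapply(edec, function(e) e$U %*% (t(e$U) / e$d))
  fast <- nk == 1L
  if (fast) {
    d <- edec[[1]]$d
    U <- edec[[1]]$U
  }
  # state
  vy <- apply(y, 2, stats::var)
  Sigma <- lapply(seq_len(nk), function(k)
    if (!is.null(fix_sigma)) as.matrix(fix_sigma[[min(k, length(fix_sigma))]])
    else diag(vy / (nk + 1), p))
  R <- if (!is.null(fix_R)) as.matrix(fix_R) else diag(vy / (nk + 1), p)
  mu <- colMeans(y)
  u <- lapply(seq_len(nk), function(k) matrix(0, n, p))
  keep <- cfg$n_iter - cfg$burn_in
  acc_u <- lapply(seq_len(nk), function(k) matrix(0, n, p))
  acc_S <- lapply(seq_len(nk), function(k) matrix(0, p, p))
  acc_R <- matrix(0, p, p); acc_mu <- numeric(p)
  In <- diag(n)
  for (it in seq_len(cfg$n_iter)) {
    Rinv <- solve(R)
    # random terms
    for (k in seq_len(nk)) {
      resid <- sweep(y, 2, mu, "-")
      for (l in seq_len(nk)) if (l != k) resid <- resid - u[[l]]
      Sinv <- solve(Sigma[[k]])
      if (fast) {
        u[[k]] <- sample_term_eigen(resid, U, d, Sinv, Rinv)
      } else {
        P <- kronecker(Sinv, Kinv[[k]]) + kronecker(Rinv, In)
        rhs <- as.vector(resid %*% Rinv)
        ch <- chol(P)
        m <- backsolve(ch, forwardsolve(t(ch), rhs))
        z <- backsolve(ch, stats::rnorm(n * p))
        u[[k]] <- matrix(m + z, n, p)
      }
      if (is.null(fix_sigma)) {
        SS <- crossprod(u[[k]], Kinv[[k]] %*% u[[k]])
        Sigma[[k]] <- riwish(nu0 + n, S0 + SS)
      }
    }
    # residual covariance
    e <- sweep(y, 2, mu, "-")
    for (k in seq_len(nk)) e <- e - u[[k]]
    if (is.null(fix_R)) R <- riwish(nu0 + n, S0 + crossprod(e))
    # overall mean (flat prior)
    em <- y
    for (k in seq_len(nk)) em <- em - u[[k]]
    mu_mean <- colMeans(em)
    Lr <- chol(R / n)
    mu <- mu_mean + as.vector(t(Lr) %*% stats::rnorm(p))
    if (it > cfg$burn_in) {
      for (k in seq_len(nk)) {
        acc_u[[k]] <- acc_u[[k]] + u[[k]]
        acc_S[[k]] <- acc_S[[k]] + Sigma[[k]]
      }
      acc_R <- acc_R + R
      acc_mu <- acc_mu + mu
    }
  }
  tn <- colnames(y)
  out_u <- lapply(acc_u, function(a) {
    a <- a / keep; dimnames(a) <- list(rownames(y), tn); a
  })
  out_S <- lapply(acc_S, function(a) {
    a <- a / keep; dimnames(a) <- list(tn, tn); a
  })
  names(out_u) <- names(out_S) <- names(kernels)
  Rm <- acc_R / keep; dimnames(Rm) <- list(tn, tn)
  list(u = out_u, Sigma = out_S, R = Rm,
       mu = stats::setNames(acc_mu / keep, tn))
}

# Sample the random term in the eigenbasis of its kernel: rows of the
# rotated effect matrix are conditionally independent with 2x2 (or p x p)
# precision Sinv / d_i + Rinv.
sample_term_eigen <- function(resid, U, d, Sinv, Rinv) {
  n <- nrow(resid); p <- ncol(resid)
  rt <- crossprod(U, resid)            # rotated residuals
  rhs <- rt %*% Rinv
  if (p == 2L) {
    a <- Sinv[1, 1] / d + Rinv[1, 1]
    b <- Sinv[1, 2] / d + Rinv[1, 2]
    cc <- Sinv[2, 2] / d + Rinv[2, 2]
    det <- a * cc - b * b
    # posterior covariance C = M^-1 entries
    C11 <- cc / det; C12 <- -b / det; C22 <- a / det
    m1 <- C11 * rhs[, 1] + C12 * rhs[, 2]
    m2 <- C12 * rhs[, 1] + C22 * rhs[, 2]
    # Cholesky of C (lower): [l11 0; l21 l22]
    l11 <- sqrt(C11); l21 <- C12 / l11; l22 <- sqrt(pmax(C22 - l21^2, 0))
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    v <- cbind(m1 + l11 * z1, m2 + l21 * z1 + l22 * z2)
  } else if (p == 1L) {
    prec <- Sinv[1, 1] / d + Rinv[1, 1]
    m <- rhs[, 1] / prec
    v <- cbind(m + stats::rnorm(n) / sqrt(prec))
  } else {
    v <- matrix(0, n, p)
    for (i in seq_len(n)) {
      M <- Sinv / d[i] + Rinv
      Cm <- solve(M)
      v[i, ] <- Cm %*% rhs[i, ] +
        as.vector(t(chol(Cm)) %*% stats::rnorm(p))
    }
  }
  U %*% v
}

# Eigen-floored linear solve for near-singular PSD kernels.
stable_solve <- function(K, B) {
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, max(eg$values) * 1e-8)
  eg$vectors %*% ((crossprod(eg$vectors, B)) / d)
}

# Inverse-Wishart draw: Sigma ~ IW(df, S)  <=>  Sigma^-1 ~ Wishart(df, S^-1)
riwish <- function(df, S) {
  S <- (S + t(S)) / 2
  W <- stats::rWishart(1, df, solve(S))[, , 1]
  Sig <- solve(W)
  (Sig + t(Sig)) / 2
}

# --- EM-REML backend (single kernel, complete data) -------------------------

em_reml_fit <- function(y, K, term_name, max_iter = 500, tol = 1e-8) {
  n <- nrow(y); p <- ncol(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, max(eg$values) * 1e-8); U <- eg$vectors
  vy <- apply(y, 2, stats::var)
  Sigma <- diag(vy / 2, p); R <- diag(vy / 2, p)
  mu <- colMeans(y)
  V <- matrix(0, n, p)
  for (it in seq_len(max_iter)) {
    Sinv <- solve(Sigma); Rinv <- solve(R)
    rt <- crossprod(U, sweep(y, 2, mu, "-"))
    SS_g <- matrix(0, p, p); SS_e <- matrix(0, p, p)
    for (i in seq_len(n)) {
      Ci <- solve(Sinv / d[i] + Rinv)
      mi <- Ci %*% Rinv %*% rt[i, ]
      V[i, ] <- mi
      SS_g <- SS_g + (tcrossprod(mi) + Ci) / d[i]
      ei <- rt[i, ] - mi
      SS_e <- SS_e + tcrossprod(ei) + Ci
    }
    Sigma_new <- SS_g / n; R_new <- SS_e / n
    uhat <- U %*% V
    mu_new <- colMeans(y - uhat)
    delta <- max(abs(Sigma_new - Sigma), abs(R_new - R), abs(mu_new - mu))
    Sigma <- (Sigma_new + t(Sigma_new)) / 2
    R <- (R_new + t(R_new)) / 2
    mu <- mu_new
    if (delta < tol) break
  }
  tn <- colnames(y)
  uhat <- U %*% V
  dimnames(uhat) <- list(rownames(y), tn)
  dimnames(Sigma) <- dimnames(R) <- list(tn, tn)
  u <- stats::setNames(list(uhat), term_name)
  list(u = u, Sigma = stats::setNames(list(Sigma), term_name), R = R,
       mu = stats::setNames(mu, tn))
}

# --- heritability ------------------------------------------------------------

#' Narrow-sense heritability from a BLUP fit
#'
#' Computes `sigma2_G / (sigma2_G + sigma2_E)` for one trait, taking
#' `sigma2_G` from the diagonal of the genetic covariance matrix of the
#' requested term and `sigma2_E` from the residual covariance diagonal.
#'
#' @param fit a `blup_fit` (from [fit_multitrait_blup()]), or a list with
#'   `Sigma` (list of p x p matrices) and `R`.
#' @param trait trait name or column index.
#' @param term which genetic term to use (default the first, i.e. the only
#'   term of gBLUP/pBLUP).
#' @return Heritability in \[0, 1\].
#' @examples
#' heritability(list(Sigma = list(g = diag(c(3, 1))), R = diag(c(1, 1))), 1)
#' @export
heritability <- function(fit, trait = 1, term = 1) {
  Sg <- fit$Sigma[[term]]
  s2g <- diag(as.matrix(Sg))[trait]
  s2e <- diag(as.matrix(fit$R))[trait]
  if (s2g < 0 || s2e < 0) stop("variance components must be nonnegative")
  if (s2g + s2e == 0) stop("both variance components are zero")
  unname(s2g / (s2g + s2e))
}

# --- cross-validation --------------------------------------------------------

#' Replicated k-fold cross-validation of BLUP prediction
#'
#' Runs `reps` replicates of `k`-fold cross-validation: in each replicate,
#' cultivars are assigned to folds stratified on quantile bins of the first
#' trait, the model is refit on k-1 folds, the held-out fold is predicted
#' from the relationship matrices, predictions from all folds are aggregated,
#' and the observed-predicted correlation and RMSE are computed per trait.
#'
#' @inheritParams fit_multitrait_blup
#' @param k number of folds.
#' @param reps number of replicates.
#' @param seed integer seed controlling fold assignment and the sampler.
#' @return A list with `per_rep` (data frame: rep, trait, r, rmse) and
#'   `summary` (per trait: mean and SD of r and RMSE across reps).
#' @export
kfold_cv <- function(y, model = "gBLUP", G = NULL, A = NULL, k = 10,
                     reps = 10, seed = 1, sampler = gibbs_config(),
                     backend = "gibbs") {
  y <- as.matrix(y)
  if (is.null(rownames(y))) rownames(y) <- paste0("id", seq_len(nrow(y)))
  n <- nrow(y); p <- ncol(y)
  if (k > n) stop("k must not exceed the number of cultivars")
  if (anyNA(y)) stop("kfold_cv requires complete phenotypes")
  set.seed(seed)
  per_rep <- list()
  for (r in seq_len(reps)) {
    folds <- stratified_folds(y[, 1], k)
    pred <- matrix(NA_real_, n, p, dimnames = dimnames(y))
    for (f in seq_len(k)) {
      ycv <- y
      ycv[folds == f, ] <- NA
      fit <- fit_multitrait_blup(ycv, model = model, G = G, A = A,
                                 sampler = sampler, backend = backend)
      pred[folds == f, ] <- fit$fitted[folds == f, , drop = FALSE]
    }
    for (tr in seq_len(p)) {
      per_rep[[length(per_rep) + 1L]] <- data.frame(
        rep = r, trait = colnames(y)[tr] %||% tr,
        r = stats::cor(y[, tr], pred[, tr]),
        rmse = sqrt(mean((y[, tr] - pred[, tr])^2)))
    }
  }
  per_rep <- do.call(rbind, per_rep)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$trait), function(d) {
    data.frame(trait = d$trait[1], r_mean = mean(d$r), r_sd = stats::sd(d$r),
               rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse))
  }))
  rownames(summ) <- NULL
  list(per_rep = per_rep, summary = summ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fold ids stratified on quantile bins of a continuous variable: within each
# bin of ~k observations, folds are assigned by random permutation, so every
# fold spans the phenotype distribution.
stratified_folds <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  folds <- integer(n)
  start <- 1L
  while (start <= n) {
    idx <- ord[start:min(start + k - 1L, n)]
    folds[idx] <- sample(seq_len(k))[seq_along(idx)]
    start <- start + k
  }
  folds
}
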