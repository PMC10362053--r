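# Closed-form mixed-model oracle for a single trait with known variances:
# posterior mean of u in y = u + e, u ~ N(0, K s2u), e ~ N(0, I s2e),
# is  s2u K (s2u K + s2e I)^-1 y.
mme_oracle <- function(y, K, s2u, s2e) {
  n <- length(y)
  as.vector(s2u * K %*% solve(s2u * K + s2e * diag(n), y))
}

test_that("fixed-variance Gibbs matches the direct mixed-model solve", {
  set.seed(101)
  n <- 60
  gp <- family_panel(n_founders = 20, n_per_gen = 20, generations = 2,
                     m_snps = 400, seed = 3)
  ids <- sample(gp$truth$id, n)
  K <- unclass(genomic_relationship(filter_maf(gp$genotypes, 0.01)))[ids, ids]
  K <- K + diag(1e-6, n)
  s2u <- 0.6; s2e <- 0.4
  u_true <- as.vector(t(chol(K)) %*% rnorm(n)) * sqrt(s2u)
  y <- matrix(u_true + rnorm(n, 0, sqrt(s2e)), ncol = 1,
              dimnames = list(ids, "trait"))
  yc <- y - mean(y)
  fit <- fit_multitrait_blup(yc, "gBLUP", G = K,
                             sampler = gibbs_config(4000, 1000, seed = 5),
                             fix_sigma = matrix(s2u), fix_R = matrix(s2e))
  oracle <- mme_oracle(yc[, 1] - fit$mu, K, s2u, s2e)
  # posterior means agree with the linear-solve oracle within MC error
  expect_gt(cor(fit$u[[1]][, 1], oracle), 0.995)
  expect_lt(mean(abs(fit$u[[1]][, 1] - oracle)), 0.04)
})

test_that("zero genetic variance yields null predictions and CV r near 0", {
  set.seed(55)
  gp <- gen_genotypes_pedigree(n_founders = 40, n_per_gen = 80,
                               generations = 2, m_snps = 500, n_causal = 40,
                               h2_alpha = 0, h2_beta = 0, seed = 21)
  expect_true(all(gp$truth$g_alpha == 0))
  G <- genomic_relationship(filter_maf(gp$genotypes))
  y <- as.matrix(gp$truth[, c("alpha", "beta")])
  rownames(y) <- gp$truth$id
  y <- y[1:200, ]
  cv <- kfold_cv(y, "gBLUP", G = G, k = 5, reps = 1, seed = 9,
                 sampler = gibbs_config(500, 200))
  expect_true(all(abs(cv$per_rep$r) < 0.15))
})

test_that("multi-trait fit recovers planted covariance structure", {
  gp <- gen_genotypes_pedigree(n_founders = 40, n_per_gen = 130,
                               generations = 2, m_snps = 1000, n_causal = 80,
                               h2_alpha = 0.7, h2_beta = 0.3, rho_g = 0.5,
                               seed = 77)
  G <- genomic_relationship(filter_maf(gp$genotypes))
  y <- as.matrix(gp$truth[, c("alpha", "beta")])
  rownames(y) <- gp$truth$id
  fit <- fit_multitrait_blup(y, "gBLUP", G = G,
                             sampler = gibbs_config(2500, 500, seed = 1))
  h2a <- heritability(fit, "alpha")
  h2b <- heritability(fit, "beta")
  expect_lt(abs(h2a - 0.7), 0.15)
  expect_lt(abs(h2b - 0.3), 0.15)
  Sg <- fit$Sigma[[1]]
  rg <- Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2])
  expect_lt(abs(rg - 0.5), 0.3)
  # REML backend lands near the Gibbs posterior means
  fr <- fit_multitrait_blup(y, "gBLUP", G = G, backend = "reml")
  expect_lt(abs(heritability(fr, "alpha") - h2a), 0.1)
  expect_lt(abs(heritability(fr, "beta") - h2b), 0.1)
})

test_that("all four model forms fit and expose their terms", {
  gp <- family_panel(n_founders = 20, n_per_gen = 40, generations = 2,
                     m_snps = 400, seed = 13)
  G <- genomic_relationship(filter_maf(gp$genotypes))
  A <- pedigree_relationship(gp$pedigree)
  y <- as.matrix(gp$truth[, c("alpha", "beta")])
  rownames(y) <- gp$truth$id
  s <- gibbs_config(300, 100, seed = 2)
  expect_named(fit_multitrait_blup(y, "gBLUP", G = G, sampler = s)$u, "g")
  expect_named(fit_multitrait_blup(y, "pBLUP", A = A, sampler = s)$u, "p")
  expect_named(fit_multitrait_blup(y, "gpBLUP", G = G, A = A, sampler = s)$u,
               c("g", "p"))
  expect_named(fit_multitrait_blup(y, "gxpBLUP", G = G, A = A, sampler = s)$u,
               c("g", "p", "gxp"))
  expect_error(fit_multitrait_blup(y, "pBLUP", G = G, sampler = s),
               "requires")
  expect_error(fit_multitrait_blup(y, "gpBLUP", G = G, A = A, backend = "reml"),
               "single-kernel")
})

test_that("held-out cultivars are predicted from their relationships", {
  set.seed(31)
  gp <- family_panel(n_founders = 30, n_per_gen = 60, generations = 2,
                     m_snps = 800, h2_alpha = 0.8, h2_beta = 0.8, seed = 41)
  G <- genomic_relationship(filter_maf(gp$genotypes))
  y <- as.matrix(gp$truth[, c("alpha", "beta")])
  rownames(y) <- gp$truth$id
  hold <- sample(rownames(y), 30)
  ycv <- y; ycv[hold, ] <- NA
  fit <- fit_multitrait_blup(ycv, "gBLUP", G = G,
                             sampler = gibbs_config(1500, 500, seed = 3))
  expect_setequal(fit$test_ids, hold)
  r <- cor(y[hold, "beta"], fit$fitted[hold, "beta"])
  expect_gt(r, 0.4)
})

test_that("heritability is the genetic variance ratio", {
  vc <- list(Sigma = list(g = diag(c(3, 0))), R = diag(c(1, 2)))
  expect_equal(heritability(vc, 1), 0.75)
  expect_equal(heritability(vc, 2), 0)
  expect_error(heritability(list(Sigma = list(matrix(0, 1, 1)),
                                 R = matrix(0, 1, 1)), 1), "zero")
})

test_that("fold assignment is seeded, stratified and exhaustive", {
  y <- cbind(trait = rnorm(57))
  rownames(y) <- paste0("c", 1:57)
  set.seed(4); f1 <- ypcgm:::stratified_folds(y[, 1], 10)
  set.seed(4); f2 <- ypcgm:::stratified_folds(y[, 1], 10)
  expect_identical(f1, f2)
  expect_true(all(f1 %in% 1:10))
  # every quantile block of 10 spreads over distinct folds
  ord <- order(y[, 1])
  expect_equal(length(unique(f1[ord[1:10]])), 10)
  expect_error(kfold_cv(y, k = 100, G = diag(57)), "exceed")
})
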