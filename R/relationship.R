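#' Filter SNPs by minor allele frequency
#'
#' Removes SNPs whose minor allele frequency, computed from non-missing
#' dosages as `min(p, 1 - p)` with `p = mean(dosage) / 2`, falls below
#' `maf_min`.
#'
#' @param gm genotype dosage matrix, cultivars in rows, SNPs in columns,
#'   entries in \{0, 1, 2\} or `NA`.
#' @param maf_min minimum minor allele frequency to retain.
#' @return The filtered matrix; retained MAFs in attribute `"maf"`.
#' @export
filter_maf <- function(gm, maf_min = 0.05) {
  gm <- as.matrix(gm)
  check_dosages(gm)
  p <- colMeans(gm, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- is.finite(maf) & maf >= maf_min
  if (!any(keep)) stop("all SNPs removed by the MAF filter")
  out <- gm[, keep, drop = FALSE]
  attr(out, "maf") <- maf[keep]
  out
}

check_dosages <- function(gm) {
  v <- gm[!is.na(gm)]
  if (length(v) == 0) stop("genotype matrix has no non-missing dosages")
  if (!all(v %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or missing")
  invisible(gm)
}

#' Genomic relationship matrix
#'
#' Computes `G = X X' / m` from SNP dosages: each SNP column is standardized
#' to zero mean and unit (population) variance, missing dosages are first
#' imputed to the column mean, and `m` is the number of SNPs. Under this
#' standardization the mean of the diagonal of G is exactly 1.
#'
#' @param gm genotype dosage matrix (cultivars x SNPs, \{0,1,2\} or `NA`).
#' @return A symmetric `n x n` matrix with cultivar dimnames, class
#'   `relationship_matrix`, attribute `kind = "genomic"`.
#' @examples
#' genomic_relationship(rbind(a = c(0, 0), b = c(2, 2)))
#' @export
genomic_relationship <- function(gm) {
  gm <- as.matrix(gm)
  check_dosages(gm)
  if (nrow(gm) < 2) stop("need at least 2 cultivars")
  n <- nrow(gm)
  # mean imputation per SNP
  if (anyNA(gm)) {
    mu <- colMeans(gm, na.rm = TRUE)
    idx <- which(is.na(gm), arr.ind = TRUE)
    gm[idx] <- mu[idx[, 2]]
  }
  mu <- colMeans(gm)
  v <- colMeans(gm^2) - mu^2           # population variance
  if (any(v <= 0))
    stop("zero-variance SNP column(s) after imputation: ",
         paste(utils::head(which(v <= 0), 5), collapse = ", "),
         " -- apply filter_maf() first")
  X <- sweep(sweep(gm, 2, mu, "-"), 2, sqrt(v), "/")
  G <- tcrossprod(X) / ncol(X)
  dimnames(G) <- list(rownames(gm), rownames(gm))
  structure(G, class = c("relationship_matrix", "matrix", "array"),
            kind = "genomic")
}

#' Pedigree (numerator) relationship matrix
#'
#' Builds the additive numerator relationship matrix A by the tabular
#' (recursive) method: `a(i,i) = 1 + 0.5 * a(p1, p2)` and
#' `a(i,j) = 0.5 * (a(j, p1) + a(j, p2))` for j processed before i, with an
#' unknown parent contributing 0. Individuals are topologically sorted so
#' parents precede offspring; cycles are reported with their path.
#'
#' @param ped data frame with columns `id`, `parent1`, `parent2`; unknown
#'   parents are `NA` or `""`.
#' @return A symmetric matrix over all ids (founders included), class
#'   `relationship_matrix`, attribute `kind = "pedigree"`.
#' @examples
#' ped <- data.frame(id = c("f1", "f2", "o"),
#'                   parent1 = c(NA, NA, "f1"), parent2 = c(NA, NA, "f2"))
#' pedigree_relationship(ped)
#' @export
pedigree_relationship <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "parent1", "parent2") %in% names(ped)))
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicate individual ids in pedigree")
  p1 <- as.character(ped$parent1); p2 <- as.character(ped$parent2)
  p1[p1 %in% c("", "NA")] <- NA; p2[p2 %in% c("", "NA")] <- NA
  unknown_parents <- setdiff(stats::na.omit(c(p1, p2)), id)
  if (length(unknown_parents)) {
    # parents never listed as individuals are treated as unrelated founders
    id <- c(unknown_parents, id)
    p1 <- c(rep(NA, length(unknown_parents)), p1)
    p2 <- c(rep(NA, length(unknown_parents)), p2)
  }
  ord <- pedigree_topo_sort(id, p1, p2)
  id <- id[ord]; p1 <- p1[ord]; p2 <- p2[ord]
  n <- length(id)
  pi1 <- match(p1, id); pi2 <- match(p2, id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    a_p1p2 <- if (!is.na(pi1[i]) && !is.na(pi2[i])) A[pi1[i], pi2[i]] else 0
    A[i, i] <- 1 + 0.5 * a_p1p2
    if (i > 1) {
      js <- seq_len(i - 1)
      v1 <- if (!is.na(pi1[i])) A[js, pi1[i]] else rep(0, i - 1)
      v2 <- if (!is.na(pi2[i])) A[js, pi2[i]] else rep(0, i - 1)
      aij <- 0.5 * (v1 + v2)
      A[js, i] <- aij
      A[i, js] <- aij
    }
  }
  structure(A, class = c("relationship_matrix", "matrix", "array"),
            kind = "pedigree")
}

# Kahn topological sort over the parent -> offspring relation; reports a
# cycle path on failure.
pedigree_topo_sort <- function(id, p1, p2) {
  n <- length(id)
  pi1 <- match(p1, id); pi2 <- match(p2, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(pi1[i], pi2[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    cyc <- id[indeg > 0L]
    stop("pedigree contains a cycle involving: ", paste(cyc, collapse = " -> "))
  }
  ord
}

#' Hadamard (element-wise) product of relationship matrices
#'
#' The covariance structure of the genome-by-pedigree interaction term:
#' entries are the element-wise products of the aligned G and A matrices.
#'
#' @param G,A relationship matrices with matching dimnames (A is subset and
#'   reordered to G's ids if it is larger).
#' @return A `relationship_matrix` of kind `"product"`.
#' @export
interaction_relationship <- function(G, A) {
  ids <- rownames(G)
  if (is.null(ids) || is.null(rownames(A)))
    stopifnot(all(dim(G) == dim(A)))
  else {
    if (!all(ids %in% rownames(A)))
      stop("A lacks ids present in G: ",
           paste(setdiff(ids, rownames(A)), collapse = ", "))
    A <- A[ids, ids]
  }
  structure(unclass(G) * unclass(A),
            class = c("relationship_matrix", "matrix", "array"),
            kind = "product")
}
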