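## Back-solving SNP effects from per-coefficient GEBV and the iterative
## realized-variance reweighting.  The back-solve uses the same centered gene
## content Z, diagonal weights D and blended G employed in the mixed-model
## equations, so the linear map u_hat = D Z' G_blended^-1 a is the exact
## adjoint of the fitted model.

#' Reweight SNP variance weights from estimated effects
#'
#' Replaces each SNP's expected-variance weight by its realized variance
#' `2 p q u_hat^2`, renormalized so `sum(d * 2 p q)` keeps the original
#' (expected-variance) scale of 1, with a strictly positive floor so no SNP
#' is ever removed from G.
#'
#' @param effects numeric vector of back-solved SNP effects.
#' @param p allele frequencies.
#' @param floor_frac floor as a fraction of the mean weight (default 1e-8).
#' @return numeric vector of new weights.
#' @export
reweight_snp_weights <- function(effects, p, floor_frac = 1e-8) {
  tpq <- 2 * p * (1 - p)
  d <- tpq * effects^2
  if (all(d <= 0)) {
    warning("all SNP effects zero: restoring uniform expected-variance weights")
    return(1 / (length(p) * tpq))
  }
  d <- d / sum(d * tpq)           # preserve sum(d * 2pq) = 1
  pmax(d, floor_frac * mean(d))
}

# one full back-solve + reweighting chain for GEBV matrix a (n_g x 3).
# Round 0 uses the expected-variance weights (and, when supplied, a
# pre-factored Cholesky of the corresponding blended G); each subsequent
# round reweights per coefficient independently and rebuilds G.
.snp_backsolve_chain <- function(a, Z, d0, w, A22, p, n_reweight = 2,
                                 cholGb0 = NULL, floor_frac = 1e-8,
                                 keep_history = FALSE) {
  m <- ncol(Z)
  eff <- matrix(0, m, 3)
  wt <- matrix(0, m, 3)
  hist <- if (keep_history) vector("list", n_reweight + 1) else NULL
  if (is.null(cholGb0)) {
    Gb0 <- w * tcrossprod(sweep(Z, 2L, d0, `*`), Z)
    if (w < 1) Gb0 <- Gb0 + (1 - w) * A22
    cholGb0 <- chol((Gb0 + t(Gb0)) / 2)
  }
  for (k in 1:3) {
    d <- d0
    ginv_a <- backsolve(cholGb0, backsolve(cholGb0, a[, k], transpose = TRUE))
    u <- d * as.numeric(crossprod(Z, ginv_a))
    if (keep_history) hist[[1]] <- cbind(hist[[1]], u)
    if (n_reweight > 0) {
      for (it in seq_len(n_reweight)) {
        d <- reweight_snp_weights(u, p, floor_frac)
        Gb <- w * tcrossprod(sweep(Z, 2L, d, `*`), Z)
        if (w < 1) Gb <- Gb + (1 - w) * A22
        R <- chol((Gb + t(Gb)) / 2)
        u <- d * as.numeric(crossprod(Z, backsolve(R,
               backsolve(R, a[, k], transpose = TRUE))))
        if (keep_history) hist[[it + 1]] <- cbind(hist[[it + 1]], u)
      }
    }
    eff[, k] <- u
    wt[, k] <- d
  }
  list(effects = eff, weights = wt, history = hist)
}

#' Back-solve SNP effects for one coefficient
#'
#' `u_hat = D Z' G_blended^-1 a`, the linear back-solution of per-SNP effects
#' from the genotyped animals' coefficient GEBV.
#'
#' @param geno a [genotype_matrix()] for the genotyped animals.
#' @param scaling a [marker_scaling()] (supply the same one used to build G;
#'   its `d` may be reweighted).
#' @param gebv numeric vector of coefficient GEBV, in `geno` animal order.
#' @param Gblend the blended genomic relationship used in the MME; default
#'   rebuilds `Z D Z'` from `scaling` (w = 1).
#' @return numeric vector of SNP effects.
#' @export
backsolve_snp_effects <- function(geno, scaling, gebv, Gblend = NULL) {
  Z <- centered_genotypes(geno, scaling)
  if (length(gebv) != nrow(Z))
    stop("GEBV length does not match the genotype index")
  if (is.null(Gblend)) Gblend <- build_G(geno, scaling)
  scaling$d * as.numeric(crossprod(Z, solve(Gblend, gebv)))
}

#' Iteratively reweighted SNP effects from a fitted model
#'
#' Runs the single-step GWAS back-solving chain on the fit's per-coefficient
#' GEBV: round 0 uses expected-variance weights, then `n_reweight` rounds
#' (default 2) replace each SNP's weight by its realized variance
#' `2 p q u_hat^2`, rebuild the blended G and back-solve again.  The GEBV are
#' held fixed across rounds; only the marker weights iterate.
#'
#' @param fit an [rr_gblup()] fit with genotypes.
#' @param n_reweight number of reweighting rounds (default 2).
#' @param floor_frac weight floor as a fraction of the mean weight.
#' @param keep_history retain per-round effect vectors.
#' @return object of class `"snp_effects"`: list with `effects` (SNP x 3
#'   matrix), `weights`, `map`, `p` (allele frequencies), `scaling`,
#'   `n_reweight` and the genotyped animal ids.
#' @export
snp_effects <- function(fit, n_reweight = 2, floor_frac = 1e-8,
                        keep_history = FALSE) {
  stopifnot(inherits(fit, "rr_gblup"))
  if (is.null(fit$kin$geno))
    stop("fit has no genotypes: SNP effects cannot be back-solved")
  geno <- fit$kin$geno
  gid <- rownames(geno$codes)
  a <- fit$u[gid, , drop = FALSE]
  scaling <- fit$kin$scaling
  Z <- centered_genotypes(geno, scaling)
  res <- .snp_backsolve_chain(a, Z, scaling$d, w = fit$kin$w,
                              A22 = fit$kin$A22, p = scaling$p,
                              n_reweight = n_reweight,
                              cholGb0 = chol(fit$kin$Gblend),
                              floor_frac = floor_frac,
                              keep_history = keep_history)
  structure(list(effects = res$effects, weights = res$weights,
                 map = geno$map, p = scaling$p, scaling = scaling,
                 n_reweight = n_reweight, geno_ids = gid,
                 history = res$history),
            class = "snp_effects")
}

#' @export
print.snp_effects <- function(x, ...) {
  cat(sprintf("Back-solved SNP effects: %d SNP x 3 coefficients (%d reweighting rounds)\n",
              nrow(x$effects), x$n_reweight))
  invisible(x)
}

#' Export SNP effects as a tidy table
#'
#' @param x a [snp_effects()] object.
#' @param ... unused.
#' @return data frame `snp, chrom, pos, coeff, effect, weight`.
#' @export
as.data.frame.snp_effects <- function(x, ...) {
  do.call(rbind, lapply(1:3, function(k) {
    data.frame(snp = x$map$snp, chrom = x$map$chrom, pos = x$map$pos,
               coeff = k - 1L, effect = x$effects[, k], weight = x$weights[, k])
  }))
}
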