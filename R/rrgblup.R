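#' Fit a Legendre random-regression GBLUP model
#'
#' The central fitting function.  Models a longitudinal trait as
#' `y = mu + CG + Parity + sum_k phi_k beta_k + sum_k phi_k u_mk +
#' sum_k phi_k pe_mk + e`, where `phi` is the order-2 Legendre basis on
#' linearly standardized age, `u ~ N(0, H (x) Ga)` are animal genetic
#' coefficient effects over a blended pedigree/genomic relationship matrix
#' and `pe ~ N(0, I (x) P)` are permanent-environment effects.  Variance
#' components are estimated by EM-REML unless supplied.
#'
#' @param records data frame with columns `animal`, `age` (days), `value`,
#'   `cg`, `parity`.
#' @param pedigree pedigree data frame (`animal`, `sire`, `dam`; 0 unknown).
#'   Restricted to `prune_generations` generations of ancestors of the
#'   phenotyped animals before building A.
#' @param genotypes optional [genotype_matrix()] for a subset (or all) of the
#'   animals; enables the single-step H matrix and downstream GWAS.
#' @param vc optional [rr_varcomp()]; when supplied and `reml = FALSE` the
#'   model is solved at these components.
#' @param reml estimate variance components by EM-REML (default when `vc` is
#'   missing).
#' @param blend_weight weight `w` on G in `G_blended = w G + (1 - w) A22`
#'   (default 0.995).
#' @param freqs optional reference allele frequencies for centering and
#'   weighting the markers; default is the observed frequencies of the
#'   genotyped set.  Note that with observed frequencies the centered gene
#'   content has zero column sums, so `Z D Z'` is singular and `w = 1`
#'   (no blending) requires external frequencies.
#' @param normalized use the orthonormal Legendre basis (default TRUE).
#' @param age_range optional `c(min, max)` override for the age
#'   standardizer; default is the observed record range.
#' @param prune_generations ancestor generations kept in the pedigree
#'   (default 3).
#' @param tol,max_iter,verbose passed to [em_reml()].
#' @return object of class `"rr_gblup"` with components `fixed`, `u`
#'   (pedigree animals x 3 coefficient breeding values), `pe`, `vc`, `std`,
#'   `kin` (relationship bookkeeping), `sys` (assembled equations, reused by
#'   the bootstrap) and the REML trace.
#' @seealso [snp_effects()], [scan_windows()], [bootstrap_windows()],
#'   [trajectory_h2_rg()]
#' @export
rr_gblup <- function(records, pedigree, genotypes = NULL, vc = NULL,
                     reml = is.null(vc), blend_weight = 0.995,
                     freqs = NULL, normalized = TRUE, age_range = NULL,
                     prune_generations = 3,
                     tol = 1e-6, max_iter = 500, verbose = FALSE) {
  stopifnot(all(c("animal", "age", "value", "cg", "parity") %in% names(records)))
  ped <- prune_pedigree(pedigree[c("animal", "sire", "dam")],
                        keep = unique(records$animal),
                        n_generations = prune_generations)
  A <- build_A(ped)

  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "genotype_matrix"))
    gid <- rownames(genotypes$codes)
    keep <- gid %in% rownames(A)
    if (!all(keep)) {
      genotypes <- genotype_matrix(genotypes$codes[keep, , drop = FALSE],
                                   genotypes$map)
    }
    pfreq <- colMeans(genotypes$codes) / 2
    mono <- pfreq <= 0 | pfreq >= 1
    if (any(mono)) {
      message("dropping ", sum(mono), " monomorphic SNP before building G")
      genotypes <- genotype_matrix(genotypes$codes[, !mono, drop = FALSE],
                                   genotypes$map[!mono, , drop = FALSE])
      if (!is.null(freqs)) freqs <- freqs[!mono]
    }
    scaling <- marker_scaling(genotypes, freqs = freqs)
    G <- build_G(genotypes, scaling)
    kin <- blend_and_invert(A, G, w = blend_weight)
    kin$scaling <- scaling
    kin$geno <- genotypes
  } else {
    kin <- list(Hinv = chol2inv(chol(A)), Gblend = NULL, A22 = NULL,
                geno_ids = character(0), w = blend_weight)
    dimnames(kin$Hinv) <- dimnames(A)
  }

  std <- if (is.null(age_range)) {
    age_standardizer(min(records$age), max(records$age))
  } else age_standardizer(age_range[1], age_range[2])

  sys <- assemble_mme(records, std, kin$Hinv, normalized = normalized)
  if (reml) {
    vc <- em_reml(sys, init = vc, tol = tol, max_iter = max_iter,
                  verbose = verbose)
  } else if (is.null(vc)) {
    stop("supply variance components or set reml = TRUE")
  }
  sol <- solve_mme(sys, vc)

  structure(list(fixed = sol$b, u = sol$U, pe = sol$PE, vc = vc,
                 std = std, normalized = normalized, kin = kin,
                 sys = sys, records = records,
                 m2logl = sol$m2logl,
                 reml_trace = attr(vc, "m2logl_trace"),
                 call = match.call()),
            class = "rr_gblup")
}

#' @export
print.rr_gblup <- function(x, ...) {
  cat("Legendre random-regression GBLUP fit\n")
  cat(sprintf("  %d records on %d phenotyped animals; %d pedigree animals",
              x$sys$n, x$sys$p, x$sys$q))
  cat(sprintf("; %d genotyped\n", length(x$kin$geno_ids)))
  cat(sprintf("  age range [%g, %g] d, %s Legendre basis\n",
              x$std$age_min, x$std$age_max,
              if (x$normalized) "orthonormal" else "raw"))
  print(x$vc)
  invisible(x)
}

#' @export
summary.rr_gblup <- function(object, phases = list(`90-118` = 90:118,
                                                   `119-146` = 119:146,
                                                   `147-175` = 147:175), ...) {
  ages <- lapply(phases, function(a) a[a >= object$std$age_min &
                                         a <= object$std$age_max])
  h2 <- vapply(ages, function(a) {
    if (length(a) == 0) return(NA_real_)
    mean(trajectory_h2_rg(object, a)$h2)
  }, numeric(1))
  out <- list(vc = object$vc, phase_h2 = h2,
              n = object$sys$n, n_animals = object$sys$p,
              m2logl = object$m2logl)
  class(out) <- "summary.rr_gblup"
  out
}

#' @export
print.summary.rr_gblup <- function(x, ...) {
  print(x$vc)
  cat("Phase-mean heritabilities:\n")
  print(round(x$phase_h2, 3))
  cat(sprintf("-2 restricted logL: %.4f  (%d records, %d animals)\n",
              x$m2logl, x$n, x$n_animals))
  invisible(x)
}

#' @export
coef.rr_gblup <- function(object, type = c("fixed", "genetic", "pe"), ...) {
  switch(match.arg(type),
         fixed = object$fixed, genetic = object$u, pe = object$pe)
}

#' @export
fitted.rr_gblup <- function(object, ...) {
  s <- object$sys
  Xb <- as.numeric(s$X %*% object$fixed)
  Xb + rowSums(s$Phi * object$u[s$ia_u, , drop = FALSE]) +
    rowSums(s$Phi * object$pe[s$ia_p, , drop = FALSE])
}

#' @export
residuals.rr_gblup <- function(object, ...) {
  object$records$value - fitted(object)
}

#' @export
logLik.rr_gblup <- function(object, ...) {
  structure(-object$m2logl / 2, df = 13, class = "logLik")
}

#' Predict from a random-regression GBLUP fit
#'
#' @param object an [rr_gblup()] fit.
#' @param ages ages (days) at which to evaluate.
#' @param type `"h2"` (heritability trajectory), `"gebv"` (per-animal genetic
#'   trajectory values at `ages`) or `"mean"` (population mean curve without
#'   contemporary-group/parity effects beyond the reference levels).
#' @param animals animal ids for `type = "gebv"` (default: all in the fit).
#' @param ... unused.
#' @export
predict.rr_gblup <- function(object, ages, type = c("h2", "gebv", "mean"),
                             animals = NULL, ...) {
  type <- match.arg(type)
  t_std <- standardize_age(ages, object$std)
  Phi <- legendre_matrix(t_std, normalized = object$normalized)
  if (type == "h2") return(trajectory_h2_rg(object, ages)$h2)
  if (type == "gebv") {
    U <- object$u
    if (!is.null(animals)) U <- U[as.character(animals), , drop = FALSE]
    return(Phi %*% t(U))
  }
  b <- object$fixed
  as.numeric(b["(Intercept)"] + Phi[, 2:3, drop = FALSE] %*%
               b[c("leg1", "leg2")])
}

#' @export
plot.rr_gblup <- function(x, ages = NULL, ...) {
  if (is.null(ages)) ages <- seq(x$std$age_min, x$std$age_max, length.out = 100)
  h2 <- trajectory_h2_rg(x, ages)$h2
  plot(ages, h2, type = "l", xlab = "age (d)", ylab = expression(h^2),
       ylim = c(0, max(h2, na.rm = TRUE) * 1.1), ...)
  invisible(x)
}

#' Simulate phenotypes from a fitted model
#'
#' Parametric simulation: keeps the fitted fixed, genetic and
#' permanent-environment parts and redraws homogeneous residuals.
#'
#' @param object an [rr_gblup()] fit.
#' @param nsim number of replicate phenotype vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame of `nsim` simulated phenotype vectors.
#' @export
simulate.rr_gblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, sqrt(object$vc$se)))
  as.data.frame(out)
}

#' Heritability and genetic-correlation trajectories
#'
#' `h2(t) = phi(t)' Ga phi(t) / (phi(t)' Ga phi(t) + phi(t)' P phi(t) +
#' sigma_e^2)` and `r_g(t, s) = phi(t)' Ga phi(s) / sqrt(phi(t)' Ga phi(t)
#' phi(s)' Ga phi(s))`.  Ages with zero genetic variance yield `NA`
#' correlations.
#'
#' @param fit an [rr_gblup()] fit, or a list with elements `vc`, `std` and
#'   `normalized`.
#' @param ages ages (days) within the standardizer range.
#' @return list with `ages`, `h2` (vector) and `rg` (matrix across ages).
#' @export
trajectory_h2_rg <- function(fit, ages) {
  vc <- fit$vc; std <- fit$std
  Phi <- legendre_matrix(standardize_age(ages, std),
                         normalized = isTRUE(fit$normalized))
  vg <- rowSums((Phi %*% vc$Ga) * Phi)
  vp <- rowSums((Phi %*% vc$P) * Phi)
  h2 <- vg / (vg + vp + vc$se)
  Cg <- Phi %*% vc$Ga %*% t(Phi)
  den <- sqrt(outer(vg, vg))
  rg <- ifelse(den > 0, Cg / den, NA_real_)
  dimnames(rg) <- list(ages, ages)
  list(ages = ages, h2 = h2, rg = rg)
}

#' Phase-mean heritability and cross-phase genetic correlations
#'
#' Averages `h2(t)` over integer ages within each phase and `r_g(t, s)` over
#' all cross-phase age pairs.  Default phases are 90-118, 119-146 and
#' 147-175 days, truncated to the standardizer range.
#'
#' @inheritParams trajectory_h2_rg
#' @param phases named list of integer age vectors.
#' @return list with `h2` (per phase) and `rg` (phase x phase matrix).
#' @export
phase_summary <- function(fit, phases = list(`90-118` = 90:118,
                                             `119-146` = 119:146,
                                             `147-175` = 147:175)) {
  std <- fit$std
  phases <- lapply(phases, function(a) a[a >= std$age_min & a <= std$age_max])
  ages <- sort(unique(unlist(phases)))
  tr <- trajectory_h2_rg(fit, ages)
  h2 <- vapply(phases, function(a) mean(tr$h2[match(a, ages)]), numeric(1))
  np <- length(phases)
  rg <- matrix(NA_real_, np, np, dimnames = list(names(phases), names(phases)))
  for (i in seq_len(np)) for (j in seq_len(np)) {
    ai <- match(phases[[i]], ages); aj <- match(phases[[j]], ages)
    if (length(ai) && length(aj)) rg[i, j] <- mean(tr$rg[ai, aj], na.rm = TRUE)
  }
  list(h2 = h2, rg = rg)
}
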