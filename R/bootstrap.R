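## Bootstrap null for putative QTL windows: the candidate region's SNP
## contribution is removed from the predicted phenotype, a fresh homogeneous
## residual is added, the mixed-model equations are re-solved at the
## full-model variance components, the reweighted back-solving is re-run and
## the window's WGEBV variance is recomputed.  The empirical p-value is the
## fraction of replicates whose statistic reaches the observed one.

# per-record genomic trajectory value from SNP effects, optionally excluding
# a set of SNP columns (for every coefficient, or one coefficient only)
.genomic_record_part <- function(fit, effects, exclude = integer(0),
                                 exclude_coeff = NULL) {
  sys <- fit$sys
  geno <- fit$kin$geno
  gid <- rownames(geno$codes)
  ia <- match(sys$pids[sys$ia_p], gid)
  if (anyNA(ia))
    stop("bootstrap requires every phenotyped animal to be genotyped")
  Z <- centered_genotypes(geno, list(p = effects$p))
  gval <- matrix(0, nrow(Z), 3)
  for (k in 1:3) {
    drop_k <- if (is.null(exclude_coeff) || (k - 1L) %in% exclude_coeff)
      exclude else integer(0)
    u <- effects$effects[, k]
    if (length(drop_k)) u[drop_k] <- 0
    gval[, k] <- as.numeric(Z %*% u)
  }
  rowSums(sys$Phi * gval[ia, , drop = FALSE])
}

#' Construct null phenotypes for a candidate window
#'
#' `y_tilde = fixed part + permanent-environment part + phi(t)' (genomic
#' value with the window's SNPs excluded) + e`, with `e ~ N(0, sigma_e^2)`
#' i.i.d. using the full-model residual variance — equivalently
#' `y_hat - u_hat + u_tilde + e` with the with/without-window GEBV
#' contributions.
#'
#' @param fit an [rr_gblup()] fit whose phenotyped animals are all genotyped.
#' @param effects a [snp_effects()] object from the full data.
#' @param window integer vector of global SNP indices to exclude.
#' @param seed integer seed for the simulated residual.
#' @param exclude_coeff `NULL` to exclude the window from all three
#'   coefficients (default), or a vector of coefficient indices (0-2).
#' @return data frame of records with `value` replaced by the null phenotype.
#' @export
build_null_phenotypes <- function(fit, effects, window, seed = 1L,
                                  exclude_coeff = NULL) {
  stopifnot(inherits(fit, "rr_gblup"), inherits(effects, "snp_effects"))
  if (length(window) && (min(window) < 1 || max(window) > nrow(effects$effects)))
    stop("window SNP indices outside the effect vectors")
  sys <- fit$sys
  Xb <- as.numeric(sys$X %*% fit$fixed)
  pe_part <- rowSums(sys$Phi * fit$pe[sys$ia_p, , drop = FALSE])
  g_part <- .genomic_record_part(fit, effects, exclude = window,
                                 exclude_coeff = exclude_coeff)
  set.seed(seed)
  e <- stats::rnorm(sys$n, 0, sqrt(fit$vc$se))
  out <- fit$records
  out$value <- Xb + pe_part + g_part + e
  out
}

# WGEBV variance of one window for each coefficient
.window_stat <- function(Z, eff, widx) {
  vapply(1:3, function(k)
    stats::var(as.numeric(Z[, widx, drop = FALSE] %*% eff[widx, k])),
    numeric(1))
}

#' Bootstrap significance test for putative QTL regions
#'
#' For each putative region (its peak window carries the test statistic;
#' its full SNP span is removed when building the null), `n_reps` null
#' phenotype vectors are generated, the MME are re-solved at the full-model
#' variance components, SNP effects are re-estimated with the same
#' reweighting schedule, and the window's WGEBV variance is recomputed.
#' The empirical p-value per coefficient is
#' `#(replicate statistic >= observed) / n_reps`.
#'
#' @param fit an [rr_gblup()] fit (all phenotyped animals genotyped).
#' @param effects full-data [snp_effects()].
#' @param regions data frame from [putative_qtl()]; only rows with
#'   `putative == TRUE` are tested unless `all = TRUE`.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed master seed; replicate seeds are derived deterministically
#'   from it, so any subset of replicates is individually reproducible.
#' @param alpha significance cutoff recorded in the output (default 0.001).
#' @param all test all regions, not only the putative ones.
#' @param exclude_coeff see [build_null_phenotypes()].
#' @param keep_replicates return the replicate statistic matrices.
#' @return object of class `"bootstrap_result"`: data frame `results` with
#'   one row per region x coefficient (`observed`, `p`, `p_label`,
#'   `significant`), plus metadata.
#' @export
bootstrap_windows <- function(fit, effects, regions, n_reps = 1000,
                              seed = 1L, alpha = 0.001, all = FALSE,
                              exclude_coeff = NULL, keep_replicates = FALSE) {
  stopifnot(inherits(fit, "rr_gblup"), inherits(effects, "snp_effects"))
  test <- if (all) regions else regions[regions$putative, , drop = FALSE]
  if (nrow(test) == 0L) stop("no putative regions to test")
  sys <- fit$sys
  geno <- fit$kin$geno
  scaling <- fit$kin$scaling
  Z <- centered_genotypes(geno, scaling)
  cholGb0 <- chol(fit$kin$Gblend)
  fac <- .mme_factor(sys, fit$vc)
  gidx <- match(fit$kin$geno_ids, sys$uids)

  res <- list(); reps_out <- list()
  for (r in seq_len(nrow(test))) {
    reg <- test[r, ]
    widx <- reg$peak_start:reg$peak_end
    span <- reg$start:reg$end
    obs <- .window_stat(Z, effects$effects, widx)
    stat <- matrix(NA_real_, n_reps, 3)
    for (b in seq_len(n_reps)) {
      sb <- .seed_stream(seed, r * 1000003 + b)
      yb <- build_null_phenotypes(fit, effects, window = span, seed = sb,
                                  exclude_coeff = exclude_coeff)$value
      rb <- as.numeric(Matrix::crossprod(sys$W, yb))
      sol <- .mme_solve_rhs(sys, fac, rb, sum(yb^2))
      ab <- sol$U[gidx, , drop = FALSE]
      eb <- .snp_backsolve_chain(ab, Z, scaling$d, w = fit$kin$w,
                                 A22 = fit$kin$A22, p = scaling$p,
                                 n_reweight = effects$n_reweight,
                                 cholGb0 = cholGb0)$effects
      stat[b, ] <- .window_stat(Z, eb, widx)
    }
    pvals <- colMeans(sweep(stat, 2L, obs, `>=`))
    res[[r]] <- data.frame(region = reg$region, coeff = 0:2,
                           chrom = reg$chrom,
                           start = reg$start, end = reg$end,
                           observed = obs, p = pvals,
                           p_label = ifelse(pvals == 0,
                                            paste0("<", format(1 / n_reps)),
                                            format(pvals)),
                           significant = pvals < alpha,
                           n_reps = n_reps, seed = seed)
    if (keep_replicates) reps_out[[reg$region]] <- stat
  }
  structure(list(results = do.call(rbind, res), alpha = alpha,
                 n_reps = n_reps, seed = seed,
                 replicates = if (keep_replicates) reps_out else NULL),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap test: %d region x coefficient combinations, %d replicates\n",
              nrow(x$results), x$n_reps))
  print(x$results[, c("region", "coeff", "observed", "p_label", "significant")],
        row.names = FALSE)
  invisible(x)
}
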