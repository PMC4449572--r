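# shared fixtures: small simulation configs, a direct GLS oracle for the
# mixed-model equations, and hand-made genotype/effect objects

quick_cfg <- function(..., seed = 1) {
  sim_config(n_founders = 30, n_generations = 2, n_per_gen = 45,
             n_snp_per_chrom = 40, n_chrom = 2, seed = seed, ...)
}

# direct generalized-least-squares solutions for an assembled system:
# independent of the Henderson-MME solve path
gls_oracle <- function(sys, vc) {
  Gu <- kronecker(solve(sys$Hinv), vc$Ga)
  Zu <- as.matrix(sys$W[, sys$f + seq_len(3 * sys$q), drop = FALSE])
  Zp <- as.matrix(sys$W[, sys$f + 3 * sys$q + seq_len(3 * sys$p),
                        drop = FALSE])
  Gp <- kronecker(diag(sys$p), vc$P)
  V <- Zu %*% Gu %*% t(Zu) + Zp %*% Gp %*% t(Zp) + vc$se * diag(sys$n)
  Vi <- solve(V)
  X <- sys$X
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% sys$y)
  Py <- Vi %*% (sys$y - X %*% b)
  u <- Gu %*% t(Zu) %*% Py
  pe <- Gp %*% t(Zp) %*% Py
  list(b = as.numeric(b),
       U = matrix(u, sys$q, 3, byrow = TRUE),
       PE = matrix(pe, sys$p, 3, byrow = TRUE))
}

# genotype_matrix from a bare code matrix on one chromosome
toy_geno <- function(codes, chrom = NULL, pos = NULL) {
  m <- ncol(codes)
  if (is.null(rownames(codes))) rownames(codes) <- seq_len(nrow(codes))
  genotype_matrix(codes,
                  data.frame(snp = paste0("s", seq_len(m)),
                             chrom = if (is.null(chrom)) rep(1L, m) else chrom,
                             pos = if (is.null(pos)) seq_len(m) * 1000 else pos))
}

# snp_effects object assembled by hand (for window/reporting tests)
toy_effects <- function(eff, geno) {
  p <- colMeans(geno$codes) / 2
  structure(list(effects = eff, weights = matrix(1, nrow(eff), 3),
                 map = geno$map, p = p,
                 scaling = list(p = p, d = rep(1, nrow(eff))),
                 n_reweight = 0L, geno_ids = rownames(geno$codes)),
            class = "snp_effects")
}
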