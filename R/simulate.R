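## Synthetic pedigree / genotype / longitudinal phenotype generator.
## The generator is the exact stochastic counterpart of the fitted model:
## order-2 Legendre genetic and permanent-environment coefficient effects,
## gene-dropped biallelic genotypes, optional QTL effects attached to specific
## coefficients, contemporary-group and parity fixed effects and homogeneous
## residual noise on per-animal observation windows of roughly 90-175 d.

# deterministic sub-seed derivation (kept below 2^31; inputs well below 2^53)
.seed_stream <- function(seed, k) {
  as.integer((1103515245 * (abs(as.numeric(seed)) %% 2^20) +
                12345 + 7919 * as.numeric(k)) %% 2147483647)
}

# symmetric PSD check and matrix square root (tolerates semi-definiteness)
.check_psd <- function(M, name) {
  if (!isSymmetric(unname(M), tol = 1e-8))
    stop(name, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop(name, " must be positive semi-definite")
  invisible(TRUE)
}

.msqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generator.  Defaults are a
#' single coherent set of "study conditions": a body-weight-like trajectory
#' rising from roughly 40 to 120 kg between 90 and 175 days, coefficient-scale
#' genetic covariance `diag(4, 1, 0.25)`, permanent-environment covariance
#' `diag(2, 0.5, 0.1)` and residual variance 4 (intercept heritability 0.4),
#' with observation windows averaging about 60 records per animal.
#'
#' @param n_founders number of founder animals (>= 2).
#' @param n_generations number of non-founder generations (default 3).
#' @param n_per_gen offspring per generation (default `n_founders`).
#' @param n_snp_per_chrom,n_chrom genome dimensions.
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param genetic_cov 3x3 symmetric PSD genetic coefficient covariance.
#' @param pe_cov 3x3 symmetric PSD permanent-environment covariance.
#' @param resid_var homogeneous residual variance (> 0 unless exactly 0 for
#'   noise-free checks).
#' @param qtl_spec `NULL` or data frame with columns `chrom`, `snp_index`
#'   (1-based within chromosome), `coeff` (0, 1 or 2) and `effect`
#'   (allele-substitution effect on that Legendre coefficient).
#' @param n_cg number of contemporary groups; `cg_sd` their effect SD.
#' @param cg_sd standard deviation of contemporary-group effects.
#' @param parity_effects length-3 vector of parity (1, 2, 3+) effects.
#' @param mean_curve length-3 fixed Legendre regression (on the same basis
#'   scale as the random coefficients).
#' @param age_window named vector `onset_mean`, `onset_sd`, `length_mean`,
#'   `length_sd` in days.
#' @param obs_per_day probability an animal is recorded on a given on-test day.
#' @param normalized use the orthonormal Legendre basis (default TRUE).
#' @param seed master seed; every generator draws from sub-streams of it.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 100, n_generations = 3,
                       n_per_gen = n_founders,
                       n_snp_per_chrom = 200, n_chrom = 5,
                       maf_range = c(0.05, 0.5),
                       genetic_cov = diag(c(4, 1, 0.25)),
                       pe_cov = diag(c(2, 0.5, 0.1)),
                       resid_var = 4,
                       qtl_spec = NULL,
                       n_cg = 10, cg_sd = 2,
                       parity_effects = c(0, 0.3, 0.5),
                       mean_curve = c(113, 33, -3),
                       age_window = c(onset_mean = 90, onset_sd = 5,
                                      length_mean = 85, length_sd = 7),
                       obs_per_day = 0.7,
                       normalized = TRUE,
                       seed = 1L) {
  if (n_founders < 2) stop("n_founders must be at least 2 (cannot mate)")
  if (n_generations < 1) stop("n_generations must be at least 1")
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  genetic_cov <- as.matrix(genetic_cov); pe_cov <- as.matrix(pe_cov)
  stopifnot(all(dim(genetic_cov) == c(3, 3)), all(dim(pe_cov) == c(3, 3)))
  .check_psd(genetic_cov, "genetic_cov")
  .check_psd(pe_cov, "pe_cov")
  stopifnot(resid_var >= 0, obs_per_day > 0, obs_per_day <= 1,
            length(parity_effects) == 3, length(mean_curve) == 3)
  if (!is.null(qtl_spec)) {
    qtl_spec <- as.data.frame(qtl_spec)
    stopifnot(all(c("chrom", "snp_index", "coeff", "effect") %in% names(qtl_spec)))
    if (any(qtl_spec$coeff < 0 | qtl_spec$coeff > 2))
      stop("qtl coefficient index must be 0, 1 or 2")
    if (any(qtl_spec$chrom < 1 | qtl_spec$chrom > n_chrom) ||
        any(qtl_spec$snp_index < 1 | qtl_spec$snp_index > n_snp_per_chrom))
      stop("qtl_spec addresses a SNP outside the simulated genome")
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_per_gen = as.integer(n_per_gen),
                 n_snp_per_chrom = as.integer(n_snp_per_chrom),
                 n_chrom = as.integer(n_chrom),
                 maf_range = as.numeric(maf_range),
                 genetic_cov = genetic_cov, pe_cov = pe_cov,
                 resid_var = resid_var, qtl_spec = qtl_spec,
                 n_cg = as.integer(n_cg), cg_sd = cg_sd,
                 parity_effects = as.numeric(parity_effects),
                 mean_curve = as.numeric(mean_curve),
                 age_window = age_window, obs_per_day = obs_per_day,
                 normalized = isTRUE(normalized),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents; each of `n_generations`
#' subsequent generations contains `n_per_gen` offspring whose sire and dam
#' are sampled from the males and females of the previous generation.  The
#' returned table is topologically ordered.
#'
#' @param cfg a [sim_config()].
#' @return data frame `animal, sire, dam, generation, sex`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.seed_stream(cfg$seed, 1))
  nf <- cfg$n_founders
  sex <- rep_len(c("M", "F"), nf)
  ped <- data.frame(animal = seq_len(nf), sire = 0L, dam = 0L,
                    generation = 0L, sex = sex)
  nid <- nf
  for (g in seq_len(cfg$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (length(males) == 0L || length(females) == 0L)
      stop("previous generation lacks one sex; increase n_founders")
    n <- cfg$n_per_gen
    off <- data.frame(animal = nid + seq_len(n),
                      sire = sample(males, n, replace = TRUE),
                      dam = sample(females, n, replace = TRUE),
                      generation = g,
                      sex = rep_len(c("M", "F"), n))
    nid <- nid + n
    ped <- rbind(ped, off)
  }
  rownames(ped) <- NULL
  ped
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder alleles are drawn under Hardy-Weinberg at per-SNP frequencies
#' uniform on `maf_range`; every non-founder inherits one allele per parent
#' per locus, independently across loci (linkage disequilibrium arises only
#' through pedigree co-segregation).
#'
#' @param ped ordered pedigree (from [simulate_pedigree()] or compatible).
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ped3 <- as_pedigree(ped[c("animal", "sire", "dam")])
  set.seed(.seed_stream(cfg$seed, 2))
  n <- nrow(ped3)
  m <- cfg$n_chrom * cfg$n_snp_per_chrom
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  si <- match(ped3$sire, ped3$animal)
  di <- match(ped3$dam, ped3$animal)
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      H1[i, ] <- rbinom(m, 1L, maf)
    } else {
      pick <- runif(m) < 0.5
      H1[i, ] <- ifelse(pick, H1[si[i], ], H2[si[i], ])
    }
    if (is.na(di[i])) {
      H2[i, ] <- rbinom(m, 1L, maf)
    } else {
      pick <- runif(m) < 0.5
      H2[i, ] <- ifelse(pick, H1[di[i], ], H2[di[i], ])
    }
  }
  codes <- H1 + H2
  rownames(codes) <- ped3$animal
  map <- data.frame(snp = sprintf("snp_%d_%d",
                                  rep(seq_len(cfg$n_chrom), each = cfg$n_snp_per_chrom),
                                  rep(seq_len(cfg$n_snp_per_chrom), cfg$n_chrom)),
                    chrom = rep(seq_len(cfg$n_chrom), each = cfg$n_snp_per_chrom),
                    pos = rep(seq_len(cfg$n_snp_per_chrom), cfg$n_chrom) * 50000)
  genotype_matrix(codes, map)
}

# global column index of a qtl_spec row
.qtl_index <- function(qtl_spec, cfg) {
  (qtl_spec$chrom - 1L) * cfg$n_snp_per_chrom + qtl_spec$snp_index
}

#' Simulate longitudinal phenotypes with known ground truth
#'
#' Polygenic coefficient breeding values are gene-dropped down the pedigree
#' (founder ~ N(0, genetic_cov); offspring = parent average + Mendelian
#' sampling N(0, genetic_cov / 2)); QTL contributions
#' `(code - 2p) * effect` are superimposed on the addressed coefficient;
#' permanent-environment vectors are i.i.d. N(0, pe_cov).  Each record is
#' `cg + parity + phi(t)' (mean_curve + g + pe) + e`.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param geno genotypes from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return list with `records` (data frame `animal, age, value, cg, parity`)
#'   and `truth` (per-animal coefficient values, QTL table, true variance
#'   components, standardizer, fixed effects).
#' @export
simulate_phenotypes <- function(ped, geno, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "genotype_matrix"))
  .check_psd(cfg$genetic_cov, "genetic_cov")
  .check_psd(cfg$pe_cov, "pe_cov")
  set.seed(.seed_stream(cfg$seed, 3))
  ped3 <- as_pedigree(ped[c("animal", "sire", "dam")])
  n <- nrow(ped3)
  si <- match(ped3$sire, ped3$animal)
  di <- match(ped3$dam, ped3$animal)

  Lg <- .msqrt(cfg$genetic_cov)
  u <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    z <- Lg %*% rnorm(3)
    if (is.na(si[i]) && is.na(di[i])) {
      u[i, ] <- z
    } else {
      us <- if (is.na(si[i])) rep(0, 3) else u[si[i], ]
      ud <- if (is.na(di[i])) rep(0, 3) else u[di[i], ]
      u[i, ] <- (us + ud) / 2 + sqrt(0.5) * z
    }
  }
  rownames(u) <- ped3$animal

  g <- u
  qtl <- NULL
  if (!is.null(cfg$qtl_spec) && nrow(cfg$qtl_spec) > 0) {
    qtl <- cfg$qtl_spec
    qtl$snp_global <- .qtl_index(qtl, cfg)
    qtl$freq <- colMeans(geno$codes[, qtl$snp_global, drop = FALSE]) / 2
    for (r in seq_len(nrow(qtl))) {
      j <- qtl$snp_global[r]
      codes <- geno$codes[match(ped3$animal, rownames(geno$codes)), j]
      g[, qtl$coeff[r] + 1L] <- g[, qtl$coeff[r] + 1L] +
        (codes - 2 * qtl$freq[r]) * qtl$effect[r]
    }
  }

  pe <- matrix(rnorm(3 * n), n, 3) %*% t(.msqrt(cfg$pe_cov))
  rownames(pe) <- ped3$animal

  cg_id <- ((seq_len(n) - 1L) %% cfg$n_cg) + 1L
  cg_eff <- rnorm(cfg$n_cg, 0, cfg$cg_sd)
  parity <- sample(1:3, n, replace = TRUE)

  aw <- cfg$age_window
  onset <- pmax(1, round(rnorm(n, aw["onset_mean"], aw["onset_sd"])))
  len <- pmax(10, round(rnorm(n, aw["length_mean"], aw["length_sd"])))
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    days <- onset[i]:(onset[i] + len[i])
    days <- days[runif(length(days)) < cfg$obs_per_day]
    if (length(days) == 0L) days <- onset[i]
    rec[[i]] <- data.frame(animal = ped3$animal[i], age = days,
                           cg = cg_id[i], parity = parity[i])
  }
  records <- do.call(rbind, rec)
  std <- age_standardizer(min(records$age), max(records$age))
  Phi <- legendre_matrix(standardize_age(records$age, std),
                         normalized = cfg$normalized)
  ia <- match(records$animal, ped3$animal)
  fixed <- cg_eff[records$cg] + cfg$parity_effects[records$parity] +
    Phi %*% cfg$mean_curve
  records$value <- as.numeric(fixed +
    rowSums(Phi * g[ia, , drop = FALSE]) +
    rowSums(Phi * pe[ia, , drop = FALSE]) +
    rnorm(nrow(records), 0, sqrt(cfg$resid_var)))
  records$cg <- factor(records$cg)
  records$parity <- factor(records$parity)
  rownames(records) <- NULL

  truth <- list(u_polygenic = u, g_total = g, pe = pe, qtl = qtl,
                genetic_cov = cfg$genetic_cov, pe_cov = cfg$pe_cov,
                resid_var = cfg$resid_var, std = std,
                cg_effects = cg_eff, parity_effects = cfg$parity_effects,
                mean_curve = cfg$mean_curve, normalized = cfg$normalized)
  list(records = records, truth = truth)
}

#' One-call synthetic data set
#'
#' Convenience wrapper running [simulate_pedigree()], [simulate_genotypes()]
#' and [simulate_phenotypes()] under a single configuration.
#'
#' @param cfg a [sim_config()].
#' @return list `ped`, `geno`, `records`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  phen <- simulate_phenotypes(ped, geno, cfg)
  list(ped = ped, geno = geno, records = phen$records, truth = phen$truth)
}

#' Allele-substitution effect for a target variance share
#'
#' Given simulated genotypes, returns the effect size `a` such that the QTL
#' at (`chrom`, `snp_index`) contributes `share` of `coeff_var` to the
#' addressed coefficient's genetic variance: `2 p q a^2 = share * coeff_var`
#' at the realized allele frequency.
#'
#' @param geno a [genotype_matrix()].
#' @param chrom,snp_index QTL address (1-based within chromosome).
#' @param coeff_var the polygenic variance of the addressed coefficient.
#' @param share target variance share (e.g. 0.05).
#' @param n_snp_per_chrom SNP per chromosome used to form the global index.
#' @return the allele-substitution effect (positive).
#' @export
qtl_effect_for_share <- function(geno, chrom, snp_index, coeff_var, share,
                                 n_snp_per_chrom) {
  j <- (chrom - 1L) * n_snp_per_chrom + snp_index
  p <- mean(geno$codes[, j]) / 2
  if (p <= 0 || p >= 1) stop("QTL SNP is monomorphic in the simulated data")
  sqrt(share * coeff_var / (2 * p * (1 - p)))
}
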