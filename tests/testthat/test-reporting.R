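test_that("variance explained is 100% for the whole genome, 0% for nothing,
           and the denominator equals Var(Z u_hat)", {
  set.seed(101)
  codes <- matrix(rbinom(50 * 30, 2, 0.4), 50, 30)
  rownames(codes) <- 1:50
  poly <- colMeans(codes) / 2
  codes[1, poly == 0] <- 1L; codes[1, poly == 1] <- 1L
  geno <- toy_geno(codes)
  eff <- toy_effects(matrix(rnorm(90), 30, 3), geno)
  all_reg <- data.frame(coeff = 0:2, start = 1L, end = 30L)
  ve <- variance_explained(geno, eff, all_reg)
  expect_equal(ve$per_coeff$pct, rep(100, 3), tolerance = 1e-10)
  expect_equal(ve$trajectory_pct, 100, tolerance = 1e-10)

  ve0 <- variance_explained(geno, eff, all_reg[0, ])
  expect_equal(ve0$per_coeff$pct, rep(0, 3))
  expect_equal(ve0$trajectory_pct, 0)

  Z <- rrgwas:::centered_genotypes(geno, list(p = eff$p))
  for (k in 1:3)
    expect_equal(ve$per_coeff$denominator[k],
                 var(as.numeric(Z %*% eff$effects[, k])), tolerance = 1e-10)
})

test_that("disjoint regions with orthogonal genotype patterns are additive", {
  # centered patterns are exactly orthogonal across the two SNPs
  codes <- cbind(c(0L, 0L, 2L, 2L), c(0L, 2L, 0L, 2L))
  rownames(codes) <- 1:4
  geno <- toy_geno(codes)
  eff <- toy_effects(matrix(c(1, 2, rep(0, 4)), 2, 3), geno)
  r1 <- data.frame(coeff = 0L, start = 1L, end = 1L)
  r2 <- data.frame(coeff = 0L, start = 2L, end = 2L)
  v1 <- variance_explained(geno, eff, r1)$per_coeff$pct[1]
  v2 <- variance_explained(geno, eff, r2)$per_coeff$pct[1]
  v12 <- variance_explained(geno, eff, rbind(r1, r2))$per_coeff$pct[1]
  expect_equal(v12, v1 + v2, tolerance = 1e-10)
  expect_equal(v12, 100, tolerance = 1e-10)
})

test_that("the correlation table has variance-ratio heritabilities on the
           diagonal and unit self-correlations off it", {
  cfg <- quick_cfg(seed = 102)
  d <- simulate_dataset(cfg)
  vc <- rr_varcomp(cfg$genetic_cov, cfg$pe_cov, cfg$resid_var)
  fit <- rr_gblup(d$records, d$ped, d$geno, vc = vc, reml = FALSE)
  eff <- snp_effects(fit)
  scan <- scan_windows(fit$kin$geno, eff)
  ct <- gebv_correlation_table(list(fit), list(scan))
  for (k in 1:3)
    expect_equal(ct[k, k],
                 vc$Ga[k, k] / (vc$Ga[k, k] + vc$P[k, k] + vc$se),
                 tolerance = 1e-12)
  expect_true(all(abs(ct[upper.tri(ct)]) <= 1))
  expect_true(all(abs(ct[lower.tri(ct)]) <= 1, na.rm = TRUE))

  # a duplicated trait correlates perfectly with itself
  ct2 <- gebv_correlation_table(list(fit, fit), list(scan, scan))
  expect_equal(ct2[1, 4], 1, tolerance = 1e-12)
  expect_equal(ct2[4, 1], 1, tolerance = 1e-10)
})

test_that("region annotation matches a hand-enumerated GFF3 overlap list and
           respects interval boundaries", {
  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1;Name=GENE1",
    "1\tsrc\tgene\t900\t1200\t.\t-\t.\tID=g2;Name=GENE2",
    "2\tsrc\tgene\t100\t200\t.\t+\t.\tID=g3;Name=GENE3"), gff)
  regions <- data.frame(region = c("r1", "r2"), coeff = 0L,
                        chrom = c(1L, 1L),
                        start = c(1L, 11L), end = c(10L, 20L),
                        start_pos = c(450L, 501L), end_pos = c(899L, 600L))
  codes <- matrix(rbinom(20 * 20, 2, 0.5), 20, 20)
  rownames(codes) <- 1:20
  geno <- toy_geno(codes)
  eff <- toy_effects(matrix(rnorm(60), 20, 3), geno)
  ann <- annotate_regions(regions, gff, eff)
  # r1 overlaps GENE1 (450 <= 500) but not GENE2 (899 < 900); r2 overlaps none
  expect_equal(ann$gene[ann$region == "r1"], "GENE1")
  expect_true(is.na(ann$gene[ann$region == "r2"]))
  # top SNP is the arg-max of 2pq u^2 within the region's SNP range
  idx <- 1:10
  pv <- 2 * eff$p[idx] * (1 - eff$p[idx]) * eff$effects[idx, 1]^2
  expect_equal(ann$top_snp[ann$region == "r1"],
               eff$map$snp[idx[which.max(pv)]])
})

test_that("tables round-trip through their readers losslessly", {
  cfg <- quick_cfg(seed = 103)
  d <- simulate_dataset(cfg)
  td <- tempfile(); dir.create(td)
  write_pedigree_csv(d$ped, file.path(td, "ped.csv"))
  ped2 <- read_pedigree_csv(file.path(td, "ped.csv"))
  expect_equal(ped2$animal, d$ped$animal)
  expect_equal(ped2$sire, d$ped$sire)

  write_phenotypes_csv(d$records, file.path(td, "ph.csv"))
  rec2 <- read_phenotypes_csv(file.path(td, "ph.csv"))
  expect_equal(rec2$value, d$records$value, tolerance = 1e-12)
  expect_equal(as.character(rec2$cg), as.character(d$records$cg))

  write_genotypes_csv(d$geno, file.path(td, "g.csv"), file.path(td, "m.csv"))
  g2 <- read_genotypes_csv(file.path(td, "g.csv"), file.path(td, "m.csv"))
  expect_equal(unname(g2$codes), unname(d$geno$codes))
  expect_equal(g2$map$pos, d$geno$map$pos)

  write_plink(d$geno, file.path(td, "pl"))
  g3 <- read_plink(file.path(td, "pl"))
  expect_equal(unname(g3$codes), unname(d$geno$codes))
  unlink(td, recursive = TRUE)
})

test_that("the pipeline is deterministic: same seed, byte-identical archive", {
  cfg <- sim_config(n_founders = 20, n_generations = 2, n_per_gen = 30,
                    n_snp_per_chrom = 60, n_chrom = 2, seed = 104,
                    qtl_spec = data.frame(chrom = 1, snp_index = 30,
                                          coeff = 0, effect = 1.5))
  config <- list(sim = cfg, seed = 7, n_reps = 6,
                 vc = rr_varcomp(cfg$genetic_cov, cfg$pe_cov, cfg$resid_var))
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_pipeline(config, out_dir = d1, verbose = FALSE)
  r2 <- run_pipeline(config, out_dir = d2, verbose = FALSE)
  m1 <- archive_md5(d1); m2 <- archive_md5(d2)
  expect_identical(names(m1), names(m2))
  expect_identical(unname(m1), unname(m2))
  expect_true(length(m1) >= 10)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a pipeline with zero bootstrap replicates completes through the
           window stage", {
  cfg <- sim_config(n_founders = 16, n_generations = 1, n_per_gen = 24,
                    n_snp_per_chrom = 40, n_chrom = 1, seed = 105)
  config <- list(sim = cfg, seed = 3, n_reps = 0,
                 vc = rr_varcomp(cfg$genetic_cov, cfg$pe_cov, cfg$resid_var))
  res <- run_pipeline(config, out_dir = NULL, verbose = FALSE)
  expect_null(res$boot)
  expect_s3_class(res$scan, "window_scan")
  expect_true(nrow(res$regions) > 0)
})
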