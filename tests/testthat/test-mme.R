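make_small_system <- function(seed = 21, n_founders = 12, n_per_gen = 18) {
  cfg <- sim_config(n_founders = n_founders, n_generations = 2,
                    n_per_gen = n_per_gen, n_snp_per_chrom = 30, n_chrom = 1,
                    seed = seed)
  d <- simulate_dataset(cfg)
  A <- build_A(d$ped)
  Hinv <- solve(A)
  dimnames(Hinv) <- dimnames(A)
  std <- age_standardizer(min(d$records$age), max(d$records$age))
  list(sys = assemble_mme(d$records, std, Hinv),
       vc = rr_varcomp(cfg$genetic_cov, cfg$pe_cov, cfg$resid_var),
       data = d)
}

test_that("MME solutions equal direct GLS on a small instance", {
  s <- make_small_system()
  sol <- solve_mme(s$sys, s$vc)
  oracle <- gls_oracle(s$sys, s$vc)
  expect_equal(as.numeric(sol$b), oracle$b, tolerance = 1e-8)
  expect_equal(unname(sol$U), oracle$U, tolerance = 1e-8)
  expect_equal(unname(sol$PE), oracle$PE, tolerance = 1e-8)
})

test_that("5-animal toy pedigree with hand-assembled H matches GLS to 1e-10", {
  set.seed(33)
  ped <- data.frame(animal = 1:5, sire = c(0, 0, 1, 1, 3),
                    dam = c(0, 0, 2, 2, 4))
  A <- build_A(ped)
  codes <- matrix(rbinom(100, 2, 0.5), 5, 20)
  codes[1, ] <- c(rep(0:2, 7)[1:20])
  rownames(codes) <- 1:5
  geno <- toy_geno(codes)
  keep <- colMeans(codes) / 2; keep <- keep > 0 & keep < 1
  geno <- genotype_matrix(codes[, keep], geno$map[keep, ])
  G <- build_G(geno)
  kin <- blend_and_invert(A, G, w = 0.95)
  records <- data.frame(animal = rep(1:5, each = 8),
                        age = rep(seq(90, 160, by = 10), 5))
  records$cg <- factor(rep(1:2, length.out = 40))
  records$parity <- factor(rep(1, 40))
  records$value <- rnorm(40, 100, 5)
  std <- age_standardizer(90, 160)
  sys <- assemble_mme(records, std, kin$Hinv)
  vc <- rr_varcomp(diag(c(4, 1, 0.25)), diag(c(2, 0.5, 0.1)), 4)
  sol <- solve_mme(sys, vc)
  oracle <- gls_oracle(sys, vc)
  expect_equal(as.numeric(sol$b), oracle$b, tolerance = 1e-10)
  expect_equal(unname(sol$U), oracle$U, tolerance = 1e-10)
  expect_equal(unname(sol$PE), oracle$PE, tolerance = 1e-10)
})

test_that("shrinkage limits behave as expected", {
  s <- make_small_system(seed = 22)
  # vanishing genetic variance: all u -> 0
  vc0 <- rr_varcomp(diag(3) * 1e-8, s$vc$P, s$vc$se)
  sol0 <- solve_mme(s$sys, vc0)
  expect_lt(max(abs(sol0$U)), 1e-5)
  # zero phenotypes: all random solutions zero
  d <- s$data
  rec0 <- d$records; rec0$value <- 0
  sys0 <- assemble_mme(rec0, age_standardizer(min(rec0$age), max(rec0$age)),
                       s$sys$Hinv)
  solz <- solve_mme(sys0, s$vc)
  expect_equal(max(abs(solz$U)), 0, tolerance = 1e-12)
  expect_equal(max(abs(solz$PE)), 0, tolerance = 1e-12)
})

test_that("solutions are invariant to record order and consistent under
           record duplication", {
  s <- make_small_system(seed = 23)
  d <- s$data
  std <- age_standardizer(min(d$records$age), max(d$records$age))
  perm <- sample(nrow(d$records))
  sys_p <- assemble_mme(d$records[perm, ], std, s$sys$Hinv)
  sol <- solve_mme(s$sys, s$vc)
  sol_p <- solve_mme(sys_p, s$vc)
  expect_equal(sol$U, sol_p$U, tolerance = 1e-9)
  expect_equal(sol$b, sol_p$b, tolerance = 1e-9)

  # duplicating every record at halved residual variance leaves solutions
  # unchanged (sufficiency of the cross-products)
  dup <- rbind(d$records, d$records)
  sys_d <- assemble_mme(dup, std, s$sys$Hinv)
  vc_half <- rr_varcomp(s$vc$Ga, s$vc$P, s$vc$se / 2)
  # same information matrix per unit variance: W'W doubles, se halves in the
  # penalty -> lambda doubles too, so solutions coincide
  sol_d <- solve_mme(sys_d, s$vc)
  sol_h <- solve_mme(s$sys, vc_half)
  expect_equal(sol_d$U, sol_h$U, tolerance = 1e-9)
})

test_that("near-infinite genetic variance approaches the per-animal least
           squares fit for a phenotyped founder", {
  set.seed(41)
  ped <- data.frame(animal = 1:2, sire = 0L, dam = 0L)
  A <- build_A(ped)
  Hinv <- solve(A); dimnames(Hinv) <- dimnames(A)
  ages <- seq(90, 170, by = 5)
  records <- data.frame(animal = rep(1:2, each = length(ages)),
                        age = rep(ages, 2),
                        cg = factor(1), parity = factor(1))
  records$value <- rnorm(nrow(records), 100, 10)
  std <- age_standardizer(90, 170)
  sys <- assemble_mme(records, std, Hinv)
  vc <- rr_varcomp(diag(3) * 1e6, diag(3) * 1e-8, 1)
  sol <- solve_mme(sys, vc)
  # direct least squares on (intercept-adjusted) records per animal
  Phi <- legendre_matrix(standardize_age(records$age, std))
  X <- cbind(sys$X[, "(Intercept)"], Phi[, 2:3])
  for (a in 1:2) {
    rows <- records$animal == a
    resid <- records$value - as.numeric(sys$X %*% sol$b)
    ls <- qr.solve(Phi[rows, ], resid[rows])
    expect_equal(unname(sol$U[a, ]), as.numeric(ls), tolerance = 1e-3)
  }
})

test_that("rank-deficient fixed designs are rejected", {
  s <- make_small_system(seed = 24)
  rec <- s$data$records
  rec$parity <- rec$cg   # perfectly confounded factors
  expect_error(assemble_mme(rec, age_standardizer(min(rec$age), max(rec$age)),
                            s$sys$Hinv), "rank-deficient")
})
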