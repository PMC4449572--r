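test_that("window counts follow m - 9 per chromosome and small chromosomes
           yield none", {
  set.seed(71)
  codes <- matrix(rbinom(40 * 130, 2, 0.5), 40, 130)
  rownames(codes) <- 1:40
  geno <- toy_geno(codes, chrom = c(rep(1L, 100), rep(2L, 25), rep(3L, 5)))
  eff <- toy_effects(matrix(rnorm(130 * 3, 0, 0.1), 130, 3), geno)
  expect_message(scan <- scan_windows(geno, eff), "chromosome 3")
  w <- scan$windows
  expect_equal(sum(w$chrom == 1), 91)
  expect_equal(sum(w$chrom == 2), 16)
  expect_equal(sum(w$chrom == 3), 0)
  expect_true(all(w$end - w$start == 9))
})

test_that("genotypically identical animals give zero window variance", {
  codes <- matrix(rep(rep(c(0L, 1L, 2L), length.out = 20), each = 10), 10, 20)
  rownames(codes) <- 1:10
  geno <- toy_geno(codes)
  eff <- toy_effects(matrix(1, 20, 3), geno)
  eff$p <- rep(0.4, 20)
  scan <- scan_windows(geno, eff)
  expect_equal(max(scan$windows$var0), 0, tolerance = 1e-14)
})

test_that("non-overlapping tiling windows telescope to the total genomic
           value", {
  set.seed(72)
  codes <- matrix(rbinom(30 * 50, 2, 0.4), 30, 50)
  rownames(codes) <- 1:30
  poly <- colMeans(codes) / 2
  codes[1, poly == 0] <- 1L
  geno <- toy_geno(codes)
  u <- matrix(rnorm(50 * 3), 50, 3)
  eff <- toy_effects(u, geno)
  scan <- scan_windows(geno, eff, window_size = 10, step = 10)
  expect_equal(nrow(scan$windows), 5)
  Z <- rrgwas:::centered_genotypes(geno, list(p = eff$p))
  for (k in 1:3) {
    total <- unname(rowSums(scan$wgebv[[k]]))
    expect_equal(total, as.numeric(Z %*% u[, k]), tolerance = 1e-10)
  }
})

test_that("stage-1 keeps exactly the top 5% and degenerate merges give one
           flagged region", {
  set.seed(73)
  v <- runif(1000)
  # synthetic scan object: 1000 windows on one chromosome
  w <- data.frame(window = 1:1000, chrom = 1L, start = 1:1000,
                  end = (1:1000) + 9L, start_pos = (1:1000) * 1e3,
                  end_pos = ((1:1000) + 9) * 1e3,
                  var0 = v, var1 = runif(1000), var2 = runif(1000))
  scan <- structure(list(windows = w, wgebv = NULL, window_size = 10,
                         step = 1), class = "window_scan")
  reg <- putative_qtl(scan)
  members0 <- unlist(strsplit(reg$members[reg$coeff == 0], ";"))
  expect_equal(length(unique(members0)), 50)

  # 50 mutually overlapping survivors merge into one flagged region
  w2 <- w
  w2$var0 <- 0; w2$var0[300:349] <- 10 + runif(50)
  scan2 <- structure(list(windows = w2, wgebv = NULL, window_size = 10,
                          step = 1), class = "window_scan")
  reg2 <- putative_qtl(scan2)
  r0 <- reg2[reg2$coeff == 0, ]
  expect_equal(nrow(r0), 1)
  expect_true(all(r0$putative))
})

test_that("two well-separated variance peaks yield exactly two aggregated
           regions and the higher peak is flagged first", {
  set.seed(76)
  w <- data.frame(window = 1:1000, chrom = 1L, start = 1:1000,
                  end = (1:1000) + 9L, start_pos = (1:1000) * 1e3,
                  end_pos = ((1:1000) + 9) * 1e3,
                  var0 = 0, var1 = 0, var2 = 0)
  # two runs of 25 elevated windows: exactly the top-5% survivors of 1000
  w$var0[101:125] <- 5 + runif(25)
  w$var0[701:725] <- 6 + runif(25)
  w$var1 <- runif(1000); w$var2 <- runif(1000)
  scan <- structure(list(windows = w, wgebv = NULL, window_size = 10,
                         step = 1), class = "window_scan")
  reg <- putative_qtl(scan)
  r0 <- reg[reg$coeff == 0, ]
  expect_equal(nrow(r0), 2)
  expect_setequal(r0$start, c(101, 701))
  # ceiling(0.10 * 2) = 1 region flagged: the one with the higher peak
  expect_equal(sum(r0$putative), 1)
  expect_equal(r0$start[r0$putative], 701)
  # a permissive stage-2 fraction flags both
  reg_all <- putative_qtl(scan, top_region_frac = 1)
  expect_true(all(reg_all$putative[reg_all$coeff == 0]))
})

test_that("selection is invariant to chromosome processing order", {
  set.seed(74)
  codes <- matrix(rbinom(30 * 60, 2, 0.4), 30, 60)
  rownames(codes) <- 1:30
  poly <- colMeans(codes) / 2
  codes[1, poly == 0] <- 1L; codes[1, poly == 1] <- 1L
  chrom <- c(rep(1L, 30), rep(2L, 30))
  geno <- toy_geno(codes, chrom = chrom)
  u <- matrix(rnorm(60 * 3), 60, 3)
  eff <- toy_effects(u, geno)
  reg <- putative_qtl(scan_windows(geno, eff))
  # reverse chromosome order
  idx <- c(31:60, 1:30)
  geno2 <- toy_geno(codes[, idx], chrom = chrom)  # chrom labels now 1<-old2
  eff2 <- toy_effects(u[idx, ], geno2)
  reg2 <- putative_qtl(scan_windows(geno2, eff2))
  expect_equal(sort(reg2$peak_var), sort(reg$peak_var), tolerance = 1e-12)
})

test_that("cross-coefficient window correlations behave under equality and
           sign flips", {
  set.seed(75)
  codes <- matrix(rbinom(40 * 30, 2, 0.4), 40, 30)
  rownames(codes) <- 1:40
  poly <- colMeans(codes) / 2
  codes[1, poly == 0] <- 1L; codes[1, poly == 1] <- 1L
  geno <- toy_geno(codes)
  u <- rnorm(30)
  eff <- toy_effects(cbind(u, u, -u), geno)
  scan <- scan_windows(geno, eff)
  wc <- window_covariance(scan)
  expect_equal(wc$mean_cor[1, 2], 1, tolerance = 1e-10)
  expect_equal(wc$mean_cor[1, 3], -1, tolerance = 1e-10)
  expect_equal(wc$mean_cor[1, 1], 1, tolerance = 1e-10)
})
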