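# body-weight series on a known quadratic growth curve
make_weight_records <- function(n_animals = 8, adg = 1.0, seed = 81,
                                noise = 0.5, quad = 0.002) {
  set.seed(seed)
  out <- list()
  for (a in seq_len(n_animals)) {
    ages <- seq(90, 170, by = 5)
    day <- ages - ages[1]
    w <- 40 + adg * day + quad * day^2 + rnorm(length(ages), 0, noise)
    out[[a]] <- data.frame(animal = a, age = ages, weight = w)
  }
  do.call(rbind, out)
}

test_that("a perfectly quadratic weight series gets unit weights and no
           removals", {
  rec <- make_weight_records(n_animals = 3, noise = 0)
  ed <- edit_body_weight(rec)
  expect_equal(nrow(ed$records), nrow(rec))
  expect_equal(ed$report$rules$removed[1], 0)
})

test_that("a gross outlier is removed and the slope is barely disturbed", {
  rec <- make_weight_records(n_animals = 6, adg = 1.0)
  slope_clean <- coef(lm(weight ~ age, rec[rec$animal == 1, ]))[["age"]]
  rec$weight[rec$animal == 1][8] <- rec$weight[rec$animal == 1][8] * 10
  ed <- edit_body_weight(rec)
  kept1 <- ed$records[ed$records$animal == 1, ]
  expect_equal(nrow(kept1), 16)   # 17 records, 1 dropped
  slope_edited <- coef(lm(value ~ age, kept1))[["age"]]
  expect_equal(slope_edited, slope_clean, tolerance = 0.01)
})

test_that("own bisquare IRLS classifies the outlier like MASS::rlm", {
  skip_if_not_installed("MASS")
  rec <- make_weight_records(n_animals = 1, adg = 1.0, seed = 83)
  y <- rec$weight; y[10] <- y[10] + 60
  day <- rec$age - min(rec$age)
  X <- cbind(1, day, day^2)
  ours <- rrgwas:::.irls_bisquare(X, y)
  # psi.bisquare's default tuning constant is the same 4.685; X already
  # carries an explicit intercept column
  mfit <- MASS::rlm(X, y, psi = MASS::psi.bisquare, maxit = 50)
  expect_lt(ours$weights[10], 0.5)
  expect_lt(mfit$w[10], 0.5)
  expect_equal(which(ours$weights < 0.5), which(mfit$w < 0.5))
})

test_that("animals with on-test ADG outside [0.4, 2.0] kg/d are removed", {
  rec <- rbind(make_weight_records(n_animals = 2, adg = 1.0, seed = 84),
               transform(make_weight_records(1, adg = 0.3, seed = 85,
                                             quad = 0),
                         animal = 99L))
  ed <- edit_body_weight(rec)
  expect_false(99 %in% ed$records$animal)
  expect_true(all(1:2 %in% ed$records$animal))
  expect_true("99" %in% ed$report$detail$animals_removed_adg)
})

test_that("same-day weights are averaged and editing is idempotent", {
  rec <- make_weight_records(n_animals = 3, seed = 86, noise = 0)
  dup <- rec[rec$animal == 1 & rec$age == 100, ]
  dup$weight <- dup$weight + 0.4
  rec <- rbind(rec, dup)
  ed <- edit_body_weight(rec)
  r1 <- ed$records[ed$records$animal == 1 & ed$records$age == 100, ]
  expect_equal(nrow(r1), 1)
  # second pass changes nothing
  rec2 <- ed$records
  names(rec2)[names(rec2) == "value"] <- "weight"
  ed2 <- edit_body_weight(rec2)
  expect_equal(ed2$records$value, ed$records$value, tolerance = 1e-12)
})

# visit-level feed intake with a known amount hidden in flagged visits
make_visits <- function(n_animals = 30, n_days = 30, loss_per_flag = 0.8,
                        seed = 87, flag_prob = 0.2) {
  set.seed(seed)
  out <- list()
  for (a in seq_len(n_animals)) {
    base <- 2.5 + rnorm(1, 0, 0.3)       # animal-level intake
    for (d in seq_len(n_days)) {
      age <- 89 + d
      total <- base + rnorm(1, 0, 0.15)  # true daily intake
      flagged <- runif(1) < flag_prob
      if (flagged) {
        out[[length(out) + 1L]] <- data.frame(
          animal = a, age = age, intake = total - loss_per_flag,
          flag_big = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          animal = a, age = age, intake = loss_per_flag, flag_big = TRUE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          animal = a, age = age, intake = total, flag_big = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

make_covariates <- function(visits) {
  ad <- unique(visits[c("animal", "age")])
  ad$cg <- factor(((ad$animal - 1) %% 3) + 1)
  ad$body_weight <- 40 + (ad$age - 90) * 1.0
  ad$adg <- 1.0
  ad$parity <- factor(1 + (ad$animal %% 3))
  ad
}

test_that("with no flagged visits the adjusted intake equals the raw daily
           sum", {
  v <- make_visits(flag_prob = 0, n_animals = 10, n_days = 25)
  adj <- adjust_daily_feed_intake(v, make_covariates(v))
  raw <- tapply(v$intake, interaction(v$animal, v$age, drop = TRUE), sum)
  got <- adj$records$value[match(names(raw),
           interaction(adj$records$animal, adj$records$age, drop = TRUE))]
  expect_equal(unname(got), unname(as.numeric(raw)), tolerance = 1e-10)
})

test_that("animals with fewer than 20 daily records are removed", {
  v <- make_visits(flag_prob = 0, n_animals = 10, n_days = 25)
  v <- v[!(v$animal == 7 & v$age > 108), ]   # animal 7 keeps 19 days
  adj <- adjust_daily_feed_intake(v, make_covariates(v))
  expect_false(7 %in% adj$records$animal)
  expect_true(all(setdiff(1:10, 7) %in% adj$records$animal))
  expect_true("7" %in% adj$report$detail$animals_removed)
})

test_that("the adjustment recovers a known per-flag intake loss and never
           decreases a daily value", {
  loss <- 0.8
  v <- make_visits(loss_per_flag = loss, n_animals = 40, n_days = 30)
  adj <- adjust_daily_feed_intake(v, make_covariates(v))
  co <- adj$report$detail$adjustment_coefficients
  est_loss <- -co[["n_big"]]
  # recovered within 2 standard errors (residual sd ~0.15 over ~1200 days)
  expect_equal(est_loss, loss, tolerance = 0.15)
  # adjusted value never below the error-free daily sum
  clean <- v[!v$flag_big, ]
  raw <- tapply(clean$intake, interaction(clean$animal, clean$age, drop = TRUE), sum)
  idx <- match(interaction(adj$records$animal, adj$records$age, drop = TRUE),
               names(raw))
  expect_true(all(adj$records$value >= as.numeric(raw)[idx] - 1e-10))
})

test_that("genotype QC applies the filters in order and is idempotent", {
  set.seed(88)
  codes <- matrix(rbinom(200 * 40, 2, 0.35), 200, 40)
  rownames(codes) <- 1:200
  # HWE-consistent polymorphic matrix passes unchanged
  geno <- toy_geno(codes)
  qc <- qc_genotypes(geno)
  expect_equal(dim(qc$codes), dim(codes))

  # monomorphic SNP removed by the MAF filter
  codes2 <- codes; codes2[, 5] <- 0L
  qc2 <- qc_genotypes(toy_geno(codes2))
  expect_equal(ncol(qc2$codes), 39)
  expect_equal(attr(qc2, "report")$rules$removed[3], 1)

  # (AA, Aa, aa) = (50, 0, 50): chi-square = n, p << 1e-4 -> removed by HWE
  codes3 <- codes[1:100, ]
  codes3[, 8] <- rep(c(0L, 2L), each = 50)
  qc3 <- qc_genotypes(toy_geno(codes3))
  expect_equal(attr(qc3, "report")$rules$removed[4], 1)
  expect_false("s8" %in% qc3$map$snp)

  # low-call-rate animal and SNP removed
  codes4 <- codes
  codes4[3, 1:20] <- NA_integer_      # animal 3: call rate 0.5
  codes4[-3, 7] <- NA_integer_        # snp 7 call rate ~0
  qc4 <- qc_genotypes(toy_geno(codes4))
  expect_false("3" %in% rownames(qc4$codes))
  expect_false("s7" %in% qc4$map$snp)

  # idempotence
  qc5 <- qc_genotypes(qc)
  expect_identical(qc5$codes, qc$codes)
})
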