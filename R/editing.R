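## Longitudinal phenotype editing: visit-error adjustment of daily feed
## intake and robust bisquare-weight cleaning of body weight, plus genotype
## quality control.  The per-visit error criteria are a configurable rule
## registry; the count of triggered rules per visit feeds the adjustment
## model as covariates.

#' Default visit-error rule registry
#'
#' Each rule is a function of the visit table returning a logical flag per
#' visit.  Shipped rules: implausibly large intake, negative intake, and
#' occupancy-time bounds (when a `duration` column in minutes is present).
#'
#' @param max_intake upper bound on a single-visit intake (kg).
#' @param max_duration,min_duration occupancy-time bounds (minutes).
#' @return named list of rule functions.
#' @export
default_visit_rules <- function(max_intake = 2, max_duration = 60,
                                min_duration = 0) {
  list(
    intake_high = function(v) v$intake > max_intake,
    intake_negative = function(v) v$intake < 0,
    duration_out = function(v) {
      if (!"duration" %in% names(v)) return(rep(FALSE, nrow(v)))
      v$duration > max_duration | v$duration < min_duration
    }
  )
}

#' Flag visits against an error-rule registry
#'
#' @param visits data frame with at least `animal`, `age`, `intake`.
#' @param rules named list of rule functions (see [default_visit_rules()]).
#' @return `visits` with one logical `flag_<rule>` column per rule.
#' @export
flag_visits <- function(visits, rules = default_visit_rules()) {
  stopifnot(all(c("animal", "age", "intake") %in% names(visits)))
  for (nm in names(rules)) {
    visits[[paste0("flag_", nm)]] <- as.logical(rules[[nm]](visits))
  }
  visits
}

#' Visit-error adjustment of daily feed intake
#'
#' Four steps: (1) error-flagged visits are excluded; (2) error-free intake
#' is summed per animal-day; (3) a linear mixed model of daily error-free
#' intake on per-day error counts, contemporary group, body weight and
#' average daily gain with a random animal intercept estimates the intake
#' lost per flagged visit; (4) each animal-day is adjusted upward by the
#' estimated loss.  Animals with fewer than `min_days` adjusted daily
#' records are removed.
#'
#' @param visits flagged visit table (see [flag_visits()]).
#' @param covariates data frame with `animal`, `age`, `cg`, `body_weight`,
#'   `adg`, `parity` (per animal-day; `parity` is carried through).
#' @param min_days minimum adjusted daily records per animal (default 20).
#' @return list with `records` (data frame `animal, age, value, cg, parity`)
#'   and `report` (an edit report, see [edit_report()]).
#' @export
adjust_daily_feed_intake <- function(visits, covariates, min_days = 20) {
  flags <- grep("^flag_", names(visits), value = TRUE)
  if (length(flags) == 0L)
    stop("visits carry no flag_ columns: run flag_visits() first")
  if (length(unique(visits$animal)) < 2L)
    stop("fewer than 2 animals: adjustment model cannot be fitted")
  counts_in <- nrow(visits)

  any_flag <- Reduce(`|`, lapply(flags, function(f) visits[[f]]))
  clean <- visits[!any_flag, , drop = FALSE]

  key <- interaction(visits$animal, visits$age, drop = TRUE)
  daily <- data.frame(animal = tapply(visits$animal, key, `[`, 1L),
                      age = tapply(visits$age, key, `[`, 1L))
  ckey <- interaction(clean$animal, clean$age, drop = TRUE)
  dfi <- tapply(clean$intake, ckey, sum)
  daily$dfi_ef <- as.numeric(dfi[match(levels(key), names(dfi))])
  daily$dfi_ef[is.na(daily$dfi_ef)] <- 0
  for (f in flags) {
    cnt <- tapply(visits[[f]], key, sum)
    daily[[sub("^flag_", "n_", f)]] <- as.numeric(cnt[match(levels(key),
                                                            names(cnt))])
  }
  daily <- merge(daily, covariates, by = c("animal", "age"))
  if (nrow(daily) == 0L) stop("no animal-days left after merging covariates")

  nvars <- sub("^flag_", "n_", flags)
  used <- nvars[vapply(nvars, function(v) stats::var(daily[[v]]) > 0,
                       logical(1))]
  form <- stats::as.formula(paste(
    "dfi_ef ~", paste(c(used, "factor(cg)", "body_weight", "adg"),
                      collapse = " + "), "+ (1 | animal)"))
  fit <- tryCatch(lme4::lmer(form, data = daily, REML = TRUE),
                  error = function(e)
                    stop("adjustment model failed (singular design?): ",
                         conditionMessage(e)))
  beta <- lme4::fixef(fit)

  loss <- rep(0, nrow(daily))
  for (v in used) loss <- loss - beta[[v]] * daily[[v]]
  daily$value <- daily$dfi_ef + pmax(loss, 0)

  n_per_animal <- table(daily$animal)
  keep <- names(n_per_animal)[n_per_animal >= min_days]
  removed_animals <- setdiff(names(n_per_animal), keep)
  out <- daily[daily$animal %in% keep,
               c("animal", "age", "value", "cg", "parity")]
  rownames(out) <- NULL

  rep_ <- edit_report(
    rules = data.frame(
      rule = c("visit_error_flagged", "min_daily_records"),
      records_in = c(counts_in, length(levels(key))),
      records_out = c(nrow(clean), nrow(out)),
      removed = c(counts_in - nrow(clean), length(levels(key)) - nrow(out))),
    detail = list(adjustment_coefficients = beta[used],
                  adjustment_se = sqrt(diag(as.matrix(stats::vcov(fit))))[
                    match(used, names(beta))],
                  animals_removed = removed_animals))
  list(records = out, report = rep_)
}

# iteratively reweighted least squares with Tukey's bisquare weights;
# zero-residual series (scale ~ 0) get unit weights by convention
.irls_bisquare <- function(X, y, c = 4.685, tol = 1e-6, max_iter = 50) {
  w <- rep(1, length(y))
  qx <- qr(X)
  keep <- qx$pivot[seq_len(qx$rank)]
  X <- X[, keep, drop = FALSE]
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.wfit(X, y, w)
    r <- y - X %*% fit$coefficients
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-10 * max(abs(y), 1)) return(list(weights = rep(1, length(y)),
                                                coef = fit$coefficients))
    u <- pmin(abs(r / (c * s)), 1)
    w_new <- as.numeric((1 - u^2)^2)
    if (max(abs(w_new - w)) < tol)
      return(list(weights = w_new, coef = fit$coefficients))
    w <- w_new
  }
  list(weights = w, coef = fit$coefficients)
}

#' Robust-regression editing of body weight
#'
#' Per animal: an iteratively reweighted bisquare robust fit of weight on a
#' quadratic in on-test day (the linear on-test age term is absorbed into
#' the per-animal design, with which it is collinear); records with bisquare
#' weight below `weight_cut` are removed.  On-test average daily gain is
#' then the ordinary least-squares slope of the surviving weights on age;
#' animals with ADG outside `adg_bounds` are removed.  Surviving same-day
#' weights are averaged.
#'
#' @param records data frame with `animal`, `age`, `weight` and optionally
#'   `cg`, `parity` (carried through).
#' @param adg_bounds admissible on-test ADG range in kg/d (default
#'   `c(0.4, 2.0)`).
#' @param weight_cut bisquare weight below which a record is an outlier
#'   (default 0.5).
#' @param min_records minimum records per animal for the robust fit
#'   (default 3).
#' @return list with `records` (`animal, age, value, cg, parity`; `value` is
#'   the day-averaged weight) and `report`.
#' @export
edit_body_weight <- function(records, adg_bounds = c(0.4, 2.0),
                             weight_cut = 0.5, min_records = 3) {
  stopifnot(all(c("animal", "age", "weight") %in% names(records)))
  n_in <- nrow(records)
  keep_rows <- list(); adg_removed <- character(0); few_removed <- character(0)
  out_removed <- 0L
  for (a in unique(records$animal)) {
    ra <- records[records$animal == a, , drop = FALSE]
    if (nrow(ra) < min_records) { few_removed <- c(few_removed, as.character(a)); next }
    day <- ra$age - min(ra$age)
    X <- cbind(1, day, day^2, ra$age)
    rob <- .irls_bisquare(X, ra$weight)
    ok <- rob$weights >= weight_cut
    out_removed <- out_removed + sum(!ok)
    ra <- ra[ok, , drop = FALSE]
    if (nrow(ra) < 2L) { few_removed <- c(few_removed, as.character(a)); next }
    adg <- stats::coef(stats::lm(weight ~ age, data = ra))[["age"]]
    if (adg < adg_bounds[1] || adg > adg_bounds[2]) {
      adg_removed <- c(adg_removed, as.character(a)); next
    }
    keep_rows[[length(keep_rows) + 1L]] <- ra
  }
  if (length(keep_rows) == 0L) stop("no animals survive body-weight editing")
  kept <- do.call(rbind, keep_rows)
  key <- interaction(kept$animal, kept$age, drop = TRUE)
  out <- data.frame(animal = tapply(kept$animal, key, `[`, 1L),
                    age = tapply(kept$age, key, `[`, 1L),
                    value = as.numeric(tapply(kept$weight, key, mean)))
  for (cc in intersect(c("cg", "parity"), names(kept)))
    out[[cc]] <- tapply(kept[[cc]], key, `[`, 1L)
  out <- out[order(out$animal, out$age), ]
  rownames(out) <- NULL

  rep_ <- edit_report(
    rules = data.frame(
      rule = c("bisquare_weight", "adg_bounds", "too_few_records"),
      records_in = n_in,
      records_out = c(n_in - out_removed, nrow(kept), nrow(kept)),
      removed = c(out_removed, NA, NA)),
    detail = list(animals_removed_adg = adg_removed,
                  animals_removed_few = few_removed))
  list(records = out, report = rep_)
}

#' Edit report container
#'
#' @param rules data frame with per-rule in/out/removed counts.
#' @param detail free-form list of rule-specific detail.
#' @return object of class `"edit_report"`.
#' @export
edit_report <- function(rules, detail = list()) {
  structure(list(rules = rules, detail = detail), class = "edit_report")
}

#' @export
print.edit_report <- function(x, ...) {
  cat("Edit report:\n"); print(x$rules, row.names = FALSE)
  invisible(x)
}

#' Genotype quality control
#'
#' Filter order: animal call rate, SNP call rate, minor allele frequency,
#' Hardy-Weinberg chi-square, then a second (analysis-subset) MAF filter.
#' Remaining missing genotypes are mean-imputed to the nearest integer code
#' (the synthetic data are complete, so this is a no-op there).
#'
#' @param geno a [genotype_matrix()] (may contain NA).
#' @param animal_call_rate,snp_call_rate keep thresholds (strictly greater
#'   than; default 0.90).
#' @param maf first MAF removal threshold (`<=`, default 0.02).
#' @param hwe_p Hardy-Weinberg chi-square p-value removal threshold
#'   (`<`, default 1e-4).
#' @param maf2 second, analysis-subset MAF removal threshold (`<`,
#'   default 0.002).
#' @return filtered [genotype_matrix()] with an `"edit_report"` attribute.
#' @export
qc_genotypes <- function(geno, animal_call_rate = 0.90, snp_call_rate = 0.90,
                         maf = 0.02, hwe_p = 1e-4, maf2 = 0.002) {
  stopifnot(inherits(geno, "genotype_matrix"))
  codes <- geno$codes; map <- geno$map
  n0 <- nrow(codes); m0 <- ncol(codes)

  acr <- rowMeans(!is.na(codes))
  codes <- codes[acr > animal_call_rate, , drop = FALSE]
  n_acr <- n0 - nrow(codes)

  scr <- colMeans(!is.na(codes))
  keep <- scr > snp_call_rate
  codes <- codes[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  n_scr <- sum(!keep)

  p <- colMeans(codes, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  keep <- mafs > maf
  codes <- codes[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  n_maf <- sum(!keep)

  hwe <- apply(codes, 2L, function(g) {
    g <- g[!is.na(g)]
    n <- length(g); pj <- mean(g) / 2
    obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    ex <- n * c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    if (any(ex == 0)) return(0)  # monomorphic: caught by MAF already
    stats::pchisq(sum((obs - ex)^2 / ex), df = 1, lower.tail = FALSE)
  })
  keep <- hwe >= hwe_p
  codes <- codes[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  n_hwe <- sum(!keep)

  p <- colMeans(codes, na.rm = TRUE) / 2
  keep <- pmin(p, 1 - p) >= maf2
  codes <- codes[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  n_maf2 <- sum(!keep)

  if (nrow(codes) == 0L || ncol(codes) == 0L)
    stop("genotype QC removed everything")
  if (anyNA(codes)) {
    for (j in which(colSums(is.na(codes)) > 0)) {
      codes[is.na(codes[, j]), j] <- as.integer(round(mean(codes[, j],
                                                           na.rm = TRUE)))
    }
  }
  out <- genotype_matrix(codes, map)
  attr(out, "report") <- edit_report(
    rules = data.frame(
      rule = c("animal_call_rate", "snp_call_rate", "maf", "hwe",
               "maf_analysis"),
      removed = c(n_acr, n_scr, n_maf, n_hwe, n_maf2)),
    detail = list(n_animals = nrow(codes), n_snp = ncol(codes)))
  out
}
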