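#' Run the full trajectory-GWAS pipeline
#'
#' Drives every stage on simulated or supplied data: genotype QC, the
#' random-regression GBLUP fit (EM-REML unless components are supplied),
#' iteratively reweighted SNP back-solving, the 10-SNP sliding-window scan,
#' two-stage putative-QTL selection, the bootstrap significance test and
#' variance-explained reporting.  Every stage's artifact is serialized as
#' plain text under `out_dir` together with a provenance manifest, and a
#' rerun with the same configuration and seed reproduces the archive
#' byte-for-byte.
#'
#' @param config list with either `sim` (a [sim_config()]) or input paths
#'   (`pedigree_csv`, `genotypes_csv`, `map_csv`, `phenotypes_csv`), plus
#'   optional analysis settings: `vc` ([rr_varcomp()] to skip REML),
#'   `blend_weight` (default 0.995), `n_reweight` (default 2),
#'   `window_size` (10), `top_window_frac` (0.05), `top_region_frac` (0.10),
#'   `n_reps` (bootstrap replicates; 0 skips the bootstrap), `alpha`
#'   (0.001), `seed`, `reml_tol`, `reml_max_iter`, `qc` (logical).
#' @param out_dir output directory (created if missing); `NULL` for no
#'   serialization.
#' @param verbose print per-stage progress.
#' @return list with every stage's object (`data`, `fit`, `effects`,
#'   `scan`, `regions`, `boot`, `varexp`, `cor_table`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  get_ <- function(nm, default) if (!is.null(config[[nm]])) config[[nm]] else default
  seed <- get_("seed", 1L)

  if (!is.null(config$sim)) {
    say("stage simulate: generating synthetic data")
    data <- simulate_dataset(config$sim)
  } else {
    say("stage load: reading input files")
    data <- list(ped = read_pedigree_csv(config$pedigree_csv),
                 geno = read_genotypes_csv(config$genotypes_csv,
                                           config$map_csv),
                 records = read_phenotypes_csv(config$phenotypes_csv),
                 truth = NULL)
  }

  geno <- data$geno
  if (isTRUE(get_("qc", TRUE))) {
    say("stage qc: genotype quality control")
    geno <- qc_genotypes(geno)
  }

  say("stage fit: random-regression GBLUP",
      if (is.null(config$vc)) " with EM-REML" else " at supplied components")
  fit <- rr_gblup(data$records, data$ped, geno,
                  vc = config$vc, reml = is.null(config$vc),
                  blend_weight = get_("blend_weight", 0.995),
                  tol = get_("reml_tol", 1e-6),
                  max_iter = get_("reml_max_iter", 500),
                  verbose = FALSE)

  say("stage gwas: back-solving SNP effects (",
      get_("n_reweight", 2), " reweighting rounds)")
  effects <- snp_effects(fit, n_reweight = get_("n_reweight", 2))

  say("stage windows: sliding-window scan and putative-QTL selection")
  scan <- scan_windows(fit$kin$geno, effects,
                       window_size = get_("window_size", 10))
  regions <- putative_qtl(scan,
                          top_window_frac = get_("top_window_frac", 0.05),
                          top_region_frac = get_("top_region_frac", 0.10))

  n_reps <- get_("n_reps", 1000)
  boot <- NULL
  if (n_reps > 0) {
    say("stage bootstrap: ", n_reps, " replicates per putative region")
    boot <- bootstrap_windows(fit, effects, regions, n_reps = n_reps,
                              seed = seed, alpha = get_("alpha", 0.001))
    sig <- boot$results[boot$results$significant, , drop = FALSE]
  } else {
    say("stage bootstrap: skipped (n_reps = 0)")
    sig <- regions[regions$putative, , drop = FALSE]
  }

  say("stage report: variance explained and correlation tables")
  sig_regions <- if (!is.null(boot)) {
    merge(unique(sig[c("region", "coeff")]), regions,
          by = c("region", "coeff"))
  } else sig
  varexp <- variance_explained(fit$kin$geno, effects, sig_regions)
  cor_table <- gebv_correlation_table(list(fit), list(scan))

  manifest <- list(
    package_version = as.character(utils::packageVersion("rrgwas")),
    seed = seed,
    n_records = fit$sys$n, n_animals = fit$sys$p,
    n_genotyped = length(fit$kin$geno_ids),
    n_snp = ncol(fit$kin$geno$codes),
    blend_weight = fit$kin$w,
    n_reweight = effects$n_reweight,
    n_reps = n_reps)

  out <- list(data = data, fit = fit, effects = effects, scan = scan,
              regions = regions, boot = boot, varexp = varexp,
              cor_table = cor_table, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_archive(out, out_dir)
  out
}

#' Serialize a pipeline result as a plain-text archive
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir target directory.
#' @return invisibly, the data frame of written files and their MD5 sums.
#' @export
write_pipeline_archive <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  fmt <- function(df) {
    for (cc in names(df)) if (is.numeric(df[[cc]]) && !is.integer(df[[cc]]))
      df[[cc]] <- format(df[[cc]], digits = 15, trim = TRUE)
    df
  }
  write_pedigree_csv(result$data$ped, p("pedigree.csv"))
  write_phenotypes_csv(result$data$records, p("phenotypes.csv"))
  write_genotypes_csv(result$fit$kin$geno, p("genotypes.csv"), p("map.csv"))
  if (!is.null(result$data$truth))
    write_ground_truth_json(result$data$truth, p("ground_truth.json"))
  vc <- result$fit$vc
  jsonlite::write_json(list(Ga = vc$Ga, P = vc$P, se = vc$se,
                            age_min = result$fit$std$age_min,
                            age_max = result$fit$std$age_max),
                       p("variance_components.json"),
                       digits = NA, auto_unbox = TRUE)
  .write_csv(fmt(data.frame(effect = names(result$fit$fixed),
                            estimate = result$fit$fixed)),
             p("fixed_effects.csv"))
  .write_csv(fmt(data.frame(animal = rownames(result$fit$u), result$fit$u)),
             p("gebv_coefficients.csv"))
  .write_csv(fmt(as.data.frame(result$effects)), p("snp_effects.csv"))
  .write_csv(fmt(result$scan$windows), p("windows.csv"))
  .write_csv(fmt(result$regions), p("regions.csv"))
  write_regions_bed(result$regions, p("regions.bed"))
  if (!is.null(result$boot))
    .write_csv(fmt(result$boot$results), p("bootstrap.csv"))
  jsonlite::write_json(list(per_coeff = result$varexp$per_coeff,
                            trajectory_pct = result$varexp$trajectory_pct),
                       p("variance_explained.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  .write_csv(fmt(as.data.frame(result$cor_table)), p("correlation_table.csv"))
  jsonlite::write_json(result$manifest, p("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  files <- sort(list.files(out_dir, full.names = TRUE))
  invisible(data.frame(file = basename(files),
                       md5 = as.character(tools::md5sum(files))))
}

#' MD5 digest of a pipeline archive
#'
#' @param out_dir archive directory.
#' @return named character vector of per-file MD5 sums.
#' @export
archive_md5 <- function(out_dir) {
  files <- sort(list.files(out_dir, full.names = TRUE))
  sums <- as.character(tools::md5sum(files))
  names(sums) <- basename(files)
  sums
}
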