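## Variance-explained accounting, GEBV/WGEBV correlation tables and local
## gene-annotation intersection.

#' Percent of additive genomic variance explained by regions
#'
#' Per coefficient: numerator = sum over regions of the across-animal
#' variance of the region's genomic value `sum_{i in region} z_i u_hat_i`;
#' denominator = variance of the whole-genome genomic value `Z u_hat`;
#' times 100.  A trajectory-level summary pools numerator and denominator
#' across coefficients.
#'
#' @param geno a [genotype_matrix()].
#' @param effects a [snp_effects()] object.
#' @param regions data frame with `coeff`, `start`, `end` (global SNP index
#'   range); typically significant rows of a [bootstrap_windows()] result or
#'   [putative_qtl()] regions.  May be empty.
#' @return list with `per_coeff` (data frame: coefficient, number of
#'   regions, percent explained, denominator) and `trajectory_pct`.
#' @export
variance_explained <- function(geno, effects, regions) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(effects, "snp_effects"))
  Z <- centered_genotypes(geno, list(p = effects$p))
  per <- data.frame(coeff = 0:2, n_regions = 0L, pct = 0,
                    denominator = NA_real_)
  num_total <- 0; den_total <- 0
  for (k in 1:3) {
    den <- stats::var(as.numeric(Z %*% effects$effects[, k]))
    rk <- regions[regions$coeff == k - 1L, , drop = FALSE]
    num <- 0
    if (nrow(rk) > 0) {
      for (r in seq_len(nrow(rk))) {
        idx <- rk$start[r]:rk$end[r]
        num <- num + stats::var(as.numeric(Z[, idx, drop = FALSE] %*%
                                             effects$effects[idx, k]))
      }
    }
    per$n_regions[k] <- nrow(rk)
    per$pct[k] <- if (den > 0) 100 * num / den else 0
    per$denominator[k] <- den
    num_total <- num_total + num; den_total <- den_total + den
  }
  list(per_coeff = per,
       trajectory_pct = if (den_total > 0) 100 * num_total / den_total else 0)
}

#' GEBV / window-GEBV correlation table
#'
#' For one or two fitted traits: the upper triangle holds Pearson
#' correlations of per-coefficient GEBV vectors (on the common genotyped
#' animals), the lower triangle the genome-averaged per-window WGEBV
#' correlations, and the diagonal the per-coefficient variance-ratio
#' heritabilities `Ga[k,k] / (Ga[k,k] + P[k,k] + sigma_e^2)`.
#'
#' @param fits list of one or two [rr_gblup()] fits.
#' @param scans matching list of [scan_windows()] results.
#' @return square numeric matrix (3 x 3 per trait).
#' @export
gebv_correlation_table <- function(fits, scans) {
  stopifnot(length(fits) == length(scans), length(fits) %in% 1:2)
  nt <- length(fits)
  ids <- Reduce(intersect, lapply(fits, function(f) f$kin$geno_ids))
  if (length(ids) < 3) stop("fewer than 3 common genotyped animals")
  gebv <- do.call(cbind, lapply(fits, function(f) f$u[ids, , drop = FALSE]))
  wg <- unlist(lapply(scans, function(s) s$wgebv), recursive = FALSE)
  wrow <- lapply(seq_along(fits), function(tr)
    match(ids, scans[[tr]]$geno_ids))
  d <- 3 * nt
  lab <- paste0(rep(paste0("t", seq_len(nt)), each = 3), "_c", 0:2)
  out <- matrix(NA_real_, d, d, dimnames = list(lab, lab))
  for (i in seq_len(d)) {
    tr <- ceiling(i / 3); k <- (i - 1) %% 3 + 1
    vc <- fits[[tr]]$vc
    out[i, i] <- vc$Ga[k, k] / (vc$Ga[k, k] + vc$P[k, k] + vc$se)
    for (j in seq_len(d)) {
      if (j <= i) next
      si <- stats::sd(gebv[, i]); sj <- stats::sd(gebv[, j])
      out[i, j] <- if (si > 0 && sj > 0) stats::cor(gebv[, i], gebv[, j])
                   else NA_real_
      tr_j <- ceiling(j / 3); l <- (j - 1) %% 3 + 1
      Wi <- wg[[i]][wrow[[tr]], , drop = FALSE]
      Wj <- wg[[j]][wrow[[tr_j]], , drop = FALSE]
      nw <- min(ncol(Wi), ncol(Wj))
      cors <- vapply(seq_len(nw), function(w) {
        vi <- stats::var(Wi[, w]); vj <- stats::var(Wj[, w])
        if (vi > 0 && vj > 0) stats::cor(Wi[, w], Wj[, w]) else NA_real_
      }, numeric(1))
      out[j, i] <- mean(cors, na.rm = TRUE)
    }
  }
  out
}

#' Intersect QTL regions with a local gene annotation
#'
#' Reads a GFF3 or BED file (via rtracklayer) and reports genes overlapping
#' each region's base-pair span, plus the region's top SNP by per-SNP
#' variance `2 p q u_hat^2`.
#'
#' @param regions data frame with `region`, `coeff`, `chrom`, `start`,
#'   `end`, `start_pos`, `end_pos` (1-based inclusive bp span).
#' @param annotation_file path to a GFF3 (`.gff`, `.gff3`) or BED file on
#'   the same assembly as the SNP map.
#' @param effects a [snp_effects()] (for the top-SNP computation).
#' @param feature_type GFF3 feature type to keep (default `"gene"`; ignored
#'   for BED).
#' @return data frame with one row per region x overlapping gene (regions
#'   without overlap get a single `NA`-gene row), plus `top_snp`.
#' @export
annotate_regions <- function(regions, annotation_file, effects,
                             feature_type = "gene") {
  for (pkg in c("rtracklayer", "GenomicRanges", "IRanges", "S4Vectors"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("package ", pkg, " is required for annotation intersection")
  ann <- rtracklayer::import(annotation_file)
  if ("type" %in% names(S4Vectors::mcols(ann)) &&
      any(ann$type == feature_type)) {
    ann <- ann[ann$type == feature_type]
  }
  gname <- if ("Name" %in% names(S4Vectors::mcols(ann))) ann$Name
           else if ("name" %in% names(S4Vectors::mcols(ann))) ann$name
           else if ("ID" %in% names(S4Vectors::mcols(ann))) ann$ID
           else as.character(seq_along(ann))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(regions$chrom),
    ranges = IRanges::IRanges(start = regions$start_pos,
                              end = regions$end_pos))
  hits <- GenomicRanges::findOverlaps(gr, ann)
  out <- list()
  for (r in seq_len(nrow(regions))) {
    idx <- regions$start[r]:regions$end[r]
    k <- regions$coeff[r] + 1L
    pv <- 2 * effects$p[idx] * (1 - effects$p[idx]) *
      effects$effects[idx, k]^2
    top <- idx[which.max(pv)]
    gi <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == r]
    if (length(gi) == 0L) {
      out[[r]] <- data.frame(regions[r, c("region", "coeff", "chrom",
                                          "start_pos", "end_pos")],
                             gene = NA_character_,
                             gene_start = NA_real_, gene_end = NA_real_,
                             top_snp = effects$map$snp[top],
                             top_snp_var = pv[match(top, idx)])
    } else {
      out[[r]] <- data.frame(regions[r, c("region", "coeff", "chrom",
                                          "start_pos", "end_pos")],
                             gene = as.character(gname[gi]),
                             gene_start = GenomicRanges::start(ann)[gi],
                             gene_end = GenomicRanges::end(ann)[gi],
                             top_snp = effects$map$snp[top],
                             top_snp_var = pv[match(top, idx)])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (all(is.na(res$gene)) && nrow(res) > 0)
    warning("no region overlaps any annotation feature: assembly mismatch?")
  res
}
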