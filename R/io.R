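## Plain-text readers and writers: pedigree CSV, phenotype CSV, 0/1/2
## genotype matrix CSV with a chrom/pos map, PLINK-style .ped/.map, and
## ground-truth JSON.  All numeric output uses full precision so that
## round-trips and re-runs are byte-stable.

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a pedigree CSV (animal, sire, dam; 0 = unknown)
#' @param ped pedigree data frame.
#' @param path file path.
#' @export
write_pedigree_csv <- function(ped, path) {
  .write_csv(ped[c("animal", "sire", "dam")], path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  as_pedigree(utils::read.csv(path))
}

#' Write / read a phenotype CSV (animal, age_days, value, cg, parity)
#' @param records phenotype data frame.
#' @param path file path.
#' @export
write_phenotypes_csv <- function(records, path) {
  out <- data.frame(animal = records$animal, age_days = records$age,
                    value = format(records$value, digits = 15, trim = TRUE),
                    cg = as.character(records$cg),
                    parity = as.character(records$parity))
  .write_csv(out, path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  x <- utils::read.csv(path)
  data.frame(animal = x$animal, age = x$age_days, value = as.numeric(x$value),
             cg = factor(x$cg), parity = factor(x$parity))
}

#' Write / read a 0/1/2 genotype matrix CSV plus map CSV
#' @param geno a [genotype_matrix()].
#' @param path genotype CSV path (first column `animal`).
#' @param map_path map CSV path (`snp, chrom, pos`).
#' @export
write_genotypes_csv <- function(geno, path, map_path) {
  df <- data.frame(animal = rownames(geno$codes), geno$codes,
                   check.names = FALSE)
  .write_csv(df, path)
  .write_csv(geno$map, map_path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(path, map_path) {
  x <- utils::read.csv(path, check.names = FALSE)
  codes <- as.matrix(x[, -1, drop = FALSE])
  rownames(codes) <- x$animal
  genotype_matrix(codes, utils::read.csv(map_path))
}

#' Write / read PLINK-style .ped/.map text files
#'
#' Alleles are coded 1/2 (0 0 for missing); the .map holds chromosome, SNP
#' id, a zero genetic distance and the bp position.
#'
#' @param geno a [genotype_matrix()].
#' @param prefix path prefix; `.ped` and `.map` are appended.
#' @export
write_plink <- function(geno, prefix) {
  codes <- geno$codes
  n <- nrow(codes)
  a1 <- ifelse(is.na(codes), 0L, ifelse(codes >= 1L, 2L, 1L))
  a2 <- ifelse(is.na(codes), 0L, ifelse(codes == 2L, 2L, 1L))
  al <- matrix(0L, n, 2L * ncol(codes))
  al[, seq(1L, ncol(al), 2L)] <- a1
  al[, seq(2L, ncol(al), 2L)] <- a2
  ped <- cbind(1L, rownames(codes), 0L, 0L, 0L, -9L, al)
  utils::write.table(ped, paste0(prefix, ".ped"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  map <- data.frame(geno$map$chrom, geno$map$snp, 0, geno$map$pos)
  utils::write.table(map, paste0(prefix, ".map"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"),
                           col.names = c("chrom", "snp", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  storage.mode(al) <- "integer"
  a1 <- al[, seq(1L, ncol(al), 2L), drop = FALSE]
  a2 <- al[, seq(2L, ncol(al), 2L), drop = FALSE]
  codes <- (a1 == 2L) + (a2 == 2L)
  codes[a1 == 0L | a2 == 0L] <- NA_integer_
  rownames(codes) <- ids
  genotype_matrix(codes, map[c("snp", "chrom", "pos")])
}

#' Write ground truth as JSON
#' @param truth the `truth` element of [simulate_phenotypes()].
#' @param path file path.
#' @export
write_ground_truth_json <- function(truth, path) {
  x <- list(u_polygenic = truth$u_polygenic, g_total = truth$g_total,
            pe = truth$pe, qtl = truth$qtl,
            genetic_cov = truth$genetic_cov, pe_cov = truth$pe_cov,
            resid_var = truth$resid_var,
            age_min = truth$std$age_min, age_max = truth$std$age_max,
            cg_effects = truth$cg_effects,
            parity_effects = truth$parity_effects,
            mean_curve = truth$mean_curve, normalized = truth$normalized)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
}

#' Write regions as a BED file (0-based half-open)
#' @param regions region data frame (1-based inclusive bp spans).
#' @param path file path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start_pos - 1L,
                    end = regions$end_pos,
                    name = regions$region,
                    score = format(regions$peak_var, digits = 15, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}
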