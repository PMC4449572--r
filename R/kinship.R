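#' Genotype matrix container
#'
#' Wraps an animals x SNP matrix of 0/1/2 allele counts together with a genome
#' map (SNP id, chromosome, position).
#'
#' @param codes integer matrix, animals in rows (rownames = animal ids),
#'   SNP in columns; entries 0/1/2 or NA for missing.
#' @param map data frame with columns `snp`, `chrom`, `pos` (one row per SNP
#'   column, in column order).
#' @return object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(codes, map) {
  codes <- as.matrix(codes)
  stopifnot(!is.null(rownames(codes)),
            all(c("snp", "chrom", "pos") %in% names(map)),
            nrow(map) == ncol(codes))
  ok <- codes %in% c(0L, 1L, 2L) | is.na(codes)
  if (!all(ok)) stop("genotype codes must be 0/1/2 or NA")
  storage.mode(codes) <- "integer"
  colnames(codes) <- map$snp
  structure(list(codes = codes,
                 map = data.frame(snp = as.character(map$snp),
                                  chrom = map$chrom, pos = as.numeric(map$pos))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d animals x %d SNP on %d chromosome(s)\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Marker scaling: allele frequencies and diagonal weights
#'
#' Computes observed allele frequencies and the expected-marker-variance
#' weights `d_i = 1 / (m * 2 p_i q_i)`, so that `G = Z D Z'` with centered
#' gene content `Z = M - 2p` has mean diagonal close to 1 and
#' `sum(d_i * 2 p_i q_i) = 1`.
#'
#' @param geno a [genotype_matrix()] with no missing values.
#' @param freqs optional externally supplied allele frequencies.
#' @return list with elements `p` (allele frequency per SNP) and `d`
#'   (diagonal weight per SNP).
#' @export
marker_scaling <- function(geno, freqs = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (anyNA(geno$codes)) stop("missing genotypes: run qc/complete data first")
  p <- if (is.null(freqs)) colMeans(geno$codes) / 2 else as.numeric(freqs)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP present (p = 0 or 1): remove them before scaling")
  m <- ncol(geno$codes)
  list(p = p, d = 1 / (m * 2 * p * (1 - p)))
}

# centered gene content Z = M - 2p (animals x SNP, dense double)
centered_genotypes <- function(geno, scaling) {
  sweep(geno$codes + 0, 2L, 2 * scaling$p, `-`)
}

#' Genomic relationship matrix G = Z D Z'
#'
#' @inheritParams marker_scaling
#' @param scaling a [marker_scaling()] list; its `d` may carry realized
#'   (reweighted) marker variances during iterative SNP-effect estimation.
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
build_G <- function(geno, scaling = marker_scaling(geno)) {
  Z <- centered_genotypes(geno, scaling)
  G <- tcrossprod(sweep(Z, 2L, scaling$d, `*`), Z)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(geno$codes), rownames(geno$codes))
  G
}

#' Blend G with A22 and assemble the single-step H inverse
#'
#' `G_blended = w G + (1 - w) A22` (default w = 0.995), then
#' `H^-1 = A^-1 + [0 0; 0 G_blended^-1 - A22^-1]` on the genotyped block.
#'
#' @param A numerator relationship matrix (dimnames = animal ids).
#' @param G genomic relationship matrix for the genotyped animals
#'   (dimnames = animal ids, all of which must appear in `A`).
#' @param w blending weight on G (default 0.995).
#' @return list with `Hinv` (dense, all pedigree animals), `Gblend`,
#'   `A22`, `geno_ids` and `w`.
#' @export
blend_and_invert <- function(A, G, w = 0.995) {
  ids <- rownames(A)
  gid <- if (nrow(G) == 0L) character(0) else rownames(G)
  stopifnot(!is.null(ids), !(nrow(G) > 0L && is.null(gid)))
  idx <- match(gid, ids)
  if (anyNA(idx)) stop("genotyped animal absent from the pedigree matrix A")
  Ainv <- chol2inv(chol(A))
  Hinv <- Ainv
  if (length(idx) > 0L) {
    A22 <- A[idx, idx, drop = FALSE]
    Gb <- w * G + (1 - w) * A22
    Gbi <- tryCatch(chol2inv(chol(Gb)), error = function(e)
      stop("blended G is not positive definite (with w = 1 this needs ",
           "more SNP than genotyped animals): ", conditionMessage(e)))
    Hinv[idx, idx] <- Hinv[idx, idx] + Gbi - chol2inv(chol(A22))
  } else {
    A22 <- matrix(0, 0, 0)
    Gb <- matrix(0, 0, 0)
  }
  Hinv <- (Hinv + t(Hinv)) / 2
  dimnames(Hinv) <- list(ids, ids)
  list(Hinv = Hinv, Gblend = Gb, A22 = A22, geno_ids = gid, w = w)
}
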