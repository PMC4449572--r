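#' Validate and order a pedigree table
#'
#' A pedigree is a data frame with integer columns `animal`, `sire`, `dam`;
#' `0` marks an unknown parent.  Animals must be topologically ordered
#' (parents appear before their offspring).
#'
#' @param ped data frame with columns `animal`, `sire`, `dam`.
#' @return the validated pedigree (ids coerced to integer).
#' @export
as_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  ped <- data.frame(animal = as.integer(ped$animal),
                    sire   = as.integer(ped$sire),
                    dam    = as.integer(ped$dam))
  if (anyDuplicated(ped$animal)) stop("duplicated animal ids in pedigree")
  idx <- match(ped$sire, ped$animal)
  if (any(!is.na(idx) & idx >= seq_len(nrow(ped))))
    stop("pedigree not ordered: a sire appears at or after its offspring")
  idx <- match(ped$dam, ped$animal)
  if (any(!is.na(idx) & idx >= seq_len(nrow(ped))))
    stop("pedigree not ordered: a dam appears at or after its offspring")
  if (any(ped$sire != 0 & is.na(match(ped$sire, ped$animal))))
    stop("sire id not present in pedigree")
  if (any(ped$dam != 0 & is.na(match(ped$dam, ped$animal))))
    stop("dam id not present in pedigree")
  ped
}

#' Numerator relationship matrix from a pedigree
#'
#' Henderson's tabular method with inbreeding: the diagonal is
#' `1 + 0.5 * a(sire, dam)` and off-diagonals follow the recursion
#' `a(i, j) = 0.5 * (a(j, sire_i) + a(j, dam_i))`.
#'
#' @param ped an ordered pedigree (see [as_pedigree()]).
#' @return dense symmetric matrix A with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal) # NA for unknown
  di <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else numeric(i - 1L)
      ad_ <- if (!is.na(d)) A[j, d] else numeric(i - 1L)
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Restrict a pedigree to recent ancestors of a focal set
#'
#' Keeps the focal animals plus at most `n_generations` generations of their
#' ancestors, mirroring the use of a 3-generation pedigree for the numerator
#' relationship matrix.  Parents outside the kept set are recoded as unknown.
#'
#' @param ped pedigree data frame.
#' @param keep integer ids of the focal (phenotyped) animals.
#' @param n_generations number of ancestor generations retained (default 3).
#' @return pruned, ordered pedigree.
#' @export
prune_pedigree <- function(ped, keep, n_generations = 3) {
  ped <- as_pedigree(ped)
  current <- unique(as.integer(keep))
  kept <- current
  for (g in seq_len(n_generations)) {
    rows <- ped[match(current, ped$animal), , drop = FALSE]
    parents <- setdiff(unique(c(rows$sire, rows$dam)), c(0L, kept))
    if (length(parents) == 0L) break
    kept <- c(kept, parents)
    current <- parents
  }
  out <- ped[ped$animal %in% kept, , drop = FALSE]
  out$sire[!(out$sire %in% out$animal)] <- 0L
  out$dam[!(out$dam %in% out$animal)] <- 0L
  rownames(out) <- NULL
  as_pedigree(out)
}
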