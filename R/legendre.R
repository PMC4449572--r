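#' Linear age standardizer
#'
#' Maps an age interval `[age_min, age_max]` (days) linearly onto `[-1, 1]`,
#' the domain of the Legendre polynomial basis.  The standardizer is stored
#' inside a fitted model so every downstream stage (SNP back-solving, window
#' scan, bootstrap) reuses the identical scaling.
#'
#' @param age_min,age_max endpoints of the age range in days; `age_max` must
#'   exceed `age_min`.
#' @return An object of class `"age_standardizer"`.
#' @examples
#' std <- age_standardizer(67, 182)
#' standardize_age(90, std)   # -0.6
#' @export
age_standardizer <- function(age_min, age_max) {
  stopifnot(is.numeric(age_min), is.numeric(age_max),
            length(age_min) == 1L, length(age_max) == 1L,
            is.finite(age_min), is.finite(age_max))
  if (age_max <= age_min)
    stop("age_max must be strictly greater than age_min")
  structure(list(age_min = as.numeric(age_min), age_max = as.numeric(age_max)),
            class = "age_standardizer")
}

#' @export
print.age_standardizer <- function(x, ...) {
  cat(sprintf("Age standardizer: [%g, %g] d -> [-1, 1]\n", x$age_min, x$age_max))
  invisible(x)
}

#' Standardize ages to the Legendre domain
#'
#' @param age numeric vector of ages in days; must lie inside the
#'   standardizer's range (a small numerical tolerance is allowed).
#' @param std an [age_standardizer()].
#' @return numeric vector of standardized ages in `[-1, 1]`.
#' @export
standardize_age <- function(age, std) {
  stopifnot(inherits(std, "age_standardizer"))
  tol <- 1e-8 * (std$age_max - std$age_min)
  if (any(age < std$age_min - tol | age > std$age_max + tol, na.rm = TRUE))
    stop("age outside the standardizer range [", std$age_min, ", ",
         std$age_max, "]")
  t <- 2 * (age - std$age_min) / (std$age_max - std$age_min) - 1
  pmin(1, pmax(-1, t))
}

#' Invert the age standardization
#'
#' @param t standardized ages in `[-1, 1]`.
#' @inheritParams standardize_age
#' @return ages in days.
#' @export
unstandardize_age <- function(t, std) {
  stopifnot(inherits(std, "age_standardizer"))
  (t + 1) / 2 * (std$age_max - std$age_min) + std$age_min
}

#' Order-2 Legendre polynomial basis row
#'
#' Evaluates the three Legendre polynomials P0, P1, P2 at a standardized age.
#' With `normalized = TRUE` (the default, the convention of the
#' random-regression literature) each polynomial is scaled by
#' `sqrt((2k + 1) / 2)` so the basis is orthonormal on `[-1, 1]`.
#'
#' @param t standardized age(s) in `[-1, 1]`.
#' @param normalized logical; scale to the orthonormal basis?
#' @return for scalar `t` a length-3 vector; see [legendre_matrix()] for the
#'   vectorized form.
#' @export
legendre_row <- function(t, normalized = TRUE) {
  if (any(abs(t) > 1 + 1e-12)) stop("standardized age must lie in [-1, 1]")
  out <- legendre_matrix(t, normalized = normalized)
  if (length(t) == 1L) drop(out) else out
}

#' Order-2 Legendre basis matrix
#'
#' @inheritParams legendre_row
#' @return numeric matrix with `length(t)` rows and 3 columns
#'   (intercept, linear, quadratic).
#' @export
legendre_matrix <- function(t, normalized = TRUE) {
  if (any(abs(t) > 1 + 1e-12)) stop("standardized age must lie in [-1, 1]")
  P <- cbind(rep(1, length(t)), t, (3 * t^2 - 1) / 2)
  colnames(P) <- c("leg0", "leg1", "leg2")
  if (normalized) P <- sweep(P, 2L, sqrt((2 * (0:2) + 1) / 2), `*`)
  P
}

# diagonal map raw -> normalized coefficient scale: phi_norm = c_k * P_k, so a
# covariance Ga expressed on the normalized-coefficient scale corresponds to
# diag(c) %*% Ga %*% diag(c) on the raw scale.
legendre_norm_const <- function() sqrt((2 * (0:2) + 1) / 2)
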