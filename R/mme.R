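## Henderson mixed-model equations for the Legendre random-regression model
##
##   y = X b + Z_u (phi ' u) + Z_pe (phi ' pe) + e
##
## with u ~ N(0, H (x) Ga) over all pedigree animals and pe ~ N(0, I (x) P)
## over phenotyped animals.  The coefficient matrix is held in sigma_e^2
## units: C = W'W + blockdiag(0, se * Hinv (x) Ga^-1, se * I (x) P^-1).
## The permanent-environment block is block-diagonal (3x3 per animal) and is
## absorbed analytically, so factorizations and the EM-REML inverse-block
## traces only ever touch the (fixed, genetic) Schur complement.

#' Variance components container
#'
#' @param Ga 3x3 genetic coefficient covariance.
#' @param P 3x3 permanent-environment coefficient covariance.
#' @param se residual variance (> 0).
#' @return list of class `"rr_varcomp"`.
#' @export
rr_varcomp <- function(Ga, P, se) {
  Ga <- as.matrix(Ga); P <- as.matrix(P)
  stopifnot(all(dim(Ga) == c(3, 3)), all(dim(P) == c(3, 3)), se > 0)
  .check_psd(Ga, "Ga"); .check_psd(P, "P")
  structure(list(Ga = (Ga + t(Ga)) / 2, P = (P + t(P)) / 2, se = se),
            class = "rr_varcomp")
}

#' @export
print.rr_varcomp <- function(x, ...) {
  cat("Genetic coefficient covariance (Ga):\n"); print(round(x$Ga, 4))
  cat("Permanent-environment covariance (P):\n"); print(round(x$P, 4))
  cat("Residual variance:", format(x$se, digits = 6), "\n")
  invisible(x)
}

#' Assemble the mixed-model equations
#'
#' Builds the fixed design (contemporary group and parity with
#' treatment-contrast identifiability, plus the linear and quadratic fixed
#' Legendre regressions; the intercept polynomial is absorbed into the
#' overall mean), the sparse random-effect incidences, and the cross-product
#' blocks reused by every solve.
#'
#' @param records data frame with columns `animal`, `age`, `value`, `cg`,
#'   `parity`.
#' @param std an [age_standardizer()] covering the record ages.
#' @param Hinv inverse relationship matrix over all pedigree animals
#'   (dimnames = animal ids); every record animal must appear in it.
#' @param normalized use the orthonormal Legendre basis.
#' @return an opaque list of class `"rr_mme"` consumed by [solve_mme()] and
#'   [em_reml()].
#' @export
assemble_mme <- function(records, std, Hinv, normalized = TRUE) {
  stopifnot(all(c("animal", "age", "value", "cg", "parity") %in% names(records)))
  uids <- rownames(Hinv)
  if (is.null(uids)) stop("Hinv must carry animal ids as dimnames")
  ia_u <- match(as.character(records$animal), uids)
  if (anyNA(ia_u)) stop("record animal absent from Hinv index")
  pids <- uids[sort(unique(ia_u))]
  ia_p <- match(as.character(records$animal), pids)
  n <- nrow(records); q <- length(uids); p <- length(pids)

  t_std <- standardize_age(records$age, std)
  Phi <- legendre_matrix(t_std, normalized = normalized)

  df <- data.frame(cg = droplevels(factor(records$cg)),
                   parity = droplevels(factor(records$parity)))
  terms <- c("cg", "parity")[c(nlevels(df$cg) > 1, nlevels(df$parity) > 1)]
  form <- if (length(terms)) paste("~", paste(terms, collapse = " + ")) else "~ 1"
  X <- stats::model.matrix(stats::as.formula(form), df)
  X <- cbind(X, Phi[, 2:3, drop = FALSE])
  rk <- qr(X)$rank
  if (rk < ncol(X))
    stop("rank-deficient fixed-effect design beyond declared constraints")
  f <- ncol(X)

  i3 <- rep(seq_len(n), each = 3L)
  xv <- as.numeric(t(Phi))
  Zu <- Matrix::sparseMatrix(i = i3, j = rep((ia_u - 1L) * 3L, each = 3L) + 1:3,
                             x = xv, dims = c(n, 3L * q))
  Zp <- Matrix::sparseMatrix(i = i3, j = rep((ia_p - 1L) * 3L, each = 3L) + 1:3,
                             x = xv, dims = c(n, 3L * p))
  W <- cbind(Matrix::Matrix(X, sparse = TRUE), Zu, Zp)
  M <- Matrix::crossprod(W)
  y <- records$value
  r <- as.numeric(Matrix::crossprod(W, y))

  d1 <- f + 3L * q
  M11 <- as.matrix(M[seq_len(d1), seq_len(d1)])
  M1p <- M[seq_len(d1), d1 + seq_len(3L * p), drop = FALSE]
  Mpp <- M[d1 + seq_len(3L * p), d1 + seq_len(3L * p)]
  Mpp_arr <- array(0, c(3, 3, p))
  for (a in seq_len(p)) {
    ix <- (a - 1L) * 3L + 1:3
    Mpp_arr[, , a] <- as.matrix(Mpp[ix, ix])
  }
  iu_of_pe <- match(pids, uids)
  # per-animal coupling of the pe equations to (fixed, own-animal genetic)
  # columns, precomputed densely: reused every EM iteration
  M1p_d <- as.matrix(M1p)
  B_arr <- array(0, c(3, f + 3L, p))
  for (a in seq_len(p)) {
    idxS <- c(seq_len(f), f + (iu_of_pe[a] - 1L) * 3L + 1:3)
    B_arr[, , a] <- t(M1p_d[idxS, (a - 1L) * 3L + 1:3, drop = FALSE])
  }

  cholHinv <- chol(Hinv)
  structure(list(X = X, W = W, M11 = M11, M1p = M1p, Mpp_arr = Mpp_arr,
                 B_arr = B_arr,
                 r = r, y = y, yy = sum(y^2), n = n, f = f, q = q, p = p,
                 uids = uids, pids = pids, iu_of_pe = iu_of_pe,
                 rankX = rk, Hinv = Hinv,
                 logdetH = -2 * sum(log(diag(cholHinv))),
                 Phi = Phi, ia_u = ia_u, ia_p = ia_p,
                 std = std, normalized = normalized),
            class = "rr_mme")
}

# factor the coefficient matrix at the given variance components;
# everything needed for repeated right-hand sides and for EM traces
.mme_factor <- function(sys, vc) {
  f <- sys$f; q <- sys$q; p <- sys$p
  Gainv <- chol2inv(chol(vc$Ga))
  Pinv <- chol2inv(chol(vc$P))
  se <- vc$se

  Cppinv <- array(0, c(3, 3, p))
  logdetCpp <- 0
  for (a in seq_len(p)) {
    Ca <- sys$Mpp_arr[, , a] + se * Pinv
    R <- chol(Ca)
    logdetCpp <- logdetCpp + 2 * sum(log(diag(R)))
    Cppinv[, , a] <- chol2inv(R)
  }
  Cppinv_sp <- Matrix::bdiag(lapply(seq_len(p), function(a) Cppinv[, , a]))

  S <- sys$M11
  uix <- f + seq_len(3L * q)
  S[uix, uix] <- S[uix, uix] + kronecker(sys$Hinv, Gainv) * se
  E <- sys$M1p %*% Cppinv_sp
  S <- S - as.matrix(E %*% Matrix::t(sys$M1p))
  S <- (S + t(S)) / 2
  cholS <- chol(S)

  list(vc = vc, Gainv = Gainv, Pinv = Pinv,
       Cppinv = Cppinv, Cppinv_sp = Cppinv_sp, cholS = cholS,
       logdetC = 2 * sum(log(diag(cholS))) + logdetCpp)
}

# solve the factored system for a right-hand side r (and phenotype y'y);
# returns solutions plus the pieces of the REML log-likelihood
.mme_solve_rhs <- function(sys, fac, r, yy) {
  f <- sys$f; q <- sys$q; p <- sys$p
  d1 <- f + 3L * q
  r1 <- r[seq_len(d1)]
  rp <- r[d1 + seq_len(3L * p)]
  rp_t <- as.numeric(fac$Cppinv_sp %*% rp)
  rhs1 <- r1 - as.numeric(sys$M1p %*% rp_t)
  sol1 <- backsolve(fac$cholS, backsolve(fac$cholS, rhs1, transpose = TRUE))
  solp <- as.numeric(fac$Cppinv_sp %*%
                       (rp - as.numeric(Matrix::crossprod(sys$M1p, sol1))))
  theta <- c(sol1, solp)
  b <- sol1[seq_len(f)]
  names(b) <- colnames(sys$X)
  U <- matrix(sol1[f + seq_len(3L * q)], q, 3, byrow = TRUE,
              dimnames = list(sys$uids, c("coef0", "coef1", "coef2")))
  PE <- matrix(solp, p, 3, byrow = TRUE,
               dimnames = list(sys$pids, c("coef0", "coef1", "coef2")))
  ypy_num <- yy - sum(theta * r)   # = sigma_e^2 * y'Py
  list(b = b, U = U, PE = PE, theta = theta, ypy_num = ypy_num)
}

# -2 restricted log-likelihood (up to an additive constant)
.reml_m2logl <- function(sys, fac, sol) {
  vc <- fac$vc
  sys$n * log(vc$se) + 3 * sys$logdetH +
    sys$q * determinant(vc$Ga, logarithm = TRUE)$modulus +
    sys$p * determinant(vc$P, logarithm = TRUE)$modulus +
    fac$logdetC - (sys$f + 3 * sys$q + 3 * sys$p) * log(vc$se) +
    sol$ypy_num / vc$se
}

#' Solve the mixed-model equations
#'
#' Direct dense Cholesky solve (after analytic absorption of the
#' permanent-environment block).  The solution satisfies the full system to
#' numerical precision; `check` verifies the relative residual norm.
#'
#' @param sys an [assemble_mme()] system.
#' @param vc an [rr_varcomp()].
#' @param check verify the residual of the linear system (default TRUE).
#' @param tol relative residual tolerance for the refinement loop.
#' @return list with fixed solutions `b`, genetic coefficient solutions `U`
#'   (all pedigree animals x 3), permanent-environment solutions `PE`
#'   (phenotyped animals x 3), and the restricted log-likelihood.
#' @export
solve_mme <- function(sys, vc, check = TRUE, tol = 1e-8) {
  stopifnot(inherits(sys, "rr_mme"), inherits(vc, "rr_varcomp"))
  fac <- .mme_factor(sys, vc)
  sol <- .mme_solve_rhs(sys, fac, sys$r, sys$yy)
  if (check) {
    # iterative refinement guards against ill-conditioned blended G
    for (i in 1:4) {
      resvec <- sys$r - .mme_apply(sys, fac, sol)
      res <- sqrt(sum(resvec^2)) / max(sqrt(sum(sys$r^2)), 1e-300)
      if (res <= tol) break
      dsol <- .mme_solve_rhs(sys, fac, resvec, 0)
      sol$theta <- sol$theta + dsol$theta
      sol$b <- sol$b + dsol$b
      sol$U <- sol$U + dsol$U
      sol$PE <- sol$PE + dsol$PE
      sol$ypy_num <- sys$yy - sum(sol$theta * sys$r)
    }
    if (res > tol)
      stop("MME solve failed: relative residual ", format(res))
  }
  sol$m2logl <- as.numeric(.reml_m2logl(sys, fac, sol))
  sol$vc <- vc
  sol
}

# apply the coefficient matrix to the current solutions without forming C
.mme_apply <- function(sys, fac, sol) {
  vc <- fac$vc
  Wt <- as.numeric(Matrix::crossprod(sys$W,
          as.numeric(sys$W %*% sol$theta)))
  pen_u <- as.numeric(fac$Gainv %*% t(sol$U) %*% sys$Hinv) * vc$se
  pen_p <- as.numeric(fac$Pinv %*% t(sol$PE)) * vc$se
  Wt + c(rep(0, sys$f), pen_u, pen_p)
}

#' EM-REML variance components
#'
#' Expectation-maximization REML for the genetic coefficient covariance,
#' permanent-environment covariance and residual variance.  Each iteration
#' solves the MME, extracts the exact inverse blocks of the coefficient
#' matrix (via the absorbed Schur complement) and applies the classical EM
#' updates; the restricted log-likelihood is non-decreasing by construction
#' and is asserted at every iteration.
#'
#' @param sys an [assemble_mme()] system.
#' @param init starting [rr_varcomp()]; if `NULL` a moment-based start from
#'   per-animal Legendre regressions is used.
#' @param tol relative parameter-change convergence criterion (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @param accelerate use safeguarded component-wise Aitken extrapolation
#'   (default TRUE); every accelerated step is validated against the
#'   restricted likelihood and falls back to the plain EM update if it
#'   overshoots, so the recorded likelihood trace is monotone either way.
#' @param verbose print the likelihood trace.
#' @return an [rr_varcomp()] with attributes `iterations`, `converged` and
#'   `m2logl_trace`.
#' @export
em_reml <- function(sys, init = NULL, tol = 1e-6, max_iter = 500,
                    accelerate = TRUE, verbose = FALSE) {
  stopifnot(inherits(sys, "rr_mme"))
  if (is.null(init)) init <- .vc_init(sys)
  vc <- init
  f <- sys$f; q <- sys$q; p <- sys$p
  uix_k <- lapply(1:3, function(k) f + 3L * (seq_len(q) - 1L) + k)
  to_par <- function(v) c(v$Ga, v$P, v$se)
  from_par <- function(th) {
    Ga <- matrix(th[1:9], 3, 3); P <- matrix(th[10:18], 3, 3)
    rr_varcomp((Ga + t(Ga)) / 2, (P + t(P)) / 2, th[19])
  }
  par_valid <- function(th) {
    Ga <- matrix(th[1:9], 3, 3); P <- matrix(th[10:18], 3, 3)
    th[19] > 1e-12 &&
      min(eigen((Ga + t(Ga)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) > 1e-10 * max(abs(Ga)) &&
      min(eigen((P + t(P)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) > 1e-10 * max(abs(P))
  }
  trace <- numeric(0)
  converged <- FALSE
  extrapolated <- FALSE
  fallback <- NULL
  last_step <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    fac <- .mme_factor(sys, vc)
    sol <- .mme_solve_rhs(sys, fac, sys$r, sys$yy)
    m2l <- as.numeric(.reml_m2logl(sys, fac, sol))
    if (length(trace) > 0 &&
        m2l > trace[length(trace)] + 1e-6 * (abs(trace[length(trace)]) + 1)) {
      if (extrapolated) {
        # the accelerated guess overshot: fall back to the guaranteed
        # plain EM update and re-evaluate
        vc <- fallback
        extrapolated <- FALSE
        fallback <- NULL
        last_step <- NULL
        next
      }
      stop("EM-REML restricted likelihood decreased at iteration ", iter,
           " (", format(trace[length(trace)]), " -> ", format(m2l), ")")
    }
    trace <- c(trace, m2l)
    extrapolated <- FALSE

    Sinv <- chol2inv(fac$cholS)

    Tu <- matrix(0, 3, 3)
    for (k in 1:3) for (l in k:3) {
      Tu[k, l] <- Tu[l, k] <- sum(sys$Hinv * Sinv[uix_k[[k]], uix_k[[l]]])
    }
    Ga_new <- (t(sol$U) %*% sys$Hinv %*% sol$U + vc$se * Tu) / q
    Ga_new <- (Ga_new + t(Ga_new)) / 2

    blocksum <- matrix(0, 3, 3)
    fix <- seq_len(f)
    for (a in seq_len(p)) {
      idxS <- c(fix, f + (sys$iu_of_pe[a] - 1L) * 3L + 1:3)
      E <- fac$Cppinv[, , a] %*% sys$B_arr[, , a]
      blocksum <- blocksum + fac$Cppinv[, , a] +
        E %*% Sinv[idxS, idxS] %*% t(E)
    }
    P_new <- (crossprod(sol$PE) + vc$se * blocksum) / p
    P_new <- (P_new + t(P_new)) / 2

    se_new <- sol$ypy_num / (sys$n - sys$rankX)

    th_cur <- to_par(vc)
    vc_new <- rr_varcomp(Ga_new, P_new, se_new)
    th_new <- to_par(vc_new)
    # per-component relative change (floored so near-zero components do not
    # dominate), not normalized by the largest parameter: small variance
    # components must converge on their own scale
    delta <- max(abs(th_new - th_cur) /
                   pmax(abs(th_cur), 0.02 * max(abs(th_cur))))
    if (verbose)
      message(sprintf("EM iter %3d  -2logL = %.6f  max rel change = %.3g",
                      iter, m2l, delta))
    if (delta < tol) { vc <- vc_new; converged <- TRUE; break }

    step <- th_new - th_cur
    if (accelerate && !is.null(last_step)) {
      # component-wise Aitken extrapolation: each variance parameter decays
      # at its own geometric rate, and the small components are the slow ones
      rr <- step / last_step
      rr[!is.finite(rr) | rr <= 0 | rr >= 1] <- 0
      beta <- pmin(rr / (1 - rr), 12)
      if (max(beta) > 0.1) {
        sc <- 1
        while (sc > 0.01 && !par_valid(th_new + sc * beta * step)) sc <- sc / 2
        if (sc > 0.01) {
          fallback <- vc_new
          vc <- from_par(th_new + sc * beta * step)
          extrapolated <- TRUE
          last_step <- NULL
          next
        }
      }
    }
    vc <- vc_new
    last_step <- step
  }
  attr(vc, "iterations") <- iter
  attr(vc, "converged") <- converged
  attr(vc, "m2logl_trace") <- trace
  vc
}

# moment-based starting values.  Per-animal OLS Legendre fits give
# coefficient scatter S ~ Ga + P + estimation noise; the genetic part is
# pre-estimated Haseman-Elston style from cross-products of related animals'
# coefficient estimates (E[c_i c_j'] = A_ij * Ga for i != j, since the
# permanent-environment and residual parts are independent across animals).
.vc_init <- function(sys) {
  resid_det <- stats::lm.fit(sys$X, sys$y)$residuals
  ids <- sys$ia_p
  coefs <- matrix(NA_real_, sys$p, 3)
  rvar <- numeric(0)
  for (a in seq_len(sys$p)) {
    rows <- which(ids == a)
    if (length(rows) >= 6) {
      fit <- stats::lm.fit(sys$Phi[rows, , drop = FALSE], resid_det[rows])
      coefs[a, ] <- fit$coefficients
      rvar <- c(rvar, sum(fit$residuals^2) / max(length(rows) - 3, 1))
    }
  }
  ok <- stats::complete.cases(coefs)
  if (sum(ok) < 5) {
    v <- stats::var(sys$y)
    return(rr_varcomp(diag(3) * v / 4, diag(3) * v / 4, v / 2))
  }
  S <- stats::cov(coefs[ok, , drop = FALSE])
  S <- S + diag(3) * 1e-4 * mean(diag(S))
  se0 <- max(mean(rvar), 1e-6)

  Ga0 <- NULL
  Arel <- tryCatch(chol2inv(chol(sys$Hinv)), error = function(e) NULL)
  if (!is.null(Arel)) {
    iu <- sys$iu_of_pe[ok]
    Ap <- Arel[iu, iu, drop = FALSE]
    W <- Ap; diag(W) <- 0; W[W < 0.2] <- 0   # informative relative pairs only
    sw2 <- sum(W^2)
    if (sw2 > 0) {
      cc <- coefs[ok, , drop = FALSE]
      cc <- sweep(cc, 2L, colMeans(cc))
      num <- t(cc) %*% W %*% cc        # sum_ij W_ij c_i c_j'
      Ga0 <- (num + t(num)) / (2 * sw2)
      ev <- eigen((Ga0 + t(Ga0)) / 2, symmetric = TRUE)
      lam <- pmin(pmax(ev$values, 0.02 * mean(diag(S))), diag(S))
      Ga0 <- ev$vectors %*% (lam * t(ev$vectors))
    }
  }
  if (is.null(Ga0)) Ga0 <- 0.5 * S
  P0 <- S - Ga0
  ev <- eigen((P0 + t(P0)) / 2, symmetric = TRUE)
  P0 <- ev$vectors %*% (pmax(ev$values, 0.02 * mean(diag(S))) * t(ev$vectors))
  rr_varcomp(Ga0, P0, se0)
}
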