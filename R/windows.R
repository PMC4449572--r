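## 10-SNP sliding-window GEBV (WGEBV): per animal, the sum of centered gene
## content times back-solved SNP effect over the window; its across-animal
## variance is the scan statistic.  Windows are SNP-count based, never span
## chromosomes, and slide with step 1 by default.

#' Sliding-window GEBV scan
#'
#' For every window `w` and animal `a`,
#' `WGEBV[a, w] = sum_{i in w} z[a, i] * u_hat[i]` with centered gene content
#' `z`, computed per coefficient; the across-animal variance of each window
#' is the scan statistic.
#'
#' @param geno a [genotype_matrix()] (same SNP index as the effects).
#' @param effects a [snp_effects()] object.
#' @param window_size SNP count per window (default 10).
#' @param step slide step in SNP (default 1).
#' @return object of class `"window_scan"`: `windows` data frame (`window`,
#'   `chrom`, `start`, `end` 1-based inclusive SNP indices, `start_pos`,
#'   `end_pos`, `var0..var2`), `wgebv` (list of animal x window matrices per
#'   coefficient) and metadata.
#' @export
scan_windows <- function(geno, effects, window_size = 10, step = 1) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(effects, "snp_effects"))
  if (nrow(effects$effects) != ncol(geno$codes))
    stop("effects and genotypes do not share a SNP index")
  Z <- centered_genotypes(geno, list(p = effects$p))
  map <- geno$map
  chroms <- unique(map$chrom)
  win <- list(); wg <- list(`0` = NULL, `1` = NULL, `2` = NULL)
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    mc <- length(idx)
    if (mc < window_size) {
      message("chromosome ", ch, " has ", mc, " SNP (< ", window_size,
              "): no windows")
      next
    }
    starts <- seq(1L, mc - window_size + 1L, by = step)
    w_df <- data.frame(chrom = ch,
                       start = idx[starts],
                       end = idx[starts + window_size - 1L])
    w_df$start_pos <- map$pos[w_df$start]
    w_df$end_pos <- map$pos[w_df$end]
    for (k in 1:3) {
      C <- sweep(Z[, idx, drop = FALSE], 2L, effects$effects[idx, k], `*`)
      cs <- cbind(0, t(apply(C, 1L, cumsum)))
      W <- cs[, starts + window_size, drop = FALSE] - cs[, starts, drop = FALSE]
      w_df[[paste0("var", k - 1L)]] <- apply(W, 2L, stats::var)
      wg[[k]] <- cbind(wg[[k]], W)
    }
    win[[length(win) + 1L]] <- w_df
  }
  if (length(win) == 0L) stop("no chromosome has enough SNP for a window")
  windows <- do.call(rbind, win)
  windows <- cbind(window = seq_len(nrow(windows)), windows)
  rownames(windows) <- NULL
  structure(list(windows = windows, wgebv = wg, window_size = window_size,
                 step = step, map = map, p = effects$p,
                 geno_ids = rownames(geno$codes)),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("Window scan: %d windows of %d SNP (step %d) on %d chromosome(s)\n",
              nrow(x$windows), x$window_size, x$step,
              length(unique(x$windows$chrom))))
  invisible(x)
}

# merge sorted windows that share at least one SNP index into regions
.merge_windows <- function(w) {
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  out <- list()
  cur <- w[1, , drop = FALSE]
  members <- cur$window
  for (i in seq_len(nrow(w))[-1]) {
    row <- w[i, , drop = FALSE]
    if (row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$end_pos <- max(cur$end_pos, row$end_pos)
      if (row$peak_var > cur$peak_var) {
        cur$peak_var <- row$peak_var
        cur$peak_window <- row$peak_window
        cur$peak_start <- row$peak_start
        cur$peak_end <- row$peak_end
      }
      members <- c(members, row$window)
      cur$n_windows <- cur$n_windows + 1L
    } else {
      cur$members <- paste(members, collapse = ";")
      out[[length(out) + 1L]] <- cur
      cur <- row
      members <- row$window
    }
  }
  cur$members <- paste(members, collapse = ";")
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

#' Two-stage putative-QTL selection
#'
#' Stage 1 keeps, per coefficient, the top `top_window_frac` windows by
#' WGEBV variance (ceiling on fractional counts).  Stage 2 sorts the
#' survivors by genome position, merges windows sharing at least one SNP
#' into regions, ranks regions by their maximum member window variance and
#' flags the top `top_region_frac` as putative QTL.
#'
#' @param scan a [scan_windows()] result.
#' @param top_window_frac stage-1 fraction (default 0.05).
#' @param top_region_frac stage-2 fraction (default 0.10).
#' @return data frame of regions: `coeff`, `chrom`, `start`, `end`,
#'   `start_pos`, `end_pos`, `n_windows`, `peak_var`, `peak_window`,
#'   `members`, `putative`.
#' @export
putative_qtl <- function(scan, top_window_frac = 0.05, top_region_frac = 0.10) {
  stopifnot(inherits(scan, "window_scan"))
  w <- scan$windows
  out <- list()
  for (k in 1:3) {
    v <- w[[paste0("var", k - 1L)]]
    nkeep <- ceiling(top_window_frac * nrow(w))
    keep <- order(v, decreasing = TRUE)[seq_len(nkeep)]
    wk <- w[keep, c("window", "chrom", "start", "end", "start_pos", "end_pos")]
    wk$peak_var <- v[keep]
    wk$peak_window <- wk$window
    wk$peak_start <- wk$start
    wk$peak_end <- wk$end
    wk$n_windows <- 1L
    reg <- .merge_windows(wk)
    reg <- reg[order(reg$peak_var, decreasing = TRUE), , drop = FALSE]
    nflag <- ceiling(top_region_frac * nrow(reg))
    reg$putative <- seq_len(nrow(reg)) <= nflag
    reg$coeff <- k - 1L
    reg$region <- paste0("c", k - 1L, "_r", seq_len(nrow(reg)))
    out[[k]] <- reg[, c("region", "coeff", "chrom", "start", "end",
                        "start_pos", "end_pos", "n_windows", "peak_var",
                        "peak_window", "peak_start", "peak_end",
                        "members", "putative")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$window <- NULL
  res
}

#' Per-window cross-coefficient WGEBV covariance
#'
#' For every window, the sample covariance across animals of the three
#' per-coefficient WGEBV values, plus the genome-averaged WGEBV correlation
#' per coefficient pair (windows where either member has zero variance are
#' skipped in the average).
#'
#' @param scan a [scan_windows()] result.
#' @return list with `cov` (3 x 3 x n_windows array) and `mean_cor`
#'   (3 x 3 matrix, unit diagonal).
#' @export
window_covariance <- function(scan) {
  stopifnot(inherits(scan, "window_scan"))
  nw <- nrow(scan$windows)
  co <- array(NA_real_, c(3, 3, nw))
  for (j in seq_len(nw)) {
    Wj <- cbind(scan$wgebv[[1]][, j], scan$wgebv[[2]][, j], scan$wgebv[[3]][, j])
    co[, , j] <- stats::cov(Wj)
  }
  mean_cor <- matrix(NA_real_, 3, 3, dimnames = list(paste0("coef", 0:2),
                                                     paste0("coef", 0:2)))
  for (k in 1:3) for (l in 1:3) {
    v1 <- co[k, k, ]; v2 <- co[l, l, ]
    ok <- v1 > 0 & v2 > 0
    mean_cor[k, l] <- if (any(ok)) {
      mean(co[k, l, ok] / sqrt(v1[ok] * v2[ok]))
    } else NA_real_
  }
  list(cov = co, mean_cor = mean_cor)
}
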