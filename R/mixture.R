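#' Bin FRET efficiencies into a fixed-width histogram
#'
#' Efficiencies are binned on `[0, 1]` with uniform bins (default width 0.05,
#' the standard binning for these histograms). The right edge 1.0 is assigned
#' to the last bin, so the counts conserve the number of inputs.
#'
#' @param efficiencies Numeric vector of efficiencies in `[0, 1]`; `NA`s are
#'   dropped (they represent excluded events).
#' @param bin_width Bin width in efficiency units; must divide 1 evenly.
#' @param label Dataset label (timepoint / variant) carried into global fits.
#' @return An object of class `efficiency_histogram` with `breaks`, `mids`,
#'   `counts` and `label`.
#' @examples
#' build_histogram(c(0.5, 0.5, 0.5))
#' @export
build_histogram <- function(efficiencies, bin_width = 0.05, label = "data") {
  stopifnot(bin_width > 0, bin_width <= 1)
  e <- efficiencies[!is.na(efficiencies)]
  if (any(e < 0 | e > 1)) {
    stop(errorCondition("efficiencies must lie in [0, 1]",
                        class = c("oligofret_out_of_range", "oligofret_error")))
  }
  n_bins <- round(1 / bin_width)
  if (abs(n_bins * bin_width - 1) > 1e-8) {
    stop(invalid_params_error("`bin_width` must divide [0, 1] into equal bins"))
  }
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(pmax(floor(e / bin_width) + 1L, 1L), n_bins)
  counts <- tabulate(idx, n_bins)
  structure(
    list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
         counts = counts, bin_width = bin_width, label = label),
    class = "efficiency_histogram"
  )
}

#' @export
print.efficiency_histogram <- function(x, ...) {
  cat(sprintf("Efficiency histogram '%s': %d events in %d bins of width %g\n",
              x$label, sum(x$counts), length(x$counts), x$bin_width))
  invisible(x)
}

gauss_comp <- function(x, amp, center, width) {
  amp * exp(-(x - center)^2 / (2 * width^2))
}

nonconvergence_error <- function(msg) {
  errorCondition(msg, class = c("oligofret_nonconvergence", "oligofret_error"))
}

degenerate_fit_error <- function(msg) {
  errorCondition(msg, class = c("oligofret_degenerate_fit", "oligofret_error"))
}

# Candidate center pairs: the two tallest well-separated modes of the pooled
# counts, plus a fixed 3x3 grid. Deterministic order; first-best SSE wins.
center_candidates <- function(histograms, min_sep) {
  mids <- histograms[[1]]$mids
  pooled <- Reduce(`+`, lapply(histograms, function(h) {
    if (length(h$counts) == length(mids)) h$counts else
      stats::approx(h$mids, h$counts, mids, rule = 2)$y
  }))
  k <- length(pooled)
  left <- c(-Inf, pooled[-k]); right <- c(pooled[-1], -Inf)
  is_peak <- pooled > 0 & pooled >= left & pooled > right
  peaks <- mids[is_peak][order(-pooled[is_peak])]
  cands <- list()
  if (length(peaks) >= 2) {
    p1 <- peaks[1]
    p2 <- peaks[which(abs(peaks - p1) >= min_sep)[1]]
    if (!is.na(p2)) cands <- list(sort(c(p1, p2)))
  }
  grid_lo <- c(0.15, 0.3, 0.45); grid_hi <- c(0.35, 0.55, 0.75)
  for (lo in grid_lo) for (hi in grid_hi) {
    if (hi - lo >= min_sep) cands <- c(cands, list(c(lo, hi)))
  }
  unique(cands)
}

#' Global two-Gaussian fit of FRET-efficiency histograms
#'
#' Fits every histogram simultaneously with the sum of two Gaussian
#' components whose centres and widths are shared across datasets while each
#' dataset keeps its own pair of amplitudes. Sharing the shape parameters
#' ensures the same two populations (lower-efficiency, loosely packed
#' "Type-A-like" and higher-efficiency, compact "Type-B-like") are identified
#' in every timepoint/treatment, pooling their information. The fit is
#' nonlinear least squares on the histogram counts with Poisson weighting
#' (residuals scaled by `1/sqrt(count)`) by default: histogram bins are
#' Poisson-distributed counts, and unweighted least squares lets the tallest
#' bins dominate, which misallocates a weak second component into a broad
#' tail term instead of its true peak. `weighting = "none"` gives plain
#' unweighted least squares. The system is solved by Levenberg-Marquardt from a
#' deterministic multi-start (data modes plus a fixed 3x3 grid of centre
#' pairs; best sum of squares wins, ties broken by candidate order).
#' Components are ordered by centre after fitting, so the higher-FRET
#' component is always the second one. Parameter standard errors come from
#' the fit covariance.
#'
#' @param histograms One [build_histogram()] result or a list of them.
#' @param weighting `"poisson"` (default; residuals scaled by
#'   `1/sqrt(max(count, 1))`) or `"none"` (unweighted least squares).
#' @param min_counts Histograms with fewer total counts trigger a warning.
#' @return An object of class `mixture_fit`: shared `centers` and `widths`
#'   (low then high), per-dataset `amplitudes` matrix, standard errors, the
#'   full parameter covariance, `sse`, `degenerate` flag and dataset labels.
#' @export
global_fit <- function(histograms, weighting = c("poisson", "none"),
                       min_counts = 50) {
  weighting <- match.arg(weighting)
  if (inherits(histograms, "efficiency_histogram")) histograms <- list(histograms)
  stopifnot(length(histograms) >= 1,
            all(vapply(histograms, inherits, logical(1), "efficiency_histogram")))
  labels <- vapply(seq_along(histograms), function(i) {
    l <- histograms[[i]]$label
    if (is.null(l) || !nzchar(l)) sprintf("dataset_%d", i) else l
  }, character(1))
  totals <- vapply(histograms, function(h) sum(h$counts), numeric(1))
  if (all(totals == 0)) {
    stop(nonconvergence_error("all histograms are empty; nothing to fit"))
  }
  if (any(totals < min_counts)) {
    warning(sprintf("histogram(s) %s have fewer than %d counts; fit may be unstable",
                    paste(labels[totals < min_counts], collapse = ", "),
                    min_counts))
  }

  H <- length(histograms)
  x <- lapply(histograms, `[[`, "mids")
  y <- lapply(histograms, function(h) as.numeric(h$counts))
  w <- lapply(y, function(yy) {
    if (weighting == "poisson") 1 / sqrt(pmax(yy, 1)) else rep(1, length(yy))
  })
  bin_width <- histograms[[1]]$bin_width

  # par = (c1, c2, w1, w2, a11, a12, a21, a22, ...)
  resid_fun <- function(par) {
    cts <- par[1:2]; wds <- par[3:4]
    unlist(lapply(seq_len(H), function(h) {
      amp <- par[4 + 2 * (h - 1) + 1:2]
      pred <- gauss_comp(x[[h]], amp[1], cts[1], wds[1]) +
        gauss_comp(x[[h]], amp[2], cts[2], wds[2])
      (y[[h]] - pred) * w[[h]]
    }))
  }

  amp_init <- function(centers) {
    unlist(lapply(seq_len(H), function(h) {
      vapply(centers, function(ct) {
        max(y[[h]][which.min(abs(x[[h]] - ct))], 1)
      }, numeric(1))
    }))
  }

  lower <- c(0, 0, bin_width / 2, bin_width / 2, rep(0, 2 * H))
  upper <- c(1, 1, 0.5, 0.5, rep(Inf, 2 * H))
  best <- NULL
  for (ct in center_candidates(histograms, min_sep = 2 * bin_width)) {
    par0 <- c(ct, 0.08, 0.08, amp_init(ct))
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, lower, upper, resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance - 1e-12) best <- fit
  }
  if (is.null(best)) {
    stop(nonconvergence_error("two-Gaussian global fit failed from all starts"))
  }

  par <- best$par
  n_obs <- sum(lengths(y)); n_par <- length(par)
  sigma2 <- best$deviance / max(n_obs - n_par, 1)
  covm <- tryCatch(2 * sigma2 * solve(best$hessian), error = function(e) {
    matrix(NA_real_, n_par, n_par)
  })

  # order components by center (low first), permuting params and covariance
  perm <- seq_len(n_par)
  if (par[1] > par[2]) {
    sw <- function(i, j) { perm[c(i, j)] <<- perm[c(j, i)] }
    sw(1, 2); sw(3, 4)
    for (h in seq_len(H)) sw(4 + 2 * (h - 1) + 1, 4 + 2 * (h - 1) + 2)
  }
  par <- par[perm]
  covm <- covm[perm, perm, drop = FALSE]
  se <- sqrt(pmax(diag(covm), 0))

  amplitudes <- matrix(par[-(1:4)], nrow = H, ncol = 2, byrow = TRUE,
                       dimnames = list(labels, c("low", "high")))
  amp_se <- matrix(se[-(1:4)], nrow = H, ncol = 2, byrow = TRUE,
                   dimnames = list(labels, c("low", "high")))
  degenerate <- abs(par[2] - par[1]) < bin_width ||
    all(amplitudes[, "high"] < 1e-8) || all(amplitudes[, "low"] < 1e-8)

  structure(
    list(
      centers = stats::setNames(par[1:2], c("low", "high")),
      widths = stats::setNames(par[3:4], c("low", "high")),
      amplitudes = amplitudes,
      center_se = stats::setNames(se[1:2], c("low", "high")),
      width_se = stats::setNames(se[3:4], c("low", "high")),
      amplitude_se = amp_se,
      cov = covm,
      sse = best$deviance,
      n_obs = n_obs,
      weighting = weighting,
      labels = labels,
      degenerate = degenerate,
      info = best$info
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Global two-Gaussian fit\n")
  cat(sprintf("  centers: low %.3f +/- %.3f, high %.3f +/- %.3f\n",
              x$centers[1], x$center_se[1], x$centers[2], x$center_se[2]))
  cat(sprintf("  widths:  low %.3f, high %.3f; SSE %.4g over %d datasets\n",
              x$widths[1], x$widths[2], x$sse, nrow(x$amplitudes)))
  if (x$degenerate) cat("  WARNING: fit flagged degenerate\n")
  invisible(x)
}

#' Fraction of the converted (high-FRET) population
#'
#' Area under the higher-efficiency Gaussian divided by the total fitted
#' area for one dataset, using analytic areas `amplitude * width *
#' sqrt(2*pi)`. The standard error is propagated to first order (delta
#' method) from the fit covariance of the amplitudes and shared widths.
#'
#' @param fit A [global_fit()] result.
#' @param dataset Dataset index or label.
#' @return A list with `fraction` and `se`.
#' @export
fraction_converted <- function(fit, dataset = 1) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$degenerate) {
    stop(degenerate_fit_error(
      "fit is degenerate (collapsed components); fraction converted undefined"))
  }
  h <- if (is.character(dataset)) match(dataset, fit$labels) else as.integer(dataset)
  if (is.na(h) || h < 1 || h > nrow(fit$amplitudes)) {
    stop(invalid_params_error("unknown dataset"))
  }
  a1 <- fit$amplitudes[h, "low"]; a2 <- fit$amplitudes[h, "high"]
  w1 <- fit$widths[1]; w2 <- fit$widths[2]
  A1 <- a1 * w1; A2 <- a2 * w2  # sqrt(2*pi) cancels in the ratio
  S <- A1 + A2
  if (S <= 0) stop(degenerate_fit_error("total fitted area is zero"))
  frac <- unname(A2 / S)

  # gradient in full parameter space (c1, c2, w1, w2, amplitudes...)
  n_par <- ncol(fit$cov)
  g <- numeric(n_par)
  dA1 <- -A2 / S^2; dA2 <- A1 / S^2
  g[3] <- dA1 * a1            # d f / d w1
  g[4] <- dA2 * a2            # d f / d w2
  g[4 + 2 * (h - 1) + 1] <- dA1 * w1
  g[4 + 2 * (h - 1) + 2] <- dA2 * w2
  se <- if (anyNA(fit$cov)) NA_real_ else
    unname(sqrt(max(drop(t(g) %*% fit$cov %*% g), 0)))
  list(fraction = frac, se = se)
}

#' Bootstrap confidence interval for a mean
#'
#' Percentile bootstrap of the sample mean (default 9,999 resamples), as used
#' for per-cell summary statistics where the handful of cells per condition
#' makes normal-theory intervals unreliable.
#'
#' @param values Numeric vector (at least 2 values).
#' @param n_resamples Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `mean`, `ci` (length-2 vector), `level`, `n_resamples`.
#' @examples
#' bootstrap_mean_ci(rnorm(20, 0.5, 0.1), n_resamples = 999, seed = 1)
#' @export
bootstrap_mean_ci <- function(values, n_resamples = 9999, level = 0.95,
                              seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop(errorCondition("need at least 2 values to bootstrap",
                        class = c("oligofret_insufficient_data",
                                  "oligofret_error")))
  }
  stopifnot(n_resamples >= 1, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  # resample in blocks to bound memory at ~8 MB
  block <- max(1L, min(n_resamples, as.integer(1e6 / n)))
  means <- numeric(n_resamples)
  done <- 0L
  while (done < n_resamples) {
    b <- min(block, n_resamples - done)
    m <- matrix(sample(values, n * b, replace = TRUE), nrow = n)
    means[done + seq_len(b)] <- colMeans(m)
    done <- done + b
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  list(mean = mean(values), ci = ci, level = level, n_resamples = n_resamples)
}
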