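#' Photobleaching intensity trace
#'
#' Intensity-versus-time trace of a single fluorescent spot under continuous
#' irradiation, in analogue-to-digital units (ADU). Each fluorophore bleaches
#' in one discrete event, so the trace is a noisy descending staircase whose
#' step count equals the number of labelled monomers in the spot.
#'
#' @param intensity Numeric intensity series (finite; >= 10 frames to fit).
#' @param frame_interval Seconds per frame (metadata only).
#' @return An object of class `bleach_trace`.
#' @export
bleach_trace <- function(intensity, frame_interval = 0.05) {
  stopifnot(is.numeric(intensity), all(is.finite(intensity)),
            frame_interval > 0)
  structure(list(intensity = as.numeric(intensity),
                 frame_interval = frame_interval),
            class = "bleach_trace")
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat(sprintf("Bleach trace: %d frames at %g s\n",
              length(x$intensity), x$frame_interval))
  invisible(x)
}

seg_rss <- function(cs, cs2, l, r) {
  n <- r - l + 1
  s <- cs[r + 1] - cs[l]
  (cs2[r + 1] - cs2[l]) - s * s / n
}

# Best single split of segment [l, r] honouring the minimum plateau length.
# Returns c(split_frame_of_right_part, rss_after) or NULL if unsplittable.
best_split <- function(cs, cs2, l, r, min_plateau) {
  ts <- (l + min_plateau - 1):(r - min_plateau)
  if (length(ts) == 0 || ts[1] > ts[length(ts)]) return(NULL)
  nl <- ts - l + 1
  sl <- cs[ts + 1] - cs[l]
  rl <- (cs2[ts + 1] - cs2[l]) - sl * sl / nl
  nr <- r - ts
  sr <- cs[r + 1] - cs[ts + 1]
  rr <- (cs2[r + 1] - cs2[ts + 1]) - sr * sr / nr
  tot <- rl + rr
  i <- which.min(tot)
  c(ts[i] + 1L, tot[i])
}

#' Fit a piecewise-constant staircase to a photobleaching trace
#'
#' Greedy change-point insertion: at each iteration the split that maximally
#' reduces the residual sum of squares (over all current segments, honouring
#' the minimum plateau length) is inserted; the insertion path is followed
#' while any split still reduces the RSS, and the returned fit is the path
#' point minimising the penalised criterion `n * log(RSS/n) + penalty * k` — a
#' Bayesian information criterion on the Gaussian residual model. The default
#' penalty is `3 * log(n)` per change point, the modified-BIC regime for
#' change-point problems: a change point contributes a level parameter plus a
#' location that is scanned over every admissible frame, and the scan maximum
#' of a spurious split's RSS reduction grows like `2 * log(n) * sigma^2`, so a
#' plain `log(n)` penalty admits false steps. After greedy insertion the fit
#' is refined (change points relocated, then pruned against the criterion).
#' Only downward steps are counted as photobleaching;
#' upward steps (blinking/recovery) are flagged and excluded from the count.
#'
#' @param trace A [bleach_trace()] (or bare numeric vector).
#' @param penalty Penalty per change point; default `3 * log(n)`.
#' @param min_plateau Minimum segment length in frames (default 3), guarding
#'   against single-frame noise excursions.
#' @return An object of class `step_fit`: `change_points` (first frame of
#'   each new plateau), `levels` (plateau means, ADU), `n_steps` (downward
#'   steps), `n_up` (flagged upward steps), `rss` and `penalty`.
#' @examples
#' y <- rep(c(350, 250, 150, 50), each = 25)
#' fit_steps(bleach_trace(y))$n_steps # 3
#' @export
fit_steps <- function(trace, penalty = NULL, min_plateau = 3) {
  y <- if (inherits(trace, "bleach_trace")) trace$intensity else as.numeric(trace)
  n <- length(y)
  if (n < 10) {
    stop(errorCondition("trace too short to fit (< 10 frames)",
                        class = c("oligofret_short_trace", "oligofret_error")))
  }
  stopifnot(min_plateau >= 1)
  if (is.null(penalty)) penalty <- 3 * log(n)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y * y))
  eps <- .Machine$double.eps * max(cs2[n + 1], 1)
  crit <- function(rss, k) n * log(max(rss, eps) / n) + penalty * k

  # Greedy insertion path: keep splitting while any split reduces the RSS,
  # then choose the path point with the best penalised criterion. Stopping at
  # the first non-improving insertion instead would stall in a local plateau
  # of the criterion on staircases with many comparable steps.
  bounds <- c(1L, n + 1L)  # segment h spans [bounds[h], bounds[h+1] - 1]
  rss <- seg_rss(cs, cs2, 1L, n)
  path <- list(list(bounds = bounds, rss = rss))
  repeat {
    segs <- cbind(bounds[-length(bounds)], bounds[-1] - 1L)
    cand <- NULL
    for (s in seq_len(nrow(segs))) {
      bs <- best_split(cs, cs2, segs[s, 1], segs[s, 2], min_plateau)
      if (is.null(bs)) next
      gain <- seg_rss(cs, cs2, segs[s, 1], segs[s, 2]) - bs[2]
      if (is.null(cand) || gain > cand$gain + 1e-12) {
        cand <- list(split = bs[1], gain = gain)
      }
    }
    if (is.null(cand) || cand$gain <= 1e-9) break
    bounds <- sort(c(bounds, as.integer(cand$split)))
    rss <- rss - cand$gain
    path[[length(path) + 1L]] <- list(bounds = bounds, rss = rss)
  }
  crits <- vapply(seq_along(path),
                  function(i) crit(path[[i]]$rss, i - 1L), numeric(1))
  best_k <- which.min(crits)
  bounds <- path[[best_k]]$bounds
  rss <- path[[best_k]]$rss
  k <- best_k - 1L

  # refine-and-prune: greedy insertion can misplace an early boundary and
  # patch it with an extra split. Re-optimise each change point within its
  # flanking segments, then drop change points that no longer pay their
  # penalty; iterate to a fixed point.
  total_rss <- function(b) {
    sum(vapply(seq_len(length(b) - 1),
               function(h) seg_rss(cs, cs2, b[h], b[h + 1] - 1L), numeric(1)))
  }
  for (pass in 1:20) {
    changed <- FALSE
    # (a) relocate
    for (j in seq_along(bounds)[-c(1, length(bounds))]) {
      bs <- best_split(cs, cs2, bounds[j - 1], bounds[j + 1] - 1L, min_plateau)
      if (!is.null(bs) && bs[1] != bounds[j]) {
        old <- seg_rss(cs, cs2, bounds[j - 1], bounds[j] - 1L) +
          seg_rss(cs, cs2, bounds[j], bounds[j + 1] - 1L)
        if (bs[2] < old - 1e-9) {
          bounds[j] <- as.integer(bs[1])
          changed <- TRUE
        }
      }
    }
    # (b) prune
    j <- 2L
    while (j < length(bounds)) {
      rss_with <- seg_rss(cs, cs2, bounds[j - 1], bounds[j] - 1L) +
        seg_rss(cs, cs2, bounds[j], bounds[j + 1] - 1L)
      rss_without <- seg_rss(cs, cs2, bounds[j - 1], bounds[j + 1] - 1L)
      rss_cur <- total_rss(bounds)
      if (crit(rss_cur - rss_with + rss_without, k - 1L) <
          crit(rss_cur, k) - 1e-9) {
        bounds <- bounds[-j]
        k <- k - 1L
        changed <- TRUE
      } else {
        j <- j + 1L
      }
    }
    if (!changed) break
  }
  rss <- total_rss(bounds)

  starts <- bounds[-length(bounds)]
  ends <- bounds[-1] - 1L
  levels <- (cs[ends + 1] - cs[starts]) / (ends - starts + 1)
  cp <- if (k > 0) bounds[2:(k + 1)] else integer(0)
  dl <- diff(levels)
  structure(
    list(change_points = cp[dl < 0], levels = levels,
         n_steps = sum(dl < 0), n_up = sum(dl > 0),
         up_points = cp[dl > 0],
         rss = rss, penalty = penalty, n_frames = n,
         min_plateau = min_plateau),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit: %d downward steps (%d upward flagged), RSS %.4g\n",
              x$n_steps, x$n_up, x$rss))
  invisible(x)
}

#' Monomer count of an oligomer from its photobleaching steps
#'
#' Each downward step is the bleaching of one fluorophore, so the step count
#' estimates the number of labelled monomers in the spot. Counts above the
#' saturation cap (default 10) cannot be resolved — larger oligomers bleach
#' multiple fluorophores within a frame — and are reported as the censored
#' ">= cap" category.
#'
#' @param fit A [fit_steps()] result.
#' @param cap Saturation cap in monomer units.
#' @return Integer monomer count, capped at `cap`; attributes `censored`
#'   (logical) and `label` (e.g. `">=10"` when censored).
#' @export
monomers_per_oligomer <- function(fit, cap = 10) {
  stopifnot(inherits(fit, "step_fit"), cap >= 1)
  n <- fit$n_steps
  censored <- n > cap
  structure(min(n, cap),
            censored = censored,
            label = if (censored) paste0(">=", cap) else as.character(n))
}

#' Histogram of monomers per oligomer
#'
#' Integer-binned histogram of step counts across a population of spots,
#' with counts at or above the saturation cap pooled into a final
#' ">= cap" category.
#'
#' @param counts Integer vector of per-spot monomer counts (each >= 1).
#' @param cap Saturation cap; counts `>= cap` fall into the last category.
#' @return Named integer vector over the observed categories, saturation
#'   category last.
#' @examples
#' size_histogram(c(2, 2, 4))
#' @export
size_histogram <- function(counts, cap = 10) {
  if (length(counts) == 0) return(stats::setNames(integer(0), character(0)))
  stopifnot(all(counts >= 1), cap >= 2)
  lab <- ifelse(counts >= cap, paste0(">=", cap), as.character(counts))
  lv <- c(as.character(seq_len(cap - 1)), paste0(">=", cap))
  tab <- table(factor(lab, levels = lv))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0]
}
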