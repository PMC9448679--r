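# Independent oracles used to cross-check the package implementations.
# These deliberately use naive scans/enumeration, not the package's code paths.

# Per-bin brute-force burst detection: walk the trace, grow runs one bin at a
# time, sum counts by explicit indexing.
oracle_detect <- function(d, a, threshold) {
  events <- list()
  i <- 1L
  n <- length(d)
  while (i <= n) {
    if (d[i] >= threshold) {
      j <- i
      while (j < n && d[j + 1] >= threshold) j <- j + 1L
      events[[length(events) + 1L]] <- data.frame(
        start = i, end = j,
        donor_raw = sum(d[i:j]), acceptor_raw = sum(a[i:j]),
        coincident = any(a[i:j] >= threshold))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(events)) do.call(rbind, events) else
    data.frame(start = integer(0), end = integer(0), donor_raw = numeric(0),
               acceptor_raw = numeric(0), coincident = logical(0))
}

# Exhaustive change-point search: minimum RSS over all placements of k change
# points with the given minimum plateau length.
oracle_step_rss <- function(y, k, min_plateau = 3) {
  n <- length(y)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  seg <- function(l, r) (cs2[r + 1] - cs2[l]) - (cs[r + 1] - cs[l])^2 / (r - l + 1)
  if (k == 0) return(seg(1, n))
  combs <- utils::combn(2:n, k)
  best <- Inf
  for (ci in seq_len(ncol(combs))) {
    b <- c(1L, combs[, ci], n + 1L)
    if (any(diff(b) < min_plateau)) next
    rss <- sum(vapply(seq_len(length(b) - 1),
                      function(h) seg(b[h], b[h + 1] - 1L), numeric(1)))
    if (rss < best) best <- rss
  }
  best
}

# Deterministic noise-free staircase fixture.
staircase <- function(levels, plateau = 20) rep(levels, each = plateau)

# Event -> efficiency vector shared by several tests: full burst pipeline on a
# simulated stream.
pipeline_efficiencies <- function(preset, seed, n_events = NULL) {
  sim <- simulate_burst_stream(preset, seed = seed, n_events = n_events)
  ev <- analyze_events(detect_events(sim$trace), preset$instrument)
  ev$E[ev$coincident & !is.na(ev$E)]
}
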