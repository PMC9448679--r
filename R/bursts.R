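#' Two-channel photon-count trace
#'
#' Container for a binned two-channel photon time series from fast-flow
#' confocal acquisition: equal-length non-negative integer series of donor-
#' and acceptor-channel counts per bin plus the bin width.
#'
#' @param donor_counts,acceptor_counts Non-negative integer count series of
#'   equal length.
#' @param bin_width Bin width in seconds (default 1 ms).
#' @return An object of class `photon_trace`.
#' @export
photon_trace <- function(donor_counts, acceptor_counts, bin_width = 0.001) {
  stopifnot(length(donor_counts) == length(acceptor_counts),
            all(donor_counts >= 0), all(acceptor_counts >= 0),
            bin_width > 0)
  structure(
    list(donor_counts = as.integer(donor_counts),
         acceptor_counts = as.integer(acceptor_counts),
         bin_width = bin_width),
    class = "photon_trace"
  )
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("Photon trace: %d bins of %g s (%.3g s total)\n",
              length(x$donor_counts), x$bin_width,
              length(x$donor_counts) * x$bin_width))
  invisible(x)
}

empty_trace_error <- function() {
  errorCondition("photon trace has no bins",
                 class = c("oligofret_empty_trace", "oligofret_error"))
}

no_events_error <- function(msg) {
  errorCondition(msg, class = c("oligofret_no_events", "oligofret_error"))
}

#' Detect single-molecule burst events in a photon trace
#'
#' A donor event is a maximal run of consecutive bins with donor counts at or
#' above `threshold`; merging consecutive supra-threshold bins into one event
#' avoids double-counting slow transits. An event is coincident when at least
#' one bin of the run also reaches `threshold` in the acceptor channel —
#' photons in both channels simultaneously imply a species carrying both dye
#' types, i.e. an oligomer. Event intensity is the summed counts over the run
#' (`intensity = "sum"`, default) or the peak single bin
#' (`intensity = "peak"`). Runs touching the trace boundary are kept and
#' flagged `edge`.
#'
#' @param trace A [photon_trace()].
#' @param threshold Counts per bin required in a channel (default 10).
#' @param intensity `"sum"` or `"peak"` per-event intensity rule.
#' @return An `event_set`: a `data.frame` with one row per donor event
#'   (`start`, `end`, `n_bins`, `donor_raw`, `acceptor_raw`, `coincident`,
#'   `edge`) carrying attributes `threshold`, `bin_width` and
#'   `n_donor_events`.
#' @examples
#' tr <- photon_trace(c(12, 15, 3), c(4, 11, 2))
#' detect_events(tr) # one event over bins 1-2, coincident
#' @export
detect_events <- function(trace, threshold = 10, intensity = c("sum", "peak")) {
  stopifnot(inherits(trace, "photon_trace"), threshold >= 1)
  intensity <- match.arg(intensity)
  d <- trace$donor_counts
  a <- trace$acceptor_counts
  n <- length(d)
  if (n == 0) stop(empty_trace_error())

  runs <- rle(d >= threshold)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]; ends <- ends[keep]

  if (length(starts) == 0) {
    ev <- data.frame(start = integer(0), end = integer(0), n_bins = integer(0),
                     donor_raw = numeric(0), acceptor_raw = numeric(0),
                     coincident = logical(0), edge = logical(0))
  } else {
    csd <- cumsum(c(0, d)); csa <- cumsum(c(0, a))
    donor_raw <- if (intensity == "sum") csd[ends + 1L] - csd[starts] else
      vapply(seq_along(starts), function(i) max(d[starts[i]:ends[i]]), numeric(1))
    acceptor_raw <- if (intensity == "sum") csa[ends + 1L] - csa[starts] else
      vapply(seq_along(starts), function(i) max(a[starts[i]:ends[i]]), numeric(1))
    coincident <- vapply(seq_along(starts), function(i) {
      any(a[starts[i]:ends[i]] >= threshold)
    }, logical(1))
    ev <- data.frame(
      start = starts, end = ends, n_bins = ends - starts + 1L,
      donor_raw = as.numeric(donor_raw),
      acceptor_raw = as.numeric(acceptor_raw),
      coincident = coincident,
      edge = starts == 1L | ends == n
    )
  }
  structure(ev,
            class = c("event_set", "data.frame"),
            threshold = threshold,
            bin_width = trace$bin_width,
            intensity_rule = intensity,
            n_donor_events = nrow(ev),
            n_coincident = sum(ev$coincident))
}

#' Mean monomer brightness from non-coincident donor bursts
#'
#' Events above threshold in the donor channel only (no acceptor signal)
#' are attributed to single donor-labelled monomers; their mean donor
#' intensity calibrates the apparent-size scale.
#'
#' @param events An `event_set` from [detect_events()].
#' @return Mean donor intensity of non-coincident events (counts).
#' @export
monomer_brightness <- function(events) {
  stopifnot(inherits(events, "event_set"))
  mono <- events$donor_raw[!events$coincident]
  if (length(mono) == 0) {
    stop(no_events_error(paste(
      "no non-coincident donor events: supply `monomer_brightness`",
      "explicitly via instrument_params()")))
  }
  mean(mono)
}

#' Compute corrected intensities, efficiency and size for detected events
#'
#' Applies the channel corrections (`I_D = D - A_D`,
#' `I_A = A - A_A - C * D`) to each coincident event, computes the FRET
#' efficiency `E = I_A / (I_A + I_D)` and the apparent size
#' `2 (I_D + I_A / gamma) / I_monomer`, and assigns the size class. Events
#' with negative corrected intensities are flagged `excluded` (not clamped)
#' and carry `NA` efficiency/size; the exclusion count is recorded in the
#' `n_excluded` attribute. If `params` carries no `monomer_brightness`, it is
#' estimated from the non-coincident donor bursts via [monomer_brightness()].
#'
#' @param events An `event_set` from [detect_events()].
#' @param params [instrument_params()].
#' @param small_max,medium_max Size-class boundaries (see [classify_size()]).
#' @return The `event_set` with columns `I_D`, `I_A`, `excluded`, `E`,
#'   `apparent_size`, `size_class` added; attributes `monomer_brightness` and
#'   `n_excluded` record the calibration used and the exclusions.
#' @export
analyze_events <- function(events, params, small_max = 3, medium_max = 20) {
  stopifnot(inherits(events, "event_set"))
  params <- as_instrument_params(params)
  i_mono <- params$monomer_brightness
  if (is.na(i_mono)) {
    i_mono <- monomer_brightness(events)
    params$monomer_brightness <- i_mono
  }

  events$I_D <- correct_donor(events$donor_raw, params)
  events$I_A <- correct_acceptor(events$acceptor_raw, events$donor_raw, params)
  events$excluded <- events$coincident &
    flag_negative_intensity(events$I_D, events$I_A)

  events$E <- NA_real_
  events$apparent_size <- NA_real_
  ok <- events$coincident & !events$excluded
  if (any(ok)) {
    events$E[ok] <- fret_efficiency(events$I_D[ok], events$I_A[ok])
    events$apparent_size[ok] <-
      apparent_size(events$I_D[ok], events$I_A[ok], params)
  }
  events$size_class <- factor(NA, levels = c("small", "medium", "large"))
  events$size_class[ok] <- classify_size(events$apparent_size[ok],
                                         small_max, medium_max)
  attr(events, "monomer_brightness") <- i_mono
  attr(events, "n_excluded") <- sum(events$excluded)
  events
}

#' Fraction of coincident events
#'
#' Number of coincident events divided by the total number of events above
#' threshold in the donor channel. For a dual-labelled sample in which every
#' molecule can undergo FRET this fraction is limited by the chance of both
#' dyes being detected and is well below 1 in practice.
#'
#' @param events An `event_set` from [detect_events()].
#' @return Fraction in `[0, 1]`.
#' @export
fraction_of_coincidence <- function(events) {
  stopifnot(inherits(events, "event_set"))
  n <- nrow(events)
  if (n == 0) stop(no_events_error("no donor events above threshold"))
  sum(events$coincident) / n
}

#' Run summary for a burst analysis
#'
#' Collects the counts, calibration and exclusions of an analysed event set
#' into a plain list suitable for JSON serialisation.
#'
#' @param events An `event_set`, ideally after [analyze_events()].
#' @return A list: thresholds, event counts, coincident fraction, monomer
#'   brightness and exclusion count.
#' @export
burst_summary <- function(events) {
  stopifnot(inherits(events, "event_set"))
  list(
    threshold = attr(events, "threshold"),
    bin_width = attr(events, "bin_width"),
    intensity_rule = attr(events, "intensity_rule"),
    n_donor_events = nrow(events),
    n_coincident = sum(events$coincident),
    fraction_coincident = if (nrow(events) > 0)
      sum(events$coincident) / nrow(events) else NA_real_,
    monomer_brightness = attr(events, "monomer_brightness"),
    n_excluded = attr(events, "n_excluded")
  )
}
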