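#' Specify a simulated oligomeric species
#'
#' A species is defined by its true size (monomer units), the centre and
#' spread of its true per-event FRET efficiency, its mixture weight and the
#' expected photon yield of one donor fluorophore per event. Per-event
#' efficiencies are drawn from a normal distribution truncated to `[0, 1]`,
#' so a species maps onto one Gaussian component of the efficiency histogram.
#'
#' @param size True size in monomer units (integer >= 1). Donor fluorophores
#'   per event are `ceiling(size / 2)`: half the monomers carry the donor dye.
#' @param efficiency True FRET efficiency centre in `[0, 1]`.
#' @param weight Mixture weight (weights are normalised across species).
#' @param brightness_per_monomer Expected photons emitted per donor
#'   fluorophore per event.
#' @param efficiency_sd Spread of the true efficiency across events.
#' @param name Optional species label.
#' @return A one-row `data.frame`; rbind several to build a mixture.
#' @export
species_spec <- function(size, efficiency, weight = 1,
                         brightness_per_monomer = 50,
                         efficiency_sd = 0, name = NULL) {
  stopifnot(size >= 1, efficiency >= 0, efficiency <= 1, weight > 0,
            brightness_per_monomer > 0, efficiency_sd >= 0)
  data.frame(
    name = if (is.null(name)) sprintf("species_E%.2f", efficiency) else name,
    size = as.integer(round(size)),
    efficiency = efficiency,
    efficiency_sd = efficiency_sd,
    weight = weight,
    brightness_per_monomer = brightness_per_monomer,
    stringsAsFactors = FALSE
  )
}

#' Load or build a simulation scenario preset
#'
#' Named presets live in the package's `presets.yaml` and are immutable;
#' `paper_mimic` generates two oligomer populations with efficiency
#' components centred at 0.24 and 0.48 (60/40 weights, spread 0.08) at an
#' event rate giving 5,000 expected events over a 600 s acquisition.
#' `monomer_only` generates a donor-only monomeric species. Pass a species
#' table and instrument to build a custom scenario instead.
#'
#' @param name Preset name (`"paper_mimic"`, `"monomer_only"`) — ignored when
#'   `species` is given, in which case it labels the custom scenario.
#' @param species Optional `data.frame` of [species_spec()] rows.
#' @param instrument Optional [instrument_params()] (preset default otherwise).
#' @param event_rate Events per second.
#' @param duration Acquisition length in seconds.
#' @param bin_width Trace bin width in seconds (default 1 ms).
#' @return An object of class `scenario_preset`.
#' @examples
#' scenario_preset("paper_mimic")
#' @export
scenario_preset <- function(name = "paper_mimic", species = NULL,
                            instrument = NULL, event_rate = NULL,
                            duration = NULL, bin_width = NULL) {
  if (is.null(species)) {
    path <- system.file("extdata", "presets.yaml", package = "oligofret",
                        mustWork = TRUE)
    presets <- yaml::read_yaml(path)
    if (!name %in% names(presets)) {
      stop(invalid_params_error(sprintf(
        "unknown preset '%s'; available: %s", name,
        paste(names(presets), collapse = ", "))))
    }
    p <- presets[[name]]
    species <- do.call(rbind, lapply(p$species, function(s) {
      species_spec(s$size, s$efficiency, s$weight, s$brightness_per_monomer,
                   s$efficiency_sd, s$name)
    }))
    if (is.null(instrument)) instrument <- do.call(instrument_params, p$instrument)
    if (is.null(event_rate)) event_rate <- p$event_rate
    if (is.null(duration)) duration <- p$duration
    if (is.null(bin_width)) bin_width <- p$bin_width
  } else {
    if (is.null(instrument)) instrument <- instrument_params()
    if (is.null(event_rate)) event_rate <- 8.333333333
    if (is.null(duration)) duration <- 600
    if (is.null(bin_width)) bin_width <- 0.001
  }
  instrument <- as_instrument_params(instrument)
  stopifnot(is.data.frame(species), nrow(species) >= 1,
            event_rate > 0, duration > 0, bin_width > 0)
  species$weight <- species$weight / sum(species$weight)
  structure(
    list(name = name, species = species, instrument = instrument,
         event_rate = event_rate, duration = duration, bin_width = bin_width),
    class = "scenario_preset"
  )
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("Scenario preset '%s': %d species, %g events/s over %g s (bin %g s)\n",
              x$name, nrow(x$species), x$event_rate, x$duration, x$bin_width))
  print(x$species)
  invisible(x)
}

# Normal draw truncated to [lo, hi] by inverse-CDF sampling.
rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- numeric(n)
  fixed <- sd == 0
  out[fixed] <- pmin(pmax(mean[fixed], lo), hi)
  if (any(!fixed)) {
    m <- mean[!fixed]; s <- sd[!fixed]
    plo <- stats::pnorm(lo, m, s); phi <- stats::pnorm(hi, m, s)
    out[!fixed] <- stats::qnorm(plo + stats::runif(sum(!fixed)) * (phi - plo), m, s)
  }
  out
}

# Draw per-event true species, efficiency and expected donor-side brightness.
draw_event_truth <- function(preset, n) {
  sp <- preset$species
  idx <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$weight)
  e_true <- rtruncnorm01(n, sp$efficiency[idx], sp$efficiency_sd[idx])
  n_donor_fluor <- ceiling(sp$size[idx] / 2)
  data.frame(
    species = sp$name[idx],
    size_true = sp$size[idx],
    e_true = e_true,
    brightness = n_donor_fluor * sp$brightness_per_monomer[idx]
  )
}

#' Simulate single-molecule FRET events (event-level generator)
#'
#' Draws `n_events` bursts directly (without placing them on a time axis):
#' per event, donor photons are Poisson with mean `B * (1 - E)`, FRET
#' acceptor photons Poisson with mean `gamma * B * E` where `B` is the
#' expected donor-side photon yield, then Poisson backgrounds `A_D`/`A_A`
#' are added and cross-talk is drawn as `Poisson(C * donor counts)` from the
#' measured donor counts — so the Eq.-style corrections remove background and
#' cross-talk without bias.
#'
#' @param preset A [scenario_preset()].
#' @param n_events Number of events to draw.
#' @param seed Optional integer seed (reproducible output for a fixed seed).
#' @return A list with `events` (`data.frame` of `donor_raw`, `acceptor_raw`)
#'   and `truth` (per-event species, true size and efficiency). Ground truth
#'   is a side channel only: analysis functions never read it.
#' @export
simulate_events <- function(preset, n_events, seed = NULL) {
  stopifnot(inherits(preset, "scenario_preset"), n_events >= 1)
  if (!is.null(seed)) set.seed(seed)
  inst <- preset$instrument
  truth <- draw_event_truth(preset, n_events)
  d_photons <- stats::rpois(n_events, truth$brightness * (1 - truth$e_true))
  a_fret <- stats::rpois(n_events, inst$gamma * truth$brightness * truth$e_true)
  donor_raw <- d_photons + stats::rpois(n_events, inst$autofluor_donor)
  acceptor_raw <- a_fret +
    stats::rpois(n_events, inst$crosstalk * donor_raw) +
    stats::rpois(n_events, inst$autofluor_acceptor)
  list(
    events = data.frame(donor_raw = donor_raw, acceptor_raw = acceptor_raw),
    truth = truth
  )
}

#' Simulate a two-channel photon-count trace of diffusing species
#'
#' Emulates fast-flow confocal acquisition: event arrivals are Poisson in
#' time (at most one bin per event at default rates; pile-up in a shared bin
#' is allowed and recorded in the ground truth), each event deposits its
#' donor and FRET-acceptor photons into one bin, per-bin Poisson backgrounds
#' `A_D`/`A_A` cover the whole trace, and acceptor cross-talk is drawn as
#' `Poisson(C * donor bin counts)` so the correction constants used by the
#' analysis are exactly the ones the generator used.
#'
#' @param preset A [scenario_preset()]; `event_rate * duration` sets the
#'   expected event count.
#' @param seed Optional integer seed.
#' @param n_events Optional fixed event count (otherwise Poisson-distributed).
#' @return A list with `trace` (a [photon_trace()]) and `truth` (per-event bin,
#'   species, true efficiency and size, plus a `pileup` flag).
#' @examples
#' sim <- simulate_burst_stream(scenario_preset("paper_mimic"), seed = 1)
#' @export
simulate_burst_stream <- function(preset, seed = NULL, n_events = NULL) {
  stopifnot(inherits(preset, "scenario_preset"))
  if (!is.null(seed)) set.seed(seed)
  inst <- preset$instrument
  n_bins <- as.integer(round(preset$duration / preset$bin_width))
  if (n_bins < 1) stop(invalid_params_error("preset duration shorter than one bin"))
  if (is.null(n_events)) {
    n_events <- stats::rpois(1, preset$event_rate * preset$duration)
  }
  truth <- if (n_events > 0) draw_event_truth(preset, n_events) else NULL

  donor <- stats::rpois(n_bins, inst$autofluor_donor)
  a_fret_bins <- integer(n_bins)
  if (n_events > 0) {
    bins <- sample.int(n_bins, n_events, replace = TRUE)
    d_photons <- stats::rpois(n_events, truth$brightness * (1 - truth$e_true))
    a_fret <- stats::rpois(n_events, inst$gamma * truth$brightness * truth$e_true)
    donor <- donor + as.integer(tapply_add(d_photons, bins, n_bins))
    a_fret_bins <- as.integer(tapply_add(a_fret, bins, n_bins))
    truth$bin <- bins
    truth$pileup <- bins %in% bins[duplicated(bins)]
  }
  acceptor <- a_fret_bins +
    stats::rpois(n_bins, inst$crosstalk * donor) +
    stats::rpois(n_bins, inst$autofluor_acceptor)
  list(
    trace = photon_trace(donor, acceptor, bin_width = preset$bin_width),
    truth = truth
  )
}

# Sum `values` into `n` accumulator slots indexed by `index`.
tapply_add <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Simulate a three-channel in-cell voxel stack with core/rim aggregates
#'
#' Aggregates are rendered as spherical cores of high FRET efficiency
#' surrounded by rims of low efficiency, matching the stereotyped geometry of
#' maturing intracellular aggregates (ordered centre, loosely ordered rim).
#' Channels are donor-excitation/donor-emission (`donor`),
#' donor-excitation/acceptor-emission (`acceptor`) and
#' acceptor-excitation/acceptor-emission (`direct`, the total-protein proxy).
#' Autofluorescence is added everywhere; every voxel is Poisson-distributed.
#'
#' @param layout `data.frame` with one aggregate per row: columns `x`, `y`,
#'   `z` (centre, voxels), `r_core`, `r_rim` (radii, voxels; rim must fit in
#'   the image), `e_core`, `e_rim` (true efficiencies), `brightness`
#'   (donor-excitation photon mean per aggregate voxel), `direct_brightness`
#'   (direct-excitation mean) and optionally `cell` (integer label). May have
#'   zero rows for a blank stack.
#' @param dim Stack dimensions `c(nx, ny, nz)`.
#' @param instrument [instrument_params()]; its autofluorescence constants are
#'   the per-voxel background means.
#' @param direct_background Mean direct-channel background per voxel.
#' @param seed Optional integer seed.
#' @return A list with `stack` (a [voxel_stack()]) and `truth` (logical `core`
#'   and `rim` arrays, integer `labels` array, and the layout).
#' @export
simulate_incell_stack <- function(layout, dim = c(64, 64, 8),
                                  instrument = instrument_params(2, 2, 0.05, 1),
                                  direct_background = 2, seed = NULL) {
  stopifnot(length(dim) == 3, all(dim >= 1))
  instrument <- as_instrument_params(instrument)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(layout)) layout <- data.frame()
  if (nrow(layout) > 0) {
    need <- c("x", "y", "z", "r_core", "r_rim", "e_core", "e_rim",
              "brightness", "direct_brightness")
    if (!all(need %in% names(layout))) {
      stop(invalid_params_error(paste("layout must have columns:",
                                      paste(need, collapse = ", "))))
    }
    if (is.null(layout$cell)) layout$cell <- seq_len(nrow(layout))
    inb <- layout$x - layout$r_rim >= 1 & layout$x + layout$r_rim <= dim[1] &
      layout$y - layout$r_rim >= 1 & layout$y + layout$r_rim <= dim[2] &
      layout$z >= 1 & layout$z <= dim[3]
    if (!all(inb)) {
      stop(errorCondition("aggregate geometry out of image bounds",
                          class = c("oligofret_geometry_oob", "oligofret_error")))
    }
  }

  e_map <- array(0, dim); t_map <- array(0, dim); direct_sig <- array(0, dim)
  core <- array(FALSE, dim); rim <- array(FALSE, dim)
  labels <- array(0L, dim)
  if (nrow(layout) > 0) {
    ax <- slice.index(e_map, 1); ay <- slice.index(e_map, 2)
    az <- slice.index(e_map, 3)
    for (i in seq_len(nrow(layout))) {
      d2 <- (ax - layout$x[i])^2 + (ay - layout$y[i])^2 + (az - layout$z[i])^2
      in_core <- d2 <= layout$r_core[i]^2
      in_rim <- d2 <= layout$r_rim[i]^2 & !in_core
      core <- core | in_core
      rim <- rim | in_rim
      sel <- in_core | in_rim
      e_map[in_core] <- layout$e_core[i]
      e_map[in_rim] <- layout$e_rim[i]
      t_map[sel] <- layout$brightness[i]
      direct_sig[sel] <- layout$direct_brightness[i]
      labels[sel] <- as.integer(layout$cell[i])
    }
  }

  nvox <- prod(dim)
  donor <- array(stats::rpois(nvox, instrument$autofluor_donor +
                                t_map * (1 - e_map)), dim)
  acceptor <- array(stats::rpois(nvox, instrument$autofluor_acceptor +
                                   instrument$gamma * t_map * e_map), dim) +
    array(stats::rpois(nvox, instrument$crosstalk * donor), dim)
  direct <- array(stats::rpois(nvox, direct_background + direct_sig), dim)

  list(
    stack = voxel_stack(donor, acceptor, direct),
    truth = list(core = core, rim = rim, labels = labels, e_true = e_map,
                 layout = layout, direct_background = direct_background)
  )
}

#' Simulate a stepwise photobleaching intensity trace
#'
#' Each of `n_fluor` fluorophores bleaches at an independent geometric time
#' (probability `bleach_prob_per_frame` per frame), truncated so every
#' fluorophore bleaches within the trace and separated by at least `min_gap`
#' frames so that steps are resolvable — simultaneous bleaching is precisely
#' the regime in which step counting saturates and is not emulated. Intensity
#' is `baseline + step_height * (fluorophores remaining)` plus Gaussian noise.
#'
#' @param n_fluor Number of fluorophores (integer >= 0).
#' @param step_height Intensity drop per bleaching event (ADU).
#' @param noise_sd Gaussian noise standard deviation (ADU).
#' @param bleach_prob_per_frame Per-frame bleaching probability.
#' @param n_frames Trace length in frames.
#' @param baseline Post-bleach background level (ADU).
#' @param min_gap Minimum frames between consecutive bleaching events.
#' @param frame_interval Seconds per frame (metadata only).
#' @param seed Optional integer seed.
#' @return A list with `trace` (a [bleach_trace()]) and `truth`
#'   (`change_points`: first frame at each new level; `n_steps`).
#' @export
simulate_bleach_trace <- function(n_fluor, step_height = 100, noise_sd = 0,
                                  bleach_prob_per_frame = 0.02,
                                  n_frames = 200, baseline = 50, min_gap = 5,
                                  frame_interval = 0.05, seed = NULL) {
  stopifnot(n_fluor >= 0, step_height > 0, noise_sd >= 0, n_frames >= 10,
            bleach_prob_per_frame > 0, bleach_prob_per_frame < 1, min_gap >= 1)
  if (!is.null(seed)) set.seed(seed)
  cp <- integer(0)
  if (n_fluor > 0) {
    if ((n_fluor + 1) * min_gap >= n_frames) {
      stop(invalid_params_error("n_frames too short for n_fluor resolvable steps"))
    }
    for (try in 1:10000) {
      t_bleach <- sort(1L + stats::rgeom(n_fluor, bleach_prob_per_frame))
      ok <- t_bleach[1] > min_gap &&
        t_bleach[n_fluor] <= n_frames - min_gap &&
        (n_fluor == 1 || all(diff(t_bleach) >= min_gap))
      if (ok) { cp <- t_bleach; break }
    }
    if (length(cp) == 0) {
      stop(invalid_params_error(
        "could not draw resolvable bleaching times; lower n_fluor or min_gap"))
    }
  }
  remaining <- n_fluor - findInterval(seq_len(n_frames), cp)
  intensity <- baseline + step_height * remaining +
    stats::rnorm(n_frames, 0, noise_sd)
  list(
    trace = bleach_trace(intensity, frame_interval = frame_interval),
    truth = list(change_points = cp, n_steps = n_fluor,
                 levels = baseline + step_height * (n_fluor:0))
  )
}

#' Simulate a two-colour spot field with a set coincidence fraction
#'
#' A fraction of spots share coordinates across the two channels (coincident
#' aggregates carrying both labels); the rest are placed independently and
#' uniformly. Spots are rendered as 2-D Gaussian point-spread functions and
#' the image is Poisson shot-noise sampled over a uniform background.
#'
#' @param n_spots Spots per channel per field.
#' @param coincidence_fraction Fraction of channel-A spots sharing a channel-B
#'   spot position, in `[0, 1]`.
#' @param fov Field-of-view size in pixels, `c(nx, ny)`. The default keeps
#'   300 spots at ~0.1 spots per square micron (100 nm pixels), the sparse
#'   regime single-aggregate imaging requires: at higher densities
#'   aggregates closer than the PSF merge and per-aggregate counting breaks
#'   down for any detector.
#' @param psf_sigma Gaussian PSF standard deviation (pixels).
#' @param n_fields Number of independent fields to generate.
#' @param mean_intensity Mean integrated spot intensity (counts); per-spot
#'   intensities are exponentially-modulated around it (gamma with shape 4).
#' @param background Mean background counts per pixel.
#' @param seed Optional integer seed.
#' @return A list of fields; each field has `images` (list of matrices `a`,
#'   `b`) and `truth` (spot coordinate tables and the coincident count).
#' @export
simulate_two_color_spots <- function(n_spots, coincidence_fraction,
                                     fov = c(1024, 1024), psf_sigma = 1.5,
                                     n_fields = 1, mean_intensity = 2000,
                                     background = 10, seed = NULL) {
  stopifnot(n_spots >= 1, coincidence_fraction >= 0, coincidence_fraction <= 1,
            length(fov) == 2, all(fov >= 16), n_fields >= 1)
  if (!is.null(seed)) set.seed(seed)
  margin <- ceiling(4 * psf_sigma) + 1
  runif_xy <- function(n) {
    cbind(x = stats::runif(n, margin, fov[1] - margin),
          y = stats::runif(n, margin, fov[2] - margin))
  }
  render <- function(coords, intens) {
    img <- matrix(0, fov[1], fov[2])
    r <- ceiling(4 * psf_sigma)
    for (i in seq_len(nrow(coords))) {
      x0 <- coords[i, 1]; y0 <- coords[i, 2]
      xs <- max(1, floor(x0) - r):min(fov[1], ceiling(x0) + r)
      ys <- max(1, floor(y0) - r):min(fov[2], ceiling(y0) + r)
      gx <- exp(-(xs - x0)^2 / (2 * psf_sigma^2))
      gy <- exp(-(ys - y0)^2 / (2 * psf_sigma^2))
      img[xs, ys] <- img[xs, ys] +
        intens[i] / (2 * pi * psf_sigma^2) * outer(gx, gy)
    }
    matrix(stats::rpois(length(img), img + background), fov[1], fov[2])
  }
  lapply(seq_len(n_fields), function(f) {
    n_co <- round(coincidence_fraction * n_spots)
    shared <- runif_xy(n_co)
    a_xy <- rbind(shared, runif_xy(n_spots - n_co))
    b_xy <- rbind(shared, runif_xy(n_spots - n_co))
    int_a <- stats::rgamma(n_spots, shape = 4, scale = mean_intensity / 4)
    int_b <- stats::rgamma(n_spots, shape = 4, scale = mean_intensity / 4)
    list(
      images = list(a = render(a_xy, int_a), b = render(b_xy, int_b)),
      truth = list(a = as.data.frame(a_xy), b = as.data.frame(b_xy),
                   n_coincident = n_co, fov = fov)
    )
  })
}
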