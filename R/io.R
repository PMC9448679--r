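#' Write / read a photon trace as CSV
#'
#' Columns: `bin_index`, `donor_counts`, `acceptor_counts`. The bin width is
#' not stored in the CSV; supply it on reading.
#'
#' @param trace A [photon_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  utils::write.csv(
    data.frame(bin_index = seq_along(trace$donor_counts),
               donor_counts = trace$donor_counts,
               acceptor_counts = trace$acceptor_counts),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param bin_width Bin width in seconds of the stored trace.
#' @export
read_trace_csv <- function(path, bin_width = 0.001) {
  df <- utils::read.csv(path)
  stopifnot(all(c("donor_counts", "acceptor_counts") %in% names(df)))
  photon_trace(df$donor_counts, df$acceptor_counts, bin_width = bin_width)
}

#' Write / read an analysed event set as CSV
#'
#' One row per event: trace position, raw and corrected intensities,
#' efficiency, apparent size, size class and flags.
#'
#' @param events An `event_set` (see [detect_events()], [analyze_events()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "event_set"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  if ("size_class" %in% names(df)) {
    df$size_class <- factor(df$size_class, levels = c("small", "medium", "large"))
  }
  structure(df, class = c("event_set", "data.frame"),
            n_donor_events = nrow(df),
            n_coincident = sum(df$coincident))
}

#' Write / read a bleach trace as CSV (`frame`, `intensity`)
#'
#' @param trace A [bleach_trace()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_bleach_csv <- function(trace, path) {
  stopifnot(inherits(trace, "bleach_trace"))
  utils::write.csv(data.frame(frame = seq_along(trace$intensity),
                              intensity = trace$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bleach_csv
#' @param frame_interval Seconds per frame of the stored trace.
#' @export
read_bleach_csv <- function(path, frame_interval = 0.05) {
  df <- utils::read.csv(path)
  stopifnot("intensity" %in% names(df))
  bleach_trace(df$intensity, frame_interval = frame_interval)
}

# Integer count images round-trip losslessly through 16-bit TIFF.
write_count_tiff <- function(x, path) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  stopifnot(all(x >= 0), all(x <= 65535))
  pages <- lapply(seq_len(dim(x)[3]), function(z) x[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

read_count_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  arr
}

#' Write / read a three-channel voxel stack as TIFF files
#'
#' Each channel is written as one multi-page 16-bit TIFF (`<prefix>_donor.tif`,
#' `<prefix>_acceptor.tif`, `<prefix>_direct.tif`); integer counts round-trip
#' exactly.
#'
#' @param stack A [voxel_stack()].
#' @param prefix Path prefix for the three channel files.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_stack_tiff <- function(stack, prefix) {
  stopifnot(inherits(stack, "voxel_stack"))
  paths <- c(donor = paste0(prefix, "_donor.tif"),
             acceptor = paste0(prefix, "_acceptor.tif"),
             direct = paste0(prefix, "_direct.tif"))
  write_count_tiff(stack$donor, paths["donor"])
  write_count_tiff(stack$acceptor, paths["acceptor"])
  write_count_tiff(stack$direct, paths["direct"])
  invisible(paths)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(prefix) {
  voxel_stack(read_count_tiff(paste0(prefix, "_donor.tif")),
              read_count_tiff(paste0(prefix, "_acceptor.tif")),
              read_count_tiff(paste0(prefix, "_direct.tif")))
}

#' Write / read an efficiency map as a 32-bit TIFF
#'
#' TIFF samples are stored on `[0, 1]`, so the map is encoded as
#' `(E + 1) / 2` — valid efficiencies occupy `[0.5, 1]` and `NA` voxels
#' (unmasked or excluded) are written as the sentinel 0. [read_e_map_tiff()]
#' inverts the encoding; 32-bit quantisation (~2^-32) is far below any
#' meaningful efficiency difference.
#'
#' @param E Efficiency array from [voxel_fret_map()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_e_map_tiff <- function(E, path) {
  if (is.matrix(E)) E <- array(E, c(dim(E), 1))
  x <- (E + 1) / 2
  x[is.na(x)] <- 0
  pages <- lapply(seq_len(dim(x)[3]), function(z) x[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_e_map_tiff
#' @export
read_e_map_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) {
    m <- pages[[z]] * 2 - 1
    m[pages[[z]] < 0.25] <- NA_real_
    arr[, , z] <- m
  }
  arr
}

#' Render an efficiency map slice as a heat-map PNG
#'
#' Maps efficiencies 0..1 onto an inferno-like palette; `NA` voxels are
#' black. Useful for the core/rim visualisation of aggregates (high-FRET
#' core, low-FRET rim).
#'
#' @param E Efficiency array or matrix.
#' @param path Output PNG path.
#' @param slice Z-slice to render when `E` is 3-D.
#' @return `path`, invisibly.
#' @export
render_e_map_png <- function(E, path, slice = 1) {
  m <- if (length(dim(E)) == 3) E[, , slice] else E
  pal <- grDevices::hcl.colors(256, "Inferno")
  rgb <- grDevices::col2rgb(pal) / 255
  idx <- pmin(pmax(round(m * 255) + 1, 1), 256)
  img <- array(0, c(nrow(m), ncol(m), 3))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(m), ncol(m))
    plane[ok] <- rgb[ch, idx[ok]]
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Write an analysis summary as JSON
#'
#' Serialises a result list together with the resolved configuration and
#' seed, the package's reproducibility contract for every artefact.
#'
#' @param x List to serialise.
#' @param path Output JSON path.
#' @param config Optional resolved [default_config()] list to embed.
#' @param seed Optional seed to embed.
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path, config = NULL, seed = NULL) {
  if (!is.null(config)) x$config <- config
  if (!is.null(seed)) x$seed <- seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
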