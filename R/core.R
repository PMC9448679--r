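#' Instrument correction constants
#'
#' Bundles the instrument-specific constants used to correct raw two-channel
#' intensities and to size oligomers: the autofluorescence background of each
#' detection channel, the donor-to-acceptor cross-talk fraction, the gamma
#' factor (relative detection efficiency x quantum yield of the two dyes) and
#' the mean brightness of a single labelled monomer.
#'
#' All intensities are in detector counts; the same constants apply whether
#' the unit of observation is a summed confocal burst or a single voxel.
#'
#' @param autofluor_donor Autofluorescence in the donor channel (counts),
#'   measured in the absence of fluorophores. Subtracted from raw donor
#'   intensity (`I_D = D - A_D`).
#' @param autofluor_acceptor Autofluorescence in the acceptor channel (counts).
#' @param crosstalk Dimensionless fraction `C` of donor signal leaking into the
#'   acceptor channel (`I_A = A - A_A - C * D`). Cross-talk from acceptor to
#'   donor is taken as negligible.
#' @param gamma Dimensionless gamma factor; must be positive. Defaults to 1
#'   and can be overridden when it has been determined for an instrument.
#' @param monomer_brightness Mean counts per event from a single donor
#'   fluorophore (`I_monomer`). `NA` until measured; required (positive) for
#'   apparent sizing.
#' @return An object of class `instrument_params` (a validated list).
#' @examples
#' instrument_params(autofluor_donor = 2, crosstalk = 0.05)
#' @export
instrument_params <- function(autofluor_donor = 0, autofluor_acceptor = 0,
                              crosstalk = 0, gamma = 1,
                              monomer_brightness = NA_real_) {
  stopifnot(
    is.numeric(autofluor_donor), length(autofluor_donor) == 1L, autofluor_donor >= 0,
    is.numeric(autofluor_acceptor), length(autofluor_acceptor) == 1L, autofluor_acceptor >= 0,
    is.numeric(crosstalk), length(crosstalk) == 1L, crosstalk >= 0,
    is.numeric(gamma), length(gamma) == 1L
  )
  if (gamma <= 0) {
    stop(invalid_params_error("`gamma` must be positive"))
  }
  if (!is.na(monomer_brightness) && monomer_brightness <= 0) {
    stop(invalid_params_error("`monomer_brightness` must be positive when supplied"))
  }
  structure(
    list(
      autofluor_donor = as.numeric(autofluor_donor),
      autofluor_acceptor = as.numeric(autofluor_acceptor),
      crosstalk = as.numeric(crosstalk),
      gamma = as.numeric(gamma),
      monomer_brightness = as.numeric(monomer_brightness)
    ),
    class = "instrument_params"
  )
}

#' @export
print.instrument_params <- function(x, ...) {
  cat("Instrument parameters\n")
  cat(sprintf("  autofluorescence: donor %.3g, acceptor %.3g counts\n",
              x$autofluor_donor, x$autofluor_acceptor))
  cat(sprintf("  cross-talk C: %.3g   gamma: %.3g\n", x$crosstalk, x$gamma))
  cat(sprintf("  monomer brightness: %s counts\n",
              if (is.na(x$monomer_brightness)) "unset" else format(x$monomer_brightness)))
  invisible(x)
}

invalid_params_error <- function(msg) {
  errorCondition(msg, class = c("oligofret_invalid_params", "oligofret_error"))
}

undefined_efficiency_error <- function(msg) {
  errorCondition(msg, class = c("oligofret_undefined_efficiency", "oligofret_error"))
}

as_instrument_params <- function(x) {
  if (inherits(x, "instrument_params")) return(x)
  if (is.list(x)) return(do.call(instrument_params, x))
  stop(invalid_params_error("`params` must be an `instrument_params` object"))
}

#' Correct raw donor intensity for autofluorescence
#'
#' `I_D = D - A_D`. Negative results are returned as-is (not clamped):
#' clamping would bias downstream efficiencies toward 0 or 1. Use
#' [flag_negative_intensity()] to identify events/voxels to exclude.
#'
#' @param D Raw donor-channel counts under donor excitation (vectorised).
#' @param params [instrument_params()].
#' @return Corrected donor intensity, same length as `D`; may be negative.
#' @seealso [correct_acceptor()], [fret_efficiency()]
#' @export
correct_donor <- function(D, params) {
  params <- as_instrument_params(params)
  stopifnot(is.numeric(D), all(D >= 0 | is.na(D)))
  D - params$autofluor_donor
}

#' Correct raw acceptor intensity for autofluorescence and cross-talk
#'
#' `I_A = A - A_A - C * D`, where the cross-talk term removes the fraction of
#' donor emission detected in the acceptor channel. Negative results are
#' returned unclamped (see [correct_donor()]).
#'
#' @param A Raw acceptor-channel counts under donor excitation (vectorised).
#' @param D Raw donor-channel counts under donor excitation.
#' @param params [instrument_params()].
#' @return Corrected acceptor intensity; may be negative.
#' @export
correct_acceptor <- function(A, D, params) {
  params <- as_instrument_params(params)
  stopifnot(is.numeric(A), is.numeric(D),
            all(A >= 0 | is.na(A)), all(D >= 0 | is.na(D)))
  A - params$autofluor_acceptor - params$crosstalk * D
}

#' Flag events/voxels with unusable corrected intensities
#'
#' An observation is flagged when either corrected intensity is negative or
#' when the corrected total is non-positive (efficiency undefined). Flagged
#' observations are excluded from histograms and sizing rather than clamped.
#'
#' @param I_D,I_A Corrected intensities.
#' @return Logical vector, `TRUE` where the observation must be excluded.
#' @export
flag_negative_intensity <- function(I_D, I_A) {
  (I_D < 0) | (I_A < 0) | ((I_D + I_A) <= 0)
}

#' FRET efficiency of an event or voxel
#'
#' `E = I_A / (I_A + I_D)` on corrected intensities. With non-negative inputs
#' the result lies in `[0, 1]`. Inputs whose total is non-positive are
#' undefined and raise a condition of class `oligofret_undefined_efficiency`;
#' apply the negative-intensity exclusion policy
#' ([flag_negative_intensity()]) first.
#'
#' @param I_D,I_A Corrected donor/acceptor intensities (vectorised).
#' @return FRET efficiency, same length as the inputs.
#' @examples
#' fret_efficiency(40, 40) # 0.5
#' fret_efficiency(20, 60) # 0.75
#' @export
fret_efficiency <- function(I_D, I_A) {
  stopifnot(is.numeric(I_D), is.numeric(I_A), length(I_D) == length(I_A))
  tot <- I_D + I_A
  if (any(tot <= 0, na.rm = TRUE)) {
    stop(undefined_efficiency_error(
      "FRET efficiency undefined: corrected total intensity I_D + I_A <= 0"))
  }
  I_A / tot
}

#' Apparent oligomer size in monomer units
#'
#' `size = 2 * (I_D + I_A / gamma) / I_monomer`. The total corrected
#' brightness (acceptor counts mapped back to donor-equivalent photons via
#' the gamma factor) is divided by the mean single-monomer brightness; the
#' factor 2 accounts for only the donor-labelled half of the monomers being
#' directly excited, so the estimate counts all monomers. "Apparent" because
#' stochastic excitation/emission and varied transit paths limit accuracy.
#'
#' @param I_D,I_A Corrected donor/acceptor intensities (vectorised).
#' @param params [instrument_params()] with positive `gamma` and
#'   `monomer_brightness`.
#' @return Apparent size in monomer units (non-negative for non-negative
#'   inputs).
#' @examples
#' p <- instrument_params(gamma = 0.5, monomer_brightness = 100)
#' apparent_size(150, 50, p) # 5
#' @export
apparent_size <- function(I_D, I_A, params) {
  params <- as_instrument_params(params)
  if (is.na(params$monomer_brightness) || params$monomer_brightness <= 0) {
    stop(invalid_params_error(
      "`monomer_brightness` must be a positive number for sizing"))
  }
  stopifnot(is.numeric(I_D), is.numeric(I_A), length(I_D) == length(I_A))
  2 * (I_D + I_A / params$gamma) / params$monomer_brightness
}

#' Size class of an oligomer
#'
#' Classifies apparent sizes into the three groups used for oligomer
#' populations: `small` (apparent dimers, size < `small_max`), `medium`
#' (`small_max` to `medium_max` monomer units, the range over which Type-A/
#' Type-B classification by FRET efficiency is performed) and `large`
#' (> `medium_max`).
#'
#' @param size Apparent size(s) in monomer units.
#' @param small_max Sizes strictly below this are `small` (default 3).
#' @param medium_max Sizes up to and including this are `medium` (default 20).
#' @return Factor with levels `small`, `medium`, `large`.
#' @examples
#' classify_size(c(2, 10, 25))
#' @export
classify_size <- function(size, small_max = 3, medium_max = 20) {
  stopifnot(small_max < medium_max)
  out <- ifelse(size < small_max, "small",
                ifelse(size <= medium_max, "medium", "large"))
  factor(out, levels = c("small", "medium", "large"))
}
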