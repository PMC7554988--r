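#' Construct a Spectrum
#'
#' @param wavelength strictly increasing wavelengths (nm) with a uniform
#'   step; non-uniform input is resampled by linear interpolation with a
#'   warning.
#' @param value absorbance (or derivative) values.
#' @param metadata optional list of provenance fields.
#' @return A [Spectrum-class].
#' @export
Spectrum <- function(wavelength, value, metadata = list()) {
  if (length(wavelength) != length(value))
    stop("wavelength and value lengths differ")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  d <- diff(wavelength)
  if (length(d) > 1L && max(abs(d - d[1])) > 1e-6) {
    warning("non-uniform sampling; resampling by linear interpolation")
    step <- median(d)
    grid <- seq(min(wavelength), max(wavelength), by = step)
    value <- approx(wavelength, value, xout = grid)$y
    wavelength <- grid
    metadata$resampled <- TRUE
  }
  metadata$step_nm <- if (length(wavelength) > 1L)
    wavelength[2] - wavelength[1] else NA_real_
  new("Spectrum", wavelength = wavelength, value = value,
      metadata = metadata)
}

#' Read a 2-column spectrum CSV (wavelength_nm, value)
#'
#' @param file CSV path; first column wavelength in nm, second the signal.
#' @return A [Spectrum-class].
#' @export
readSpectrum <- function(file) {
  if (!file.exists(file)) stop("spectrum file not found: ", file)
  df <- read.csv(file)
  if (ncol(df) < 2L) stop("expected at least 2 columns")
  Spectrum(df[[1]], df[[2]], metadata = list(source = file))
}

#' Savitzky-Golay smoothing / derivative spectrum
#'
#' Applies a Savitzky-Golay convolution of odd window length
#' `windowPoints` and polynomial order `polyOrder`, returning the
#' `derivOrder`-th derivative (0 = smoothing). The filter reproduces any
#' polynomial of degree at most `polyOrder` exactly, so a fourth-order
#' derivative annihilates cubic baselines while retaining sharp
#' aromatic absorption bands. The half-window edge region, where the
#' convolution is not defined, is marked `NA`.
#'
#' @param s a [Spectrum-class].
#' @param windowPoints odd window length (points); default 11 (1.1 nm at
#'   the 0.1 nm sampling used for UV spectra).
#' @param polyOrder polynomial order; must satisfy
#'   `derivOrder <= polyOrder < windowPoints`. Default 5.
#' @param derivOrder derivative order; default 4.
#' @return A [Spectrum-class] of the derivative, with filter parameters
#'   recorded in its metadata.
#' @export
derivativeSpectrum <- function(s, windowPoints = 11L, polyOrder = 5L,
                               derivOrder = 4L) {
  stopifnot(is(s, "Spectrum"))
  windowPoints <- as.integer(windowPoints)
  if (windowPoints %% 2L == 0L) stop("windowPoints must be odd")
  if (polyOrder < derivOrder)
    stop("polyOrder must be at least derivOrder")
  if (windowPoints <= polyOrder)
    stop("windowPoints must exceed polyOrder")
  step <- s@metadata$step_nm
  d <- signal::sgolayfilt(s@value, p = polyOrder, n = windowPoints,
                          m = derivOrder, ts = step)
  half <- windowPoints %/% 2L
  d[seq_len(half)] <- NA_real_
  d[seq(length(d) - half + 1L, length(d))] <- NA_real_
  Spectrum(s@wavelength, d,
           metadata = c(s@metadata[setdiff(names(s@metadata), "step_nm")],
                        list(window_points = windowPoints,
                             poly_order = polyOrder,
                             deriv_order = derivOrder)))
}

#' Peak (band) positions in a derivative spectrum
#'
#' Local maxima within a wavelength range whose topographic prominence
#' exceeds `minProminence` times the signal span in the range; each peak
#' position is refined below the sampling step by parabolic
#' interpolation through its three top points.
#'
#' @param s a [Spectrum-class] (typically a 4th-derivative spectrum).
#' @param range length-2 numeric wavelength window in nm.
#' @param minProminence fraction of the in-range signal span; default 0.1.
#' @return data.frame: `wavelength` (refined, nm), `height`; zero rows
#'   for a featureless spectrum.
#' @examples
#' sim <- simulateSpectrum(list(c(center = 293.3, sigma = 4, amplitude = 1)),
#'                         seed = 1)
#' d4 <- derivativeSpectrum(sim$spectrum)
#' bandPositions(d4, range = c(285, 300))
#' @export
bandPositions <- function(s, range = c(285, 300), minProminence = 0.1) {
  stopifnot(is(s, "Spectrum"))
  if (length(range) != 2L || range[2] <= range[1])
    stop("range must be an increasing length-2 interval")
  sel <- which(s@wavelength >= range[1] & s@wavelength <= range[2] &
                 !is.na(s@value))
  if (length(sel) < 3L) stop("no valid points in the requested range")
  wl <- s@wavelength[sel]
  y <- s@value[sel]
  span <- diff(base::range(y))
  if (span == 0)
    return(data.frame(wavelength = numeric(0), height = numeric(0)))

  n <- length(y)
  peaks <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                   y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(peaks))
    return(data.frame(wavelength = numeric(0), height = numeric(0)))

  prom <- vapply(peaks, function(i) .prominence(y, i), numeric(1))
  keep <- prom >= minProminence * span
  peaks <- peaks[keep]
  if (!length(peaks))
    return(data.frame(wavelength = numeric(0), height = numeric(0)))

  refined <- vapply(peaks, function(i) {
    if (i == 1L || i == n) return(wl[i])
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom == 0) return(wl[i])
    delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
    wl[i] + delta * (wl[2] - wl[1])
  }, numeric(1))
  out <- data.frame(wavelength = refined, height = y[peaks])
  out[order(out$wavelength), , drop = FALSE]
}

# topographic prominence of peak i: height above the higher of the two
# minima separating it from higher terrain (or from the window edges)
.prominence <- function(y, i) {
  n <- length(y)
  left <- y[seq_len(i - 1)]
  right <- y[seq(i + 1, n)]
  higherL <- which(left > y[i])
  higherR <- which(right > y[i])
  minL <- if (length(higherL)) min(left[(max(higherL) + 1):(i - 1)]) else
    min(left)
  minR <- if (length(higherR)) min(right[1:(min(higherR) - 1)]) else
    min(right)
  y[i] - max(minL, minR)
}

#' Composition-matched chromophore reference mixture
#'
#' Concentrations of N-acetyltryptophanamide (NATA),
#' N-acetyltyrosinamide (NAYA) and free phenylalanine that match, per
#' chromophore, the molar residue concentration of a protein solution:
#' each equals protein concentration times the residue count. Used to
#' compare the absorbance of free chromophores against the same residues
#' in the protein context.
#'
#' @param proteinConcUM protein concentration in uM.
#' @param nTrp,nTyr,nPhe aromatic residue counts.
#' @return Named numeric: `NATA_uM`, `NAYA_uM`, `Phe_uM`.
#' @examples
#' referenceMixture(36.5, nTrp = 3, nTyr = 3, nPhe = 5)
#' @export
referenceMixture <- function(proteinConcUM, nTrp, nTyr, nPhe) {
  if (proteinConcUM < 0 || nTrp < 0 || nTyr < 0 || nPhe < 0)
    stop("inputs must be non-negative")
  c(NATA_uM = proteinConcUM * nTrp,
    NAYA_uM = proteinConcUM * nTyr,
    Phe_uM = proteinConcUM * nPhe)
}

#' Free thiols per molecule from an Ellman (DTNB) endpoint
#'
#' `ratio = deltaA / (epsilonTNB * proteinConc * path)`: the released
#' TNB anion absorbance divided by the per-molar signal expected for one
#' thiol. The detection wavelength and epsilon are instrument/assay
#' choices and must be supplied (no canonical default is assumed).
#'
#' @param deltaA blank-corrected absorbance change (AU), non-negative.
#' @param epsilonTNB TNB extinction coefficient at the detection
#'   wavelength (1/M/cm), positive.
#' @param proteinConcM protein concentration in M, positive.
#' @param pathCm optical path in cm, default 1.
#' @return Thiols per protein molecule.
#' @export
thiolRatio <- function(deltaA, epsilonTNB, proteinConcM, pathCm = 1.0) {
  if (epsilonTNB <= 0 || proteinConcM <= 0 || pathCm <= 0)
    stop("epsilonTNB, proteinConcM and pathCm must be positive")
  if (deltaA < 0) stop("deltaA must be non-negative")
  deltaA / (epsilonTNB * proteinConcM * pathCm)
}
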