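#' Run code with a private, restored RNG state
#' @noRd
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Construct a spectrum object
#'
#' @param mz Strictly increasing m/z vector.
#' @param intensity Non-negative intensity vector, same length.
#' @param mode Acquisition mode, `"linear"` or `"reflector"`.
#' @param metadata Named list (spot coordinate, seed, ...).
#' @return Object of class `maldi_spectrum`.
#' @export
spectrum <- function(mz, intensity, mode = c("linear", "reflector"),
                     metadata = list()) {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity), !is.unsorted(mz, strictly = TRUE),
            all(intensity >= 0))
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 mode = mode, metadata = metadata),
            class = "maldi_spectrum")
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat("<maldi_spectrum>", x$mode, "mode,", length(x$mz), "points,",
      sprintf("%.1f-%.1f m/z", min(x$mz), max(x$mz)), "\n")
  invisible(x)
}

#' Simulate a MALDI micro-spot spectrum
#'
#' Renders each analyte as a Gaussian of FWHM = m/z / resolution at its
#' true m/z, adds an exponentially decaying chemical baseline and additive
#' Gaussian noise, on a uniform 0.05 Da grid. Deterministic for a fixed
#' seed.
#'
#' @param peaks data.frame with columns `mz` (true m/z) and `intensity`
#'   (peak height).
#' @param seed Mandatory integer seed.
#' @param mz_range Acquisition window (Da), default 750-7000 (linear-mode
#'   full scan).
#' @param resolution Mass resolution m/dm (FWHM), default 1000.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param baseline_amplitude,baseline_decay Baseline height at the low-mass
#'   edge and exponential decay length (Da).
#' @param grid_step Grid spacing (Da).
#' @param mode Acquisition mode tag.
#' @param metadata Extra metadata stored on the spectrum.
#' @return A [spectrum()].
#' @export
#' @examples
#' sp <- simulate_spectrum(data.frame(mz = c(1312.536, 1468.637),
#'                                    intensity = c(80, 100)), seed = 1)
simulate_spectrum <- function(peaks, seed, mz_range = c(750, 7000),
                              resolution = 1000, noise_sd = 1,
                              baseline_amplitude = 0, baseline_decay = 1000,
                              grid_step = 0.05, mode = "linear",
                              metadata = list()) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)),
            all(peaks$intensity > 0), resolution > 0, !missing(seed))
  out_of_range <- peaks$mz < mz_range[1] | peaks$mz > mz_range[2]
  if (any(out_of_range)) {
    stop("peak at m/z ", peaks$mz[which(out_of_range)[1]],
         " outside the acquisition range [", mz_range[1], ", ",
         mz_range[2], "]")
  }
  grid <- seq(mz_range[1], mz_range[2], by = grid_step)
  y <- numeric(length(grid))
  for (i in seq_len(nrow(peaks))) {
    mu <- peaks$mz[i]
    fwhm <- mu / resolution
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    lo <- max(1L, floor((mu - 5 * fwhm - mz_range[1]) / grid_step) + 1L)
    hi <- min(length(grid), ceiling((mu + 5 * fwhm - mz_range[1]) / grid_step) + 1L)
    w <- lo:hi
    y[w] <- y[w] + peaks$intensity[i] * exp(-(grid[w] - mu)^2 / (2 * sigma^2))
  }
  if (baseline_amplitude > 0) {
    y <- y + baseline_amplitude * exp(-(grid - mz_range[1]) / baseline_decay)
  }
  if (noise_sd > 0) {
    y <- y + .with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  }
  y <- pmax(y, 0)
  spectrum(grid, y, mode = mode,
           metadata = c(metadata, list(seed = seed, resolution = resolution,
                                       noise_sd = noise_sd,
                                       grid_step = grid_step)))
}

.segment_stat <- function(mz, y, width, fun) {
  span <- max(mz) - min(mz)
  nseg <- max(1L, round(span / width))
  if (nseg == 1L) return(rep(fun(y), length(mz)))
  breaks <- seq(min(mz), max(mz), length.out = nseg + 1L)
  seg <- findInterval(mz, breaks, all.inside = TRUE)
  centers <- (breaks[-1L] + breaks[-(nseg + 1L)]) / 2
  vals <- as.numeric(tapply(y, factor(seg, levels = seq_len(nseg)), fun))
  ok <- is.finite(vals)
  stats::approx(centers[ok], vals[ok], xout = mz, rule = 2)$y
}

# robust noise scale from the upper flank of the residual distribution;
# insensitive to a zero-clipped lower tail
.upper_scale <- function(v) {
  (stats::quantile(v, 0.95, names = FALSE) - stats::median(v)) /
    stats::qnorm(0.95)
}

.moving_average <- function(y, k) {
  s <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- y[is.na(s)]
  s
}

#' Subtract the slowly varying baseline from a spectrum
#'
#' Estimates the baseline as the interpolated per-segment minimum of a
#' heavily smoothed intensity trace (a rolling-minimum estimate that slips
#' under the sparse analyte peaks without chasing individual noise
#' excursions) and subtracts it, flooring at zero. Peak centroids are
#' unchanged up to the local baseline slope.
#'
#' @param x A [spectrum()].
#' @param segment_da Segment width (Da) over which minima are taken; must
#'   exceed the widest peak FWHM.
#' @param smooth_points Moving-average width (grid points) applied before
#'   taking minima.
#' @return A baseline-subtracted [spectrum()].
#' @export
subtract_baseline <- function(x, segment_da = 25, smooth_points = 51L) {
  stopifnot(inherits(x, "maldi_spectrum"))
  s <- .moving_average(x$intensity, smooth_points)
  base <- .segment_stat(x$mz, s, segment_da, min)
  spectrum(x$mz, pmax(x$intensity - base, 0), mode = x$mode,
           metadata = c(x$metadata, list(baseline_subtracted = TRUE)))
}

#' Pick peaks above a signal-to-noise threshold
#'
#' Smooths the trace with a short moving average to localise apexes, then
#' reports every local maximum whose height exceeds `snr_threshold` times
#' the local noise. Noise is a robust scale estimate (median absolute
#' deviation x 1.4826) of the smoothing residual over sliding segments, so
#' S/N keeps its raw-noise meaning while grid-level noise wiggles cannot
#' surface as peaks. Centroids are intensity-weighted means over the
#' contiguous points above half of the apex height.
#'
#' @param x A [spectrum()], baseline-subtracted or baseline-free.
#' @param snr_threshold Minimum signal-to-noise ratio (default 3).
#' @param smooth_points Moving-average width in grid points (odd).
#' @param noise_segment_da Segment width (Da) for the noise estimate.
#' @return data.frame with columns `mz` (centroid), `intensity` (apex
#'   height) and `snr`; zero rows when nothing qualifies.
#' @export
pick_peaks <- function(x, snr_threshold = 3, smooth_points = 5L,
                       noise_segment_da = 50) {
  stopifnot(inherits(x, "maldi_spectrum"), smooth_points %% 2L == 1L)
  y <- x$intensity
  n <- length(y)
  if (n < smooth_points + 2L) {
    return(data.frame(mz = numeric(), intensity = numeric(), snr = numeric()))
  }
  s <- .moving_average(y, smooth_points)
  resid <- y - s
  # unbias the residual scale back to the raw noise scale
  noise <- .segment_stat(x$mz, resid, noise_segment_da, .upper_scale)
  noise <- noise / sqrt(1 - 1 / smooth_points)
  noise <- pmax(noise, 0.5 * stats::median(noise), max(s) * 1e-9,
                .Machine$double.eps)
  # local intensity floor: heights and thresholds are measured above it so
  # that a clipped-at-zero noise pedestal does not bias peak heights
  floor_ <- .segment_stat(x$mz, s, noise_segment_da, stats::median)
  h <- s - floor_

  i <- 2:(n - 1L)
  apex <- i[s[i] >= s[i - 1L] & s[i] > s[i + 1L] &
              h[i] >= snr_threshold * noise[i]]
  if (!length(apex)) {
    return(data.frame(mz = numeric(), intensity = numeric(), snr = numeric()))
  }
  # half-height window around each apex (contiguous points above half)
  win <- t(vapply(apex, function(a) {
    half <- h[a] / 2
    lo <- a
    while (lo > 1L && h[lo - 1L] >= half) lo <- lo - 1L
    hi <- a
    while (hi < n && h[hi + 1L] >= half) hi <- hi + 1L
    c(lo, hi)
  }, integer(2)))
  # merge apexes whose half-height windows overlap: one (noisy) peak can
  # surface as several local maxima of the smoothed trace
  ord <- order(apex)
  apex <- apex[ord]; win <- win[ord, , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(win[-1L, 1L] > cummax(win[-nrow(win), 2L]))))
  rows <- lapply(split(seq_along(apex), grp), function(ix) {
    a <- apex[ix][which.max(h[apex[ix]])]
    w <- min(win[ix, 1L]):max(win[ix, 2L])
    wt <- pmax(h[w], 0)
    data.frame(mz = sum(x$mz[w] * wt) / sum(wt),
               intensity = h[a], snr = h[a] / noise[a])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the spectrum of one assay's micro-spot
#'
#' Convenience generator for panel-decoding and quantification studies:
#' renders the light-channel variants of one assay (and, for labelled
#' assays, the heavy channel scaled by the heavy:light ratio) at a target
#' signal-to-noise ratio, then simulates acquisition.
#'
#' @param panel An [compile_panel()] result.
#' @param assay_id Which assay the spot contains.
#' @param hl_ratio Heavy:light intensity ratio injected for labelled
#'   variants.
#' @param snr Target signal-to-noise of the weakest rendered peak (so at
#'   `snr = 20` every variant of the spot, both channels, is at S/N of at
#'   least 20).
#' @param seed Integer seed.
#' @param rel_abundance Optional named vector of relative abundances per
#'   light `variant_id` (default: equal, scaled down 40% per extra missed
#'   cleavage to mimic the dominance of fully cleaved products).
#' @param noise_sd Noise standard deviation passed to
#'   [simulate_spectrum()].
#' @param ... Passed to [simulate_spectrum()].
#' @return A [spectrum()] whose metadata records the true assay id.
#' @export
simulate_spot <- function(panel, assay_id, hl_ratio = 1, snr = 50, seed,
                          rel_abundance = NULL, noise_sd = 1, ...) {
  stopifnot(inherits(panel, "assay_panel"),
            assay_id %in% names(panel$assays))
  v <- panel$index[panel$index$assay_id == assay_id, , drop = FALSE]
  light <- v[v$channel %in% c("light", "both"), , drop = FALSE]
  heavy <- v[v$channel == "heavy", , drop = FALSE]
  if (is.null(rel_abundance)) {
    rel <- 0.6^(light$missed - min(light$missed))
  } else {
    rel <- unname(rel_abundance[light$variant_id])
  }
  pk <- data.frame(mz = light$mono_mass, intensity = rel)
  if (nrow(heavy) && hl_ratio > 0) {
    hv <- merge(
      data.frame(key = sub("\\.light", "", light$variant_id), rel = rel),
      data.frame(key = sub("\\.heavy", "", heavy$variant_id),
                 mz = heavy$mono_mass),
      by = "key"
    )
    pk <- rbind(pk, data.frame(mz = hv$mz, intensity = hv$rel * hl_ratio))
  }
  # scale so the weakest rendered peak sits at the requested S/N
  pk$intensity <- pk$intensity / min(pk$intensity) * snr * noise_sd
  pk <- pk[order(pk$mz), , drop = FALSE]
  simulate_spectrum(pk, seed = seed, noise_sd = noise_sd,
                    metadata = list(true_assay = assay_id,
                                    hl_ratio = hl_ratio), ...)
}
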