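#' Intensity ratio of a light/heavy pair
#'
#' A simple quotient of peak heights in the declared orientation. Ratios
#' with a zero or missing denominator are undefined and returned as `NA`
#' (never silently zero); both channels zero/missing is also undefined.
#'
#' @param light,heavy Channel intensities (>= 0, may be NA).
#' @param orientation `"H:L"` or `"L:H"`.
#' @return Numeric ratio, or `NA_real_` when undefined.
#' @export
#' @examples
#' pair_ratio(339, 1000, "L:H")   # 0.339
pair_ratio <- function(light, heavy, orientation = c("H:L", "L:H")) {
  orientation <- match.arg(orientation)
  light <- ifelse(is.na(light), 0, light)
  heavy <- ifelse(is.na(heavy), 0, heavy)
  stopifnot(all(light >= 0), all(heavy >= 0))
  num <- if (orientation == "H:L") heavy else light
  den <- if (orientation == "H:L") light else heavy
  ifelse(den > 0, num / den, NA_real_)
}

#' Quantify the SILAC pairs of an annotated spot
#'
#' Turns a [find_silac_pairs()] table into quantification records with an
#' explicit ratio orientation. Undefined ratios (missing channel) propagate
#' as flagged records.
#'
#' @param pairs data.frame from [find_silac_pairs()].
#' @param orientation `"H:L"` or `"L:H"`.
#' @param assay_id,replicate Metadata carried onto the records.
#' @return data.frame with `assay_id`, `variant_id`, `replicate`,
#'   `light_intensity`, `heavy_intensity`, `ratio`, `orientation`,
#'   `defined`.
#' @export
quantify_pairs <- function(pairs, orientation = c("H:L", "L:H"),
                           assay_id = NA_character_, replicate = NA) {
  orientation <- match.arg(orientation)
  ratio <- pair_ratio(pairs$light_intensity, pairs$heavy_intensity,
                      orientation)
  data.frame(
    assay_id = assay_id, variant_id = pairs$variant_id,
    replicate = replicate,
    light_intensity = pairs$light_intensity,
    heavy_intensity = pairs$heavy_intensity,
    ratio = ratio, orientation = orientation, defined = !is.na(ratio),
    stringsAsFactors = FALSE
  )
}

#' Replicate mean and coefficient of variation
#'
#' CV is 100 x sd/mean with the n-1 denominator. A single replicate yields
#' a mean only (CV is NA); undefined ratios are dropped with a warning.
#'
#' @param ratios Numeric vector of replicate ratios.
#' @return Object of class `replicate_summary`: list with `mean`, `cv`
#'   (percent), `n`.
#' @export
#' @examples
#' replicate_stats(c(13.0, 13.5, 14.0))
replicate_stats <- function(ratios) {
  if (length(ratios) == 0L) stop("no ratios supplied")
  if (anyNA(ratios)) {
    warning(sum(is.na(ratios)), " undefined ratio(s) dropped")
    ratios <- ratios[!is.na(ratios)]
    if (!length(ratios)) stop("all ratios undefined")
  }
  m <- mean(ratios)
  cv <- if (length(ratios) >= 2L) 100 * stats::sd(ratios) / m else NA_real_
  structure(list(mean = m, cv = cv, n = length(ratios)),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> mean %.4g, CV %s%%, n = %d\n", x$mean,
              ifelse(is.na(x$cv), "NA", sprintf("%.2f", x$cv)), x$n))
  invisible(x)
}

#' Fold change between two replicate summaries
#'
#' Quotient of the mean ratios, A over B. Scale-invariant: rescaling both
#' channels of every replicate leaves the fold change unchanged.
#'
#' @param a,b [replicate_stats()] results (or bare numbers).
#' @return Numeric fold change.
#' @export
fold_change <- function(a, b) {
  ma <- if (inherits(a, "replicate_summary")) a$mean else as.numeric(a)
  mb <- if (inherits(b, "replicate_summary")) b$mean else as.numeric(b)
  if (!is.finite(mb) || mb == 0) stop("undefined fold change: zero or missing denominator")
  ma / mb
}

#' Normalise spectra (or peak lists) to a shared reference peak
#'
#' Scales each spectrum so the intensity of the reference peak equals one,
#' preserving all intra-spectrum ratios -- the cross-spectrum normalisation
#' used to overlay, e.g., histone-ladder acquisitions on a common internal
#' peak.
#'
#' @param spectra List of [spectrum()] objects or of peak data.frames
#'   (`mz`, `intensity`).
#' @param reference_mz m/z of the reference peak.
#' @param tol Absolute matching tolerance, Da.
#' @return List of scaled objects, same classes as the input.
#' @export
normalize_to_reference <- function(spectra, reference_mz, tol = 0.25) {
  ref_int <- function(obj, i) {
    mz <- if (inherits(obj, "maldi_spectrum")) obj$mz else obj$mz
    y <- if (inherits(obj, "maldi_spectrum")) obj$intensity else obj$intensity
    w <- abs(mz - reference_mz) <= tol
    if (!any(w) || max(y[w]) <= 0) {
      stop("reference peak at m/z ", reference_mz,
           " absent from spectrum ", i)
    }
    max(y[w])
  }
  lapply(seq_along(spectra), function(i) {
    obj <- spectra[[i]]
    s <- ref_int(obj, i)
    if (inherits(obj, "maldi_spectrum")) {
      spectrum(obj$mz, obj$intensity / s, mode = obj$mode,
               metadata = c(obj$metadata, list(normalized_to = reference_mz)))
    } else {
      obj$intensity <- obj$intensity / s
      obj
    }
  })
}
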