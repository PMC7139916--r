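#' Mass-matching tolerance settings
#'
#' Linear-mode matching uses an absolute window (typical single-digit
#' fraction of a Da on unresolved isotope envelopes); a wider documented
#' fallback tier absorbs the larger deviations routinely seen on linear
#' acquisitions. Reflector-mode matching is relative (ppm).
#'
#' @param linear_da Strict linear-mode tolerance, Da (default 0.25).
#' @param linear_fallback_da Fallback linear tier, Da (default 0.5).
#' @param reflector_ppm Reflector-mode tolerance, ppm (default 25).
#' @return Object of class `tolerance_settings`.
#' @export
tolerance_settings <- function(linear_da = 0.25, linear_fallback_da = 0.5,
                               reflector_ppm = 25) {
  stopifnot(linear_da > 0, linear_fallback_da >= linear_da,
            reflector_ppm > 0)
  structure(list(linear_da = linear_da,
                 linear_fallback_da = linear_fallback_da,
                 reflector_ppm = reflector_ppm),
            class = "tolerance_settings")
}

.tol_window <- function(mz, mode, tol, tier = c("strict", "fallback")) {
  tier <- match.arg(tier)
  if (mode == "reflector") {
    mz * tol$reflector_ppm * 1e-6
  } else if (tier == "strict") {
    rep(tol$linear_da, length(mz))
  } else {
    rep(tol$linear_fallback_da, length(mz))
  }
}

#' Match a spot's picked peaks against a compiled panel
#'
#' Each peak is assigned to the nearest reference mass within tolerance
#' (ties broken by smaller absolute error, then lower assay id). The spot's
#' assay identity is the assay with the highest summed matched intensity --
#' the decoding step that recovers which bead eluted at an arbitrary array
#' position. Mass errors are observed minus expected. In linear mode,
#' matches inside the strict window are tagged tier `"strict"`, matches
#' only inside the fallback window `"fallback"`.
#'
#' @param peaks data.frame from [pick_peaks()] (columns `mz`, `intensity`).
#' @param panel An [compile_panel()] result.
#' @param mode `"linear"` or `"reflector"`.
#' @param tol A [tolerance_settings()]; defaults to the panel's.
#' @param spot Optional spot identifier carried through.
#' @return Object of class `spot_annotation`: list with `spot`, `assay`
#'   (assigned id or NA), `matches` (data.frame), `unmatched`,
#'   `explained_fraction`.
#' @export
match_spot <- function(peaks, panel, mode = c("linear", "reflector"),
                       tol = NULL, spot = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "assay_panel"))
  if (nrow(panel$index) == 0L) stop("empty panel")
  if (is.null(tol)) tol <- panel$tolerances
  idx <- panel$index

  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(structure(list(spot = spot, assay = NA_character_,
                          matches = data.frame(), unmatched = data.frame(),
                          explained_fraction = 0),
                     class = "spot_annotation"))
  }
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    obs <- peaks$mz[i]
    err <- obs - idx$mono_mass
    win <- .tol_window(idx$mono_mass, mode, tol, "fallback")
    if (mode == "reflector") win <- .tol_window(idx$mono_mass, mode, tol)
    ok <- which(abs(err) <= win)
    if (!length(ok)) return(NULL)
    ok <- ok[order(abs(err[ok]), idx$assay_id[ok])]
    j <- ok[1L]
    tier <- if (mode == "reflector") {
      "strict"
    } else if (abs(err[j]) <= tol$linear_da) "strict" else "fallback"
    data.frame(peak = i, assay_id = idx$assay_id[j],
               variant_id = idx$variant_id[j],
               expected_mz = idx$mono_mass[j], observed_mz = obs,
               error_da = err[j], error_ppm = err[j] / obs * 1e6,
               intensity = peaks$intensity[i], snr = peaks$snr[i] %||% NA_real_,
               tier = tier, stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, rows)
  if (is.null(matches)) matches <- data.frame()
  unmatched <- peaks[setdiff(seq_len(nrow(peaks)), matches$peak), ,
                     drop = FALSE]
  assay <- NA_character_
  explained <- 0
  if (nrow(matches)) {
    by_assay <- tapply(matches$intensity, matches$assay_id, sum)
    assay <- names(by_assay)[order(-by_assay, names(by_assay))][1L]
    explained <- sum(matches$intensity[matches$assay_id == assay]) /
      sum(peaks$intensity)
  }
  structure(list(spot = spot, assay = assay, matches = matches,
                 unmatched = unmatched,
                 explained_fraction = min(explained, 1)),
            class = "spot_annotation")
}

#' @export
print.spot_annotation <- function(x, ...) {
  cat("<spot_annotation>", if (is.na(x$assay)) "unassigned" else x$assay,
      "-", nrow(x$matches), "matched peak(s),",
      sprintf("%.0f%%", 100 * x$explained_fraction), "intensity explained\n")
  invisible(x)
}

.parse_label_counts <- function(label) {
  # "2xphospho+1xacetyl" -> c(phospho = 2, acetyl = 1)
  if (label == "unmod") return(c(none = 0)[-1])
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  n <- as.integer(sub("x.*", "", parts))
  stats::setNames(n, sub(".*x", "", parts))
}

#' Label the members of a modification ladder
#'
#' For a spot assigned to a ladder-type assay (variable phosphorylation,
#' acetyl/methyl combinatorics, ...), annotates each matched mass with its
#' modification composition and missed-cleavage level. Variants that share
#' a mass but differ in composition are reported with their `ambiguous`
#' flag set.
#'
#' @param annotation A [match_spot()] result.
#' @param panel The panel it was matched against.
#' @param assay_id Assay to annotate; defaults to the assigned assay.
#' @return data.frame with one row per matched variant: `variant_id`,
#'   `observed_mz`, `expected_mz`, `intensity`, `channel`, `missed`,
#'   `n_phospho`, `n_acetyl`, `n_methyl_units`, `label`, `ambiguous`.
#' @export
annotate_ladder <- function(annotation, panel, assay_id = annotation$assay) {
  stopifnot(inherits(annotation, "spot_annotation"),
            inherits(panel, "assay_panel"))
  if (is.na(assay_id)) stop("spot is unassigned; no ladder to annotate")
  m <- annotation$matches
  m <- m[m$assay_id == assay_id, , drop = FALSE]
  idx <- panel$index[panel$index$assay_id == assay_id, , drop = FALSE]
  v <- idx[match(m$variant_id, idx$variant_id), , drop = FALSE]
  counts <- lapply(v$label, .parse_label_counts)
  methyl_units <- vapply(counts, function(cn) {
    sum(cn[names(cn) == "methyl"]) + 2L * sum(cn[names(cn) == "dimethyl"]) +
      3L * sum(cn[names(cn) == "trimethyl"])
  }, numeric(1))
  out <- data.frame(
    variant_id = m$variant_id, observed_mz = m$observed_mz,
    expected_mz = m$expected_mz, intensity = m$intensity,
    channel = v$channel, missed = v$missed,
    n_phospho = vapply(counts, function(cn) sum(cn[names(cn) == "phospho"]),
                       numeric(1)),
    n_acetyl = vapply(counts, function(cn) sum(cn[names(cn) == "acetyl"]),
                      numeric(1)),
    n_methyl_units = methyl_units,
    label = v$label, ambiguous = v$ambiguous,
    stringsAsFactors = FALSE
  )
  out[order(out$missed, out$expected_mz), , drop = FALSE]
}

#' Locate SILAC light/heavy peak pairs for a labelled assay
#'
#' For every light-channel variant of the assay, looks for peaks at the
#' light mass and at light + label delta, within tolerance. Complete pairs
#' carry both intensities; singletons are reported as `light_only` or
#' `heavy_only`.
#'
#' @param peaks data.frame of picked peaks (`mz`, `intensity`).
#' @param assay An [build_assay()] result with a label scheme.
#' @param mode,tol As in [match_spot()].
#' @return data.frame with columns `variant_id`, `expected_light`,
#'   `expected_heavy`, `delta`, `light_mz`, `light_intensity`, `heavy_mz`,
#'   `heavy_intensity`, `status` (`pair`/`light_only`/`heavy_only`/
#'   `absent`).
#' @export
find_silac_pairs <- function(peaks, assay, mode = c("linear", "reflector"),
                             tol = tolerance_settings()) {
  mode <- match.arg(mode)
  stopifnot(inherits(assay, "assay_definition"))
  if (is.null(assay$scheme)) stop("assay '", assay$id, "' declares no labels")
  v <- assay$variants
  light <- v[v$channel == "light", , drop = FALSE]
  heavy <- v[v$channel == "heavy", , drop = FALSE]
  key_l <- sub("\\.light", "", light$variant_id)
  key_h <- sub("\\.heavy", "", heavy$variant_id)
  hmass <- heavy$mono_mass[match(key_l, key_h)]

  nearest <- function(target) {
    if (is.na(target) || nrow(peaks) == 0L) return(NA_integer_)
    win <- .tol_window(target, mode, tol)
    err <- abs(peaks$mz - target)
    j <- which.min(err)
    if (err[j] <= win) j else NA_integer_
  }
  rows <- lapply(seq_len(nrow(light)), function(i) {
    li <- nearest(light$mono_mass[i])
    hi <- nearest(hmass[i])
    status <- if (!is.na(li) && !is.na(hi)) "pair"
      else if (!is.na(li)) "light_only"
      else if (!is.na(hi)) "heavy_only"
      else "absent"
    data.frame(
      variant_id = key_l[i],
      expected_light = light$mono_mass[i], expected_heavy = hmass[i],
      delta = hmass[i] - light$mono_mass[i],
      light_mz = if (is.na(li)) NA_real_ else peaks$mz[li],
      light_intensity = if (is.na(li)) NA_real_ else peaks$intensity[li],
      heavy_mz = if (is.na(hi)) NA_real_ else peaks$mz[hi],
      heavy_intensity = if (is.na(hi)) NA_real_ else peaks$intensity[hi],
      status = status, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
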