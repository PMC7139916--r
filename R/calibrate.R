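#' Spike calibration design
#'
#' A forward curve holds the heavy (labelled) standard constant and varies
#' the light spike -- its low-spike plateau reads out the endogenous
#' analyte level. A reverse curve holds light constant and varies heavy --
#' it reads out assay LOD/LOQ. Levels form a geometric dilution series,
#' optionally with a blank (zero spike).
#'
#' @param orientation `"forward"` or `"reverse"`.
#' @param constant_fmol Amount of the constant channel per well (fmol).
#' @param top_fmol Highest spike level (fmol).
#' @param dilution_factor Serial dilution factor (> 1).
#' @param n_levels Number of non-blank levels.
#' @param include_blank Append a zero-spike sample.
#' @param replicates Replicates per level.
#' @return Object of class `spike_design` with `levels_fmol` (descending,
#'   blank last as 0).
#' @export
#' @examples
#' d <- spike_design("forward", 1000, 10000, 3, 11)
#' min(d$levels_fmol[d$levels_fmol > 0])  # ~0.17 fmol
spike_design <- function(orientation = c("forward", "reverse"),
                         constant_fmol = 1000, top_fmol = 10000,
                         dilution_factor = 3, n_levels = 11,
                         include_blank = TRUE, replicates = 3L) {
  orientation <- match.arg(orientation)
  stopifnot(constant_fmol > 0, top_fmol > 0, dilution_factor > 1,
            n_levels >= 1, replicates >= 1)
  levels <- top_fmol / dilution_factor^(seq_len(n_levels) - 1L)
  if (include_blank) levels <- c(levels, 0)
  structure(list(orientation = orientation, constant_fmol = constant_fmol,
                 levels_fmol = levels, replicates = as.integer(replicates),
                 dilution_factor = dilution_factor),
            class = "spike_design")
}

#' @export
print.spike_design <- function(x, ...) {
  cat("<spike_design>", x$orientation, "curve:", x$constant_fmol,
      "fmol constant,", length(x$levels_fmol), "levels x", x$replicates,
      "replicates\n")
  invisible(x)
}

#' Simulate replicate responses for a spike design
#'
#' Generates the per-level, per-replicate measured ratios (varied over
#' constant channel) and detection flags a calibration run would produce.
#' The measured ratio is the true amount ratio under multiplicative
#' lognormal noise of the given CV; a replicate is "identifiable" when the
#' simulated varied-channel peak reaches S/N >= `snr_threshold`, with S/N
#' proportional to the analyte amount.
#'
#' @param design A [spike_design()].
#' @param seed Integer seed.
#' @param endogenous_fmol Endogenous analyte in the background (adds to the
#'   light channel; relevant to forward curves).
#' @param cv Multiplicative noise CV (fraction, e.g. 0.2).
#' @param snr_per_fmol S/N contributed per fmol of the varied analyte.
#' @param snr_threshold Detection threshold (default 3).
#' @return data.frame with `level_fmol`, `replicate`, `ratio`, `snr`,
#'   `detected`.
#' @export
simulate_calibration <- function(design, seed, endogenous_fmol = 0,
                                 cv = 0.2, snr_per_fmol = 1,
                                 snr_threshold = 3) {
  stopifnot(inherits(design, "spike_design"))
  sdlog <- sqrt(log(1 + cv^2))
  .with_seed(seed, {
    rows <- lapply(design$levels_fmol, function(lev) {
      varied <- if (design$orientation == "forward") {
        lev + endogenous_fmol
      } else {
        lev
      }
      true_ratio <- varied / design$constant_fmol
      noise <- exp(stats::rnorm(design$replicates, -sdlog^2 / 2, sdlog))
      det_noise <- exp(stats::rnorm(design$replicates, -sdlog^2 / 2, sdlog))
      snr <- snr_per_fmol * varied * det_noise
      detected <- snr >= snr_threshold
      data.frame(level_fmol = lev, replicate = seq_len(design$replicates),
                 ratio = ifelse(detected, true_ratio * noise, NA_real_),
                 snr = snr, detected = detected)
    })
    do.call(rbind, rows)
  })
}

#' Fit the log-log calibration line
#'
#' Least squares on log10(ratio) versus log10(spike), after iteratively
#' excluding levels whose mean residual exceeds `resid_cutoff` (plateau or
#' saturated levels). The retained-level span is the linear dynamic range
#' in orders of magnitude.
#'
#' @param design A [spike_design()].
#' @param measurements data.frame as from [simulate_calibration()] (or read
#'   from a calibration table): `level_fmol`, `replicate`, `ratio`,
#'   `detected`.
#' @param resid_cutoff Maximum |mean residual| (log10 units) for a level to
#'   stay in the linear fit.
#' @return Object of class `calibration_fit`: `slope`, `intercept`, `r2`,
#'   `retained_levels`, `excluded_levels`, `dynamic_range` (log10 orders),
#'   `linear` (flag).
#' @export
fit_curve <- function(design, measurements, resid_cutoff = 0.15) {
  stopifnot(inherits(design, "spike_design"))
  m <- measurements[measurements$level_fmol > 0 & measurements$detected &
                      !is.na(measurements$ratio) & measurements$ratio > 0, ,
                    drop = FALSE]
  if (length(unique(m$level_fmol)) < 3L) {
    stop("fewer than 3 detected levels; cannot fit a calibration line")
  }
  # trim one level at a time (the worst violator) so that curvature at one
  # end cannot trigger a premature mass exclusion
  lv <- sort(unique(m$level_fmol))
  keep_flag <- rep(TRUE, length(lv))
  repeat {
    d <- m[m$level_fmol %in% lv[keep_flag], , drop = FALSE]
    fit <- stats::lm(log10(ratio) ~ log10(level_fmol), data = d)
    res <- tapply(stats::residuals(fit),
                  factor(d$level_fmol, levels = lv[keep_flag]), mean)
    worst <- which.max(abs(res))
    if (abs(res[worst]) <= resid_cutoff || sum(keep_flag) <= 3L) break
    keep_flag[which(keep_flag)[worst]] <- FALSE
  }
  keep <- lv[keep_flag]
  d <- m[m$level_fmol %in% keep, , drop = FALSE]
  fit <- stats::lm(log10(ratio) ~ log10(level_fmol), data = d)
  slope <- unname(stats::coef(fit)[2L])
  # a noiseless fit is legitimate here; silence the perfect-fit notice
  r2 <- suppressWarnings(summary(fit)$r.squared)
  linear <- is.finite(slope) && stats::sd(log10(d$level_fmol)) > 0
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1L]), r2 = r2,
         retained_levels = sort(keep, decreasing = TRUE),
         excluded_levels = sort(setdiff(unique(m$level_fmol), keep),
                                decreasing = TRUE),
         dynamic_range = log10(max(keep) / min(keep)), linear = linear),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> slope %.3f, R^2 %.4f, %.1f orders dynamic range (%d levels)\n",
    x$slope, x$r2, x$dynamic_range, length(x$retained_levels)))
  invisible(x)
}

.level_detection <- function(measurements) {
  lv <- sort(unique(measurements$level_fmol[measurements$level_fmol > 0]))
  data.frame(
    level_fmol = lv,
    n = vapply(lv, function(l) sum(measurements$level_fmol == l), numeric(1)),
    n_detected = vapply(lv, function(l) {
      sum(measurements$detected[measurements$level_fmol == l])
    }, numeric(1)),
    cv = vapply(lv, function(l) {
      r <- measurements$ratio[measurements$level_fmol == l &
                                measurements$detected]
      r <- r[!is.na(r)]
      if (length(r) >= 2L) 100 * stats::sd(r) / mean(r) else NA_real_
    }, numeric(1))
  )
}

#' Limit of detection from replicate detection flags
#'
#' The lowest spiked level identifiable in more than half of its
#' replicates (for triplicates: at least two of three).
#'
#' @param measurements Calibration measurements (`level_fmol`, `detected`).
#' @param design The [spike_design()] (levels taken from the measurements;
#'   kept for interface symmetry).
#' @return LOD in fmol, or `NA` with a message attribute when no level
#'   qualifies.
#' @export
lod <- function(measurements, design = NULL) {
  d <- .level_detection(measurements)
  ok <- d$level_fmol[d$n_detected > d$n / 2]
  if (!length(ok)) {
    return(structure(NA_real_, status = "not detected"))
  }
  min(ok)
}

#' Limit of quantification from replicate detection flags and CV
#'
#' The lowest spiked level that satisfies the LOD rule and whose replicate
#' ratio CV is below `cv_limit` percent. Always >= the LOD.
#'
#' @inheritParams lod
#' @param cv_limit Maximum replicate CV, percent (default 30).
#' @return LOQ in fmol, or flagged `NA`.
#' @export
loq <- function(measurements, design = NULL, cv_limit = 30) {
  d <- .level_detection(measurements)
  ok <- d$level_fmol[d$n_detected > d$n / 2 & !is.na(d$cv) & d$cv < cv_limit]
  if (!length(ok)) {
    return(structure(NA_real_, status = "not quantifiable"))
  }
  min(ok)
}

#' Endogenous level from the forward-curve plateau
#'
#' At low spikes the forward-curve ratio plateaus at endogenous/constant;
#' the estimate is the mean of (ratio x constant - spike) over the plateau
#' levels. Plateau membership is found iteratively: starting from the
#' blank (or lowest-level) estimate, levels whose spike is below
#' `plateau_fraction` of the current endogenous estimate are included.
#' The top spike levels never enter the plateau window.
#'
#' @param measurements Forward-curve measurements.
#' @param design The forward [spike_design()].
#' @param plateau_fraction Spike must stay below this fraction of the
#'   endogenous estimate to count as plateau (default 0.5).
#' @return Endogenous amount estimate, fmol.
#' @export
endogenous_estimate <- function(measurements, design,
                                plateau_fraction = 0.5) {
  stopifnot(inherits(design, "spike_design"))
  if (design$orientation != "forward") {
    stop("endogenous estimation requires a forward curve")
  }
  m <- measurements[measurements$detected & !is.na(measurements$ratio), ,
                    drop = FALSE]
  if (!nrow(m)) stop("no detected measurements")
  lowest <- min(m$level_fmol)
  est <- mean(m$ratio[m$level_fmol == lowest]) * design$constant_fmol - lowest
  for (it in 1:3) {
    plateau <- m$level_fmol < plateau_fraction * max(est, lowest + 1e-12)
    if (!any(plateau)) break
    est <- mean(m$ratio[plateau] * design$constant_fmol -
                  m$level_fmol[plateau])
  }
  if (!any(m$level_fmol < plateau_fraction * est) && est > lowest) {
    stop("no plateau detected at the low-spike end")
  }
  max(est, 0)
}

#' Median replicate CV across calibration levels
#'
#' @param measurements Calibration measurements.
#' @return Median of the per-level replicate CVs (percent).
#' @export
median_replicate_cv <- function(measurements) {
  d <- .level_detection(measurements)
  stats::median(d$cv, na.rm = TRUE)
}
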