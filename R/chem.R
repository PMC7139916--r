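.chem <- new.env(parent = emptyenv())

#' Mass constants used throughout the package
#'
#' Water and proton masses used to convert summed residue masses into the
#' singly protonated (MH+) ion mass reported by MALDI-TOF instruments.
#'
#' @return Named numeric vector with elements `water_mono`, `water_avg`
#'   and `proton` (Da).
#' @export
#' @examples
#' mass_constants()["proton"]
mass_constants <- function() {
  c(water_mono = 18.010565, water_avg = 18.0153, proton = 1.007276)
}

#' Residue mass table
#'
#' Monoisotopic and average residue masses for the 20 standard amino acids,
#' shipped as a versioned plain-text table under `inst/extdata` so that the
#' constant set can be diffed and pinned.
#'
#' @return A data.frame with columns `residue`, `mono`, `avg`.
#' @export
residue_masses <- function() {
  if (is.null(.chem$tab)) {
    path <- system.file("extdata", "residue_masses.tsv", package = "maldipanel")
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 20L, all(tab$mono < tab$avg))
    .chem$tab <- tab
    .chem$mono <- stats::setNames(tab$mono, tab$residue)
    .chem$avg <- stats::setNames(tab$avg, tab$residue)
  }
  .chem$tab
}

.residue_vec <- function(kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  residue_masses()
  if (kind == "mono") .chem$mono else .chem$avg
}

#' Built-in modification definitions
#'
#' Mass deltas and residue specificities for the modifications the package
#' understands: phosphorylation, acetylation, mono/di/tri-methylation and
#' carbamidomethylation.
#'
#' @return A data.frame with columns `name`, `delta_mono`, `delta_avg`,
#'   `targets` (string of allowed residues).
#' @export
#' @examples
#' modifications()
modifications <- function() {
  data.frame(
    name = c("phospho", "acetyl", "methyl", "dimethyl", "trimethyl",
             "carbamidomethyl"),
    delta_mono = c(79.966331, 42.010565, 14.015650, 28.031300, 42.046950,
                   57.021464),
    delta_avg = c(79.9799, 42.0367, 14.0266, 28.0532, 42.0797, 57.0513),
    targets = c("STY", "K", "KR", "KR", "K", "C"),
    stringsAsFactors = FALSE
  )
}

#' Mass delta of a named modification
#'
#' @param name Modification name, see [modifications()].
#' @param kind `"mono"` or `"avg"`.
#' @return Mass delta in Da.
#' @export
modification_delta <- function(name, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  tab <- modifications()
  i <- match(name, tab$name)
  if (anyNA(i)) stop("unknown modification: ", paste(name[is.na(i)], collapse = ", "))
  if (kind == "mono") tab$delta_mono[i] else tab$delta_avg[i]
}

#' Stable-isotope label scheme
#'
#' Per-residue mass deltas for metabolic (SILAC) or synthetic (SIS) heavy
#' labels. `nominal` mode uses the integer shifts conventionally quoted for
#' the labels (+8 Lys, +10 Arg, +6 Val); `exact` mode uses the isotopologue
#' mass differences.
#'
#' @param deltas Named numeric vector of per-residue deltas (Da). Defaults
#'   to the K/R/V set appropriate for the chosen mode.
#' @param mode `"nominal"` (integer shifts) or `"exact"`.
#' @return An object of class `label_scheme`.
#' @export
#' @examples
#' label_scheme()                  # K+8, R+10, V+6, nominal
#' label_scheme(mode = "exact")
label_scheme <- function(deltas = NULL, mode = c("nominal", "exact")) {
  mode <- match.arg(mode)
  if (is.null(deltas)) {
    deltas <- if (mode == "nominal") {
      c(K = 8, R = 10, V = 6)
    } else {
      c(K = 8.014199, R = 10.008269, V = 6.013809)
    }
  }
  stopifnot(is.numeric(deltas), length(names(deltas)) == length(deltas))
  structure(list(deltas = deltas, mode = mode), class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> mode =", x$mode, "\n")
  print(x$deltas)
  invisible(x)
}

.parse_mods <- function(mods) {
  if (is.null(mods) || (is.data.frame(mods) && nrow(mods) == 0L) ||
      length(mods) == 0L) {
    return(data.frame(position = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(mods)) {
    stopifnot(all(c("position", "name") %in% names(mods)))
    out <- data.frame(position = as.integer(mods$position),
                      name = as.character(mods$name),
                      stringsAsFactors = FALSE)
  } else {
    # named numeric shorthand: c(phospho = 3, phospho = 4)
    stopifnot(is.numeric(mods), !is.null(names(mods)))
    out <- data.frame(position = as.integer(mods), name = names(mods),
                      stringsAsFactors = FALSE)
  }
  out[order(out$position), , drop = FALSE]
}

#' Construct a modified peptide
#'
#' The unit of everything downstream: a peptide sequence with positioned
#' modifications, labelled residues and optional provenance (parent protein
#' and start coordinate) and mutation annotation.
#'
#' @param sequence Peptide sequence, 1-letter codes, standard residues only.
#' @param mods Modifications, either a data.frame with columns
#'   `position`, `name` or named-numeric shorthand `c(phospho = 3)`
#'   (name = modification, value = 1-based position).
#' @param labeled Integer vector of 1-based positions carrying a heavy label.
#' @param protein,start Optional parent accession and 1-based start
#'   coordinate of the peptide in that protein.
#' @param mutation Optional mutation annotation string (e.g. `"A2V"`).
#' @return An object of class `modified_peptide`.
#' @export
#' @examples
#' modified_peptide("VADPDHDHTGFLTEYVATR", mods = c(phospho = 13, phospho = 15))
modified_peptide <- function(sequence, mods = NULL, labeled = integer(),
                             protein = NA_character_, start = NA_integer_,
                             mutation = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% residue_masses()$residue)
  if (length(bad)) {
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1],
         " of '", sequence, "'")
  }
  mods <- .parse_mods(mods)
  if (nrow(mods)) {
    if (any(mods$position < 1L | mods$position > length(res))) {
      stop("modification position outside peptide")
    }
    if (anyDuplicated(mods$position)) {
      stop("more than one modification at position ",
           mods$position[duplicated(mods$position)][1])
    }
    tab <- modifications()
    tgt <- tab$targets[match(mods$name, tab$name)]
    if (anyNA(tgt)) stop("unknown modification: ",
                         mods$name[is.na(tgt)][1])
    ok <- mapply(grepl, res[mods$position], tgt, MoreArgs = list(fixed = TRUE))
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(mods$name[i], " not allowed on residue ", res[mods$position[i]],
           " at position ", mods$position[i])
    }
  }
  labeled <- sort(unique(as.integer(labeled)))
  if (length(labeled) && (min(labeled) < 1L || max(labeled) > length(res))) {
    stop("labeled position outside peptide")
  }
  structure(
    list(sequence = sequence, residues = res, mods = mods, labeled = labeled,
         protein = protein, start = as.integer(start), mutation = mutation),
    class = "modified_peptide"
  )
}

#' @export
print.modified_peptide <- function(x, ...) {
  ann <- if (nrow(x$mods)) {
    paste(paste0(x$mods$name, "@", x$mods$position), collapse = " + ")
  } else "none"
  lab <- if (length(x$labeled)) paste(x$labeled, collapse = ",") else "none"
  cat("<modified_peptide>", x$sequence, "\n  mods:", ann,
      "\n  labeled:", lab, "\n")
  if (!is.na(x$mutation)) cat("  mutation:", x$mutation, "\n")
  invisible(x)
}

.as_peptide <- function(x) {
  if (inherits(x, "modified_peptide")) x else modified_peptide(x)
}

.label_delta_of <- function(pep, scheme) {
  if (!length(pep$labeled)) return(0)
  if (is.null(scheme)) stop("peptide has labeled positions but no label scheme given")
  res <- pep$residues[pep$labeled]
  i <- match(res, names(scheme$deltas))
  if (anyNA(i)) {
    stop("label scheme does not define residue ", res[is.na(i)][1])
  }
  sum(scheme$deltas[i])
}

#' Monoisotopic MH+ mass of a peptide
#'
#' Sum of residue monoisotopic masses plus water, one proton, modification
#' deltas and (when a label scheme is supplied) label deltas.
#'
#' @param x A [modified_peptide()] or a plain sequence string.
#' @param scheme Optional [label_scheme()] applied to labeled positions.
#' @return MH+ mass in Da.
#' @export
#' @examples
#' mono_mass("AGGEESQFEMDI")     # 1312.536
mono_mass <- function(x, scheme = NULL) {
  pep <- .as_peptide(x)
  rm <- .residue_vec("mono")
  k <- mass_constants()
  m <- sum(rm[pep$residues]) + k[["water_mono"]] + k[["proton"]]
  if (nrow(pep$mods)) m <- m + sum(modification_delta(pep$mods$name, "mono"))
  m + .label_delta_of(pep, scheme)
}

#' Average MH+ mass of a peptide
#'
#' @inheritParams mono_mass
#' @return MH+ mass in Da (average isotopic composition).
#' @export
avg_mass <- function(x, scheme = NULL) {
  pep <- .as_peptide(x)
  rm <- .residue_vec("avg")
  k <- mass_constants()
  m <- sum(rm[pep$residues]) + k[["water_avg"]] + k[["proton"]]
  if (nrow(pep$mods)) m <- m + sum(modification_delta(pep$mods$name, "avg"))
  m + .label_delta_of(pep, scheme)
}

#' Total label mass delta of a peptide
#'
#' Additive over labeled residues; in `nominal` mode the result is an exact
#' integer (e.g. two K+8 labels give 16).
#'
#' @inheritParams mono_mass
#' @return Label delta in Da.
#' @export
#' @examples
#' p <- modified_peptide("DMYDKEYYSVHNK", labeled = c(5, 13))
#' label_delta(p, label_scheme())   # 16
label_delta <- function(x, scheme = label_scheme()) {
  pep <- .as_peptide(x)
  .label_delta_of(pep, scheme)
}

#' Singly charged b/y fragment ion series
#'
#' b_i is the sum of the first i residue masses (plus their modifications)
#' plus a proton; y_i is the sum of the last i residues plus water and a
#' proton. Only singly charged ions are produced (MALDI context).
#'
#' @inheritParams mono_mass
#' @param series Which series to compute, subset of `c("b", "y")`.
#' @return data.frame with columns `ion` (e.g. `"b2"`), `series`, `index`,
#'   `mz`.
#' @export
#' @examples
#' fragment_ions("RAGGEESQFEMDI", series = "b")
fragment_ions <- function(x, series = c("b", "y"), scheme = NULL) {
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  pep <- .as_peptide(x)
  n <- length(pep$residues)
  if (n < 2L) stop("fragment ions need at least 2 residues")
  rm <- .residue_vec("mono")
  k <- mass_constants()
  per <- unname(rm[pep$residues])
  if (nrow(pep$mods)) {
    per[pep$mods$position] <- per[pep$mods$position] +
      modification_delta(pep$mods$name, "mono")
  }
  if (length(pep$labeled)) {
    if (is.null(scheme)) scheme <- label_scheme()
    i <- match(pep$residues[pep$labeled], names(scheme$deltas))
    per[pep$labeled] <- per[pep$labeled] + scheme$deltas[i]
  }
  out <- list()
  if ("b" %in% series) {
    mz <- cumsum(per)[1:(n - 1L)] + k[["proton"]]
    out$b <- data.frame(ion = paste0("b", 1:(n - 1L)), series = "b",
                        index = 1:(n - 1L), mz = mz,
                        stringsAsFactors = FALSE)
  }
  if ("y" %in% series) {
    mz <- cumsum(rev(per))[1:(n - 1L)] + k[["water_mono"]] + k[["proton"]]
    out$y <- data.frame(ion = paste0("y", 1:(n - 1L)), series = "y",
                        index = 1:(n - 1L), mz = mz,
                        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply a point mutation to a peptide
#'
#' Substitutes one residue and records the change (e.g. `"A2V"`), keeping
#' modifications and labels in place. Used to encode alternative alleles of
#' an assay's base peptide.
#'
#' @param x A [modified_peptide()] or sequence string.
#' @param position 1-based peptide position to substitute.
#' @param to Replacement residue (1-letter code).
#' @return A new `modified_peptide`.
#' @export
#' @examples
#' apply_mutation("RAGGEESQFEMDI", 2, "V")  # A107V in protein coordinates
apply_mutation <- function(x, position, to) {
  pep <- .as_peptide(x)
  position <- as.integer(position)
  stopifnot(position >= 1L, position <= length(pep$residues),
            is.character(to), nchar(to) == 1L)
  to <- toupper(to)
  if (!to %in% residue_masses()$residue) stop("unknown residue: ", to)
  from <- pep$residues[position]
  res <- pep$residues
  res[position] <- to
  modified_peptide(paste(res, collapse = ""), mods = pep$mods,
                   labeled = pep$labeled, protein = pep$protein,
                   start = pep$start,
                   mutation = paste0(from, position, to))
}
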