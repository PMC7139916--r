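#' Protease cleavage rule
#'
#' Built-in specificities follow common usage: trypsin cleaves C-terminal to
#' K/R, chymotrypsin C-terminal to F/Y/W/L (optionally M), ArgC after R,
#' LysC after K, GluC after E, and AspN N-terminal to D. Cleavage before
#' proline is suppressed by default (Keil rule) for the C-terminal cutters.
#'
#' @param name One of `"trypsin"`, `"chymotrypsin"`, `"argc"`, `"lysc"`,
#'   `"aspn"`, `"gluc"`, or `"custom"`.
#' @param residues For `"custom"`: string of cleavage residues.
#' @param side For `"custom"`: `"C"` or `"N"` terminal cleavage side.
#' @param suppress_proline Suppress cleavage when the following residue is
#'   proline. Default TRUE for C-side rules (the printed reference peptides
#'   are consistent either way for trypsin).
#' @param include_met Chymotrypsin only: also cleave after methionine.
#' @return An object of class `protease_rule`.
#' @export
#' @examples
#' protease_rule("trypsin")
#' protease_rule("chymotrypsin")
protease_rule <- function(name = c("trypsin", "chymotrypsin", "argc", "lysc",
                                   "aspn", "gluc", "custom"),
                          residues = NULL, side = NULL,
                          suppress_proline = TRUE, include_met = FALSE) {
  name <- match.arg(name)
  spec <- switch(name,
    trypsin = list(residues = "KR", side = "C"),
    chymotrypsin = list(residues = paste0("FYWL", if (include_met) "M"),
                        side = "C"),
    argc = list(residues = "R", side = "C"),
    lysc = list(residues = "K", side = "C"),
    aspn = list(residues = "D", side = "N"),
    gluc = list(residues = "E", side = "C"),
    custom = {
      stopifnot(is.character(residues), !is.null(side))
      list(residues = toupper(residues), side = match.arg(side, c("C", "N")))
    }
  )
  structure(
    list(name = name, residues = strsplit(spec$residues, "")[[1]],
         side = spec$side,
         suppress_proline = isTRUE(suppress_proline) && spec$side == "C"),
    class = "protease_rule"
  )
}

#' @export
print.protease_rule <- function(x, ...) {
  cat("<protease_rule>", x$name, "- cleave", x$side, "terminal to",
      paste(x$residues, collapse = "/"),
      if (x$suppress_proline) "(not before P)", "\n")
  invisible(x)
}

.as_rule <- function(rule) {
  if (inherits(rule, "protease_rule")) rule else protease_rule(rule)
}

#' Cut-site positions for a protease rule
#'
#' A site at position `i` means cleavage between residues `i` and `i + 1`.
#' Deterministic: identical inputs always give the identical site set.
#'
#' @param sequence Protein or peptide sequence.
#' @param rule A [protease_rule()] or its name.
#' @param mod_positions Optional 1-based positions of modified residues.
#' @param suppress_near_mods When TRUE, sites whose flanking residues lie
#'   within +/-1 of a modified position are skipped, emulating the missed
#'   cleavages that modification adjacent to K/R tends to force.
#' @return Sorted integer vector of cut positions.
#' @export
cut_sites <- function(sequence, rule = "trypsin", mod_positions = NULL,
                      suppress_near_mods = FALSE) {
  rule <- .as_rule(rule)
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  if (n < 1L) stop("empty sequence")
  if (n == 1L) return(integer())
  idx <- seq_len(n - 1L)
  sites <- if (rule$side == "C") {
    hit <- res[idx] %in% rule$residues
    if (rule$suppress_proline) hit <- hit & res[idx + 1L] != "P"
    idx[hit]
  } else {
    idx[res[idx + 1L] %in% rule$residues]
  }
  if (isTRUE(suppress_near_mods) && length(mod_positions) && length(sites)) {
    near <- vapply(sites, function(i) {
      any(abs(mod_positions - i) <= 1L | mod_positions == i + 1L)
    }, logical(1))
    sites <- sites[!near]
  }
  sites
}

#' In silico proteolytic digest
#'
#' Enumerates all digestion products with 0 to `max_missed` internal
#' (uncut) sites, reporting protein coordinates and the preceding/following
#' residues in P1/P1' flanking notation (`-` at the termini).
#'
#' @inheritParams cut_sites
#' @param max_missed Maximum number of internal missed cleavage sites.
#' @return data.frame with columns `sequence`, `start`, `end`, `missed`,
#'   `previous`, `following`.
#' @export
#' @examples
#' digest("MEASQSHLRNSPEDKRAGGEESQFEMDI", "trypsin", max_missed = 1)
digest <- function(sequence, rule = "trypsin", max_missed = 2L,
                   mod_positions = NULL, suppress_near_mods = FALSE) {
  stopifnot(max_missed >= 0L)
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 1L) stop("empty sequence")
  bad <- which(!res %in% residue_masses()$residue)
  if (length(bad)) {
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  }
  sites <- cut_sites(sequence, rule, mod_positions, suppress_near_mods)
  bounds <- c(0L, sites, n)
  nb <- length(bounds)
  out <- list()
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    for (j in (i + 1L):jmax) {
      s <- bounds[i] + 1L
      e <- bounds[j]
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, s, e),
        start = s, end = e, missed = j - i - 1L,
        previous = if (s == 1L) "-" else res[s - 1L],
        following = if (e == n) "-" else res[e + 1L],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Epitope specification
#'
#' The linear residue range an antibody recognises, with the modification
#' state it requires. `semantics = "any"` encodes cross-reactive antibodies
#' that capture peptides carrying at least one of the named sites (e.g. a
#' motif antibody recognising singly or doubly phosphorylated forms);
#' `"all"` requires every named site.
#'
#' @param start,end 1-based inclusive residue range in the protein.
#' @param required_mods Modifications required by the antibody, in protein
#'   coordinates (data.frame `position`/`name` or `c(phospho = 235)`).
#' @param semantics `"all"` or `"any"` over the required sites.
#' @param accession Optional protein accession.
#' @return Object of class `epitope_spec`.
#' @export
epitope_spec <- function(start, end, required_mods = NULL,
                         semantics = c("all", "any"),
                         accession = NA_character_) {
  semantics <- match.arg(semantics)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start >= 1L, end >= start)
  mods <- .parse_mods(required_mods)
  if (nrow(mods) && any(mods$position < start | mods$position > end)) {
    stop("required modification position outside epitope range")
  }
  structure(list(start = start, end = end, required_mods = mods,
                 semantics = semantics, accession = accession),
            class = "epitope_spec")
}

.as_epitope <- function(x) {
  if (inherits(x, "epitope_spec")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(epitope_spec(x[1], x[2]))
  stop("epitope must be an epitope_spec or a length-2 numeric range")
}

#' Digestion products that preserve an epitope
#'
#' Filters a digest for peptides that fully contain the epitope range,
#' ranked by fewest missed cleavages, then shortest length, then lowest
#' start coordinate. An empty result signals that the protease destroys
#' the epitope at the requested missed-cleavage ceiling.
#'
#' @inheritParams digest
#' @param epitope An [epitope_spec()] or `c(start, end)`.
#' @return data.frame as [digest()], ranked; zero rows if no product
#'   preserves the epitope.
#' @export
peptides_covering_epitope <- function(sequence, epitope, rule = "trypsin",
                                      max_missed = 2L) {
  ep <- .as_epitope(epitope)
  n <- nchar(sequence)
  if (ep$end > n) stop("epitope extends beyond protein (length ", n, ")")
  pep <- digest(sequence, rule, max_missed)
  keep <- pep$start <= ep$start & pep$end >= ep$end
  out <- pep[keep, , drop = FALSE]
  len <- out$end - out$start + 1L
  out <- out[order(out$missed, len, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare proteases for epitope-preserving assay design
#'
#' For each protease, reports the best epitope-preserving peptide (by the
#' ranking of [peptides_covering_epitope()]), its MH+ monoisotopic mass, and
#' the flanking protein positions the peptide exposes beyond the epitope --
#' the residues an alternative protease makes newly interrogable (e.g. an
#' upstream phosphosite that tryptic products never cover).
#'
#' @inheritParams peptides_covering_epitope
#' @param rules List of [protease_rule()] objects or names.
#' @return data.frame with one row per protease: `protease`, `sequence`,
#'   `start`, `end`, `missed`, `mono_mass`, `n_extra`, `extra_positions`
#'   (comma-separated residue+position labels outside the epitope; empty if
#'   no covering peptide exists).
#' @export
#' @examples
#' prot <- paste0("AIPATRRVVLGDGVQLPPGDYSTTPGGTLFSTTPGGTRIIYDRKFLMECR",
#'                "NSPVTKTPPRDLPTIPGVTSPSSDEPPMEASQSHLRNSPEDKRAGGEESQFEMDI")
#' compare_proteases(prot, c(96, 105), c("trypsin", "chymotrypsin"))
compare_proteases <- function(sequence, epitope, rules, max_missed = 2L) {
  ep <- .as_epitope(epitope)
  res <- strsplit(toupper(sequence), "")[[1]]
  rows <- lapply(rules, function(r) {
    rule <- .as_rule(r)
    cand <- peptides_covering_epitope(sequence, ep, rule, max_missed)
    if (nrow(cand) == 0L) {
      return(data.frame(protease = rule$name, sequence = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        missed = NA_integer_, mono_mass = NA_real_,
                        n_extra = 0L, extra_positions = "",
                        stringsAsFactors = FALSE))
    }
    best <- cand[1L, ]
    extra <- setdiff(seq(best$start, best$end), seq(ep$start, ep$end))
    data.frame(protease = rule$name, sequence = best$sequence,
               start = best$start, end = best$end, missed = best$missed,
               mono_mass = mono_mass(best$sequence),
               n_extra = length(extra),
               extra_positions = paste0(res[extra], extra, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
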