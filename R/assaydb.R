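.MAX_VARIANTS <- 10000L

.mod_count_label <- function(mods) {
  if (!nrow(mods)) return("unmod")
  cnt <- table(mods$name)
  paste(paste0(as.integer(cnt), "x", names(cnt)), collapse = "+")
}

.mod_sig <- function(mods) {
  if (!nrow(mods)) return("")
  paste(paste0(mods$name, "@", mods$position), collapse = "+")
}

#' Enumerate the modification/label/mutation variant space of a peptide
#'
#' Generates every reference variant an assay must recognise: the required
#' modifications (all of them, or each non-empty subset for cross-reactive
#' antibodies), 0..`max_extra` placements of a variable modification on
#' eligible residues, optional mutation alleles (wild type is always kept),
#' and, when a label scheme is given, the heavy channel with every residue
#' named in the scheme labelled. Variants that are indistinguishable by
#' mass (same sequence, channel and mass) are collapsed with their
#' multiplicity recorded.
#'
#' @param sequence Base peptide sequence (positions below are 1-based
#'   peptide coordinates).
#' @param required Required modifications (`c(phospho = 3, phospho = 4)` or
#'   data.frame `position`/`name`).
#' @param required_semantics `"all"` (every site) or `"any"` (each
#'   non-empty subset of the sites is a variant).
#' @param variable_mod Name of a variable modification, or NULL.
#' @param variable_residues Residues eligible for the variable modification
#'   (string, e.g. `"ST"`); defaults to the modification's target set.
#' @param max_extra Maximum number of variable modifications added.
#' @param mutations List of `list(position =, to =)` alternative alleles.
#' @param scheme Optional [label_scheme()]; adds the heavy channel.
#' @param missed,start Optional provenance carried into the output.
#' @param max_variants Hard cap on enumerated variants before collapsing.
#' @return data.frame with one row per distinguishable variant:
#'   `variant_id`, `sequence`, `start`, `missed`, `channel`, `mutation`,
#'   `mods`, `label`, `multiplicity`, `ambiguous`, `mono_mass`, `avg_mass`.
#' @export
#' @examples
#' enumerate_variants("RLSSLRASTSKSESSQK",
#'   required = c(phospho = 3, phospho = 4),
#'   variable_mod = "phospho", variable_residues = "ST", max_extra = 3)
enumerate_variants <- function(sequence, required = NULL,
                               required_semantics = c("all", "any"),
                               variable_mod = NULL, variable_residues = NULL,
                               max_extra = 0L, mutations = NULL,
                               scheme = NULL, missed = NA_integer_,
                               start = NA_integer_,
                               max_variants = .MAX_VARIANTS) {
  required_semantics <- match.arg(required_semantics)
  stopifnot(max_extra >= 0L)
  required <- .parse_mods(required)
  res <- strsplit(toupper(sequence), "")[[1]]

  req_sets <- if (!nrow(required)) {
    list(required)
  } else if (required_semantics == "all") {
    list(required)
  } else {
    unlist(lapply(seq_len(nrow(required)), function(k) {
      apply(utils::combn(nrow(required), k), 2L, function(ix) {
        required[ix, , drop = FALSE]
      }, simplify = FALSE)
    }), recursive = FALSE)
  }

  extra_sets <- list(integer())
  if (!is.null(variable_mod) && max_extra > 0L) {
    if (is.null(variable_residues)) {
      tab <- modifications()
      variable_residues <- tab$targets[match(variable_mod, tab$name)]
    }
    eligible <- which(res %in% strsplit(toupper(variable_residues), "")[[1]])
    eligible <- setdiff(eligible, required$position)
    kmax <- min(max_extra, length(eligible))
    if (kmax > 0L) {
      extra_sets <- c(extra_sets, unlist(lapply(seq_len(kmax), function(k) {
        # index-based combn: a length-1 eligible set must not be treated as 1:n
        apply(utils::combn(length(eligible), k), 2L,
              function(ix) eligible[ix], simplify = FALSE)
      }), recursive = FALSE))
    }
  }

  alleles <- c(list(NULL), if (!is.null(mutations)) mutations)
  channels <- if (is.null(scheme)) "light" else c("light", "heavy")

  n_total <- length(req_sets) * length(extra_sets) * length(alleles) *
    length(channels)
  if (n_total > max_variants) {
    stop("variant space too large (", n_total, " > ", max_variants,
         "); restrict max_extra or the eligible residues")
  }

  rows <- vector("list", n_total)
  k <- 0L
  for (al in alleles) {
    seq_i <- sequence
    mut_i <- NA_character_
    if (!is.null(al)) {
      mutated <- apply_mutation(sequence, al$position, al$to)
      seq_i <- mutated$sequence
      mut_i <- mutated$mutation
    }
    for (req in req_sets) {
      for (extra in extra_sets) {
        mods <- req
        if (length(extra)) {
          mods <- rbind(mods, data.frame(position = extra,
                                         name = variable_mod,
                                         stringsAsFactors = FALSE))
        }
        mods <- mods[order(mods$position), , drop = FALSE]
        for (ch in channels) {
          labeled <- if (ch == "heavy") {
            which(strsplit(seq_i, "")[[1]] %in% names(scheme$deltas))
          } else integer()
          pep <- modified_peptide(seq_i, mods = mods, labeled = labeled,
                                  start = start, mutation = mut_i)
          k <- k + 1L
          rows[[k]] <- data.frame(
            sequence = seq_i, start = start, missed = missed,
            channel = ch, mutation = mut_i,
            mods = .mod_sig(mods), label = .mod_count_label(mods),
            multiplicity = 1L,
            mono_mass = mono_mass(pep, scheme),
            avg_mass = avg_mass(pep, scheme),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])

  # collapse variants indistinguishable by mass within a sequence/channel
  key <- paste(out$sequence, out$channel, out$mutation,
               sprintf("%.4f", out$mono_mass))
  grp <- split(seq_len(nrow(out)), key)
  out <- do.call(rbind, lapply(grp, function(ix) {
    first <- out[ix[1L], , drop = FALSE]
    first$multiplicity <- length(ix)
    first$ambiguous <- length(unique(out$label[ix])) > 1L
    first
  }))

  # a heavy channel identical in mass to light (no labelable residue)
  # collapses onto the light row
  key2 <- paste(out$sequence, out$mutation, sprintf("%.4f", out$mono_mass))
  grp2 <- split(seq_len(nrow(out)), key2)
  out <- do.call(rbind, lapply(grp2, function(ix) {
    first <- out[ix[1L], , drop = FALSE]
    if (length(ix) > 1L) first$channel <- "both"
    first
  }))

  out <- out[order(out$channel, out$mono_mass), , drop = FALSE]
  out$variant_id <- paste0(
    ifelse(is.na(out$start), "", paste0("s", out$start, ".")),
    ifelse(is.na(out$missed), "", paste0(out$missed, "XC.")),
    out$label, ".", out$channel,
    ifelse(is.na(out$mutation), "", paste0(".", out$mutation))
  )
  rownames(out) <- NULL
  out[, c("variant_id", "sequence", "start", "missed", "channel", "mutation",
          "mods", "label", "multiplicity", "ambiguous", "mono_mass",
          "avg_mass")]
}

#' Build a validated assay definition
#'
#' Selects every digestion product (up to the missed-cleavage ceiling) that
#' preserves the antibody's epitope, enumerates the PTM/label/mutation
#' variant space of each, and stores the reference masses in both
#' acquisition conventions. If the protease destroys the epitope, a
#' structured error of class `maldipanel_no_assay` names the offending cut
#' site(s).
#'
#' @param id Unique assay identifier.
#' @param protein_sequence Target protein (or region) sequence.
#' @param epitope An [epitope_spec()] carrying the required modifications in
#'   protein coordinates, or `c(start, end)`.
#' @param protease A [protease_rule()] or its name.
#' @param max_missed Missed-cleavage ceiling for covering peptides.
#' @param variable_mod,variable_residues,max_extra Variable-modification
#'   rule, as in [enumerate_variants()].
#' @param mutations List of `list(position =, to =)` in protein coordinates.
#' @param scheme Optional [label_scheme()] (adds the heavy channel).
#' @param accession,protein_name,site Assay metadata.
#' @return Object of class `assay_definition` with a `variants` data.frame.
#' @export
build_assay <- function(id, protein_sequence, epitope, protease = "trypsin",
                        max_missed = 2L, variable_mod = NULL,
                        variable_residues = NULL, max_extra = 0L,
                        mutations = NULL, scheme = NULL,
                        accession = NA_character_,
                        protein_name = NA_character_, site = NA_character_) {
  ep <- .as_epitope(epitope)
  rule <- .as_rule(protease)
  cand <- peptides_covering_epitope(protein_sequence, ep, rule, max_missed)
  if (nrow(cand) == 0L) {
    sites <- cut_sites(protein_sequence, rule)
    inside <- sites[sites >= ep$start & sites < ep$end]
    stop(errorCondition(
      paste0("no assay possible for '", id, "': ", rule$name,
             " cleaves inside the epitope at position",
             if (length(inside) > 1L) "s ", paste(inside, collapse = ", "),
             " (max_missed = ", max_missed, ")"),
      class = c("maldipanel_no_assay", "error", "condition")
    ))
  }
  vars <- lapply(seq_len(nrow(cand)), function(i) {
    p <- cand[i, ]
    req <- ep$required_mods
    if (nrow(req)) {
      req$position <- req$position - p$start + 1L
    }
    mut <- NULL
    if (!is.null(mutations)) {
      mut <- Filter(function(m) m$position >= p$start && m$position <= p$end,
                    mutations)
      mut <- lapply(mut, function(m) {
        list(position = m$position - p$start + 1L, to = m$to)
      })
      if (!length(mut)) mut <- NULL
    }
    enumerate_variants(p$sequence, required = req,
                       required_semantics = ep$semantics,
                       variable_mod = variable_mod,
                       variable_residues = variable_residues,
                       max_extra = max_extra, mutations = mut,
                       scheme = scheme, missed = p$missed, start = p$start)
  })
  variants <- do.call(rbind, vars)
  variants <- variants[order(variants$channel, variants$mono_mass), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  structure(
    list(id = id, accession = accession, protein_name = protein_name,
         site = site, epitope = ep, protease = rule$name,
         max_missed = as.integer(max_missed), scheme = scheme,
         peptides = cand, variants = variants),
    class = "assay_definition"
  )
}

#' @export
print.assay_definition <- function(x, ...) {
  cat("<assay_definition>", x$id,
      if (!is.na(x$site)) paste0("[", x$site, "]"),
      "-", nrow(x$variants), "variants from", nrow(x$peptides),
      "covering peptide(s),", x$protease, "\n")
  invisible(x)
}

#' Compile assays into a searchable multiplexed panel
#'
#' Builds the sorted reference-mass index used to decode randomly arrayed
#' spots and reports every cross-assay mass collision within the strict
#' linear-mode tolerance. Collisions are reported (and warned about), not
#' fatal: a collided panel is still usable, with reduced decodability.
#'
#' @param assays List of [build_assay()] results.
#' @param tolerances A [tolerance_settings()] object.
#' @return Object of class `assay_panel` with elements `assays` (named
#'   list), `index` (data.frame sorted by `mono_mass`), `collisions`,
#'   `tolerances`.
#' @export
compile_panel <- function(assays, tolerances = tolerance_settings()) {
  stopifnot(length(assays) >= 1L)
  ids <- vapply(assays, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate assay ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  index <- do.call(rbind, lapply(assays, function(a) {
    cbind(assay_id = a$id, a$variants, stringsAsFactors = FALSE)
  }))
  index <- index[order(index$mono_mass), , drop = FALSE]
  rownames(index) <- NULL

  coll <- list()
  if (nrow(index) > 1L) {
    for (i in seq_len(nrow(index) - 1L)) {
      j <- i + 1L
      while (j <= nrow(index) &&
             index$mono_mass[j] - index$mono_mass[i] <= tolerances$linear_da) {
        if (index$assay_id[i] != index$assay_id[j]) {
          coll[[length(coll) + 1L]] <- data.frame(
            assay_a = index$assay_id[i], variant_a = index$variant_id[i],
            mass_a = index$mono_mass[i],
            assay_b = index$assay_id[j], variant_b = index$variant_id[j],
            mass_b = index$mono_mass[j],
            delta = index$mono_mass[j] - index$mono_mass[i],
            stringsAsFactors = FALSE
          )
        }
        j <- j + 1L
      }
    }
  }
  collisions <- if (length(coll)) do.call(rbind, coll) else
    data.frame(assay_a = character(), variant_a = character(),
               mass_a = numeric(), assay_b = character(),
               variant_b = character(), mass_b = numeric(),
               delta = numeric(), stringsAsFactors = FALSE)
  if (nrow(collisions)) {
    warning(nrow(collisions), " cross-assay mass collision(s) within ",
            tolerances$linear_da, " Da")
  }
  structure(
    list(assays = stats::setNames(assays, ids), index = index,
         collisions = collisions, tolerances = tolerances),
    class = "assay_panel"
  )
}

#' @export
print.assay_panel <- function(x, ...) {
  cat("<assay_panel>", length(x$assays), "assays,", nrow(x$index),
      "reference variants,", nrow(x$collisions),
      "cross-assay collision(s)\n")
  invisible(x)
}
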