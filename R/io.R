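#' Micro-spot array layout
#'
#' Geometry of the elution array on a standard 25 x 75 mm slide: a grid of
#' micro-spots at a fixed pitch, produced by a micro-well gasket of given
#' spot diameter. The default 26 x 88 grid at 0.8 mm pitch gives the
#' 2288-spot full-slide array.
#'
#' @param rows,columns Grid dimensions.
#' @param pitch_mm Centre-to-centre spot spacing, mm.
#' @param spot_um Spot diameter, micrometres.
#' @param slide_mm Slide size c(width, length), mm; rows run along the
#'   width, columns along the length.
#' @return Object of class `array_layout`.
#' @export
array_layout <- function(rows = 26, columns = 88, pitch_mm = 0.8,
                         spot_um = 500, slide_mm = c(25, 75)) {
  stopifnot(rows >= 1, columns >= 1, pitch_mm > 0, spot_um > 0)
  extent_y <- (rows - 1) * pitch_mm + spot_um / 1000
  extent_x <- (columns - 1) * pitch_mm + spot_um / 1000
  if (extent_y > slide_mm[1] || extent_x > slide_mm[2]) {
    stop(sprintf(
      "%d x %d spots at %.2f mm pitch (%.0f um spots) exceed the %g x %g mm slide",
      rows, columns, pitch_mm, spot_um, slide_mm[1], slide_mm[2]))
  }
  structure(list(rows = as.integer(rows), columns = as.integer(columns),
                 pitch_mm = pitch_mm, spot_um = spot_um,
                 slide_mm = slide_mm),
            class = "array_layout")
}

#' Spot coordinates of an array layout
#'
#' Row-major spot ids; the origin is the centre of the top-left spot, x
#' along the long (75 mm) axis in mm.
#'
#' @param layout An [array_layout()].
#' @return data.frame with `spot` (id), `row`, `column`, `x_mm`, `y_mm`.
#' @export
#' @examples
#' nrow(layout_coordinates(array_layout()))  # 2288
layout_coordinates <- function(layout = array_layout()) {
  stopifnot(inherits(layout, "array_layout"))
  g <- expand.grid(column = seq_len(layout$columns),
                   row = seq_len(layout$rows))
  g <- g[order(g$row, g$column), ]
  data.frame(
    spot = sprintf("R%02dC%02d", g$row, g$column),
    row = g$row, column = g$column,
    x_mm = (g$column - 1) * layout$pitch_mm,
    y_mm = (g$row - 1) * layout$pitch_mm,
    row.names = NULL
  )
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names are the first word
#'   of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*", "", names(set))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.read_numeric_table <- function(path, columns) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  # optional header row
  if (length(body) && grepl("^[A-Za-z]", body[1])) {
    body <- body[-1]
    lineno <- lineno[-1]
  }
  if (!length(body)) {
    return(stats::setNames(as.data.frame(matrix(numeric(), 0, length(columns))),
                           columns))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < length(columns)) {
      stop("line ", lineno[i], " of ", path, ": expected ",
           length(columns), " tab-separated fields, found ", length(p))
    }
    v <- suppressWarnings(as.numeric(p[seq_along(columns)]))
    if (anyNA(v)) {
      stop("line ", lineno[i], " of ", path, ": non-numeric value '",
           p[which(is.na(v))[1]], "'")
    }
    v
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- columns
  out
}

#' Read a peak list (m/z, intensity[, snr]) from tab-separated text
#'
#' Lines starting with `#` are comments; malformed lines are reported with
#' their line number.
#'
#' @param path Peak-list file.
#' @return data.frame with `mz`, `intensity` and, when present, `snr`.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*(#|$)", first)]
  ncol <- if (length(first)) {
    length(strsplit(first[length(first)], "\t", fixed = TRUE)[[1]])
  } else 2L
  cols <- if (ncol >= 3L) c("mz", "intensity", "snr") else c("mz", "intensity")
  .read_numeric_table(path, cols)
}

#' Write a peak list to tab-separated text
#'
#' @param peaks data.frame with `mz`, `intensity` and optionally `snr`.
#' @param path Output file.
#' @export
write_peaklist <- function(peaks, path) {
  cols <- intersect(c("mz", "intensity", "snr"), names(peaks))
  utils::write.table(format(peaks[, cols], digits = 10, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from the package text format
#'
#' Format: optional `#mode=linear|reflector` and `#seed=N` header lines,
#' then tab-separated m/z and intensity.
#'
#' @param path Spectrum file.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, n = 10L)
  mode <- sub("^#mode=", "", grep("^#mode=", lines, value = TRUE))
  seed <- sub("^#seed=", "", grep("^#seed=", lines, value = TRUE))
  tab <- .read_numeric_table(path, c("mz", "intensity"))
  spectrum(tab$mz, tab$intensity,
           mode = if (length(mode)) mode else "linear",
           metadata = if (length(seed)) list(seed = as.integer(seed)) else list())
}

#' Write a spectrum in the package text format
#'
#' @param x A [spectrum()].
#' @param path Output file.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "maldi_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#mode=", x$mode), con)
  if (!is.null(x$metadata$seed)) {
    writeLines(paste0("#seed=", x$metadata$seed), con)
  }
  writeLines(paste(format(x$mz, trim = TRUE, digits = 10),
                   format(x$intensity, trim = TRUE, digits = 10),
                   sep = "\t"), con)
  invisible(path)
}

#' Read and compile a panel configuration
#'
#' The configuration is a YAML file with keys `proteins` (FASTA path,
#' relative to the config), optional `tolerances` and `labels`, and
#' `assays`: a list of per-assay entries with keys `id`, `protein`,
#' `epitope` (`start`/`end`), optional `required_mods`
#' (`position`/`name` pairs), `required_semantics`, `variable_mod`,
#' `variable_residues`, `max_extra`, `protease`, `max_missed`,
#' `mutations`.
#'
#' @param path YAML panel configuration.
#' @return An [compile_panel()] result.
#' @export
#' @examples
#' cfg <- system.file("extdata", "demo_panel.yaml", package = "maldipanel")
#' panel <- read_panel_config(cfg)
read_panel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fasta <- cfg$proteins
  if (!file.exists(fasta)) fasta <- file.path(dirname(path), fasta)
  proteins <- read_fasta(fasta)
  tol <- do.call(tolerance_settings, cfg$tolerances %||% list())
  scheme <- if (!is.null(cfg$labels)) {
    label_scheme(unlist(cfg$labels))
  }
  assays <- lapply(cfg$assays, function(a) {
    if (is.null(proteins[[a$protein]])) {
      stop("assay '", a$id, "': protein '", a$protein, "' not in FASTA")
    }
    req <- if (!is.null(a$required_mods)) {
      do.call(rbind, lapply(a$required_mods, function(m) {
        data.frame(position = m$position, name = m$name,
                   stringsAsFactors = FALSE)
      }))
    }
    ep <- epitope_spec(a$epitope$start, a$epitope$end, required_mods = req,
                       semantics = a$required_semantics %||% "all",
                       accession = a$accession %||% NA_character_)
    build_assay(
      id = a$id, protein_sequence = proteins[[a$protein]], epitope = ep,
      protease = a$protease %||% "trypsin",
      max_missed = a$max_missed %||% 2L,
      variable_mod = a$variable_mod,
      variable_residues = a$variable_residues,
      max_extra = a$max_extra %||% 0L,
      mutations = a$mutations, scheme = scheme,
      accession = a$accession %||% NA_character_,
      protein_name = a$protein, site = a$site %||% NA_character_
    )
  })
  compile_panel(assays, tol)
}

#' Write the compiled reference table of a panel
#'
#' Tab-separated reference table (assay, variant, sequence, mods, masses),
#' the serialised form of the panel's mass index.
#'
#' @param panel An [compile_panel()] result.
#' @param path Output file.
#' @export
write_panel_table <- function(panel, path) {
  stopifnot(inherits(panel, "assay_panel"))
  idx <- panel$index
  idx$mono_mass <- sprintf("%.6f", idx$mono_mass)
  idx$avg_mass <- sprintf("%.6f", idx$avg_mass)
  utils::write.table(idx, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compiled reference table
#'
#' @param path File written by [write_panel_table()].
#' @return data.frame mass index.
#' @export
read_panel_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$mono_mass <- as.numeric(tab$mono_mass)
  tab$avg_mass <- as.numeric(tab$avg_mass)
  tab
}

#' Write annotation matches as a tab-separated table
#'
#' @param annotation A [match_spot()] result.
#' @param path Output file.
#' @export
write_annotation <- function(annotation, path) {
  m <- annotation$matches
  if (nrow(m)) m <- cbind(spot = annotation$spot, m)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
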