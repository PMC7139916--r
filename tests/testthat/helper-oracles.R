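# Independent oracles used across the suite. These deliberately do not call
# package internals: masses come from elemental composition, digests from an
# exhaustive substring enumerator.

# atoms per residue: C, H, N, O, S (residue = amino acid minus water)
.ORACLE_FORMULA <- list(
  G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0)
)
.ATOM_MONO <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069, P = 30.97376151)
.ATOM_AVG <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994,
               S = 32.065, P = 30.973761)

# MH+ from summed atomic composition; nphospho adds HPO3 groups
oracle_mh <- function(sequence, nphospho = 0, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  tab <- if (kind == "mono") .ATOM_MONO else .ATOM_AVG
  counts <- Reduce(`+`, .ORACLE_FORMULA[strsplit(sequence, "")[[1]]])
  m <- sum(counts * tab[c("C", "H", "N", "O", "S")])
  m <- m + 2 * tab[["H"]] + tab[["O"]]                       # water
  m <- m + nphospho * (tab[["H"]] + tab[["P"]] + 3 * tab[["O"]])
  unname(m + 1.007276)                                       # proton
}

# straightforward per-position cleavage logic, written independently of the
# package's vectorised rule engine
oracle_cut_sites <- function(sequence, rule) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  out <- integer()
  for (i in seq_len(max(0L, n - 1L))) {
    cut <- switch(rule,
      trypsin = res[i] %in% c("K", "R") && res[i + 1] != "P",
      chymotrypsin = res[i] %in% c("F", "Y", "W", "L") && res[i + 1] != "P",
      argc = res[i] == "R" && res[i + 1] != "P",
      lysc = res[i] == "K" && res[i + 1] != "P",
      gluc = res[i] == "E" && res[i + 1] != "P",
      aspn = res[i + 1] == "D",
      stop("oracle does not know rule ", rule)
    )
    if (cut) out <- c(out, i)
  }
  out
}

# exhaustive digest: every substring is tested for valid boundaries and
# missed-cleavage count
oracle_digest <- function(sequence, rule, max_missed) {
  n <- nchar(sequence)
  is_cut <- rep(FALSE, n)
  is_cut[oracle_cut_sites(sequence, rule)] <- TRUE
  cum <- c(0L, cumsum(is_cut))              # cum[i + 1] = #sites <= i
  rows <- list()
  for (s in seq_len(n)) {
    if (!(s == 1L || is_cut[s - 1L])) next
    e <- s:n
    right_ok <- e == n | is_cut[e]
    internal <- cum[e] - cum[s]             # sites in [s, e - 1]
    keep <- e[right_ok & internal <= max_missed]
    if (length(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = keep, missed = cum[keep] - cum[s])
    }
  }
  out <- do.call(rbind, rows)
  out$sequence <- substring(sequence, out$start, out$end)
  out <- out[order(out$start, out$end),
             c("sequence", "start", "end", "missed")]
  rownames(out) <- NULL
  out
}

random_sequence <- function(len, residues = names(.ORACLE_FORMULA)) {
  paste(sample(residues, len, replace = TRUE), collapse = "")
}

# brute-force evaluation of the replicate detection rules, written as plain
# loops over the level table
oracle_lod_loq <- function(measurements, cv_limit = 30) {
  levels <- sort(unique(measurements$level_fmol[measurements$level_fmol > 0]))
  lod <- NA_real_
  loq <- NA_real_
  for (lv in levels) {
    rows <- measurements[measurements$level_fmol == lv, ]
    det <- sum(rows$detected)
    pass_det <- det > nrow(rows) / 2
    r <- rows$ratio[rows$detected & !is.na(rows$ratio)]
    cv <- if (length(r) >= 2) 100 * stats::sd(r) / mean(r) else NA
    if (pass_det && is.na(lod)) lod <- lv
    if (pass_det && !is.na(cv) && cv < cv_limit && is.na(loq)) loq <- lv
    if (!is.na(lod) && !is.na(loq)) break
  }
  list(lod = lod, loq = loq)
}

demo_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- system.file("extdata", "demo_panel.yaml", package = "maldipanel")
      cache <<- read_panel_config(cfg)
    }
    cache
  }
})

demo_proteins <- function() {
  read_fasta(system.file("extdata", "demo_proteins.fasta",
                         package = "maldipanel"))
}
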