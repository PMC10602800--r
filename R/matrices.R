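# Substitution score tables: the single-residue 20x20 matrix and the
# 400x400 pair-substitution matrix over ordered residue pairs.
#
# The 20x20 table is symmetric by definition and stored over the canonical
# NCBI alphabet order. The 400x400 table is indexed by 4-tuples (i,j,k,l):
# residue pair (i,j) in sequence A aligned against pair (k,l) in sequence B.
# The only identity imposed is scores(i,j,k,l) == scores(j,i,l,k) — reading
# the same physical event with the two endpoints swapped — which leaves room
# for directional substitution asymmetry (scores(i,j,k,l) may differ from
# scores(k,l,i,j)).

#' Construct a 20x20 substitution matrix object
#'
#' @param scores Numeric 20x20 matrix with dimnames over [aa_alphabet()]
#'   (any row/column order; reordered internally). Must be symmetric.
#' @param name Token naming the matrix.
#' @return Object of class `subst_matrix20`.
#' @export
subst_matrix20 <- function(scores, name = "custom") {
  ab <- aa_alphabet()
  if (!all(ab %in% rownames(scores)) || !all(ab %in% colnames(scores)))
    stopf("matrix must cover all 20 canonical amino acids")
  scores <- scores[ab, ab, drop = FALSE]
  if (any(!is.finite(scores))) stopf("non-finite matrix entries")
  if (!isTRUE(all.equal(scores, t(scores), tolerance = 1e-12))) {
    bad <- which(abs(scores - t(scores)) > 1e-9, arr.ind = TRUE)[1, ]
    stopf("asymmetric entries: (%s,%s) != (%s,%s)",
          ab[bad[1]], ab[bad[2]], ab[bad[2]], ab[bad[1]])
  }
  structure(list(name = name, alphabet = ab, scores = scores),
            class = "subst_matrix20")
}

#' @export
print.subst_matrix20 <- function(x, ...) {
  cat(sprintf("subst_matrix20 '%s' (range %g..%g)\n", x$name,
              min(x$scores), max(x$scores)))
  invisible(x)
}

# score for the unknown residue: minimum off-diagonal entry
m20_unknown_score <- function(m) {
  s <- m$scores
  diag(s) <- NA
  min(s, na.rm = TRUE)
}

#' Look up single-residue substitution scores
#'
#' Vectorized over `a`/`b`. Unknown (non-canonical) residues score the
#' matrix's minimum off-diagonal value.
#'
#' @param m A [subst_matrix20()].
#' @param a,b Character vectors of single residues.
#' @return Numeric vector of scores.
#' @export
m20_score <- function(m, a, b) {
  len <- max(length(a), length(b))
  ia <- rep_len(match(a, m$alphabet), len)
  ib <- rep_len(match(b, m$alphabet), len)
  out <- numeric(len)
  known <- !is.na(ia) & !is.na(ib)
  out[known] <- m$scores[cbind(ia[known], ib[known])]
  if (any(!known)) out[!known] <- m20_unknown_score(m)
  out
}

#' Parse an NCBI/EMBOSS-format substitution matrix
#'
#' Accepts the text layout distributed with BLAST and EMBOSS: `#` comment
#' lines, a header row of single-letter column labels, then one labelled row
#' per residue. Columns beyond the 20 canonical letters (B, Z, X, `*`, ...)
#' are parsed and dropped. Asymmetric entries are an error, not averaged.
#'
#' @param text Character scalar or vector of lines.
#' @param name Matrix name token.
#' @return A [subst_matrix20()].
#' @export
parse_matrix20 <- function(text, name = "matrix") {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stopf("not a matrix file: no header/data lines")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (!all(nchar(header) == 1L)) stopf("malformed matrix header row")
  rows <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != length(header) + 1L)
      stopf("matrix row '%s' has %d fields, expected %d",
            parts[1], length(parts) - 1L, length(header))
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(vals))) stopf("non-numeric entry in row '%s'", parts[1])
    rows[[parts[1]]] <- vals
  }
  m <- do.call(rbind, rows)
  colnames(m) <- header
  missing <- setdiff(aa_alphabet(), intersect(rownames(m), colnames(m)))
  if (length(missing))
    stopf("matrix is missing canonical letter(s): %s",
          paste(missing, collapse = ", "))
  m <- m[aa_alphabet(), aa_alphabet(), drop = FALSE]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12))) {
    bad <- which(abs(m - t(m)) > 1e-9, arr.ind = TRUE)[1, ]
    stopf("asymmetric matrix entries at (%s,%s)",
          aa_alphabet()[bad[1]], aa_alphabet()[bad[2]])
  }
  subst_matrix20(m, name = name)
}

#' Read a 20x20 matrix from a file or bundled name
#'
#' `name_or_path` may be a file path or the name of a bundled matrix
#' (`"BLOSUM62"`, `"EPAM250"`).
#'
#' @param name_or_path Path or bundled matrix name.
#' @return A [subst_matrix20()].
#' @export
read_matrix20 <- function(name_or_path) {
  path <- name_or_path
  if (!file.exists(path)) {
    bundled <- system.file("extdata", name_or_path, package = "coralign")
    if (!nzchar(bundled)) stopf("matrix file not found: %s", name_or_path)
    path <- bundled
  }
  parse_matrix20(readLines(path, warn = FALSE),
                 name = sub("\\.[^.]*$", "", basename(name_or_path)))
}

#' Write a 20x20 matrix in NCBI text layout
#'
#' @param m A [subst_matrix20()].
#' @param path Output path; `NULL` returns the lines.
#' @param digits Significant digits for non-integer entries.
#' @return Lines (invisibly when written to a file).
#' @export
write_matrix20 <- function(m, path = NULL, digits = 10) {
  ab <- m$alphabet
  fmt <- function(v) {
    if (all(abs(v - round(v)) < 1e-12)) sprintf("%d", as.integer(round(v)))
    else sprintf("%.*g", digits, v)
  }
  cells <- matrix(fmt(m$scores), 20, 20)
  wid <- max(nchar(cells)) + 1L
  lines <- c(sprintf("# %s", m$name),
             paste0("  ", paste(formatC(ab, width = wid), collapse = "")),
             vapply(seq_len(20), function(r) {
               paste0(ab[r], " ",
                      paste(formatC(cells[r, ], width = wid), collapse = ""))
             }, character(1)))
  if (is.null(path)) return(lines)
  write_atomic(lines, path)
  invisible(lines)
}

# ---------------------------------------------------------------------------
# 400x400 pair-substitution matrix

pair_labels <- function() {
  ab <- aa_alphabet()
  as.vector(t(outer(ab, ab, paste0)))  # "AA","AR",... lexicographic in (i,j)
}

# swap both pairs: "XY","ZW" -> "YX","WZ"
swap_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))

#' Construct a 400x400 pair-substitution matrix object
#'
#' Rows index the sequence-A residue pair, columns the sequence-B pair, both
#' as two-letter strings over the canonical alphabet. The simultaneous-swap
#' identity `scores["XY","ZW"] == scores["YX","WZ"]` is required.
#'
#' @param scores Numeric 400x400 matrix with pair-string dimnames.
#' @param name Token.
#' @return Object of class `pair_matrix400`.
#' @export
pair_matrix400 <- function(scores, name = "custom") {
  lab <- pair_labels()
  if (!all(lab %in% rownames(scores)) || !all(lab %in% colnames(scores)))
    stopf("pair matrix must cover all 400 residue pairs on both axes")
  scores <- scores[lab, lab, drop = FALSE]
  if (any(!is.finite(scores))) stopf("non-finite pair-matrix entries")
  sw <- scores[swap_pair(lab), swap_pair(lab)]
  if (max(abs(scores - sw)) > 1e-9)
    stopf("pair matrix violates the (i,j,k,l)==(j,i,l,k) swap identity")
  structure(list(name = name, scores = scores), class = "pair_matrix400")
}

#' @export
print.pair_matrix400 <- function(x, ...) {
  cat(sprintf("pair_matrix400 '%s' (range %g..%g)\n", x$name,
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Look up pair-substitution scores
#'
#' Vectorized: score for residue pair (`ai`,`aj`) in A aligned to (`bk`,`bl`)
#' in B. Any tuple containing an unknown residue scores the matrix minimum.
#'
#' @param m A [pair_matrix400()].
#' @param ai,aj,bk,bl Character vectors of single residues.
#' @return Numeric vector.
#' @export
m400_score <- function(m, ai, aj, bk, bl) {
  len <- max(length(ai), length(aj), length(bk), length(bl))
  ra <- rep_len(match(paste0(ai, aj), rownames(m$scores)), len)
  cb <- rep_len(match(paste0(bk, bl), colnames(m$scores)), len)
  out <- numeric(len)
  known <- !is.na(ra) & !is.na(cb)
  out[known] <- m$scores[cbind(ra[known], cb[known])]
  if (any(!known)) out[!known] <- min(m$scores)
  out
}

#' Parse a 400x400 pair matrix from its TSV representation
#'
#' Format: `#` comments; an optional `default=<real>` line supplying the
#' value for unlisted tuples; data lines `<XY> <ZW> <score>` where `XY` is
#' the sequence-A residue pair and `ZW` the sequence-B pair. If only one of
#' the two swap-equivalent orientations is present the other is filled; if
#' both are present with different values it is an error.
#'
#' @param text Character scalar or vector of lines.
#' @param name Token.
#' @return A [pair_matrix400()].
#' @export
parse_matrix400 <- function(text, name = "matrix400") {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  default <- NA_real_
  isdef <- grepl("^default\\s*=", lines)
  if (any(isdef)) {
    default <- as.numeric(sub("^default\\s*=\\s*", "", lines[isdef][1]))
    if (is.na(default)) stopf("malformed default= header")
    lines <- lines[!isdef]
  }
  lab <- pair_labels()
  scores <- matrix(NA_real_, 400, 400, dimnames = list(lab, lab))
  if (length(lines)) {
    parts <- data.table::tstrsplit(lines, "\\s+")
    if (length(parts) != 3L) stopf("malformed pair-matrix data line(s)")
    key_a <- toupper(parts[[1]]); key_b <- toupper(parts[[2]])
    val <- suppressWarnings(as.numeric(parts[[3]]))
    ok <- key_a %in% lab & key_b %in% lab & !is.na(val)
    if (any(!ok)) stopf("malformed tuple key or value: '%s %s %s'",
                        key_a[!ok][1], key_b[!ok][1], parts[[3]][!ok][1])
    idx <- cbind(match(key_a, lab), match(key_b, lab))
    dup <- duplicated(idx)
    if (any(dup)) {
      first <- !dup
      scores[idx[first, , drop = FALSE]] <- val[first]
      conflict <- dup & abs(scores[idx] - val) > 1e-12
      if (any(conflict))
        stopf("conflicting duplicate entry for %s %s",
              key_a[conflict][1], key_b[conflict][1])
    } else {
      scores[idx] <- val
    }
  }
  # enforce / fill the swap identity
  sw <- scores[swap_pair(lab), swap_pair(lab)]
  both <- !is.na(scores) & !is.na(sw)
  if (any(abs(scores[both] - sw[both]) > 1e-9)) {
    bad <- which(!is.na(scores) & !is.na(sw) & abs(scores - sw) > 1e-9,
                 arr.ind = TRUE)[1, ]
    stopf("conflicting swap-equivalent entries: %s %s vs %s %s",
          lab[bad[1]], lab[bad[2]], swap_pair(lab[bad[1]]),
          swap_pair(lab[bad[2]]))
  }
  fill <- is.na(scores) & !is.na(sw)
  scores[fill] <- sw[fill]
  if (anyNA(scores)) {
    if (is.na(default))
      stopf("missing tuples and no default= header (first missing: %s %s)",
            lab[which(is.na(scores), arr.ind = TRUE)[1, 1]],
            lab[which(is.na(scores), arr.ind = TRUE)[1, 2]])
    scores[is.na(scores)] <- default
  }
  pair_matrix400(scores, name = name)
}

#' Read a 400x400 pair matrix from a file
#' @param path File in the TSV format of [parse_matrix400()].
#' @return A [pair_matrix400()].
#' @export
read_matrix400 <- function(path) {
  if (!file.exists(path)) stopf("pair matrix file not found: %s", path)
  parse_matrix400(readLines(path, warn = FALSE),
                  name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a 400x400 pair matrix (all 160,000 tuples, lexicographic)
#'
#' @param m A [pair_matrix400()].
#' @param path Output path; `NULL` returns the lines.
#' @return Lines (invisibly when written to a file).
#' @export
write_matrix400 <- function(m, path = NULL) {
  lab <- pair_labels()
  grid <- expand.grid(b = lab, a = lab, stringsAsFactors = FALSE)
  vals <- as.vector(t(m$scores[lab, lab]))
  lines <- c(sprintf("# %s", m$name),
             sprintf("%s %s %.10g", grid$a, grid$b, vals))
  if (is.null(path)) return(lines)
  write_atomic(lines, path)
  invisible(lines)
}

#' Alignment scoring parameters
#'
#' @param w1 Weight of the single-residue score (default 1.0).
#' @param w2 Relative weight of the pair-substitution score, in \[0, 0.9\]
#'   (default 0.1; 0 disables the pair term).
#' @param gap_open Gap opening penalty p (the first residue of a gap costs
#'   `p + q`).
#' @param gap_extend Gap extension penalty q per further gapped residue.
#' @param window Sliding half-window W for pair-partner probing.
#' @param free_end_gaps If `TRUE`, leading and trailing gaps are free
#'   (semi-global alignment).
#' @return Object of class `dp_params`.
#' @export
dp_params <- function(w1 = 1.0, w2 = 0.1, gap_open = 10, gap_extend = 0.5,
                      window = 10L, free_end_gaps = FALSE) {
  if (w1 < 0) stopf("w1 must be >= 0")
  if (w2 < 0 || w2 > 0.9) stopf("w2 must be in [0, 0.9]")
  if (gap_open < gap_extend || gap_extend < 0)
    stopf("require gap_open >= gap_extend >= 0")
  if (window < 0) stopf("window must be >= 0")
  structure(list(w1 = w1, w2 = w2, gap_open = gap_open,
                 gap_extend = gap_extend, window = as.integer(window),
                 free_end_gaps = isTRUE(free_end_gaps)),
            class = "dp_params")
}
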