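# Structural congruence evaluation: optimal rigid superposition (Kabsch) and
# the length-normalized RMSD of an alignment's matched columns.
#
# The congruence statistic divides the superposed RMSD over matched columns
# by the number of matched columns, so that sparse, fragmentary alignments
# of the right regions score better than long sloppy ones.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of point set `Y` onto `X` via SVD of the
#' cross-covariance, with the determinant correction that guarantees a
#' proper rotation.
#'
#' @param X,Y Numeric n x 3 matrices, n >= 3, finite, row-paired.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the fit is `Y %*% rotation + translation`), and `rmsd`. For degenerate
#'   (e.g. collinear) point sets the RMSD is still valid but the rotation
#'   need not be unique.
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != 3L || ncol(Y) != 3L)
    stopf("X and Y must be n x 3 with equal n")
  if (nrow(X) < 3L) stopf("need at least 3 points")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stopf("non-finite coordinates")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Yc, Xc)            # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)       # Y %*% t(R)? define mapping below
  rot <- t(R)                       # so that Yc %*% rot approximates Xc
  fit <- Yc %*% rot
  rmsd <- sqrt(mean(rowSums((fit - Xc)^2)))
  list(rotation = rot, translation = as.numeric(cx - cy %*% rot),
       rmsd = rmsd)
}

#' Normalized RMSD of an alignment against two structures
#'
#' Collects representative-atom coordinates at MATCH columns where both
#' sides are present, superposes them optimally, and divides the RMSD by
#' the number of such columns.
#'
#' @param result An [alignment_result()].
#' @param coordsA,coordsB Numeric length(A) x 3 / length(B) x 3 coordinate
#'   matrices (rows with `NA` mark unresolved residues).
#' @return Scalar: `rmsd / n_matched`.
#' @export
normalized_aligned_rmsd <- function(result, coordsA, coordsB) {
  ops <- result$ops
  mrows <- which(ops$op == "M")
  ia <- ops$i[mrows] + 1L
  ib <- ops$k[mrows] + 1L
  okA <- !apply(is.na(coordsA[ia, , drop = FALSE]), 1, any)
  okB <- !apply(is.na(coordsB[ib, , drop = FALSE]), 1, any)
  use <- okA & okB
  if (sum(use) < 3L)
    stopf("fewer than 3 matched columns with coordinates on both sides")
  sup <- kabsch_superpose(coordsA[ia[use], , drop = FALSE],
                          coordsB[ib[use], , drop = FALSE])
  sup$rmsd / sum(use)
}

#' Read representative-atom coordinates from a PDB file
#'
#' Minimal fixed-column PDB reader: first model only, `ATOM` records,
#' optional chain filter. `atom = "CB"` falls back to CA for glycine (and
#' any residue lacking a CB atom). Returns one row per residue in order of
#' appearance; alternate locations other than ' '/'A' are skipped.
#'
#' @param path PDB file path.
#' @param chain Single chain identifier or `NULL` for the first chain seen.
#' @param atom `"CA"` or `"CB"` (CB with CA fallback).
#' @return Numeric n x 3 matrix with residue numbers as rownames.
#' @export
read_pdb_coords <- function(path, chain = NULL, atom = c("CA", "CB")) {
  atom <- match.arg(atom)
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  rec <- lines[startsWith(lines, "ATOM")]
  if (!length(rec)) stopf("no ATOM records in %s", path)
  fld <- function(x, a, b) trimws(substr(x, a, b))
  aname <- fld(rec, 13, 16)
  alt <- substr(rec, 17, 17)
  ch <- substr(rec, 22, 22)
  resno <- fld(rec, 23, 27)   # includes insertion code
  keep <- alt %in% c(" ", "A", "")
  rec <- rec[keep]; aname <- aname[keep]; ch <- ch[keep]; resno <- resno[keep]
  if (is.null(chain)) chain <- ch[1]
  sel <- ch == chain
  if (!any(sel)) stopf("chain '%s' not found in %s", chain, path)
  rec <- rec[sel]; aname <- aname[sel]; resno <- resno[sel]
  res_order <- unique(resno)
  want <- if (atom == "CA") "CA" else "CB"
  coords <- t(vapply(res_order, function(rn) {
    rows <- which(resno == rn & aname == want)
    if (!length(rows) && atom == "CB")
      rows <- which(resno == rn & aname == "CA")
    if (!length(rows)) return(c(NA_real_, NA_real_, NA_real_))
    r <- rec[rows[1]]
    c(as.numeric(substr(r, 31, 38)), as.numeric(substr(r, 39, 46)),
      as.numeric(substr(r, 47, 54)))
  }, numeric(3)))
  rownames(coords) <- res_order
  coords
}

#' Write a minimal CA-trace PDB file
#'
#' Companion writer for synthetic structures; one `ATOM` CA record per
#' present residue, chain A, residue type ALA.
#'
#' @param coords Numeric n x 3 matrix (`NA` rows skipped).
#' @param path Output path.
#' @export
write_pdb_ca <- function(coords, path) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(coords))) {
    if (any(is.na(coords[i, ]))) next
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, i, coords[i, 1], coords[i, 2], coords[i, 3]))
  }
  write_atomic(c(lines, "END"), path)
}
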