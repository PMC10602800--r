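# Position-by-position correlation / contact maps and the selection of the
# correlated pairs that drive pair-substitution scoring.
#
# A corr_map is symmetric with a zero diagonal. Maps are produced externally
# (e.g. by a protein language model) or synthetically; asymmetric dense input
# is symmetrized by averaging because the downstream use is undirected.

#' Construct a correlation/contact map
#'
#' @param values Square numeric matrix; symmetrized by averaging, diagonal
#'   forced to zero.
#' @param kind `"correlation"` or `"contact"` (contact maps must be 0/1).
#' @return Object of class `corr_map` with fields `n`, `values`, `kind`.
#' @export
corr_map <- function(values, kind = c("correlation", "contact")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stopf("map must be a square matrix")
  if (any(!is.finite(values))) stopf("non-finite map entries")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (kind == "contact" && !all(values %in% c(0, 1)))
    stopf("contact map values must be 0/1")
  structure(list(n = nrow(values), values = unname(values), kind = kind),
            class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  cat(sprintf("corr_map (%s) %dx%d, %d nonzero upper-triangle entries\n",
              x$kind, x$n, x$n, sum(x$values[upper.tri(x$values)] != 0)))
  invisible(x)
}

#' Load a correlation map from a text file
#'
#' Dense format: `n` whitespace-separated rows of `n` numbers. Sparse
#' format: triplet lines `i j value` with 1-based indices; entries are
#' mirrored. Detected by column count.
#'
#' @param path Input file.
#' @param expected_n Required map dimension (the sequence length).
#' @param kind Map kind, as in [corr_map()].
#' @return A [corr_map()].
#' @export
load_corrmap <- function(path, expected_n, kind = "correlation") {
  if (!file.exists(path)) stopf("map file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stopf("empty map file: %s", path)
  fields <- strsplit(lines, "\\s+")
  ncol1 <- length(fields[[1]])
  if (ncol1 == 3L && length(lines) != expected_n) {
    # sparse triplets
    vals <- matrix(0, expected_n, expected_n)
    for (f in fields) {
      if (length(f) != 3L) stopf("malformed sparse triplet line")
      i <- suppressWarnings(as.integer(f[1]))
      j <- suppressWarnings(as.integer(f[2]))
      v <- suppressWarnings(as.numeric(f[3]))
      if (is.na(i) || is.na(j) || is.na(v)) stopf("non-numeric triplet entry")
      if (i < 1 || j < 1 || i > expected_n || j > expected_n)
        stopf("triplet index (%d,%d) outside 1..%d", i, j, expected_n)
      vals[i, j] <- v; vals[j, i] <- v
    }
    return(corr_map(vals, kind = kind))
  }
  nums <- suppressWarnings(lapply(fields, as.numeric))
  if (any(vapply(nums, anyNA, logical(1)))) stopf("non-numeric map entry")
  if (length(nums) != expected_n ||
      any(lengths(nums) != expected_n))
    stopf("dense map is %dx%d, expected %dx%d", length(nums),
          lengths(nums)[1], expected_n, expected_n)
  corr_map(do.call(rbind, nums), kind = kind)
}

#' Write a map as sparse 1-based triplets (upper triangle)
#' @param map A [corr_map()].
#' @param path Output path; `NULL` returns lines.
#' @return Lines (invisibly when written to file).
#' @export
write_corrmap_sparse <- function(map, path = NULL) {
  idx <- which(upper.tri(map$values) & map$values != 0, arr.ind = TRUE)
  lines <- sprintf("%d %d %.10g", idx[, 1], idx[, 2],
                   map$values[idx])
  if (is.null(path)) return(lines)
  write_atomic(lines, path)
  invisible(lines)
}

#' Min-max rescale a correlation map to [0, 1]
#'
#' Applied before cutoff-based pair selection when maps come from arbitrary
#' providers, so that a single cutoff scale is meaningful. Constant maps
#' rescale to all zeros.
#'
#' @param map A [corr_map()].
#' @return Rescaled [corr_map()].
#' @export
corrmap_rescale <- function(map) {
  v <- map$values
  off <- v[row(v) != col(v)]
  rng <- range(off)
  if (diff(rng) == 0) v[] <- 0
  else v <- (v - rng[1]) / diff(rng)
  diag(v) <- 0
  corr_map(pmax(v, 0), kind = map$kind)
}

#' Select correlated position pairs from a map
#'
#' Keeps pairs `(i, j)` (0-based, `i < j`) with `values(i,j) >= cutoff`,
#' strictly positive value, and sequence separation `j - i >= min_separation`.
#' If a position participates in more than `max_partners` surviving pairs,
#' only its `max_partners` highest-valued pairs are kept (ties broken toward
#' the smaller partner index); a pair must survive the cap at both endpoints.
#'
#' @param map A [corr_map()].
#' @param cutoff Minimum map value.
#' @param min_separation Minimum `j - i` (default 3).
#' @param max_partners Per-position partner cap (default 16; `Inf` for
#'   unlimited).
#' @return Object of class `selected_pairs`: data frame `i`, `j`, `weight`
#'   plus a `source` attribute.
#' @export
select_pairs <- function(map, cutoff = 0.5, min_separation = 3L,
                         max_partners = 16L) {
  if (min_separation < 1L) stopf("min_separation must be >= 1")
  if (max_partners < 1L) stopf("max_partners must be >= 1")
  v <- map$values
  idx <- which(upper.tri(v), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  keep <- v[idx] >= cutoff & v[idx] > 0 & sep >= min_separation
  df <- data.frame(i = idx[keep, 1] - 1L, j = idx[keep, 2] - 1L,
                   weight = v[idx[keep, , drop = FALSE]])
  if (nrow(df) && is.finite(max_partners)) {
    # deterministic order: weight desc, then smaller partner span
    repeat {
      cnt <- table(factor(c(df$i, df$j), levels = 0:(map$n - 1)))
      over <- as.integer(names(cnt)[cnt > max_partners])
      if (!length(over)) break
      p <- over[1]
      rows <- which(df$i == p | df$j == p)
      partner <- ifelse(df$i[rows] == p, df$j[rows], df$i[rows])
      ord <- rows[order(-df$weight[rows], partner)]
      df <- df[-ord[-seq_len(max_partners)], , drop = FALSE]
    }
  }
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("selected_pairs", "data.frame"),
            source = map$kind, n = map$n)
}

#' Derive a binary contact map from representative-atom coordinates
#'
#' Contact: Euclidean distance at most `distance_cutoff` Angstrom and index
#' separation at least `min_separation`. Rows of `coords` with any `NA`
#' denote absent residues and form no contacts.
#'
#' @param coords Numeric n x 3 matrix of per-residue representative-atom
#'   coordinates (conventionally C-beta with C-alpha fallback for glycine).
#' @param distance_cutoff Distance threshold in Angstrom (default 8).
#' @param min_separation Minimum index separation (default 5).
#' @return A [corr_map()] of kind `"contact"`.
#' @export
contacts_from_coords <- function(coords, distance_cutoff = 8.0,
                                 min_separation = 5L) {
  if (!is.matrix(coords) || ncol(coords) != 3L)
    stopf("coords must be an n x 3 matrix")
  present <- !apply(is.na(coords), 1, any)
  if (sum(present) < 2L) stopf("fewer than 2 present residues")
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  d[is.na(d)] <- Inf
  sep <- abs(row(d) - col(d))
  m <- (d <= distance_cutoff & sep >= min_separation) * 1
  corr_map(m, kind = "contact")
}
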