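# Deterministic synthetic-data generators. Every generator takes an
# explicit seed and is a pure function of its arguments; nothing is
# downloaded and no global RNG state is left disturbed.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random protein sequence
#'
#' @param length Number of residues.
#' @param seed RNG seed.
#' @param alphabet Residue alphabet to draw from (default the 20 canonical
#'   letters, uniform).
#' @param id Record identifier.
#' @return A [protein_seq()].
#' @export
random_protein <- function(length, seed, alphabet = aa_alphabet(),
                           id = sprintf("rnd%d", seed)) {
  with_seed(seed, {
    protein_seq(id, paste(sample(alphabet, length, replace = TRUE),
                          collapse = ""))
  })
}

#' Generate an MSA with planted covarying column pairs
#'
#' Rows are drawn i.i.d. from `background` (optionally as mutated copies of
#' a family consensus when `mutation_rate < 1`). At each planted pair
#' `(i, j, perm)`, with probability `coupling` the column-j letter of a row
#' is deterministically the permutation image of its column-i letter,
#' otherwise it stays independent. This emulates the strongly co-substituting
#' position pairs that coevolution statistics are designed to detect.
#'
#' @param depth Number of rows.
#' @param width Number of columns.
#' @param planted_pairs List of `list(i =, j =, perm =)` with 0-based,
#'   disjoint column indices and `perm` a named character vector mapping
#'   each letter to its partner letter (default: a fixed cyclic shift).
#' @param coupling Probability in \[0, 1\] that the planted rule fires.
#' @param background Composition over [aa_alphabet()] (default uniform).
#' @param mutation_rate Probability a cell is redrawn from the background
#'   instead of copying the consensus (1 = i.i.d. rows, the default).
#' @param seed RNG seed.
#' @return An [msa()].
#' @export
make_covarying_msa <- function(depth, width, planted_pairs = list(),
                               coupling = 1.0, background = NULL,
                               mutation_rate = 1.0, seed = 1L) {
  ab <- aa_alphabet()
  if (is.null(background)) background <- rep(1 / 20, 20)
  cols <- unlist(lapply(planted_pairs, function(p) c(p$i, p$j)))
  if (anyDuplicated(cols)) stopf("planted pairs must be disjoint")
  if (length(cols) && (min(cols) < 0 || max(cols) >= width))
    stopf("planted pair column outside 0..%d", width - 1L)
  with_seed(seed, {
    mat <- matrix(sample(ab, depth * width, replace = TRUE,
                         prob = background), depth, width)
    if (mutation_rate < 1) {
      consensus <- sample(ab, width, replace = TRUE, prob = background)
      keep <- matrix(stats::runif(depth * width) >= mutation_rate,
                     depth, width)
      mat[keep] <- consensus[col(mat)[keep]]
    }
    for (p in planted_pairs) {
      perm <- p$perm %||% stats::setNames(ab[c(2:20, 1)], ab)
      fire <- stats::runif(depth) < coupling
      mat[fire, p$j + 1L] <- perm[mat[fire, p$i + 1L]]
    }
    msa(sprintf("row%03d", seq_len(depth)),
        apply(mat, 1, paste, collapse = ""))
  })
}

#' Ideal-geometry toy CA trace
#'
#' `"helix"`: alpha-helical parameters (radius 2.3 A, rise 1.5 A per
#' residue, 100 degrees per turn step), giving consecutive CA-CA distances
#' of ~3.8 A. `"hairpin"`: two antiparallel strands with 3.8 A CA spacing,
#' 4.8 A apart, so cross-strand residues are in contact at an 8 A cutoff.
#' Coordinates are deterministic; `jitter` adds seeded Gaussian noise.
#'
#' @param length Number of residues.
#' @param fold `"helix"` or `"hairpin"`.
#' @param seed Seed (used only when `jitter > 0`).
#' @param jitter Standard deviation (A) of optional coordinate noise.
#' @return Numeric length x 3 coordinate matrix.
#' @export
make_toy_structure <- function(length, fold = c("helix", "hairpin"),
                               seed = 1L, jitter = 0) {
  fold <- match.arg(fold)
  i <- seq_len(length) - 1L
  if (fold == "helix") {
    ang <- i * 100 * pi / 180
    coords <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  } else {
    half <- ceiling(length / 2)
    x <- ifelse(i < half, 0, 4.8)
    z <- ifelse(i < half, i * 3.8, (length - 1L - i) * 3.8)
    coords <- cbind(x, 0, z)
  }
  if (jitter > 0) {
    coords <- coords + with_seed(seed, matrix(stats::rnorm(3 * length,
                                                           sd = jitter),
                                              length, 3))
  }
  unname(coords)
}

#' Random symmetric correlation map
#'
#' Off-diagonal entries at separation `>= min_separation` are nonzero with
#' the given density, with values uniform in (0, 1]; everything else is 0.
#'
#' @param n Map dimension.
#' @param density Fraction of eligible pairs that are nonzero.
#' @param seed RNG seed.
#' @param min_separation Minimum index separation of nonzero entries.
#' @return A [corr_map()].
#' @export
make_random_corrmap <- function(n, density, seed = 1L, min_separation = 3L) {
  with_seed(seed, {
    v <- matrix(0, n, n)
    idx <- which(upper.tri(v) & (col(v) - row(v)) >= min_separation,
                 arr.ind = TRUE)
    if (nrow(idx)) {
      on <- stats::runif(nrow(idx)) < density
      v[idx[on, , drop = FALSE]] <- stats::runif(sum(on), min = 1e-6, max = 1)
    }
    corr_map(v + t(v))
  })
}

#' Random per-residue embedding matrix
#'
#' @param n Number of residues (rows).
#' @param dim Embedding dimension (columns).
#' @param seed RNG seed.
#' @return Numeric n x dim matrix of standard normals.
#' @export
make_random_embeddings <- function(n, dim, seed = 1L) {
  with_seed(seed, matrix(stats::rnorm(n * dim), n, dim))
}
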