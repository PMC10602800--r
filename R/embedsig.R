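# Fixed-size embedding signatures for homolog-closeness gating.
#
# Per-residue embedding matrices (N residues x D dimensions) from a protein
# language model are compressed to fixed shapes by 2D discrete cosine
# transform truncation: orthonormal DCT-II of the input, keep the top-left
# low-frequency block, orthonormal inverse DCT at the target size, then
# rescale by sqrt((tr*tc)/(N*D)) so that a constant input stays constant.
# The conventional signature keeps one deep layer at 5 x 44 and one
# mid-depth layer at 3 x 85; the distance between two signatures is the sum
# of absolute element differences (L1), computed on uint8-quantized blocks
# by default. The distance gates the correlation-map cutoff and the pair-
# matrix weight w2: close homologs get more pair-term weight.

# orthonormal DCT-II basis matrix (k x n entries)
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  m <- outer(k, 0:(n - 1), function(kk, nn) cos(pi * (nn + 0.5) * kk / n))
  m * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

#' Compress a matrix via 2D DCT truncation
#'
#' @param x Numeric N x D matrix with `N >= target_rows`,
#'   `D >= target_cols`.
#' @param target_rows,target_cols Output shape.
#' @return `target_rows x target_cols` numeric matrix.
#' @export
compress_embedding <- function(x, target_rows, target_cols) {
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < target_rows || d < target_cols)
    stopf("input %dx%d smaller than target %dx%d", n, d,
          target_rows, target_cols)
  Cn <- dct_matrix(n); Cd <- dct_matrix(d)
  coef <- Cn %*% x %*% t(Cd)
  block <- coef[seq_len(target_rows), seq_len(target_cols), drop = FALSE]
  Ctr <- dct_matrix(target_rows); Ctc <- dct_matrix(target_cols)
  out <- t(Ctr) %*% block %*% Ctc
  out * sqrt((target_rows * target_cols) / (n * d))
}

#' Quantize a signature block to integers in [0, 255]
#'
#' Min-max affine map to the uint8 range, rounded half-up; a constant block
#' maps to all 128.
#'
#' @param block Numeric matrix with finite entries.
#' @return Integer matrix with values in 0..255.
#' @export
quantize <- function(block) {
  if (any(!is.finite(block))) stopf("non-finite entries in signature block")
  rng <- range(block)
  if (diff(rng) == 0) {
    out <- block; out[] <- 128L
    return(out)
  }
  out <- round_half_up((block - rng[1]) / diff(rng) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Build an embedding signature from two layer matrices
#'
#' @param layer_deep N x D matrix for the deep layer (compressed to 5 x 44).
#' @param layer_mid N x D matrix for the mid layer (compressed to 3 x 85).
#' @param quantized Quantize both blocks to uint8 (default `TRUE`).
#' @return Object of class `embed_signature` with fields `block_deep`
#'   (5 x 44), `block_mid` (3 x 85), `quantized`.
#' @export
embed_signature <- function(layer_deep, layer_mid, quantized = TRUE) {
  bd <- compress_embedding(layer_deep, 5L, 44L)
  bm <- compress_embedding(layer_mid, 3L, 85L)
  if (quantized) { bd <- quantize(bd); bm <- quantize(bm) }
  structure(list(block_deep = bd, block_mid = bm, quantized = quantized),
            class = "embed_signature")
}

#' @export
print.embed_signature <- function(x, ...) {
  cat(sprintf("embed_signature: 5x44 + 3x85 blocks (%s)\n",
              if (x$quantized) "quantized uint8" else "float"))
  invisible(x)
}

#' L1 distance between two embedding signatures
#'
#' @param sigA,sigB [embed_signature()] objects of matching shape and
#'   quantization state.
#' @return Nonnegative scalar: sum of absolute element differences over both
#'   blocks.
#' @export
embedding_distance <- function(sigA, sigB) {
  if (!identical(dim(sigA$block_deep), dim(sigB$block_deep)) ||
      !identical(dim(sigA$block_mid), dim(sigB$block_mid)))
    stopf("signature shapes differ")
  if (!identical(sigA$quantized, sigB$quantized))
    stopf("signature quantization states differ")
  sum(abs(sigA$block_deep - sigB$block_deep)) +
    sum(abs(sigA$block_mid - sigB$block_mid))
}

#' Read a dense whitespace-separated embedding matrix file
#' @param path Text file: one row per residue, one column per dimension.
#' @return Numeric matrix.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stopf("embedding file not found: %s", path)
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

# ---------------------------------------------------------------------------
# gating

#' Build a gate schedule
#'
#' A gate schedule maps an embedding distance to the correlation-map cutoff
#' and pair-matrix weight w2 used for alignment. Rows are
#' `(distance_upper_bound, corr_cutoff, w2)`; the terminal row (bound `Inf`)
#' applies beyond the last bound. The schedule must be monotone: w2
#' non-increasing and cutoff non-decreasing with distance.
#'
#' @param bounds Strictly increasing numeric vector of distance upper
#'   bounds; the last entry may be `Inf` (appended if absent, reusing the
#'   last row's values).
#' @param corr_cutoff Cutoffs per row (on the min-max rescaled map scale).
#' @param w2 Pair-term weights per row, each in \[0, 0.9\].
#' @return Object of class `gate_schedule`.
#' @export
gate_schedule <- function(bounds, corr_cutoff, w2) {
  stopifnot(length(bounds) == length(corr_cutoff),
            length(bounds) == length(w2))
  if (!length(bounds)) stopf("empty gate schedule")
  if (any(diff(bounds) <= 0)) stopf("schedule bounds must strictly increase")
  if (any(w2 < 0 | w2 > 0.9)) stopf("schedule w2 values must lie in [0, 0.9]")
  if (any(diff(w2) > 0)) stopf("schedule w2 must be non-increasing with distance")
  if (any(diff(corr_cutoff) < 0))
    stopf("schedule corr_cutoff must be non-decreasing with distance")
  if (is.finite(bounds[length(bounds)])) {
    bounds <- c(bounds, Inf)
    corr_cutoff <- c(corr_cutoff, corr_cutoff[length(corr_cutoff)])
    w2 <- c(w2, w2[length(w2)])
  }
  structure(data.frame(bound = bounds, corr_cutoff = corr_cutoff, w2 = w2),
            class = c("gate_schedule", "data.frame"))
}

#' Default gate schedule
#'
#' Close homologs (distance at most 20% of the maximum possible signature
#' distance) align with cutoff 0.3 and the default pair weight w2 = 0.1;
#' intermediate pairs (at most 50%) with cutoff 0.5 and w2 = 0.05; anything
#' farther disables the pair term (cutoff 1.1 selects no pairs, w2 = 0) so
#' the single-residue matrix is the sole score. The bounds are this
#' package's convention, configurable and not externally validated.
#'
#' @param quantized If `TRUE` (default) the distance scale is uint8-based:
#'   maximum distance 255 per cell over the 475 signature cells.
#' @param d_max Override for the maximum possible distance.
#' @return A [gate_schedule()].
#' @export
default_gate_schedule <- function(quantized = TRUE,
                                  d_max = if (quantized) 255 * 475 else 475) {
  gate_schedule(bounds = c(0.20 * d_max, 0.50 * d_max, Inf),
                corr_cutoff = c(0.3, 0.5, 1.1),
                w2 = c(0.1, 0.05, 0.0))
}

#' Gate alignment parameters by embedding distance
#'
#' @param distance Nonnegative embedding distance.
#' @param schedule A [gate_schedule()].
#' @return List with `corr_cutoff` and `w2` from the first row whose bound
#'   exceeds (or equals) the distance.
#' @export
gate_parameters <- function(distance, schedule = default_gate_schedule()) {
  if (!nrow(schedule)) stopf("empty gate schedule")
  row <- which(distance <= schedule$bound)[1]
  if (is.na(row)) row <- nrow(schedule)
  list(corr_cutoff = schedule$corr_cutoff[row], w2 = schedule$w2[row])
}
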