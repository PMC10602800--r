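# Core dynamic-programming global aligner with affine gaps and an optional
# correlated-pair bonus term.
#
# Cell score: S(i,k) = w1 * m20(A[i], B[k]) + w2 * pair_bonus(i, k).
# Affine gaps: a gap run of length L costs p + L*q (first gapped residue
# p + q, each further residue q). Pair bonuses attach to match states only.
#
# The pair bonus probes, for every selected partner j of position i in
# sequence A, a sliding window of candidate positions l around the diagonal
# projection l = k + (j - i) in sequence B, takes the best pair-matrix score
# over the window, and combines partners by mean (default) or sum. Because
# the bonus depends only on (i, k), the recurrence stays Markovian and the
# usual Gotoh optimality argument applies unchanged.

#' Pair-bonus evaluation context
#'
#' @param pairs A [select_pairs()] result over sequence A positions.
#' @param matrix400 A [pair_matrix400()].
#' @param window Half-window W >= 0 for partner probing (candidate positions
#'   `l` in `k + (j-i) +/- W`).
#' @param normalization `"mean"` (default; keeps the bonus on the scale of a
#'   single pair score regardless of partner count) or `"sum"`.
#' @param endpoint_scale Multiplier applied to every bonus; `1` lets each
#'   endpoint of a correlated pair contribute its own bonus, `0.5` halves
#'   that so a pair contributes once in total across its two endpoints.
#' @return Object of class `pair_bonus_ctx`.
#' @export
pair_bonus_ctx <- function(pairs, matrix400, window = 10L,
                           normalization = c("mean", "sum"),
                           endpoint_scale = 1.0) {
  normalization <- match.arg(normalization)
  if (window < 0L) stopf("window must be >= 0")
  structure(list(pairs = pairs, matrix400 = matrix400,
                 window = as.integer(window), normalization = normalization,
                 endpoint_scale = endpoint_scale),
            class = "pair_bonus_ctx")
}

# partner list per 0-based A position
partner_index <- function(pairs, n) {
  out <- vector("list", n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (i < 0L || j >= n)
      stopf("selected pair (%d,%d) out of range for sequence of length %d",
            i, j, n)
    out[[i + 1L]] <- c(out[[i + 1L]], j)
    out[[j + 1L]] <- c(out[[j + 1L]], i)
  }
  out
}

#' Correlated-pair bonus at one alignment cell
#'
#' @param i,k 0-based positions in sequences A and B.
#' @param seqA,seqB `protein_seq` records.
#' @param ctx A [pair_bonus_ctx()].
#' @return Scalar bonus; 0 when position `i` has no selected partners (or all
#'   partner windows fall outside sequence B).
#' @export
pair_bonus <- function(i, k, seqA, seqB, ctx) {
  a <- seq_chars(seqA); b <- seq_chars(seqB)
  partners <- partner_index(ctx$pairs, seqA$length)[[i + 1L]]
  pair_bonus_cell(i, k, a, b, partners, ctx)
}

# internal fast path: residues pre-split, partners pre-indexed
pair_bonus_cell <- function(i, k, a, b, partners, ctx) {
  if (is.null(partners) || !length(partners)) return(0)
  m <- length(b)
  vals <- numeric(0)
  for (j in partners) {
    centre <- k + (j - i)
    lo <- max(0L, centre - ctx$window)
    hi <- min(m - 1L, centre + ctx$window)
    if (lo > hi) next
    ls <- lo:hi
    vals <- c(vals, max(m400_score(ctx$matrix400, a[i + 1L], a[j + 1L],
                                   b[k + 1L], b[ls + 1L])))
  }
  if (!length(vals)) return(0)
  comb <- if (ctx$normalization == "mean") mean(vals) else sum(vals)
  ctx$endpoint_scale * comb
}

# Precompute the n x m cell-score matrix S(i,k) (1-based storage).
cell_score_matrix <- function(seqA, seqB, m20, params, ctx = NULL) {
  a <- seq_chars(seqA); b <- seq_chars(seqB)
  n <- length(a); m <- length(b)
  S <- params$w1 * outer(seq_len(n), seq_len(m),
                         function(ii, kk) m20_score(m20, a[ii], b[kk]))
  if (!is.null(ctx) && params$w2 != 0 && nrow(ctx$pairs) > 0) {
    pidx <- partner_index(ctx$pairs, n)
    for (i0 in which(lengths(pidx) > 0) - 1L) {
      for (k0 in 0:(m - 1L)) {
        S[i0 + 1L, k0 + 1L] <- S[i0 + 1L, k0 + 1L] +
          params$w2 * pair_bonus_cell(i0, k0, a, b, pidx[[i0 + 1L]], ctx)
      }
    }
  }
  S
}

# Gotoh DP over a precomputed cell-score matrix. Returns list(ops, score).
# States: 1 = M (match), 2 = X (gap in B, consumes A), 3 = Y (gap in A,
# consumes B). Tie order M > X > Y everywhere, which makes the traceback
# deterministic.
gotoh_core <- function(S, params) {
  n <- nrow(S); m <- ncol(S)
  p <- params$gap_open; q <- params$gap_extend
  open <- p + q
  free <- params$free_end_gaps
  M <- matrix(-Inf, n + 1L, m + 1L)
  X <- matrix(-Inf, n + 1L, m + 1L)
  Y <- matrix(-Inf, n + 1L, m + 1L)
  PM <- matrix(0L, n + 1L, m + 1L)
  PX <- matrix(0L, n + 1L, m + 1L)
  PY <- matrix(0L, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (ii in 1:n) {
    X[ii + 1L, 1] <- if (free) 0 else -(p + ii * q)
    PX[ii + 1L, 1] <- if (ii == 1L) 1L else 2L
  }
  for (kk in 1:m) {
    Y[1, kk + 1L] <- if (free) 0 else -(p + kk * q)
    PY[1, kk + 1L] <- if (kk == 1L) 1L else 3L
  }
  best3 <- function(vm, vx, vy) {
    if (vm >= vx && vm >= vy) c(vm, 1)
    else if (vx >= vy) c(vx, 2)
    else c(vy, 3)
  }
  for (ii in 1:n) {
    for (kk in 1:m) {
      bm <- best3(M[ii, kk], X[ii, kk], Y[ii, kk])
      M[ii + 1L, kk + 1L] <- bm[1] + S[ii, kk]
      PM[ii + 1L, kk + 1L] <- bm[2]
      bx <- best3(M[ii, kk + 1L] - open, X[ii, kk + 1L] - q,
                  Y[ii, kk + 1L] - open)
      X[ii + 1L, kk + 1L] <- bx[1]
      PX[ii + 1L, kk + 1L] <- bx[2]
      by <- best3(M[ii + 1L, kk] - open, X[ii + 1L, kk] - open,
                  Y[ii + 1L, kk] - q)
      Y[ii + 1L, kk + 1L] <- by[1]
      PY[ii + 1L, kk + 1L] <- by[2]
    }
  }
  end_i <- n; end_k <- m
  bend <- best3(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  best_score <- bend[1]; best_state <- bend[2]
  if (free) {
    for (ii in 0:n) {
      cand <- best3(M[ii + 1L, m + 1L], X[ii + 1L, m + 1L], Y[ii + 1L, m + 1L])
      if (cand[1] > best_score) {
        best_score <- cand[1]; best_state <- cand[2]; end_i <- ii; end_k <- m
      }
    }
    for (kk in 0:m) {
      cand <- best3(M[n + 1L, kk + 1L], X[n + 1L, kk + 1L], Y[n + 1L, kk + 1L])
      if (cand[1] > best_score) {
        best_score <- cand[1]; best_state <- cand[2]; end_i <- n; end_k <- kk
      }
    }
  }
  op <- character(0); oi <- integer(0); ok <- integer(0)
  ii <- end_i; kk <- end_k; st <- best_state
  while (ii > 0L || kk > 0L) {
    if (st == 1) {
      nst <- PM[ii + 1L, kk + 1L]
      op <- c(op, "M"); oi <- c(oi, ii - 1L); ok <- c(ok, kk - 1L)
      ii <- ii - 1L; kk <- kk - 1L
    } else if (st == 2) {
      nst <- PX[ii + 1L, kk + 1L]
      op <- c(op, "IA"); oi <- c(oi, ii - 1L); ok <- c(ok, NA_integer_)
      ii <- ii - 1L
    } else {
      nst <- PY[ii + 1L, kk + 1L]
      op <- c(op, "IB"); oi <- c(oi, NA_integer_); ok <- c(ok, kk - 1L)
      kk <- kk - 1L
    }
    st <- nst
  }
  ord <- rev(seq_along(op))
  ops <- data.frame(op = op[ord], i = oi[ord], k = ok[ord])
  if (end_i < n)
    ops <- rbind(ops, data.frame(op = "IA", i = end_i:(n - 1L),
                                 k = NA_integer_))
  if (end_k < m)
    ops <- rbind(ops, data.frame(op = "IB", i = NA_integer_,
                                 k = end_k:(m - 1L)))
  list(ops = ops, score = best_score)
}

#' Global pairwise alignment with affine gaps and pair bonuses
#'
#' Needleman-Wunsch/Gotoh dynamic programming over the combined cell score.
#' Traceback is deterministic with tie order match > gap-in-B > gap-in-A
#' (a gap-in-B column consumes a residue of A).
#'
#' @param seqA,seqB `protein_seq` records (nonempty).
#' @param m20 A [subst_matrix20()].
#' @param params A [dp_params()].
#' @param ctx Optional [pair_bonus_ctx()] whose pairs index `seqA`.
#' @return An [alignment_result()] whose `score` is the DP optimum.
#' @export
align_global <- function(seqA, seqB, m20, params = dp_params(), ctx = NULL) {
  if (seqA$length == 0L || seqB$length == 0L) stopf("empty sequence")
  S <- cell_score_matrix(seqA, seqB, m20, params, ctx)
  core <- gotoh_core(S, params)
  res <- alignment_result(core$ops, core$score, params, c(seqA$id, seqB$id))
  check_result_consistency(res, seqA, seqB)
  res
}

#' Recompute the alignment objective for a fixed op list
#'
#' Uses the same gap accounting and pair-bonus semantics as [align_global()].
#' With `free_end_gaps`, the first and last gap run of the alignment (if the
#' alignment starts or ends with a gap) cost nothing.
#'
#' @param result An [alignment_result()].
#' @param seqA,seqB The aligned `protein_seq` records.
#' @param m20 A [subst_matrix20()].
#' @param params A [dp_params()].
#' @param ctx Optional [pair_bonus_ctx()].
#' @return Numeric score.
#' @export
score_alignment <- function(result, seqA, seqB, m20, params = dp_params(),
                            ctx = NULL) {
  check_result_consistency(result, seqA, seqB)
  S <- cell_score_matrix(seqA, seqB, m20, params, ctx)
  ops <- result$ops
  mrows <- ops$op == "M"
  total <- sum(S[cbind(ops$i[mrows] + 1L, ops$k[mrows] + 1L)])
  runs <- rle(ops$op)
  gap_runs <- which(runs$values != "M")
  if (length(gap_runs)) {
    costs <- params$gap_open + runs$lengths[gap_runs] * params$gap_extend
    if (params$free_end_gaps) {
      freeruns <- c(if (gap_runs[1] == 1L) 1L,
                    if (gap_runs[length(gap_runs)] == length(runs$values) &&
                        length(runs$values) > 1L) length(gap_runs))
      freeruns <- unique(freeruns)
      if (length(freeruns)) costs[freeruns] <- 0
    }
    total <- total - sum(costs)
  }
  total
}

#' Percent sequence identity of an alignment
#'
#' 100 x (matched columns with identical residues) / (total alignment
#' columns, gap columns included).
#'
#' @param result An [alignment_result()].
#' @param seqA,seqB The aligned sequences.
#' @return Percentage in \[0, 100\].
#' @export
sequence_identity <- function(result, seqA, seqB) {
  check_result_consistency(result, seqA, seqB)
  a <- seq_chars(seqA); b <- seq_chars(seqB)
  ops <- result$ops
  mrows <- ops$op == "M"
  ident <- sum(a[ops$i[mrows] + 1L] == b[ops$k[mrows] + 1L])
  100 * ident / nrow(ops)
}

#' Iterative frozen-alignment mode
#'
#' Sensitivity-analysis alternative to windowed pair probing: align with the
#' pair term off, map each selected partner j of A through the current
#' alignment to its aligned position l in B, rescore cells with that frozen
#' partner placement, realign, and repeat until the op list is stable or
#' `max_iter` is reached.
#'
#' @param seqA,seqB `protein_seq` records.
#' @param m20 A [subst_matrix20()].
#' @param params A [dp_params()].
#' @param ctx A [pair_bonus_ctx()].
#' @param max_iter Iteration cap (default 10).
#' @return An [alignment_result()] with an `iterations` attribute.
#' @export
align_iterative <- function(seqA, seqB, m20, params = dp_params(), ctx,
                            max_iter = 10L) {
  p0 <- params; p0$w2 <- 0
  cur <- align_global(seqA, seqB, m20, p0)
  a <- seq_chars(seqA); b <- seq_chars(seqB)
  pidx <- partner_index(ctx$pairs, seqA$length)
  it <- 0L
  for (it in seq_len(max_iter)) {
    amap <- rep(NA_integer_, seqA$length)
    mrows <- cur$ops$op == "M"
    amap[cur$ops$i[mrows] + 1L] <- cur$ops$k[mrows]
    S <- cell_score_matrix(seqA, seqB, m20, p0)
    for (i0 in which(lengths(pidx) > 0) - 1L) {
      partners <- pidx[[i0 + 1L]]
      ls <- amap[partners + 1L]
      okp <- !is.na(ls)
      if (!any(okp)) next
      for (k0 in 0:(seqB$length - 1L)) {
        vals <- m400_score(ctx$matrix400, a[i0 + 1L], a[partners[okp] + 1L],
                           b[k0 + 1L], b[ls[okp] + 1L])
        comb <- if (ctx$normalization == "mean") mean(vals) else sum(vals)
        S[i0 + 1L, k0 + 1L] <- S[i0 + 1L, k0 + 1L] +
          params$w2 * ctx$endpoint_scale * comb
      }
    }
    core <- gotoh_core(S, params)
    nxt <- alignment_result(core$ops, core$score, params,
                            c(seqA$id, seqB$id))
    if (identical(nxt$ops, cur$ops)) { cur <- nxt; break }
    cur <- nxt
  }
  attr(cur, "iterations") <- it
  cur
}
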