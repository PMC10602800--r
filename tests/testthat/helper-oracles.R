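# Independent oracles used by the test suite. Each one deliberately takes a
# different computational route from the package implementation it checks:
# exhaustive enumeration for the aligner, explicit cosine-basis sums for the
# DCT, the quaternion eigen method for superposition, and plain nested-loop
# counting for the matrix builders.

# ---------------------------------------------------------------------------
# exhaustive global-alignment enumeration
#
# cellfun(i, k): score of matching A[i] with B[k] (1-based). Affine gaps:
# each maximal gap run of length L costs p + L*q. free_end: the first and
# last run cost nothing if they are gap runs. Visits every global alignment.
enum_align_best <- function(n, m, cellfun, p, q, free_end = FALSE) {
  best <- -Inf
  # lead: still inside the run that starts the alignment (free if a gap run
  # under free_end; only that first run and a trailing gap run are free)
  rec <- function(i, k, last, lead, acc) {
    if (i == n && k == m) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i < n && k < m)
      rec(i + 1L, k + 1L, "M", FALSE, acc + cellfun(i + 1L, k + 1L))
    if (i < n) {
      in_lead <- lead && last %in% c("start", "IA")
      cost <- if (free_end && (in_lead || k == m)) 0
      else if (last == "IA") q else p + q
      rec(i + 1L, k, "IA", in_lead, acc - cost)
    }
    if (k < m) {
      in_lead <- lead && last %in% c("start", "IB")
      cost <- if (free_end && (in_lead || i == n)) 0
      else if (last == "IB") q else p + q
      rec(i, k + 1L, "IB", in_lead, acc - cost)
    }
    invisible(NULL)
  }
  rec(0L, 0L, "start", TRUE, 0)
  best
}

# brute-force pair bonus: direct nested loops over partners and window
brute_pair_bonus <- function(i, k, a, b, pairs, m400, W, normalization) {
  partners <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    if (pairs$i[r] == i) partners <- c(partners, pairs$j[r])
    if (pairs$j[r] == i) partners <- c(partners, pairs$i[r])
  }
  vals <- c()
  for (j in partners) {
    lo <- k + (j - i) - W; hi <- k + (j - i) + W
    cand <- c()
    for (l in lo:hi) {
      if (l >= 0 && l < length(b))
        cand <- c(cand, m400_score(m400, a[i + 1], a[j + 1], b[k + 1], b[l + 1]))
    }
    if (length(cand)) vals <- c(vals, max(cand))
  }
  if (!length(vals)) return(0)
  if (normalization == "mean") mean(vals) else sum(vals)
}

# ---------------------------------------------------------------------------
# independent plain affine-gap (Gotoh) reference aligner, same conventions
# (first gap residue p+q, extensions q, tie order M > gap-in-B > gap-in-A),
# coded with a single combined traceback over state-annotated cells.
gotoh_ref <- function(a, b, score20, p, q) {
  n <- length(a); m <- length(b)
  open <- p + q
  Hm <- matrix(-Inf, n + 1, m + 1)
  Hx <- matrix(-Inf, n + 1, m + 1)  # gap in B
  Hy <- matrix(-Inf, n + 1, m + 1)  # gap in A
  Hm[1, 1] <- 0
  for (i in 2:(n + 1)) Hx[i, 1] <- -(p + (i - 1) * q)
  for (k in 2:(m + 1)) Hy[1, k] <- -(p + (k - 1) * q)
  for (i in 2:(n + 1)) {
    for (k in 2:(m + 1)) {
      s <- score20[a[i - 1], b[k - 1]]
      Hm[i, k] <- s + max(Hm[i - 1, k - 1], Hx[i - 1, k - 1], Hy[i - 1, k - 1])
      Hx[i, k] <- max(Hm[i - 1, k] - open, Hx[i - 1, k] - q,
                      Hy[i - 1, k] - open)
      Hy[i, k] <- max(Hm[i, k - 1] - open, Hx[i, k - 1] - open,
                      Hy[i, k - 1] - q)
    }
  }
  # traceback with explicit tie order M > X > Y
  pick <- function(vm, vx, vy) {
    if (vm >= vx && vm >= vy) "M" else if (vx >= vy) "X" else "Y"
  }
  i <- n + 1; k <- m + 1
  st <- pick(Hm[i, k], Hx[i, k], Hy[i, k])
  score <- max(Hm[i, k], Hx[i, k], Hy[i, k])
  ops <- character(0)
  while (i > 1 || k > 1) {
    if (st == "M") {
      ops <- c("M", ops)
      prev <- pick(Hm[i - 1, k - 1], Hx[i - 1, k - 1], Hy[i - 1, k - 1])
      i <- i - 1; k <- k - 1; st <- prev
    } else if (st == "X") {
      ops <- c("IA", ops)
      if (k == 1) { i <- i - 1; st <- if (i == 1) "M" else "X"; next }
      vm <- Hm[i - 1, k] - open; vx <- Hx[i - 1, k] - q
      vy <- Hy[i - 1, k] - open
      st <- pick(vm, vx, vy)
      i <- i - 1
    } else {
      ops <- c("IB", ops)
      if (i == 1) { k <- k - 1; st <- if (k == 1) "M" else "Y"; next }
      vm <- Hm[i, k - 1] - open; vx <- Hx[i, k - 1] - open
      vy <- Hy[i, k - 1] - q
      st <- pick(vm, vx, vy)
      k <- k - 1
    }
  }
  list(ops = ops, score = score)
}

# ---------------------------------------------------------------------------
# naive DCT compression oracle: explicit cosine-basis summation
naive_compress <- function(x, tr, tc) {
  n <- nrow(x); d <- ncol(x)
  s <- function(k, len) if (k == 0) sqrt(1 / len) else sqrt(2 / len)
  coef <- matrix(0, tr, tc)
  for (k1 in 0:(tr - 1)) {
    cr <- cos(pi * (0:(n - 1) + 0.5) * k1 / n)
    for (k2 in 0:(tc - 1)) {
      cc <- cos(pi * (0:(d - 1) + 0.5) * k2 / d)
      coef[k1 + 1, k2 + 1] <- s(k1, n) * s(k2, d) * sum(x * outer(cr, cc))
    }
  }
  out <- matrix(0, tr, tc)
  for (r in 0:(tr - 1)) {
    for (cix in 0:(tc - 1)) {
      acc <- 0
      for (k1 in 0:(tr - 1)) for (k2 in 0:(tc - 1)) {
        acc <- acc + s(k1, tr) * s(k2, tc) * coef[k1 + 1, k2 + 1] *
          cos(pi * (r + 0.5) * k1 / tr) * cos(pi * (cix + 0.5) * k2 / tc)
      }
      out[r + 1, cix + 1] <- acc
    }
  }
  out * sqrt((tr * tc) / (n * d))
}

# ---------------------------------------------------------------------------
# quaternion-method optimal-superposition RMSD oracle
quaternion_rmsd <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  n <- nrow(X)
  M <- crossprod(Yc, Xc)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# ---------------------------------------------------------------------------
# brute-force pair/single substitution counting for the log-odds builders
# (ordered row pairs, both column read orders, gap tuples skipped)
brute_count_tables <- function(m, selected, all_pairs) {
  mat <- msa_char_matrix(m)
  lab <- coralign_pair_labels()
  count <- function(pairs) {
    acc <- matrix(0, 400, 400, dimnames = list(lab, lab))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r] + 1; j <- pairs$j[r] + 1
      for (s in seq_len(nrow(mat))) for (t in seq_len(nrow(mat))) {
        if (s == t) next
        tupA1 <- paste0(mat[s, i], mat[s, j]); tupB1 <- paste0(mat[t, i], mat[t, j])
        if (grepl("-", paste0(tupA1, tupB1))) next
        acc[tupA1, tupB1] <- acc[tupA1, tupB1] + 1
        tupA2 <- paste0(mat[s, j], mat[s, i]); tupB2 <- paste0(mat[t, j], mat[t, i])
        acc[tupA2, tupB2] <- acc[tupA2, tupB2] + 1
      }
    }
    acc
  }
  list(fg = count(selected), bg = count(all_pairs))
}

brute_single_tables <- function(m, selected, all_pairs) {
  mat <- msa_char_matrix(m)
  ab <- aa_alphabet()
  count <- function(pairs) {
    acc <- matrix(0, 20, 20, dimnames = list(ab, ab))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r] + 1; j <- pairs$j[r] + 1
      for (s in seq_len(nrow(mat))) for (t in seq_len(nrow(mat))) {
        if (s == t) next
        if (mat[s, i] == "-" || mat[s, j] == "-" ||
            mat[t, i] == "-" || mat[t, j] == "-") next
        acc[mat[s, i], mat[t, i]] <- acc[mat[s, i], mat[t, i]] + 1
        acc[mat[s, j], mat[t, j]] <- acc[mat[s, j], mat[t, j]] + 1
      }
    }
    acc
  }
  list(fg = count(selected), bg = count(all_pairs))
}

# helpers reaching package internals used by the brute counters
msa_char_matrix <- function(m) do.call(rbind, strsplit(m$rows, "", fixed = TRUE))
coralign_pair_labels <- function() {
  ab <- aa_alphabet()
  as.vector(t(outer(ab, ab, paste0)))
}
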