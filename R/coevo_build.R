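# Coevolution-derived substitution matrices from MSAs.
#
# Two column-pair statistics are provided: mutual information (marginal,
# fast, transitive-correlation-blind) and mean-field direct coupling
# analysis (global model; inverts the pseudocounted covariance matrix over
# 20 non-reference states per column and scores pairs by direct
# information, which strips transitive correlations).
#
# Two builders consume the rankings. The 400x400 pair-substitution builder
# counts, at the top-ranked column pairs, how one residue pair substitutes
# for another across all ordered pairs of MSA rows, against an identical
# count over ALL eligible column pairs as background, and stores natural-log
# odds. The 20x20 builder does the analogous single-residue counting at
# selected (optionally structure-filtered) pairs.
#
# Gap handling (the source statistics never define it): columns with > 50%
# gaps are excluded from ranking and counting, and any substitution tuple
# touching a gap is skipped.

GAP_STATE <- 21L

# integer state matrix (depth x width): 1..20 canonical, 21 gap/unknown
msa_states <- function(m) {
  mat <- msa_matrix(m)
  st <- matrix(match(mat, aa_alphabet(), nomatch = GAP_STATE),
               nrow(mat), ncol(mat))
  st
}

# 0-based indices of columns with gap fraction <= 0.5
eligible_columns <- function(states) {
  gapfrac <- colMeans(states == GAP_STATE)
  which(gapfrac <= 0.5) - 1L
}

#' Sequence weights by identity clustering
#'
#' Standard coevolution-analysis reweighting: each row's weight is the
#' reciprocal of the number of rows (itself included) with which it shares
#' at least `identity` fractional identity over the eligible columns.
#'
#' @param m An [msa()].
#' @param identity Clustering threshold (default 0.8).
#' @return Numeric weight per row; their sum is the effective depth.
#' @export
msa_seq_weights <- function(m, identity = 0.8) {
  st <- msa_states(m)
  cols <- eligible_columns(st) + 1L
  st <- st[, cols, drop = FALSE]
  M <- nrow(st)
  nsim <- integer(M)
  for (s in seq_len(M)) {
    idfrac <- rowMeans(st == matrix(st[s, ], M, ncol(st), byrow = TRUE))
    nsim[s] <- sum(idfrac >= identity)
  }
  1 / nsim
}

rank_df <- function(i, j, stat, method) {
  structure(data.frame(i = i, j = j, stat = stat),
            class = c("pair_ranking", "data.frame"), method = method)
}

#' Mutual information between MSA column pairs
#'
#' MI(i,j) = sum_ab f_ab log2(f_ab / (f_a f_b)) over the 20-letter alphabet,
#' using (optionally weighted) frequencies with `pseudocount` added to every
#' joint cell. Rows gapped at either column are excluded from that pair's
#' counts.
#'
#' @param m An [msa()] of depth >= 2.
#' @param weights Optional per-row weights (default: unit weights).
#' @param pseudocount Count added to each 20 x 20 joint cell (default 0).
#' @return A `pair_ranking` data frame with 0-based columns `i`, `j` and
#'   `stat` in bits, covering every eligible column pair.
#' @export
column_mi <- function(m, weights = NULL, pseudocount = 0) {
  if (m$depth < 2L) stopf("MSA depth must be >= 2")
  st <- msa_states(m)
  weights <- weights %||% rep(1, m$depth)
  cols <- eligible_columns(st)
  if (length(cols) < 2L) stopf("fewer than 2 eligible columns (gap fraction > 0.5)")
  combs <- utils::combn(cols, 2L)
  mi <- vapply(seq_len(ncol(combs)), function(cidx) {
    i <- combs[1, cidx] + 1L; j <- combs[2, cidx] + 1L
    ok <- st[, i] != GAP_STATE & st[, j] != GAP_STATE
    if (!any(ok)) return(0)
    joint <- matrix(pseudocount, 20, 20)
    idx <- cbind(st[ok, i], st[ok, j])
    w <- weights[ok]
    for (r in seq_along(w))
      joint[idx[r, 1], idx[r, 2]] <- joint[idx[r, 1], idx[r, 2]] + w[r]
    tot <- sum(joint)
    if (tot <= 0) return(0)
    f <- joint / tot
    fi <- rowSums(f); fj <- colSums(f)
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / outer(fi, fj)[nz]))
  }, numeric(1))
  rank_df(combs[1, ], combs[2, ], mi, "MI")
}

#' Mean-field direct coupling analysis
#'
#' Standard mean-field DCA over the 21-state alphabet (20 residues + gap):
#' identity-clustered sequence weights, pseudocounted single and pair
#' frequencies, covariance over the 20 non-gap states per column, couplings
#' as the negative inverse covariance, and per-pair direct information from
#' the two-site model with self-consistent fields.
#'
#' @param m An [msa()] of depth >= 2.
#' @param weights Optional per-row weights; default [msa_seq_weights()] at
#'   80% identity.
#' @param pseudocount_fraction Fraction of the probability mass given to
#'   the uniform pseudocount (default 0.5, the common mean-field choice).
#' @return A `pair_ranking` data frame (0-based `i`, `j`, `stat` = DI in
#'   nats) over every eligible column pair.
#' @export
mfdca_di <- function(m, weights = NULL, pseudocount_fraction = 0.5) {
  if (m$depth < 2L) stopf("MSA depth must be >= 2")
  if (pseudocount_fraction <= 0 || pseudocount_fraction >= 1)
    stopf("pseudocount_fraction must be in (0,1)")
  st <- msa_states(m)
  cols0 <- eligible_columns(st)
  L <- length(cols0)
  if (L < 2L) stopf("fewer than 2 eligible columns")
  st <- st[, cols0 + 1L, drop = FALSE]
  weights <- weights %||% msa_seq_weights(m)
  meff <- sum(weights)
  q <- 21L; pc <- pseudocount_fraction
  # single-site frequencies (L x 21)
  fi <- matrix(pc / q, L, q)
  for (i in seq_len(L)) {
    tab <- tapply(weights, factor(st[, i], levels = 1:q), sum)
    tab[is.na(tab)] <- 0
    fi[i, ] <- pc / q + (1 - pc) * tab / meff
  }
  # raw weighted joint counts for all column pairs via one-hot crossprod
  M <- nrow(st)
  onehot <- matrix(0, M, L * q)
  onehot[cbind(rep(seq_len(M), L),
               (rep(seq_len(L), each = M) - 1L) * q + as.vector(st))] <- 1
  Fjoint <- crossprod(onehot * weights, onehot) / meff   # (L*q) x (L*q)
  # covariance over the 20 non-gap states of each column
  qs <- q - 1L
  C <- matrix(0, L * qs, L * qs)
  blk <- function(i) ((i - 1L) * qs + 1L):(i * qs)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) {
        C[blk(i), blk(j)] <- diag(fi[i, 1:qs]) - tcrossprod(fi[i, 1:qs])
      } else {
        fij <- pc / q^2 +
          (1 - pc) * Fjoint[((i - 1L) * q + 1L):((i - 1L) * q + qs),
                            ((j - 1L) * q + 1L):((j - 1L) * q + qs)]
        C[blk(i), blk(j)] <- fij - tcrossprod(fi[i, 1:qs], fi[j, 1:qs])
      }
    }
  }
  Jneg <- tryCatch(solve(C), error = function(e)
    stopf("covariance matrix is singular; increase pseudocount_fraction (%s)",
          conditionMessage(e)))
  # DI per pair from the two-site model
  combs <- utils::combn(seq_len(L), 2L)
  di <- vapply(seq_len(ncol(combs)), function(cidx) {
    i <- combs[1, cidx]; j <- combs[2, cidx]
    e <- matrix(0, q, q)
    e[1:qs, 1:qs] <- -Jneg[blk(i), blk(j)]
    W <- exp(e)
    pi_ <- fi[i, ]; pj_ <- fi[j, ]
    mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
    for (iter in 1:200) {
      new1 <- pi_ / as.vector(W %*% mu2); new1 <- new1 / sum(new1)
      new2 <- pj_ / as.vector(crossprod(W, mu1)); new2 <- new2 / sum(new2)
      del <- max(abs(new1 - mu1), abs(new2 - mu2))
      mu1 <- new1; mu2 <- new2
      if (del < 1e-6) break
    }
    Pdir <- W * tcrossprod(mu1, mu2)
    Pdir <- Pdir / sum(Pdir)
    prod0 <- tcrossprod(pi_, pj_)
    nz <- Pdir > 1e-300
    sum(Pdir[nz] * log(Pdir[nz] / prod0[nz]))
  }, numeric(1))
  rank_df(cols0[combs[1, ]], cols0[combs[2, ]], di, "mfDCA")
}

# top-fraction selection with deterministic tie order (stat desc, then i, j)
top_pairs <- function(ranking, top_fraction) {
  if (top_fraction <= 0 || top_fraction > 1)
    stopf("top_fraction must be in (0, 1]")
  k <- ceiling(top_fraction * nrow(ranking))
  ord <- order(-ranking$stat, ranking$i, ranking$j)
  ranking[ord[seq_len(k)], , drop = FALSE]
}

# 400-type index of residue-state pairs (a,b in 1..20): (a-1)*20 + b
pair_type <- function(a, b) (a - 1L) * 20L + b

# accumulate ordered-row-pair substitution counts of pair types at one
# column pair into a 400 x 400 matrix (both row directions)
count_pair_subs <- function(st, i1, j1, acc) {
  ok <- st[, i1] != GAP_STATE & st[, j1] != GAP_STATE
  if (sum(ok) < 2L) return(acc)
  types <- pair_type(st[ok, i1], st[ok, j1])
  tab <- table(types)
  idx <- as.integer(names(tab)); cnt <- as.numeric(tab)
  block <- tcrossprod(cnt)           # row-pair counts between types
  diag(block) <- cnt * (cnt - 1)     # exclude self pairs
  acc[idx, idx] <- acc[idx, idx] + block
  acc
}

# Smoothed log-odds of two count tables with unequal totals. Flat additive
# pseudocounts would hand every tuple unseen in BOTH tables the constant
# ln(N_bg/N_fg) > 0, i.e. the largest scores in the matrix; smoothing the
# relative frequencies instead (f + pc/K, K = number of cells) sends
# unseen-everywhere tuples to exactly 0 and keeps foreground==background
# at the all-zero matrix.
logodds_smoothed <- function(FG, BG, pseudocount) {
  K <- length(FG)
  ffg <- FG / sum(FG)
  fbg <- if (sum(BG) > 0) BG / sum(BG) else BG
  log((ffg + pseudocount / K) / (fbg + pseudocount / K))
}

ranking_for <- function(m, ranking_method, weights = NULL) {
  switch(ranking_method,
         mfdca = mfdca_di(m, weights = weights),
         mi = column_mi(m, weights = weights),
         stopf("unknown ranking method '%s'", ranking_method))
}

#' Build a 400x400 pair-substitution log-odds matrix from MSAs
#'
#' Per MSA, ranks column pairs by coevolution statistic and keeps the top
#' fraction (default 15%). For every ordered pair of rows and each selected
#' column pair, the 4-tuple "residue pair in row s at (i,j) substitutes to
#' the pair in row t" is counted (gap-touching tuples skipped); the
#' background repeats the identical count over ALL eligible column pairs.
#' Entries are natural-log odds of pseudocounted foreground vs background
#' probabilities; both read orders of each column pair are accumulated, so
#' the (i,j,k,l) == (j,i,l,k) identity holds by construction.
#'
#' @param msas A single [msa()] or list of them.
#' @param ranking_method `"mfdca"` (default) or `"mi"`.
#' @param top_fraction Fraction of top-ranked column pairs kept per MSA.
#' @param pseudocount Smoothing mass: each relative frequency is shifted by
#'   `pseudocount / 160000` before taking the ratio, so tuples unseen in
#'   both tables score exactly 0 (default 0.5).
#' @param name Matrix name token.
#' @return A [pair_matrix400()].
#' @export
build_ps400 <- function(msas, ranking_method = c("mfdca", "mi"),
                        top_fraction = 0.15, pseudocount = 0.5,
                        name = "PS400-style") {
  ranking_method <- match.arg(ranking_method)
  if (inherits(msas, "msa")) msas <- list(msas)
  if (!length(msas)) stopf("need at least one MSA")
  FG <- matrix(0, 400, 400)
  BG <- matrix(0, 400, 400)
  for (m in msas) {
    ranking <- ranking_for(m, ranking_method)
    sel <- top_pairs(ranking, top_fraction)
    st <- msa_states(m)
    for (r in seq_len(nrow(sel)))
      FG <- count_pair_subs(st, sel$i[r] + 1L, sel$j[r] + 1L, FG)
    for (r in seq_len(nrow(ranking)))
      BG <- count_pair_subs(st, ranking$i[r] + 1L, ranking$j[r] + 1L, BG)
  }
  if (sum(FG) == 0) stopf("no gap-free foreground tuple observations")
  # accumulate the swapped read order (i,j)->(j,i), (k,l)->(l,k)
  ab <- aa_alphabet()
  lab <- pair_labels()
  dimnames(FG) <- dimnames(BG) <- list(lab, lab)
  swp <- swap_pair(lab)
  FG <- FG + FG[swp, swp]
  BG <- BG + BG[swp, swp]
  pair_matrix400(logodds_smoothed(FG, BG, pseudocount), name = name)
}

# single-residue substitution counts (20 x 20) at one column of a column
# pair, over ordered row pairs, rows gapped at either column excluded
count_single_subs <- function(st, icol, jcol, acc) {
  ok <- st[, icol] != GAP_STATE & st[, jcol] != GAP_STATE
  if (sum(ok) < 2L) return(acc)
  for (cc in c(icol, jcol)) {
    tab <- table(factor(st[ok, cc], levels = 1:20))
    cnt <- as.numeric(tab)
    block <- tcrossprod(cnt)
    diag(block) <- cnt * (cnt - 1)
    acc <- acc + block
  }
  acc
}

#' Build a 20x20 single-residue log-odds matrix from coevolving pairs
#'
#' Selected column pairs are the top fraction by the ranking statistic
#' (default mutual information), optionally intersected with a structural
#' proximity filter (a contact map in MSA-column coordinates: a pair
#' survives only if its columns are in contact). Single-residue
#' substitution counts are accumulated over ordered row pairs at both
#' columns of each selected pair; the background is the identical count
#' over all eligible column pairs. Entries are natural-log odds
#' (symmetric by construction).
#'
#' @param msas A single [msa()] or list of them.
#' @param ranking_method `"mi"` (default) or `"mfdca"`.
#' @param top_fraction Fraction of top-ranked pairs kept (default 0.15).
#' @param proximity_filter Optional [corr_map()] of kind contact (or a list
#'   of one per MSA) in MSA-column coordinates.
#' @param pseudocount Smoothing mass on relative frequencies, as in
#'   [build_ps400()] but over 400 cells (default 0.5).
#' @param name Matrix name token.
#' @return A [subst_matrix20()].
#' @export
build_protsub <- function(msas, ranking_method = c("mi", "mfdca"),
                          top_fraction = 0.15, proximity_filter = NULL,
                          pseudocount = 0.5, name = "coevo20") {
  ranking_method <- match.arg(ranking_method)
  if (inherits(msas, "msa")) msas <- list(msas)
  if (!length(msas)) stopf("need at least one MSA")
  if (inherits(proximity_filter, "corr_map"))
    proximity_filter <- list(proximity_filter)
  FG <- matrix(0, 20, 20)
  BG <- matrix(0, 20, 20)
  for (mi_ in seq_along(msas)) {
    m <- msas[[mi_]]
    ranking <- ranking_for(m, ranking_method)
    sel <- top_pairs(ranking, top_fraction)
    if (!is.null(proximity_filter)) {
      cm <- proximity_filter[[mi_]]
      incontact <- cm$values[cbind(sel$i + 1L, sel$j + 1L)] > 0
      sel <- sel[incontact, , drop = FALSE]
    }
    st <- msa_states(m)
    for (r in seq_len(nrow(sel)))
      FG <- count_single_subs(st, sel$i[r] + 1L, sel$j[r] + 1L, FG)
    for (r in seq_len(nrow(ranking)))
      BG <- count_single_subs(st, ranking$i[r] + 1L, ranking$j[r] + 1L, BG)
  }
  if (sum(FG) == 0) stopf("no foreground substitution observations")
  scores <- logodds_smoothed(FG, BG, pseudocount)
  dimnames(scores) <- list(aa_alphabet(), aa_alphabet())
  subst_matrix20((scores + t(scores)) / 2, name = name)
}

#' Export a real-valued 20x20 matrix in integer half-bit units
#'
#' Scales natural-log scores by 2/ln(2) and rounds, the classic integer
#' matrix-file convention.
#'
#' @param m A [subst_matrix20()].
#' @return A [subst_matrix20()] with integer-valued scores.
#' @export
to_half_bits <- function(m) {
  s <- round_half_up(m$scores * 2 / log(2))
  subst_matrix20(s, name = paste0(m$name, "-halfbits"))
}
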