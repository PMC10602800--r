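test_that("identical sequences align all-match with the diagonal sum", {
  a <- protein_seq("a", "ACDE")
  b <- protein_seq("b", "ACDE")
  res <- align_global(a, b, b62, dp_params(w2 = 0, gap_open = 10,
                                           gap_extend = 0.5))
  expect_true(all(res$ops$op == "M"))
  expect_equal(res$score, 4 + 9 + 6 + 5)  # BLOSUM62 diagonal of A,C,D,E
  expect_equal(sequence_identity(res, a, b), 100)
})

test_that("empty sequences and out-of-range pair contexts error", {
  a <- protein_seq("a", "ACDE")
  expect_no_error(e <- protein_seq("e", ""))  # length-0 construction allowed
  expect_error(align_global(e, a, b62), "empty")
  v <- matrix(0, 9, 9); v[1, 8] <- v[8, 1] <- 1
  ctx <- pair_bonus_ctx(select_pairs(corr_map(v), 0.5, 3, 16),
                        const_matrix400(1), window = 1)
  expect_error(align_global(a, a, b62, dp_params(), ctx), "out of range")
})

test_that("pair_bonus handles empty partner sets and degenerate windows", {
  a <- protein_seq("a", "ACDEFGHIK")
  b <- protein_seq("b", "ACDEFGHIK")
  m400 <- rnd_matrix400(seed = 2)
  v <- matrix(0, 9, 9); v[1, 5] <- v[5, 1] <- 0.9   # pair (0,4)
  ctx <- pair_bonus_ctx(select_pairs(corr_map(v), 0.5, 3, 16), m400,
                        window = 0)
  expect_equal(pair_bonus(2, 2, a, b, ctx), 0)      # no partners
  # W=0 forces l = k + 4 = 5, i.e. residue G of B
  expect_equal(pair_bonus(0, 1, a, b, ctx),
               m400_score(m400, "A", "F", "C", "G"))
  # partner in reverse orientation: i=4 probes l = k - 4
  expect_equal(pair_bonus(4, 5, a, b, ctx),
               m400_score(m400, "F", "A", "G", "C"))
  # window entirely outside B -> 0
  expect_equal(pair_bonus(4, 0, a, b, ctx), 0)
})

test_that("pair_bonus equals the brute-force window enumeration", {
  set.seed(21)
  m400 <- rnd_matrix400(seed = 3)
  for (rep in 1:10) {
    a <- rnd_seq(12, aa_alphabet(), id = "a")
    b <- rnd_seq(10, aa_alphabet(), id = "b")
    map <- make_random_corrmap(12, density = 0.4, seed = rep,
                               min_separation = 2)
    for (norm in c("mean", "sum")) {
      ctx <- pair_bonus_ctx(select_pairs(map, 0.3, 2, 16), m400,
                            window = 2, normalization = norm)
      ach <- strsplit(a$residues, "")[[1]]
      bch <- strsplit(b$residues, "")[[1]]
      for (i in c(0, 3, 7, 11)) for (k in c(0, 4, 9)) {
        expect_equal(pair_bonus(i, k, a, b, ctx),
                     brute_pair_bonus(i, k, ach, bch, ctx$pairs, m400, 2,
                                      norm))
      }
    }
  }
})

test_that("w2=0 reproduces plain Gotoh op-for-op", {
  set.seed(31)
  for (rep in 1:25) {
    a <- rnd_seq(sample(2:50, 1), aa_alphabet(), id = "a")
    b <- rnd_seq(sample(2:50, 1), aa_alphabet(), id = "b")
    p <- sample(c(2, 5, 10), 1); q <- sample(c(0.5, 1, 2), 1)
    res <- align_global(a, b, b62, dp_params(w2 = 0, gap_open = p,
                                             gap_extend = q))
    ref <- gotoh_ref(strsplit(a$residues, "")[[1]],
                     strsplit(b$residues, "")[[1]], b62$scores, p, q)
    expect_equal(res$score, ref$score)
    expect_equal(res$ops$op, ref$ops)
  }
})

test_that("DP optimum equals exhaustive enumeration (small instances)", {
  set.seed(41)
  for (rep in 1:30) {
    a <- rnd_seq(sample(3:6, 1), id = "a")
    b <- rnd_seq(sample(3:6, 1), id = "b")
    p <- runif(1, 1, 8); q <- runif(1, 0.2, min(p, 2))
    for (free in c(FALSE, TRUE)) {
      params <- dp_params(w2 = 0, gap_open = p, gap_extend = q,
                          free_end_gaps = free)
      res <- align_global(a, b, b62, params)
      cf <- make_cellfun(a, b, b62, params)
      expect_equal(res$score,
                   enum_align_best(a$length, b$length, cf, p, q, free),
                   tolerance = 1e-9)
      expect_equal(score_alignment(res, a, b, b62, params), res$score,
                   tolerance = 1e-9)
    }
  }
})

test_that("planted pair correspondence is recovered only with the pair term", {
  # Two gapless placements of A in B: offset 0 scores 19 (W:Y=2) and the
  # planted offset 4 scores 18 (W:F=1) under BLOSUM62 alone, so w2=0 picks
  # offset 0. A single 400-matrix reward on the tuple (W,C)->(F,C) at the
  # correlated pair (0,3) flips the optimum to the planted placement.
  a <- protein_seq("a", "WAAC")
  b <- protein_seq("b", "YAACFAAC")
  lab <- coralign_pair_labels()
  s <- matrix(0, 400, 400, dimnames = list(lab, lab))
  s["WC", "FC"] <- 30
  s["CW", "CF"] <- 30   # swap identity
  m400 <- pair_matrix400(s)
  v <- matrix(0, 4, 4); v[1, 4] <- v[4, 1] <- 1
  ctx <- pair_bonus_ctx(select_pairs(corr_map(v), 0.5, 3, 16), m400,
                        window = 0)
  base <- dp_params(w2 = 0, gap_open = 10, gap_extend = 1,
                    free_end_gaps = TRUE)
  with_pairs <- dp_params(w2 = 0.5, gap_open = 10, gap_extend = 1,
                          free_end_gaps = TRUE)
  r0 <- align_global(a, b, b62, base, ctx)
  r1 <- align_global(a, b, b62, with_pairs, ctx)
  m0 <- r0$ops[r0$ops$op == "M", ]
  m1 <- r1$ops[r1$ops$op == "M", ]
  expect_true(all(m0$k == m0$i))        # w2=0: offset-0 placement
  expect_true(all(m1$k == m1$i + 4L))   # pair term: planted offset-4
  # both optima verified by enumeration with the full objective
  for (pr in list(list(params = base, res = r0),
                  list(params = with_pairs, res = r1))) {
    cf <- make_cellfun(a, b, b62, pr$params, ctx)
    expect_equal(pr$res$score,
                 enum_align_best(a$length, b$length, cf, 10, 1, TRUE),
                 tolerance = 1e-9)
  }
})

test_that("alignment is symmetric under argument swap without pair context", {
  set.seed(51)
  for (rep in 1:10) {
    a <- rnd_seq(sample(5:25, 1), aa_alphabet(), id = "a")
    b <- rnd_seq(sample(5:25, 1), aa_alphabet(), id = "b")
    params <- dp_params(w2 = 0, gap_open = 5, gap_extend = 1)
    rab <- align_global(a, b, b62, params)
    rba <- align_global(b, a, b62, params)
    expect_equal(rab$score, rba$score)
  }
})

test_that("pair-term monotonicity: raising used 400-entries never hurts", {
  set.seed(61)
  a <- rnd_seq(15, aa_alphabet(), id = "a")
  b <- rnd_seq(15, aa_alphabet(), id = "b")
  map <- make_random_corrmap(15, 0.4, seed = 6)
  m400 <- rnd_matrix400(seed = 6, scale = 2)
  params <- dp_params(w2 = 0.3, gap_open = 5, gap_extend = 1)
  ctx <- pair_bonus_ctx(select_pairs(map, 0.3), m400, window = 2)
  s0 <- align_global(a, b, b62, params, ctx)$score
  bumped <- pair_matrix400(m400$scores + 1, name = "bumped")
  ctx2 <- pair_bonus_ctx(select_pairs(map, 0.3), bumped, window = 2)
  s1 <- align_global(a, b, b62, params, ctx2)$score
  expect_gte(s1 + 1e-9, s0)
})

test_that("score_alignment applies affine accounting to fixed op lists", {
  a <- protein_seq("a", "ACDEFG")
  b <- protein_seq("b", "ACFG")
  # hand-built: match ACxxFG with interior gap of length 2 in B
  ops <- data.frame(op = c("M", "M", "IA", "IA", "M", "M"),
                    i = c(0L, 1L, 2L, 3L, 4L, 5L),
                    k = c(0L, 1L, NA, NA, 2L, 3L))
  res <- alignment_result(ops, 0, dp_params(), c("a", "b"))
  params <- dp_params(w2 = 0, gap_open = 10, gap_extend = 1)
  matches <- m20_score(b62, "A", "A") + m20_score(b62, "C", "C") +
    m20_score(b62, "F", "F") + m20_score(b62, "G", "G")
  expect_equal(score_alignment(res, a, b, b62, params), matches - 12)
})

test_that("identity percentages follow the column-count definition", {
  a <- protein_seq("a", "AC")
  b <- protein_seq("b", "CD")
  ops <- data.frame(op = c("M", "M"), i = 0:1, k = 0:1)
  res <- alignment_result(ops, 0, dp_params(), c("a", "b"))
  expect_equal(sequence_identity(res, a, b), 0)
  a2 <- protein_seq("a", "ACD")
  b2 <- protein_seq("b", "AD")
  ops2 <- data.frame(op = c("M", "IA", "M"), i = c(0L, 1L, 2L),
                     k = c(0L, NA, 1L))
  res2 <- alignment_result(ops2, 0, dp_params(), c("a", "b"))
  expect_equal(sequence_identity(res2, a2, b2), 100 * 2 / 3)
})

test_that("free end gaps produce semi-global behaviour", {
  a <- protein_seq("a", "ACDE")
  b <- protein_seq("b", "WWWACDEWWW")
  res <- align_global(a, b, b62, dp_params(w2 = 0, gap_open = 10,
                                           gap_extend = 1,
                                           free_end_gaps = TRUE))
  m <- res$ops[res$ops$op == "M", ]
  expect_equal(m$k, m$i + 3L)         # ACDE sits on positions 3..6 of B
  expect_equal(res$score, 4 + 9 + 6 + 5)
  expect_equal(score_alignment(res, a, b, b62,
                               dp_params(w2 = 0, gap_open = 10,
                                         gap_extend = 1,
                                         free_end_gaps = TRUE)),
               res$score)
})

test_that("iterative frozen-alignment mode converges and stays consistent", {
  set.seed(71)
  a <- rnd_seq(20, aa_alphabet(), id = "a")
  b <- rnd_seq(22, aa_alphabet(), id = "b")
  map <- make_random_corrmap(20, 0.3, seed = 7)
  ctx <- pair_bonus_ctx(select_pairs(map, 0.3), rnd_matrix400(seed = 7))
  res <- align_iterative(a, b, b62, dp_params(w2 = 0.2), ctx)
  expect_lte(attr(res, "iterations"), 10)
  expect_s3_class(res, "alignment_result")
  gs <- write_alignment(res, a, b, format = "fasta")
  expect_equal(parse_alignment_fasta(gs), res$ops)
})
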