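test_that("MI is exact on forced joint distributions", {
  # column j an exact copy of column i, letters A,C,D,E once each:
  # joint is uniform on 4 diagonal cells -> MI = log2(4) = 2 bits
  m <- msa(paste0("r", 1:4), c("AA", "CC", "DD", "EE"))
  r <- column_mi(m)
  expect_equal(r$stat, 2.0)
  # constant columns carry zero information
  m2 <- msa(paste0("r", 1:4), c("AA", "AA", "AA", "AA"))
  expect_equal(column_mi(m2)$stat, 0.0)
})

test_that("MI of independently shuffled deep columns is near zero", {
  # 4-letter background: finite-sample MI bias ~ (q-1)^2/(2N ln 2) = 0.003
  bg <- c(rep(0.25, 4), rep(0, 16))
  m <- make_covarying_msa(2000, 6, planted_pairs = list(), background = bg,
                          seed = 97)
  r <- column_mi(m)
  expect_lte(max(r$stat), 0.05)
  expect_equal(nrow(r), choose(6, 2))
})

test_that("MI weighting and gap exclusion behave", {
  m <- msa(paste0("r", 1:4), c("AA", "CC", "D-", "-E"))
  # rows 3,4 have a gap at one of the two columns -> only rows 1,2 count
  r <- column_mi(m)
  expect_equal(r$stat, 1.0)  # two equiprobable diagonal cells
  # zero weight on row 2 leaves a single-cell joint -> MI 0
  r2 <- column_mi(m, weights = c(1, 0, 1, 1))
  expect_equal(r2$stat, 0.0)
})

test_that("columns with >50% gaps are excluded from rankings", {
  rows <- c("AC-", "CA-", "AC-", "CAW")
  m <- msa(paste0("r", 1:4), rows)
  r <- column_mi(m)
  expect_equal(nrow(r), 1)            # only columns 0,1 eligible
  expect_equal(c(r$i, r$j), c(0, 1))
})

test_that("mfDCA ranks a planted coupled pair first", {
  m <- make_covarying_msa(500, 15, planted_pairs = list(list(i = 3L, j = 10L)),
                          coupling = 1.0, seed = 11)
  r <- mfdca_di(m)
  expect_equal(nrow(r), choose(15, 2))
  top <- r[which.max(r$stat), ]
  expect_equal(c(top$i, top$j), c(3, 10))
  # independent columns stay well below the planted signal
  m0 <- make_covarying_msa(500, 15, planted_pairs = list(), seed = 11)
  r0 <- mfdca_di(m0)
  expect_gte(top$stat, 5 * max(r0$stat))
})

test_that("mfDCA suppresses transitive correlations", {
  # chain A -> B -> C: column 9 copies column 2, column 14 copies column 9
  # (with noise); the direct pairs should outrank the transitive (2,14)
  ab <- aa_alphabet()
  perm <- stats::setNames(ab[c(2:20, 1)], ab)
  set.seed(13)
  m <- make_covarying_msa(800, 15, planted_pairs = list(), seed = 13)
  mat <- do.call(rbind, strsplit(m$rows, ""))
  fire1 <- runif(800) < 0.9
  mat[fire1, 10] <- perm[mat[fire1, 3]]
  fire2 <- runif(800) < 0.9
  mat[fire2, 15] <- perm[mat[fire2, 10]]
  m <- msa(m$ids, apply(mat, 1, paste, collapse = ""))
  r <- mfdca_di(m)
  di <- function(i, j) r$stat[r$i == i & r$j == j]
  expect_lt(di(2, 14), min(di(2, 9), di(9, 14)))
})

test_that("planted pairs land in the top 15% of DI across seeded replicates", {
  hits <- 0L
  for (seed in 1:20) {
    m <- make_covarying_msa(500, 15,
                            planted_pairs = list(list(i = 2L, j = 9L)),
                            coupling = 1.0, seed = seed)
    r <- mfdca_di(m)
    k <- ceiling(0.15 * nrow(r))
    topk <- r[order(-r$stat), ][seq_len(k), ]
    if (any(topk$i == 2 & topk$j == 9)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("PS400 log-odds is zero when foreground equals background", {
  m <- make_covarying_msa(12, 8, seed = 5)
  ps <- build_ps400(m, ranking_method = "mi", top_fraction = 1.0)
  expect_equal(max(abs(ps$scores)), 0)
})

test_that("PS400 counting matches brute-force enumeration on a small family", {
  m <- make_covarying_msa(6, 6, planted_pairs = list(list(i = 0L, j = 3L)),
                          coupling = 1.0, seed = 8)
  ranking <- column_mi(m)
  sel <- ranking[order(-ranking$stat, ranking$i, ranking$j), ][
    seq_len(ceiling(0.15 * nrow(ranking))), ]
  tabs <- brute_count_tables(m, sel, ranking)
  pc <- 0.5
  expected <- log((tabs$fg / sum(tabs$fg) + pc / 160000) /
                  (tabs$bg / sum(tabs$bg) + pc / 160000))
  got <- build_ps400(m, ranking_method = "mi", top_fraction = 0.15,
                     pseudocount = pc)
  expect_equal(got$scores, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PS400 rewards planted co-substitutions and penalizes others", {
  # family where the selected pair co-substitutes AC <-> DE exclusively
  rows <- c(rep("ACWWW", 5), rep("DEWWW", 5))
  m <- msa(sprintf("r%02d", 1:10), rows)
  # single eligible pair set; select pair (0,1) via top_fraction on MI
  ps <- build_ps400(m, ranking_method = "mi", top_fraction = 0.1)
  expect_gt(m400_score(ps, "A", "C", "D", "E"), 0)
  # background-frequent, foreground-absent tuple scores negative
  expect_lt(m400_score(ps, "W", "W", "W", "W"), 0)
  # swap identity by construction
  expect_equal(ps$scores, ps$scores[swap_lab(), swap_lab()],
               ignore_attr = TRUE)
})

test_that("3-sequence toy matches the closed-form log ratio", {
  # fully hand-checkable 4-column, 3-row family: the selected pair (0,1)
  # reads AC, DE, AC across rows; the other five column pairs are the
  # background. All counts below were enumerated by hand.
  m <- msa(c("r1", "r2", "r3"), c("ACWY", "DEWY", "ACWY"))
  got <- build_ps400(m, ranking_method = "mi", top_fraction = 1 / 6,
                     pseudocount = 0.5)
  # foreground at (0,1): ordered row pairs give AC->DE twice, DE->AC twice,
  # AC->AC twice; doubling for the reversed column read order yields
  # N_fg = 12 with count(AC,DE) = 2. Background N_bg = 72 (6 column pairs)
  # with count(AC,DE) = 2 as well (only pair (0,1) produces it).
  pc <- 0.5 / 160000
  expect_equal(m400_score(got, "A", "C", "D", "E"),
               log((2 / 12 + pc) / (2 / 72 + pc)))
  # never-seen tuple scores exactly zero under frequency smoothing
  expect_equal(m400_score(got, "W", "W", "A", "A"), 0)
  # and the full matrix agrees with the brute-force enumeration oracle
  ranking <- column_mi(m)
  sel <- ranking[order(-ranking$stat, ranking$i, ranking$j), ][1, ]
  tabs <- brute_count_tables(m, sel, ranking)
  expected <- log((tabs$fg / sum(tabs$fg) + pc) /
                  (tabs$bg / sum(tabs$bg) + pc))
  expect_equal(got$scores, expected, ignore_attr = TRUE)
})

test_that("20x20 builder mirrors planted conservative substitutions", {
  # A <-> S enriched at the selected (perfectly coupled) pair
  rows <- c(rep("AAWGH", 4), rep("SSWGH", 4))
  m <- msa(sprintf("r%02d", 1:8), rows)
  ps <- build_protsub(m, ranking_method = "mi", top_fraction = 0.1)
  expect_gt(m20_score(ps, "A", "S"), m20_score(ps, "A", "W"))
  # zero when foreground == background
  ps0 <- build_protsub(m, ranking_method = "mi", top_fraction = 1.0)
  expect_equal(max(abs(ps0$scores)), 0)
})

test_that("proximity filter removes non-contacting pairs from the foreground", {
  # planted pair (0,1) substitutes A<->S at rate 4/7; columns 2-4 carry the
  # same letters at the background rate 2/7. Restricting the foreground to
  # the non-planted contact (2,3) pulls the A,S score back toward zero.
  rows <- c("AASAA", "AAASA", "AAAAS", "AAAAA",
            "SSSAA", "SSASA", "SSAAS", "SSAAA")
  m <- msa(sprintf("r%02d", 1:8), rows)
  v <- matrix(0, 5, 5); v[3, 4] <- v[4, 3] <- 1
  cm <- corr_map(v, kind = "contact")
  ps_filtered <- build_protsub(m, ranking_method = "mi", top_fraction = 1.0,
                               proximity_filter = cm)
  ps_open <- build_protsub(m, ranking_method = "mi", top_fraction = 0.1)
  expect_gt(m20_score(ps_open, "A", "S"), 0)
  expect_lt(abs(m20_score(ps_filtered, "A", "S")),
            abs(m20_score(ps_open, "A", "S")))
})

test_that("20x20 builder counting matches brute-force enumeration", {
  m <- make_covarying_msa(6, 6, planted_pairs = list(list(i = 1L, j = 4L)),
                          coupling = 1.0, seed = 17)
  ranking <- column_mi(m)
  sel <- ranking[order(-ranking$stat, ranking$i, ranking$j), ][
    seq_len(ceiling(0.15 * nrow(ranking))), ]
  tabs <- brute_single_tables(m, sel, ranking)
  pc <- 0.5
  raw <- log((tabs$fg / sum(tabs$fg) + pc / 400) /
             (tabs$bg / sum(tabs$bg) + pc / 400))
  expected <- (raw + t(raw)) / 2
  got <- build_protsub(m, ranking_method = "mi", top_fraction = 0.15,
                       pseudocount = pc)
  expect_equal(got$scores, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rankings are deterministic and builders reproducible", {
  m <- make_covarying_msa(60, 10, planted_pairs = list(list(i = 1L, j = 6L)),
                          coupling = 0.9, seed = 23)
  expect_identical(mfdca_di(m), mfdca_di(m))
  expect_identical(build_ps400(m, "mi", 0.2)$scores,
                   build_ps400(m, "mi", 0.2)$scores)
})

test_that("half-bit export scales and rounds", {
  m <- build_protsub(msa(paste0("r", 1:4), c("AAWW", "SSWW", "AAWW", "SSWW")),
                     ranking_method = "mi", top_fraction = 0.2)
  hb <- to_half_bits(m)
  expect_true(all(hb$scores == round(hb$scores)))
  expect_equal(hb$scores[1, 2],
               floor(m$scores[1, 2] * 2 / log(2) + 0.5))
})
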