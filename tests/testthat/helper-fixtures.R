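# Shared fixtures, generated in code — nothing on disk except the bundled
# matrix files.

b62 <- read_matrix20("BLOSUM62")

`%||%` <- function(a, b) if (is.null(a)) b else a

# whole-file content as a single string (for byte-identity checks)
digest_lines <- function(f) paste(readLines(f), collapse = "\n")

swap_lab <- function() {
  lab <- coralign_pair_labels()
  paste0(substr(lab, 2, 2), substr(lab, 1, 1))
}

rnd_seq <- function(len, alphabet = c("A", "C", "D", "E"), id = "s") {
  protein_seq(id, paste(sample(alphabet, len, replace = TRUE), collapse = ""))
}

# a pair matrix with seeded random entries satisfying the swap identity
rnd_matrix400 <- function(seed = 1, scale = 4) {
  set.seed(seed)
  lab <- coralign_pair_labels()
  s <- matrix(stats::rnorm(160000, sd = scale), 400, 400,
              dimnames = list(lab, lab))
  swp <- paste0(substr(lab, 2, 2), substr(lab, 1, 1))
  s <- (s + s[swp, swp]) / 2
  pair_matrix400(s, name = "rnd")
}

# constant-value pair matrix
const_matrix400 <- function(value = 0) {
  lab <- coralign_pair_labels()
  pair_matrix400(matrix(value, 400, 400, dimnames = list(lab, lab)),
                 name = "const")
}

# cellfun closure for the enumeration oracle: w1*m20 + w2*brute pair bonus
make_cellfun <- function(seqA, seqB, m20, params, ctx = NULL) {
  a <- strsplit(seqA$residues, "")[[1]]
  b <- strsplit(seqB$residues, "")[[1]]
  function(i1, k1) {
    s <- params$w1 * m20_score(m20, a[i1], b[k1])
    if (!is.null(ctx) && params$w2 != 0) {
      s <- s + params$w2 * ctx$endpoint_scale *
        brute_pair_bonus(i1 - 1L, k1 - 1L, a, b, ctx$pairs, ctx$matrix400,
                         ctx$window, ctx$normalization)
    }
    s
  }
}
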