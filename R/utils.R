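# Internal helpers shared across modules.

#' Canonical amino-acid alphabet
#'
#' The 20 standard amino-acid one-letter codes in NCBI matrix-file order
#' (ARNDCQEGHILKMFPSTWYV). All matrices in the package are indexed in this
#' order; FASTA input is sanitized onto this alphabet plus a single internal
#' unknown symbol.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Internal unknown residue marker (post-sanitization placeholder for X etc.).
UNKNOWN_AA <- "X"

# Ambiguity codes collapsed onto the canonical alphabet; anything else that
# is not a canonical letter becomes the unknown symbol.
AA_REMAP <- c(B = "D", Z = "E", J = "L", U = "C", O = "K")

sanitize_residues <- function(x, id = "<sequence>") {
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  remap <- AA_REMAP[chars]
  chars[!is.na(remap)] <- remap[!is.na(remap)]
  bad <- !(chars %in% c(aa_alphabet(), UNKNOWN_AA))
  if (any(bad)) {
    # digits / '*' / '.' are hard errors; letters fall back to unknown
    nonletter <- bad & !grepl("^[A-Za-z]$", chars)
    if (any(nonletter)) {
      pos <- which(nonletter)[1]
      stop(sprintf("record '%s': invalid residue character '%s' at position %d",
                   id, chars[pos], pos), call. = FALSE)
    }
    chars[bad] <- UNKNOWN_AA
  }
  paste(chars, collapse = "")
}

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Atomic file write: write to a sibling temp file, then rename.
write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp.", Sys.getpid())
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
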