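# Sequence, MSA and alignment input/output.
#
# Sequences are plain S3 objects: a protein_seq is list(id, residues, length)
# over the 20-letter alphabet (non-standard letters collapsed on read, see
# sanitize rules in utils.R). Gap character is '-'; '.' is accepted on input
# and normalized. Coordinates are 0-based half-open internally and 1-based in
# human-readable output.

#' Construct a protein sequence record
#'
#' @param id Identifier token (first whitespace-delimited word is kept).
#' @param residues Residue string; sanitized onto the canonical alphabet
#'   (B to D, Z to E, J to L, U to C, O to K; other letters become the unknown
#'   symbol which scores the minimum off-diagonal matrix value).
#' @return An object of class `protein_seq` with fields `id`, `residues`,
#'   `length`.
#' @export
protein_seq <- function(id, residues) {
  id <- strsplit(trimws(id), "\\s+")[[1]][1]
  if (is.na(id) || !nzchar(id)) stopf("empty sequence identifier")
  residues <- sanitize_residues(residues, id = id)
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("protein_seq %s (%d aa)\n", x$id, x$length))
  invisible(x)
}

seq_chars <- function(s) strsplit(s$residues, "", fixed = TRUE)[[1]]

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return List of [protein_seq()] records, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("cannot parse FASTA '%s': %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0L) stopf("no records in FASTA file: %s", path)
  lapply(seq_along(set), function(i) {
    protein_seq(names(set)[i], as.character(set[[i]]))
  })
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs List of `protein_seq` records (or of `list(id=, residues=)`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  lines <- unlist(lapply(seqs, function(s) {
    body <- gsub(sprintf("(.{%d})", width), "\\1\n", s$residues)
    body <- strsplit(body, "\n", fixed = TRUE)[[1]]
    c(paste0(">", s$id), body)
  }))
  write_atomic(lines, path)
}

#' Construct an MSA object
#'
#' @param ids Character vector of row identifiers.
#' @param rows Character vector of aligned residue strings (gap '-'; '.' is
#'   normalized to '-').
#' @return Object of class `msa` with fields `ids`, `rows`, `width`, `depth`.
#' @export
msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows))
  rows <- toupper(gsub(".", "-", rows, fixed = TRUE))
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    off <- ids[widths != widths[1]]
    stopf("ragged MSA rows (aligned lengths differ): %s",
          paste(off, collapse = ", "))
  }
  # sanitize non-gap characters per-row
  rows <- vapply(seq_along(rows), function(i) {
    ch <- strsplit(rows[i], "", fixed = TRUE)[[1]]
    ng <- ch != "-"
    if (any(ng)) {
      ch[ng] <- strsplit(sanitize_residues(paste(ch[ng], collapse = ""),
                                           id = ids[i]), "", fixed = TRUE)[[1]]
    }
    paste(ch, collapse = "")
  }, character(1))
  structure(list(ids = unname(ids), rows = unname(rows),
                 width = unname(widths[1]), depth = length(rows)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows x %d columns\n", x$depth, x$width))
  invisible(x)
}

# depth x width character matrix view of an MSA
msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$rows, "", fixed = TRUE))
}

#' Read a multiple sequence alignment
#'
#' Aligned FASTA or Stockholm (sequence lines only; annotation is dropped).
#'
#' @param path Input file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return An [msa()] object.
#' @export
read_msa <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stopf("no records in MSA file: %s", path)
    ids <- vapply(names(set), function(n) strsplit(trimws(n), "\\s+")[[1]][1],
                  character(1), USE.NAMES = FALSE)
    return(msa(ids, as.character(set)))
  }
  # Stockholm: '# ...' annotations ignored, '//' terminates, sequence lines
  # are '<name> <aligned residues>'; multi-block files are concatenated.
  lines <- readLines(path, warn = FALSE)
  acc <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#") || ln == "//") next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2L) stopf("malformed Stockholm sequence line: '%s'", ln)
    acc[[parts[1]]] <- paste0(acc[[parts[1]]] %||% "", parts[2])
  }
  if (length(acc) == 0L) stopf("no records in Stockholm file: %s", path)
  msa(names(acc), unlist(acc, use.names = FALSE))
}

#' Write an MSA as aligned FASTA
#'
#' @param m An [msa()] object.
#' @param path Output path.
#' @export
write_msa <- function(m, path) {
  write_fasta(Map(function(id, row) list(id = id, residues = row),
                  m$ids, m$rows), path)
}

# ---------------------------------------------------------------------------
# AlignmentResult: ops is a data.frame with columns op ("M","IA","IB"),
# i (0-based index into A or NA), k (0-based index into B or NA).
# "IA" inserts a residue of A against a gap in B; "IB" the converse.

#' Construct an alignment result
#'
#' @param ops Data frame with columns `op` (`"M"`, `"IA"`, `"IB"`), `i`, `k`
#'   (0-based residue indices; `NA` where the op does not consume a residue).
#' @param score Total alignment score.
#' @param params The [dp_params()] used.
#' @param seq_ids Character pair of sequence identifiers.
#' @return Object of class `alignment_result`.
#' @export
alignment_result <- function(ops, score, params, seq_ids) {
  stopifnot(is.data.frame(ops), all(ops$op %in% c("M", "IA", "IB")))
  ia <- ops$i[!is.na(ops$i)]
  ik <- ops$k[!is.na(ops$k)]
  if (any(diff(ia) != 1L) || any(diff(ik) != 1L) ||
      (length(ia) && ia[1] != 0L) || (length(ik) && ik[1] != 0L))
    stopf("alignment ops do not consume residues consecutively")
  structure(list(ops = ops, score = score, params = params,
                 seq_ids = seq_ids),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  nm <- sum(x$ops$op == "M")
  cat(sprintf("alignment %s vs %s: %d columns (%d matched), score %.4f\n",
              x$seq_ids[1], x$seq_ids[2], nrow(x$ops), nm, x$score))
  invisible(x)
}

check_result_consistency <- function(result, seqA, seqB) {
  ops <- result$ops
  na <- sum(ops$op != "IB")
  nb <- sum(ops$op != "IA")
  if (na != seqA$length || nb != seqB$length)
    stopf("alignment result is inconsistent with the sequences (consumes %d/%d, have %d/%d)",
          na, nb, seqA$length, seqB$length)
  invisible(TRUE)
}

# two gapped strings for a result
gapped_strings <- function(result, seqA, seqB) {
  check_result_consistency(result, seqA, seqB)
  a <- seq_chars(seqA); b <- seq_chars(seqB)
  ops <- result$ops
  ga <- ifelse(ops$op == "IB", "-", a[ops$i + 1L])
  gb <- ifelse(ops$op == "IA", "-", b[ops$k + 1L])
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""))
}

#' Serialize an alignment
#'
#' `"fasta"` writes the two gapped records; `"pair"` writes EMBOSS-needle-like
#' blocks (50 columns per line with an identity/similarity midline: `|` for
#' identical residues, `:` for positive single-residue matrix score when a
#' matrix is supplied, space otherwise).
#'
#' @param result An [alignment_result()].
#' @param seqA,seqB The two `protein_seq` records the result aligns.
#' @param format `"pair"` or `"fasta"`.
#' @param m20 Optional [subst_matrix20()] used for the similarity midline.
#' @return Character vector of output lines.
#' @export
write_alignment <- function(result, seqA, seqB, format = c("pair", "fasta"),
                            m20 = NULL) {
  format <- match.arg(format)
  gs <- gapped_strings(result, seqA, seqB)
  if (format == "fasta") {
    return(c(paste0(">", seqA$id), gs$a, paste0(">", seqB$id), gs$b))
  }
  ca <- strsplit(gs$a, "")[[1]]
  cb <- strsplit(gs$b, "")[[1]]
  mid <- vapply(seq_along(ca), function(j) {
    if (ca[j] == "-" || cb[j] == "-") return(" ")
    if (ca[j] == cb[j]) return("|")
    if (!is.null(m20) && m20_score(m20, ca[j], cb[j]) > 0) return(":")
    " "
  }, character(1))
  ident <- sequence_identity(result, seqA, seqB)
  w <- max(nchar(seqA$id), nchar(seqB$id))
  lines <- c(sprintf("# A: %s (%d aa)", seqA$id, seqA$length),
             sprintf("# B: %s (%d aa)", seqB$id, seqB$length),
             sprintf("# Score: %.4f", result$score),
             sprintf("# Identity: %.1f%% (%d/%d columns)", ident,
                     sum(ca == cb & ca != "-"), length(ca)),
             "")
  posa <- 0L; posb <- 0L
  for (start in seq(1L, length(ca), by = 50L)) {
    end <- min(start + 49L, length(ca))
    blka <- ca[start:end]; blkb <- cb[start:end]
    sa <- posa + 1L; sb <- posb + 1L
    posa <- posa + sum(blka != "-"); posb <- posb + sum(blkb != "-")
    chunk <- function(v) paste(vapply(split(v, (seq_along(v) - 1L) %/% 10L),
                                      paste, character(1), collapse = ""),
                               collapse = " ")
    lines <- c(lines,
               sprintf("%-*s %4d %s %4d", w, seqA$id, sa, chunk(blka), posa),
               sprintf("%-*s      %s", w, "", chunk(mid[start:end])),
               sprintf("%-*s %4d %s %4d", w, seqB$id, sb, chunk(blkb), posb),
               "")
  }
  lines
}

#' Parse an aligned-FASTA pairwise alignment back into ops
#'
#' Inverse of `write_alignment(format = "fasta")`.
#'
#' @param lines Character vector with exactly two gapped FASTA records.
#' @return Data frame of ops as in [alignment_result()].
#' @export
parse_alignment_fasta <- function(lines) {
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  set <- Biostrings::readBStringSet(tmp)
  if (length(set) != 2L) stopf("expected exactly 2 aligned records, got %d",
                               length(set))
  a <- strsplit(as.character(set[[1]]), "")[[1]]
  b <- strsplit(as.character(set[[2]]), "")[[1]]
  if (length(a) != length(b)) stopf("aligned records differ in length")
  op <- ifelse(a != "-" & b != "-", "M", ifelse(b == "-", "IA", "IB"))
  if (any(a == "-" & b == "-")) stopf("column with gaps in both records")
  i <- ifelse(op != "IB", cumsum(op != "IB") - 1L, NA_integer_)
  k <- ifelse(op != "IA", cumsum(op != "IA") - 1L, NA_integer_)
  data.frame(op = op, i = as.integer(i), k = as.integer(k))
}
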