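# File formats: FASTA input (via Biostrings), gapped-FASTA / TSV alignment
# output with enough header metadata to round-trip, and the TSV special-rows
# checkpoint with an integrity checksum.

#' Read sequences from a FASTA file
#'
#' Parses (multi-line, LF or CRLF) FASTA through `Biostrings` and returns
#' [dna_sequence()] objects, uppercased. IUPAC ambiguity codes are kept and
#' will score as mismatches.
#'
#' @param path Readable FASTA file.
#' @return List of [dna_sequence()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("format error: ", conditionMessage(e)))
  if (length(set) == 0L) stop("format error: FASTA file holds no records")
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  lapply(seq_along(set), function(t) {
    dna_sequence(toupper(as.character(set[[t]])), id = ids[t])
  })
}

#' Write a pair of sequences as FASTA
#'
#' @param seqs List of [dna_sequence()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(set) <- vapply(seqs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

aln_meta_string <- function(aln) {
  sprintf("mode=%s gap_model=%s score=%g range0=%d-%d range1=%d-%d",
          aln$mode, aln$gap_model, aln$score,
          aln$start0, aln$end0, aln$start1, aln$end1)
}

parse_aln_meta <- function(line) {
  grab <- function(key) sub(paste0(".*", key, "="), "", line)
  first <- function(x) strsplit(x, "[ \t]")[[1]][1]
  rng <- function(key) as.integer(strsplit(first(grab(key)), "-")[[1]])
  r0 <- rng("range0"); r1 <- rng("range1")
  list(mode = first(grab("mode")), gap_model = first(grab("gap_model")),
       score = as.numeric(first(grab("score"))),
       start0 = r0[1], end0 = r0[2], start1 = r1[1], end1 = r1[2])
}

#' Write an alignment to a file
#'
#' `gapped-fasta` writes two records of equal length with `-` gaps (the
#' coordinates, mode and score ride in the headers); `tsv-pairs` writes one
#' row per column with 1-based residue positions (`NA` on a gap) and the
#' column class (`match`, `mismatch`, `gap`). Both formats round-trip
#' through [read_alignment()].
#'
#' @param aln An [new_alignment()].
#' @param path Output file.
#' @param format `"gapped-fasta"` or `"tsv-pairs"`.
#' @param ids Character pair of record names.
#' @return The path, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("gapped-fasta", "tsv-pairs"),
                            ids = c("S0", "S1")) {
  format <- match.arg(format)
  if (format == "gapped-fasta") {
    lines <- c(
      sprintf(">%s %s", ids[1], aln_meta_string(aln)),
      paste(aln$top, collapse = ""),
      sprintf(">%s %s", ids[2], aln_meta_string(aln)),
      paste(aln$bottom, collapse = "")
    )
    writeLines(lines, path)
  } else {
    cls <- ifelse(aln$top == "-" | aln$bottom == "-", "gap",
                  ifelse(aln$top == aln$bottom, "match", "mismatch"))
    pos0 <- ifelse(aln$top == "-", NA_integer_,
                   cumsum(aln$top != "-") + aln$start0 - 1L)
    pos1 <- ifelse(aln$bottom == "-", NA_integer_,
                   cumsum(aln$bottom != "-") + aln$start1 - 1L)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s", aln_meta_string(aln)), con)
    df <- data.frame(pos0 = pos0, res0 = aln$top,
                     pos1 = pos1, res1 = aln$bottom, class = cls,
                     stringsAsFactors = FALSE)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
  }
  invisible(path)
}

#' Read an alignment written by [write_alignment()]
#'
#' @param path File to read.
#' @param format `"gapped-fasta"` or `"tsv-pairs"`.
#' @return An [new_alignment()].
#' @export
read_alignment <- function(path, format = c("gapped-fasta", "tsv-pairs")) {
  format <- match.arg(format)
  if (format == "gapped-fasta") {
    lines <- readLines(path)
    heads <- grep("^>", lines)
    if (length(heads) != 2L) stop("format error: expected two gapped records")
    meta <- parse_aln_meta(lines[heads[1]])
    top <- strsplit(paste(lines[(heads[1] + 1L):(heads[2] - 1L)],
                          collapse = ""), "")[[1]]
    bottom <- strsplit(paste(lines[(heads[2] + 1L):length(lines)],
                             collapse = ""), "")[[1]]
  } else {
    lines <- readLines(path)
    meta <- parse_aln_meta(sub("^# ", "", lines[1]))
    df <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                            colClasses = c("integer", "character",
                                           "integer", "character", "character"),
                            na.strings = "NA")
    top <- df$res0; bottom <- df$res1
  }
  if (length(top) != length(bottom)) {
    stop("format error: records differ in length")
  }
  new_alignment(top, bottom, meta$score, meta$start0, meta$end0,
                meta$start1, meta$end1, meta$mode, meta$gap_model)
}

#' Persist special-row checkpoints
#'
#' Plain-TSV checkpoint keyed by (partition, row), holding the H and
#' vertical-gap F values of every stored special row over the partition's
#' columns, plus a checksum verified on read (bit-exact round trip; the
#' values are integers).
#'
#' @param specials A `special_rows` object from [band_fill()]/[stage1()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_special_rows <- function(specials, path) {
  stopifnot(inherits(specials, "special_rows"))
  con <- file(path, "w")
  on.exit(close(con))
  vals <- c(specials$H, specials$F)
  vals <- vals[is.finite(vals)]
  writeLines(sprintf("# special_rows partition=%d j_lo=%d j_hi=%d k=%d checksum=%.0f",
                     specials$partition, specials$j_lo, specials$j_hi,
                     specials$k, sum(vals)), con)
  for (si in seq_along(specials$rows)) {
    writeLines(sprintf("H\t%d\t%s", specials$rows[si],
                       paste(specials$H[si, ], collapse = "\t")), con)
    writeLines(sprintf("F\t%d\t%s", specials$rows[si],
                       paste(specials$F[si, ], collapse = "\t")), con)
  }
  invisible(path)
}

#' Re-read special-row checkpoints
#'
#' @param path File written by [write_special_rows()].
#' @return A `special_rows` object.
#' @export
read_special_rows <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("integrity error: empty or truncated checkpoint")
  hd <- lines[1]
  num <- function(key) {
    m <- regmatches(hd, regexpr(paste0(key, "=[-0-9.]+"), hd))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  partition <- as.integer(num("partition")); j_lo <- as.integer(num("j_lo"))
  j_hi <- as.integer(num("j_hi")); k <- as.integer(num("k"))
  checksum <- num("checksum")
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, character(1), 1L)
  rows <- as.integer(vapply(parts, `[[`, character(1), 2L))
  vals <- lapply(parts, function(p) as.numeric(p[-(1:2)]))
  hsel <- kind == "H"
  row_ids <- rows[hsel]
  H <- do.call(rbind, vals[hsel])
  F <- do.call(rbind, vals[!hsel])
  stopifnot(identical(rows[!hsel], row_ids))
  got <- c(H, F); got <- sum(got[is.finite(got)])
  if (!isTRUE(all.equal(got, checksum))) {
    stop("integrity error: checkpoint checksum mismatch")
  }
  new_special_rows(partition, j_lo, j_hi, k, row_ids, H, F)
}
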