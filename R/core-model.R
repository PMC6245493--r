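#' Construct a DNA sequence
#'
#' A `dna_sequence` is the basic unit every aligner function consumes: an
#' identifier plus a residue string over the DNA alphabet. Residues are
#' uppercased on construction. Letters outside `{A,C,G,T}` (e.g. `N` or other
#' IUPAC ambiguity codes) are kept but are scored as mismatches against every
#' residue, including themselves, so they can never inflate a score.
#'
#' @param residues Character scalar with the residues (may be empty).
#' @param id Character scalar label.
#' @return An object of class `dna_sequence` with fields `id`, `residues` and
#'   `length`.
#' @examples
#' dna_sequence("acgtn", id = "s1")
#' @export
dna_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  res <- toupper(residues)
  if (grepl("[^A-Z*]", res)) {
    stop("alphabet error: residues must be letters (got non-letter characters)")
  }
  structure(
    list(id = as.character(id), residues = res, length = nchar(res)),
    class = "dna_sequence"
  )
}

#' @export
print.dna_sequence <- function(x, ...) {
  prev <- if (x$length > 60L) paste0(substr(x$residues, 1L, 60L), "...") else x$residues
  cat(sprintf("<dna_sequence> %s (%d bp)\n%s\n", x$id, x$length, prev))
  invisible(x)
}

# coerce characters / Biostrings-like inputs to dna_sequence
as_dna_sequence <- function(x, id = "seq") {
  if (inherits(x, "dna_sequence")) return(x)
  if (is.character(x) && length(x) == 1L) return(dna_sequence(x, id = id))
  stop("cannot interpret input as a DNA sequence")
}

#' Scoring scheme for DNA alignment
#'
#' Holds the match value, the mismatch penalty magnitude and the gap model.
#' Penalties are stored as non-negative magnitudes and applied with minus
#' signs: a mismatch contributes `-mismatch`, a linear gap column `-gap`, and
#' an affine gap run of length `x` contributes `-gap_run_cost(x, scheme)`
#' where the run cost is `gap_open + (x - 1) * gap_extend`.
#'
#' @param match Match value, integer > 0. Default `1` (the worked-example
#'   scoring of the reference figures: +1 / -1 / -2).
#' @param mismatch Mismatch penalty magnitude, integer >= 0. Default `1`.
#' @param gap Linear gap penalty magnitude (linear model). Default `2`.
#' @param gap_open,gap_extend Affine gap opening/extension magnitudes. Supply
#'   both to select the affine model; `gap_open >= gap_extend >= 0` required.
#' @param substitution_hook Optional `function(a, b)` returning an integer
#'   substitution score that overrides match/mismatch (e.g. an ad hoc matrix
#'   lookup). Residues are passed as single uppercase characters.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()                                  # +1 / -1, linear gap -2
#' scoring_scheme(gap_open = 5, gap_extend = 1)      # affine
#' @export
scoring_scheme <- function(match = 1L, mismatch = 1L, gap = 2L,
                           gap_open = NULL, gap_extend = NULL,
                           substitution_hook = NULL) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  stopifnot(match > 0L, mismatch >= 0L)
  affine <- !is.null(gap_open) || !is.null(gap_extend)
  if (affine) {
    if (is.null(gap_open) || is.null(gap_extend)) {
      stop("affine model needs both gap_open and gap_extend")
    }
    gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
    if (!(gap_open >= gap_extend && gap_extend >= 0L)) {
      stop("affine model requires gap_open >= gap_extend >= 0")
    }
    gap <- NA_integer_
  } else {
    gap <- as.integer(gap)
    stopifnot(gap >= 0L)
    gap_open <- gap_extend <- NA_integer_
  }
  if (!is.null(substitution_hook)) stopifnot(is.function(substitution_hook))
  structure(
    list(
      match = match, mismatch = mismatch,
      gap_model = if (affine) "affine" else "linear",
      gap = gap, gap_open = gap_open, gap_extend = gap_extend,
      substitution_hook = substitution_hook
    ),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  gm <- if (x$gap_model == "linear") {
    sprintf("linear gap -%d", x$gap)
  } else {
    sprintf("affine gap open -%d / extend -%d", x$gap_open, x$gap_extend)
  }
  cat(sprintf("<scoring_scheme> match +%d, mismatch -%d, %s%s\n",
              x$match, x$mismatch, gm,
              if (is.null(x$substitution_hook)) "" else ", substitution hook"))
  invisible(x)
}

# effective open/extend magnitudes; the linear model is the affine model with
# open == extend == gap, which the whole engine relies on
scheme_open <- function(scheme) {
  if (scheme$gap_model == "affine") scheme$gap_open else scheme$gap
}
scheme_extend <- function(scheme) {
  if (scheme$gap_model == "affine") scheme$gap_extend else scheme$gap
}

#' Substitution score of a residue pair
#'
#' Returns `match` when the two residues are identical members of
#' `{A,C,G,T}`, `-mismatch` otherwise; the optional substitution hook of the
#' scheme takes precedence over both.
#'
#' @param a,b Single uppercase residue characters.
#' @param scheme A [scoring_scheme()].
#' @return Integer substitution score.
#' @export
p_score <- function(a, b, scheme) {
  stopifnot(is.character(a), is.character(b), nchar(a) == 1L, nchar(b) == 1L)
  if (a != toupper(a) || b != toupper(b)) {
    stop("alphabet error: residues must be normalized (uppercase)")
  }
  if (!is.null(scheme$substitution_hook)) {
    return(as.integer(scheme$substitution_hook(a, b)))
  }
  if (a == b && a %in% c("A", "C", "G", "T")) scheme$match else -scheme$mismatch
}

#' Affine cost of a gap run
#'
#' Cost magnitude of a maximal run of `x` gap columns:
#' `gap_open + (x - 1) * gap_extend` under the affine model, `x * gap` under
#' the linear model.
#'
#' @param x Run length, integer >= 1 (vectorized).
#' @param scheme A [scoring_scheme()].
#' @return Non-negative integer penalty magnitude (applied as its negative).
#' @examples
#' gap_run_cost(3, scoring_scheme(gap_open = 5, gap_extend = 1))  # 7
#' @export
gap_run_cost <- function(x, scheme) {
  x <- as.integer(x)
  if (any(x < 1L)) stop("domain error: gap run length must be >= 1")
  scheme_open(scheme) + (x - 1L) * scheme_extend(scheme)
}

# -- substitution matrix over the observed alphabet --------------------------
# Vectorized lookup used by every fill routine; the hook (if any) is expanded
# into a dense matrix once so hooks do not slow down the inner loops.
build_submat <- function(alphabet, scheme) {
  n <- length(alphabet)
  if (is.null(scheme$substitution_hook)) {
    S <- matrix(-as.numeric(scheme$mismatch), n, n)
    core <- alphabet %in% c("A", "C", "G", "T")
    diag(S)[core] <- as.numeric(scheme$match)
  } else {
    S <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      as.numeric(scheme$substitution_hook(alphabet[i], alphabet[j]))
    }))
  }
  dimnames(S) <- list(alphabet, alphabet)
  S
}

# integer-encode both sequences over a shared alphabet
encode_pair <- function(s0, s1, scheme) {
  ch0 <- strsplit(s0$residues, "", fixed = TRUE)[[1]]
  ch1 <- strsplit(s1$residues, "", fixed = TRUE)[[1]]
  alphabet <- union(c("A", "C", "G", "T"), union(ch0, ch1))
  list(
    c0 = match(ch0, alphabet),
    c1 = match(ch1, alphabet),
    S = build_submat(alphabet, scheme),
    alphabet = alphabet
  )
}

# -- alignments --------------------------------------------------------------

#' Construct an alignment object
#'
#' An alignment is an ordered list of columns, each pairing a residue or gap
#' of the top sequence (S0) with one of the bottom sequence (S1), plus the
#' score and the 1-based inclusive coordinates of the aligned region. No
#' column may be (gap, gap).
#'
#' @param top,bottom Character vectors of single characters; `"-"` is a gap.
#' @param score Alignment score.
#' @param start0,end0,start1,end1 1-based inclusive coordinates of the aligned
#'   region in S0/S1 (0s for an empty local alignment).
#' @param mode `"global"` or `"local"`.
#' @param gap_model `"linear"` or `"affine"`.
#' @return An object of class `alignment`.
#' @export
new_alignment <- function(top, bottom, score, start0, end0, start1, end1,
                          mode, gap_model) {
  stopifnot(length(top) == length(bottom))
  if (any(top == "-" & bottom == "-")) {
    stop("malformed-alignment error: (gap, gap) column")
  }
  structure(
    list(top = top, bottom = bottom, score = as.numeric(score),
         start0 = as.integer(start0), end0 = as.integer(end0),
         start1 = as.integer(start1), end1 = as.integer(end1),
         mode = mode, gap_model = gap_model),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, width = 60L, ...) {
  cat(sprintf("<alignment> %s/%s, score %g, %d columns\n",
              x$mode, x$gap_model, x$score, length(x$top)))
  cat(sprintf("  S0 %d..%d, S1 %d..%d\n", x$start0, x$end0, x$start1, x$end1))
  n <- length(x$top)
  at <- 1L
  while (at <= n) {
    hi <- min(n, at + width - 1L)
    t <- paste(x$top[at:hi], collapse = "")
    b <- paste(x$bottom[at:hi], collapse = "")
    mid <- paste(ifelse(x$top[at:hi] == x$bottom[at:hi] & x$top[at:hi] != "-",
                        "|", " "), collapse = "")
    cat(" ", t, "\n ", mid, "\n ", b, "\n", sep = "")
    at <- hi + 1L
  }
  invisible(x)
}

#' Recompute an alignment score from its columns
#'
#' Independent consistency oracle used across the package: sums the
#' substitution score of every residue column and charges each maximal gap run
#' its run cost (`gap_run_cost` under the affine model, `gap` per column under
#' the linear model). For every alignment the package produces, this must
#' equal the stored score.
#'
#' @param aln An [new_alignment()] object.
#' @param scheme The [scoring_scheme()] the alignment was computed under.
#' @return Numeric score.
#' @export
score_alignment <- function(aln, scheme) {
  top <- aln$top; bottom <- aln$bottom
  if (length(top) == 0L) return(0)
  if (any(top == "-" & bottom == "-")) {
    stop("malformed-alignment error: (gap, gap) column")
  }
  gapcol <- top == "-" | bottom == "-"
  sc <- 0
  if (any(!gapcol)) {
    a <- top[!gapcol]; b <- bottom[!gapcol]
    if (!is.null(scheme$substitution_hook)) {
      sc <- sc + sum(mapply(function(x, y) p_score(x, y, scheme), a, b))
    } else {
      core <- a %in% c("A", "C", "G", "T")
      sc <- sc + sum(ifelse(a == b & core, scheme$match, -scheme$mismatch))
    }
  }
  if (any(gapcol)) {
    runs <- rle(gapcol)
    lens <- runs$lengths[runs$values]
    sc <- sc - sum(gap_run_cost(lens, scheme))
  }
  sc
}

# lengths of the aligned (non-gap) spans; used for coordinate invariants
aligned_span <- function(aln) {
  c(sum(aln$top != "-"), sum(aln$bottom != "-"))
}

# internal validity assertion shared by tests and the pipeline
check_alignment <- function(aln, scheme, s0 = NULL, s1 = NULL) {
  stopifnot(length(aln$top) == length(aln$bottom))
  if (length(aln$top) > 0L) {
    sp <- aligned_span(aln)
    stopifnot(aln$end0 - aln$start0 + 1L == sp[1],
              aln$end1 - aln$start1 + 1L == sp[2])
    if (!is.null(s0)) {
      stopifnot(paste(aln$top[aln$top != "-"], collapse = "") ==
                  substr(s0$residues, aln$start0, aln$end0))
    }
    if (!is.null(s1)) {
      stopifnot(paste(aln$bottom[aln$bottom != "-"], collapse = "") ==
                  substr(s1$residues, aln$start1, aln$end1))
    }
  }
  stopifnot(isTRUE(all.equal(score_alignment(aln, scheme), aln$score)))
  invisible(TRUE)
}
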