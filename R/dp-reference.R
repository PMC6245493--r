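# Quadratic-space reference kernels with full traceback: Needleman-Wunsch
# global, Smith-Waterman local, and Gotoh affine-gap alignment, plus
# exhaustive enumeration of co-optimal local alignments. These are the truth
# oracles the linear-space and pipeline modules are tested against.

ARROW_DIAG <- 1L; ARROW_UP <- 2L; ARROW_LEFT <- 4L; ARROW_STOP <- 8L

# shared fill; returns a dp_matrices object
dp_fill <- function(s0, s1, scheme, mode) {
  s0 <- as_dna_sequence(s0, "S0"); s1 <- as_dna_sequence(s1, "S1")
  enc <- encode_pair(s0, s1, scheme)
  go <- scheme_open(scheme); ge <- scheme_extend(scheme)
  m <- s0$length; n <- s1$length
  local <- identical(mode, "local")
  if (local) {
    top_H <- rep(0, n + 1L); left_H <- rep(0, m + 1L)
  } else {
    top_H <- boundary_gamma(n, go, ge); left_H <- boundary_gamma(m, go, ge)
  }
  mats <- box_fill(enc$c0, enc$c1, enc$S, go, ge, mode,
                   top_H = top_H, top_F = rep(NEG_INF, n + 1L),
                   left_H = left_H, left_E = rep(NEG_INF, m + 1L))
  arrows <- dp_arrows(mats, enc, go, ge, mode)
  dp <- structure(
    list(H = mats$H,
         E = if (scheme$gap_model == "affine") mats$E else NULL,
         F = if (scheme$gap_model == "affine") mats$F else NULL,
         arrows = arrows, m = m, n = n, mode = mode,
         gap_model = scheme$gap_model,
         s0 = s0, s1 = s1, scheme = scheme, enc = enc),
    class = "dp_matrices"
  )
  if (scheme$gap_model == "linear") {
    # the gap matrices are an internal detail of the linear kernels (the
    # recurrence is H-only) but the shared traceback machine still uses them
    attr(dp, "Efull") <- mats$E
    attr(dp, "Ffull") <- mats$F
  }
  dp
}

# per-cell arrow provenance (bitmask): every predecessor attaining the cell
# value; "stop" marks local cells whose value is the zero branch
dp_arrows <- function(mats, enc, go, ge, mode) {
  H <- mats$H; E <- mats$E; Fm <- mats$F
  m <- length(enc$c0); n <- length(enc$c1)
  A <- matrix(0L, m + 1L, n + 1L)
  if (m > 0L && n > 0L) {
    P <- enc$S[enc$c0, enc$c1, drop = FALSE]
    core <- H[2:(m + 1L), 2:(n + 1L), drop = FALSE]
    A[2:(m + 1L), 2:(n + 1L)] <-
      ARROW_DIAG * (core == H[1:m, 1:n, drop = FALSE] + P) +
      ARROW_UP   * (core == Fm[2:(m + 1L), 2:(n + 1L), drop = FALSE]) +
      ARROW_LEFT * (core == E[2:(m + 1L), 2:(n + 1L), drop = FALSE])
  }
  if (identical(mode, "local")) {
    A[H == 0] <- bitwOr(A[H == 0], ARROW_STOP)
  } else {
    if (m > 0L) A[2:(m + 1L), 1L] <- ARROW_UP
    if (n > 0L) A[1L, 2:(n + 1L)] <- ARROW_LEFT
  }
  A
}

#' @export
print.dp_matrices <- function(x, ...) {
  cat(sprintf("<dp_matrices> %s/%s, %d x %d cells, optimal %g\n",
              x$mode, x$gap_model, x$m, x$n,
              if (x$mode == "local") max(x$H) else x$H[x$m + 1L, x$n + 1L]))
  invisible(x)
}

# alignment from a filled dp_matrices object via the canonical greedy walk
dp_traceback <- function(dp, end_i, end_j) {
  go <- scheme_open(dp$scheme); ge <- scheme_extend(dp$scheme)
  mats <- list(H = dp$H,
               E = if (is.null(dp$E)) attr(dp, "Efull") else dp$E,
               F = if (is.null(dp$F)) attr(dp, "Ffull") else dp$F)
  wk <- walk_box(mats, dp$enc$c0, dp$enc$c1, dp$enc$S, go, ge, dp$mode,
                 end_i, end_j, "H")
  moves <- wk$moves
  if (dp$mode == "global") {
    if (wk$reason == "top" && wk$j > 0L) moves <- c(rep("left", wk$j), moves)
    if (wk$reason == "left" && wk$i > 0L) moves <- c(rep("up", wk$i), moves)
    i0 <- 0L; j0 <- 0L
  } else {
    i0 <- wk$i; j0 <- wk$j
  }
  ch0 <- strsplit(dp$s0$residues, "")[[1]]
  ch1 <- strsplit(dp$s1$residues, "")[[1]]
  cols <- moves_to_columns(ch0, ch1, moves, i0, j0)
  score <- dp$H[end_i + 1L, end_j + 1L]
  if (length(moves) == 0L) {
    return(new_alignment(character(0), character(0), score, 0L, 0L, 0L, 0L,
                         dp$mode, dp$gap_model))
  }
  # empty intervals come out as (i0+1, i0), keeping span == end - start + 1
  new_alignment(cols$top, cols$bottom, score,
                start0 = i0 + 1L, end0 = cols$i_end,
                start1 = j0 + 1L, end1 = cols$j_end,
                mode = dp$mode, gap_model = dp$gap_model)
}

#' Needleman-Wunsch global fill
#'
#' Fills the (m+1) x (n+1) dynamic-programming matrix of the global linear-gap
#' recurrence: boundary `H[i,0] = -G*i`, `H[0,j] = -G*j`, interior cell the
#' maximum of the diagonal plus substitution score and the two gap moves.
#' Arrow provenance records every maximizing predecessor of every cell.
#'
#' @param s0,s1 [dna_sequence()] objects (or plain residue strings).
#' @param scheme A linear-gap [scoring_scheme()].
#' @return A `dp_matrices` object with fields `H`, `arrows`, `m`, `n`.
#' @export
nw_fill <- function(s0, s1, scheme = scoring_scheme()) {
  if (scheme$gap_model != "linear") {
    stop("wrong-kernel error: nw_fill requires a linear gap scheme (use gotoh_fill)")
  }
  dp_fill(s0, s1, scheme, "global")
}

#' Needleman-Wunsch global alignment
#'
#' Fills the global matrix and walks the arrows back from `H[m,n]` to the
#' origin. Where several arrows attain the maximum the preference order is
#' diagonal > up > left, so the result is deterministic.
#'
#' @inheritParams nw_fill
#' @return An [new_alignment()] with `score == H[m,n]`.
#' @export
nw_align <- function(s0, s1, scheme = scoring_scheme()) {
  if (scheme$gap_model != "linear") {
    stop("wrong-kernel error: nw_align requires a linear gap scheme (use gotoh_align)")
  }
  dp <- dp_fill(s0, s1, scheme, "global")
  dp_traceback(dp, dp$m, dp$n)
}

#' Smith-Waterman local fill
#'
#' Same recurrence as [nw_fill()] plus a zero branch: negative values are
#' clamped to zero and the boundary row/column are zero, so every cell is
#' non-negative. Cells whose value is the zero branch carry a "stop" arrow.
#'
#' @inheritParams nw_fill
#' @return A `dp_matrices` object.
#' @export
sw_fill <- function(s0, s1, scheme = scoring_scheme()) {
  if (scheme$gap_model != "linear") {
    stop("wrong-kernel error: sw_fill requires a linear gap scheme (use gotoh_fill)")
  }
  dp_fill(s0, s1, scheme, "local")
}

#' Best cell(s) of a local fill
#'
#' The exact maximum of `H` and all cells attaining it, in row-major order.
#' A maximum of zero means no positive-scoring local alignment exists; by
#' convention the result is then score 0 with no cells (the empty alignment).
#'
#' @param dp A local-mode `dp_matrices` object.
#' @return `list(score =, cells =)` where `cells` is a two-column matrix of
#'   (i, j) coordinates.
#' @export
sw_best <- function(dp) {
  stopifnot(inherits(dp, "dp_matrices"), dp$mode == "local")
  mx <- max(dp$H)
  if (mx == 0) {
    return(list(score = 0, cells = matrix(integer(0), 0L, 2L,
                                          dimnames = list(NULL, c("i", "j")))))
  }
  idx <- which(dp$H == mx, arr.ind = TRUE) - 1L
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  list(score = mx, cells = idx)
}

# canonical end cell: highest score, ties broken by smallest i+j then i
sw_best_cell <- function(dp) {
  b <- sw_best(dp)
  if (b$score == 0) return(NULL)
  cells <- b$cells
  key <- order(cells[, 1L] + cells[, 2L], cells[, 1L])
  list(score = b$score, i = cells[key[1L], 1L], j = cells[key[1L], 2L])
}

#' Smith-Waterman local alignment
#'
#' Traceback from the best cell (ties: smallest i+j, then smallest i) until a
#' zero-valued cell is reached, with arrow preference diagonal > up > left.
#'
#' @inheritParams nw_fill
#' @return An [new_alignment()]; the empty alignment (score 0) when no
#'   positive-scoring pair of segments exists.
#' @export
sw_align <- function(s0, s1, scheme = scoring_scheme()) {
  if (scheme$gap_model != "linear") {
    stop("wrong-kernel error: sw_align requires a linear gap scheme (use gotoh_align)")
  }
  dp <- dp_fill(s0, s1, scheme, "local")
  best <- sw_best_cell(dp)
  if (is.null(best)) {
    return(new_alignment(character(0), character(0), 0, 0L, 0L, 0L, 0L,
                         "local", scheme$gap_model))
  }
  dp_traceback(dp, best$i, best$j)
}

#' Gotoh affine-gap fill
#'
#' Fills the three matrices of the affine-gap recurrences: `H` (best score),
#' `E` (best score ending in a horizontal gap) and `F` (vertical gap), with a
#' gap run of length x charged `gap_open + (x-1)*gap_extend`. Global mode
#' initializes the boundaries with run costs and takes the optimum at the
#' last cell; local mode adds the zero branch to `H` and zero boundaries.
#'
#' @inheritParams nw_fill
#' @param scheme An affine [scoring_scheme()].
#' @param mode `"global"` or `"local"`.
#' @return A `dp_matrices` object with `H`, `E`, `F` and arrows.
#' @export
gotoh_fill <- function(s0, s1, scheme, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (scheme$gap_model != "affine") {
    stop("wrong-kernel error: gotoh_fill requires an affine gap scheme")
  }
  dp_fill(s0, s1, scheme, mode)
}

#' Gotoh affine-gap alignment
#'
#' Traceback follows matrix `H` for matches/mismatches and switches into `E`
#' or `F` to track gap runs; ties are resolved diagonal > `F` (up) > `E`
#' (left), and inside a gap run closing the gap is preferred to extending it.
#'
#' @inheritParams gotoh_fill
#' @return An [new_alignment()].
#' @export
gotoh_align <- function(s0, s1, scheme, mode = c("global", "local")) {
  mode <- match.arg(mode)
  dp <- gotoh_fill(s0, s1, scheme, mode)
  if (mode == "global") return(dp_traceback(dp, dp$m, dp$n))
  best <- sw_best_cell(dp)
  if (is.null(best)) {
    return(new_alignment(character(0), character(0), 0, 0L, 0L, 0L, 0L,
                         "local", scheme$gap_model))
  }
  dp_traceback(dp, best$i, best$j)
}

#' Enumerate all co-optimal local alignments
#'
#' Starts a traceback at every cell attaining the maximum score and branches
#' on every maximizing arrow (through the gap matrices in affine mode),
#' stopping at zero cells; identical column lists are deduplicated. Intended
#' for toy-scale inputs: the product of the sequence lengths is guarded.
#'
#' @inheritParams nw_fill
#' @param scheme Any [scoring_scheme()].
#' @param max_cells Size guard on `m * n` (default `1e5`).
#' @return List of [new_alignment()] objects (empty when the best score is 0).
#' @export
enumerate_optimal_local <- function(s0, s1, scheme = scoring_scheme(),
                                    max_cells = 1e5) {
  s0 <- as_dna_sequence(s0, "S0"); s1 <- as_dna_sequence(s1, "S1")
  if (s0$length * s1$length > max_cells) {
    stop("size error: enumerate_optimal_local is guarded to m*n <= ", max_cells)
  }
  dp <- dp_fill(s0, s1, scheme, "local")
  best <- sw_best(dp)
  if (best$score == 0) return(list())
  H <- dp$H
  E <- if (is.null(dp$E)) attr(dp, "Efull") else dp$E
  Fm <- if (is.null(dp$F)) attr(dp, "Ffull") else dp$F
  go <- scheme_open(scheme); ge <- scheme_extend(scheme)
  enc <- dp$enc
  ch0 <- strsplit(s0$residues, "")[[1]]
  ch1 <- strsplit(s1$residues, "")[[1]]
  results <- list()
  # depth-first branch on (cell, state); moves collected backward
  branch <- function(i, j, state, moves) {
    if (state == "H") {
      hv <- H[i + 1L, j + 1L]
      if (hv == 0) {
        cols <- moves_to_columns(ch0, ch1, rev(moves), i, j)
        aln <- new_alignment(cols$top, cols$bottom, best$score,
                             i + 1L, cols$i_end, j + 1L, cols$j_end,
                             "local", scheme$gap_model)
        results[[length(results) + 1L]] <<- aln
        return(invisible())
      }
      if (i > 0L && j > 0L && hv == H[i, j] + enc$S[enc$c0[i], enc$c1[j]]) {
        branch(i - 1L, j - 1L, "H", c(moves, "diag"))
      }
      if (hv == Fm[i + 1L, j + 1L]) branch(i, j, "F", moves)
      if (hv == E[i + 1L, j + 1L]) branch(i, j, "E", moves)
    } else if (state == "F") {
      fv <- Fm[i + 1L, j + 1L]
      if (i > 0L && fv == H[i, j + 1L] - go) branch(i - 1L, j, "H", c(moves, "up"))
      # under the linear model (open == extend) the extension branch repeats
      # the close branch move-for-move, so it is only followed when affine
      if (go != ge && i > 0L && fv == Fm[i, j + 1L] - ge) {
        branch(i - 1L, j, "F", c(moves, "up"))
      }
    } else {
      ev <- E[i + 1L, j + 1L]
      if (j > 0L && ev == H[i + 1L, j] - go) branch(i, j - 1L, "H", c(moves, "left"))
      if (j > 0L && ev == E[i + 1L, j] - ge && go != ge) branch(i, j - 1L, "E", c(moves, "left"))
    }
    invisible()
  }
  cells <- best$cells
  for (r in seq_len(nrow(cells))) {
    branch(cells[r, 1L], cells[r, 2L], "H", character(0))
  }
  keys <- vapply(results, function(a) {
    paste(a$start0, a$start1, paste(a$top, collapse = ""),
          paste(a$bottom, collapse = ""), sep = "|")
  }, character(1))
  results[!duplicated(keys)]
}
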