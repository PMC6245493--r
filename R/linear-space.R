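# Linear-space alignment: Hirschberg divide and conquer with the
# Myers-Miller affine-gap extension. The matrix is never materialized:
# forward and reverse passes keep one column of state each, the midpoint is
# found by matching the two middle-row vectors, and the recursion bottoms
# out in small quadratic boxes.

# forward fill of rows 1..i_star collecting the middle row; returns CC/DD
# over j = 0..n. waive_open: a vertical run entering through the top-left
# corner pays extensions only (junction plumbing, see align_box_flags).
mm_forward <- function(c0_prefix, c1, S, go, ge, waive_open = FALSE) {
  m <- length(c0_prefix); n <- length(c1)
  if (m == 0L) {
    CC <- c(0, if (n > 0L) -(go + (0:(n - 1L)) * ge))
    return(list(CC = CC, DD = rep(NEG_INF, n + 1L)))
  }
  h_in <- boundary_gamma(m, go, ge, waive_open = waive_open)
  fl <- fill_columns(c0_prefix, c1, S, go, ge, "global",
                     h_in = h_in, e_in = rep(NEG_INF, m + 1L),
                     spec_rows = m)
  bnd <- h_in[m + 1L]  # column 0: the all-vertical-gap path
  list(CC = c(bnd, fl$spec_H[1L, ]), DD = c(bnd, fl$spec_F[1L, ]))
}

#' Forward score vectors to a middle row
#'
#' `CC[j+1]` is the best global score of aligning a prefix of S0 against
#' `S1[1..j]`; `DD[j+1]` is the same restricted to paths that end in a
#' vertical gap run (a run of S0 residues against gaps). Computed in memory
#' proportional to `n`, never materializing the matrix.
#'
#' @param s0_prefix The S0 prefix (a [dna_sequence()] or string).
#' @param s1 The full S1.
#' @param scheme A [scoring_scheme()].
#' @return `list(CC =, DD =)`, numeric vectors of length `n + 1`.
#' @export
forward_vectors <- function(s0_prefix, s1, scheme) {
  s0_prefix <- as_dna_sequence(s0_prefix, "S0"); s1 <- as_dna_sequence(s1, "S1")
  enc <- encode_pair(s0_prefix, s1, scheme)
  mm_forward(enc$c0, enc$c1, enc$S, scheme_open(scheme), scheme_extend(scheme))
}

#' Reverse score vectors from a middle row
#'
#' Mirror of [forward_vectors()] computed over the reversed sequences:
#' `RR[x+1]` is the best score of aligning the S0 suffix against the last `x`
#' residues of S1, and `SS[x+1]` the same restricted to paths that begin with
#' a vertical gap run.
#'
#' @param s0_suffix The S0 suffix.
#' @inheritParams forward_vectors
#' @return `list(RR =, SS =)`, numeric vectors of length `n + 1`.
#' @export
reverse_vectors <- function(s0_suffix, s1, scheme) {
  s0_suffix <- as_dna_sequence(s0_suffix, "S0"); s1 <- as_dna_sequence(s1, "S1")
  enc <- encode_pair(s0_suffix, s1, scheme)
  out <- mm_forward(rev(enc$c0), rev(enc$c1), enc$S,
                    scheme_open(scheme), scheme_extend(scheme))
  list(RR = out$CC, SS = out$DD)
}

# midpoint matching shared by the public op and the recursion. Returns the
# smallest maximizing j and whether the optimum merges a vertical gap run
# across the middle row (type 2). DD/SS both charge a full gap opening, so
# merging a run refunds one opening minus one extension: gamma(x1) +
# gamma(x2) == gamma(x1 + x2) + (G_open - G_ext).
mm_match <- function(CC, DD, RRr, SSr, go, ge) {
  n <- length(CC) - 1L
  v1 <- CC + rev(RRr)
  v2 <- DD + rev(SSr) + (go - ge)
  v <- pmax(v1, v2)
  j <- which.max(v) - 1L   # smallest j on ties
  list(j_star = j, value = v[j + 1L], type2 = v2[j + 1L] > v1[j + 1L])
}

#' Midpoint of an optimal global alignment
#'
#' Matches the forward vectors of the top half against the reverse vectors of
#' the bottom half on the middle row `i* = floor(m/2)`: the midpoint
#' `(i*, j*)` maximizes either `CC(j) + RR(n-j)` (the path crosses the middle
#' row in match state) or `DD(j) + SS(n-j) + (G_open - G_ext)` (a vertical
#' gap run spans the middle row; the refund keeps the opening charged once).
#' The achieved maximum is the optimal global score and the midpoint lies on
#' an optimal path. Ties take the smallest `j*`.
#'
#' @inheritParams forward_vectors
#' @param s0,s1 Sequences; `length(s0) >= 2` required.
#' @return `list(i_star =, j_star =, value =, type2 =)`.
#' @export
mm_midpoint <- function(s0, s1, scheme) {
  s0 <- as_dna_sequence(s0, "S0"); s1 <- as_dna_sequence(s1, "S1")
  if (s0$length < 2L) {
    stop("base-case error: mm_midpoint needs m >= 2 (solve small problems directly)")
  }
  enc <- encode_pair(s0, s1, scheme)
  go <- scheme_open(scheme); ge <- scheme_extend(scheme)
  i_star <- s0$length %/% 2L
  fwd <- mm_forward(enc$c0[seq_len(i_star)], enc$c1, enc$S, go, ge)
  rv <- mm_forward(rev(enc$c0[(i_star + 1L):s0$length]), rev(enc$c1), enc$S, go, ge)
  mt <- mm_match(fwd$CC, fwd$DD, rv$CC, rv$DD, go, ge)
  list(i_star = i_star, j_star = mt$j_star, value = mt$value, type2 = mt$type2)
}

# recursive Myers-Miller: returns the move list of one optimal global
# alignment of c0 vs c1 under the junction flags
mm_recurse <- function(c0, c1, S, go, ge, open_top, end_vgap, base_area) {
  M <- length(c0); N <- length(c1)
  if (M <= 1L || N == 0L || (M + 1) * (N + 1) <= base_area) {
    return(align_box_flags(c0, c1, S, go, ge, open_top, end_vgap)$moves)
  }
  i_star <- M %/% 2L
  fwd <- mm_forward(c0[seq_len(i_star)], c1, S, go, ge, waive_open = open_top)
  rv <- mm_forward(rev(c0[(i_star + 1L):M]), rev(c1), S, go, ge,
                   waive_open = end_vgap)
  mt <- mm_match(fwd$CC, fwd$DD, rv$CC, rv$DD, go, ge)
  j_star <- mt$j_star
  upper <- mm_recurse(c0[seq_len(i_star)], c1[seq_len(j_star)], S, go, ge,
                      open_top, mt$type2, base_area)
  lower <- mm_recurse(c0[(i_star + 1L):M],
                      if (j_star < N) c1[(j_star + 1L):N] else integer(0),
                      S, go, ge, mt$type2, end_vgap, base_area)
  c(upper, lower)
}

#' Linear-space optimal alignment
#'
#' Divide-and-conquer alignment in memory proportional to the shorter
#' problem dimension: the midpoint of the middle row splits the problem in
#' two until subproblems are small enough (`base_case_area` cells) to solve
#' by direct quadratic DP. Global mode aligns the full sequences; local mode
#' first locates the optimal end cell with a linear-memory local fill, then
#' the start cell with a reverse fill, and aligns the bounded subproblem
#' globally. Scores are identical to the quadratic-space kernels.
#'
#' @inheritParams forward_vectors
#' @param s0,s1 Sequences.
#' @param mode `"global"` or `"local"`.
#' @param base_case_area Subproblems with at most this many cells go to
#'   direct DP (default 4096).
#' @return An [new_alignment()].
#' @export
linear_align <- function(s0, s1, scheme = scoring_scheme(),
                         mode = c("global", "local"), base_case_area = 4096) {
  mode <- match.arg(mode)
  s0 <- as_dna_sequence(s0, "S0"); s1 <- as_dna_sequence(s1, "S1")
  enc <- encode_pair(s0, s1, scheme)
  go <- scheme_open(scheme); ge <- scheme_extend(scheme)
  ch0 <- strsplit(s0$residues, "")[[1]]
  ch1 <- strsplit(s1$residues, "")[[1]]
  m <- s0$length; n <- s1$length
  if (mode == "global") {
    moves <- mm_recurse(enc$c0, enc$c1, enc$S, go, ge, FALSE, FALSE,
                        base_case_area)
    cols <- moves_to_columns(ch0, ch1, moves, 0L, 0L)
    aln <- new_alignment(cols$top, cols$bottom, 0, 1L, m, 1L, n,
                         "global", scheme$gap_model)
    aln$score <- score_alignment(aln, scheme)
    return(aln)
  }
  # local: end cell by forward linear-memory local fill; start cell by a
  # *global* reverse fill over the bounded prefix pair, which only scores
  # paths anchored at the end cell (an optimal local path never starts or
  # ends with a gap, so its start shows up as the reverse maximum)
  empty <- new_alignment(character(0), character(0), 0, 0L, 0L, 0L, 0L,
                         "local", scheme$gap_model)
  if (m == 0L || n == 0L) return(empty)
  fwd <- fill_columns(enc$c0, enc$c1, enc$S, go, ge, "local",
                      h_in = rep(0, m + 1L), e_in = rep(NEG_INF, m + 1L),
                      track_best = TRUE)
  if (fwd$best$score <= 0) return(empty)
  i_e <- fwd$best$i; j_e <- fwd$best$j; opt <- fwd$best$score
  c0p <- rev(enc$c0[seq_len(i_e)]); c1p <- rev(enc$c1[seq_len(j_e)])
  rv <- fill_columns(c0p, c1p, enc$S, go, ge, "global",
                     h_in = boundary_gamma(i_e, go, ge),
                     e_in = rep(NEG_INF, i_e + 1L),
                     track_best = TRUE)
  stopifnot(rv$best$score == opt)
  i_s <- i_e - rv$best$i + 1L; j_s <- j_e - rv$best$j + 1L
  moves <- mm_recurse(enc$c0[i_s:i_e], enc$c1[j_s:j_e], enc$S, go, ge,
                      FALSE, FALSE, base_case_area)
  cols <- moves_to_columns(ch0, ch1, moves, i_s - 1L, j_s - 1L)
  new_alignment(cols$top, cols$bottom, opt, i_s, i_e, j_s, j_e,
                "local", scheme$gap_model)
}
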