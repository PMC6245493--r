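# Wavefront (anti-diagonal) evaluation over a column band. A band is the
# column range one worker owns: it receives the exact DP column to its left
# (a border column), sweeps its columns keeping two columns of state, emits
# its right border column, and checkpoints "special rows" every k rows for
# the later traceback stages. Chained bands reproduce the monolithic matrix
# bit-exactly because integer arithmetic is exact and the evaluation order
# respects the anti-diagonal dependency structure.

#' Anti-diagonal schedule of a DP matrix
#'
#' Cells of an m x n matrix grouped by anti-diagonal: diagonal `d` holds all
#' cells `(i, j)` with `i + j - 1 == d`. Cells on one diagonal depend only on
#' the two previous diagonals, so they can be computed in parallel; counts
#' rise `1..min(m, n)`, plateau, and fall back to 1 over `m + n - 1`
#' diagonals.
#'
#' @param m,n Positive matrix dimensions (residue rows/columns).
#' @return List of two-column matrices (`i`, `j`), one per diagonal.
#' @examples
#' length(antidiagonal_schedule(5, 9))       # 13 diagonals
#' @export
antidiagonal_schedule <- function(m, n) {
  stopifnot(m >= 1L, n >= 1L)
  lapply(seq_len(m + n - 1L), function(d) {
    i <- max(1L, d - n + 1L):min(m, d)
    cbind(i = i, j = d - i + 1L)
  })
}

#' Maximum wavefront parallelism
#'
#' The largest number of cells on any anti-diagonal: `min(m, n)`.
#'
#' @inheritParams antidiagonal_schedule
#' @return Integer.
#' @export
max_parallelism <- function(m, n) {
  stopifnot(m >= 1L, n >= 1L)
  min(m, n)
}

# constructors for the dataflow records exchanged between bands
new_border_column <- function(partition, j, H, E = NULL) {
  structure(list(partition = partition, j = j, H = H, E = E),
            class = "border_column")
}

new_special_rows <- function(partition, j_lo, j_hi, k, rows, H, F) {
  structure(list(partition = partition, j_lo = j_lo, j_hi = j_hi, k = k,
                 rows = rows, H = H, F = F),
            class = "special_rows")
}

#' @export
print.border_column <- function(x, ...) {
  cat(sprintf("<border_column> partition %d, column %d, %d rows\n",
              x$partition, x$j, length(x$H) - 1L))
  invisible(x)
}

#' @export
print.special_rows <- function(x, ...) {
  cat(sprintf("<special_rows> partition %d, columns %d..%d, rows {%s}\n",
              x$partition, x$j_lo, x$j_hi,
              paste(x$rows, collapse = ", ")))
  invisible(x)
}

# special-row positions: every k-th row plus the last row
special_row_set <- function(m, k) {
  if (m == 0L) return(integer(0))
  base <- if (k <= m) seq.int(k, m, by = k) else integer(0)
  sort(unique(c(base, m)))
}

# default checkpoint interval
default_interval <- function(m) max(1L, as.integer(ceiling(m / 100)))

#' Fill one column band and emit its border column
#'
#' Computes the DP values of the columns `j_lo..j_hi` of the monolithic
#' matrix in memory proportional to `m`, given the exact column `j_lo - 1`
#' as input border (or the global boundary for the first band). Emits the
#' exact column `j_hi` (H, and the horizontal-gap values E so affine runs
#' crossing the border stay exact), checkpoints the H and vertical-gap F
#' values of every special row over the band's columns, and tracks the
#' band's best cell (local mode).
#'
#' @param s0 The full S0 ([dna_sequence()] or string).
#' @param s1_band The band's slice of S1.
#' @param scheme A [scoring_scheme()].
#' @param mode `"global"` or `"local"`.
#' @param in_border A `border_column` for column `j_lo - 1`, or `NULL` for
#'   the global boundary (then `j_lo` must be 1).
#' @param k Special-row interval in rows; default `ceiling(m / 100)`.
#' @param j_lo 1-based first absolute column of the band.
#' @param partition Worker index owning the band (bookkeeping only).
#' @return `list(out_border =, specials =, local_best =)`.
#' @export
band_fill <- function(s0, s1_band, scheme = scoring_scheme(),
                      mode = c("local", "global"), in_border = NULL,
                      k = NULL, j_lo = if (is.null(in_border)) 1L else in_border$j + 1L,
                      partition = 0L) {
  mode <- match.arg(mode)
  s0 <- as_dna_sequence(s0, "S0"); s1_band <- as_dna_sequence(s1_band, "S1")
  enc <- encode_pair(s0, s1_band, scheme)
  go <- scheme_open(scheme); ge <- scheme_extend(scheme)
  m <- s0$length; w <- s1_band$length
  stopifnot(m >= 1L, w >= 1L)
  if (is.null(k)) k <- default_interval(m)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (is.null(in_border)) {
    if (j_lo != 1L) stop("dataflow error: missing in_border for an interior band")
    h_in <- if (mode == "local") rep(0, m + 1L) else boundary_gamma(m, go, ge)
    e_in <- rep(NEG_INF, m + 1L)
  } else {
    if (length(in_border$H) != m + 1L) {
      stop("dataflow error: in_border length does not match m + 1")
    }
    h_in <- in_border$H
    e_in <- if (is.null(in_border$E)) rep(NEG_INF, m + 1L) else in_border$E
    if (j_lo != in_border$j + 1L) {
      stop("dataflow error: in_border is not the column left of the band")
    }
  }
  rows <- special_row_set(m, k)
  fl <- fill_columns(enc$c0, enc$c1, enc$S, go, ge, mode,
                     h_in = h_in, e_in = e_in, spec_rows = rows,
                     track_best = TRUE, j_offset = j_lo - 1L)
  list(
    out_border = new_border_column(partition, j_lo + w - 1L, fl$h, fl$e),
    specials = new_special_rows(partition, j_lo, j_lo + w - 1L, k, rows,
                                fl$spec_H, fl$spec_F),
    local_best = fl$best
  )
}
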