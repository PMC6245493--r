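# Internal DP engine.
#
# All kernels in the package reduce to the affine Gotoh recurrences
#   E(i,j) = max(E(i,j-1) - Ge, H(i,j-1) - Go)          horizontal gap
#   F(i,j) = max(F(i-1,j) - Ge, H(i-1,j) - Go)          vertical gap
#   H(i,j) = max(H(i-1,j-1) + p(i,j), E(i,j), F(i,j)[, 0 in local mode])
# with the linear model as the special case Go == Ge == G (a run of x gaps
# then costs exactly x*G). Values are kept as doubles holding exact integers
# (-Inf is the unreachable-state sentinel), so all comparisons are exact.
#
# The fills sweep columns. Within a column the vertical-gap matrix F couples
# rows, but because Go >= Ge it satisfies
#   F(i,j) = max_{t < i} ( Hpre(t,j) - Go - (i-1-t)*Ge )
# where Hpre is H before the F contribution (H = max(Hpre, F)), which is a
# running-max scan: F = cummax(Hpre + t*Ge) - Go - (i-1)*Ge. This makes every
# column a handful of vectorized operations, i.e. wavefront-style evaluation
# with the dependency order of the anti-diagonal schedule.

NEG_INF <- -Inf

# left/top boundary builders (global mode); waive_open replaces the opening
# penalty by an extension on the boundary run (a gap run continuing across a
# subproblem junction must not pay the opening twice)
boundary_gamma <- function(len, go, ge, waive_open = FALSE) {
  if (len == 0L) return(0)
  run <- if (waive_open) (1:len) * ge else go + (0:(len - 1L)) * ge
  c(0, -run)
}

# One pass over a column band in linear memory.
#
# c0: integer codes of S0 (rows 1..m); c1cols: codes of the band's columns;
# h_in/e_in: exact H and E values of the column left of the band (rows 0..m);
# spec_rows: rows whose H and F values are checkpointed; track_best: record
# the band's maximum H with the (score, i+j, i) tie-break, j_offset being the
# absolute column of the band's first column minus one.
fill_columns <- function(c0, c1cols, S, go, ge, mode,
                         h_in, e_in,
                         spec_rows = integer(0),
                         track_best = FALSE, j_offset = 0L) {
  m <- length(c0)
  w <- length(c1cols)
  stopifnot(length(h_in) == m + 1L, length(e_in) == m + 1L)
  local <- identical(mode, "local")
  geseq <- (0:(m - 1L)) * ge
  nsp <- length(spec_rows)
  spH <- if (nsp) matrix(NA_real_, nsp, w) else NULL
  spF <- if (nsp) matrix(NA_real_, nsp, w) else NULL
  best <- list(score = NEG_INF, i = NA_integer_, j = NA_integer_)
  H <- h_in; E <- e_in
  rows1 <- 2:(m + 1L)
  for (jj in seq_len(w)) {
    Enew <- pmax(E - ge, H - go)
    pcol <- unname(S[c0, c1cols[jj]])
    Hd <- H[1:m] + pcol
    pre <- pmax(Hd, Enew[rows1])
    if (local) pre <- pmax(pre, 0)
    top <- if (local) 0 else Enew[1L]
    z <- if (m > 1L) c(top, pre[1:(m - 1L)]) else top
    Fv <- cummax(z + geseq) - go - geseq
    Hrows <- pmax(pre, Fv)
    Hnew <- c(top, Hrows)
    if (nsp) {
      spH[, jj] <- Hnew[spec_rows + 1L]
      spF[, jj] <- Fv[spec_rows]
    }
    if (track_best) {
      mx <- max(Hrows)
      if (mx > NEG_INF) {
        i <- which.max(Hrows)           # smallest row on ties
        jab <- j_offset + jj
        if (mx > best$score ||
            (mx == best$score && (i + jab < best$i + best$j ||
                                  (i + jab == best$i + best$j && i < best$i)))) {
          best <- list(score = mx, i = i, j = jab)
        }
      }
    }
    H <- Hnew; E <- Enew
  }
  list(h = H, e = E, spec_H = spH, spec_F = spF,
       spec_rows = spec_rows, best = best)
}

# Full H/E/F matrices of a box whose top row and left column carry exact
# boundary values (global boundaries, a checkpointed special row, or a saved
# border column). Matrix index [i+1, j+1] is cell (i, j), box-local.
box_fill <- function(c0, c1, S, go, ge, mode,
                     top_H, top_F, left_H, left_E) {
  h <- length(c0); w <- length(c1)
  stopifnot(length(top_H) == w + 1L, length(top_F) == w + 1L,
            length(left_H) == h + 1L, length(left_E) == h + 1L)
  local <- identical(mode, "local")
  H <- matrix(NEG_INF, h + 1L, w + 1L)
  E <- matrix(NEG_INF, h + 1L, w + 1L)
  Fm <- matrix(NEG_INF, h + 1L, w + 1L)
  H[, 1L] <- left_H; E[, 1L] <- left_E
  H[1L, ] <- top_H;  Fm[1L, ] <- top_F
  if (h == 0L || w == 0L) return(list(H = H, E = E, F = Fm))
  geseq <- (0:(h - 1L)) * ge
  iext <- (1:h) * ge
  rows1 <- 2:(h + 1L)
  for (j in seq_len(w)) {
    Ecol <- pmax(E[, j] - ge, H[, j] - go)
    pcol <- unname(S[c0, c1[j]])
    Hd <- H[1:h, j] + pcol
    pre <- pmax(Hd, Ecol[rows1])
    if (local) pre <- pmax(pre, 0)
    z <- if (h > 1L) c(top_H[j + 1L], pre[1:(h - 1L)]) else top_H[j + 1L]
    Fcol <- pmax(cummax(z + geseq) - go - geseq, top_F[j + 1L] - iext)
    Hrows <- pmax(pre, Fcol)
    H[rows1, j + 1L] <- Hrows
    E[, j + 1L] <- Ecol
    Fm[rows1, j + 1L] <- Fcol
  }
  list(H = H, E = E, F = Fm)
}

# Canonical greedy traceback over a filled box, walked backward from
# (start_i, start_j) in start_state. Arrow preference is diagonal > up >
# left; inside a gap state the gap is closed in preference to extended. The
# walk stops when it reaches the box's top row ("top"), left column
# ("left"), the origin ("origin"), or -- in local mode -- a zero-valued H
# cell in match state ("zero"). Returns the moves in forward order.
walk_box <- function(mats, c0, c1, S, go, ge, mode,
                     start_i, start_j, start_state = "H") {
  H <- mats$H; E <- mats$E; Fm <- mats$F
  local <- identical(mode, "local")
  i <- start_i; j <- start_j; state <- start_state
  moves <- character(0)
  nm <- 0L
  repeat {
    if (i == 0L && j == 0L) { reason <- "origin"; break }
    if (i == 0L) { reason <- "top"; break }
    if (j == 0L) { reason <- "left"; break }
    if (state == "H") {
      hv <- H[i + 1L, j + 1L]
      if (local && hv == 0) { reason <- "zero"; break }
      if (hv == H[i, j] + S[c0[i], c1[j]]) {
        nm <- nm + 1L; moves[nm] <- "diag"; i <- i - 1L; j <- j - 1L
      } else if (hv == Fm[i + 1L, j + 1L]) {
        state <- "F"
      } else if (hv == E[i + 1L, j + 1L]) {
        state <- "E"
      } else {
        stop("traceback integrity error: no arrow matches (corrupt checkpoint?)")
      }
    } else if (state == "F") {
      fv <- Fm[i + 1L, j + 1L]
      if (fv == H[i, j + 1L] - go) {
        nm <- nm + 1L; moves[nm] <- "up"; i <- i - 1L; state <- "H"
      } else if (fv == Fm[i, j + 1L] - ge) {
        nm <- nm + 1L; moves[nm] <- "up"; i <- i - 1L
      } else {
        stop("traceback integrity error: no arrow matches (corrupt checkpoint?)")
      }
    } else {
      ev <- E[i + 1L, j + 1L]
      if (ev == H[i + 1L, j] - go) {
        nm <- nm + 1L; moves[nm] <- "left"; j <- j - 1L; state <- "H"
      } else if (ev == E[i + 1L, j] - ge) {
        nm <- nm + 1L; moves[nm] <- "left"; j <- j - 1L
      } else {
        stop("traceback integrity error: no arrow matches (corrupt checkpoint?)")
      }
    }
  }
  list(moves = rev(moves), i = i, j = j, state = state, reason = reason)
}

# expand a move list starting at cell (i0, j0) into alignment columns
moves_to_columns <- function(ch0, ch1, moves, i0, j0) {
  n <- length(moves)
  top <- character(n); bottom <- character(n)
  i <- i0; j <- j0
  for (t in seq_len(n)) {
    mv <- moves[t]
    if (mv == "diag") {
      i <- i + 1L; j <- j + 1L
      top[t] <- ch0[i]; bottom[t] <- ch1[j]
    } else if (mv == "up") {
      i <- i + 1L
      top[t] <- ch0[i]; bottom[t] <- "-"
    } else {
      j <- j + 1L
      top[t] <- "-"; bottom[t] <- ch1[j]
    }
  }
  list(top = top, bottom = bottom, i_end = i, j_end = j)
}

# Global alignment of a (sub)problem with junction flags, solved by a direct
# quadratic-space fill plus greedy traceback. open_top waives the opening of
# a vertical gap run entering through the top-left corner (the run was opened
# above the junction); end_in_vgap constrains the path to reach the bottom-
# right corner inside a vertical gap run (the run continues below).
align_box_flags <- function(c0, c1, S, go, ge,
                            open_top = FALSE, end_in_vgap = FALSE) {
  h <- length(c0); w <- length(c1)
  if (h == 0L && w == 0L) return(list(moves = character(0), score = 0))
  if (w == 0L) {
    cost <- if (open_top) h * ge else go + (h - 1L) * ge
    return(list(moves = rep("up", h), score = -cost))
  }
  if (h == 0L) {
    return(list(moves = rep("left", w), score = -(go + (w - 1L) * ge)))
  }
  mats <- box_fill(c0, c1, S, go, ge, "global",
                   top_H = boundary_gamma(w, go, ge),
                   top_F = rep(NEG_INF, w + 1L),
                   left_H = boundary_gamma(h, go, ge, waive_open = open_top),
                   left_E = rep(NEG_INF, h + 1L))
  state <- if (end_in_vgap) "F" else "H"
  score <- if (end_in_vgap) mats$F[h + 1L, w + 1L] else mats$H[h + 1L, w + 1L]
  wk <- walk_box(mats, c0, c1, S, go, ge, "global", h, w, state)
  lead <- if (wk$reason == "top" && wk$j > 0L) rep("left", wk$j)
          else if (wk$reason == "left" && wk$i > 0L) rep("up", wk$i)
          else character(0)
  list(moves = c(lead, wk$moves), score = score)
}
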