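# Independent oracles, deliberately written with none of the package's
# engine machinery: a textbook nested-loop DP for each recurrence, and an
# exhaustive enumeration over all alignments (run-aware scoring) for tiny
# inputs.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# plain nested-loop linear-gap DP (global or local); returns the H matrix
loop_linear_dp <- function(s0, s1, ma, mi, G, local = FALSE) {
  a <- split_chars(s0); b <- split_chars(s1)
  m <- length(a); n <- length(b)
  H <- matrix(0, m + 1, n + 1)
  if (!local) {
    H[, 1] <- -G * (0:m)
    H[1, ] <- -G * (0:n)
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      p <- if (a[i] == b[j]) ma else -mi
      v <- max(H[i, j] + p, H[i, j + 1] - G, H[i + 1, j] - G)
      H[i + 1, j + 1] <- if (local) max(v, 0) else v
    }
  }
  H
}

# plain nested-loop affine-gap DP; returns list(H, E, F)
loop_affine_dp <- function(s0, s1, ma, mi, go, ge, local = FALSE) {
  a <- split_chars(s0); b <- split_chars(s1)
  m <- length(a); n <- length(b)
  gam <- function(x) ifelse(x >= 1, go + (x - 1) * ge, 0)
  H <- matrix(-Inf, m + 1, n + 1); E <- H; F <- H
  H[1, 1] <- 0
  for (i in seq_len(m)) H[i + 1, 1] <- if (local) 0 else -gam(i)
  for (j in seq_len(n)) H[1, j + 1] <- if (local) 0 else -gam(j)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      p <- if (a[i] == b[j]) ma else -mi
      E[i + 1, j + 1] <- max(E[i + 1, j] - ge, H[i + 1, j] - go)
      F[i + 1, j + 1] <- max(F[i, j + 1] - ge, H[i, j + 1] - go)
      v <- max(H[i, j] + p, E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- if (local) max(v, 0) else v
    }
  }
  list(H = H, E = E, F = F)
}

# exhaustive global alignment score by recursion over every move sequence,
# charging gamma per maximal run (exponential; keep lengths <= 6)
brute_global_score <- function(s0, s1, ma, mi, go, ge) {
  a <- split_chars(s0); b <- split_chars(s1)
  m <- length(a); n <- length(b)
  rec <- function(i, j, last) {
    if (i > m && j > n) return(0)
    best <- -Inf
    if (i <= m && j <= n) {
      p <- if (a[i] == b[j]) ma else -mi
      best <- max(best, p + rec(i + 1, j + 1, "none"))
    }
    if (i <= m) {
      cost <- if (last == "up") ge else go
      best <- max(best, -cost + rec(i + 1, j, "up"))
    }
    if (j <= n) {
      cost <- if (last == "left") ge else go
      best <- max(best, -cost + rec(i, j + 1, "left"))
    }
    best
  }
  rec(1, 1, "none")
}

# exhaustive local score: best global score over every substring pair, or 0
brute_local_score <- function(s0, s1, ma, mi, go, ge) {
  a <- split_chars(s0); b <- split_chars(s1)
  m <- length(a); n <- length(b)
  best <- 0
  for (i1 in seq_len(m)) for (i2 in i1:m) {
    for (j1 in seq_len(n)) for (j2 in j1:n) {
      best <- max(best, brute_global_score(
        paste(a[i1:i2], collapse = ""), paste(b[j1:j2], collapse = ""),
        ma, mi, go, ge))
    }
  }
  best
}

# Enumerate every distinct optimal local alignment retrievable by arrow
# traceback, by walking forward from every zero-valued cell (tiny inputs,
# linear gap model). Traceback semantics mean a path is only discoverable
# when its running score equals the cell value at every step (strictly
# positive after the start), so the enumeration enforces exactly that
# against the independent loop DP.
brute_local_optima <- function(s0, s1, ma, mi, G) {
  H <- loop_linear_dp(s0, s1, ma, mi, G, local = TRUE)
  opt <- max(H)
  if (opt == 0) return(character(0))
  a <- split_chars(s0); b <- split_chars(s1)
  m <- length(a); n <- length(b)
  found <- character(0)
  rec <- function(i, j, score, top, bottom) {
    # (i, j) is the 0-based cell whose value equals the running score
    if (score == opt) {
      found <<- c(found, paste(paste(top, collapse = ""),
                               paste(bottom, collapse = ""), sep = "/"))
    }
    if (i < m && j < n) {
      p <- if (a[i + 1] == b[j + 1]) ma else -mi
      if (score + p > 0 && H[i + 2, j + 2] == score + p) {
        rec(i + 1, j + 1, score + p, c(top, a[i + 1]), c(bottom, b[j + 1]))
      }
    }
    if (length(top) > 0) {
      if (i < m && score - G > 0 && H[i + 2, j + 1] == score - G) {
        rec(i + 1, j, score - G, c(top, a[i + 1]), c(bottom, "-"))
      }
      if (j < n && score - G > 0 && H[i + 1, j + 2] == score - G) {
        rec(i, j + 1, score - G, c(top, "-"), c(bottom, b[j + 1]))
      }
    }
  }
  for (i0 in 0:m) for (j0 in 0:n) {
    if (H[i0 + 1, j0 + 1] == 0) rec(i0, j0, 0, character(0), character(0))
  }
  unique(found)
}

expect_valid_alignment <- function(aln, scheme, s0 = NULL, s1 = NULL) {
  expect_true(stagealign:::check_alignment(aln, scheme, s0, s1))
}

alignment_signature <- function(aln) {
  paste(paste(aln$top, collapse = ""), paste(aln$bottom, collapse = ""),
        aln$score, aln$start0, aln$end0, aln$start1, aln$end1, sep = "|")
}
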