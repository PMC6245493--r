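# The staged multi-worker aligner. Stage 1 distributes the matrix over
# column partitions (chained band fills, border-column exchange, special-row
# checkpoints) and finds the optimal score. Stage 2 resolves the crosspoints
# where the optimal path crosses partition borders, either serially right to
# left (Pipeline Traceback) or speculatively from the border-column maxima
# (Incremental Speculative Traceback). Stage 3 refines the chain to every
# special row. Stage 4 aligns the small subproblems between consecutive
# crosspoints with the linear-space recursion, and Stage 5 concatenates them
# into the optimal alignment.
#
# Workers are deterministic logical workers exchanging immutable messages
# (border columns, crosspoints); scheduling is emulated, dataflow is real.
# The final alignment is byte-identical for every worker count because the
# traceback recomputes the canonical greedy path from bit-exact checkpoints
# and Stage-4 subproblems are delimited by special rows only (which depend
# on k and m, never on the partitioning).

#' Partition DP columns among workers
#'
#' `W` contiguous column ranges tiling `1..n`, sizes differing by at most
#' one, remainder columns going to the leftmost partitions.
#'
#' @param n Number of DP columns (residues of S1).
#' @param workers Number of workers `W`, `1 <= W <= n`.
#' @return List of `partition` objects with fields `index` (0-based),
#'   `j_lo`, `j_hi`.
#' @export
partition_columns <- function(n, workers) {
  workers <- as.integer(workers); n <- as.integer(n)
  if (workers < 1L || workers > n) {
    stop("configuration error: need 1 <= workers <= n")
  }
  base <- n %/% workers; rem <- n %% workers
  sizes <- rep(base, workers) + c(rep(1L, rem), rep(0L, workers - rem))
  hi <- cumsum(sizes)
  lo <- c(1L, hi[-workers] + 1L)
  lapply(seq_len(workers), function(p) {
    structure(list(index = p - 1L, j_lo = lo[p], j_hi = hi[p]),
              class = "partition")
  })
}

new_crosspoint <- function(i, j, score, gap_state, on, state = "H") {
  structure(list(i = as.integer(i), j = as.integer(j), score = score,
                 gap_state = isTRUE(gap_state), on = on, state = state),
            class = "crosspoint")
}

#' @export
print.crosspoint <- function(x, ...) {
  cat(sprintf("<crosspoint> (%d, %d) on %s, score %g, %s\n",
              x$i, x$j, x$on, x$score,
              if (x$gap_state) "inside gap run" else "match state"))
  invisible(x)
}

crosspoint_equal <- function(a, b) {
  a$i == b$i && a$j == b$j && a$gap_state == b$gap_state
}

partition_of <- function(partitions, j) {
  for (p in seq_along(partitions)) {
    if (j <= partitions[[p]]$j_hi) return(p)
  }
  stop("internal error: column outside every partition")
}

#' Stage 1: distributed matrix fill and optimal score
#'
#' Chains [band_fill()]-equivalent passes over the column partitions,
#' retaining the border column at every internal partition edge (for Stage-2
#' speculation and strip recomputation) and the special-row checkpoints of
#' every partition. Local mode reports the maximum cell with the canonical
#' tie-break (smallest i+j, then smallest i); global mode reports `H[m, n]`.
#'
#' @param s0,s1 [dna_sequence()] objects (or strings).
#' @param scheme A [scoring_scheme()].
#' @param workers Number of column partitions.
#' @param k Special-row interval; default `ceiling(m / 100)`.
#' @param mode `"local"` or `"global"`.
#' @return A `stage1_result` carrying the optimal score, end cell, saved
#'   border columns and special rows, and everything Stages 2-5 need.
#' @export
stage1 <- function(s0, s1, scheme = scoring_scheme(), workers = 1L,
                   k = NULL, mode = c("local", "global")) {
  mode <- match.arg(mode)
  s0 <- as_dna_sequence(s0, "S0"); s1 <- as_dna_sequence(s1, "S1")
  m <- s0$length; n <- s1$length
  stopifnot(m >= 1L, n >= 1L)
  if (is.null(k)) k <- default_interval(m)
  k <- as.integer(k); stopifnot(k >= 1L)
  partitions <- partition_columns(n, workers)
  enc <- encode_pair(s0, s1, scheme)
  go <- scheme_open(scheme); ge <- scheme_extend(scheme)
  rows <- special_row_set(m, k)
  local <- identical(mode, "local")
  h_in <- if (local) rep(0, m + 1L) else boundary_gamma(m, go, ge)
  e_in <- rep(NEG_INF, m + 1L)
  borders <- vector("list", workers)
  specials <- vector("list", workers)
  best <- list(score = NEG_INF, i = NA_integer_, j = NA_integer_)
  for (p in seq_len(workers)) {
    pt <- partitions[[p]]
    fl <- fill_columns(enc$c0, enc$c1[pt$j_lo:pt$j_hi], enc$S, go, ge, mode,
                       h_in = h_in, e_in = e_in, spec_rows = rows,
                       track_best = local, j_offset = pt$j_lo - 1L)
    borders[[p]] <- new_border_column(pt$index, pt$j_hi, fl$h, fl$e)
    specials[[p]] <- new_special_rows(pt$index, pt$j_lo, pt$j_hi, k, rows,
                                      fl$spec_H, fl$spec_F)
    if (local) {
      b <- fl$best
      if (b$score > best$score ||
          (b$score == best$score && (b$i + b$j < best$i + best$j ||
                                     (b$i + b$j == best$i + best$j && b$i < best$i)))) {
        best <- b
      }
    }
    h_in <- fl$h; e_in <- fl$e
  }
  if (local) {
    if (best$score <= 0) {
      opt <- 0; end_cell <- NULL
    } else {
      opt <- best$score; end_cell <- c(i = best$i, j = best$j)
    }
  } else {
    opt <- h_in[m + 1L]; end_cell <- c(i = m, j = n)
  }
  structure(
    list(opt_score = opt, end_cell = end_cell,
         partitions = partitions, borders = borders, specials = specials,
         s0 = s0, s1 = s1, scheme = scheme, mode = mode,
         m = m, n = n, workers = workers, k = k,
         enc = enc, go = go, ge = ge,
         stage1_cells = as.numeric(m) * n),
    class = "stage1_result"
  )
}

#' @export
print.stage1_result <- function(x, ...) {
  cat(sprintf("<stage1_result> %s, %d x %d, %d worker(s), k = %d, optimal %g\n",
              x$mode, x$m, x$n, x$workers, x$k, x$opt_score))
  invisible(x)
}

# exact boundary values of the column left of partition p (global boundary
# for the first partition, the saved border column otherwise)
left_border_values <- function(st1, p) {
  if (p == 1L) {
    H <- if (st1$mode == "local") rep(0, st1$m + 1L)
         else boundary_gamma(st1$m, st1$go, st1$ge)
    list(H = H, E = rep(NEG_INF, st1$m + 1L))
  } else {
    b <- st1$borders[[p - 1L]]
    list(H = b$H, E = if (is.null(b$E)) rep(NEG_INF, st1$m + 1L) else b$E)
  }
}

# full H/E/F matrices of the strip rows r0..r1, columns (j_lo - 1)..j_hi_box
# of partition p, rebuilt from the checkpoints (exact by construction)
strip_box <- function(st1, p, r0, r1, j_hi_box) {
  pt <- st1$partitions[[p]]
  j0 <- pt$j_lo - 1L
  wdt <- j_hi_box - j0
  lb <- left_border_values(st1, p)
  cols_idx <- seq_len(wdt)
  if (r0 == 0L) {
    if (st1$mode == "local") {
      top_H <- rep(0, wdt + 1L)
    } else {
      jj <- j0 + 0:wdt
      top_H <- ifelse(jj == 0L, 0, -(st1$go + (jj - 1L) * st1$ge))
    }
    top_F <- rep(NEG_INF, wdt + 1L)
  } else {
    sp <- st1$specials[[p]]
    si <- match(r0, sp$rows)
    if (is.na(si)) stop("checkpoint error: row ", r0, " is not a stored special row")
    top_H <- c(lb$H[r0 + 1L], sp$H[si, cols_idx])
    top_F <- c(NEG_INF, sp$F[si, cols_idx])
  }
  mats <- box_fill(st1$enc$c0[(r0 + 1L):r1], st1$enc$c1[(j0 + 1L):j_hi_box],
                   st1$enc$S, st1$go, st1$ge, st1$mode,
                   top_H = top_H, top_F = top_F,
                   left_H = lb$H[(r0:r1) + 1L], left_E = lb$E[(r0:r1) + 1L])
  list(mats = mats, r0 = r0, j0 = j0,
       c0 = st1$enc$c0[(r0 + 1L):r1], c1 = st1$enc$c1[(j0 + 1L):j_hi_box],
       cells = (r1 - r0) * wdt)
}

# Traceback across one partition: from the entry anchor, rebuild the strip
# between consecutive special rows and walk the canonical greedy path until
# it crosses the partition's left edge (exit crosspoint), or the path start
# is found. Records the crosspoint on every special row it crosses.
walk_partition <- function(st1, p, anchor) {
  pt <- st1$partitions[[p]]
  local <- identical(st1$mode, "local")
  rows_set <- st1$specials[[p]]$rows
  i_a <- anchor$i; j_a <- anchor$j; state <- anchor$state
  row_cps <- list(); cells <- 0
  repeat {
    if (i_a == 0L) {
      start <- if (local) c(i = 0L, j = j_a) else c(i = 0L, j = 0L)
      return(list(exit = NULL, start = start, rows = row_cps, cells = cells))
    }
    cand <- c(0L, rows_set[rows_set < i_a])
    r0 <- max(cand)
    bx <- strip_box(st1, p, r0, i_a, j_a)
    cells <- cells + bx$cells
    wk <- walk_box(bx$mats, bx$c0, bx$c1, st1$enc$S, st1$go, st1$ge, st1$mode,
                   i_a - r0, j_a - bx$j0, state)
    abs_i <- r0 + wk$i; abs_j <- bx$j0 + wk$j
    if (wk$reason == "zero") {
      return(list(exit = NULL, start = c(i = abs_i, j = abs_j),
                  rows = row_cps, cells = cells))
    }
    hit_top <- wk$reason %in% c("top", "origin")
    hit_left <- wk$reason %in% c("left", "origin")
    if (hit_top && r0 > 0L) {
      # crossing of special row r0; in-gap iff a vertical run straddles it
      row_cps[[length(row_cps) + 1L]] <-
        new_crosspoint(r0, abs_j, bx$mats$H[wk$i + 1L, wk$j + 1L],
                       wk$state == "F", on = "row", state = wk$state)
    }
    if (hit_left && bx$j0 > 0L) {
      cp <- new_crosspoint(abs_i, bx$j0, bx$mats$H[wk$i + 1L, wk$j + 1L],
                           wk$state == "E", on = "col", state = wk$state)
      return(list(exit = cp, start = NULL, rows = row_cps, cells = cells))
    }
    if (hit_left && bx$j0 == 0L) {
      if (local) {
        return(list(exit = NULL, start = c(i = abs_i, j = 0L),
                    rows = row_cps, cells = cells))
      }
      # global: the rest of the path is the boundary run up column 0; record
      # its special-row crossings so the chain keeps its <= k spacing
      if (abs_i > 0L) {
        for (r in rev(rows_set[rows_set < abs_i])) {
          row_cps[[length(row_cps) + 1L]] <-
            new_crosspoint(r, 0L, -gap_run_cost(r, st1$scheme), r >= 1L,
                           on = "row", state = "F")
        }
      }
      return(list(exit = NULL, start = c(i = 0L, j = 0L),
                  rows = row_cps, cells = cells))
    }
    if (hit_top && r0 == 0L) {
      start <- if (local) c(i = 0L, j = abs_j) else c(i = 0L, j = 0L)
      return(list(exit = NULL, start = start, rows = row_cps, cells = cells))
    }
    # continue with the strip above
    i_a <- r0; j_a <- abs_j; state <- wk$state
  }
}

#' Speculate the crosspoint of a border column
#'
#' The Stage-2 speculation heuristic: the optimal path tends to cross a
#' border column at the cell holding the column's maximum. Ties take the
#' smallest row; the in-gap state is predicted from whether the maximum is
#' attained by the horizontal-gap matrix `E`.
#'
#' @param border A `border_column` saved by [stage1()].
#' @return A `crosspoint`.
#' @export
speculate_crosspoint <- function(border) {
  stopifnot(inherits(border, "border_column"))
  i <- which.max(border$H) - 1L
  g <- !is.null(border$E) && is.finite(border$E[i + 1L]) &&
    border$E[i + 1L] == border$H[i + 1L]
  new_crosspoint(i, border$j, border$H[i + 1L], g, on = "col",
                 state = if (g) "E" else "H")
}

# shared stage-2 driver; speculative = NULL for PT, or a list of
# pre-computed speculative walks + predictions for IST
stage2_run <- function(st1, speculative = NULL) {
  local <- identical(st1$mode, "local")
  if (local && st1$opt_score == 0) {
    return(structure(list(crosspoints = list(), start = NULL, rows = list(),
                          records = if (is.null(speculative)) NULL else list(),
                          end = NULL, cells = 0, spec_cells = 0),
                     class = "stage2_result"))
  }
  end <- c(i = unname(st1$end_cell[["i"]]), j = unname(st1$end_cell[["j"]]))
  p <- partition_of(st1$partitions, end[["j"]])
  anchor <- list(i = end[["i"]], j = end[["j"]], state = "H")
  chain <- list(); rows_all <- list(); records <- list()
  cells <- 0; spec_cells <- 0
  first <- TRUE   # the first anchor is the end cell, not a border crosspoint
  if (!is.null(speculative)) {
    spec_cells <- sum(vapply(speculative,
                             function(s) if (is.null(s)) 0 else s$walk$cells,
                             numeric(1)))
  }
  repeat {
    used_spec <- FALSE
    if (!first && !is.null(speculative) && p <= length(speculative) &&
        !is.null(speculative[[p]])) {
      sp <- speculative[[p]]
      actual <- new_crosspoint(anchor$i, anchor$j,
                               st1$borders[[p]]$H[anchor$i + 1L],
                               identical(anchor$state, "E"), on = "col",
                               state = anchor$state)
      hit <- crosspoint_equal(sp$predicted, actual)
      records[[length(records) + 1L]] <-
        structure(list(partition = p - 1L, predicted = sp$predicted,
                       actual = actual, hit = hit),
                  class = "speculation_record")
      if (hit) {
        res <- sp$walk
        used_spec <- TRUE
      }
    }
    if (!used_spec) {
      res <- walk_partition(st1, p, anchor)
      cells <- cells + res$cells
    }
    rows_all <- c(rows_all, res$rows)
    if (is.null(res$exit)) {
      start <- res$start
      break
    }
    chain[[length(chain) + 1L]] <- res$exit
    anchor <- list(i = res$exit$i, j = res$exit$j, state = res$exit$state)
    p <- p - 1L
    first <- FALSE
    stopifnot(p >= 1L)
  }
  # order left-to-right / top-to-bottom (walk collected right-to-left)
  chain <- rev(chain)
  rows_all <- rows_all[order(vapply(rows_all, function(x) x$i, numeric(1)))]
  structure(
    list(crosspoints = chain, start = start, rows = rows_all,
         records = if (is.null(speculative)) NULL else records,
         end = end, cells = cells, spec_cells = spec_cells),
    class = "stage2_result"
  )
}

#' Stage 2, Pipeline Traceback (PT)
#'
#' Serial right-to-left crosspoint resolution: the partition holding the
#' alignment end walks its partial traceback first; the crosspoint it finds
#' on its left border is handed to the previous partition, and so on until
#' the path start is reached. Each partial traceback recomputes only the
#' strips between special rows that the path actually crosses.
#'
#' @param st1 A `stage1_result`.
#' @return A `stage2_result`: border `crosspoints` (left to right), the path
#'   `start`, the special-row crosspoints `rows`, and cell accounting.
#' @export
stage2_pt <- function(st1) {
  stopifnot(inherits(st1, "stage1_result"))
  stage2_run(st1, speculative = NULL)
}

#' Stage 2, Incremental Speculative Traceback (IST)
#'
#' Every partition starts its partial traceback immediately from the
#' speculated crosspoint of its right border ([speculate_crosspoint()]).
#' When the true entry crosspoint arrives from the right neighbour, a hit
#' reuses the speculative result and a miss recomputes from the true
#' crosspoint, so speculation never changes the final chain -- it only
#' trades extra (possibly wasted) cell updates for pipeline idle time.
#' Only borders the optimal path actually crosses are recorded.
#'
#' @param st1 A `stage1_result`.
#' @return A `stage2_result` whose `records` field holds one
#'   `speculation_record` (predicted, actual, hit) per crossed border.
#' @export
stage2_ist <- function(st1) {
  stopifnot(inherits(st1, "stage1_result"))
  W <- st1$workers
  speculative <- vector("list", max(W - 1L, 0L))
  if (W > 1L && !(identical(st1$mode, "local") && st1$opt_score == 0)) {
    for (p in seq_len(W - 1L)) {
      pred <- speculate_crosspoint(st1$borders[[p]])
      walk <- walk_partition(st1, p,
                             list(i = pred$i, j = pred$j, state = pred$state))
      speculative[[p]] <- list(predicted = pred, walk = walk)
    }
  }
  stage2_run(st1, speculative = speculative)
}

#' Stage 3: split a partition's traceback at its special rows
#'
#' Recomputes the strips between consecutive special rows bounded by the
#' entry crosspoint and records where the optimal path crosses every stored
#' special row, so consecutive crosspoints end up at most `k` rows apart.
#' When the exit crosspoint is supplied it is checked against the walk
#' (an inconsistency means corrupt checkpoints).
#'
#' @param st1 A `stage1_result`.
#' @param p Partition number (1-based).
#' @param entry Entry anchor: a `crosspoint` on the partition's right border
#'   or the alignment end cell as `list(i =, j =, state = "H")`.
#' @param exit Optional expected exit `crosspoint` on the left border.
#' @return List of `crosspoint`s on special rows, ascending in row.
#' @export
stage3_split <- function(st1, p, entry, exit = NULL) {
  stopifnot(inherits(st1, "stage1_result"))
  anchor <- if (inherits(entry, "crosspoint")) {
    list(i = entry$i, j = entry$j, state = entry$state)
  } else {
    list(i = entry$i, j = entry$j,
         state = if (is.null(entry$state)) "H" else entry$state)
  }
  res <- walk_partition(st1, p, anchor)
  if (!is.null(exit)) {
    if (is.null(res$exit) || !crosspoint_equal(res$exit, exit)) {
      stop("integrity error: crosspoints inconsistent with stored special rows")
    }
  }
  res$rows[order(vapply(res$rows, function(x) x$i, numeric(1)))]
}

# chain of path points delimiting Stage-4 subproblems: start, special-row
# crosspoints, end (duplicates collapsed)
build_chain <- function(st2) {
  pts <- c(
    list(list(i = unname(st2$start[["i"]]), j = unname(st2$start[["j"]]),
              gap_state = FALSE)),
    lapply(st2$rows, function(cp) list(i = cp$i, j = cp$j,
                                       gap_state = cp$gap_state)),
    list(list(i = unname(st2$end[["i"]]), j = unname(st2$end[["j"]]),
              gap_state = FALSE))
  )
  keep <- c(TRUE, vapply(seq_along(pts)[-1L], function(t) {
    !(pts[[t]]$i == pts[[t - 1L]]$i && pts[[t]]$j == pts[[t - 1L]]$j)
  }, logical(1)))
  pts[keep]
}

#' Stage 4: balanced alignment of the inter-crosspoint subproblems
#'
#' Each subproblem between consecutive crosspoints is solved independently
#' by the linear-space recursion ([linear_align()] machinery) down to
#' `max_area`-cell base cases, with gap runs spanning a junction charged
#' their opening exactly once (the crosspoint's in-gap state waives the
#' opening on the downstream side and pins the upstream side inside the
#' run). The result does not depend on processing order.
#'
#' @param st1 A `stage1_result`.
#' @param chain List of chain points `list(i =, j =, gap_state =)`,
#'   ascending; typically from [stage2_pt()]/[stage2_ist()] via the
#'   pipeline, or assembled from [stage3_split()] output.
#' @param max_area Base-case area for the recursion (default 4096).
#' @return List of sub-alignments `list(from =, to =, moves =)`.
#' @export
stage4_balanced <- function(st1, chain, max_area = 4096) {
  stopifnot(inherits(st1, "stage1_result"), length(chain) >= 2L)
  lapply(seq_len(length(chain) - 1L), function(t) {
    a <- chain[[t]]; b <- chain[[t + 1L]]
    stopifnot(a$i <= b$i, a$j <= b$j)
    c0 <- if (b$i > a$i) st1$enc$c0[(a$i + 1L):b$i] else integer(0)
    c1 <- if (b$j > a$j) st1$enc$c1[(a$j + 1L):b$j] else integer(0)
    moves <- mm_recurse(c0, c1, st1$enc$S, st1$go, st1$ge,
                        open_top = isTRUE(a$gap_state),
                        end_vgap = isTRUE(b$gap_state),
                        base_area = max_area)
    list(from = a, to = b, moves = moves)
  })
}

#' Stage 5: concatenate sub-alignments
#'
#' Joins the Stage-4 pieces at their crosspoints into one well-formed
#' alignment and verifies the result: pieces must be contiguous, no
#' (gap, gap) column may appear, and the score recomputed from the columns
#' must equal the Stage-1 optimal score.
#'
#' @param st1 A `stage1_result`.
#' @param subs Sub-alignments from [stage4_balanced()].
#' @return An [new_alignment()].
#' @export
stage5_concat <- function(st1, subs) {
  stopifnot(inherits(st1, "stage1_result"), length(subs) >= 1L)
  for (t in seq_len(length(subs) - 1L)) {
    a <- subs[[t]]$to; b <- subs[[t + 1L]]$from
    if (a$i != b$i || a$j != b$j) {
      stop("concatenation error: sub-alignments are not contiguous")
    }
  }
  from <- subs[[1L]]$from
  moves <- unlist(lapply(subs, `[[`, "moves"))
  if (is.null(moves)) moves <- character(0)
  ch0 <- strsplit(st1$s0$residues, "")[[1]]
  ch1 <- strsplit(st1$s1$residues, "")[[1]]
  cols <- moves_to_columns(ch0, ch1, moves, as.integer(from$i), as.integer(from$j))
  aln <- new_alignment(cols$top, cols$bottom, st1$opt_score,
                       start0 = from$i + 1L, end0 = cols$i_end,
                       start1 = from$j + 1L, end1 = cols$j_end,
                       mode = st1$mode, gap_model = st1$scheme$gap_model)
  if (score_alignment(aln, st1$scheme) != aln$score) {
    stop("concatenation error: recomputed score does not match the optimum")
  }
  aln
}

#' Summarize speculation records
#'
#' Exact hit/miss counts and the hit ratio of an IST run. With no records
#' (nothing to speculate on) the ratio is reported as 1 by convention:
#' vacuous speculation never mispredicts.
#'
#' @param records List of `speculation_record`s from [stage2_ist()].
#' @return `list(hits =, misses =, hit_ratio =)`.
#' @export
speculation_summary <- function(records) {
  if (is.null(records) || length(records) == 0L) {
    return(list(hits = 0L, misses = 0L, hit_ratio = 1.0))
  }
  hits <- sum(vapply(records, function(r) isTRUE(r$hit), logical(1)))
  misses <- length(records) - hits
  list(hits = hits, misses = misses, hit_ratio = hits / (hits + misses))
}

#' Run the full staged alignment pipeline
#'
#' Orchestrates Stages 1-5: distributed fill, crosspoint resolution (PT or
#' IST), special-row splitting, balanced subproblem alignment and
#' concatenation. The result equals the quadratic-space reference kernels
#' in score on every input, and is byte-identical for every worker count.
#'
#' @param s0,s1 [dna_sequence()] objects (or strings).
#' @param scheme A [scoring_scheme()].
#' @param mode `"local"` or `"global"`.
#' @param workers Number of logical workers (column partitions).
#' @param special_row_interval Checkpoint interval `k` in rows; default
#'   `ceiling(m / 100)`.
#' @param speculation `"pt"` (pipeline traceback, default), `"ist"`
#'   (incremental speculative traceback) or `"none"` (same dataflow as PT).
#' @param max_area Stage-4 base-case area.
#' @return A `staged_alignment`: fields `alignment`, `stats`, `records`,
#'   `speculation` (summary), `crosspoints`, `report`.
#' @export
align_full <- function(s0, s1, scheme = scoring_scheme(),
                       mode = c("local", "global"), workers = 1L,
                       special_row_interval = NULL,
                       speculation = c("pt", "ist", "none"),
                       max_area = 4096) {
  mode <- match.arg(mode)
  speculation <- match.arg(speculation)
  t0 <- proc.time()[["elapsed"]]
  s0 <- as_dna_sequence(s0, "S0"); s1 <- as_dna_sequence(s1, "S1")
  m <- s0$length; n <- s1$length
  if (m == 0L || n == 0L) {
    aln <- degenerate_alignment(s0, s1, scheme, mode)
    return(finish_staged(aln, NULL, NULL, list(), mode, workers,
                         speculation, m, n, t0))
  }
  st1 <- stage1(s0, s1, scheme, workers = workers,
                k = special_row_interval, mode = mode)
  st2 <- if (speculation == "ist") stage2_ist(st1) else stage2_pt(st1)
  if (is.null(st2$end)) {
    aln <- new_alignment(character(0), character(0), 0, 0L, 0L, 0L, 0L,
                         "local", scheme$gap_model)
    return(finish_staged(aln, st1, st2, st2$records %||% list(), mode,
                         workers, speculation, m, n, t0))
  }
  chain <- build_chain(st2)
  subs <- stage4_balanced(st1, chain, max_area = max_area)
  aln <- stage5_concat(st1, subs)
  finish_staged(aln, st1, st2, st2$records %||% list(), mode, workers,
                speculation, m, n, t0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pure gap-run alignment for an empty side (global), empty alignment (local)
degenerate_alignment <- function(s0, s1, scheme, mode) {
  m <- s0$length; n <- s1$length
  if (mode == "local" || (m == 0L && n == 0L)) {
    return(new_alignment(character(0), character(0), 0, 1L, 0L, 1L, 0L,
                         mode, scheme$gap_model))
  }
  ch0 <- strsplit(s0$residues, "")[[1]]
  ch1 <- strsplit(s1$residues, "")[[1]]
  if (n == 0L) {
    new_alignment(ch0, rep("-", m), -gap_run_cost(m, scheme),
                  1L, m, 1L, 0L, "global", scheme$gap_model)
  } else {
    new_alignment(rep("-", n), ch1, -gap_run_cost(n, scheme),
                  1L, 0L, 1L, n, "global", scheme$gap_model)
  }
}

finish_staged <- function(aln, st1, st2, records, mode, workers,
                          speculation, m, n, t0) {
  elapsed <- proc.time()[["elapsed"]] - t0
  cells <- as.numeric(m) * n
  report <- list(
    cells = cells,
    stage1_cells = if (is.null(st1)) 0 else st1$stage1_cells,
    traceback_cells = if (is.null(st2)) 0 else st2$cells,
    speculative_cells = if (is.null(st2)) 0 else st2$spec_cells,
    workers = workers, mode = mode, speculation = speculation,
    k = if (is.null(st1)) NA_integer_ else st1$k,
    elapsed_s = elapsed,
    gcups = if (elapsed > 0) cells / (1e9 * elapsed) else NA_real_
  )
  structure(
    list(alignment = aln,
         stats = alignment_stats(aln, m, n),
         records = records,
         speculation = speculation_summary(records),
         crosspoints = list(
           borders = if (is.null(st2)) list() else st2$crosspoints,
           rows = if (is.null(st2)) list() else st2$rows
         ),
         report = report),
    class = "staged_alignment"
  )
}

#' @export
print.staged_alignment <- function(x, ...) {
  cat(sprintf("<staged_alignment> score %g over %d columns (%s, %d worker(s), %s)\n",
              x$alignment$score, length(x$alignment$top), x$report$mode,
              x$report$workers, x$report$speculation))
  s <- x$stats
  cat(sprintf("  matches %.1f%%, mismatches %.1f%%, gaps %.1f%%, coverage %.1f%%\n",
              s$matches_pct, s$mismatches_pct, s$gaps_pct, s$coverage_pct))
  if (x$report$speculation == "ist") {
    sp <- x$speculation
    cat(sprintf("  speculation: %d hit(s), %d miss(es), ratio %.2f\n",
                sp$hits, sp$misses, sp$hit_ratio))
  }
  invisible(x)
}
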