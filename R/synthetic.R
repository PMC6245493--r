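# Synthetic homologous DNA pairs with controlled substitution/indel
# structure, so chromosome-style comparisons are testable at desk scale:
# the realistic regime to emulate is a high-similarity pair (roughly 88-94%
# matching columns with a few percent of clustered gaps), which is what
# closely related homologous chromosomes produce.

#' Generate a homologous DNA pair
#'
#' Draws a random ancestor uniformly over `{A,C,G,T}` and derives a second
#' sequence from it by independent substitutions (each position mutates to a
#' different base with probability `sub_rate`) and indels (before each
#' position, with probability `indel_rate`, an insertion or deletion of
#' geometric length with mean `mean_indel_len` is applied; insertions and
#' deletions are equiprobable). The full edit record is returned so tests
#' can reconcile lengths and rates exactly. A fixed seed gives byte-identical
#' output.
#'
#' @param length Ancestor length, `>= 1`.
#' @param sub_rate Substitution probability per position, in `[0, 1)`.
#' @param indel_rate Indel probability per position, in `[0, 1)`.
#' @param mean_indel_len Mean indel length, `>= 1`.
#' @param seed Mandatory integer seed.
#' @return `list(s0 =, s1 =, edits =)` where `s0` is the ancestor, `s1` the
#'   derived copy and `edits` a data frame (`op`, `position`, `length`,
#'   `bases`) with `position` referring to the ancestor coordinate.
#' @export
generate_homolog_pair <- function(length, sub_rate = 0.05, indel_rate = 0.001,
                                  mean_indel_len = 5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  length <- as.integer(length)
  if (length < 1L) stop("domain error: length must be >= 1")
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1) {
    stop("domain error: rates must lie in [0, 1)")
  }
  if (indel_rate > 0 && mean_indel_len < 1) {
    stop("domain error: mean_indel_len must be >= 1")
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(as.integer(seed), {
    anc <- sample(bases, length, replace = TRUE)
    # substitutions: mutate to one of the three other bases
    der <- anc
    subs <- which(stats::runif(length) < sub_rate)
    if (length(subs) > 0L) {
      shift <- sample.int(3L, length(subs), replace = TRUE)
      der[subs] <- bases[(match(der[subs], bases) - 1L + shift) %% 4L + 1L]
    }
    edits <- list()
    if (length(subs) > 0L) {
      edits[[1L]] <- data.frame(op = "sub", position = subs, length = 1L,
                                bases = der[subs], stringsAsFactors = FALSE)
    }
    # indels on the substituted copy, walked in ancestor coordinates
    if (indel_rate > 0) {
      sites <- which(stats::runif(length) < indel_rate)
      if (length(sites) > 0L) {
        ops <- sample(c("ins", "del"), length(sites), replace = TRUE)
        lens <- 1L + stats::rgeom(length(sites), prob = 1 / mean_indel_len)
        pieces <- character(0)
        ev <- list()
        prev <- 1L   # next ancestor position not yet emitted
        for (t in seq_along(sites)) {
          pos <- sites[t]
          if (pos < prev) next   # site swallowed by a previous deletion
          if (pos > prev) pieces <- c(pieces, der[prev:(pos - 1L)])
          if (ops[t] == "ins") {
            ins <- sample(bases, lens[t], replace = TRUE)
            pieces <- c(pieces, ins)
            ev[[length(ev) + 1L]] <-
              data.frame(op = "ins", position = pos, length = lens[t],
                         bases = paste(ins, collapse = ""),
                         stringsAsFactors = FALSE)
            prev <- pos
          } else {
            del_len <- min(lens[t], length - pos + 1L)
            ev[[length(ev) + 1L]] <-
              data.frame(op = "del", position = pos, length = del_len,
                         bases = paste(der[pos:(pos + del_len - 1L)],
                                       collapse = ""),
                         stringsAsFactors = FALSE)
            prev <- pos + del_len
          }
        }
        if (prev <= length) pieces <- c(pieces, der[prev:length])
        der <- pieces
        if (length(ev) > 0L) {
          edits[[length(edits) + 1L]] <- do.call(rbind, ev)
        }
      }
    }
    edits <- if (length(edits) > 0L) do.call(rbind, edits)
             else data.frame(op = character(0), position = integer(0),
                             length = integer(0), bases = character(0),
                             stringsAsFactors = FALSE)
    list(
      s0 = dna_sequence(paste(anc, collapse = ""), id = "ancestor"),
      s1 = dna_sequence(paste(der, collapse = ""), id = "derived"),
      edits = edits
    )
  })
}

#' Plant a decoy repeat
#'
#' Copies a high-similarity block of S1 into S0 at an off-path position,
#' creating a strong off-diagonal local match. This is the adversarial
#' construction for speculative-traceback tests: a border column whose
#' maximum sits on the decoy diagonal rather than on the optimal path forces
#' a speculation miss. The target region must not overlap the diagonal
#' corridor of the optimal path around the source block (placement error
#' otherwise).
#'
#' @param pair A pair from [generate_homolog_pair()] (fields `s0`, `s1`).
#' @param block_len Length of the copied block (0 returns the pair
#'   unchanged).
#' @param position 1-based start in S0 where the copy is written.
#' @param seed Integer seed (selects the source block when `source` is not
#'   given).
#' @param source Optional 1-based start of the source block in S1; chosen
#'   seeded among off-corridor positions when `NULL`.
#' @return The modified pair (same shape as the input, plus `decoy` with the
#'   source/target coordinates).
#' @export
plant_decoy_repeat <- function(pair, block_len, position, seed, source = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  block_len <- as.integer(block_len); position <- as.integer(position)
  if (block_len == 0L) return(pair)
  stopifnot(block_len > 0L, position >= 1L)
  m <- pair$s0$length; n <- pair$s1$length
  if (position + block_len - 1L > m) stop("placement error: block does not fit in S0")
  # the optimal path of a homologous pair runs near the main diagonal; the
  # copy must land off the source block's diagonal footprint (offset at
  # least the block length) or it would sit on the path instead of decoying
  if (is.null(source)) {
    cand <- seq_len(max(n - block_len + 1L, 0L))
    cand <- cand[abs(cand - position) >= block_len]
    if (length(cand) == 0L) {
      stop("placement error: decoy overlaps the optimal-path corridor")
    }
    withr::with_seed(as.integer(seed), {
      src <- cand[sample.int(length(cand), 1L)]
    })
  } else {
    src <- as.integer(source)
    if (src < 1L || src + block_len - 1L > n) {
      stop("placement error: source block does not fit in S1")
    }
    if (abs(src - position) < block_len) {
      stop("placement error: decoy overlaps the optimal-path corridor")
    }
  }
  block <- substr(pair$s1$residues, src, src + block_len - 1L)
  res <- pair$s0$residues
  substr(res, position, position + block_len - 1L) <- block
  pair$s0 <- dna_sequence(res, id = paste0(pair$s0$id, "+decoy"))
  pair$decoy <- list(source_s1 = src, target_s0 = position,
                     block_len = block_len)
  pair
}
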