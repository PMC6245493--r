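# Alignment characterization and the arithmetic accounting used to compare
# chromosome-scale runs: matrix size in Petacells, throughput in GCUPS,
# energy/cost bookkeeping and the speculation trade-off model.

#' Characterize an alignment
#'
#' Column-level percentages in the style of whole-chromosome comparison
#' tables: `length` counts every column (including gap columns), matches /
#' mismatches / gaps are percentages of columns (summing to 100), and
#' coverage is the mean of the aligned span fractions of the two sequences,
#' `(span0/m + span1/n) / 2 * 100`. Coverage distinguishes a whole-sequence
#' alignment (near 100%) from a short high-identity island (a few percent)
#' even when their match percentages look alike.
#'
#' @param aln An [new_alignment()].
#' @param m,n Full lengths of S0 and S1.
#' @return `list(length =, matches_pct =, mismatches_pct =, gaps_pct =,
#'   coverage_pct =, score =)`.
#' @export
alignment_stats <- function(aln, m, n) {
  len <- length(aln$top)
  if (len == 0L) {
    return(list(length = 0L, matches_pct = 0, mismatches_pct = 0,
                gaps_pct = 0, coverage_pct = 0, score = aln$score))
  }
  gaps <- sum(aln$top == "-" | aln$bottom == "-")
  matches <- sum(aln$top == aln$bottom & aln$top != "-")
  mism <- len - gaps - matches
  sp <- aligned_span(aln)
  cov <- if (m > 0L && n > 0L) mean(c(sp[1] / m, sp[2] / n)) * 100 else 0
  list(length = len,
       matches_pct = 100 * matches / len,
       mismatches_pct = 100 * mism / len,
       gaps_pct = 100 * gaps / len,
       coverage_pct = cov,
       score = aln$score)
}

#' Matrix size in Petacells
#'
#' `m * n / 1e15`: the number of DP cells of the comparison, in units of
#' 10^15 cells. A human/chimpanzee chromosome-22 comparison is about 2.55
#' Petacells.
#'
#' @param m,n Sequence lengths.
#' @return Numeric (report at 2 decimals).
#' @export
petacells <- function(m, n) {
  stopifnot(m >= 1, n >= 1)
  as.numeric(m) * as.numeric(n) / 1e15
}

#' Throughput in GCUPS
#'
#' Billions of cell updates per second: `cells / (1e9 * seconds)`.
#'
#' @param cells Number of DP cells updated.
#' @param seconds Elapsed seconds, `> 0`.
#' @return Numeric.
#' @export
gcups <- function(cells, seconds) {
  if (seconds <= 0) stop("domain error: seconds must be positive")
  cells / (1e9 * seconds)
}

#' Energy and monetary cost of a run
#'
#' Pure arithmetic on user-supplied measurements (this package never claims
#' to measure power): energy per device in kilojoules is
#' `power * seconds / 1000`, and the total cost over `n_devices` at a
#' `tariff_per_kwh` fare converts kJ to kWh (divide by 3600).
#'
#' @param avg_power_w Average power per device in watts.
#' @param seconds Execution time in seconds.
#' @param n_devices Number of devices drawing that power.
#' @param tariff_per_kwh Price per kWh (e.g. 0.13).
#' @return `list(kj_per_device =, total_cost =)`.
#' @export
energy_cost <- function(avg_power_w, seconds, n_devices = 1, tariff_per_kwh = 0.13) {
  stopifnot(avg_power_w >= 0, seconds >= 0, n_devices >= 0)
  kj <- avg_power_w * seconds / 1000
  list(kj_per_device = kj,
       total_cost = n_devices * kj / 3600 * tariff_per_kwh)
}

#' Break-even hit/miss ratio of speculation
#'
#' A speculation hit changes the energy budget by `delta_e_hit_pct` (< 0, a
#' saving) and a miss by `delta_e_miss_pct` (> 0, a penalty). The smallest
#' integer ratio r of hits per miss whose mixture is not a net penalty,
#' i.e. `(r * hit + miss) / (r + 1) <= 0`, is `ceiling(miss / |hit|)`.
#'
#' @param delta_e_hit_pct Per-hit energy change in percent, negative.
#' @param delta_e_miss_pct Per-miss energy change in percent, positive.
#' @return Integer ratio.
#' @examples
#' speculation_breakeven(-6.5, 11.0)  # 2
#' @export
speculation_breakeven <- function(delta_e_hit_pct, delta_e_miss_pct) {
  if (!(delta_e_hit_pct < 0 && delta_e_miss_pct > 0)) {
    stop("domain error: need delta_e_hit_pct < 0 < delta_e_miss_pct")
  }
  as.integer(ceiling(delta_e_miss_pct / abs(delta_e_hit_pct)))
}

#' Expected time saving of speculation
#'
#' Mixture of the per-hit and per-miss time savings at a given hit/miss
#' ratio: `(ratio * per_hit + per_miss) / (ratio + 1)`, in percent. At the
#' break-even ratio of 2 with an 18% per-hit saving and no per-miss effect
#' this is a 12% expected saving.
#'
#' @param ratio Hits per miss, `>= 0`.
#' @param per_hit_saving_pct Time saved by a hit, percent.
#' @param per_miss_saving_pct Time saved by a miss, percent (usually 0).
#' @return Numeric percent.
#' @export
expected_time_saving <- function(ratio, per_hit_saving_pct,
                                 per_miss_saving_pct = 0) {
  stopifnot(ratio >= 0)
  (ratio * per_hit_saving_pct + per_miss_saving_pct) / (ratio + 1)
}

#' Write an alignment-statistics report as TSV
#'
#' One metric per row (`metric`, `value`), mirroring the row labels of
#' whole-chromosome comparison tables: Petacells, Score, Length, Coverage,
#' Matches, Mismatches, Gaps. Percentages are written with one decimal,
#' Petacells with two.
#'
#' @param stats Result of [alignment_stats()].
#' @param m,n Sequence lengths.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_stats_tsv <- function(stats, m, n, path) {
  rows <- data.frame(
    metric = c("Petacells", "Score", "Length", "Coverage",
               "Matches", "Mismatches", "Gaps"),
    value = c(sprintf("%.2f", petacells(max(m, 1), max(n, 1))),
              format(stats$score, scientific = FALSE),
              format(stats$length, scientific = FALSE),
              sprintf("%.1f%%", stats$coverage_pct),
              sprintf("%.1f%%", stats$matches_pct),
              sprintf("%.1f%%", stats$mismatches_pct),
              sprintf("%.1f%%", stats$gaps_pct)),
    stringsAsFactors = FALSE
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
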