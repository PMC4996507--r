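#' Run-level cooperation classification
#'
#' A run counts as cooperative when equal sharing held throughout: a group
#' agreement existed in every tick and every agent chose the group extraction
#' level in every tick. A single defection, or any tick without an agreement
#' (nobody spoke), makes the run non-cooperative.
#'
#' @param run A `cpr_run` object from [simulate_run()].
#' @return Logical.
#' @export
classify_cooperation <- function(run) {
  all(!is.na(run$ticks$group_knowledge)) && all(run$agents$chose_group)
}

#' Run-level exploitation classification
#'
#' Classifies a run by the mean post-harvest stock over ticks 2..n against
#' the maximum-regeneration stock bin of the table: below the bin (minus
#' `tolerance`) is overexploitation, above the bin (plus `tolerance`) is
#' underexploitation, inside is optimal. On the default table the bin is
#' 25-29, so with the default tolerance of 2 the optimal band of mean
#' post-harvest stock is 23-31.
#'
#' @param run A `cpr_run` object.
#' @param table The [regen_table()] the run was simulated with.
#' @param tolerance Stock units added on both sides of the bin.
#' @return One of `"over"`, `"optimal"`, `"under"`.
#' @export
classify_exploitation <- function(run, table = default_regen_table(),
                                  tolerance = 2) {
  bin <- msy(table)$bin
  p <- run$ticks$post_harvest
  m <- if (length(p) >= 2) mean(p[-1]) else mean(p)
  if (m < bin[1] - tolerance) "over"
  else if (m > bin[2] + tolerance) "under"
  else "optimal"
}

#' Per-tick deviation of group extraction from the optimal policy
#'
#' For each tick, the group's total extraction minus the extraction the
#' optimal policy would take at the stock actually facing the group that
#' tick. Positive values indicate overexploitation, negative values
#' underexploitation; an optimally managed run has all zeros.
#'
#' @param run A `cpr_run` object.
#' @param table The [regen_table()] the run was simulated with.
#' @param policy Optional precomputed [optimal_policy_vector()] (pass it when
#'   calling in a loop).
#' @return Numeric vector of signed deviations, one per tick.
#' @export
deviation_series <- function(run, table = default_regen_table(),
                             policy = optimal_policy_vector(table)) {
  run$ticks$total_extraction -
    optimal_extraction(table, run$ticks$stock_start, policy = policy)
}

#' Learning trend of a deviation series
#'
#' The least-squares slope of the absolute deviation against the tick index.
#' A negative slope means the group moves closer to the optimal exploitation
#' path as the game progresses.
#'
#' @param deviations Signed per-tick deviations (e.g. from
#'   [deviation_series()]).
#' @return The slope (stock units per tick).
#' @export
learning_trend <- function(deviations) {
  n <- length(deviations)
  if (n < 2) stop("need at least two ticks to estimate a trend", call. = FALSE)
  t <- seq_len(n)
  y <- abs(deviations)
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Pattern-oriented validation of a sweep
#'
#' Checks whether a set of simulated runs reproduces the qualitative outcome
#' patterns of the behavioral experiments: (a) both cooperative and
#' non-cooperative runs occur; (b) all three exploitation classes (over,
#' under, optimal) occur; (c) all three exploitation classes occur among the
#' cooperative runs.
#'
#' @param run_stats A data frame with logical column `cooperative` and
#'   character column `exploitation` (one row per run), e.g. the stacked
#'   `run_stats` of [run_sweep()] or [simulate_batch()].
#' @return A list of three logicals, `a`, `b` and `c`.
#' @export
pattern_check <- function(run_stats) {
  classes <- c("over", "optimal", "under")
  if (is.null(run_stats) || nrow(run_stats) == 0) {
    return(list(a = FALSE, b = FALSE, c = FALSE))
  }
  coop <- run_stats$cooperative
  list(
    a = any(coop) && any(!coop),
    b = all(classes %in% run_stats$exploitation),
    c = all(classes %in% run_stats$exploitation[coop])
  )
}

#' Mean distance of a stock trajectory from the MSY stock band
#'
#' Distance zero means the reported stock sits inside the band from which
#' the maximum sustainable yield can be harvested every tick.
#'
#' @param stock Vector of reported stock sizes.
#' @param table A [regen_table()] object.
#' @return Mean distance in stock units.
#' @export
band_distance <- function(stock, table = default_regen_table()) {
  band <- msy_stock_band(table)
  mean(pmax(0, band[1] - stock, stock - band[2]))
}
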