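#' Stepwise regeneration table for a renewable resource
#'
#' The ecological core of the model is a discrete, binned version of logistic
#' growth: the per-tick regeneration of the resource is piecewise constant on
#' consecutive stock bins of width `bin_width`, zero below `min_regen_stock`
#' (the stock must retain a minimum of breeding units to regenerate at all)
#' and zero at or above `capacity` (a full habitat adds nothing). The table is
#' required to be unimodal with a unique maximum bin; the maximum value is the
#' maximum sustainable yield (MSY) of the system.
#'
#' @param regen_by_bin Integer vector of non-negative regeneration values, one
#'   per bin, for bins starting at `min_regen_stock`, `min_regen_stock +
#'   bin_width`, ... up to `capacity`. The final bin (lower edge `capacity`)
#'   must be zero.
#' @param capacity Maximum stock size (carrying capacity), in stock units.
#' @param min_regen_stock Smallest stock size with positive regeneration.
#' @param bin_width Width of each constant-regeneration bin, in stock units.
#'
#' @return An object of class `regen_table`: a list with fields `capacity`,
#'   `min_regen_stock`, `bin_width`, `bin_lower` (lower edge of each bin),
#'   `regen_by_bin`, and `regen_by_stock` (a lookup vector over integer
#'   stocks `0:capacity`).
#' @seealso [default_regen_table()], [regen()], [resource_step()], [msy()]
#' @export
#' @examples
#' tab <- default_regen_table()
#' regen(tab, 25)
#' msy(tab)
regen_table <- function(regen_by_bin,
                        capacity = 50,
                        min_regen_stock = 5,
                        bin_width = 5) {
  stopifnot(
    length(capacity) == 1, capacity > 0,
    length(min_regen_stock) == 1, min_regen_stock >= 0,
    length(bin_width) == 1, bin_width >= 1
  )
  bin_lower <- seq(min_regen_stock, capacity, by = bin_width)
  if (length(regen_by_bin) != length(bin_lower)) {
    stop(sprintf(
      "expected %d regeneration values (one per bin from stock %d to %d), got %d",
      length(bin_lower), min_regen_stock, capacity, length(regen_by_bin)
    ), call. = FALSE)
  }
  if (any(regen_by_bin < 0) || any(regen_by_bin != floor(regen_by_bin))) {
    stop("regeneration values must be non-negative integers", call. = FALSE)
  }
  if (regen_by_bin[length(regen_by_bin)] != 0) {
    stop("regeneration must be 0 at and above carrying capacity", call. = FALSE)
  }
  # unimodality with a unique maximum bin
  peak <- which.max(regen_by_bin)
  if (sum(regen_by_bin == regen_by_bin[peak]) != 1) {
    stop("regeneration table must have a unique maximum bin", call. = FALSE)
  }
  rising <- regen_by_bin[seq_len(peak)]
  falling <- regen_by_bin[peak:length(regen_by_bin)]
  if (is.unsorted(rising) || is.unsorted(rev(falling))) {
    stop("regeneration table must be unimodal", call. = FALSE)
  }

  # lookup over integer stocks 0..capacity
  stocks <- 0:capacity
  idx <- findInterval(stocks, bin_lower)           # 0 below first bin
  regen_by_stock <- ifelse(idx == 0, 0, regen_by_bin[pmax(idx, 1)])
  regen_by_stock[stocks >= capacity] <- 0

  structure(
    list(
      capacity = as.numeric(capacity),
      min_regen_stock = as.numeric(min_regen_stock),
      bin_width = as.numeric(bin_width),
      bin_lower = bin_lower,
      regen_by_bin = as.numeric(regen_by_bin),
      regen_by_stock = as.numeric(regen_by_stock)
    ),
    class = "regen_table"
  )
}

#' Default stepwise-logistic regeneration table
#'
#' Builds the default table by evaluating the discrete logistic increment
#' `floor(r * s * (1 - s / K))` with growth rate `r = 0.72` and carrying
#' capacity `K = 50` at the lower edge `s` of each 5-unit bin starting at
#' `s = 5`, and 0 elsewhere. The resulting per-bin values (by ascending bin
#' lower edge 5, 10, ..., 50) are 3, 5, 7, 8, 9, 8, 7, 5, 3, 0, so the MSY is
#' 9 units, attained on the stock bin 25-29.
#'
#' @param r Logistic growth rate used in the binned construction.
#' @param capacity Carrying capacity `K`, in stock units.
#' @param min_regen_stock Smallest stock with positive regeneration.
#' @param bin_width Bin width in stock units.
#' @return A [regen_table()] object.
#' @export
default_regen_table <- function(r = 0.72, capacity = 50,
                                min_regen_stock = 5, bin_width = 5) {
  s <- seq(min_regen_stock, capacity, by = bin_width)
  vals <- floor(r * s * (1 - s / capacity))
  vals[s >= capacity] <- 0
  regen_table(vals, capacity = capacity,
              min_regen_stock = min_regen_stock, bin_width = bin_width)
}

#' @export
print.regen_table <- function(x, ...) {
  cat(sprintf(
    "Stepwise regeneration table: capacity %g, regeneration threshold %g, bin width %g\n",
    x$capacity, x$min_regen_stock, x$bin_width
  ))
  print(stats::setNames(x$regen_by_bin, x$bin_lower))
  m <- msy(x)
  cat(sprintf("MSY %g on stock bin [%g, %g]\n", m$yield, m$bin[1], m$bin[2]))
  invisible(x)
}

#' Read a regeneration table from CSV
#'
#' The file must have a header row and two columns, `bin_lower_edge` and
#' `regeneration`, one row per bin. Bin lower edges must be equally spaced;
#' the first edge is the regeneration threshold and the last edge the
#' carrying capacity. The loaded table is validated against all
#' `regen_table` invariants.
#'
#' @param path Path to the CSV file.
#' @return A [regen_table()] object.
#' @export
read_regen_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("bin_lower_edge", "regeneration") %in% names(df))) {
    stop("regeneration table CSV must have columns 'bin_lower_edge' and 'regeneration'",
         call. = FALSE)
  }
  df <- df[order(df$bin_lower_edge), ]
  edges <- df$bin_lower_edge
  if (length(edges) < 2) stop("regeneration table needs at least two bins", call. = FALSE)
  widths <- diff(edges)
  if (length(unique(widths)) != 1) {
    stop("bin lower edges must be equally spaced", call. = FALSE)
  }
  regen_table(df$regeneration,
              capacity = edges[length(edges)],
              min_regen_stock = edges[1],
              bin_width = widths[1])
}

#' Write a regeneration table to CSV
#'
#' @param table A [regen_table()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regen_table <- function(table, path) {
  utils::write.csv(
    data.frame(bin_lower_edge = table$bin_lower,
               regeneration = table$regen_by_bin),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Per-tick regeneration at a given stock size
#'
#' Returns the bin value for `floor(stock)`: 0 below the regeneration
#' threshold and at or above capacity. Stock may be real-valued (group shares
#' are generally non-integer); regeneration is looked up by the integer part.
#' A stock within `1e-9` below a bin edge counts as the edge, so accumulated
#' floating-point noise cannot flip a stock into the neighboring bin.
#'
#' @param table A [regen_table()] object.
#' @param stock Stock size(s), >= 0. Vectorised.
#' @return Regeneration in stock units, same length as `stock`.
#' @export
regen <- function(table, stock) {
  if (any(stock < 0)) stop("negative stock: corrupted state", call. = FALSE)
  s <- pmin(floor(stock + 1e-9), table$capacity)
  table$regen_by_stock[s + 1]
}

#' One ecological step: extraction followed by regeneration
#'
#' Extraction is capped at the available stock; the post-harvest stock then
#' regenerates according to the table, and the result is capped at carrying
#' capacity. The resource regenerates depending on the post-harvest stock
#' size, which is determined by the group's total extraction.
#'
#' @param table A [regen_table()] object.
#' @param stock Current stock in `[0, capacity]`. Vectorised.
#' @param total_extraction Total units extracted this tick, >= 0.
#' @return New stock size in `[0, capacity]`.
#' @export
resource_step <- function(table, stock, total_extraction) {
  e <- pmin(total_extraction, stock)
  p <- pmax(stock - e, 0)
  pmin(table$capacity, p + regen(table, p))
}

#' Maximum sustainable yield of a regeneration table
#'
#' @param table A [regen_table()] object.
#' @return A list with `yield` (the maximum regeneration value) and `bin`
#'   (the `[lower, upper]` stock interval attaining it).
#' @export
msy <- function(table) {
  i <- which.max(table$regen_by_bin)
  lower <- table$bin_lower[i]
  upper <- min(lower + table$bin_width - 1, table$capacity)
  list(yield = table$regen_by_bin[i], bin = c(lower, upper))
}

#' Stock band on which the maximum sustainable yield can be harvested forever
#'
#' The set of (pre-harvest) stock sizes from which extracting the MSY leaves
#' the post-harvest stock inside the maximum-regeneration bin, so the same
#' harvest is available again next tick. Its lower edge is the recovery
#' threshold of the optimal policy: after depletion, the optimal strategy
#' lets the stock recover to this level before extraction resumes.
#'
#' @param table A [regen_table()] object.
#' @return Numeric `[lower, upper]` stock interval.
#' @export
msy_stock_band <- function(table) {
  m <- msy(table)
  c(m$bin[1] + m$yield, min(m$bin[2] + m$yield, table$capacity))
}

#' @rdname msy_stock_band
#' @export
recovery_threshold <- function(table) msy_stock_band(table)[1]

# Finite-horizon value iteration over integer stock states.
# V[s+1] = best total harvest from stock s with `iters` ticks remaining.
# Returns the final value vector.
.value_iterate <- function(table, iters) {
  K <- as.integer(table$capacity)
  states <- 0:K
  # next-state matrix: rows = stock s, cols = action e (0..K), e > s invalid
  nxt <- matrix(NA_integer_, nrow = K + 1, ncol = K + 1)
  for (s in states) {
    e <- 0:s
    p <- s - e
    nxt[s + 1, e + 1] <- as.integer(pmin(K, p + table$regen_by_stock[p + 1]))
  }
  V <- numeric(K + 1)
  for (it in seq_len(iters)) {
    Vn <- numeric(K + 1)
    for (s in states) {
      e <- 0:s
      Vn[s + 1] <- max(e + V[nxt[s + 1, e + 1] + 1])
    }
    V <- Vn
  }
  V
}

# Greedy action per integer state w.r.t. a continuation value vector,
# breaking ties by the largest extraction.
.greedy_actions <- function(table, V) {
  K <- as.integer(table$capacity)
  a <- integer(K + 1)
  for (s in 0:K) {
    e <- 0:s
    p <- s - e
    nxt <- pmin(K, p + table$regen_by_stock[p + 1])
    q <- e + V[nxt + 1]
    best <- max(q)
    a[s + 1] <- max(e[q >= best - 1e-9])
  }
  a
}

#' Stationary optimal harvest policy over integer stock states
#'
#' Computes, by dynamic programming over the integer stock states, the
#' extraction that maximizes long-run per-tick harvest from each stock size,
#' with ties broken in favour of harvesting earlier. The game end is treated
#' as unknown: values are iterated far beyond the horizon of interest so that
#' no terminal-round liquidation occurs. On the default table the policy is
#' "harvest down to the lower edge of the maximum-regeneration bin, else
#' wait".
#'
#' @param table A [regen_table()] object.
#' @param lookahead Number of value-iteration sweeps used to approximate the
#'   infinite-horizon continuation value. The default is ample for tables of
#'   this size (transients die out within a handful of ticks).
#' @return Integer vector of length `capacity + 1`: the optimal extraction
#'   for integer stocks `0:capacity`.
#' @export
optimal_policy_vector <- function(table, lookahead = 200L) {
  V <- .value_iterate(table, lookahead)
  .greedy_actions(table, V)
}

#' Optimal extraction sequence from a given stock
#'
#' Rolls the stationary optimal policy (see [optimal_policy_vector()])
#' forward from `initial_stock` for `horizon` ticks and returns the per-tick
#' group extraction sequence.
#'
#' @param table A [regen_table()] object.
#' @param initial_stock Starting stock in `[0, capacity]`.
#' @param horizon Number of ticks, >= 1.
#' @return Numeric vector of length `horizon`.
#' @export
#' @examples
#' optimal_policy(default_regen_table(), 50, 5) # 25 then 9 per tick
optimal_policy <- function(table, initial_stock, horizon) {
  stopifnot(horizon >= 1,
            initial_stock >= 0, initial_stock <= table$capacity)
  a <- optimal_policy_vector(table, lookahead = as.integer(horizon) + 200L)
  s <- as.integer(floor(initial_stock))
  out <- numeric(horizon)
  for (t in seq_len(horizon)) {
    e <- a[s + 1]
    out[t] <- e
    s <- as.integer(resource_step(table, s, e))
  }
  out
}

#' Optimal extraction at a single stock size
#'
#' Convenience lookup into [optimal_policy_vector()]; real-valued stocks are
#' floored before the lookup.
#'
#' @param table A [regen_table()] object.
#' @param stock Stock size(s) in `[0, capacity]`. Vectorised.
#' @param policy Optional precomputed policy vector (for repeated calls).
#' @return Optimal extraction(s) in stock units.
#' @export
optimal_extraction <- function(table, stock, policy = optimal_policy_vector(table)) {
  policy[pmin(floor(stock), table$capacity) + 1]
}
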