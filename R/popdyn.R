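#' Binned rate matrix of a simulation
#'
#' Spike counts per cell in non-overlapping 100 ms bins, restricted to cells
#' with at least `min_spikes` spikes.
#'
#' @param result A `simulation_result` (or any list of per-cell spike-time
#'   vectors via `result$spike_times`).
#' @param bin Bin width in seconds (default 0.1).
#' @param duration Total duration in seconds (defaults to the config's).
#' @param min_spikes Minimum spikes for inclusion (default 10).
#' @return List with `counts` (cells x bins integer matrix), `cells` (the
#'   indices kept), and `bin`.
#' @export
rate_matrix <- function(result, bin = 0.1, duration = NULL, min_spikes = 10) {
  st <- result$spike_times
  if (is.null(duration)) duration <- result$config$duration
  nb <- floor(duration / bin)
  keep <- which(lengths(st) >= min_spikes)
  counts <- t(vapply(st[keep], function(s)
    tabulate(pmin(floor(s / bin), nb - 1L) + 1L, nbins = nb), integer(nb)))
  list(counts = counts, cells = keep, bin = bin)
}

#' Eigenvalue entropy of the rate correlation matrix
#'
#' Computes the Pearson correlation matrix of the binned single-cell rates,
#' its eigenvalues \eqn{\lambda_i}, the explained-variance shares
#' \eqn{p_i = \lambda_i / \sum_j \lambda_j}, and their entropy
#' \eqn{H = -\sum_i p_i \ln p_i}. Low entropy means a few collective modes
#' dominate the rate fluctuations (coherent assemblies); entropy near
#' \eqn{\ln N} means uncorrelated cells.
#'
#' @param result A `simulation_result`.
#' @param bin Rate bin width in seconds.
#' @param min_spikes Cell inclusion threshold.
#' @return List with `eigenvalues`, `shares`, `entropy`, `n_cells`, and
#'   `dropped` (zero-variance cells removed).
#' @export
rate_correlation_entropy <- function(result, bin = 0.1, min_spikes = 10) {
  rm_ <- rate_matrix(result, bin = bin, min_spikes = min_spikes)
  if (nrow(rm_$counts) < 2) stop("need at least 2 qualifying cells")
  v <- apply(rm_$counts, 1, stats::var)
  dropped <- rm_$cells[v == 0]
  x <- rm_$counts[v > 0, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 cells with rate variance")
  cm <- stats::cor(t(x))
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  p <- ev / sum(ev)
  list(eigenvalues = ev, shares = p,
       entropy = -sum(p[p > 0] * log(p[p > 0])),
       n_cells = nrow(x), dropped = dropped)
}

#' Raster-display cell ordering by K-means clustering
#'
#' Clusters the rows of the rate correlation matrix into `k` groups (Lloyd
#' iterations with multiple seeded starts) and returns a permutation of the
#' qualifying cells that lists cluster members contiguously, for raster
#' plots in which coherent assemblies appear as stripes.
#'
#' @param result A `simulation_result`.
#' @param k Number of clusters (default 30; reduced with a warning when
#'   fewer cells qualify).
#' @param seed Seed for the clustering starts.
#' @param bin,min_spikes Passed to [rate_matrix()].
#' @return List with `order` (cell indices, a permutation of the qualifying
#'   cells), `cluster` assignments, and `cells`.
#' @export
raster_order <- function(result, k = 30, seed = 1, bin = 0.1,
                         min_spikes = 10) {
  rm_ <- rate_matrix(result, bin = bin, min_spikes = min_spikes)
  v <- apply(rm_$counts, 1, stats::var)
  x <- rm_$counts[v > 0, , drop = FALSE]
  cells <- rm_$cells[v > 0]
  if (length(cells) < k) {
    warning(sprintf("only %d cells; reducing k from %d", length(cells), k))
    k <- max(1L, length(cells) %/% 2L)
  }
  cm <- stats::cor(t(x))
  set.seed(seed)
  km <- stats::kmeans(cm, centers = k, iter.max = 50, nstart = 5)
  ord <- order(km$cluster)
  list(order = cells[ord], cluster = km$cluster, cells = cells)
}

#' Active-cell counts of a simulation
#'
#' @param result A `simulation_result`.
#' @return List with `n_any_spike` (cells with at least one spike; the
#'   quantity whose g_I dependence has an interior minimum at the
#'   frozen-to-active transition) and `n_ge11_spikes` (cells with at least
#'   11 spikes, the statistics-eligible count).
#' @export
active_cell_counts <- function(result) {
  ns <- lengths(result$spike_times)
  list(n_any_spike = sum(ns >= 1L), n_ge11_spikes = sum(ns >= 11L))
}

#' Balance-rescaled mean firing rate
#'
#' \eqn{r \cdot g_I / g_E}: under excitation-inhibition balance the
#' population rate is proportional to \eqn{g_E / g_I}, so this rescaled rate
#' is approximately constant across the active regime.
#'
#' @param rate Mean firing rate (Hz).
#' @param g_E,g_I Network parameters (`g_E > 0`).
#' @return Scalar rescaled rate.
#' @export
dmft_rescaled_rate <- function(rate, g_E, g_I) {
  if (g_E <= 0) stop("g_E must be > 0")
  if (g_I == 0 || rate == 0) return(0)
  rate * g_I / g_E
}

#' Segment-wise network statistics
#'
#' Divides a simulation into non-overlapping segments (default 40 s), and in
#' each segment averages per-cell statistics (rate, ISI CV, lognormal shape)
#' over the cells with at least 11 spikes in that segment; the standard
#' error across segments quantifies the fluctuation of the network averages.
#'
#' @param result A `simulation_result`.
#' @param segment_len Segment length in seconds (default 40).
#' @return List with `per_segment` (data frame: segment, n_cells, rate, cv,
#'   sigma_ln) and `summary` (means and SEMs across segments).
#' @export
segmentwise_network_stats <- function(result, segment_len = 40) {
  dur <- result$config$duration
  n_seg <- floor(dur / segment_len)
  if (n_seg < 1) stop("duration shorter than one segment")
  rows <- lapply(seq_len(n_seg), function(s) {
    t0 <- (s - 1) * segment_len; t1 <- s * segment_len
    stats_ <- lapply(result$spike_times, function(st) {
      st <- st[st >= t0 & st < t1]
      if (length(st) < 11L) return(NULL)
      isis <- diff(st)
      mu <- mean(isis); sd_ <- stats::sd(isis) * sqrt((length(isis) - 1) / length(isis))
      l <- log(isis)
      c(rate = length(st) / segment_len, cv = sd_ / mu,
        sigma_ln = sqrt(mean((l - mean(l))^2)))
    })
    stats_ <- do.call(rbind, stats_[!vapply(stats_, is.null, TRUE)])
    if (is.null(stats_))
      return(data.frame(segment = s, n_cells = 0L, rate = NA_real_,
                        cv = NA_real_, sigma_ln = NA_real_))
    data.frame(segment = s, n_cells = nrow(stats_),
               rate = mean(stats_[, "rate"]), cv = mean(stats_[, "cv"]),
               sigma_ln = mean(stats_[, "sigma_ln"]))
  })
  per <- do.call(rbind, rows)
  ok <- stats::complete.cases(per)
  summ <- vapply(c("rate", "cv", "sigma_ln"), function(q) {
    x <- per[[q]][ok]
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
  }, c(mean = 0, sem = 0))
  list(per_segment = per, summary = summ)
}
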