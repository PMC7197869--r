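#' Inter-spike-interval sequence of a spike train
#'
#' Converts strictly increasing spike times into the ordered sequence of
#' inter-spike intervals (ISIs) \eqn{I_i = t_{i+1} - t_i}.
#'
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing.
#' @return Numeric vector of ISIs in seconds (length `length(spike_times) - 1`).
#' @export
spike_isis <- function(spike_times) {
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  diff(spike_times)
}

#' ISI moment statistics
#'
#' Mean ISI, coefficient of variation, rescaled skew and firing rate of one
#' spike-train segment. Moments are the plain (population) moments of the ISI
#' sequence: \eqn{\mu = \langle I \rangle},
#' \eqn{\sigma^2 = \langle I^2 \rangle - \mu^2},
#' skew \eqn{S = (\langle I^3 \rangle - 3\mu\sigma^2 - \mu^3)/\sigma^3},
#' reported rescaled as \eqn{S/CV}. The firing rate is the spike count divided
#' by the observation window, which can differ substantially from \eqn{1/\mu}
#' when spikes cluster in a sub-interval of the window.
#'
#' @param isis Numeric vector of ISIs (seconds), at least 10 intervals.
#' @param t_seg Observation window length in seconds (default 200).
#' @param n_spikes Spike count used for the rate; defaults to
#'   `length(isis) + 1`.
#' @return A list with `mu`, `cv`, `rescaled_skew`, `rate`, and a logical
#'   `degenerate` flag (`TRUE` when the ISI standard deviation is numerically
#'   zero, in which case `cv` is 0 and `rescaled_skew` is `NA`).
#' @export
isi_moments <- function(isis, t_seg = 200, n_spikes = length(isis) + 1L) {
  if (length(isis) < 10L) stop("need at least 10 ISIs")
  mu <- mean(isis)
  s2 <- mean(isis^2) - mu^2
  s2 <- max(s2, 0)
  sd_ <- sqrt(s2)
  rate <- n_spikes / t_seg
  if (sd_ < 1e-9 * mu) {
    return(list(mu = mu, cv = 0, rescaled_skew = NA_real_, rate = rate,
                degenerate = TRUE))
  }
  cv <- sd_ / mu
  skew <- (mean(isis^3) - 3 * mu * s2 - mu^3) / sd_^3
  list(mu = mu, cv = cv, rescaled_skew = skew / cv, rate = rate,
       degenerate = FALSE)
}

#' Serial ISI autocorrelation at a given lag
#'
#' \eqn{\rho(n) = (\langle I_{i+n} I_i \rangle - \mu^2)/\sigma^2}, averaging
#' over \eqn{i = 1, \dots, N-n}, with \eqn{\mu} and \eqn{\sigma} the
#' whole-sequence moments. For an i.i.d. ISI sequence this vanishes for all
#' lags; for a perfectly alternating sequence it tends to -1 at lag 1.
#'
#' @param isis Numeric vector of ISIs.
#' @param lag Positive integer lag.
#' @return Scalar autocorrelation, or `NA` (flagged degenerate) when the ISI
#'   variance is numerically zero.
#' @export
serial_autocorrelation <- function(isis, lag = 1L) {
  lag <- as.integer(lag)
  n <- length(isis)
  if (n <= lag + 1L) stop("need more than lag + 1 ISIs")
  mu <- mean(isis)
  s2 <- mean(isis^2) - mu^2
  if (s2 < (1e-9 * mu)^2) return(NA_real_)
  (mean(isis[seq_len(n - lag) + lag] * isis[seq_len(n - lag)]) - mu^2) / s2
}

#' Local CV quintile distribution
#'
#' The local CV of successive intervals is
#' \eqn{X_i = |I_{i+1} - I_i| / (I_{i+1} + I_i) \in [0, 1]}. Its distribution
#' is summarized by the fraction of \eqn{X_i} falling in each of five equal
#' bins. Bins are half-open `[j/5, (j+1)/5)` with the last bin closed at 1, so
#' the five fractions always partition and sum to exactly 1; a value of
#' exactly 0.5 falls in the third bin.
#'
#' @param isis Numeric vector of ISIs, at least 2.
#' @return Numeric vector of length 5 (`LCV(1)` .. `LCV(5)`), summing to 1.
#' @export
local_cv_quintiles <- function(isis) {
  n <- length(isis)
  if (n < 2L) stop("need at least 2 ISIs")
  x <- abs(diff(isis)) / (isis[-1] + isis[-n])
  idx <- pmin(floor(x * 5), 4) + 1L
  as.numeric(tabulate(idx, nbins = 5L)) / (n - 1L)
}

#' Maximum-likelihood lognormal parameters
#'
#' Exact ML estimators on the log scale: scale
#' \eqn{\mu_{LN} = \langle \ln I \rangle} and shape
#' \eqn{\sigma_{LN} = \sqrt{\langle (\ln I - \mu_{LN})^2 \rangle}}.
#'
#' @param isis Numeric vector of strictly positive ISIs.
#' @return List with `mu_ln`, `sigma_ln`.
#' @export
ml_lognormal <- function(isis) {
  if (any(isis <= 0)) stop("ISIs must be strictly positive")
  l <- log(isis)
  mu_ln <- mean(l)
  list(mu_ln = mu_ln, sigma_ln = sqrt(mean((l - mu_ln)^2)))
}

#' Maximum-likelihood gamma parameters (closed-form approximation)
#'
#' Shape from the standard closed-form approximation to the gamma ML
#' equations: with \eqn{z = \ln\mu - \langle \ln I \rangle},
#' \deqn{\sigma_\gamma = \frac{3 - z + \sqrt{(3 - z)^2 + 24 z}}{12 z},}
#' and scale \eqn{\mu_\gamma = \mu / \sigma_\gamma}. For exponential data
#' \eqn{z} approaches the Euler-Mascheroni constant and the shape is close to
#' 1; as \eqn{z \to 0^+} (constant data) the shape diverges.
#'
#' @param isis Numeric vector of strictly positive ISIs.
#' @return List with `shape` (\eqn{\sigma_\gamma}), `scale`
#'   (\eqn{\mu_\gamma}), `log_scale` (\eqn{\ln \mu_\gamma}) and a `degenerate`
#'   flag set when \eqn{z \le 0}.
#' @export
ml_gamma <- function(isis) {
  if (any(isis <= 0)) stop("ISIs must be strictly positive")
  mu <- mean(isis)
  z <- log(mu) - mean(log(isis))
  if (!is.finite(z) || z <= 0) {
    return(list(shape = Inf, scale = 0, log_scale = -Inf, degenerate = TRUE))
  }
  shape <- (3 - z + sqrt((3 - z)^2 + 24 * z)) / (12 * z)
  list(shape = shape, scale = mu / shape, log_scale = log(mu / shape),
       degenerate = FALSE)
}

#' Maximum-likelihood inverse-Gaussian shape parameter
#'
#' Exact ML estimator \eqn{\sigma_{IG} = (\langle I^{-1} \rangle -
#' \mu^{-1})^{-1}}; the ML scale parameter of the inverse-Gaussian family is
#' the sample mean itself.
#'
#' @param isis Numeric vector of strictly positive ISIs.
#' @return List with `shape` (\eqn{\sigma_{IG}}), `mean` (\eqn{\mu}) and a
#'   `degenerate` flag (constant data drives the shape to infinity).
#' @export
ml_invgauss <- function(isis) {
  if (any(isis <= 0)) stop("ISIs must be strictly positive")
  mu <- mean(isis)
  d <- mean(1 / isis) - 1 / mu
  if (d <= 0) return(list(shape = Inf, mean = mu, degenerate = TRUE))
  list(shape = 1 / d, mean = mu, degenerate = FALSE)
}

#' Censorship-corrected cumulative ISI distribution
#'
#' Histogram weights
#' \eqn{P(n) = \sum_i 1\{n\Delta\tau \le I_i < (n+1)\Delta\tau\} \cdot
#' T/(T - I_i)} reweight each observed interval by the inverse probability
#' that an interval of its length fits inside the finite observation window
#' \eqn{T} (long intervals are under-sampled), and
#' \eqn{Q(n) = \sum_{k \ge n} P(k) / \sum_{k \ge 0} P(k)} is the corrected
#' survival function on the bin lattice, with \eqn{Q(0) = 1}.
#'
#' @param isis Numeric vector of ISIs, all < `t_seg`.
#' @param delta_tau Bin width in seconds (0.01 for display; 1e-4 for KS fits).
#' @param t_seg Observation window in seconds.
#' @return An object of class `cumulative_isi`: a list with `q` (survival
#'   values for bins `0 .. m_max`), `delta_tau`, `t_seg`, and `m_last`, the
#'   largest bin index with `q > 1e-8`.
#' @export
censored_cumulative <- function(isis, delta_tau = 0.01, t_seg = 200) {
  if (any(isis >= t_seg)) stop("ISIs must be shorter than the segment")
  if (any(isis <= 0)) stop("ISIs must be positive")
  bins <- floor(isis / delta_tau)
  w <- t_seg / (t_seg - isis)
  nb <- max(bins) + 1L
  p <- vapply(split(w, factor(bins, levels = 0:(nb - 1L))), sum, 0)
  surv <- rev(cumsum(rev(p)))
  q <- surv / surv[1]
  structure(list(q = unname(q), delta_tau = delta_tau, t_seg = t_seg,
                 m_last = max(which(q > 1e-8)) - 1L),
            class = "cumulative_isi")
}

#' Kolmogorov-Smirnov distance from a fitted ISI family
#'
#' Compares the censorship-corrected survival function `Q(n)` with a fitted
#' family's CDF `D(n)` evaluated on the same bin lattice:
#' \eqn{KS = \max_n |1 - D(n) - Q(n)|} over `n = 1 .. M` where `M` is the
#' largest index with `Q(M) > 1e-8`. Family CDFs: gamma (regularized
#' incomplete gamma), lognormal, inverse-Gaussian (Gaussian-mixture closed
#' form), and exponential with mean \eqn{\mu}. Because `Q` is piecewise
#' constant and `D` monotone, the maximum is attained at a bin where `Q`
#' changes (or at the range ends), so only those bins are evaluated.
#'
#' @param q A `cumulative_isi` built with the KS bin width (1e-4 s).
#' @param family One of `"exponential"`, `"gamma"`, `"lognormal"`,
#'   `"invgauss"`.
#' @param params Named list of fitted parameters: `mu` (exponential), `shape`
#'   and `scale` (gamma), `mu_ln` and `sigma_ln` (lognormal), `shape` and
#'   `mean` (invgauss).
#' @return Scalar KS distance; degenerate parameter sets give 1 with
#'   attribute `degenerate = TRUE`.
#' @export
ks_distance <- function(q, family = c("exponential", "gamma", "lognormal",
                                      "invgauss"), params) {
  family <- match.arg(family)
  stopifnot(inherits(q, "cumulative_isi"))
  dt <- q$delta_tau
  m <- q$m_last
  if (m < 1L) return(structure(1, degenerate = TRUE))
  degen <- switch(family,
    exponential = !is.finite(params$mu) || params$mu <= 0,
    gamma = !is.finite(params$shape) || params$shape <= 0 ||
      !is.finite(params$scale) || params$scale <= 0,
    lognormal = !is.finite(params$sigma_ln) || params$sigma_ln <= 0,
    invgauss = !is.finite(params$shape) || params$shape <= 0)
  if (degen) return(structure(1, degenerate = TRUE))
  qn <- q$q[seq_len(m + 1L)]            # Q(0) .. Q(m)
  # bins where Q changes, plus the range ends
  change <- which(diff(qn) != 0)        # Q(change) != Q(change+1), 1-based on n = change
  n_eval <- sort(unique(pmin(pmax(c(1L, change, change + 1L, m), 1L), m)))
  x <- n_eval * dt
  d <- switch(family,
    exponential = 1 - exp(-x / params$mu),
    gamma = stats::pgamma(x, shape = params$shape, scale = params$scale),
    lognormal = stats::pnorm((log(x) - params$mu_ln) / params$sigma_ln),
    invgauss = {
      a <- sqrt(params$shape / x)
      b <- exp(2 * params$shape / params$mean)
      stats::pnorm(a * x / params$mean - a) +
        b * stats::pnorm(-a * x / params$mean - a)
    })
  max(abs(1 - d - qn[n_eval + 1L]))
}

#' Morlet-wavelet spike-train power spectrum
#'
#' Spike counts in non-overlapping 4 ms windows are convolved with complex
#' Morlet wavelets on the canonical frequency ladder
#' \eqn{f_k = 2^{k/8}/64} Hz (capped at the 125 Hz Nyquist frequency of the
#' count series). Each wavelet has temporal standard deviation
#' \eqn{\sigma_t = 6/(2\pi f)} and support truncated at \eqn{\pm 3\sigma_t}.
#' The spectrum is the time average of the squared modulus of the
#' time-frequency representation, normalized by the train's mean rate so that
#' a homogeneous Poisson train gives \eqn{S(f) \approx 1} at every frequency.
#' The first and last \eqn{3\sigma_t} of each convolution are discarded to
#' avoid edge artifacts; frequencies whose support exceeds the segment return
#' `NA`.
#'
#' @param spike_times Spike times in seconds.
#' @param t_seg Segment length in seconds.
#' @param bin Count-window width in seconds (default 0.004).
#' @return Data frame with columns `freq` (Hz) and `power`.
#' @export
morlet_power_spectrum <- function(spike_times, t_seg = 200, bin = 0.004) {
  if (length(spike_times) < 11L) stop("need at least 11 spikes")
  nb <- floor(t_seg / bin)
  counts <- tabulate(pmin(floor(spike_times / bin), nb - 1L) + 1L, nbins = nb)
  rate <- length(spike_times) / t_seg
  nyq <- 1 / (2 * bin)
  k <- 0:200
  freqs <- (1 / 64) * 2^(k / 8)
  freqs <- freqs[freqs <= nyq]
  n_fft <- stats::nextn(2L * nb, 2)
  xf <- stats::fft(c(counts, rep(0, n_fft - nb)))
  power <- vapply(freqs, function(f) {
    sig_t <- 6 / (2 * pi * f)
    half <- floor(3 * sig_t / bin)
    if (2L * half + 1L >= nb) return(NA_real_)
    tt <- (-half:half) * bin
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sig_t^2))
    w <- w / sqrt(sum(Mod(w)^2) * bin)   # so Poisson noise power / rate = 1
    wf <- stats::fft(c(w, rep(0, n_fft - length(w))))
    conv <- stats::fft(xf * wf, inverse = TRUE)[seq_len(nb + 2L * half)] / n_fft
    # full convolution index i corresponds to signal position i - half;
    # keep positions where the kernel lies entirely inside the signal
    valid <- conv[(2L * half + 1L):nb]
    mean(Mod(valid)^2) / rate
  }, 0)
  data.frame(freq = freqs, power = power)
}

#' Canonical feature order of the 15-statistic battery
#' @return Character vector of the 15 feature names in canonical order.
#' @export
feature_names <- function() {
  c("rho1", "rho2", "mu", "cv", "rescaled_skew", "rate",
    "lcv1", "lcv2", "lcv4", "lcv5",
    "log_mu_gamma", "sigma_gamma", "mu_ln", "sigma_ln", "sigma_ig")
}

#' The 15-feature vector of one spike-train segment
#'
#' Assembles, in canonical order, the two lagged serial ISI autocorrelations,
#' the four ISI moment statistics, four of the five local-CV quintiles (the
#' third quintile is excluded from the battery), and the five ML distribution
#' parameters (log gamma scale, gamma shape, lognormal scale and shape,
#' inverse-Gaussian shape).
#'
#' @param spike_times Spike times in seconds within `[0, t_seg]`, at least 11.
#' @param t_seg Segment length in seconds.
#' @return Named numeric vector of length 15, or `NULL` with attribute-free
#'   rejection when a sub-statistic is degenerate (constant ISIs).
#' @export
feature_vector <- function(spike_times, t_seg = 200) {
  if (length(spike_times) < 11L) stop("need at least 11 spikes")
  isis <- spike_isis(spike_times)
  mom <- isi_moments(isis, t_seg, n_spikes = length(spike_times))
  if (mom$degenerate) return(NULL)
  g <- ml_gamma(isis)
  ig <- ml_invgauss(isis)
  if (g$degenerate || ig$degenerate) return(NULL)
  ln <- ml_lognormal(isis)
  lcv <- local_cv_quintiles(isis)
  out <- c(serial_autocorrelation(isis, 1L), serial_autocorrelation(isis, 2L),
           mom$mu, mom$cv, mom$rescaled_skew, mom$rate,
           lcv[1], lcv[2], lcv[4], lcv[5],
           g$log_scale, g$shape, ln$mu_ln, ln$sigma_ln, ig$shape)
  names(out) <- feature_names()
  if (any(!is.finite(out))) return(NULL)
  out
}

#' Feature table for a set of spike-train segments
#'
#' Applies [feature_vector()] to each segment and binds the results with the
#' segment metadata into one data frame (one row per usable segment).
#'
#' @param segments A list of segments, each a list with `spike_times`,
#'   `t_seg`, and optional metadata fields `group`, `age`, `source`.
#' @return Data frame with 15 feature columns plus metadata columns.
#' @export
feature_table <- function(segments) {
  rows <- lapply(segments, function(s) {
    fv <- feature_vector(s$spike_times, s$t_seg)
    if (is.null(fv)) return(NULL)
    meta <- data.frame(group = s$group %||% NA_character_,
                       age = s$age %||% NA_real_,
                       source = s$source %||% NA_character_,
                       stringsAsFactors = FALSE)
    cbind(as.data.frame(as.list(fv)), meta)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- as.data.frame(as.list(stats::setNames(numeric(15), feature_names())))
    return(out[0, ])
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter spike trains and segments by the analysis inclusion rules
#'
#' Experimental mode first removes whole cells whose session-wide ISI
#' rescaled skew exceeds 60 (suggesting recording artifacts) or whose mean
#' rate over the whole session exceeds 10 Hz, then removes 200-s segments
#' with fewer than 11 spikes. Model mode only removes cells (segments) with
#' 10 or fewer spikes; simulated trains carry no artifacts.
#'
#' @param segments List of segments (as in [feature_table()]); in
#'   experimental mode each must carry `cell_rate` (session mean rate, Hz)
#'   and `cell_skew` (session ISI rescaled skew) metadata.
#' @param mode `"experimental"` or `"model"`.
#' @return List with `kept` (segments) and `log` (data frame of rejections
#'   with reasons).
#' @export
filter_segments <- function(segments, mode = c("experimental", "model")) {
  mode <- match.arg(mode)
  reasons <- character(length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (mode == "experimental") {
      if (!is.null(s$cell_skew) && is.finite(s$cell_skew) && s$cell_skew > 60) {
        reasons[i] <- "cell skew > 60"; next
      }
      if (!is.null(s$cell_rate) && is.finite(s$cell_rate) && s$cell_rate > 10) {
        reasons[i] <- "cell rate > 10 Hz"; next
      }
    }
    if (length(s$spike_times) < 11L) reasons[i] <- "fewer than 11 spikes"
  }
  keep <- reasons == ""
  log <- data.frame(index = which(!keep), reason = reasons[!keep],
                    stringsAsFactors = FALSE)
  list(kept = segments[keep], log = log)
}
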