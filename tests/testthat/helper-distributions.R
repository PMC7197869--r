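# Inverse-Gaussian sampler (Michael, Schucany & Haas transformation),
# used as an independent oracle for the IG maximum-likelihood estimator.
statmod_rinvgauss <- function(n, mu = 1, lambda = 1) {
  nu <- rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  z <- runif(n)
  ifelse(z <= mu / (mu + x), x, mu^2 / x)
}

# Build a censorship-corrected survival object directly from an exact CDF on
# the bin lattice, bypassing sampling (for KS self-distance checks).
q_from_cdf <- function(cdf_fun, delta_tau, m_max, t_seg = 200) {
  q <- 1 - cdf_fun((0:m_max) * delta_tau)
  q[1] <- 1
  structure(list(q = q, delta_tau = delta_tau, t_seg = t_seg,
                 m_last = max(which(q > 1e-8)) - 1L),
            class = "cumulative_isi")
}
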