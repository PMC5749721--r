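# Independent numerical oracles used across the suite.  These deliberately
# avoid the package's own integration/fitting code paths.

# high-resolution Riemann-sum overlap integral for two analytic Gaussians:
# donor emission (area-normalised analytically) x extinction x lambda^4
oracle_gaussian_overlap <- function(em_peak, em_sigma, ex_peak, ex_sigma,
                                    eps_peak, lo = 300, hi = 900,
                                    dx = 0.01) {
  wl <- seq(lo, hi, by = dx)
  fd <- exp(-(wl - em_peak)^2 / (2 * em_sigma^2)) /
    (em_sigma * sqrt(2 * pi))
  ea <- eps_peak * exp(-(wl - ex_peak)^2 / (2 * ex_sigma^2))
  sum(fd * ea * wl^4) * dx
}

# frequency response of a multi-exponential decay by adaptive quadrature of
# its Fourier integral at angular frequency omega (rad/s, tau in ns)
oracle_fd_quadrature <- function(a, tau, omega) {
  decay <- function(t) {  # t in ns, intensity fractions a
    rowSums(sapply(seq_along(a),
                   function(i) (a[i] / tau[i]) * exp(-t / tau[i])))
  }
  w <- omega * 1e-9  # rad per ns
  quad <- function(f) stats::integrate(f, 0, Inf, rel.tol = 1e-12,
                                       abs.tol = 1e-13)$value
  denom <- quad(decay)
  re <- quad(function(t) decay(t) * cos(w * t)) / denom
  im <- quad(function(t) decay(t) * sin(w * t)) / denom
  list(phase = atan2(im, re), modulation = sqrt(re^2 + im^2))
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))
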