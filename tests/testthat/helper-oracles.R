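# Independent oracles used by the tests; deliberately written with
# different algorithms than the package implementations.

# Bout segmentation by explicit scan: walk the lick train, closing a bout
# whenever the next inter-lick interval reaches max_ili, and keep runs of
# at least two licks.
oracle_bouts <- function(licks, max_ili = 2) {
  bouts <- list()
  cur <- c()
  for (l in licks) {
    if (length(cur) == 0L) {
      cur <- l
    } else if (l - cur[length(cur)] < max_ili) {
      cur <- c(cur, l)
    } else {
      if (length(cur) >= 2L) bouts[[length(bouts) + 1L]] <- cur
      cur <- l
    }
  }
  if (length(cur) >= 2L) bouts[[length(bouts) + 1L]] <- cur
  if (length(bouts) == 0L) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      n_licks = integer()))
  }
  data.frame(start_s = sapply(bouts, function(b) b[1L]),
             end_s = sapply(bouts, function(b) b[length(b)]),
             n_licks = sapply(bouts, length))
}

# Difference-of-exponentials transient, written from the closed form
# (independent of transient_kernel()).
oracle_kernel <- function(t, rise = 0.2, decay = 1.5) {
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / peak)
}

# Fine-grid trapezoidal quadrature of a function on [a, b].
oracle_quadrature <- function(f, a, b, n = 20000L) {
  tt <- seq(a, b, length.out = n)
  y <- f(tt)
  sum(diff(tt) * (y[-1L] + y[-n]) / 2)
}

# Pearson r from the covariance formula, term by term.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small noiseless session builder used by several photometry tests.
noiseless_config <- function(duration_s = 40, rate_hz = 15, ...) {
  photometry_sim_config(duration_s = duration_s, rate_hz = rate_hz,
                        noise_sd = 0, ...)
}
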