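# Shared fixtures: all synthetic, generated in code.

AA20 <- c(
  "G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
  "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W"
)

random_protein <- function(n) {
  paste0(sample(AA20, n, replace = TRUE), collapse = "")
}

# Independent cleavage oracle: the K/R-not-before-P rule via a PCRE regex,
# structurally different from the package's character scan.
regex_cleave <- function(s) {
  m <- gregexpr(".(?:(?<![KR](?!P)).)*", s, perl = TRUE)
  regmatches(s, m)[[1]]
}

# A smooth normalized spectrum: Gaussian mixture evaluated at bin centers.
smooth_spectrum <- function(centers, weights = rep(1, length(centers)),
                            sigma = 2, label = NA_character_) {
  x <- seq(0.5, 99.5, by = 1)
  v <- rep(0, 100)
  for (i in seq_along(centers)) {
    v <- v + weights[i] * exp(-(x - centers[i])^2 / (2 * sigma^2))
  }
  new_spectrum(v / sum(v), normalized = TRUE, label = label)
}

# Minimal event table from raw I_ex% values.
event_table <- function(iex) {
  tibble::tibble(iex_pct = iex, accepted = TRUE)
}

# Render gNDF events at known positions onto a noisy baseline; returns the
# trace plus the parameter table. Independent of simulate_trace().
render_trace <- function(mus, iex, beta, dwell, i_o = 100, noise = 2,
                         rate = 50000, duration = max(mus) + 0.05) {
  n <- round(duration * rate)
  tvec <- (seq_len(n) - 1) / rate
  cur <- rep(i_o, n)
  sigma <- dwell / (2 * sqrt(2 * log(2)^(1 / beta)))
  for (i in seq_along(mus)) {
    cur <- cur - (iex[i] / 100 * i_o) * gndf(tvec, mus[i], sigma[i]^2, beta[i])
  }
  cur <- cur + stats::rnorm(n, 0, noise)
  list(
    trace = new_trace(cur, rate),
    params = tibble::tibble(
      mu = mus, iex = iex, beta = beta, dwell = dwell,
      sigma2 = sigma^2, delta_ib = iex / 100 * i_o
    )
  )
}

# Match detected events to injected ones by nearest center.
match_events <- function(detected, truth_mu, tol) {
  vapply(detected, function(m) {
    i <- which.min(abs(truth_mu - m))
    if (abs(truth_mu[i] - m) <= tol) i else NA_integer_
  }, integer(1))
}
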