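#' Simulation settings for synthetic nanopore recordings
#'
#' Defaults emulate the study conditions of a FraC peptide recording: a
#' 100 pA open-pore current (about the magnitude observed at -70 mV in 1 M
#' KCl, taken positive per the package sign convention), 2 pA white noise,
#' 50 kHz sampling. Event dwell times are log-normal around 2 ms, shapes are
#' uniform over `beta_range` (spanning spike-like through flat-top events so
#' the shape filter is exercised), per-event excluded currents are the
#' calibrated value for the peptide's mass plus Gaussian jitter, and each
#' replicate receives a global spectral offset emulating run-to-run drift.
#'
#' @param i_o Open-pore current, pA.
#' @param noise_sigma White-noise standard deviation, pA.
#' @param sampling_rate Hz.
#' @param duration Trace length, s.
#' @param event_rate Mean event rate, events/s (Poisson process).
#' @param dwell_median,dwell_shape Log-normal dwell-time parameters
#'   (median in s; shape = sdlog).
#' @param beta_range Uniform range of the gNDF shape parameter.
#' @param iex_jitter_sigma Per-event I_ex% jitter, percent.
#' @param replicate_offset_sigma Per-replicate I_ex% offset scale, percent.
#' @param abundance_weights Optional per-peptide relative capture weights
#'   (recycled against the peptide table); stands in for charge and
#'   hydrophobicity capture bias without modelling its physics.
#' @param filter_cutoff Optional digital Gaussian filter (-3 dB Hz) applied
#'   to the rendered trace; `NULL` leaves the trace unfiltered.
#' @param spacing `"poisson"` (uniform event times, default) or `"even"`
#'   (equally spaced with jitter, guaranteeing separation).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(i_o = 100, noise_sigma = 2, sampling_rate = 50000,
                       duration = 10, event_rate = 5,
                       dwell_median = 0.002, dwell_shape = 0.3,
                       beta_range = c(0.7, 3.0), iex_jitter_sigma = 1.0,
                       replicate_offset_sigma = 1.0,
                       abundance_weights = NULL, filter_cutoff = NULL,
                       spacing = c("poisson", "even"), seed = 1L) {
  stopifnot(
    i_o > 0, noise_sigma > 0, sampling_rate > 0, duration > 0,
    event_rate >= 0, dwell_median > 0, dwell_shape > 0,
    length(beta_range) == 2L, beta_range[1] > 0,
    beta_range[2] >= beta_range[1],
    iex_jitter_sigma >= 0, replicate_offset_sigma >= 0
  )
  structure(
    list(
      i_o = i_o, noise_sigma = noise_sigma, sampling_rate = sampling_rate,
      duration = duration, event_rate = event_rate,
      dwell_median = dwell_median, dwell_shape = dwell_shape,
      beta_range = beta_range, iex_jitter_sigma = iex_jitter_sigma,
      replicate_offset_sigma = replicate_offset_sigma,
      abundance_weights = abundance_weights, filter_cutoff = filter_cutoff,
      spacing = match.arg(spacing), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a synthetic ionic-current trace with ground truth
#'
#' Draws event times from a Poisson process, peptide identities from the
#' abundance weights, per-event excluded currents from the calibration model
#' plus Gaussian jitter (clamped to `[0, 100]`), dwell times from the
#' log-normal, and shape parameters uniformly; renders each event as a gNDF
#' blockade subtracted from the open-pore current; adds white Gaussian
#' noise; and applies one replicate-level offset to all event depths.
#' Deterministic under the config seed.
#'
#' @param peptides A tibble with a `mass` column (Da) and optionally
#'   `sequence`/`parent_id`, e.g. from [digest_protein()].
#' @param model A `porefp_calibration`; peptide masses must lie inside its
#'   domain.
#' @param config A [sim_config()].
#' @return A list of class `porefp_simulation`: `trace` (a
#'   [new_trace()] tibble), `truth` (tibble `event`, `peptide`, `mass`,
#'   `mu`, `dwell`, `beta`, `iex_true`, `iex_applied`), and
#'   `replicate_offset` (I_ex%).
#' @export
simulate_trace <- function(peptides, model = default_calibration(),
                           config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot("mass" %in% names(peptides), nrow(peptides) >= 1L)
  if (any(peptides$mass < model$domain[1] | peptides$mass > model$domain[2])) {
    rlang::abort("peptide masses must lie inside the calibration domain")
  }
  if (config$event_rate * config$dwell_median > 0.1) {
    rlang::abort(paste(
      "expected event density too high (rate x median dwell > 0.1);",
      "lower event_rate or dwell_median to keep events sparse"
    ))
  }
  set.seed(config$seed)
  n_samples <- round(config$duration * config$sampling_rate)
  tvec <- (seq_len(n_samples) - 1) / config$sampling_rate
  current <- rep(config$i_o, n_samples)
  offset <- stats::rnorm(1, 0, config$replicate_offset_sigma)

  n_ev <- stats::rpois(1, config$event_rate * config$duration)
  if (n_ev == 0L) {
    current <- current + stats::rnorm(n_samples, 0, config$noise_sigma)
    tr <- new_trace(current, config$sampling_rate, source_id = "simulated")
    if (!is.null(config$filter_cutoff)) {
      tr <- gaussian_lowpass(tr, config$filter_cutoff)
    }
    return(structure(
      list(trace = tr, truth = empty_truth(), replicate_offset = offset),
      class = "porefp_simulation"
    ))
  }
  margin <- 10 * config$dwell_median
  mus <- if (config$spacing == "poisson") {
    sort(stats::runif(n_ev, margin, config$duration - margin))
  } else {
    span <- (config$duration - 2 * margin) / n_ev
    margin + span * (seq_len(n_ev) - 0.5) +
      stats::runif(n_ev, -0.2 * span, 0.2 * span)
  }
  w <- config$abundance_weights %||% rep(1, nrow(peptides))
  pick <- sample.int(nrow(peptides), n_ev, replace = TRUE,
                     prob = rep_len(w, nrow(peptides)))
  mass <- peptides$mass[pick]
  iex_true <- predict_iex(model, mass) +
    stats::rnorm(n_ev, 0, config$iex_jitter_sigma)
  iex_true <- pmin(pmax(iex_true, 0), 100)
  iex_applied <- pmin(pmax(iex_true + offset, 0), 100)
  dwell <- stats::rlnorm(n_ev, log(config$dwell_median), config$dwell_shape)
  beta <- stats::runif(n_ev, config$beta_range[1], config$beta_range[2])
  sigma <- dwell / (2 * sqrt(2 * log(2)^(1 / beta)))

  for (i in seq_len(n_ev)) {
    depth <- iex_applied[i] / 100 * config$i_o
    # render only where the gNDF term exceeds ~1e-6
    half <- sqrt(2) * sigma[i] * log(1e6)^(1 / (2 * beta[i])) +
      2 / config$sampling_rate
    lo <- max(1L, ceiling((mus[i] - half) * config$sampling_rate))
    hi <- min(n_samples, floor((mus[i] + half) * config$sampling_rate) + 1L)
    idx <- lo:hi
    current[idx] <- current[idx] -
      depth * gndf(tvec[idx], mus[i], sigma[i]^2, beta[i])
  }
  current <- current + stats::rnorm(n_samples, 0, config$noise_sigma)
  tr <- new_trace(current, config$sampling_rate, source_id = "simulated")
  if (!is.null(config$filter_cutoff)) {
    tr <- gaussian_lowpass(tr, config$filter_cutoff)
  }
  truth <- tibble::tibble(
    event = seq_len(n_ev),
    peptide = if ("sequence" %in% names(peptides)) {
      peptides$sequence[pick]
    } else {
      as.character(pick)
    },
    mass = mass, mu = mus, dwell = dwell, beta = beta,
    iex_true = iex_true, iex_applied = iex_applied
  )
  structure(
    list(trace = tr, truth = truth, replicate_offset = offset),
    class = "porefp_simulation"
  )
}

empty_truth <- function() {
  tibble::tibble(
    event = integer(), peptide = character(), mass = numeric(),
    mu = numeric(), dwell = numeric(), beta = numeric(),
    iex_true = numeric(), iex_applied = numeric()
  )
}

#' Simulate replicate recordings for a set of proteins
#'
#' Digests each protein in silico, then simulates `n_replicates` traces per
#' protein with independent replicate offsets and derived seeds. The result
#' is a manifest-style tibble ready for the detection -> spectrum ->
#' matching pipeline.
#'
#' @param proteins A FASTA path or tibble with columns `id`, `sequence`.
#' @param n_replicates Replicates per protein (default 3).
#' @param config A [sim_config()]; per-trace seeds are derived from
#'   `config$seed`.
#' @param params A [digest_params()] for the in-silico digest.
#' @param model A `porefp_calibration`.
#' @return A tibble with columns `label`, `replicate`, `seed`,
#'   `replicate_offset`, `trace` (list), `truth` (list).
#' @export
simulate_replicates <- function(proteins, n_replicates = 3,
                                config = sim_config(),
                                params = digest_params(),
                                model = default_calibration()) {
  tbl <- if (is.character(proteins)) read_fasta(proteins) else proteins
  stopifnot(all(c("id", "sequence") %in% names(tbl)))
  purrr::map_dfr(seq_len(nrow(tbl)), function(i) {
    peps <- digest_protein(tbl$sequence[i], params, parent_id = tbl$id[i])
    if (nrow(peps) < 3L) {
      rlang::abort(sprintf(
        "digest of protein '%s' yields only %d peptide(s) in the mass window; need >= 3",
        tbl$id[i], nrow(peps)
      ))
    }
    purrr::map_dfr(seq_len(n_replicates), function(j) {
      cfg <- config
      cfg$seed <- config$seed + 1009L * (i - 1L) + j
      sim <- simulate_trace(peps, model, cfg)
      tibble::tibble(
        label = tbl$id[i], replicate = j, seed = cfg$seed,
        replicate_offset = sim$replicate_offset,
        trace = list(sim$trace), truth = list(sim$truth)
      )
    })
  })
}

#' Detect events and build spectra for simulated (or real) replicates
#'
#' Runs [detect_events()] and [build_spectrum()] over every trace of a
#' replicate table, returning a spectra table ready for
#' [realign_replicates()] and [leave_one_out()].
#'
#' @param replicates A tibble with columns `label`, `replicate`, `trace`
#'   (list-column of traces), e.g. from [simulate_replicates()].
#' @param ... Passed to [detect_events()].
#' @return The input tibble with added list-columns `events` and `spectrum`.
#' @export
fingerprint_replicates <- function(replicates, ...) {
  stopifnot(all(c("label", "replicate", "trace") %in% names(replicates)))
  replicates$events <- purrr::map(replicates$trace, detect_events, ...)
  replicates$spectrum <- purrr::map2(
    replicates$events, replicates$label,
    function(ev, lab) build_spectrum(ev, label = lab)
  )
  replicates
}
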