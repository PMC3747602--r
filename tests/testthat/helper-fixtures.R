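# Shared lazily-built fixtures (generated in code; nothing stored on disk)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

clean_recording <- function() fixture("clean_rec", function()
  generate_recording(beat_template(0.4),
                     recording_spec(n_beats = 30, period_jitter = 0,
                                    noise_sd = 0, drift_amplitude = 0,
                                    seed = 3)))

realistic_recording <- function() fixture("real_rec", function()
  generate_recording(beat_template(0.4),
                     recording_spec(n_beats = 30, seed = 5)))

clean_analysis <- function() fixture("clean_ana", function()
  analyze_ppg(clean_recording()$signal, run_config(n_beats = 15)))

# Brute-force reference wave detector: enumerates every interior local
# extremum of the SDPPG between consecutive fourth-derivative zero
# crossings by direct neighbour comparison, then applies the a(max),
# b(min), c(max), d(min), e(max) polarity sequence with the
# fourth-derivative-extremum fallback for c and d.
oracle_detect_waves <- function(tau, sdppg, d4, search_window_s = 0.7,
                                search_pre_s = 0.2) {
  keep <- which(tau >= -search_pre_s & tau <= search_window_s)
  tw <- tau[keep]; sw <- sdppg[keep]; dw <- d4[keep]
  n <- length(dw)
  cr <- numeric(0)
  for (i in seq_len(n - 1L)) {
    if (dw[i] == 0 && (i == 1L || dw[i - 1L] != 0)) cr <- c(cr, i - 1)
    else if (dw[i] * dw[i + 1L] < 0)
      cr <- c(cr, (i - 1) + dw[i] / (dw[i] - dw[i + 1L]))
  }
  if (dw[n] == 0 && dw[n - 1L] != 0) cr <- c(cr, n - 1)
  cr <- sort(unique(cr))
  if (length(cr) < 2L) return(NULL)
  extrema_in <- function(r, what) {
    pts <- which(seq_along(sw) - 1 > cr[r] & seq_along(sw) - 1 < cr[r + 1L])
    pts <- pts[pts > 1L & pts < length(sw)]
    hits <- integer(0)
    for (j in pts) {
      if (what > 0 && sw[j] >= sw[j - 1L] && sw[j] >= sw[j + 1L]) hits <- c(hits, j)
      if (what < 0 && sw[j] <= sw[j - 1L] && sw[j] <= sw[j + 1L]) hits <- c(hits, j)
    }
    hits
  }
  r_a <- NA
  for (r in seq_len(length(cr) - 1L)) {
    h <- extrema_in(r, 1)
    h <- h[sw[h] > 0 & sw[h] >= 0.2 * max(sw)]
    if (length(h)) { r_a <- r; break }
  }
  if (is.na(r_a)) return(NULL)
  pol <- c(1, -1, 1, -1, 1)
  picks <- integer(5)
  for (wi in 1:5) {
    r <- r_a + wi - 1L
    if (r + 1L > length(cr)) return(NULL)
    h <- extrema_in(r, pol[wi])
    if (length(h)) {
      best <- h[1]
      for (j in h) if (pol[wi] * sw[j] > pol[wi] * sw[best]) best <- j
      picks[wi] <- best
    } else {
      if (wi %in% c(1, 2)) return(NULL)
      pts <- which(seq_along(sw) - 1 > cr[r] & seq_along(sw) - 1 < cr[r + 1L])
      if (!length(pts)) return(NULL)
      picks[wi] <- pts[which.max(abs(dw[pts]))]
    }
  }
  list(t = tw[picks], amp = sw[picks])
}

# random band-limited waveform set on the averaged-waveform grid, built
# from a random template plus optional smooth perturbation
random_waveform_set <- function(seed) {
  set.seed(seed)
  tpl <- beat_template(runif(1, 0.05, 0.95),
                       n_harmonics = sample(6:8, 1), validate = FALSE)
  tau_abs <- seq(0.02, 0.95, by = 1e-3)
  sd2 <- template_eval(tpl, tau_abs, 2)
  d4 <- template_eval(tpl, tau_abs, 4)
  if (runif(1) < 0.5) {       # small extra smooth component, like residual noise
    k <- sample(7:10, 1)
    amp <- 0.01 * max(abs(sd2)) * runif(1)
    ph <- runif(1, 0, 2 * pi)
    sd2 <- sd2 + amp * sin(2 * pi * k * tau_abs + ph)
    d4 <- d4 + amp * (2 * pi * k)^2 * sin(2 * pi * k * tau_abs + ph + pi)
  }
  p <- template_eval(tpl, tau_abs)
  ref <- 0.02 + rising_front_reference(p) * 1e-3
  list(tau = tau_abs - ref, sdppg = sd2, d4 = d4)
}
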