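# Shared fixture builders (all generated in code; nothing on disk).

# recording from an explicit channels-x-samples matrix
toy_recording <- function(mat, labels = paste0("ch", seq_len(nrow(mat))),
                          srate = 250) {
  eeg_recording(mat, labels, srate)
}

# epochs built directly from a recording of sinusoids/noise
toy_epochs <- function(mat, srate = 250, epoch_len = 2,
                       labels = paste0("ch", seq_len(nrow(mat)))) {
  segment_epochs(eeg_recording(mat, labels, srate), epoch_len)
}

# multi-epoch white-noise epoch set with a fixed seed
white_epochs <- function(n_epochs = 20, n_ch = 2, srate = 250,
                         epoch_len = 2, seed = 1, sd = 1) {
  set.seed(seed)
  n <- n_epochs * epoch_len * srate
  mat <- matrix(rnorm(n_ch * n, sd = sd), n_ch, n)
  toy_epochs(mat, srate, epoch_len)
}

# a single-channel spectrum tibble on the standard 2-45 Hz grid
toy_avg_spectrum <- function(power_fun) {
  freq <- seq(2, 45, by = 0.5)
  tibble::tibble(freq = freq, power = power_fun(freq))
}

# independent periodogram-averaging oracle for the Welch PSD: a second,
# loop-based implementation kept deliberately separate from the package's
# vectorized path
oracle_welch <- function(es, fmin = 2, fmax = 45) {
  kept <- which(es$keep)
  n <- dim(es$data)[3]
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hanning
  res <- 1 / es$epoch_len
  k <- seq(ceiling(fmin / res), floor(fmax / res))
  out <- NULL
  for (ch in seq_along(es$labels)) {
    acc <- numeric(length(k))
    for (e in kept) {
      x <- es$data[e, ch, ] * w
      px <- Mod(stats::fft(x))^2
      acc <- acc + 2 * px[k + 1] / (es$srate * sum(w^2))
    }
    out <- rbind(out, acc / length(kept))
  }
  list(freq = k * res, power = out)
}

# balanced split-plot dataset: g groups x f bands x p pairs, n_per
# subjects per group, with an optional three-way effect
make_anova_data <- function(g, f, p, n_per, seed, effect = 0) {
  set.seed(seed)
  grid <- expand.grid(band = paste0("b", 1:f), pair = paste0("p", 1:p))
  out <- list()
  id <- 0
  for (gi in 1:g) for (si in 1:n_per) {
    id <- id + 1
    subj_eff <- rnorm(1, 0, 0.5)
    y <- rnorm(nrow(grid), sd = 1) + subj_eff +
      effect * gi * as.integer(grid$band) * as.integer(grid$pair)
    out[[id]] <- tibble::tibble(subject = sprintf("s%02d", id),
                                group = paste0("g", gi),
                                band = grid$band, pair = grid$pair, y = y)
  }
  dplyr::bind_rows(out)
}
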