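# Second-order wavelet time scattering with analytic Morlet filter banks.
#
# Conventions (frozen; frequencies are normalized cycles/sample, T_s = T*fs):
#   * scaling filter phi: Gaussian, frequency std sigma_phi = 1.5 / T_s
#   * wavelet frequency std sigma_psi(lambda) = lambda * (2^(1/Q) - 1)
#   * bank: geometric centers 0.4 * 2^(-k/Q) while sigma_psi > sigma_phi,
#     then a linear tail of constant-bandwidth (sigma_phi) filters spaced
#     2*sigma_phi apart down to lambda > 2*sigma_phi
#   * order-2 path (l1, l2) admitted iff l2 < sigma_psi(l1)
#   * hop = 2^(round(log2(T_s)) - 2); outputs sampled at 0, hop, 2*hop, ...
# The two reference configurations (30 kHz/450/0.006 s and 3 kHz/420/0.081 s,
# Q = (8, 1)) yield 40 paths x 15 windows and 65 paths x 7 windows under
# these rules; see the methods vignette for the calibration rationale.

LAMBDA_MAX <- 0.4
SIGMA_PHI_FACTOR <- 1.5
EPS_GRID <- 1e-12

build_bank_freqs <- function(q, sigma_phi) {
  rho <- 2^(1 / q)
  beta <- rho - 1
  freqs <- numeric()
  l <- LAMBDA_MAX
  while (beta * l > sigma_phi + EPS_GRID) {
    freqs <- c(freqs, l)
    l <- l / rho
  }
  # constant-bandwidth linear tail at the scaling-filter floor
  l <- if (length(freqs)) freqs[length(freqs)] - 2 * sigma_phi else LAMBDA_MAX
  while (l > 2 * sigma_phi + EPS_GRID) {
    freqs <- c(freqs, l)
    l <- l - 2 * sigma_phi
  }
  if (!length(freqs)) abort("invariance scale admits no wavelet filters")
  tibble(lambda = freqs, sigma = pmax(beta * freqs, sigma_phi))
}

# frequency responses on the padded FFT grid; analytic Morlet with the
# zero-mean correction term, plus the Gaussian scaling filter
bank_responses <- function(bank, sigma_phi, npad) {
  f <- (seq_len(npad) - 1) / npad
  psi_hat <- vapply(seq_len(nrow(bank)), function(j) {
    l <- bank$lambda[j]; s <- bank$sigma[j]
    exp(-(f - l)^2 / (2 * s^2)) -
      exp(-l^2 / (2 * s^2)) * exp(-f^2 / (2 * s^2))
  }, numeric(npad))
  fd <- pmin(f, 1 - f)
  phi_hat <- exp(-fd^2 / (2 * sigma_phi^2))
  # tight-frame normalization: rescale the wavelet responses so that
  # |phi|^2 + sum |psi|^2 equals 1 wherever the bank has appreciable
  # response (non-expansiveness bound), with amplification capped at 2x
  # so spectral regions the bank does not cover stay uncovered
  lp_psi <- rowSums(psi_hat^2)
  target <- pmax(1 - phi_hat^2, 0)
  w2 <- rep(0, npad)
  pos <- lp_psi > 1e-12
  w2[pos] <- pmin(target[pos] / lp_psi[pos], 4)
  list(psi_hat = psi_hat * sqrt(w2), phi_hat = phi_hat)
}

#' Build a wavelet scattering network
#'
#' Constructs the two analytic Morlet filter banks (quality factors `Q1`,
#' `Q2`) and the Gaussian scaling (averaging) filter of time support equal
#' to the invariance scale `T`, together with the admissible scattering
#' paths of orders 0--2 and the critically sampled output grid. The
#' construction is deterministic. Filter frequency grids are geometric
#' (constant-Q) down to the scaling-filter bandwidth, then linearly spaced
#' at that bandwidth, so the analysed band is covered without gaps; all
#' filters are jointly normalised so the Littlewood--Paley sum never
#' exceeds 1 (the non-expansiveness bound).
#'
#' @param fs_hz Sampling rate in Hz.
#' @param signal_length Series length in samples.
#' @param invariance_scale_s Invariance scale `T` in seconds; must exceed
#'   one sample and not exceed the signal duration.
#' @param q_factors Integer pair `(Q1, Q2)`: wavelets per octave of the
#'   first- and second-order filter banks.
#' @return An object of class `scattering_network`: a list with the filter
#'   banks, the path table (`paths`), the hop size and window count, and
#'   the precomputed frequency responses.
#' @examples
#' net <- scattering_network(30000, 450, 0.006, c(8, 1))
#' count_paths(net)
#' @export
scattering_network <- function(fs_hz, signal_length, invariance_scale_s,
                               q_factors = c(8, 1)) {
  if (length(q_factors) != 2 || any(q_factors < 1)) {
    abort("q_factors must be two quality factors >= 1")
  }
  t_samples <- invariance_scale_s * fs_hz
  if (t_samples <= 1) abort("invariance scale must exceed one sample")
  if (invariance_scale_s > signal_length / fs_hz) {
    abort("invariance scale is longer than the signal duration")
  }
  sigma_phi <- SIGMA_PHI_FACTOR / t_samples
  bank1 <- build_bank_freqs(q_factors[1], sigma_phi)
  bank2 <- build_bank_freqs(q_factors[2], sigma_phi)
  # order-2 admissibility: lambda2 below the order-1 envelope bandwidth
  pairs <- purrr::map(seq_len(nrow(bank1)), function(i) {
    l2 <- bank2$lambda[bank2$lambda < bank1$sigma[i] - EPS_GRID]
    if (!length(l2)) return(NULL)
    tibble(order = 2L, lambda1 = bank1$lambda[i], lambda2 = l2)
  })
  paths <- bind_rows(
    tibble(order = 0L, lambda1 = NA_real_, lambda2 = NA_real_),
    tibble(order = 1L, lambda1 = bank1$lambda, lambda2 = NA_real_),
    bind_rows(pairs)
  ) %>%
    mutate(path_id = path_label(.data$order, .data$lambda1, .data$lambda2,
                                fs_hz), .before = 1)
  hop <- 2^max(0, round(log2(t_samples)) - 2)
  positions <- seq(1L, signal_length, by = hop)
  npad <- 2^ceiling(log2(2 * signal_length))
  structure(list(
    fs_hz = fs_hz, signal_length = as.integer(signal_length),
    invariance_scale_s = invariance_scale_s, q_factors = q_factors,
    sigma_phi = sigma_phi, hop = as.integer(hop),
    n_windows = length(positions), positions = positions,
    window_times_ms = (positions - 1) / fs_hz * 1000,
    npad = as.integer(npad),
    bank1 = bank1, bank2 = bank2, paths = paths,
    resp1 = bank_responses(bank1, sigma_phi, npad),
    resp2 = bank_responses(bank2, sigma_phi, npad)
  ), class = "scattering_network")
}

path_label <- function(order, lambda1, lambda2, fs_hz) {
  hz <- function(l) formatC(l * fs_hz, format = "f", digits = 1)
  dplyr::case_when(
    order == 0L ~ "m0",
    order == 1L ~ paste0("m1:", hz(lambda1)),
    TRUE ~ paste0("m2:", hz(lambda1), ":", hz(lambda2))
  )
}

#' @export
print.scattering_network <- function(x, ...) {
  cp <- count_paths(x)
  cat("<scattering_network>\n",
      " fs: ", x$fs_hz, " Hz, length: ", x$signal_length,
      ", invariance scale: ", x$invariance_scale_s, " s\n",
      " Q = (", x$q_factors[1], ", ", x$q_factors[2], "), paths: ",
      cp[["total"]], " (", cp[["n_order0"]], "/", cp[["n_order1"]], "/",
      cp[["n_order2"]], " by order), windows: ", x$n_windows,
      " (hop ", x$hop, ")\n", sep = "")
  invisible(x)
}

#' Count scattering paths per order
#'
#' @param network A [scattering_network()].
#' @return Named integer vector `n_order0`, `n_order1`, `n_order2`, `total`.
#' @export
count_paths <- function(network) {
  stopifnot(inherits(network, "scattering_network"))
  tab <- table(factor(network$paths$order, levels = 0:2))
  c(n_order0 = unname(tab[["0"]]), n_order1 = unname(tab[["1"]]),
    n_order2 = unname(tab[["2"]]), total = nrow(network$paths))
}

# mirror indices (1-based) into [1, n] by half-sample symmetric reflection
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n)
  m <- ifelse(m < 0L, m + 2L * n, m)
  ifelse(m < n, m + 1L, 2L * n - m)
}

pad_reflect <- function(x, npad) {
  n <- length(x)
  pl <- (npad - n) %/% 2L
  x[reflect_index(seq(1L - pl, npad - pl), n)]
}

# circular convolution on the padded grid via FFT; returns the central
# n samples aligned with the input
conv_filter <- function(x_hat, filt_hat, npad, n, pl) {
  y <- fft(x_hat * filt_hat, inverse = TRUE) / npad
  y[pl + seq_len(n)]
}

#' Second-order wavelet scattering transform of one signal
#'
#' Computes `S0 = x * phi`, `S1(t, l1) = |x * psi_l1| * phi` and
#' `S2(t, l1, l2) = ||x * psi_l1| * psi_l2| * phi` over the admissible
#' paths of the network, with symmetric-reflection boundary padding and
#' FFT-based convolution, and samples the outputs on the critically
#' downsampled window grid implied by the invariance scale.
#'
#' @param x Numeric signal (length must equal `network$signal_length`), or
#'   a one-row record tibble.
#' @param network A [scattering_network()].
#' @return An object of class `scattering_tensor`: list with `coefficients`
#'   (paths x windows matrix, non-negative), `paths`, `window_times_ms`,
#'   and `log` (`FALSE` for the raw tensor).
#' @export
scatter <- function(x, network) {
  stopifnot(inherits(network, "scattering_network"))
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- x$samples[[1]]
  }
  n <- network$signal_length
  if (length(x) != n) {
    abort(paste0("signal length ", length(x), " does not match the network (",
                 n, "); use truncate_records() for an explicit change"))
  }
  npad <- network$npad
  pl <- (npad - n) %/% 2L
  paths <- network$paths
  coef <- matrix(0, nrow(paths), network$n_windows,
                 dimnames = list(paths$path_id, NULL))
  xp_hat <- fft(pad_reflect(x, npad))
  phi1 <- network$resp1$phi_hat
  grid <- network$positions
  # order 0: modulus keeps the raw tensor non-negative (and the log
  # transform defined) for signed voltage series
  s0 <- Mod(conv_filter(xp_hat, phi1, npad, n, pl))
  coef[paths$order == 0L, ] <- s0[grid]
  # orders 1 and 2
  b1 <- network$bank1
  for (i in seq_len(nrow(b1))) {
    u1 <- Mod(conv_filter(xp_hat, network$resp1$psi_hat[, i], npad, n, pl))
    u1_hat <- fft(pad_reflect(u1, npad))
    s1 <- Re(conv_filter(u1_hat, network$resp2$phi_hat, npad, n, pl))
    coef[paths$order == 1L & paths$lambda1 == b1$lambda[i], ] <- s1[grid]
    l2s <- paths$lambda2[paths$order == 2L & paths$lambda1 == b1$lambda[i]]
    for (l2 in l2s) {
      j <- which(network$bank2$lambda == l2)
      u2 <- Mod(conv_filter(u1_hat, network$resp2$psi_hat[, j], npad, n, pl))
      u2_hat <- fft(pad_reflect(u2, npad))
      s2 <- Re(conv_filter(u2_hat, network$resp2$phi_hat, npad, n, pl))
      coef[paths$order == 2L & paths$lambda1 == b1$lambda[i] &
             paths$lambda2 == l2, ] <- s2[grid]
    }
  }
  # the cascade of moduli and Gaussian averages is non-negative up to
  # round-off on the order-0/1/2 phi outputs
  coef[coef < 0 & coef > -1e-12] <- 0
  structure(list(coefficients = coef, paths = paths,
                 window_times_ms = network$window_times_ms, log = FALSE),
            class = "scattering_tensor")
}

#' @export
print.scattering_tensor <- function(x, ...) {
  cat("<scattering_tensor> ", nrow(x$coefficients), " paths x ",
      ncol(x$coefficients), " windows (",
      if (x$log) "log" else "raw", ")\n", sep = "")
  invisible(x)
}

#' Tidy a scattering tensor into long format
#'
#' @param x A `scattering_tensor`.
#' @param ... Unused.
#' @return Tibble with one row per path and window.
#' @export
tidy.scattering_tensor <- function(x, ...) {
  tidyr::expand_grid(path_id = x$paths$path_id,
                     window = seq_along(x$window_times_ms)) %>%
    mutate(time_ms = x$window_times_ms[.data$window],
           value = as.vector(t(x$coefficients))) %>%
    left_join(x$paths, by = "path_id") %>%
    select("path_id", "order", "lambda1", "lambda2", "window",
           "time_ms", "value")
}

#' Natural-log transform of scattering coefficients
#'
#' Elementwise `log(max(value, floor))` on a raw (non-negative) tensor;
#' the path/window structure is preserved.
#'
#' @param tensor A raw `scattering_tensor`.
#' @param floor Small positive constant guarding `log(0)`.
#' @return The log tensor (`log = TRUE`).
#' @export
log_coeffs <- function(tensor, floor = 1e-12) {
  stopifnot(inherits(tensor, "scattering_tensor"))
  if (tensor$log) abort("tensor is already log-transformed")
  if (any(tensor$coefficients < 0)) {
    abort("negative raw scattering coefficient: upstream integrity error")
  }
  tensor$coefficients <- log(pmax(tensor$coefficients, floor))
  tensor$log <- TRUE
  tensor
}

#' Average a scattering tensor over its time windows
#'
#' Wavelet-scale averaging: the arithmetic mean across windows per path,
#' reducing the paths-by-windows matrix to one feature per path.
#'
#' @param tensor A `scattering_tensor` (raw or log).
#' @return Named numeric vector, one value per path, in path order.
#' @export
scale_average <- function(tensor) {
  stopifnot(inherits(tensor, "scattering_tensor"))
  rowMeans(tensor$coefficients)
}

#' Scattering energy fractions by order
#'
#' Sum of squared raw coefficients per order, divided by the total over
#' orders 0--2.
#'
#' @param tensor A raw `scattering_tensor`.
#' @return Named numeric vector `order0`, `order1`, `order2`; sums to 1.
#' @export
energy_by_order <- function(tensor) {
  stopifnot(inherits(tensor, "scattering_tensor"))
  if (tensor$log) abort("energy_by_order needs the raw (pre-log) tensor")
  e <- vapply(0:2, function(m) {
    sum(tensor$coefficients[tensor$paths$order == m, , drop = FALSE]^2)
  }, numeric(1))
  if (sum(e) == 0) abort("all-zero tensor: energy fractions undefined")
  setNames(e / sum(e), c("order0", "order1", "order2"))
}

#' Scattering feature matrix for a set of records
#'
#' Applies [scatter()] to every record, optionally log-transforms the
#' coefficients (the default), and scale-averages each tensor into one row
#' of features per record. With `log_first = TRUE` (default) the log is
#' taken before window averaging; set it to `FALSE` to average first.
#'
#' @param records Record tibble of a single subtype and common length.
#' @param network A [scattering_network()] matching the records.
#' @param log Apply the natural-log transform (default `TRUE`).
#' @param floor Log floor, see [log_coeffs()].
#' @param log_first Log before scale averaging (default) or after.
#' @return Tibble: `record_id`, `patient_id`, `ear`, `subtype`, then one
#'   column per scattering path.
#' @export
scatter_features <- function(records, network, log = TRUE, floor = 1e-12,
                             log_first = TRUE) {
  validate_aep_records(records, notify_deviations = FALSE)
  feats <- purrr::map(seq_len(nrow(records)), function(i) {
    tensor <- scatter(records$samples[[i]], network)
    if (log && log_first) {
      v <- scale_average(log_coeffs(tensor, floor))
    } else if (log) {
      v <- log(pmax(scale_average(tensor), floor))
    } else {
      v <- scale_average(tensor)
    }
    as_tibble(as.list(v))
  })
  dplyr::bind_cols(
    records %>% select("record_id", "patient_id", "ear", "subtype"),
    bind_rows(feats)
  )
}

#' Littlewood--Paley sums of a network's filter banks
#'
#' The aggregate squared frequency response `|phi|^2 + sum |psi|^2` of each
#' (normalised) filter bank, evaluated on the padded FFT grid. A near-flat
#' sum bounded by 1 indicates a stable, energy-controlled analysis.
#'
#' @param network A [scattering_network()].
#' @return Tibble with columns `bank`, `freq_hz`, `lp_sum`.
#' @export
littlewood_paley <- function(network) {
  stopifnot(inherits(network, "scattering_network"))
  f <- (seq_len(network$npad) - 1) / network$npad
  keep <- f <= 0.5
  purrr::map2(c(1, 2), list(network$resp1, network$resp2), function(b, r) {
    tibble(bank = paste0("Q", b, " = ", network$q_factors[b]),
           freq_hz = f[keep] * network$fs_hz,
           lp_sum = (r$phi_hat^2 + rowSums(r$psi_hat^2))[keep])
  }) %>% bind_rows()
}

#' Plot the Littlewood--Paley sums of a scattering network
#'
#' @param object A [scattering_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scattering_network <- function(object, ...) {
  littlewood_paley(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$freq_hz, y = .data$lp_sum)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~bank, ncol = 1) +
    ggplot2::labs(x = "frequency (Hz)", y = "Littlewood-Paley sum",
                  title = "Filter-bank frame quality") +
    ggplot2::theme_minimal()
}
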