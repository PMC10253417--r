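abr_net <- function() scattering_network(30000, 450, 0.006, c(8, 1))
amlr_net <- function() scattering_network(3000, 420, 0.081, c(8, 1))

test_that("the reference configurations reproduce the expected tensor shapes", {
  na <- abr_net()
  expect_equal(unname(count_paths(na)["total"]), 40)
  expect_equal(na$n_windows, 15)
  nm <- amlr_net()
  expect_equal(unname(count_paths(nm)["total"]), 65)
  expect_equal(nm$n_windows, 7)
  tn <- scatter(rnorm(450), na)
  expect_equal(dim(tn$coefficients), c(40, 15))
  tm <- scatter(rnorm(420), nm)
  expect_equal(dim(tm$coefficients), c(65, 7))
  expect_length(scale_average(tn), 40)
  expect_length(scale_average(tm), 65)
  expect_length(c(scale_average(tn), scale_average(tm)), 105)
})

test_that("path counts match an exhaustive enumeration of the rules", {
  for (net in list(abr_net(), amlr_net(),
                   scattering_network(1000, 256, 0.02, c(1, 1)),
                   scattering_network(2000, 300, 0.05, c(4, 2)))) {
    b1 <- net$bank1; b2 <- net$bank2
    # brute-force enumeration: every (l1, l2) with l2 below the order-1
    # envelope bandwidth
    n2 <- 0L
    for (i in seq_len(nrow(b1))) {
      for (j in seq_len(nrow(b2))) {
        if (b2$lambda[j] < b1$sigma[i] - 1e-12) n2 <- n2 + 1L
      }
    }
    cp <- count_paths(net)
    expect_equal(unname(cp["n_order0"]), 1)
    expect_equal(unname(cp["n_order1"]), nrow(b1))
    expect_equal(unname(cp["n_order2"]), n2)
    expect_equal(unname(cp["total"]), 1L + nrow(b1) + n2)
    # order-2 paths in the path table agree
    expect_equal(sum(net$paths$order == 2), n2)
  }
})

test_that("filter banks satisfy the Littlewood-Paley frame bounds", {
  for (net in list(abr_net(), amlr_net())) {
    lp <- littlewood_paley(net)
    expect_lte(max(lp$lp_sum), 1 + 1e-9)
    # >= 0.5 across the covered band: the scaling filter's half-power
    # band plus the span of wavelet center frequencies, per bank
    banks <- list(net$bank1, net$bank2)
    for (k in 1:2) {
      sub <- lp[lp$bank == unique(lp$bank)[k], ]
      fnorm <- sub$freq_hz / net$fs_hz
      covered <- fnorm <= sqrt(log(2)) * net$sigma_phi |
        (fnorm >= min(banks[[k]]$lambda) & fnorm <= max(banks[[k]]$lambda))
      expect_gte(min(sub$lp_sum[covered]), 0.5 - 1e-9)
    }
    # center frequencies strictly decreasing in both banks
    expect_true(all(diff(net$bank1$lambda) < 0))
    expect_true(all(diff(net$bank2$lambda) < 0))
  }
})

test_that("FFT convolution agrees with direct convolution on short signals", {
  withr::with_seed(5, {
    for (npad in c(16, 64)) {
      x <- rnorm(npad)
      h_hat <- complex(real = rnorm(npad), imaginary = rnorm(npad))
      via_fft <- fft(fft(x) * h_hat, inverse = TRUE) / npad
      h <- fft(h_hat, inverse = TRUE) / npad  # impulse response
      direct <- vapply(seq_len(npad), function(n) {
        sum(vapply(seq_len(npad), function(m) {
          x[m] * h[((n - m) %% npad) + 1]
        }, complex(1)))
      }, complex(1))
      expect_lt(max(Mod(via_fft - direct)), 1e-8)
    }
  })
})

test_that("a zero signal yields an exactly zero tensor", {
  tn <- scatter(rep(0, 450), abr_net())
  expect_true(all(tn$coefficients == 0))
  expect_error(energy_by_order(tn), "all-zero")
})

test_that("a sinusoid at a wavelet's center dominates that order-1 path", {
  net <- abr_net()
  k <- 5  # an interior first-bank wavelet
  f0 <- net$bank1$lambda[k]
  x <- sin(2 * pi * f0 * seq_len(450))
  tn <- scatter(x, net)
  o1 <- tn$coefficients[tn$paths$order == 1L, , drop = FALSE]
  means <- rowMeans(o1)
  expect_equal(unname(which.max(means)), k)
})

test_that("raw tensors are non-negative and log transforms behave", {
  tn <- scatter(rnorm(450), abr_net())
  expect_gte(min(tn$coefficients), 0)
  lt <- log_coeffs(tn)
  expect_true(lt$log)
  expect_equal(dim(lt$coefficients), dim(tn$coefficients))
  # analytic cases on a hand-built tensor
  fake <- tn
  fake$coefficients[] <- 1
  expect_true(all(log_coeffs(fake)$coefficients == 0))
  fake$coefficients[] <- exp(1)
  expect_equal(unique(as.vector(log_coeffs(fake)$coefficients)), 1)
  fake$coefficients[] <- 0
  expect_equal(unique(as.vector(log_coeffs(fake, floor = 1e-12)$coefficients)),
               log(1e-12), tolerance = 1e-9)
  fake$coefficients[1] <- -1
  expect_error(log_coeffs(fake), "integrity")
  expect_error(log_coeffs(log_coeffs(tn)), "already")
})

test_that("scale averaging equals an independently computed row mean", {
  tn <- scatter(rnorm(450), abr_net())
  v <- scale_average(tn)
  for (i in seq_len(nrow(tn$coefficients))) {
    expect_equal(unname(v[i]), sum(tn$coefficients[i, ]) /
                   ncol(tn$coefficients), tolerance = 1e-12)
  }
  # constant along windows: vector equals any column
  fake <- tn
  fake$coefficients <- matrix(rep(rnorm(40), 15), 40, 15,
                              dimnames = dimnames(tn$coefficients))
  expect_equal(unname(scale_average(fake)),
               unname(fake$coefficients[, 1]))
})

test_that("energy fractions are exact on a hand-built tensor", {
  net <- abr_net()
  fake <- scatter(rnorm(450), net)
  fake$coefficients[] <- 0
  fake$coefficients[fake$paths$order == 0L, 1] <- 2
  fake$coefficients[which(fake$paths$order == 1L)[1], 1] <- 1
  fake$coefficients[which(fake$paths$order == 2L)[1], 1] <- 1
  e <- energy_by_order(fake)
  expect_equal(unname(e), c(4 / 6, 1 / 6, 1 / 6))
  fake$coefficients[] <- 0
  fake$coefficients[fake$paths$order == 0L, ] <- 3
  expect_equal(unname(energy_by_order(fake)), c(1, 0, 0))
})

test_that("order-2 energy never exceeds order-1 energy on AEP signals", {
  ch <- fixture_cohort()
  net <- abr_net()
  abr <- dplyr::filter(ch$records, subtype == "ABR")
  for (i in 1:10) {
    e <- energy_by_order(scatter(abr$samples[[i]], net))
    expect_lte(e[["order2"]], e[["order1"]])
  }
})

test_that("invalid network configurations are rejected", {
  expect_error(scattering_network(30000, 450, 1e-6, c(8, 1)), "one sample")
  expect_error(scattering_network(30000, 450, 0.5, c(8, 1)), "duration")
  expect_error(scattering_network(30000, 450, 0.006, c(8, 0)), "quality")
  expect_error(scatter(rnorm(100), abr_net()), "length")
})

test_that("scatter_features returns one labelled row per record", {
  ch <- fixture_cohort()
  abr <- dplyr::filter(ch$records, subtype == "ABR")[1:6, ]
  net <- abr_net()
  f <- scatter_features(abr, net)
  expect_equal(nrow(f), 6)
  expect_equal(ncol(f), 4 + 40)
  expect_identical(f$record_id, abr$record_id)
  # log-after-average mode differs but has the same shape
  f2 <- scatter_features(abr, net, log_first = FALSE)
  expect_equal(dim(f2), dim(f))
  expect_false(identical(f, f2))
  # deterministic
  expect_identical(f, scatter_features(abr, net))
})

test_that("the filter-bank plot builds", {
  p <- autoplot(abr_net())
  expect_s3_class(p, "ggplot")
})
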