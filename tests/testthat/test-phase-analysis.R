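fs <- 500
t_s <- seq(0, 20, by = 1 / fs)

test_that("the beta band-pass has the specified frequency response", {
  resp <- function(f) {
    x <- sin(2 * pi * f * t_s)
    y <- bandpass_beta(x, fs)
    mid <- seq(round(length(y) * 0.2), round(length(y) * 0.8))
    max(abs(y[mid]))
  }
  expect_gte(resp(20), 0.9); expect_lte(resp(20), 1.1)
  expect_lt(resp(2), 0.1)
  # >= 20 dB attenuation at the band edges +/- 5 Hz
  expect_lt(resp(5), 0.1)
  expect_lt(resp(35), 0.1)
  # zero phase lag: filtered 20 Hz tone aligns with the original
  x <- sin(2 * pi * 20 * t_s)
  y <- bandpass_beta(x, fs)
  mid <- seq(round(length(y) * 0.2), round(length(y) * 0.8))
  expect_gt(stats::cor(x[mid], y[mid]), 0.999)
  # constant signals filter to zero
  expect_lt(max(abs(bandpass_beta(rep(3, length(t_s)), fs))), 1e-8)
  expect_error(bandpass_beta(rnorm(30), fs), "at least")
})

test_that("instantaneous phase advances at 2 pi f and ignores amplitude", {
  x <- sin(2 * pi * 20 * t_s)
  ph <- instantaneous_phase(x, time = t_s * 1000)
  mid <- seq(round(length(t_s) * 0.2), round(length(t_s) * 0.8))
  un <- stngpe:::unwrap_phase(ph$phase)
  slope <- stats::coef(stats::lm(un[mid] ~ t_s[mid]))[2]
  expect_equal(unname(slope), 2 * pi * 20, tolerance = 0.01 * 2 * pi * 20)
  expect_true(all(ph$phase > -pi & ph$phase <= pi + 1e-12))
  # positive rescaling leaves the phase untouched
  ph2 <- instantaneous_phase(5 * x)
  expect_equal(ph$phase, ph2$phase, tolerance = 1e-9)
  # negation shifts the phase by pi
  ph3 <- instantaneous_phase(-x)
  d <- abs(stngpe:::wrap_phase(ph3$phase - ph$phase))
  expect_equal(mean(d[mid]), pi, tolerance = 1e-6)
})

mk_phase <- function(phase, time) {
  structure(list(time = time, phase = stngpe:::wrap_phase(phase), source = ""),
            class = "phase_series")
}

test_that("the return map records one spike phase per LFP cycle", {
  tm <- seq(0, 10000, by = 2)  # ms
  base <- 2 * pi * 20 * tm / 1000
  lfp <- mk_phase(base, tm)
  # identical phases: every recorded value equals the checkpoint
  m <- build_return_map(lfp, mk_phase(base, tm), checkpoint = 0)
  expect_true(all(abs(m$phi) < 1e-6))
  # constant lag delta is recovered
  m2 <- build_return_map(lfp, mk_phase(base + 0.7, tm), checkpoint = 0)
  expect_true(all(abs(m2$phi - 0.7) < 1e-6))
  # a 20 Hz phase over 10 s crosses the checkpoint ~200 times
  expect_gte(m$n, 199); expect_lte(m$n, 201)
  expect_error(build_return_map(mk_phase(base[1:4], tm[1:4]),
                                mk_phase(base[1:4], tm[1:4])),
               "crossings")
})

test_that("region partition distinguishes locked, antiphase, and uniform states", {
  tm <- seq_len(500)
  # tightly locked: all points in the synchronization region, no transitions
  locked <- mk_phase(0.4 + 0.05 * sin(seq(0, 8 * pi, length.out = 500)), tm)
  map <- list(phi = locked$phase, n = 500)
  part <- partition_regions(map)
  expect_true(all(part$labels == 1L))
  rates <- transition_rates(part$labels)
  expect_equal(rates$rate[1], 0)
  expect_true(all(is.na(rates$rate[2:4])))

  # antiphase points relative to an explicit centre fall in region 3
  anti <- list(phi = stngpe:::wrap_phase(rep(0.4 + pi, 50) +
                                           rnorm(50, 0, 0.05)), n = 50)
  part3 <- partition_regions(anti, center = 0.4)
  expect_true(all(part3$labels == 3L))

  # uniform phases occupy each region ~25%
  set.seed(123)
  unif <- list(phi = runif(10000, -pi, pi), n = 10000)
  pu <- partition_regions(unif, center = 0)
  occ <- tabulate(pu$labels, 4) / length(pu$labels)
  expect_true(all(abs(occ - 0.25) < 0.02))
})

test_that("transition rates match hand counts and the brute-force oracle", {
  # hand-counted example
  tr <- transition_rates(c(1L, 1L, 2L, 3L, 1L, 1L, 1L, 2L))
  expect_equal(tr$occupancy, c(5L, 2L, 1L, 0L))
  expect_equal(tr$rate[1:3], c(2 / 5, 1 / 2, 1))
  expect_true(is.na(tr$rate[4]))
  expect_error(transition_rates(1L), "at least 2")

  # independent brute-force enumeration over every sequence of length <= 8
  oracle <- function(labels) {
    m <- length(labels)
    vapply(1:4, function(k) {
      occ <- 0; lv <- 0
      for (i in seq_len(m)) {
        if (labels[i] == k) {
          occ <- occ + 1
          if (i < m && labels[i + 1] != k) lv <- lv + 1
        }
      }
      if (occ == 0) NA_real_ else lv / occ
    }, numeric(1))
  }
  for (len in 2:8) {
    seqs <- if (len <= 6) {
      as.matrix(expand.grid(rep(list(1:4), len)))
    } else {
      set.seed(len)
      matrix(sample(1:4, 3000 * len, replace = TRUE), ncol = len)
    }
    got <- apply(seqs, 1, function(s) transition_rates(as.integer(s))$rate)
    want <- apply(seqs, 1, oracle)
    expect_equal(got, want)
    # occupancies over the m map points sum to m (= N - 1 crossings)
    expect_true(all(colSums(apply(seqs, 1,
      function(s) transition_rates(as.integer(s))$occupancy)) == len))
  }
})

test_that("the experiment-match criterion is boundary-inclusive", {
  crit <- match_criterion(c(0.3, 0.7, 0.5, 0.7), rep(0.1, 4), k = 0.7)
  mk <- function(r) structure(tibble::tibble(region = 1:4, occupancy = 10L,
                                             leaves = 1L, rate = r),
                              class = c("transition_rates", "tbl_df", "tbl", "data.frame"))
  expect_true(matches_experiment(mk(c(0.3, 0.7, 0.5, 0.7)), crit))
  expect_true(matches_experiment(mk(c(0.3 + 0.07, 0.7, 0.5, 0.7)), crit))
  expect_false(matches_experiment(mk(c(0.3 + 0.08, 0.7, 0.5, 0.7)), crit))
  miss <- matches_experiment(mk(c(NA, 0.7, 0.5, 0.7)), crit)
  expect_false(miss)
  expect_match(attr(miss, "reason"), "region")
  expect_error(match_criterion(c(0.3, 0.7), rep(0.1, 2)), "length 4")
  expect_error(match_criterion(rep(0.5, 4), c(0.1, 0, 0.1, 0.1)), "SD")
})

test_that("locked signals give full synchronization occupancy for any checkpoint", {
  tm <- seq(0, 20000, by = 2)
  set.seed(42)
  base <- 2 * pi * 20 * tm / 1000 + cumsum(rnorm(length(tm), 0, 0.01))
  drift <- cumsum(rnorm(length(tm), 0, 0.005))
  lfp <- mk_phase(base, tm)
  spk <- mk_phase(base + 0.5 + drift, tm)
  rates_at <- function(cp) {
    m <- build_return_map(lfp, spk, checkpoint = cp)
    transition_rates(partition_regions(m)$labels)$rate
  }
  r0 <- rates_at(0)
  expect_equal(r0[1], 0, tolerance = 0.02)
  # checkpoint shifts leave the rates essentially unchanged
  for (cp in c(-pi / 4, pi / 4)) {
    rc <- rates_at(cp)
    expect_true(all(abs(rc - r0) < 0.02, na.rm = TRUE))
  }
})

test_that("independent phase processes show the desynchronized null", {
  set.seed(7)
  fs2 <- 500
  n <- 30 * fs2
  mkp <- function() {
    x <- bandpass_beta(rnorm(n), fs2)
    instantaneous_phase(x, time = (seq_len(n) - 1) / fs2 * 1000)
  }
  m <- build_return_map(mkp(), mkp())
  part <- partition_regions(m)
  occ <- tabulate(part$labels, 4) / length(part$labels)
  expect_lt(abs(occ[1] - 0.25), 0.1)
  rates <- transition_rates(part$labels)
  # structural null: leaving the mixed regions (2, 4) is certain, while the
  # diagonal regions (1, 3) are left about half the time because consecutive
  # map points share a coordinate
  expect_true(all(rates$rate[c(2, 4)] > 0.9, na.rm = TRUE))
  expect_true(all(rates$rate > 0.4, na.rm = TRUE))
  expect_gt(mean(rates$rate, na.rm = TRUE), 0.6)
})

test_that("the full synchrony-pattern chain runs on a simulation", {
  sim <- simulate_network(duration = 6000, transient = 1000, seed = 3,
                          g_syn = 0.9, i_app = 5)
  sp <- synchrony_patterns(sim)
  expect_s3_class(sp$map, "return_map_series")
  expect_gt(sp$map$n, 20)
  expect_true(all(sp$rates$rate >= 0 & sp$rates$rate <= 1, na.rm = TRUE))
  expect_equal(sum(sp$rates$occupancy), sp$map$n - 1L)
  expect_type(sp$matched, "logical")
})
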