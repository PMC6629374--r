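test_that("spike detection finds constructed APs and rejects subthreshold blips", {
  tr <- synthetic_ap_trace(baseline = -70, peak = 20, rise_ms = 1, fall_ms = 2)
  st <- detect_spikes(tr)
  expect_length(st$spike_times, 1)
  # threshold = first sample with slope >= 10 mV/ms (the whole 90 mV/ms
  # upstroke qualifies, so threshold sits at the foot of the rise)
  expect_equal(st$spike_times, 20, tolerance = 0.05)
  expect_equal(st$peaks, 20, tolerance = 0.2)

  blip <- synthetic_ap_trace(baseline = -70, peak = -40)  # 30 mV, subthreshold
  expect_length(detect_spikes(blip)$spike_times, 0)
  # overshoot rule: a 45 mV spike peaking below -10 mV is invalid
  low <- synthetic_ap_trace(baseline = -70, peak = -25)
  expect_length(detect_spikes(low)$spike_times, 0)
})

test_that("spike detection matches an independent peak-finding oracle on simulations", {
  tr <- cached_trace("step100", function()
    simulate_cell(model_parameters(), step_protocol(100), seed = 1, noise = TRUE))
  n_detect <- length(detect_spikes(tr)$spike_times)
  n_oracle <- peak_count_oracle(tr$v, tr$dt)
  expect_equal(n_detect, n_oracle)
})

test_that("spike detection is idempotent and windowing-consistent", {
  tr <- cached_trace("step100", function()
    simulate_cell(model_parameters(), step_protocol(100), seed = 1, noise = TRUE))
  st_all <- detect_spikes(tr, window = c(100, 700))
  mid <- 400
  st_a <- detect_spikes(tr, window = c(100, mid))
  st_b <- detect_spikes(tr, window = c(mid, 700))
  stopifnot(!any(abs(st_all$spike_times - mid) < 1))  # no spike straddles
  expect_equal(sort(c(st_a$spike_times, st_b$spike_times)), st_all$spike_times)
})

test_that("waveform features reproduce triangular-spike geometry", {
  # threshold -40, peak +40: 80 mV amplitude, symmetric 1 ms flanks
  dt <- 0.01
  t <- seq(0, 40, by = dt)
  v <- rep(-40, length(t))
  up <- t >= 10 & t < 11
  v[up] <- -40 + 80 * (t[up] - 10)
  down <- t >= 11 & t < 12
  v[down] <- 40 - 80 * (t[down] - 11)
  v[t >= 12] <- -40
  tr <- structure(list(t = t, v = v, dt = dt,
                       protocol = list(pulse_onset_ms = 0, pulse_end_ms = 40)),
                  class = "voltage_trace")
  st <- detect_spikes(tr)
  w <- ap_waveform(tr, st)
  expect_equal(w$amplitude, 80, tolerance = 0.02)
  expect_equal(w$halfwidth, 1.0, tolerance = 0.02)
  expect_equal(w$rise_time, 1.0, tolerance = 0.02)
})

test_that("AHP depth is measured relative to threshold", {
  tr <- synthetic_ap_trace(baseline = -40, peak = 40, rise_ms = 1,
                           fall_ms = 2, after = -55)
  st <- detect_spikes(tr)
  w <- ap_waveform(tr, st)
  expect_equal(w$ahp_amplitude, -40 - (-55), tolerance = 0.1)
})

test_that("waveform features are time-shift invariant and voltage-offset equivariant", {
  tr <- cached_trace("step100nf", function()
    simulate_cell(model_parameters(), step_protocol(100), noise = FALSE))
  st <- detect_spikes(tr)
  w <- ap_waveform(tr, st)

  shifted <- tr; shifted$t <- tr$t + 123.4
  st2 <- detect_spikes(shifted)
  w2 <- ap_waveform(shifted, st2)
  expect_equal(w2[, c("amplitude", "halfwidth", "rise_time", "ahp_amplitude")],
               w[, c("amplitude", "halfwidth", "rise_time", "ahp_amplitude")])
  expect_equal(st2$spike_times, st$spike_times + 123.4)

  offset <- tr; offset$v <- tr$v + 7
  st3 <- detect_spikes(offset)
  w3 <- ap_waveform(offset, st3)
  expect_equal(w3$threshold, w$threshold + 7, tolerance = 1e-6)
  expect_equal(w3$amplitude, w$amplitude, tolerance = 1e-6)
  expect_equal(w3$halfwidth, w$halfwidth, tolerance = 1e-6)
})

test_that("simulated AP features are stable under step refinement", {
  p <- model_parameters()
  pr <- step_protocol(100, pre_ms = 20, post_ms = 20)
  w1 <- {
    tr <- simulate_cell(p, pr, dt = 0.01, noise = FALSE)
    ap_waveform(tr, detect_spikes(tr))[2, ]  # a mid-train spike
  }
  w2 <- {
    tr <- simulate_cell(p, pr, dt = 0.005, noise = FALSE)
    ap_waveform(tr, detect_spikes(tr))[2, ]
  }
  for (f in c("amplitude", "halfwidth", "rise_time"))
    expect_equal(w1[[f]], w2[[f]], tolerance = 0.02, info = f)
})

test_that("passive properties of a leak-only cell are the analytic RC values", {
  p <- model_parameters(g_na = 0, g_kdr = 0, g_ks = 0)
  rest <- simulate_cell(p, step_protocol(0, duration_ms = 1000, pre_ms = 0,
                                         post_ms = 0), noise = FALSE)
  hyp <- simulate_cell(p, step_protocol(-50), noise = FALSE)
  pp <- passive_properties(list(hyp), rest)
  expect_equal(pp$r_in, input_resistance(p), tolerance = 0.02)
  expect_equal(pp$v_rest, -70, tolerance = 0.1)
  expect_equal(pp$time_constant, p$c_m / p$g_leak, tolerance = 0.05)
  expect_lt(abs(pp$sag_percent), 1)   # an RC membrane has no sag
})

test_that("sag follows its definition on an undershooting relaxation", {
  # V_min exactly -80, V_ss exactly -75, baseline -70  ->  sag 50%
  dt <- 0.1
  t <- seq(0, 700, by = dt)
  v <- rep(-70, length(t))
  seg <- function(a, b) t >= a & t < b
  v[seg(100, 150)] <- -70 - 10 * (t[seg(100, 150)] - 100) / 50   # to -80
  v[seg(150, 400)] <- -80 + 5 * (t[seg(150, 400)] - 150) / 250   # rebound
  v[seg(400, 701)] <- -75                                        # steady
  tr <- structure(list(t = t, v = v, dt = dt,
                       protocol = list(pulse_onset_ms = 100, pulse_end_ms = 700,
                                       segments = data.frame(duration = c(100, 600),
                                                             start = c(0, -50),
                                                             end = c(0, -50)))),
                  class = "voltage_trace")
  rest <- structure(list(t = t, v = rep(-70, length(t)), dt = dt,
                         protocol = list(pulse_onset_ms = 0, pulse_end_ms = 700)),
                    class = "voltage_trace")
  pp <- suppressWarnings(passive_properties(list(tr), rest))
  expect_equal(pp$sag_percent, 50, tolerance = 1e-3)
})

test_that("the membrane time constant is recovered from a known exponential", {
  dt <- 0.05
  tau <- 18
  t <- seq(0, 700, by = dt)
  v <- rep(-70, length(t))
  pulse <- t >= 100
  v[pulse] <- -85 + 15 * exp(-(t[pulse] - 100) / tau)
  tr <- structure(list(t = t, v = v, dt = dt,
                       protocol = list(pulse_onset_ms = 100, pulse_end_ms = 700,
                                       segments = data.frame(duration = c(100, 600),
                                                             start = c(0, -50),
                                                             end = c(0, -50)))),
                  class = "voltage_trace")
  rest <- structure(list(t = t, v = rep(-70, length(t)), dt = dt,
                         protocol = list(pulse_onset_ms = 0, pulse_end_ms = 700)),
                    class = "voltage_trace")
  pp <- passive_properties(list(tr), rest)
  expect_equal(pp$time_constant, tau, tolerance = 0.05)
})

test_that("passive_properties rejects depolarizing sweeps", {
  p <- model_parameters(g_na = 0, g_kdr = 0, g_ks = 0)
  rest <- simulate_cell(p, step_protocol(0, duration_ms = 200, pre_ms = 0,
                                         post_ms = 0), noise = FALSE)
  dep <- simulate_cell(p, step_protocol(20, duration_ms = 200), noise = FALSE)
  expect_error(passive_properties(list(dep), rest), "hyperpolarizing")
})

test_that("rheobase picks the first spiking step and reports its spike count", {
  p <- model_parameters()
  fam <- lapply(seq(0, 60, 10), function(a)
    simulate_cell(p, step_protocol(a), noise = FALSE))
  rb <- rheobase(fam)
  expect_true(rb$rheobase %in% seq(10, 60, 10))
  expect_gte(rb$aps_at_rheobase, 1)
  # all steps below rheobase are silent
  below <- fam[seq(0, 60, 10) < rb$rheobase]
  expect_true(all(vapply(below, function(tr)
    length(detect_spikes(tr)$spike_times) == 0, logical(1))))

  # bisection oracle on continuous amplitude: within one 10 pA step
  lo <- 0; hi <- rb$rheobase
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    tr <- simulate_cell(p, step_protocol(mid), noise = FALSE)
    if (length(detect_spikes(tr)$spike_times) >= 1) hi <- mid else lo <- mid
  }
  expect_lte(rb$rheobase - hi, 10)
  expect_gte(rb$rheobase, hi - 1e-6)
})

test_that("an all-subthreshold family yields the no-rheobase sentinel", {
  p <- model_parameters(g_na = 0, g_kdr = 0, g_ks = 0)
  fam <- lapply(c(0, 10, 20), function(a)
    simulate_cell(p, step_protocol(a, duration_ms = 100), noise = FALSE))
  rb <- rheobase(fam)
  expect_true(is.na(rb$rheobase))
  expect_true(is.na(rb$aps_at_rheobase))
})

test_that("firing-frequency arithmetic follows the printed definitions", {
  # 4 spikes in the last 300 ms -> 13.33 Hz; and the count recovers exactly
  dt <- 0.1
  t <- seq(0, 800, by = dt)
  v <- rep(-70, length(t))
  for (ts in c(150, 480, 520, 600, 690)) {  # 1 early + 4 in [400, 700]
    i <- which.min(abs(t - ts))
    v[i:(i + 10)] <- c(seq(-70, 30, length.out = 6), seq(10, -70, length.out = 5))
  }
  tr <- structure(list(t = t, v = v, dt = dt,
                       protocol = list(pulse_onset_ms = 100, pulse_end_ms = 700)),
                  class = "voltage_trace")
  f <- suppressWarnings(steady_state_frequency(tr))
  expect_equal(f, 4 / 0.3)
  expect_equal(f * 0.3, round(f * 0.3))  # frequency x window is a count
})

test_that("instantaneous maximum is the reciprocal of the minimum ISI", {
  p <- model_parameters(g_ks = 0)
  fam <- lapply(c(0, 100, 200), function(a)
    simulate_cell(p, step_protocol(a), noise = FALSE))
  fi <- instantaneous_max(fam)
  best <- which.max(if_curve(fam)$frequency_hz)
  st <- detect_spikes(fam[[best]], window = c(100, 700))
  expect_equal(fi, 1000 / min(diff(st$spike_times)))
})

test_that("the I-f curve is nondecreasing up to its maximum for a tonic cell", {
  p <- model_parameters(g_ks = 0)
  fam <- lapply(seq(0, 200, 40), function(a)
    simulate_cell(p, step_protocol(a), noise = FALSE))
  ic <- if_curve(fam)
  expect_true(all(diff(ic$frequency_hz[1:which.max(ic$frequency_hz)]) >= 0))
  expect_true(all(ic$frequency_hz >= 0))
})

test_that("rundown ratios follow their definition", {
  mk_train <- function(amps) {
    dt <- 0.05
    t <- seq(0, 700, by = dt)
    v <- rep(-70, length(t))
    for (k in seq_along(amps)) {
      i <- which.min(abs(t - (150 + 40 * k)))
      v[i:(i + 20)] <- c(seq(-70, -70 + amps[k], length.out = 11),
                         seq(-70 + amps[k] - 10, -70, length.out = 10))
    }
    structure(list(t = t, v = v, dt = dt,
                   protocol = list(pulse_onset_ms = 100, pulse_end_ms = 700)),
              class = "voltage_trace")
  }
  rd <- rundown(mk_train(rep(100, 12)))
  expect_equal(rd$series, rep(1, 12), tolerance = 1e-6)
  expect_equal(rd$tenth_to_first, 1, tolerance = 1e-6)
  expect_false(rd$partial)

  geo <- rundown(mk_train(100 * 0.95^(0:11)))
  expect_equal(geo$tenth_to_first, 0.95^9, tolerance = 0.01)

  few <- rundown(mk_train(rep(100, 4)))
  expect_true(few$partial)
  expect_equal(few$tenth_to_first, 1, tolerance = 1e-6)
})

test_that("ISI CoV follows the sample-SD definition and its invariances", {
  expect_equal(isi_cov(c(0, 100, 200, 300, 400)), 0)
  # ISIs {100, 300}: sample SD sqrt(2)*100, mean 200
  expect_equal(isi_cov(c(0, 100, 400)), sqrt(2) * 100 / 200, tolerance = 1e-12)
  expect_true(is.na(isi_cov(c(0, 100))))
  # scale invariance
  times <- cumsum(c(0, rexp(50, 1 / 30)))
  expect_equal(isi_cov(times), isi_cov(times * 3.7), tolerance = 1e-12)
})

test_that("the CoV of a long Poisson train approaches 1", {
  set.seed(421)
  times <- cumsum(rexp(2001, rate = 1 / 50))
  expect_equal(isi_cov(times), 1, tolerance = 0.05)
})

test_that("population rate maps are flat for regular trains and linear in cells", {
  train50 <- seq(20, 980, by = 20)  # 50 Hz
  m <- population_rate_map(list(list(train50)), duration_ms = 1000)
  inner <- m[1, 5:45]
  expect_true(all(abs(inner - 50) < 1))
  m0 <- population_rate_map(list(list(numeric(0))), duration_ms = 1000)
  expect_true(all(m0 == 0))
  # two-cell average is the mean of the individual maps
  train25 <- seq(20, 980, by = 40)
  m2 <- population_rate_map(list(list(train50), list(train25)), 1000)
  ma <- population_rate_map(list(list(train50)), 1000)
  mb <- population_rate_map(list(list(train25)), 1000)
  expect_equal(m2, (ma + mb) / 2)
})

test_that("voltage-clamp features match analytic fixtures", {
  t <- seq(0, 120, by = 0.01)
  i1 <- -1000 * exp(-t / 0.5)
  f1 <- vclamp_features(t, i1)
  expect_equal(f1$peak_current, -1000, tolerance = 1)
  expect_equal(f1$tau_inactivation, 0.5, tolerance = 0.01)
  expect_lt(abs(f1$persistent_percent), 0.5)

  i2 <- -1000 * exp(-t / 0.5) - 50
  f2 <- vclamp_features(t, i2)
  expect_equal(f2$persistent_percent, 100 * 50 / 1050, tolerance = 0.05)
  expect_equal(f2$tau_inactivation, 0.5, tolerance = 0.02)

  i3 <- -800 * exp(-t / 0.5) - 200 * exp(-t / 5)
  f3 <- vclamp_features(t, i3)
  expect_equal(f3$tau_inactivation, 0.5, tolerance = 0.05)  # dominant term
  i4 <- -200 * exp(-t / 0.5) - 800 * exp(-t / 5)
  f4 <- vclamp_features(t, i4)
  expect_equal(f4$tau_inactivation, 5, tolerance = 0.5)
})

test_that("vclamp_features enforces its trace-length precondition", {
  t <- seq(0, 50, by = 0.01)
  expect_error(vclamp_features(t, -exp(-t)), "100 ms")
})
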