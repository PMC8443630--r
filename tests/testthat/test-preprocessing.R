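make_rec <- function(x, fs = 20, experiment = "synthetic") {
  trial_recording(as.matrix(x), fs = fs, experiment = experiment)
}

test_that("moving average matches hand-computed means and edge handling", {
  expect_equal(moving_average(make_rec(rep(3, 40)), 10)$positions[, 1],
               rep(3, 40))
  r <- moving_average(make_rec(1:5), 5)
  expect_equal(unname(r$positions[3, 1]), 3)       # full centred window
  expect_equal(unname(r$positions[1, 1]), mean(1:3))  # shrunk at the edge
  x <- rnorm(30)
  expect_equal(moving_average(make_rec(x), 1)$positions[, 1], x)
  expect_error(moving_average(make_rec(1:5), 6), "exceeds")
})

test_that("spline resampling reproduces smooth signals on the fine grid", {
  tt <- seq(0, 9.9, by = 0.1)
  ramp <- make_rec(2 * tt + 1, fs = 10)
  up <- resample_spline(ramp, 100)
  t_out <- (seq_len(nrow(up$positions)) - 1) / 100
  expect_equal(up$fs, 100)
  expect_lt(max(abs(up$positions[, 1] - (2 * t_out + 1))), 1e-9)

  s <- make_rec(sin(2 * pi * tt), fs = 10)
  us <- resample_spline(s, 100)
  interior <- t_out > 0.5 & t_out < 9.4
  expect_lt(max(abs(us$positions[interior, 1] -
                      sin(2 * pi * t_out[interior]))), 5e-3)

  same <- resample_spline(s, 10)
  expect_identical(same$positions, s$positions)
  expect_error(resample_spline(make_rec(1:3, fs = 10), 100), "4 samples")
})

test_that("zero-phase Butterworth filtering matches its magnitude response", {
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  const <- butterworth_lowpass(make_rec(rep(2, length(tt)), fs = fs))
  expect_lt(max(abs(const$positions[, 1] - 2)), 1e-6)

  # two-pass 4th-order magnitude response |H|^2 = (1 + (f/fc)^8)^-1
  gain2 <- function(f, fc = 6) 1 / (1 + (f / fc)^8)
  mix <- sin(2 * pi * 1 * tt) + sin(2 * pi * 20 * tt)
  filt <- butterworth_lowpass(make_rec(mix, fs = fs), 6, 4)$positions[, 1]
  keep <- tt > 2 & tt < 18
  # recover component amplitudes by least squares on the quadrature pair
  amp <- function(y, f) {
    b <- coef(lm(y ~ sin(2 * pi * f * tt[keep]) + cos(2 * pi * f * tt[keep])))
    sqrt(b[2]^2 + b[3]^2)
  }
  expect_gt(amp(filt[keep], 1), gain2(1) * 0.995)
  expect_lt(abs(amp(filt[keep], 1) - 1), 0.01)       # < 1% attenuation
  expect_lt(amp(filt[keep], 20), 0.01)               # > 99% attenuation
  expect_error(butterworth_lowpass(make_rec(mix, fs = fs), 60), "Nyquist")
})

test_that("linear filters are linear", {
  set.seed(77)
  x <- rnorm(200); y <- rnorm(200)
  for (f in list(function(r) moving_average(r, 10),
                 function(r) butterworth_lowpass(r, 6, 4))) {
    fx <- f(make_rec(x, fs = 100))$positions[, 1]
    fy <- f(make_rec(y, fs = 100))$positions[, 1]
    fxy <- f(make_rec(2 * x - 3 * y, fs = 100))$positions[, 1]
    expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-9)
  }
})

test_that("Hilbert phase recovers frequency, quadrature lag and is amplitude-free", {
  fs <- 100
  tt <- seq(0, 30, by = 1 / fs)
  n <- length(tt)
  interior <- seq(round(0.1 * n), round(0.9 * n))

  ph_cos <- hilbert_phase(make_rec(cos(2 * pi * tt), fs = fs))$theta[, 1]
  slope <- coef(lm(ph_cos[interior] ~ tt[interior]))[2]
  expect_lt(abs(slope - 2 * pi) / (2 * pi), 0.01)

  ph_sin <- hilbert_phase(make_rec(sin(2 * pi * tt), fs = fs))$theta[, 1]
  expect_lt(max(abs((ph_cos - ph_sin)[interior] - pi / 2)), 0.05)

  two <- hilbert_phase(make_rec(cbind(cos(2 * pi * tt), cos(2 * pi * tt)),
                                fs = fs))
  expect_equal(two$theta[, 1], two$theta[, 2])

  scaled <- hilbert_phase(make_rec(5.3 * cos(2 * pi * tt), fs = fs))$theta[, 1]
  expect_lt(max(abs(scaled - ph_cos)[interior]), 1e-9)

  expect_error(hilbert_phase(make_rec(rep(1, 100))), "constant")
})

test_that("preprocessing dispatches on the experiment tag", {
  tt <- seq(0, 30, by = 0.05)
  pos <- sapply(2 * pi * c(0.9, 1.0, 1.1), function(w) sin(w * tt))
  syn <- preprocess(make_rec(pos, fs = 20, experiment = "synthetic"))
  expect_match(syn$source, "moving_average")
  expect_match(syn$source, "hilbert")

  tt10 <- seq(0, 30, by = 0.1)
  pos10 <- sapply(2 * pi * c(0.9, 1.0, 1.1), function(w) sin(w * tt10))
  chr <- preprocess(make_rec(pos10, fs = 10, experiment = "chronos"))
  expect_equal(chr$fs, 100)
  expect_match(chr$source, "butterworth")

  bad <- make_rec(pos, fs = 20)
  bad$experiment <- "telepathy"
  expect_error(preprocess(bad), "unknown experiment")

  # planted frequencies are recovered through either chain within 2%
  for (ph in list(syn, chr)) {
    k <- nrow(ph$theta)
    tg <- (seq_len(k) - 1) / ph$fs
    sl <- apply(ph$theta, 2, function(col) coef(lm(col ~ tg))[2])
    expect_lt(max(abs(sl - 2 * pi * c(0.9, 1.0, 1.1)) /
                    (2 * pi * c(0.9, 1.0, 1.1))), 0.02)
  }
})

test_that("end trimming drops the requested fraction at both ends", {
  ph <- phase_matrix(matrix(seq_len(200), 100, 2), fs = 20)
  tr <- trim_phases(ph, 0.05)
  expect_equal(nrow(tr$theta), 90)
  expect_equal(tr$theta[1, 1], 6)
})
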