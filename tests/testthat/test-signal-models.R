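cardiac <- cardiac_protocol()

test_that("forward models evaluate their closed forms", {
  expect_equal(predict_monoexp(monoexp_params(100, 10),
                               echo_protocol(c(5, 10)))[2],
               100 * exp(-1), tolerance = 1e-12)
  # identity at TE -> 0 via a protocol with a tiny first echo
  expect_equal(predict_monoexp(monoexp_params(100, 10),
                               echo_protocol(c(1e-12, 10)))[1],
               100, tolerance = 1e-9)
  # frozen reference values, PD = 100, T2* = 20 ms on the cardiac train
  expect_equal(predict_monoexp(monoexp_params(100, 20), cardiac),
               c(88.2496902585, 77.8800783071, 68.7289278791, 60.6530659713,
                 53.5261428519, 47.2366552741, 41.6862019679, 36.7879441171,
                 32.4652467358, 28.6504796860),
               tolerance = 1e-10)

  expect_equal(predict_offset(offset_params(100, 10, 5),
                              echo_protocol(c(5, 10)))[2],
               100 * exp(-1) + 5, tolerance = 1e-12)
  # zero offset degenerates to the monoexponential
  expect_equal(predict_offset(offset_params(100, 10, 0), cardiac),
               predict_monoexp(monoexp_params(100, 10), cardiac))
  # its long-TE limit is the offset itself
  expect_equal(predict_offset(offset_params(100, 0.5, 7),
                              echo_protocol(c(100, 200)))[2],
               7, tolerance = 1e-9)

  expect_equal(predict_second_moment(noise_corrected_params(100, 10, 300),
                                     echo_protocol(c(5, 10)))[2],
               (100 * exp(-1))^2 + 300, tolerance = 1e-9)
  expect_equal(predict_second_moment(noise_corrected_params(100, 10, 0),
                                     cardiac),
               predict_monoexp(monoexp_params(100, 10), cardiac)^2)
})

test_that("parameter constructors reject invalid values", {
  expect_error(monoexp_params(-1, 10), "pd")
  expect_error(monoexp_params(100, 0), "t2")
  expect_error(offset_params(100, 10, -1), "non-negative")
  expect_error(noise_corrected_params(100, 10, -1), "non-negative")
})

test_that("WLSL is exact on noiseless monoexponential data", {
  for (t2 in c(2, 10, 35)) {
    for (p in list(cardiac, liver_protocol())) {
      f <- wlsl_fit(noiseless_signal(p, pd = 100, t2 = t2))
      expect_equal(f$pd, 100, tolerance = 1e-9)
      expect_equal(f$t2, t2, tolerance = 1e-9)
    }
  }
  # two points determine the log-line
  f2 <- wlsl_fit(decay_signal(echo_protocol(c(2.5, 5)),
                              c(77.8801, 60.6531)))
  expect_equal(f2$pd, 100, tolerance = 1e-4)
  expect_equal(f2$t2, 10, tolerance = 1e-4)
})

test_that("WLSL on noisy data solves the weighted normal equations", {
  y <- c(78.7177217465, 62.1252862913, 47.4445481270, 37.6135031164,
         28.1353921224, 22.4502979870, 16.6428039296, 13.8689343394,
         10.3497704463, 7.6941329637)
  f <- wlsl_fit(decay_signal(cardiac, y))
  # frozen solution of the 2x2 weighted normal equations (weights y^2)
  expect_equal(f$pd, 102.0395486900, tolerance = 1e-8)
  expect_equal(f$t2, 9.8558431467, tolerance = 1e-8)
  # and against an in-test lm() fit, an independent route
  lmfit <- stats::lm(log(y) ~ tes, data.frame(tes = cardiac$tes),
                     weights = y^2)
  expect_equal(f$pd, exp(unname(coef(lmfit)[1])), tolerance = 1e-9)
  expect_equal(f$t2, -1 / unname(coef(lmfit)[2]), tolerance = 1e-9)
})

test_that("WLSL rejects non-positive signals and clamps non-decaying fits", {
  expect_error(wlsl_fit(decay_signal(cardiac, c(rep(10, 9), 0))),
               "positive")
  rising <- decay_signal(echo_protocol(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(wlsl_fit(rising)$t2, 30)  # 10 x max TE ceiling
})

test_that("fit_model recovers noiseless generating parameters", {
  f <- fit_model("monoexp", noiseless_signal(cardiac, 100, 10))
  expect_equal(f$params$pd, 100, tolerance = 1e-6)
  expect_equal(f$params$t2, 10, tolerance = 1e-6)
  expect_true(f$diagnostics$converged)

  f3 <- fit_model("offset", noiseless_signal(cardiac, 100, 10, c = 8))
  expect_equal(f3$params$pd, 100, tolerance = 1e-4)
  expect_equal(f3$params$t2, 10, tolerance = 1e-4)
  expect_equal(f3$params$c, 8, tolerance = 1e-3)

  # second-moment model on a series that matches sqrt(S^2 + k)
  k <- 400
  y <- sqrt((100 * exp(-cardiac$tes / 10))^2 + k)
  fk <- fit_model("second_moment", decay_signal(cardiac, y))
  expect_equal(fk$params$t2, 10, tolerance = 1e-4)
  expect_equal(fk$params$k, k, tolerance = 1e-2)
})

test_that("fit_model started at the optimum stays there", {
  s <- noiseless_signal(cardiac, 100, 10)
  f <- fit_model("monoexp", s, init = monoexp_params(100, 10))
  expect_lt(f$diagnostics$sse, 1e-8)
  expect_equal(f$params$pd, 100, tolerance = 1e-7)
  expect_equal(f$params$t2, 10, tolerance = 1e-7)
})

test_that("fitted SSE never exceeds the SSE of the initialization", {
  sse_mono <- function(p, s)
    sum((s$values - p$pd * exp(-s$protocol$tes / p$t2))^2)
  set.seed(7)
  for (i in 1:20) {
    y <- 100 * exp(-cardiac$tes / runif(1, 3, 30)) + rnorm(10, 0, 3)
    s <- decay_signal(cardiac, pmax(y, 0.1))
    init <- monoexp_params(runif(1, 50, 200), runif(1, 2, 50))
    f <- fit_model("monoexp", s, init = init)
    expect_lte(f$diagnostics$sse, sse_mono(init, s) + 1e-9)
  }
})

test_that("fitted SSE dominates a brute-force parameter grid", {
  set.seed(11)
  y <- pmax(100 * exp(-cardiac$tes / 10) + rnorm(10, 0, 4), 0.1)
  s <- decay_signal(cardiac, y)
  f <- fit_model("monoexp", s)
  grid <- expand.grid(pd = seq(50, 150, length.out = 100),
                      t2 = seq(5, 15, length.out = 100))
  sse_grid <- vapply(seq_len(nrow(grid)), function(i)
    sum((y - grid$pd[i] * exp(-cardiac$tes / grid$t2[i]))^2), 0)
  expect_lte(f$diagnostics$sse, min(sse_grid))
})

test_that("the simplex engine agrees with stats::optim Nelder-Mead", {
  set.seed(13)
  y <- pmax(100 * exp(-cardiac$tes / 8) + rnorm(10, 0, 3), 0.1)
  s <- decay_signal(cardiac, y)
  obj <- function(x) {
    if (x[2] <= 0) return(1e12)
    sum((y - x[1] * exp(-cardiac$tes / x[2]))^2)
  }
  init <- wlsl_fit(s)
  ref <- stats::optim(c(init$pd, init$t2), obj,
                      control = list(reltol = 1e-12, maxit = 5000))
  f <- fit_model("monoexp", s)
  expect_equal(f$diagnostics$sse, ref$value, tolerance = 1e-6)
  expect_equal(f$params$t2, ref$par[2], tolerance = 1e-4)
})

test_that("fit_model enforces its preconditions", {
  short <- decay_signal(echo_protocol(c(1, 2)), c(3, 2))
  expect_error(fit_model("offset", short), "under-determined")
  expect_error(fit_model("monoexp", noiseless_signal(cardiac),
                         init = offset_params(100, 10, 1)),
               "does not match")
})

test_that("m2ncm_fit recovers T2* when the noise term is exact", {
  sigma <- 100 / 15; L <- 6
  y <- sqrt((100 * exp(-cardiac$tes / 10))^2 + 2 * L * sigma^2)
  f <- m2ncm_fit(decay_signal(cardiac, y), sigma, L)
  expect_equal(f$params$t2, 10, tolerance = 1e-5)
  expect_equal(f$params$k, 2 * L * sigma^2)
})
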