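std_normal <- function() parameter_spec("z", "normal", c(mean = 0, sd = 1))

test_that("the 5-point normal rule matches the closed-form Hermite roots and weights", {
  r <- quadrature_rule(std_normal(), 5)
  # roots of the 5th probabilists' Hermite polynomial x^5 - 10x^3 + 15x
  roots <- c(-sqrt(5 + sqrt(10)), -sqrt(5 - sqrt(10)), 0,
             sqrt(5 - sqrt(10)), sqrt(5 + sqrt(10)))
  expect_equal(r$nodes, roots, tolerance = 1e-12)
  gw <- oracle_gauss_hermite_prob(5)
  expect_equal(r$weights, gw$weights, tolerance = 1e-12)
  expect_equal(r$weights[3], 8 / 15, tolerance = 1e-10)
  # the non-extreme off-centre nodes sit at +-1.3556 SD
  expect_equal(abs(r$nodes[c(2, 4)]), rep(1.355626179974266, 2),
               tolerance = 1e-12)
})

test_that("quadrature rules reproduce distribution moments to order 2N-1", {
  # normal(mu, sigma): raw moments via central double factorials
  spec <- parameter_spec("x", "normal", c(mean = 1.7, sd = 0.6))
  for (N in c(3, 5, 7)) {
    r <- quadrature_rule(spec, N)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    for (k in seq_len(2 * N - 1)) {
      central <- if (k %% 2 == 1) 0 else prod(seq(k - 1, 1, by = -2)) * 0.6^k
      want <- sum(choose(k, 0:k) * 1.7^(k - (0:k)) *
                    vapply(0:k, function(j)
                      if (j %% 2 == 1) 0
                      else if (j == 0) 1
                      else prod(seq(j - 1, 1, by = -2)) * 0.6^j, numeric(1)))
      expect_equal(sum(r$weights * r$nodes^k), want,
                   tolerance = 1e-10 * max(1, abs(want)), ignore_attr = TRUE)
      if (k == 2) expect_equal(sum(r$weights * (r$nodes - 1.7)^2), 0.6^2,
                               tolerance = 1e-12)
    }
  }
  # uniform(a, b): raw moments (b^(k+1) - a^(k+1)) / ((k+1)(b-a))
  u <- parameter_spec("u", "uniform", c(low = 0.3, high = 2.1))
  for (N in c(2, 5)) {
    r <- quadrature_rule(u, N)
    for (k in seq_len(2 * N - 1)) {
      want <- (2.1^(k + 1) - 0.3^(k + 1)) / ((k + 1) * (2.1 - 0.3))
      expect_equal(sum(r$weights * r$nodes^k), want,
                   tolerance = 1e-10 * want, ignore_attr = TRUE)
    }
  }
  u01 <- quadrature_rule(parameter_spec("u", "uniform", c(low = 0, high = 1)), 4)
  expect_equal(sum(u01$weights * u01$nodes), 0.5, tolerance = 1e-14)
  # lognormal: exact in log space
  ln <- parameter_spec("s", "lognormal", c(log_mean = -1.45, log_sd = 0.45))
  r <- quadrature_rule(ln, 5)
  for (k in seq_len(9)) {
    want <- if (k %% 2 == 1) 0 else prod(seq(k - 1, 1, by = -2)) * 0.45^k
    expect_equal(sum(r$weights * (log(r$nodes) + 1.45)^k), want,
                 tolerance = 1e-10 * max(1, abs(want)), ignore_attr = TRUE)
  }
  expect_equal(r$nodes[3], exp(-1.45), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the shared-nominal design has n(N-1)+1 runs, each off-nominal in one parameter", {
  des <- fx_design()
  expect_equal(nrow(des$runs), 7 * (5 - 1) + 1)
  expect_equal(nrow(build_design(fx_params(), 3)$runs), 15)
  one <- build_design(list(std_normal()), 5)
  expect_equal(nrow(one$runs), 5)
  nominal <- as.numeric(des$runs[des$runs$run_id == "nominal",
                                 names(des$rules)])
  for (i in 2:nrow(des$runs)) {
    x <- as.numeric(des$runs[i, names(des$rules)])
    expect_equal(sum(abs(x - nominal) > 1e-12), 1)
  }
  # even N has no centre node at the nominal: sharing must fail loudly
  expect_error(build_design(fx_params(), 4), "shared-nominal")
})

test_that("moments contract node outputs with the Gauss weights", {
  des <- fx_design()
  runs <- des$runs
  const <- setNames(rep(4.2, nrow(runs)), runs$run_id)
  mom <- mdrm_moments(const, des)
  expect_equal(mom$rho, rep(4.2, 7))
  expect_equal(mom$theta, rep(4.2^2, 7))

  # h(x) = z for a single standard normal parameter: rho = 0, theta = 1
  d1 <- build_design(list(std_normal()), 5)
  h <- setNames(as.numeric(d1$runs$z), d1$runs$run_id)
  m1 <- mdrm_moments(h, d1)
  expect_equal(m1$rho, 0, tolerance = 1e-12)
  expect_equal(m1$theta, 1, tolerance = 1e-12)

  # h(x) = prod x_i on uniforms [1, 2]: closed-form one-dimensional integrals
  specs <- lapply(1:3, function(i)
    parameter_spec(paste0("u", i), "uniform", c(low = 1, high = 2)))
  d3 <- build_design(specs, 5)
  prod_out <- apply(d3$runs[, vapply(specs, `[[`, "", "name")], 1, prod)
  m3 <- mdrm_moments(setNames(prod_out, d3$runs$run_id), d3)
  expect_equal(m3$rho, rep(1.5 * 1.5^2, 3), tolerance = 1e-10)
  expect_equal(m3$theta, rep((7 / 3) * 1.5^4, 3), tolerance = 1e-10)
  expect_true(all(m3$theta >= m3$rho^2))
  expect_error(mdrm_moments(const[-1], des), "missing outputs")
})

test_that("indices: equal shares for exchangeable parameters, all-or-nothing for single drivers", {
  specs <- lapply(1:7, function(i)
    parameter_spec(paste0("u", i), "uniform", c(low = 1, high = 2)))
  des <- build_design(specs, 5)
  nms <- vapply(specs, `[[`, "", "name")
  prod_out <- apply(des$runs[, nms], 1, prod)
  s <- sensitivity_indices(mdrm_moments(setNames(prod_out, des$runs$run_id),
                                        des))
  expect_equal(s$S, rep(1 / 7, 7), tolerance = 1e-12)
  expect_equal(sum(s$S), 1, tolerance = 1e-9)

  only1 <- setNames(as.numeric(des$runs[, nms[1]]), des$runs$run_id)
  s1 <- sensitivity_indices(mdrm_moments(only1, des))
  expect_equal(s1$S, c(1, rep(0, 6)), tolerance = 1e-12)

  # degenerate cases fail loudly or warn
  zero_rho <- data.frame(parameter = "a", rho = 0, theta = 1)
  expect_error(sensitivity_indices(zero_rho, h0 = 1), "rho is zero")
  flat <- data.frame(parameter = c("a", "b"), rho = c(2, 3), theta = c(4, 9))
  expect_warning(sf <- sensitivity_indices(flat, h0 = 1), "undefined")
  expect_true(all(is.nan(sf$S)))
})

test_that("M-DRM indices match Monte-Carlo Sobol indices for multiplicative responses", {
  params <- fx_params()
  a <- c(spine_pc1 = 0.10, spine_pc2 = 0.07, neural_delay = 0.08,
         muscle_pcsa = 0.14, adipose_props = 0.06, muscle_props = 0.07,
         skin_mu = 0.04)
  scale <- vapply(params, function(s) switch(s$family,
    normal = unname(s$params["sd"]),
    uniform = unname(diff(s$params[c("low", "high")])) / sqrt(12),
    lognormal = unname(s$params["log_sd"])), numeric(1))
  f <- function(X) {
    out <- rep(1, nrow(X))
    for (nm in names(a)) {
      x <- X[, nm]
      if (params[[nm]]$family == "lognormal") x <- log(x)
      ref <- if (params[[nm]]$family == "lognormal")
        params[[nm]]$params["log_mean"] else params[[nm]]$nominal
      out <- out * exp(a[nm] * (x - ref) / scale[nm])
    }
    out
  }
  des <- fx_design()
  y <- f(as.matrix(des$runs[, names(des$rules)]))
  s <- sensitivity_indices(mdrm_moments(setNames(y, des$runs$run_id), des))
  sob <- oracle_sobol(f, params, n = 1e5, seed = 99)
  expect_lt(max(abs(s$S - sob)), 0.02)
  expect_equal(sum(s$S), 1, tolerance = 1e-9)
})

test_that("the product surrogate is exact at the cut-point and at design points", {
  params <- fx_params()
  des <- fx_design()
  X <- as.matrix(des$runs[, names(des$rules)])
  # a genuinely multiplicative response
  f <- function(X) apply(X, 1, function(x)
    (1 + 0.1 * x["spine_pc1"]) * (2 + x["muscle_pcsa"]) * exp(0.5 * x["skin_mu"]))
  y <- f(X)
  mom <- mdrm_moments(setNames(y, des$runs$run_id), des)
  hh <- mdrm_approximate(mom, des)
  nominal <- X[des$runs$run_id == "nominal", ]
  expect_equal(hh(nominal), attr(mom, "h0"), tolerance = 1e-12)
  expect_equal(hh(X), y, tolerance = 1e-9)
  # an additive response has a finite, nonzero model error off-axis
  g <- function(X) 1 + X[, "spine_pc1"] + X[, "muscle_pcsa"]
  momg <- mdrm_moments(setNames(g(X), des$runs$run_id), des)
  hg <- mdrm_approximate(momg, des)
  off <- nominal; off["spine_pc1"] <- 1; off["muscle_pcsa"] <- 1.2
  err <- abs(hg(off) - g(matrix(off, 1, dimnames = list(NULL, names(off)))))
  expect_true(is.finite(err) && err > 0)
})
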