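# build a spine whose measurement nodes are set directly (other landmarks
# kept from the template); only meas nodes enter the shape model fit
spine_with_nodes <- function(nodes, template = template_spine()) {
  df <- template$landmarks
  for (lv in rownames(nodes)) {
    i <- which(df$level == lv & df$role == "meas")
    df$x[i] <- nodes[lv, 1]
    df$z[i] <- nodes[lv, 2]
  }
  kinesens:::new_spine_model(df)
}

base_nodes <- function() {
  tp <- template_spine()
  lev <- setdiff(vertebra_levels(), "S1")
  t(vapply(lev, function(lv) kinesens:::spine_point(tp, lv, "meas"),
           numeric(2)))
}

test_that("degenerate and rank-1 training sets are handled exactly", {
  b <- base_nodes()
  same <- replicate(5, spine_with_nodes(b), simplify = FALSE)
  m <- fit_shape_model(same)
  expect_equal(m$sds, rep(0, 2))
  expect_equal(m$explained, rep(0, 2))

  v <- matrix(0, nrow(b), 2); v[, 1] <- seq_len(nrow(b)); v <- v / sqrt(sum(v^2))
  s <- c(-3, -1, 0, 1, 3)
  rank1 <- lapply(s, function(si) spine_with_nodes(b + si * v))
  m1 <- fit_shape_model(rank1)
  expect_equal(explained_variance(m1, 1), 1)
  # PC1 spans v (up to sign)
  load1 <- matrix(m1$loadings[, 1], ncol = 2, byrow = TRUE)
  cosang <- abs(sum(load1 * v))
  expect_equal(cosang, 1, tolerance = 1e-10)
})

test_that("a 2-factor population is recovered: subspace, variance split, score properties", {
  set.seed(11)
  b <- base_nodes()
  n <- nrow(b)
  v1 <- matrix(rnorm(2 * n), n, 2); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- matrix(rnorm(2 * n), n, 2)
  v2 <- v2 - v1 * sum(v1 * v2); v2 <- v2 / sqrt(sum(v2^2))
  # variance split 3:1, no noise
  s1 <- rnorm(36, sd = sqrt(3)); s2 <- rnorm(36, sd = 1)
  s1 <- (s1 - mean(s1)) / sd(s1) * sqrt(3)
  s2 <- stats::residuals(stats::lm(s2 ~ s1))
  s2 <- (s2 - mean(s2)) / sd(s2)
  spines <- lapply(seq_len(36), function(i)
    spine_with_nodes(b + s1[i] * v1 + s2[i] * v2))
  m <- fit_shape_model(spines)
  expect_equal(explained_variance(m, 1), 0.75, tolerance = 1e-12)
  expect_equal(explained_variance(m, 2), 1, tolerance = 1e-12)
  # principal angles between the fitted and generating subspaces
  V <- cbind(as.numeric(t(v1)), as.numeric(t(v2)))
  sv <- svd(crossprod(m$loadings, V))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
  # training scores are uncorrelated across PCs
  sc <- t(vapply(spines, function(sp) shape_scores(m, sp), numeric(2)))
  expect_lt(abs(cor(sc[, 1], sc[, 2])), 1e-10)
})

test_that("the fitted model is orthonormal with ordered spectrum and the documented PC sign", {
  m <- fx_shape()
  G <- crossprod(m$loadings)
  expect_lt(max(abs(G - diag(2))), 1e-10)
  all_m <- fit_shape_model(fx_spines(), n_pcs = length(fx_spines()) - 1)
  expect_true(all(diff(all_m$sds) <= 1e-12))
  expect_true(all(diff(all_m$explained_all) <= 1e-12))
  expect_lte(sum(all_m$explained_all), 1 + 1e-12)
  c7x <- 2 * match("C7", m$levels) - 1
  expect_lt(m$loadings[c7x, 1], 0)  # positive PC1 moves C7 posteriorly
})

test_that("generation is affine in scores and reproduces training spines exactly", {
  m <- fx_shape()
  a <- shape_nodes(m, c(1.2, -0.7))
  b <- shape_nodes(m, c(-0.4, 2.1))
  z <- shape_nodes(m, c(0, 0))
  expect_equal(a + b - z, shape_nodes(m, c(0.8, 1.4)), tolerance = 1e-9)
  expect_equal(z, matrix(m$mean, ncol = 2, byrow = TRUE,
                         dimnames = list(m$levels, c("x", "z"))))
  # +1 / -1 SD are symmetric about the mean
  expect_equal(shape_nodes(m, c(1, 0)) + shape_nodes(m, c(-1, 0)), 2 * z,
               tolerance = 1e-9)
  # full-rank reconstruction of every training spine to 1e-6 mm
  all_m <- fit_shape_model(fx_spines(), n_pcs = length(fx_spines()) - 1)
  for (i in c(2, 17, 30)) {
    sp <- fx_spines()[[i]]
    g <- generate_spine(all_m, shape_scores(all_m, sp))
    got <- t(vapply(all_m$levels,
                    function(lv) kinesens:::spine_point(g, lv, "meas"),
                    numeric(2)))
    want <- t(vapply(all_m$levels,
                     function(lv) kinesens:::spine_point(sp, lv, "meas"),
                     numeric(2)))
    expect_lt(max(abs(got - want)), 1e-6)
  }
  expect_error(shape_nodes(m, c(1, 2, 3)), "scores")
})

test_that("shape model JSON round-trips", {
  m <- fx_shape()
  f <- withr::local_tempfile(fileext = ".json")
  write_shape_model(m, f)
  rt <- read_shape_model(f)
  expect_equal(rt$mean, unname(m$mean))
  expect_equal(unname(rt$loadings), unname(m$loadings), tolerance = 1e-12)
  expect_equal(rt$sds, unname(m$sds))
  expect_equal(rt$levels, m$levels)
})
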