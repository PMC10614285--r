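# Shared fixtures, built once per test run. Everything is generated in code
# from a fixed seed; no stored data.

.fx <- new.env(parent = emptyenv())

fx_population <- function() {
  if (is.null(.fx$pop)) .fx$pop <- generate_fixture_population(36, seed = 1)
  .fx$pop
}

fx_spines <- function() {
  if (is.null(.fx$spines)) .fx$spines <- align_population(fx_population())
  .fx$spines
}

fx_shape <- function() {
  if (is.null(.fx$shape)) .fx$shape <- fit_shape_model(fx_spines())
  .fx$shape
}

fx_params <- function() {
  if (is.null(.fx$params)) .fx$params <- build_parameter_set()
  .fx$params
}

fx_design <- function() {
  if (is.null(.fx$design)) .fx$design <- build_design(fx_params(), 5)
  .fx$design
}

# the 29 surrogate runs' metric matrix for the default design
fx_design_metrics <- function() {
  if (is.null(.fx$met)) {
    des <- fx_design()
    X <- as.matrix(des$runs[, names(des$rules)])
    .fx$met <- kinesens:::surrogate_metrics(X, fx_shape())
  }
  .fx$met
}

# independent signed-angle oracle: atan2 of each endplate vector, difference
oracle_segment_angle <- function(spine, seg) {
  if (is.character(seg)) seg <- segment_spec(seg)
  ep <- function(level, plate) {
    roles <- if (plate == "superior") c("sup_post", "sup_ant")
             else c("inf_post", "inf_ant")
    a <- kinesens:::spine_point(spine, level, roles[1])
    b <- kinesens:::spine_point(spine, level, roles[2])
    atan2(b[2] - a[2], b[1] - a[1])
  }
  d <- ep(seg$upper_ref[1], seg$upper_ref[2]) - ep(seg$lower_ref[1], seg$lower_ref[2])
  d <- seg$sense * d * 180 / pi
  ((d + 180) %% 360) - 180
}

landmark_matrix <- function(spine) {
  as.matrix(spine$landmarks[, c("x", "z")])
}

# independent Gauss-Hermite oracle via the Golub-Welsch eigenvalue method on
# the probabilists' Jacobi matrix (off-diagonals sqrt(1..n-1))
oracle_gauss_hermite_prob <- function(n) {
  J <- diag(0, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values[order(e$values)],
       weights = (e$vectors[1, ]^2)[order(e$values)])
}

# pick-freeze Monte-Carlo first-order Sobol estimator for an arbitrary
# function over a parameter_set (oracle; independent of the M-DRM path)
oracle_sobol <- function(f, params, n, seed) {
  set.seed(seed)
  k <- length(params)
  draw <- function() {
    m <- vapply(params, parameter_sample, numeric(n), n = n)
    colnames(m) <- vapply(params, `[[`, "", "name")
    m
  }
  A <- draw(); B <- draw()
  fA <- f(A); fB <- f(B)
  V <- stats::var(c(fA, fB))
  vapply(seq_len(k), function(i) {
    ABi <- A; ABi[, i] <- B[, i]
    mean(fB * (f(ABi) - fA)) / V
  }, numeric(1))
}
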