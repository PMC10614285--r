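# Multiplicative dimensional reduction method (M-DRM): a multivariate
# response h(x) is approximated by a product of univariate cuts through a
# shared cut-point c,
#   h(x) ~ h(c)^(1-n) * prod_i h(x_i, c_{-i}),
# so the per-parameter mean rho_i = E[h(X_i, c_{-i})] and mean square
# theta_i = E[h(X_i, c_{-i})^2] are one-dimensional integrals, evaluated by
# Gaussian quadrature matched to each parameter's distribution. Primary
# (first-order) sensitivity indices follow from the per-parameter variance
# inflations theta_i / rho_i^2 - 1.

#' Gaussian quadrature rule matched to a parameter distribution
#'
#' Normal parameters get probabilists' Gauss-Hermite nodes scaled by the SD
#' and shifted by the mean; uniform parameters Gauss-Legendre nodes mapped to
#' the support with weights normalised to 1; lognormal parameters
#' Gauss-Hermite in log space with nodes exponentiated. Each rule integrates
#' polynomials (in the transformed variable) of degree up to 2N-1 exactly.
#' For odd N the centre node equals the parameter's nominal value, which is
#' what allows the shared-nominal design.
#'
#' @param spec a [parameter_spec()].
#' @param n_points number of nodes N (>= 2).
#' @return A `quadrature_rule`: `parameter`, `nodes` (ascending, parameter
#'   units), `weights` (probabilities summing to 1).
#' @export
quadrature_rule <- function(spec, n_points = 5) {
  stopifnot(n_points >= 2)
  if (spec$family %in% c("normal", "lognormal")) {
    gh <- pracma::gaussHermite(n_points)
    z <- gh$x * sqrt(2)              # probabilists' nodes (standard normal)
    w <- gh$w / sqrt(pi)
    nodes <- if (spec$family == "normal") {
      spec$params["mean"] + spec$params["sd"] * z
    } else {
      exp(spec$params["log_mean"] + spec$params["log_sd"] * z)
    }
  } else {
    gl <- pracma::gaussLegendre(n_points, -1, 1)
    lo <- spec$params["low"]; hi <- spec$params["high"]
    nodes <- lo + (gl$x + 1) / 2 * (hi - lo)
    w <- gl$w / 2
  }
  ord <- order(nodes)
  structure(list(parameter = spec$name, nodes = unname(nodes[ord]),
                 weights = unname(w[ord])),
            class = "quadrature_rule")
}

#' @export
print.quadrature_rule <- function(x, ...) {
  cat(sprintf("<quadrature_rule> %s, %d nodes\n", x$parameter, length(x$nodes)))
  print(rbind(node = x$nodes, weight = x$weights))
  invisible(x)
}

#' Build the shared-nominal one-at-a-time design
#'
#' One run at the cut-point (all parameters nominal) plus, for each
#' parameter, one run per off-centre quadrature node with all other
#' parameters held at nominal: `n * (N - 1) + 1` runs in total. Requires each
#' rule's centre node to coincide with the parameter's nominal (odd N); the
#' nominal run is then reused as every parameter's centre evaluation. Point
#' labels P1..PN index the ascending nodes, the centre being the nominal.
#'
#' @param params a `parameter_set` (or list of `parameter_spec`).
#' @param n_points Gauss points per parameter (odd for run sharing).
#' @param rules optional pre-built list of quadrature rules.
#' @return An `mdrm_design`: `runs` (data frame `run_id`, `label`,
#'   `parameter`, `point`, plus one column per parameter), `rules`, `params`.
#' @export
build_design <- function(params, n_points = 5, rules = NULL) {
  if (is.null(rules)) rules <- lapply(params, quadrature_rule, n_points = n_points)
  names(rules) <- vapply(params, `[[`, "", "name")
  nominal <- vapply(params, `[[`, numeric(1), "nominal")
  names(nominal) <- names(rules)
  centre <- (n_points + 1) / 2
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (n_points %% 2 == 0 ||
        abs(r$nodes[centre] - nominal[nm]) >
          1e-9 * max(1, abs(nominal[nm])))
      stop("centre node of ", nm, " does not equal its nominal; ",
           "a shared-nominal design is impossible (use an explicit n*N design)")
  }
  rows <- list(data.frame(run_id = "nominal", label = "nominal",
                          parameter = NA_character_, point = NA_integer_,
                          t(nominal), check.names = FALSE))
  for (nm in names(rules)) {
    for (j in setdiff(seq_len(n_points), centre)) {
      x <- nominal
      x[nm] <- rules[[nm]]$nodes[j]
      rows[[length(rows) + 1L]] <-
        data.frame(run_id = sprintf("%s_P%d", nm, j),
                   label = sprintf("%s P%d", nm, j),
                   parameter = nm, point = j, t(x), check.names = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  structure(list(runs = runs, rules = rules, params = params,
                 n_points = n_points), class = "mdrm_design")
}

#' @export
print.mdrm_design <- function(x, ...) {
  cat(sprintf("<mdrm_design> %d parameters x %d Gauss points, %d runs (shared nominal)\n",
              length(x$rules), x$n_points, nrow(x$runs)))
  invisible(x)
}

#' Write / read a design as CSV
#'
#' Columns: `run_id`, `label`, then one column per parameter in physical
#' units.
#'
#' @param design an `mdrm_design`.
#' @param path file path.
#' @export
write_design_csv <- function(design, path) {
  keep <- c("run_id", "label", names(design$rules))
  write.csv(design$runs[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-parameter approximate mean and mean square from design outputs
#'
#' Assembles, for each parameter, its N node outputs (reusing the nominal
#' run's output at the centre node) and contracts them with the Gauss
#' weights: `rho_i = sum_j w_ij h(x_ij, c_-i)`,
#' `theta_i = sum_j w_ij h(x_ij, c_-i)^2`.
#'
#' @param outputs named numeric vector of one metric value per run
#'   (names = `run_id`), or a data frame with columns `run_id` and `value`.
#' @param design the `mdrm_design` the outputs correspond to.
#' @return An `mdrm_moments` data frame: `parameter`, `rho`, `theta`, plus
#'   attribute `"h0"` (nominal-run output) and `"node_outputs"`.
#' @export
mdrm_moments <- function(outputs, design) {
  if (is.data.frame(outputs))
    outputs <- setNames(outputs$value, outputs$run_id)
  missing <- setdiff(design$runs$run_id, names(outputs))
  if (length(missing))
    stop("missing outputs for run(s): ", paste(missing, collapse = ", "))
  h0 <- unname(outputs["nominal"])
  centre <- (design$n_points + 1) / 2
  node_h <- list()
  res <- do.call(rbind, lapply(names(design$rules), function(nm) {
    r <- design$rules[[nm]]
    h <- vapply(seq_along(r$nodes), function(j) {
      if (j == centre) h0
      else unname(outputs[sprintf("%s_P%d", nm, j)])
    }, numeric(1))
    node_h[[nm]] <<- h
    data.frame(parameter = nm,
               rho = sum(r$weights * h),
               theta = sum(r$weights * h^2))
  }))
  rownames(res) <- NULL
  structure(res, h0 = h0, node_outputs = node_h, class = c("mdrm_moments", "data.frame"))
}

#' Primary sensitivity indices from M-DRM moments
#'
#' Each parameter's variance contribution is its cut-function variance
#' inflation `v_i = theta_i / rho_i^2 - 1`; the primary index is the
#' normalised share `S_i = v_i / sum_k v_k`, so indices are non-negative and
#' sum to one (a function with equal sensitivity to all n parameters gets
#' `S_i = 1/n` exactly).
#'
#' @param moments an `mdrm_moments` object (or data frame with `parameter`,
#'   `rho`, `theta`).
#' @param h0 nominal-run output (defaults to the moments' attribute).
#' @param metric optional metric name carried into the result.
#' @return A `sensitivity_result` data frame: `parameter`, `rho`, `theta`,
#'   `S`; attributes `h0` and `metric`.
#' @export
sensitivity_indices <- function(moments, h0 = attr(moments, "h0"),
                                metric = NA_character_) {
  rho <- moments$rho; theta <- moments$theta
  if (any(rho == 0))
    stop("rho is zero for parameter(s) ",
         paste(moments$parameter[rho == 0], collapse = ", "),
         "; the multiplicative decomposition is undefined for zero-mean cuts")
  v <- theta / rho^2 - 1
  v <- pmax(v, 0)  # clip quadrature round-off below Jensen's bound
  if (all(v == 0)) {
    warning("all variance contributions are zero; indices undefined")
    S <- rep(NaN, length(v))
  } else {
    S <- v / sum(v)
  }
  out <- data.frame(parameter = moments$parameter, rho = rho, theta = theta,
                    S = S)
  structure(out, h0 = h0, metric = metric,
            class = c("sensitivity_result", "data.frame"))
}

#' @export
print.sensitivity_result <- function(x, ...) {
  m <- attr(x, "metric")
  cat(sprintf("<sensitivity_result>%s h0 = %.4g\n",
              if (!is.na(m)) paste0(" metric ", m, ",") else "", attr(x, "h0")))
  df <- as.data.frame(x)
  df$S <- sprintf("%.4f", df$S)
  print(df, row.names = FALSE)
  invisible(x)
}

#' M-DRM product surrogate of the full response
#'
#' Builds `hhat(x) = h0^(1-n) * prod_i f_i(x_i)` where each univariate
#' factor `f_i` interpolates the design's node outputs with a monotone
#' piecewise-cubic (Fritsch-Carlson) spline, clamped to the node range
#' outside it. Exact at the cut-point and at every design point.
#'
#' @param moments an `mdrm_moments` object carrying the node outputs.
#' @param design the `mdrm_design` used.
#' @param h0 nominal output (defaults to the moments' attribute).
#' @return A function taking a named parameter vector (or matrix with named
#'   columns) and returning the surrogate prediction.
#' @export
mdrm_approximate <- function(moments, design, h0 = attr(moments, "h0")) {
  if (h0 == 0) stop("h0 must be nonzero for the multiplicative surrogate")
  node_h <- attr(moments, "node_outputs")
  factors <- lapply(names(design$rules), function(nm) {
    r <- design$rules[[nm]]
    f <- splinefun(r$nodes, node_h[[nm]], method = "monoH.FC")
    rng <- range(r$nodes)
    function(x) f(pmin(pmax(x, rng[1]), rng[2]))
  })
  names(factors) <- names(design$rules)
  n <- length(factors)
  function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
    prod_f <- rep(h0^(1 - n), nrow(x))
    for (nm in names(factors))
      prod_f <- prod_f * factors[[nm]](x[, nm])
    unname(prod_f)
  }
}
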