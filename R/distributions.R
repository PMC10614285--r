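# Population distributions for the seven varied occupant parameters:
# two-stage pooling of published coefficients of variation, quartile-based
# normal/lognormal fits, and uniform ranges for between-study spreads.

#' Per-study coefficients of variation
#'
#' @param study_id label of the source experiment.
#' @param condition_values coefficients of variation (SD/mean), one per
#'   reported condition, all positive.
#' @return A `study_cov` list.
#' @export
study_cov <- function(study_id, condition_values) {
  v <- as.numeric(condition_values)
  if (!length(v) || any(!is.finite(v)) || any(v <= 0))
    stop("condition_values must be positive and non-empty")
  structure(list(study_id = as.character(study_id), condition_values = v),
            class = "study_cov")
}

#' Two-stage unweighted pooling of coefficients of variation
#'
#' Averages the coefficients of variation within each study, then averages
#' those per-study means with equal weight, so studies reporting many
#' conditions do not dominate the pooled dispersion.
#'
#' @param studies list of [study_cov()] objects (a bare numeric vector is
#'   treated as a single study's conditions).
#' @return The pooled coefficient of variation.
#' @export
pooled_cov <- function(studies) {
  if (inherits(studies, "study_cov")) studies <- list(studies)
  if (!length(studies)) stop("at least one study required")
  per_study <- vapply(studies, function(s) {
    if (is.numeric(s)) s <- study_cov("study", s)
    mean(s$condition_values)
  }, numeric(1))
  mean(per_study)
}

#' Convert a coefficient of variation to a standard deviation
#'
#' @param cov dimensionless coefficient of variation (> 0).
#' @param nominal nominal parameter value (> 0), in target units.
#' @return `cov * nominal`, in the nominal's units.
#' @export
cov_to_sd <- function(cov, nominal) {
  if (!is.finite(cov) || cov <= 0) stop("cov must be positive")
  if (!is.finite(nominal) || nominal <= 0) stop("nominal must be positive")
  cov * nominal
}

.z75 <- qnorm(0.75)  # 0.6744898...

#' Fit a normal distribution to a median and quartiles
#'
#' Least-squares fit of (mean, sd) to the three quantile equations
#' `q_p = mean + sd * z_p` at p = 0.25, 0.5, 0.75. For symmetric triples this
#' reduces to `mean = median`, `sd = (q75 - q25) / (2 * z_0.75)` and the
#' fitted quartiles reproduce the inputs exactly.
#'
#' @param median,q25,q75 sample median and quartiles, `q25 < median < q75`.
#' @return Named vector `c(mean, sd)`.
#' @export
normal_from_quartiles <- function(median, q25, q75) {
  if (!(q25 < median && median < q75)) stop("require q25 < median < q75")
  z <- c(-.z75, 0, .z75)
  q <- c(q25, median, q75)
  # closed-form LS for q ~ mean + sd * z (z is centred, so terms decouple)
  m <- mean(q)
  s <- sum(z * q) / sum(z^2)
  c(mean = m, sd = s)
}

#' Fit a lognormal distribution to a median and quartiles
#'
#' Fits on the log scale: `log_mean = log(median)`,
#' `log_sd = (log(q75) - log(q25)) / (2 * z_0.75)`; the fitted distribution's
#' median equals the input median exactly and log-symmetric quartiles
#' round-trip.
#'
#' @param median,q25,q75 positive quantiles, `q25 < median < q75`.
#' @return Named vector `c(log_mean, log_sd)`.
#' @export
lognormal_from_quartiles <- function(median, q25, q75) {
  if (!(q25 > 0)) stop("quantiles must be positive")
  if (!(q25 < median && median < q75)) stop("require q25 < median < q75")
  c(log_mean = log(median),
    log_sd = (log(q75) - log(q25)) / (2 * .z75))
}

#' Define one varied parameter
#'
#' @param name identifier.
#' @param family `"normal"` (params `mean`, `sd`), `"uniform"` (`low`,
#'   `high`) or `"lognormal"` (`log_mean`, `log_sd`).
#' @param params named numeric vector of family parameters.
#' @param units unit string.
#' @param nominal cut-point value; must sit inside the support and, for the
#'   shared-nominal design, at the centre quadrature node (the mean for
#'   normal/uniform, the median for lognormal).
#' @param coupling optional group label for jointly varied parameters.
#' @param partner optional description of a comonotone partner marginal
#'   (list with `name`, `family`, `params`) varied together with this one.
#' @return A `parameter_spec`.
#' @export
parameter_spec <- function(name, family = c("normal", "uniform", "lognormal"),
                           params, units = "", nominal = NULL,
                           coupling = NULL, partner = NULL) {
  family <- match.arg(family)
  params <- unlist(params)
  need <- switch(family, normal = c("mean", "sd"), uniform = c("low", "high"),
                 lognormal = c("log_mean", "log_sd"))
  if (!all(need %in% names(params)))
    stop(name, ": ", family, " family needs params ", paste(need, collapse = ", "))
  params <- params[need]
  switch(family,
    normal = if (params["sd"] <= 0) stop(name, ": sd must be > 0"),
    uniform = if (params["high"] <= params["low"])
      stop(name, ": high must exceed low"),
    lognormal = if (params["log_sd"] <= 0) stop(name, ": log_sd must be > 0"))
  if (is.null(nominal))
    nominal <- switch(family,
      normal = unname(params["mean"]),
      uniform = unname((params["low"] + params["high"]) / 2),
      lognormal = exp(unname(params["log_mean"])))
  sup <- parameter_support(family, params)
  if (nominal < sup[1] || nominal > sup[2])
    stop(name, ": nominal outside support")
  if (!is.null(partner)) partner$params <- unlist(partner$params)
  structure(list(name = name, family = family, params = params, units = units,
                 nominal = nominal, coupling = coupling, partner = partner),
            class = "parameter_spec")
}

parameter_support <- function(family, params) {
  switch(family,
    normal = c(-Inf, Inf),
    uniform = unname(c(params["low"], params["high"])),
    lognormal = c(0, Inf))
}

#' Quantile, density sampling helpers for a parameter
#'
#' @param spec a `parameter_spec`.
#' @param p probabilities / `n` sample count.
#' @return Numeric vector in the parameter's units.
#' @export
parameter_quantile <- function(spec, p) {
  switch(spec$family,
    normal = qnorm(p, spec$params["mean"], spec$params["sd"]),
    uniform = spec$params["low"] + p * diff(spec$params[c("low", "high")]),
    lognormal = qlnorm(p, spec$params["log_mean"], spec$params["log_sd"]))
}

#' @rdname parameter_quantile
#' @param n number of draws (uses the current RNG state).
#' @export
parameter_sample <- function(spec, n) {
  switch(spec$family,
    normal = rnorm(n, spec$params["mean"], spec$params["sd"]),
    uniform = runif(n, spec$params["low"], spec$params["high"]),
    lognormal = rlnorm(n, spec$params["log_mean"], spec$params["log_sd"]))
}

#' Default configuration for the seven varied parameters
#'
#' Two spinal-alignment PC scores (standard normal in score-SD units), neck
#' neural delay (normal, 20 ms nominal, SD 3.16 ms from the pooled
#' coefficient of variation; the lumbar delay tracks it at the 25:20 nominal
#' ratio), muscle PCSA scale (normal, mean 1, SD 0.19), adipose and passive
#' muscle tissue stiffness scales (uniform on 0.5 to 1.5; between-study
#' ranges), and skin stiffness mu across Langer's lines (lognormal
#' log-mean -1.45, log-sd 0.45, used for the quadrature integral) coupled
#' comonotonically with the along-lines mu (normal, 0.1, 0.028).
#'
#' @return A named list of per-parameter config entries.
#' @export
default_parameter_config <- function() {
  list(
    spine_pc1 = list(family = "normal", params = c(mean = 0, sd = 1),
                     units = "score SD"),
    spine_pc2 = list(family = "normal", params = c(mean = 0, sd = 1),
                     units = "score SD"),
    neural_delay = list(family = "normal", params = c(mean = 20, sd = 3.16),
                        units = "ms"),
    muscle_pcsa = list(family = "normal", params = c(mean = 1, sd = 0.19),
                       units = "scale"),
    adipose_props = list(family = "uniform", params = c(low = 0.5, high = 1.5),
                         units = "scale"),
    muscle_props = list(family = "uniform", params = c(low = 0.5, high = 1.5),
                        units = "scale"),
    skin_mu = list(family = "lognormal",
                   params = c(log_mean = -1.45, log_sd = 0.45),
                   units = "strain", coupling = "skin",
                   partner = list(name = "skin_mu_along", family = "normal",
                                  params = c(mean = 0.1, sd = 0.028))))
}

#' Build the seven-parameter set from a configuration
#'
#' @param config named list as returned by [default_parameter_config()]; the
#'   seven entries `spine_pc1`, `spine_pc2`, `neural_delay`, `muscle_pcsa`,
#'   `adipose_props`, `muscle_props`, `skin_mu` are all required.
#' @return A `parameter_set`: list of seven [parameter_spec()] objects.
#' @export
build_parameter_set <- function(config = default_parameter_config()) {
  wanted <- c("spine_pc1", "spine_pc2", "neural_delay", "muscle_pcsa",
              "adipose_props", "muscle_props", "skin_mu")
  if (!setequal(names(config), wanted))
    stop("config must contain exactly: ", paste(wanted, collapse = ", "))
  specs <- lapply(wanted, function(nm) {
    e <- config[[nm]]
    parameter_spec(nm, e$family, e$params,
                   units = e$units %||% "", nominal = e$nominal,
                   coupling = e$coupling, partner = e$partner)
  })
  names(specs) <- wanted
  structure(specs, class = "parameter_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d parameters\n", length(x)))
  for (s in x)
    cat(sprintf("  %-14s %-9s nominal %.4g %s%s\n", s$name, s$family,
                s$nominal, s$units,
                if (!is.null(s$coupling)) paste0(" [", s$coupling, "]") else ""))
  invisible(x)
}

#' Comonotone partner value for a coupled parameter
#'
#' Maps a value of the primary marginal to its jointly varied partner through
#' the shared uniform score: `partner_quantile(primary_cdf(value))`.
#'
#' @param spec a `parameter_spec` with a `partner` entry.
#' @param value value(s) of the primary parameter.
#' @return Partner parameter value(s).
#' @export
coupled_partner_value <- function(spec, value) {
  if (is.null(spec$partner)) stop(spec$name, " has no coupled partner")
  u <- switch(spec$family,
    normal = pnorm(value, spec$params["mean"], spec$params["sd"]),
    uniform = (value - spec$params["low"]) /
      diff(spec$params[c("low", "high")]),
    lognormal = plnorm(value, spec$params["log_mean"], spec$params["log_sd"]))
  p <- spec$partner
  switch(p$family,
    normal = qnorm(u, p$params["mean"], p$params["sd"]),
    lognormal = qlnorm(u, p$params["log_mean"], p$params["log_sd"]),
    stop("unsupported partner family: ", p$family))
}

#' Read / write a parameter set as JSON
#'
#' @param params a `parameter_set`.
#' @param path file path.
#' @export
write_parameter_set <- function(params, path) {
  obj <- lapply(params, function(s) {
    partner <- s$partner
    if (!is.null(partner)) partner$params <- as.list(partner$params)
    list(family = s$family, params = as.list(s$params), units = s$units,
         nominal = s$nominal, coupling = s$coupling, partner = partner)
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_parameter_set(obj)
}
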