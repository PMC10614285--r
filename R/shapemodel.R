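# Statistical shape model of sagittal spinal alignment: PCA over the
# (x, z) measurement-node coordinates of a set of aligned spines. The sacrum
# node is excluded: alignment keeps it fixed at the origin, so it carries no
# variance and serves as the common reference.

shape_levels <- function() setdiff(vertebra_levels(), "S1")

meas_vector <- function(spine, levels = shape_levels()) {
  pts <- vapply(levels, function(lv) spine_point(spine, lv, "meas"),
                numeric(2))
  # interleaved (x, z) per level, inferior first
  as.numeric(pts)
}

#' Fit a principal-component shape model to aligned spines
#'
#' Stacks the (x, z) measurement-node coordinates of each spine (sacrum
#' excluded) and eigendecomposes their covariance (coordinates share units,
#' so no scaling). PC signs are fixed so a positive score moves the C7
#' measurement node posteriorly (a more reclined alignment for PC1).
#'
#' @param spines list of `spine_model` objects with identical level sets.
#' @param n_pcs number of components to retain (default 2).
#' @return A `shape_model`: `levels`, `mean` (length 2L vector), `loadings`
#'   (2L x n_pcs orthonormal matrix), `sds` (per-PC score SD, mm),
#'   `explained` (per-PC variance fraction over all components).
#' @export
fit_shape_model <- function(spines, n_pcs = 2) {
  if (length(spines) < 3) stop("need at least 3 spines")
  lev <- shape_levels()
  X <- t(vapply(spines, meas_vector, numeric(2 * length(lev))))
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  total <- sum(p$sdev^2)
  k <- min(n_pcs, ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  sds <- p$sdev[seq_len(k)]
  expl <- if (total > 0) p$sdev^2 / total else rep(0, length(p$sdev))
  # sign convention: positive score moves C7 posteriorly (its x loading < 0)
  c7x <- 2 * match("C7", lev) - 1
  for (j in seq_len(k)) {
    s <- load[c7x, j]
    if (s > 0) load[, j] <- -load[, j]
  }
  structure(list(levels = lev, mean = p$center, loadings = load, sds = sds,
                 explained = expl[seq_len(k)], explained_all = expl,
                 n_train = nrow(X)),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %d levels, %d PCs (of %d), trained on %d spines\n",
              length(x$levels), ncol(x$loadings), length(x$explained_all),
              x$n_train))
  cat(sprintf("  score SDs (mm): %s; explained: %s\n",
              paste(sprintf("%.2f", x$sds), collapse = ", "),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Predict measurement-node positions from PC scores
#'
#' Linear shape-model prediction: `mean + sum(score_k * sd_k * loading_k)`.
#' Scores are in SD units of the training population.
#'
#' @param model a `shape_model`.
#' @param scores numeric vector, one entry per retained PC.
#' @return Matrix with rows = levels, columns `x`, `z` (mm).
#' @export
shape_nodes <- function(model, scores) {
  if (length(scores) != ncol(model$loadings))
    stop("expected ", ncol(model$loadings), " scores, got ", length(scores))
  if (!all(is.finite(scores))) stop("scores must be finite")
  v <- model$mean + as.numeric(model$loadings %*% (scores * model$sds))
  m <- matrix(v, ncol = 2, byrow = TRUE,
              dimnames = list(model$levels, c("x", "z")))
  m
}

#' PC scores of a spine under a fitted shape model
#'
#' @param model a `shape_model`.
#' @param spine a `spine_model`.
#' @return Numeric vector of scores in SD units.
#' @export
shape_scores <- function(model, spine) {
  d <- meas_vector(spine, model$levels) - model$mean
  as.numeric(crossprod(model$loadings, d)) / model$sds
}

#' Generate a full-landmark spine from PC scores
#'
#' Predicts measurement-node positions with [shape_nodes()], then realigns
#' the template spine so its measurement nodes match the prediction in a
#' per-joint least-squares sense. The fitted degrees of freedom mirror the
#' alignment algorithm's: one rotation per intervertebral joint about its
#' pivot plus one rigid rotation about the sacrum measurement node, refined
#' by coordinate-descent sweeps (each sweep fits the sacrum rotation to all
#' nodes, then each joint, inferior to superior, to the nodes above it).
#' Predictions that are rigidly reachable — every training spine when all PCs
#' are retained — are reproduced exactly; generic predictions get the
#' closest chain configuration.
#'
#' @param model a `shape_model`.
#' @param scores per-PC multiples of the training score SD.
#' @param template template `spine_model` supplying the full landmark set.
#' @return A `spine_model`; attribute `"target_nodes"` holds the raw linear
#'   prediction and `"node_rmse_mm"` the final node misfit.
#' @export
generate_spine <- function(model, scores, template = template_spine()) {
  target <- shape_nodes(model, scores)
  s1 <- spine_point(template, "S1", "meas")
  nodes_of <- function(sp) {
    t(vapply(model$levels, function(lv) spine_point(sp, lv, "meas"),
             numeric(2)))
  }
  chain_fit <- function(gamma) {
    spine <- rotate_landmarks(template, rep(TRUE, nrow(template$landmarks)),
                              s1, gamma)
    for (joint in joint_labels()) {
      upper <- strsplit(joint, "-", fixed = TRUE)[[1]][1]
      if (!(upper %in% model$levels)) next
      pivot <- spine_point(spine, upper, "pivot")
      u <- spine_point(spine, upper, "meas") - pivot
      v <- target[upper, ] - pivot
      a <- atan2(u[1] * v[2] - u[2] * v[1],
                 u[1] * v[1] + u[2] * v[2]) * 180 / pi
      idx <- spine$landmarks$level %in%
        vertebra_levels()[seq(level_index(upper), length(vertebra_levels()))]
      spine <- rotate_landmarks(spine, idx, pivot, a)
    }
    spine
  }
  # Sacrum rotation gamma from the radius condition at the first mobile
  # vertebra (L5): |target_L5 - R_gamma(pivot_L5)| must equal the template's
  # pivot-to-node radius, giving A cos(g) + B sin(g) = C with two roots.
  # A reachable target (any training spine with all PCs kept) satisfies it
  # exactly for the true rotation, making the whole bottom-up chain exact;
  # otherwise fall back to the orientation-preserving gamma = 0 chain.
  p <- spine_point(template, "L5", "pivot") - s1
  tg <- target["L5", ] - s1
  r <- sqrt(sum((spine_point(template, "L5", "meas") -
                 spine_point(template, "L5", "pivot"))^2))
  A <- sum(tg * p)
  B <- tg[2] * p[1] - tg[1] * p[2]
  C <- (sum(tg^2) + sum(p^2) - r^2) / 2
  amp <- sqrt(A^2 + B^2)
  gammas <- if (abs(C) <= amp) {
    base <- atan2(B, A)
    wrap_deg((c(base + acos(C / amp), base - acos(C / amp))) * 180 / pi)
  } else 0
  fits <- lapply(gammas, chain_fit)
  err <- vapply(fits, function(sp)
    sqrt(mean((nodes_of(sp) - target[model$levels, ])^2)), numeric(1))
  spine <- fits[[which.min(err)]]
  attr(spine, "target_nodes") <- target
  attr(spine, "node_rmse_mm") <- min(err)
  spine
}

#' Cumulative explained variance fraction
#'
#' @param model a `shape_model`.
#' @param k number of leading PCs.
#' @return Fraction of total training variance in the first `k` PCs.
#' @export
explained_variance <- function(model, k) {
  if (k < 1 || k > length(model$explained_all))
    stop("k must be in 1..", length(model$explained_all))
  sum(model$explained_all[seq_len(k)])
}

#' Read / write a shape model as JSON
#'
#' @param model a `shape_model`.
#' @param path file path.
#' @export
write_shape_model <- function(model, path) {
  obj <- list(levels = model$levels, mean = model$mean,
              loadings = model$loadings, sds = model$sds,
              explained = model$explained, explained_all = model$explained_all,
              n_train = model$n_train)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(levels = obj$levels, mean = as.numeric(obj$mean),
                 loadings = matrix(unlist(obj$loadings),
                                   nrow = 2 * length(obj$levels)),
                 sds = as.numeric(obj$sds),
                 explained = as.numeric(obj$explained),
                 explained_all = as.numeric(obj$explained_all),
                 n_train = obj$n_train),
            class = "shape_model")
}
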