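# Comparison metrics for displacement time histories, in the vehicle frame
# (x forward positive, z downward positive): the first forward-displacement
# peak of head and T1 and the average vertical displacement of each.

body_column <- function(body, axis) {
  body <- match.arg(tolower(body), c("head", "t1"))
  paste0(body, "_", axis, "_mm")
}

#' First forward-displacement peak
#'
#' Returns the first interior local maximum of the x-displacement inside the
#' analysis window whose topographic prominence is at least
#' `prominence_mm`; if no interior peak qualifies, the window maximum is
#' returned with `flag = "no_interior_peak"`.
#'
#' @param resp a `response_record` (data frame with `time_s` and
#'   displacement columns).
#' @param body `"head"` or `"t1"`.
#' @param window analysis window, s (default `c(0.1, 0.8)`).
#' @param prominence_mm minimum peak prominence, mm.
#' @return List `value_mm`, `time_s`, `flag` (`NA` if a true peak was
#'   found).
#' @export
peak_forward <- function(resp, body = "head", window = c(0.1, 0.8),
                         prominence_mm = 1) {
  t <- resp$time_s
  x <- resp[[body_column(body, "x")]]
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) < 2) stop("empty analysis window")
  lo <- idx[1]; hi <- idx[length(idx)]
  for (i in seq(lo + 1, hi - 1)) {
    if (!(x[i] >= x[i - 1] && x[i] > x[i + 1])) next
    minL <- x[i]
    for (j in seq(i - 1, lo)) {
      if (x[j] > x[i]) break
      minL <- min(minL, x[j])
    }
    minR <- x[i]
    for (j in seq(i + 1, hi)) {
      if (x[j] > x[i]) break
      minR <- min(minR, x[j])
    }
    if (x[i] - max(minL, minR) >= prominence_mm)
      return(list(value_mm = x[i], time_s = t[i], flag = NA_character_))
  }
  k <- idx[which.max(x[idx])]
  list(value_mm = x[k], time_s = t[k], flag = "no_interior_peak")
}

#' Average vertical displacement over a window
#'
#' Time average (trapezoidal integral divided by window length) of the
#' z-displacement, downward positive, over `window` (default the interval
#' from maneuver onset to `t_max`).
#'
#' @param resp a `response_record`.
#' @param body `"head"` or `"t1"`.
#' @param window averaging window, s; defaults to `c(0, max(time))`.
#' @return Mean vertical displacement, mm.
#' @export
average_vertical <- function(resp, body = "head", window = NULL) {
  t <- resp$time_s
  z <- resp[[body_column(body, "z")]]
  if (is.null(window)) window <- c(0, max(t))
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) < 2) stop("empty averaging window")
  pracma::trapz(t[idx], z[idx]) / (t[idx[length(idx)]] - t[idx[1]])
}

#' Metric table for a batch of runs
#'
#' @param runs named list of `response_record` objects (names = run ids).
#' @param peak_window window for [peak_forward()], s.
#' @param avg_window window for [average_vertical()], s (`NULL` = full
#'   record).
#' @param prominence_mm peak prominence threshold, mm.
#' @return Data frame ordered by `run_id` with the four metrics, the peak
#'   times and a `flags` column.
#' @export
metric_table <- function(runs, peak_window = c(0.1, 0.8), avg_window = NULL,
                         prominence_mm = 1) {
  if (!length(runs))
    return(data.frame(run_id = character(), head_peak_fwd_mm = numeric(),
                      head_peak_time_s = numeric(), t1_peak_fwd_mm = numeric(),
                      t1_peak_time_s = numeric(), head_avg_vert_mm = numeric(),
                      t1_avg_vert_mm = numeric(), flags = character()))
  ids <- names(runs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("runs must be a named list (names are run ids)")
  if (anyDuplicated(ids)) stop("duplicate run_id: ",
                               ids[duplicated(ids)][1])
  ord <- order(ids)
  rows <- lapply(ord, function(i) {
    r <- runs[[i]]
    ph <- peak_forward(r, "head", peak_window, prominence_mm)
    pt <- peak_forward(r, "t1", peak_window, prominence_mm)
    flags <- paste(stats::na.omit(c(
      if (!is.na(ph$flag)) paste0("head:", ph$flag),
      if (!is.na(pt$flag)) paste0("t1:", pt$flag))), collapse = ";")
    data.frame(run_id = ids[i],
               head_peak_fwd_mm = ph$value_mm, head_peak_time_s = ph$time_s,
               t1_peak_fwd_mm = pt$value_mm, t1_peak_time_s = pt$time_s,
               head_avg_vert_mm = average_vertical(r, "head", avg_window),
               t1_avg_vert_mm = average_vertical(r, "t1", avg_window),
               flags = flags)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Influential parameters above a sensitivity threshold
#'
#' Parameters whose primary sensitivity index strictly exceeds the threshold
#' (default 1/7, equal shares among seven parameters), sorted by descending
#' index.
#'
#' @param sens a `sensitivity_result`.
#' @param threshold sensitivity threshold.
#' @return Character vector of parameter names.
#' @export
influential <- function(sens, threshold = 1 / 7) {
  keep <- sens$S > threshold
  sens$parameter[keep][order(sens$S[keep], decreasing = TRUE)]
}
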