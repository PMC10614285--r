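# End-to-end study replica: parameter distributions -> spine population and
# shape model -> shared-nominal quadrature design -> surrogate runs ->
# metrics -> primary sensitivity indices, with seeded reproducibility and a
# run manifest of file digests.

#' Generate a synthetic population of spinal measurements
#'
#' Draws `n` subjects' lumbar lordosis, thoracic kyphosis, cervical lordosis
#' and C7-sacrum horizontal offset from independent normal distributions.
#' Defaults are seated-cohort values: angle means (SDs) of 0.9 (9.2), 20.5
#' (8.0) and 1.3 (8.8) degrees; the offset is centred on the template
#' spine's own offset with a 20 mm SD.
#'
#' @param n number of subjects (>= 3).
#' @param seed RNG seed.
#' @param means_sds named list of `c(mean, sd)` pairs for
#'   `lumbar_lordosis_deg`, `thoracic_kyphosis_deg`, `cervical_lordosis_deg`,
#'   `c7_sacrum_dx_mm`.
#' @return Data frame with `subject_id` and the four measurement columns.
#' @export
generate_fixture_population <- function(n = 36, seed = 1,
                                        means_sds = NULL) {
  stopifnot(n >= 3)
  if (is.null(means_sds)) {
    dx0 <- measure_spine(template_spine())$c7_sacrum_dx_mm
    means_sds <- list(lumbar_lordosis_deg = c(0.9, 9.2),
                      thoracic_kyphosis_deg = c(20.5, 8.0),
                      cervical_lordosis_deg = c(1.3, 8.8),
                      c7_sacrum_dx_mm = c(dx0, 20))
  }
  set.seed(seed)
  cols <- lapply(means_sds, function(ms) rnorm(n, ms[1], ms[2]))
  data.frame(subject_id = sprintf("subj%02d", seq_len(n)), cols)
}

#' Read / write a measurements CSV
#'
#' Columns: `subject_id`, `lumbar_lordosis_deg`, `thoracic_kyphosis_deg`,
#' `cervical_lordosis_deg`, `c7_sacrum_dx_mm`.
#'
#' @param path file path.
#' @export
read_measurements_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "lumbar_lordosis_deg", "thoracic_kyphosis_deg",
            "cervical_lordosis_deg", "c7_sacrum_dx_mm")
  if (!all(need %in% names(df)))
    stop("measurements CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_measurements_csv
#' @param measurements data frame as from [generate_fixture_population()].
#' @export
write_measurements_csv <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a template spine to every row of a measurements table
#'
#' @param measurements data frame of per-subject measurements.
#' @param template template `spine_model`.
#' @param tol per-segment tolerance, degrees.
#' @return Named list of aligned `spine_model`s.
#' @export
align_population <- function(measurements, template = template_spine(),
                             tol = 0.01) {
  out <- lapply(seq_len(nrow(measurements)), function(i) {
    r <- measurements[i, ]
    align_spine(template,
                spine_measurements(r$lumbar_lordosis_deg,
                                   r$thoracic_kyphosis_deg,
                                   r$cervical_lordosis_deg,
                                   r$c7_sacrum_dx_mm),
                tol = tol)
  })
  names(out) <- measurements$subject_id
  out
}

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed root seed; stage seeds are derived from it.
#' @param n_subjects synthetic cohort size.
#' @param n_gauss_points Gauss points per parameter (odd, >= 3).
#' @param n_pcs retained shape-model components.
#' @param parameter_config see [default_parameter_config()].
#' @param pulse a [braking_pulse()].
#' @param surrogate surrogate constants, see [surrogate_config()].
#' @param tol_deg spine alignment tolerance, degrees.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("kinesens"), seed = 1,
                            n_subjects = 36, n_gauss_points = 5, n_pcs = 2,
                            parameter_config = default_parameter_config(),
                            pulse = braking_pulse(),
                            surrogate = surrogate_config(),
                            tol_deg = 0.01) {
  stopifnot(n_gauss_points >= 2, seed >= 0, n_subjects >= 3)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = n_subjects, n_gauss_points = n_gauss_points,
                 n_pcs = n_pcs, parameter_config = parameter_config,
                 pulse = pulse, surrogate = surrogate, tol_deg = tol_deg),
            class = "pipeline_config")
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full sensitivity pipeline
#'
#' Stages, in order: build the seven-parameter set; generate the synthetic
#' measurement cohort; align the template spine to every subject; fit the
#' PCA shape model; build the shared-nominal quadrature design; simulate the
#' surrogate for every design run; compute the four kinematic metrics; and
#' compute per-metric M-DRM primary sensitivity indices. All file outputs go
#' under `cfg$out_dir`; a manifest of digests makes reruns checkable.
#'
#' @param cfg a [pipeline_config()].
#' @return A `run_manifest` list: `config_digest`, per-file `digests`,
#'   `seed`, `timestamp`, plus in-memory `results` (design, metrics,
#'   sensitivity per metric).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)

  stage_log("params", "building parameter set")
  params <- build_parameter_set(cfg$parameter_config)
  write_parameter_set(params, out("paramset.json"))

  stage_log("population", sprintf("%d synthetic subjects", cfg$n_subjects))
  meas <- generate_fixture_population(cfg$n_subjects, seed = cfg$seed)
  write_measurements_csv(meas, out("measurements.csv"))

  stage_log("spine", "aligning template to cohort")
  template <- template_spine()
  write_spine_csv(template, out("template_spine.csv"))
  spines <- align_population(meas, template, tol = cfg$tol_deg)

  stage_log("shapemodel", sprintf("PCA, %d PCs", cfg$n_pcs))
  shape <- fit_shape_model(spines, n_pcs = cfg$n_pcs)
  write_shape_model(shape, out("shape_model.json"))

  stage_log("design", sprintf("%d parameters x %d points",
                              length(params), cfg$n_gauss_points))
  design <- build_design(params, n_points = cfg$n_gauss_points)
  write_design_csv(design, out("design.csv"))

  stage_log("simulate", sprintf("%d surrogate runs", nrow(design$runs)))
  dir.create(out("runs"), showWarnings = FALSE)
  run_list <- list()
  for (i in seq_len(nrow(design$runs))) {
    rid <- design$runs$run_id[i]
    x <- as.numeric(design$runs[i, names(design$rules)])
    names(x) <- names(design$rules)
    st <- occupant_from_parameters(x, shape, cfg$surrogate, params)
    rec <- simulate_occupant(st, cfg$pulse)
    utils::write.csv(format(rec, digits = 10), out("runs", paste0(rid, ".csv")),
                     row.names = FALSE, quote = FALSE)
    run_list[[rid]] <- rec
  }

  stage_log("metrics", "4 metrics per run")
  mt <- metric_table(run_list, peak_window = cfg$surrogate$peak_window_s,
                     avg_window = c(0, cfg$pulse$duration),
                     prominence_mm = cfg$surrogate$peak_prominence_mm)
  write.csv(mt, out("metrics.csv"), row.names = FALSE, quote = FALSE)

  stage_log("sensitivity", "M-DRM indices per metric")
  metric_cols <- c("head_peak_fwd_mm", "t1_peak_fwd_mm",
                   "head_avg_vert_mm", "t1_avg_vert_mm")
  sens <- lapply(metric_cols, function(mc) {
    mom <- mdrm_moments(setNames(mt[[mc]], mt$run_id), design)
    sensitivity_indices(mom, metric = mc)
  })
  names(sens) <- metric_cols
  sens_json <- lapply(sens, function(s)
    list(h0 = attr(s, "h0"),
         parameters = setNames(
           lapply(seq_len(nrow(s)), function(i)
             list(rho = s$rho[i], theta = s$theta[i], S = s$S[i])),
           s$parameter)))
  jsonlite::write_json(sens_json, out("sensitivity.json"),
                       digits = NA, auto_unbox = TRUE)
  writeLines(sensitivity_report(sens), out("report.txt"))

  files <- c("paramset.json", "measurements.csv", "template_spine.csv",
             "shape_model.json", "design.csv", "metrics.csv",
             "sensitivity.json", "report.txt")
  cfg_file <- out("config.json")
  # the digest covers the scientific configuration, not the output location
  jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")],
                       cfg_file, digits = NA, auto_unbox = TRUE, force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("kinesens")),
    seed = cfg$seed,
    config_digest = unname(tools::md5sum(cfg_file)),
    digests = setNames(unname(tools::md5sum(out(files))), files),
    timestamp = format(Sys.time(), tz = "UTC"),
    results = list(design = design, metrics = mt, sensitivity = sens,
                   shape = shape, params = params))
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, %d outputs, %s\n", x$seed,
              length(x$digests), x$timestamp))
  invisible(x)
}

#' Plain-text sensitivity report
#'
#' Per metric, a bar table of the primary sensitivity index of each
#' parameter, in the canonical parameter order.
#'
#' @param sens named list of `sensitivity_result`s.
#' @return Character vector of report lines.
#' @export
sensitivity_report <- function(sens) {
  lines <- character()
  for (mc in names(sens)) {
    s <- sens[[mc]]
    lines <- c(lines, sprintf("%s (h0 = %.2f)", mc, attr(s, "h0")))
    for (i in seq_len(nrow(s))) {
      bar <- strrep("#", round(40 * s$S[i]))
      lines <- c(lines, sprintf("  %-14s %6.1f%% %s", s$parameter[i],
                                100 * s$S[i], bar))
    }
    lines <- c(lines, "")
  }
  lines
}
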