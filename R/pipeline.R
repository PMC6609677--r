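# End-to-end orchestration: configuration, phantom simulation, per-session
# quantification (kinetics + static SUV), and the repeatability /
# sample-size reports.

#' Pipeline configuration
#'
#' Validated bundle of every tunable the pipeline stages use.  Defaults
#' follow the analysis the package implements: fixed SUV threshold 6,
#' 30%-of-max threshold, two-sided alpha 5%, power 95%, relative changes
#' -20/-30/-50%.
#'
#' @param fixed_suv_threshold fixed SUV segmentation threshold (`> 0`).
#' @param percent_max percent-of-max segmentation threshold, in `(0, 100)`.
#' @param static_window_s `c(t0, t1)` window (s) averaged into the static
#'   volume for SUV analysis.
#' @param n_clusters k-means cluster count for IDIF extraction (`>= 2`).
#' @param fit_vb fit a blood volume fraction in the kinetic model.
#' @param weights fit weighting, `"uniform"` or `"duration"`.
#' @param frames dynamic frame schedule (`start`/`duration`, s).
#' @param noise_cov phantom fractional noise SD.
#' @param alpha,power,changes statistics options (see
#'   [sample_size_table()]).
#' @param seed integer seed for all simulation randomness.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(fixed_suv_threshold = 6, percent_max = 30,
                            static_window_s = c(180, 360), n_clusters = 3,
                            fit_vb = FALSE, weights = "uniform",
                            frames = default_frame_schedule(),
                            noise_cov = 0.05, alpha = 0.05, power = 0.95,
                            changes = c(-0.2, -0.3, -0.5), seed = 1) {
  if (!is.numeric(fixed_suv_threshold) || fixed_suv_threshold <= 0)
    .stop_validation("config: fixed_suv_threshold must be > 0")
  if (!is.numeric(percent_max) || percent_max <= 0 || percent_max >= 100)
    .stop_validation("config: percent_max must be in (0, 100)")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    .stop_validation("config: alpha and power must be in (0, 1)")
  if (noise_cov < 0) .stop_validation("config: noise_cov must be >= 0")
  if (n_clusters < 2) .stop_validation("config: n_clusters must be >= 2")
  frames <- as.data.frame(frames)[c("start", "duration")]
  structure(list(fixed_suv_threshold = fixed_suv_threshold,
                 percent_max = percent_max, static_window_s = static_window_s,
                 n_clusters = n_clusters, fit_vb = fit_vb, weights = weights,
                 frames = frames, noise_cov = noise_cov, alpha = alpha,
                 power = power, changes = changes, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  segmentation: fixed SUV %g / %g%% of max; static window %g-%g s\n",
              x$fixed_suv_threshold, x$percent_max, x$static_window_s[1],
              x$static_window_s[2]))
  cat(sprintf("  kinetics: %d IDIF clusters, vb %s, %s weights\n",
              x$n_clusters, if (x$fit_vb) "fitted" else "fixed 0", x$weights))
  cat(sprintf("  statistics: alpha %g, power %g, changes %s; seed %d\n",
              x$alpha, x$power, paste(x$changes, collapse = "/"), x$seed))
  invisible(x)
}

.log_step <- function(config, what, ...) {
  message(sprintf("[rbflow %s | seed %d | cfg %s] %s",
                  as.character(utils::packageVersion("rbflow")), config$seed,
                  .config_hash(config), sprintf(what, ...)))
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config)[order(names(unclass(config)))], tf)
  # md5 over the serialised, name-sorted fields
  substr(unname(tools::md5sum(tf)), 1, 8)
}

#' Simulate phantom sessions to disk
#'
#' Generates one dynamic phantom per session label and writes each as
#' NIfTI + JSON truth record + input CSV under `out_dir` (prefix
#' `phantom_<session>`).  Reproducible: the same config and seed give
#' byte-identical truth records.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param sessions session labels (default `c("test", "retest")`); each
#'   session uses seed `config$seed + index - 1`.
#' @return Named list of path vectors, one element per session.
#' @export
pipeline_simulate <- function(config, out_dir, sessions = c("test", "retest")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log_step(config, "simulating %d phantom session(s) -> %s", length(sessions), out_dir)
  out <- lapply(seq_along(sessions), function(i) {
    ph <- sim_phantom(frames = config$frames, noise_cov = config$noise_cov,
                      seed = config$seed + i - 1L)
    write_phantom(ph, file.path(out_dir, paste0("phantom_", sessions[i])))
  })
  names(out) <- sessions
  invisible(out)
}

#' Quantify one phantom session
#'
#' Runs the full per-session analysis chain on a phantom written by
#' [pipeline_simulate()]: extracts the image-derived input function by
#' cluster analysis, extracts the tumor time-activity curve over the tumor
#' mask, fits the one-tissue compartment model for K1, averages the frames
#' inside the static window and computes SUV metrics over a
#' percent-of-max VOI searched within the tumor mask.
#'
#' @param config a [pipeline_config()].
#' @param prefix phantom path prefix (as passed to [write_phantom()]).
#' @param patient_id,lesion_id,session labels for the output row.
#' @return One [paired_table]-schema row (plain data frame) with the fitted
#'   `k1` and the SUV metrics.
#' @export
pipeline_quantify <- function(config, prefix, patient_id = "phantom",
                              lesion_id = "1", session = "test") {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in paste0(prefix, c(".nii", "_regions.nii", "_truth.json", "_input.csv")))
    if (!file.exists(p)) .stop_validation("required input not found: %s", p)
  ph <- read_phantom(prefix)
  .log_step(config, "quantifying %s (%s)", prefix, session)
  idif <- extract_idif(ph$volume, ph$frames, n_clusters = config$n_clusters,
                       seed = config$seed)
  tumor <- ph$region_map == "tumor"
  if (!any(tumor)) .stop_compute("phantom has no tumor region")
  nt <- nrow(ph$frames)
  tumor_tac <- tac(ph$frames$start, ph$frames$duration,
                   colMeans(matrix(ph$volume, ncol = nt)[as.vector(tumor), , drop = FALSE]))
  fit <- onetc_fit(tumor_tac, idif, weights = config$weights,
                   fit_vb = config$fit_vb)
  w <- config$static_window_s
  mid <- .tac_mid(ph$frames)
  in_static <- mid >= w[1] & mid <= w[2]
  if (!any(in_static)) .stop_validation("static window %g-%g s covers no frame", w[1], w[2])
  static <- array(rowMeans(matrix(ph$volume, ncol = nt)[, in_static, drop = FALSE]),
                  dim(ph$volume)[1:3])
  voi <- segment_percent_max(static, config$percent_max, vox_mm = ph$vox_mm,
                             search = tumor)
  met <- suv_metrics(static, voi)
  data.frame(patient_id = patient_id, lesion_id = lesion_id, session = session,
             tumor_volume_cm3 = met$voi_volume_cm3,
             k1 = unname(coef(fit)["k1"]), suv_max = met$suv_max,
             suv_mean = met$suv_mean, suv_peak = met$suv_peak,
             voi_source = "psma_pct30")
}

#' Repeatability and sample-size report
#'
#' Runs [repeatability()] and [sample_size_table()] on a paired measurement
#' table and optionally writes the two reports as CSV and JSON.
#'
#' @param table a [paired_table] or a path readable by
#'   [read_measurements()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for
#'   `repeatability.{csv,json}` and `sample_size.{csv,json}`.
#' @return A list with elements `repeatability` and `sample_size`.
#' @export
#' @examples
#' pipeline_report(table1_fixture(), pipeline_config())
pipeline_report <- function(table, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(table)) table <- read_measurements(table)
  stopifnot(inherits(table, "paired_table"))
  if (nrow(table) == 0L) .stop_validation("report: empty measurement table")
  .log_step(config, "reporting on %d lesion pairs", n_lesions(table))
  rep_tab <- repeatability(table)
  ss_tab <- sample_size_table(table, changes = config$changes,
                              alpha = config$alpha, power = config$power)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(rep_tab),
                     file.path(out_dir, "repeatability.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ss_tab),
                     file.path(out_dir, "sample_size.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(as.data.frame(rep_tab), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
               file.path(out_dir, "repeatability.json"))
    writeLines(jsonlite::toJSON(as.data.frame(ss_tab), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
               file.path(out_dir, "sample_size.json"))
  }
  list(repeatability = rep_tab, sample_size = ss_tab)
}
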