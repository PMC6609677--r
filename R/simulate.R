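# Synthetic-data generators: paired log-normal measurement tables, arterial
# input functions, 4-D dynamic phantoms, and static SUV volumes.  Defaults
# mirror the test-retest study the statistics modules analyse (11 lesion
# pairs; log-scale spreads estimated from the bundled fixture).

#' Default dynamic frame schedule
#'
#' A short dynamic acquisition: 24 frames of 5 s followed by 8 frames of
#' 30 s (6 min total).  Used as the default by the phantom and input-function
#' generators; real protocols can be substituted by passing any
#' `start`/`duration` frame table.
#'
#' @return A data frame with columns `start`, `duration` (s).
#' @export
default_frame_schedule <- function() {
  data.frame(start = c(seq(0, 115, by = 5), seq(120, 330, by = 30)),
             duration = c(rep(5, 24), rep(30, 8)))
}

#' Simulate a paired log-normal test-retest table
#'
#' Lesion `i` of measure `m` has true log-level \eqn{\mu_m + b_i} with
#' \eqn{b_i \sim N(0, \sigma_b^2)}; each session value is
#' \eqn{\exp(\mu_m + b_i + e)} with \eqn{e \sim N(0, \sigma_w^2)} drawn
#' independently per session.  Measures are generated independently.  The
#' defaults reproduce the scale of the bundled fixture: 11 lesions,
#' between-lesion log-SD 0.75, and within-lesion log-SDs near the fixture's
#' per-measure estimates.
#'
#' @param n_lesions number of lesion pairs (`>= 1`).
#' @param mu_log log-scale grand mean; scalar or one value per measure
#'   (`k1`, `suv_max`, `suv_mean`, `suv_peak`).
#' @param sigma_between between-lesion log-scale SD (`>= 0`); scalar or
#'   per-measure.
#' @param sigma_within within-lesion (test-retest) log-scale SD (`>= 0`);
#'   scalar or per-measure.
#' @param seed RNG seed.
#' @return A [paired_table] with `2 * n_lesions` rows.
#' @export
#' @examples
#' sim_paired_table(n_lesions = 4, seed = 7)
sim_paired_table <- function(n_lesions = 11,
                             mu_log = log(c(0.17, 3.7, 2.2, 3.0)),
                             sigma_between = 0.75,
                             sigma_within = c(0.10, 0.16, 0.17, 0.19),
                             seed = 1) {
  if (n_lesions < 1) .stop_validation("sim_paired_table: need n_lesions >= 1")
  mu_log <- rep_len(mu_log, 4)
  sigma_between <- rep_len(sigma_between, 4)
  sigma_within <- rep_len(sigma_within, 4)
  if (any(sigma_between < 0) || any(sigma_within < 0))
    .stop_validation("sim_paired_table: sigmas must be >= 0")
  vals <- .with_seed(seed, {
    lapply(1:4, function(j) {
      b <- stats::rnorm(n_lesions, 0, sigma_between[j])
      e1 <- stats::rnorm(n_lesions, 0, sigma_within[j])
      e2 <- stats::rnorm(n_lesions, 0, sigma_within[j])
      cbind(test = exp(mu_log[j] + b + e1), retest = exp(mu_log[j] + b + e2))
    })
  })
  ids <- sprintf("S%03d", seq_len(n_lesions))
  rec <- data.frame(patient_id = rep(ids, each = 2), lesion_id = "1",
                    session = rep(c("test", "retest"), n_lesions))
  for (j in seq_along(.measures))
    rec[[.measures[j]]] <- as.vector(t(vals[[j]]))
  rec$voi_source <- "psma_suv6"
  paired_table(rec)
}

#' Simulate an arterial input function
#'
#' A gamma-variate first-pass bolus with a mono-exponential recirculation
#' tail, frame-averaged onto the given schedule:
#' \deqn{C_a(t) = A\,u^{\alpha} e^{\alpha(1-u)} +
#'       A f \,(1 - e^{-u}) e^{-(t - t_0)/\tau_r}, \quad
#'       u = (t - t_0)/(t_p - t_0),}
#' zero before the appearance time \eqn{t_0}.  The bolus peaks with
#' amplitude \eqn{A} at \eqn{t_p}; the tail has relative amplitude \eqn{f}
#' and decay constant \eqn{\tau_r}.  The curve is generated decay-corrected.
#'
#' @param frames frame schedule (`start`/`duration` data frame, s).
#' @param peak_time bolus peak time \eqn{t_p} (s); must fall inside the
#'   schedule.
#' @param peak_amplitude peak amplitude \eqn{A} (`>= 0`), arbitrary
#'   concentration units.
#' @param onset appearance time \eqn{t_0} (s).
#' @param shape gamma-variate shape \eqn{\alpha}.
#' @param tail_fraction recirculation amplitude as a fraction of the peak.
#' @param tail_tau recirculation decay constant \eqn{\tau_r} (s).
#' @param nsub quadrature sub-samples per frame for the frame average.
#' @return An [input_function] (`delay = dispersion_tau = 0`).
#' @export
sim_input_function <- function(frames = default_frame_schedule(),
                               peak_time = 25, peak_amplitude = 60,
                               onset = 5, shape = 3,
                               tail_fraction = 0.15, tail_tau = 120,
                               nsub = 50) {
  frames <- as.data.frame(frames)[c("start", "duration")]
  if (peak_amplitude < 0)
    .stop_validation("sim_input_function: negative peak amplitude")
  t_end <- max(frames$start + frames$duration)
  if (peak_time <= frames$start[1] || peak_time >= t_end || peak_time <= onset)
    .stop_validation("sim_input_function: peak time outside the frame schedule")
  f <- function(t) {
    u <- pmax(t - onset, 0) / (peak_time - onset)
    peak_amplitude * (u^shape * exp(shape * (1 - u)) +
                        tail_fraction * (1 - exp(-u)) *
                          exp(-pmax(t - onset, 0) / tail_tau))
  }
  avg <- vapply(seq_len(nrow(frames)), function(i) {
    s <- frames$start[i]; e <- s + frames$duration[i]
    tt <- seq(s, e, length.out = nsub + 1L)
    yy <- f(tt)
    sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2) / (e - s)
  }, numeric(1))
  input_function(tac(frames$start, frames$duration, avg))
}

#' Simulate a 4-D dynamic phantom with known kinetics
#'
#' Builds a voxel phantom whose blood-pool voxels carry the arterial input
#' curve and whose tissue voxels follow the one-tissue compartment forward
#' model of their region, plus independent Gaussian noise with a fractional
#' SD of `noise_cov` per voxel-frame (noise SD = `noise_cov` x the noiseless
#' value).  Tissue curves share the [onetc_forward()] code path with the
#' fitting module, so a zero-noise phantom is exactly consistent with it.
#'
#' @param shape voxel grid dimensions, length 3 (default `c(12, 12, 6)`).
#' @param vox_mm voxel size in mm, length 3 (default 4 mm isotropic).
#' @param frames frame schedule (`start`/`duration`, s).
#' @param regions named list mapping region labels to kinetics: either
#'   `list(blood = TRUE)` for blood-pool regions or `list(k1 = , k2 = )`
#'   (min^-1 units for `k2`).  Every label in `region_map` must appear.
#' @param region_map integer/character 3-D array of region labels, or `NULL`
#'   for the default geometry (a blood-pool slab at `x <= 3`, a tumor block
#'   in the centre, background elsewhere).
#' @param input an [input_function]; default [sim_input_function()] on
#'   `frames`.
#' @param noise_cov fractional noise SD per frame (`>= 0`).
#' @param seed RNG seed.
#' @return A list of class `"rb_phantom"`: `volume` (4-D array),
#'   `region_map` (character 3-D array), `input`, `frames`, and `truth`
#'   (all generating parameters).
#' @export
sim_phantom <- function(shape = c(12, 12, 6), vox_mm = c(4, 4, 4),
                        frames = default_frame_schedule(),
                        regions = list(blood = list(blood = TRUE),
                                       tumor = list(k1 = 0.36, k2 = 0.9),
                                       background = list(k1 = 0.05, k2 = 0.3)),
                        region_map = NULL, input = NULL,
                        noise_cov = 0.05, seed = 1) {
  stopifnot(length(shape) == 3L, length(vox_mm) == 3L)
  frames <- as.data.frame(frames)[c("start", "duration")]
  if (noise_cov < 0) .stop_validation("sim_phantom: noise_cov must be >= 0")
  if (is.null(region_map)) {
    region_map <- array("background", shape)
    region_map[seq_len(min(3, shape[1])), , ] <- "blood"
    cx <- (shape[1] %/% 2):min(shape[1] %/% 2 + 2, shape[1])
    cy <- (shape[2] %/% 2):min(shape[2] %/% 2 + 2, shape[2])
    cz <- max(1, shape[3] %/% 2):min(shape[3] %/% 2 + 1, shape[3])
    region_map[cx, cy, cz] <- "tumor"
  }
  region_map <- array(as.character(region_map), shape)
  labs <- sort(unique(as.vector(region_map)))
  missing_kin <- setdiff(labs, names(regions))
  if (length(missing_kin))
    .stop_validation("sim_phantom: region(s) with no kinetics assigned: %s",
                     paste(missing_kin, collapse = ", "))
  if (is.null(input)) input <- sim_input_function(frames)
  nt <- nrow(frames)
  curves <- lapply(regions[labs], function(r) {
    if (isTRUE(r$blood)) input$curve$value
    else if (!is.null(r$k1) && !is.null(r$k2))
      onetc_forward(r$k1, r$k2, input, frames)$value
    else .stop_validation("sim_phantom: region kinetics need 'blood' or (k1, k2)")
  })
  vol <- array(0, c(shape, nt))
  flat <- matrix(vol, ncol = nt)
  lab_vec <- as.vector(region_map)
  for (lb in labs)
    flat[lab_vec == lb, ] <- rep(curves[[lb]], each = sum(lab_vec == lb))
  if (noise_cov > 0)
    flat <- .with_seed(seed,
                       flat * (1 + matrix(stats::rnorm(length(flat), 0, noise_cov),
                                          nrow = nrow(flat))))
  truth <- list(shape = shape, vox_mm = vox_mm, frames = frames,
                regions = regions[labs], noise_cov = noise_cov, seed = seed,
                input_params = "sim_input_function defaults unless supplied",
                region_voxels = as.list(table(lab_vec)))
  structure(list(volume = array(flat, c(shape, nt)), region_map = region_map,
                 input = input, frames = frames, vox_mm = vox_mm, truth = truth),
            class = "rb_phantom")
}

#' @export
print.rb_phantom <- function(x, ...) {
  cat(sprintf("Dynamic phantom: %s voxels x %d frames; regions: %s; noise_cov %.3g\n",
              paste(dim(x$volume)[1:3], collapse = "x"), dim(x$volume)[4],
              paste(sort(unique(as.vector(x$region_map))), collapse = ", "),
              x$truth$noise_cov))
  invisible(x)
}

#' Write / read a phantom as NIfTI + JSON truth record
#'
#' The 4-D volume and region map are written as NIfTI (`<prefix>.nii`,
#' `<prefix>_regions.nii`, with region labels coded by sorted index), the
#' generating parameters as `<prefix>_truth.json`, and the input curve as
#' `<prefix>_input.csv`.
#'
#' @param phantom an `"rb_phantom"` from [sim_phantom()].
#' @param prefix output path prefix.
#' @return `write_phantom()` invisibly returns the named vector of paths;
#'   `read_phantom()` returns a list with `volume`, `region_map`, `frames`,
#'   `input`, `truth`, `vox_mm`.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "rb_phantom"))
  labs <- sort(unique(as.vector(phantom$region_map)))
  codes <- array(match(phantom$region_map, labs), dim(phantom$region_map))
  paths <- c(volume = paste0(prefix, ".nii"),
             regions = paste0(prefix, "_regions.nii"),
             truth = paste0(prefix, "_truth.json"),
             input = paste0(prefix, "_input.csv"))
  img <- RNifti::asNifti(phantom$volume)
  RNifti::pixdim(img) <- c(phantom$vox_mm, 1)
  RNifti::writeNifti(img, paths[["volume"]])
  rimg <- RNifti::asNifti(codes)
  RNifti::pixdim(rimg) <- phantom$vox_mm
  RNifti::writeNifti(rimg, paths[["regions"]])
  truth <- phantom$truth
  truth$region_labels <- labs
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             paths[["truth"]])
  write_tac(phantom$input$curve, paths[["input"]])
  invisible(paths)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  tpath <- paste0(prefix, "_truth.json")
  if (!file.exists(tpath)) .stop_validation("truth record not found: %s", tpath)
  truth <- jsonlite::fromJSON(tpath)
  vol <- array(RNifti::readNifti(paste0(prefix, ".nii")),
               dim = c(truth$shape, nrow(truth$frames)))
  codes <- array(as.integer(RNifti::readNifti(paste0(prefix, "_regions.nii"))),
                 dim = truth$shape)
  list(volume = vol,
       region_map = array(truth$region_labels[codes], truth$shape),
       frames = as.data.frame(truth$frames),
       input = input_function(read_tac(paste0(prefix, "_input.csv"))),
       truth = truth, vox_mm = truth$vox_mm)
}

#' Simulate a static SUV volume with spherical lesions
#'
#' Voxels take the level of the last listed sphere containing their centre
#' (so nested spheres listed outer-first resolve to the inner level), and
#' the background level elsewhere.
#'
#' @param shape voxel grid dimensions, length 3.
#' @param vox_mm voxel size (mm), length 3.
#' @param background background level.
#' @param spheres list of `list(center = c(x, y, z) (mm), radius = r (mm),
#'   level = v)`; sphere centres are in the volume's mm coordinate system
#'   (voxel `i` centre at `(i - 0.5) * vox_mm`).  All spheres must lie
#'   inside the grid.
#' @return A 3-D array with attribute `"vox_mm"`.
#' @export
sim_static_volume <- function(shape, vox_mm = c(2, 2, 2), background = 1,
                              spheres = list()) {
  stopifnot(length(shape) == 3L, length(vox_mm) == 3L)
  vol <- array(background, shape)
  extent <- shape * vox_mm
  cx <- lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * vox_mm[a])
  for (sp in spheres) {
    if (any(sp$center - sp$radius < 0) || any(sp$center + sp$radius > extent))
      .stop_validation("sim_static_volume: sphere extends outside the grid")
    d2 <- outer(outer((cx[[1]] - sp$center[1])^2, (cx[[2]] - sp$center[2])^2, `+`),
                (cx[[3]] - sp$center[3])^2, `+`)
    vol[d2 <= sp$radius^2] <- sp$level
  }
  attr(vol, "vox_mm") <- vox_mm
  vol
}
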