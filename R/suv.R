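# Static SUV analysis: SUV scaling, threshold VOI segmentation with an
# exclusion (bladder) mask, and SUVmax/mean/peak metrics.

#' Scale an activity volume to SUV
#'
#' Body-weight SUV: activity concentration divided by injected dose per body
#' mass, `SUV = C [Bq/mL] / (dose [Bq] / weight [g])`.  The normaliser is an
#' argument so that other conventions can be substituted.
#'
#' @param activity numeric array of activity concentrations (Bq/mL).
#' @param dose_mbq injected dose (MBq, `> 0`).
#' @param weight_kg body weight (kg, `> 0`).
#' @return Array of SUV values with the same dimensions.
#' @export
#' @examples
#' suv_scale(30000, dose_mbq = 1110, weight_kg = 74)  # 2.0
suv_scale <- function(activity, dose_mbq, weight_kg) {
  if (!is.numeric(dose_mbq) || dose_mbq <= 0 || !is.numeric(weight_kg) || weight_kg <= 0)
    .stop_validation("suv_scale: dose and weight must be > 0")
  activity / (dose_mbq * 1e6 / (weight_kg * 1e3))
}

# 6-connectivity connected-component labelling of a logical 3-D array;
# returns an integer array of component labels (0 outside the mask)
.label_components <- function(mask) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  lab <- array(0L, d)
  idx_all <- which(mask)
  cur <- 0L
  for (seed in idx_all) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      i0 <- (frontier - 1L) %% nx + 1L
      j0 <- ((frontier - 1L) %/% nx) %% ny + 1L
      k0 <- (frontier - 1L) %/% (nx * ny) + 1L
      nb <- c(frontier[i0 > 1L] - 1L, frontier[i0 < nx] + 1L,
              frontier[j0 > 1L] - nx, frontier[j0 < ny] + nx,
              frontier[k0 > 1L] - nx * ny, frontier[k0 < nz] + nx * ny)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

.largest_component <- function(mask) {
  lab <- .label_components(mask)
  sizes <- tabulate(lab)
  lab == which.max(sizes)
}

.as_voi <- function(mask, vox_mm, provenance, threshold, percent = NA_real_) {
  structure(list(mask = mask, vox_mm = vox_mm, provenance = provenance,
                 threshold = threshold, percent = percent),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("VOI mask (%s, threshold %.3g): %d voxels, %.2f cm^3\n",
              x$provenance, x$threshold, sum(x$mask),
              sum(x$mask) * prod(x$vox_mm) / 1000))
  invisible(x)
}

#' Segment a VOI by fixed SUV threshold
#'
#' Voxels inside the search region (after removing the exclusion mask, e.g.
#' a manually masked bladder) with `SUV >= threshold` are selected and the
#' largest 6-connected component is retained, emulating segmentation "at the
#' tumor site".
#'
#' @param volume 3-D SUV array.
#' @param threshold fixed SUV threshold (`> 0`); comparison is closed
#'   (`>=`).
#' @param vox_mm voxel size (mm); defaults to the volume's `"vox_mm"`
#'   attribute, else 1 mm isotropic.
#' @param search logical search-region mask; default the whole volume.
#' @param exclude logical exclusion mask removed before thresholding;
#'   default none.
#' @return A `"voi_mask"` object (`mask`, `vox_mm`, `provenance`,
#'   `threshold`).
#' @export
segment_fixed_threshold <- function(volume, threshold, vox_mm = NULL,
                                    search = NULL, exclude = NULL) {
  if (threshold <= 0) .stop_validation("segment_fixed_threshold: threshold must be > 0")
  vox_mm <- vox_mm %||% attr(volume, "vox_mm") %||% c(1, 1, 1)
  sel <- .candidate_region(volume, search, exclude) & volume >= threshold
  if (!any(sel))
    .stop_compute("empty VOI: no voxel reaches SUV threshold %.3g", threshold)
  .as_voi(.largest_component(sel), vox_mm, "fixed_threshold", threshold)
}

#' Segment a VOI by percent-of-max threshold
#'
#' The threshold is `percent/100` of the maximum SUV inside the search
#' region after exclusion; segmentation then proceeds as in
#' [segment_fixed_threshold()].
#'
#' @inheritParams segment_fixed_threshold
#' @param percent percent of the regional maximum, in `(0, 100]`.
#' @return A `"voi_mask"` with `provenance = "percent_max"`; `threshold`
#'   holds the effective SUV threshold and `percent` the requested percent.
#' @export
segment_percent_max <- function(volume, percent, vox_mm = NULL,
                                search = NULL, exclude = NULL) {
  if (percent <= 0 || percent > 100)
    .stop_validation("segment_percent_max: percent must be in (0, 100]")
  vox_mm <- vox_mm %||% attr(volume, "vox_mm") %||% c(1, 1, 1)
  region <- .candidate_region(volume, search, exclude)
  if (!any(region)) .stop_validation("segment_percent_max: empty search region")
  thr <- percent / 100 * max(volume[region])
  sel <- region & volume >= thr
  if (!any(sel)) .stop_compute("empty VOI at %.3g%% of max", percent)
  out <- .as_voi(.largest_component(sel), vox_mm, "percent_max", thr, percent)
  out
}

.candidate_region <- function(volume, search, exclude) {
  d <- dim(volume)
  region <- if (is.null(search)) array(TRUE, d) else search
  stopifnot(identical(dim(region), d))
  if (!is.null(exclude)) {
    stopifnot(identical(dim(exclude), d))
    region <- region & !exclude
  }
  region
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SUV metrics over a VOI
#'
#' `suv_max` and `suv_mean` are the maximum and mean SUV over the VOI;
#' `suv_peak` is the maximum, over VOI voxels, of the mean SUV within a
#' 1 cm^3 sphere centred on the voxel (radius 6.2 mm; the sphere may extend
#' outside the VOI but is clipped to the volume).  `voi_volume_cm3` is the
#' voxel count times the voxel volume.
#'
#' @param volume 3-D SUV array.
#' @param voi a `"voi_mask"` from the segmentation functions (or a logical
#'   array, in which case `vox_mm` must be supplied).
#' @param vox_mm voxel size (mm) when `voi` is a bare logical array.
#' @return A list of class `"suv_metrics"`: `suv_max`, `suv_mean`,
#'   `suv_peak`, `voi_volume_cm3`.
#' @export
suv_metrics <- function(volume, voi, vox_mm = NULL) {
  if (inherits(voi, "voi_mask")) {
    mask <- voi$mask
    vox_mm <- voi$vox_mm
  } else {
    mask <- voi
    vox_mm <- vox_mm %||% attr(volume, "vox_mm") %||%
      .stop_validation("suv_metrics: vox_mm required with a bare mask")
  }
  stopifnot(identical(dim(mask), dim(volume)))
  if (!any(mask)) .stop_validation("suv_metrics: empty mask")
  vals <- volume[mask]
  r_mm <- (3 * 1000 / (4 * pi))^(1 / 3)  # 1 cm^3 sphere
  off <- .sphere_offsets(r_mm, vox_mm)
  d <- dim(volume)
  ijk <- which(mask, arr.ind = TRUE)
  peak <- max(vapply(seq_len(nrow(ijk)), function(r) {
    ci <- ijk[r, 1] + off[, 1]; cj <- ijk[r, 2] + off[, 2]; ck <- ijk[r, 3] + off[, 3]
    ok <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] & ck >= 1 & ck <= d[3]
    mean(volume[cbind(ci[ok], cj[ok], ck[ok])])
  }, numeric(1)))
  structure(list(suv_max = max(vals), suv_mean = mean(vals), suv_peak = peak,
                 voi_volume_cm3 = sum(mask) * prod(vox_mm) / 1000),
            class = "suv_metrics")
}

# voxel offsets whose centres lie within r_mm of the origin voxel centre
.sphere_offsets <- function(r_mm, vox_mm) {
  nmax <- ceiling(r_mm / vox_mm)
  g <- expand.grid(i = -nmax[1]:nmax[1], j = -nmax[2]:nmax[2], k = -nmax[3]:nmax[3])
  d2 <- (g$i * vox_mm[1])^2 + (g$j * vox_mm[2])^2 + (g$k * vox_mm[3])^2
  as.matrix(g[d2 <= r_mm^2, , drop = FALSE])
}

#' @export
print.suv_metrics <- function(x, ...) {
  cat(sprintf("SUVmax %.3f, SUVmean %.3f, SUVpeak %.3f over %.2f cm^3\n",
              x$suv_max, x$suv_mean, x$suv_peak, x$voi_volume_cm3))
  invisible(x)
}
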