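#' Detect diffraction-limited puncta in a z-stack
#'
#' Detection follows the standard spot-quantification recipe: the stack is
#' background-subtracted with a per-slice median filter (kernel scaled to
#' the PSF), candidate puncta are 3-D local maxima exceeding \code{k}
#' robust standard deviations of the residual, nearby maxima are collapsed
#' onto the brightest, and each punctum's integrated intensity is the sum
#' of raw counts in an ellipsoidal mask of radius \code{r_mask} (xy) minus
#' the median of a surrounding annulus times the mask voxel count, so the
#' local background cancels.
#'
#' @param stack \code{[ny, nx, nz]} numeric array of camera counts.
#' @param sigma_xy,sigma_z PSF sigmas in voxels.
#' @param k detection threshold in robust SDs (default 5).
#' @param r_mask mask radius in voxels (default \code{2 * sigma_xy}).
#' @param sat_level counts at which a maximum is flagged saturated.
#' @return data.frame with one row per punctum: centroid (\code{y, x, z},
#'   continuous voxels), \code{peak}, background-corrected
#'   \code{integrated_intensity}, and \code{saturated}. Zero rows is a
#'   valid result.
#' @export
detect_puncta <- function(stack, sigma_xy, sigma_z = sigma_xy,
                          k = 5, r_mask = 2 * sigma_xy,
                          sat_level = 65535) {
  d <- dim(stack)
  med_r <- ceiling(4 * sigma_xy)
  top <- max(stack)
  bgsub <- stack
  for (kk in seq_len(d[3])) {
    sl <- stack[, , kk] / top
    bg <- as.matrix(EBImage::medianFilter(EBImage::Image(sl), med_r)) * top
    bgsub[, , kk] <- stack[, , kk] - bg
  }
  noise <- stats::mad(bgsub)  # scaled MAD: robust SD of the residual
  # floor keeps quantization ripple of the median filter from surfacing as
  # maxima in noise-free images
  thr <- max(k * noise, 1e-4 * max(bgsub, 0))
  # 26-neighbourhood local maxima above threshold
  inner <- bgsub[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  is_max <- inner > thr
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    nb <- bgsub[2:(d[1] - 1) + dy, 2:(d[2] - 1) + dx, 2:(d[3] - 1) + dz]
    is_max <- is_max & (inner >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(punctum_id = integer(0), y = numeric(0),
                      x = numeric(0), z = numeric(0), peak = numeric(0),
                      integrated_intensity = numeric(0),
                      saturated = logical(0)))
  }
  idx <- idx + 1L  # back to full-stack coordinates
  vals <- bgsub[idx]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  vals <- vals[ord]
  # non-maximum suppression within r_mask (xy) to merge shoulder maxima
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1):nrow(idx)
      close <- sqrt((idx[later, 1] - idx[i, 1])^2 +
                      (idx[later, 2] - idx[i, 2])^2) < r_mask &
        abs(idx[later, 3] - idx[i, 3]) <= ceiling(2 * sigma_z)
      keep[later][close] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  rz <- max(1, round(2 * sigma_z))
  out <- lapply(seq_len(nrow(idx)), function(i) {
    cy <- idx[i, 1]; cx <- idx[i, 2]; cz <- idx[i, 3]
    yy <- max(1, floor(cy - 2 * r_mask)):min(d[1], ceiling(cy + 2 * r_mask))
    xx <- max(1, floor(cx - 2 * r_mask)):min(d[2], ceiling(cx + 2 * r_mask))
    zz <- max(1, cz - 2 * rz):min(d[3], cz + 2 * rz)
    gy <- yy - cy; gx <- xx - cx; gz <- (zz - cz) * (r_mask / rz)
    r2 <- outer(outer(gy^2, gx^2, "+"), gz^2, "+")
    sub <- stack[yy, xx, zz, drop = FALSE]
    subb <- bgsub[yy, xx, zz, drop = FALSE]
    in_mask <- r2 <= r_mask^2
    in_ann <- r2 > r_mask^2 & r2 <= (2 * r_mask)^2
    local_bg <- stats::median(sub[in_ann])
    intensity <- sum(sub[in_mask]) - local_bg * sum(in_mask)
    w <- pmax(subb[in_mask], 0)
    ww <- if (sum(w) > 0) w / sum(w) else rep(1 / sum(in_mask), sum(in_mask))
    pos_y <- slice.index(sub, 1)[in_mask] + min(yy) - 1
    pos_x <- slice.index(sub, 2)[in_mask] + min(xx) - 1
    pos_z <- slice.index(sub, 3)[in_mask] + min(zz) - 1
    data.frame(y = sum(ww * pos_y), x = sum(ww * pos_x),
               z = sum(ww * pos_z), peak = stack[cy, cx, cz],
               integrated_intensity = intensity,
               saturated = stack[cy, cx, cz] >= sat_level)
  })
  res <- do.call(rbind, out)
  res <- cbind(punctum_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Calibrate punctum intensities into absolute molecule counts
#'
#' Transforms background-corrected intensities into molecules using a
#' reference strain of known copy number imaged in the same session: the
#' median reference intensity is assumed to correspond to
#' \code{reference_count} molecules (default 80, the copy number of the
#' kinetochore standard Cse4-EGFP), so
#' \code{molecules = reference_count * I / median(I_ref)}.
#'
#' @param puncta data.frame with \code{integrated_intensity} (target).
#' @param ref_puncta data.frame with \code{integrated_intensity}
#'   (reference strain), at least 10 puncta.
#' @param reference_count molecules per reference punctum.
#' @return \code{puncta} with \code{molecules_raw} (can be negative under
#'   noise) and \code{molecules} (clamped at 0) added; the calibration
#'   model is attached as \code{attr(, "calibration")}.
#' @export
calibrate_counts <- function(puncta, ref_puncta, reference_count = 80) {
  if (nrow(ref_puncta) < 10) {
    stop_mcsarch("need at least 10 reference puncta",
                 "insufficient_data_error")
  }
  ref_med <- stats::median(ref_puncta$integrated_intensity)
  if (!is.finite(ref_med) || ref_med <= 0) {
    stop_mcsarch("non-positive reference median intensity",
                 "calibration_error")
  }
  scale <- reference_count / ref_med
  puncta$molecules_raw <- scale * puncta$integrated_intensity
  puncta$molecules <- pmax(puncta$molecules_raw, 0)
  attr(puncta, "calibration") <- list(reference_median_intensity = ref_med,
                                      reference_count = reference_count,
                                      scale = scale,
                                      n_reference = nrow(ref_puncta))
  puncta
}

#' Summarize molecules per punctum across experimental repeats
#'
#' Per repeat, the median and unscaled MAD of molecules per punctum;
#' across repeats, the mean of the per-repeat medians with its sample
#' standard deviation (n-1 denominator) — the headline statistic for
#' copy-number comparisons between strains.
#'
#' @param repeats list of numeric vectors, one vector of molecule counts
#'   per experimental repeat (each non-empty).
#' @return List of class \code{"strain_summary"}: \code{per_repeat}
#'   data.frame, pooled \code{n_puncta}, \code{median_molecules},
#'   \code{mad_molecules}, \code{mean_of_medians}, \code{sd_of_medians}.
#' @export
summarize_strain <- function(repeats) {
  if (!is.list(repeats)) repeats <- list(repeats)
  stopifnot(length(repeats) >= 1, all(lengths(repeats) >= 1))
  per <- data.frame(
    repeat_id = seq_along(repeats),
    n = lengths(repeats),
    median = vapply(repeats, stats::median, numeric(1)),
    mad = vapply(repeats, mad_unscaled, numeric(1)))
  pooled <- unlist(repeats)
  structure(list(per_repeat = per,
                 n_puncta = length(pooled),
                 median_molecules = stats::median(pooled),
                 mad_molecules = mad_unscaled(pooled),
                 mean_of_medians = mean(per$median),
                 sd_of_medians = if (nrow(per) > 1) stats::sd(per$median)
                                 else NA_real_),
            class = "strain_summary")
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf(
    "strain_summary: %d puncta, %d repeat(s)\n  pooled median %.1f (MAD %.1f); mean of medians %.1f (SD %.2f)\n",
    x$n_puncta, nrow(x$per_repeat), x$median_molecules, x$mad_molecules,
    x$mean_of_medians, x$sd_of_medians))
  invisible(x)
}

#' Ratio of median molecule counts between two strains
#'
#' Used to validate the calibration workflow against a protein pair of
#' published stoichiometry (e.g. Nuf2 vs the Cse4 standard).
#'
#' @param target,reference \code{strain_summary} objects from the same
#'   imaging session.
#' @return The ratio of pooled median molecule counts.
#' @export
ratio_of_medians <- function(target, reference) {
  if (!is.finite(reference$median_molecules) ||
      reference$median_molecules == 0) {
    stop_mcsarch("reference median is zero", "calibration_error")
  }
  target$median_molecules / reference$median_molecules
}

#' Correlation of punctum intensities across two channels
#'
#' Matches puncta across channels by mutual nearest centroid within
#' \code{match_radius} voxels and computes Pearson's correlation of the
#' background-corrected intensities with a two-sided p-value from the t
#' transform.
#'
#' @param puncta_a,puncta_b punctum data.frames with \code{y, x, z} and
#'   \code{integrated_intensity}.
#' @param match_radius maximum centroid distance for a match, voxels.
#' @return List with \code{r}, \code{p_value}, \code{n} (matched pairs)
#'   and the matched pair table.
#' @export
intensity_correlation <- function(puncta_a, puncta_b, match_radius = 3) {
  if (nrow(puncta_a) == 0 || nrow(puncta_b) == 0) {
    stop_mcsarch("need at least 3 matched pairs", "insufficient_data_error")
  }
  pa <- as.matrix(puncta_a[, c("y", "x", "z")])
  pb <- as.matrix(puncta_b[, c("y", "x", "z")])
  dmat <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  dmat <- sqrt(pmax(dmat, 0))
  near_ab <- apply(dmat, 1, which.min)
  near_ba <- apply(dmat, 2, which.min)
  ia <- which(near_ba[near_ab] == seq_len(nrow(pa)) &
                dmat[cbind(seq_len(nrow(pa)), near_ab)] <= match_radius)
  if (length(ia) < 3) {
    stop_mcsarch("need at least 3 matched pairs", "insufficient_data_error")
  }
  ib <- near_ab[ia]
  ct <- stats::cor.test(puncta_a$integrated_intensity[ia],
                        puncta_b$integrated_intensity[ib],
                        method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(ia),
       pairs = data.frame(a = ia, b = ib,
                          intensity_a = puncta_a$integrated_intensity[ia],
                          intensity_b = puncta_b$integrated_intensity[ib]))
}

#' Corrected total mitochondrial fluorescence per cell
#'
#' Per z-slice, the red (mitochondrial marker) channel inside a circular
#' cell ROI is binarized with an adaptive local-mean threshold; the
#' integrated green density inside the mitochondrial mask is corrected by
#' subtracting the mask area times the mean green intensity of the cell
#' background (ROI minus mask). The per-slice corrected values are summed
#' into the total. Slices whose mask covers the whole ROI have no
#' background estimate; they are flagged and excluded with a warning.
#'
#' @param red_stack,green_stack equal-shape \code{[ny, nx, nz]} arrays.
#' @param cell_roi numeric \code{c(cx, cy, r)} circle in pixel units.
#' @param block adaptive-threshold window size in pixels (local mean).
#' @param offset threshold offset above the local mean, in normalized
#'   intensity units.
#' @return List with \code{total} (counts) and \code{slices}, a data.frame
#'   of per-slice measurements (\code{z, int_den, area, mean_bg,
#'   corrected, flagged}).
#' @export
total_mito_fluorescence <- function(red_stack, green_stack, cell_roi,
                                    block = 25, offset = 0) {
  stopifnot(identical(dim(red_stack), dim(green_stack)))
  d <- dim(red_stack)
  cx <- cell_roi[1]; cy <- cell_roi[2]; r <- cell_roi[3]
  if (cx - r < 0 || cy - r < 0 || cx + r > d[2] || cy + r > d[1]) {
    stop_mcsarch("cell ROI extends outside the image", "configuration_error")
  }
  yy <- matrix(seq_len(d[1]), d[1], d[2])
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  in_roi <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  top <- max(red_stack)
  w <- floor(block / 2)
  slices <- lapply(seq_len(d[3]), function(k) {
    red_n <- red_stack[, , k] / top
    if (diff(range(red_n)) < 1e-9) {
      # constant slice (no marker signal): nothing above an adaptive
      # threshold, and the local-mean comparison is numerically unstable
      bin <- matrix(FALSE, d[1], d[2])
    } else {
      # 1e-6 floor guards against FFT round-off in flat regions of the
      # local-mean filter marking zero-signal pixels as above threshold
      bin <- as.matrix(EBImage::thresh(EBImage::Image(red_n), w = w, h = w,
                                       offset = offset + 1e-6)) > 0.5
    }
    mask <- bin & in_roi
    area <- sum(mask)
    bgpix <- in_roi & !mask
    if (sum(bgpix) == 0) {
      return(data.frame(z = k, int_den = NA_real_, area = area,
                        mean_bg = NA_real_, corrected = NA_real_,
                        flagged = TRUE))
    }
    g <- green_stack[, , k]
    int_den <- sum(g[mask])
    mean_bg <- mean(g[bgpix])
    data.frame(z = k, int_den = int_den, area = area, mean_bg = mean_bg,
               corrected = int_den - area * mean_bg, flagged = FALSE)
  })
  slices <- do.call(rbind, slices)
  if (any(slices$flagged)) {
    warning(sprintf("%d slice(s) had no background pixels and were excluded",
                    sum(slices$flagged)))
  }
  list(total = sum(slices$corrected[!slices$flagged]), slices = slices)
}
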