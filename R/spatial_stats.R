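point_kind_coords <- function(t, point_kind) {
  cols <- switch(point_kind,
                 er_anchor = c("er_x", "er_y", "er_z"),
                 centre = c("cx", "cy", "cz"),
                 omm_anchor = c("omm_x", "omm_y", "omm_z"),
                 stop_mcsarch("point_kind must be er_anchor, centre or omm_anchor",
                              "configuration_error"))
  if (!all(cols %in% names(t))) {
    stop_mcsarch(sprintf("columns %s absent; run dipole_to_particle first",
                         paste(setdiff(cols, names(t)), collapse = ", ")),
                 "format_error")
  }
  as.matrix(t[, cols])
}

#' Nearest-neighbour distances within tomograms
#'
#' For each bridge, the 3-D Euclidean distance to the nearest bridge of
#' the same tomogram, measured between points of one kind: the ER anchor
#' points, the bridge centres, or the OMM anchor points (re-centring on an
#' anchor simply means using that anchor's coordinates). Tomograms holding
#' fewer than \code{min_per_tomogram} bridges are excluded, and the
#' exclusions are reported in the result attributes.
#'
#' @param t a \code{particle_table}; centres require
#'   \code{\link{dipole_to_particle}} first.
#' @param point_kind \code{"er_anchor"}, \code{"centre"} or
#'   \code{"omm_anchor"}.
#' @param min_per_tomogram minimum bridges per tomogram for eligibility
#'   (default 3, i.e. tomograms with only one or two bridges are dropped).
#' @return data.frame of records (\code{tomogram_id, bridge_id,
#'   point_kind, nn_distance, nn_bridge_id}, and \code{nn_class} when
#'   \code{length_class} is present), with attributes
#'   \code{excluded_tomograms}, \code{n_excluded_bridges} and
#'   \code{n_tomograms_used}.
#' @export
nn_distances <- function(t, point_kind = c("centre", "er_anchor",
                                           "omm_anchor"),
                         min_per_tomogram = 3) {
  point_kind <- match.arg(point_kind)
  pts <- point_kind_coords(t, point_kind)
  tomo <- as.character(t$tomogram_id)
  counts <- table(tomo)
  eligible <- names(counts)[counts >= min_per_tomogram]
  if (length(eligible) == 0) {
    stop_mcsarch("no tomogram meets the minimum particle count",
                 "insufficient_data_error")
  }
  excluded <- setdiff(names(counts), eligible)
  res <- lapply(eligible, function(tm) {
    sel <- which(tomo == tm)
    p <- pts[sel, , drop = FALSE]
    dmat <- as.matrix(stats::dist(p))
    diag(dmat) <- Inf
    j <- apply(dmat, 1, which.min)
    out <- data.frame(tomogram_id = t$tomogram_id[sel],
                      bridge_id = t$bridge_id[sel],
                      point_kind = point_kind,
                      nn_distance = dmat[cbind(seq_along(sel), j)],
                      nn_bridge_id = t$bridge_id[sel][j])
    if (!is.null(t$length_class)) {
      out$focal_class <- t$length_class[sel]
      out$nn_class <- t$length_class[sel][j]
    }
    out
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  attr(res, "excluded_tomograms") <- excluded
  attr(res, "n_excluded_bridges") <- sum(counts[excluded])
  attr(res, "n_tomograms_used") <- length(eligible)
  res
}

#' Median and MAD of nearest-neighbour distances
#'
#' @param records output of \code{\link{nn_distances}}.
#' @return List with \code{median}, \code{mad} (unscaled), \code{n} and
#'   \code{n_tomograms}.
#' @export
nn_summary <- function(records) {
  if (nrow(records) == 0) {
    stop_mcsarch("no nearest-neighbour records", "insufficient_data_error")
  }
  c(median_mad(records$nn_distance),
    list(n_tomograms = attr(records, "n_tomograms_used") %||%
           length(unique(records$tomogram_id))))
}

#' Short/long nearest-neighbour contingency
#'
#' Cross-tabulates each classified bridge's length class against the class
#' of its nearest neighbour (by centre distance) and tests association
#' with Pearson's chi-square (no continuity correction, df = 1). Row
#' percentages give, for each focal class, the share of nearest neighbours
#' in each class.
#'
#' @param records \code{\link{nn_distances}} output carrying
#'   \code{focal_class} and \code{nn_class}.
#' @return List with the 2 x 2 \code{table} (rows = focal class),
#'   \code{chi_square}, \code{df}, \code{p_value} and
#'   \code{row_percent}.
#' @export
class_contingency <- function(records) {
  if (is.null(records$focal_class) || is.null(records$nn_class)) {
    stop_mcsarch("records carry no length classes; classify first",
                 "format_error")
  }
  tab <- table(factor(records$focal_class, c("short", "long")),
               factor(records$nn_class, c("short", "long")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_mcsarch("degenerate 2x2 table (zero marginal)",
                 "degenerate_table_error")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab,
       chi_square = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = ct$p.value,
       row_percent = 100 * prop.table(tab, margin = 1))
}

#' ER contact-site surface area
#'
#' Sums the areas of mesh triangles whose centroid lies within
#' \code{d_contact} of the opposing (OMM) mesh — the in-silico counterpart
#' of segmenting "the ER membrane in proximity to the OMM" and measuring
#' its area. Degenerate (zero-area) triangles are skipped and counted.
#'
#' @param mesh the ER \code{membrane_patch}.
#' @param omm_mesh the opposing OMM patch; \code{NULL} keeps every
#'   triangle (the whole patch is in contact). Proximity is measured from
#'   each ER triangle centroid to the nearest OMM vertex, which is
#'   accurate when the OMM mesh edge length is small relative to
#'   \code{d_contact}.
#' @param d_contact contact distance threshold, nm (default 40).
#' @return Area in nm^2, with attributes \code{n_triangles_used} and
#'   \code{n_degenerate}.
#' @export
surface_area <- function(mesh, omm_mesh = NULL, d_contact = 40) {
  ar <- triangle_areas(mesh)
  degen <- ar == 0
  keep <- !degen
  if (!is.null(omm_mesh)) {
    ctr <- triangle_centroids(mesh)
    ov <- omm_mesh$vertices
    near <- vapply(seq_len(nrow(ctr)), function(i)
      min(colSums((t(ov) - ctr[i, ])^2)), numeric(1))
    keep <- keep & near <= d_contact^2
  }
  out <- sum(ar[keep])
  attr(out, "n_triangles_used") <- sum(keep)
  attr(out, "n_degenerate") <- sum(degen)
  out
}

#' Membrane area serviced per bridge, and bridge density
#'
#' Per contact site, the ER contact area divided by the number of bridges;
#' pooled across contact sites as median with unscaled MAD. Also reports
#' each site's density as bridges per 10,000 nm^2 and the dataset maximum
#' density. Sites with zero bridges are excluded and reported.
#'
#' @param mcs data.frame with one row per MCS: \code{mcs_id},
#'   \code{er_contact_area} (nm^2) and \code{n_bridges}.
#' @return List with the augmented per-MCS table (\code{area_per_bridge},
#'   \code{density_per_1e4nm2}), pooled \code{median}/\code{mad}/\code{n},
#'   \code{max_density} and \code{n_excluded}.
#' @export
area_per_bridge <- function(mcs) {
  stopifnot(all(c("er_contact_area", "n_bridges") %in% names(mcs)))
  if (any(mcs$er_contact_area <= 0)) {
    stop_mcsarch("contact areas must be positive", "invalid_input_error")
  }
  excl <- mcs$n_bridges == 0
  kept <- mcs[!excl, , drop = FALSE]
  kept$area_per_bridge <- kept$er_contact_area / kept$n_bridges
  kept$density_per_1e4nm2 <- 1e4 * kept$n_bridges / kept$er_contact_area
  c(list(mcs = kept),
    median_mad(kept$area_per_bridge),
    list(max_density = max(kept$density_per_1e4nm2),
         n_excluded = sum(excl)))
}

#' Predicted bridge spacing under equal distribution
#'
#' If bridges were equally distributed within the contact site, each
#' occupying \code{A} nm^2 of membrane, their nearest-neighbour spacing on
#' the densest equal-spacing arrangement (the hexagonal lattice) would be
#' \code{sqrt(2 * A / sqrt(3))}.
#'
#' @param A area per bridge, nm^2.
#' @return Spacing in nm.
#' @examples
#' uniform_spacing(1407) # about 40 nm
#' @export
uniform_spacing <- function(A) {
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop_mcsarch("area per bridge must be positive", "invalid_input_error")
  }
  sqrt(2 * A / sqrt(3))
}

#' Bridge count versus contact area across contact sites
#'
#' @param mcs data.frame with \code{er_contact_area} and \code{n_bridges},
#'   at least 3 rows.
#' @return List with the \code{pairs} table, Pearson \code{r} between area
#'   and count, and \code{max_density} (bridges per 10,000 nm^2).
#' @export
bridges_vs_area <- function(mcs) {
  if (nrow(mcs) < 3) {
    stop_mcsarch("need at least 3 contact sites", "insufficient_data_error")
  }
  r <- stats::cor(mcs$er_contact_area, mcs$n_bridges, method = "pearson")
  list(pairs = mcs[, c("er_contact_area", "n_bridges")],
       r = r,
       max_density = max(1e4 * mcs$n_bridges / mcs$er_contact_area))
}
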