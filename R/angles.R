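#' Tilt of a bridge axis relative to a membrane normal
#'
#' The acute angle between the bridge axis and the local membrane normal,
#' \code{acos(|axis . normal|)} in degrees, in [0, 90]. The absolute value
#' makes the result independent of the sign convention of either vector.
#'
#' @param axis,normal unit 3-vectors (checked to 1e-6).
#' @return Angle in degrees.
#' @examples
#' tilt_angle(c(0, 0, 1), c(0, 0, 1))            # 0
#' tilt_angle(c(1, 0, 1) / sqrt(2), c(0, 0, 1))  # 45
#' @export
tilt_angle <- function(axis, normal) {
  check_unit_vector(axis, tol = 1e-6, what = "axis")
  check_unit_vector(normal, tol = 1e-6, what = "normal")
  acos(min(1, max(0, abs(sum(axis * normal))))) * 180 / pi
}

#' Bridge tilt relative to ER and OMM membranes
#'
#' For every bridge, estimates the local membrane normal at its anchor
#' point by a total-least-squares plane fit to nearby mesh vertices
#' (\code{\link{local_normal}}) and returns the tilt of the bridge axis
#' relative to that normal — the geometric counterpart of re-aligning
#' subtomograms to the membrane and comparing zenith angles.
#'
#' @param t a \code{particle_table} with axes (see
#'   \code{\link{dipole_to_particle}}).
#' @param mesh the membrane \code{membrane_patch}.
#' @param membrane \code{"er"} or \code{"omm"}: which anchor the normals
#'   are evaluated at.
#' @param radius plane-fit neighbourhood radius, nm.
#' @return data.frame of tilt records: \code{tomogram_id, bridge_id,
#'   membrane, tilt} (degrees), the local normal components and
#'   \code{n_mesh_vertices_used}.
#' @export
bridge_tilts <- function(t, mesh, membrane = c("er", "omm"), radius = 20) {
  membrane <- match.arg(membrane)
  if (is.null(t$ax)) t <- dipole_to_particle(t)
  anchors <- if (membrane == "er") {
    as.matrix(t[, c("er_x", "er_y", "er_z")])
  } else {
    as.matrix(t[, c("omm_x", "omm_y", "omm_z")])
  }
  centres <- as.matrix(t[, c("cx", "cy", "cz")])
  axes <- as.matrix(t[, c("ax", "ay", "az")])
  out <- lapply(seq_len(nrow(t)), function(i) {
    nrm <- local_normal(mesh, anchors[i, ], radius = radius,
                        towards = centres[i, ])
    data.frame(tomogram_id = t$tomogram_id[i], bridge_id = t$bridge_id[i],
               membrane = membrane,
               tilt = tilt_angle(axes[i, ], as.numeric(nrm)),
               normal_x = nrm[1], normal_y = nrm[2], normal_z = nrm[3],
               n_mesh_vertices_used = attr(nrm, "n_vertices_used"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Median and MAD of bridge tilts
#'
#' @param records output of \code{\link{bridge_tilts}} (one membrane).
#' @return List with \code{median} (degrees), \code{mad} (unscaled) and
#'   \code{n}.
#' @export
tilt_summary <- function(records) {
  if (nrow(records) == 0) {
    stop_mcsarch("no tilt records", "insufficient_data_error")
  }
  median_mad(records$tilt)
}
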