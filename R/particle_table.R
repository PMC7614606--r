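#' Particle tables of bridge dipoles
#'
#' A particle table is a plain \code{data.frame} (class
#' \code{"particle_table"}) holding one row per picked bridge. Mandatory
#' columns identify the bridge and its two membrane anchor points, in
#' nanometres:
#' \itemize{
#'   \item \code{tomogram_id}, \code{bridge_id} — identifiers, unique as a
#'     pair within a table;
#'   \item \code{er_x}, \code{er_y}, \code{er_z} — the ER-membrane anchor;
#'   \item \code{omm_x}, \code{omm_y}, \code{omm_z} — the outer
#'     mitochondrial membrane (OMM) anchor.
#' }
#' Optional columns carry derived particle geometry (\code{cx}, \code{cy},
#' \code{cz} centre; \code{ax}, \code{ay}, \code{az} unit axis oriented
#' ER to OMM; \code{length_nm}; \code{length_class} one of \code{"short"},
#' \code{"long"}, \code{"unassigned"}) and bookkeeping \code{flags}
#' (semicolon-separated, from the vocabulary \code{"misaligned"},
#' \code{"peroxisome_mcs"}). Provenance (source file, filters applied,
#' generator seed) accumulates append-only in \code{attr(x, "provenance")}.
#'
#' @param df data.frame with at least the mandatory columns above.
#' @param provenance list of provenance records to attach.
#' @return A \code{particle_table}.
#' @export
particle_table <- function(df, provenance = list()) {
  req <- c("tomogram_id", "bridge_id",
           "er_x", "er_y", "er_z", "omm_x", "omm_y", "omm_z")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop_mcsarch(sprintf("missing mandatory column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "format_error")
  }
  coord_cols <- req[-(1:2)]
  for (cc in coord_cols) df[[cc]] <- as.numeric(df[[cc]])
  check_finite_coords(as.matrix(df[coord_cols]), "anchor coordinates")
  if (anyDuplicated(df[, c("tomogram_id", "bridge_id")])) {
    stop_mcsarch("(tomogram_id, bridge_id) pairs must be unique",
                 "invalid_input_error")
  }
  degen <- df$er_x == df$omm_x & df$er_y == df$omm_y & df$er_z == df$omm_z
  if (any(degen)) {
    stop_mcsarch(sprintf("%d dipole(s) with coincident anchors", sum(degen)),
                 "degenerate_geometry_error")
  }
  if (is.null(df$flags)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("particle_table", "data.frame"))
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("particle_table: %d bridges, %d tomogram(s)\n",
              nrow(x), length(unique(x$tomogram_id))))
  if (!is.null(x$length_class)) {
    tb <- table(x$length_class)
    cat("  length classes:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  prov <- attr(x, "provenance")
  if (length(prov) > 0) cat(sprintf("  provenance records: %d\n", length(prov)))
  NextMethod()
}

add_provenance <- function(t, record) {
  attr(t, "provenance") <- c(attr(t, "provenance"), list(record))
  t
}

flag_vocabulary <- c("misaligned", "peroxisome_mcs")

split_flags <- function(flags) {
  strsplit(ifelse(is.na(flags) | flags == "", "", flags), ";", fixed = TRUE)
}

#' Bridge length of a dipole
#'
#' Euclidean distance in nm between the ER and OMM anchor points of each
#' bridge dipole.
#'
#' @param t a \code{particle_table} (or data.frame with anchor columns).
#' @return Numeric vector of lengths, one per row.
#' @examples
#' t <- particle_table(data.frame(tomogram_id = 1, bridge_id = 1,
#'   er_x = 0, er_y = 0, er_z = 0, omm_x = 0, omm_y = 0, omm_z = 24))
#' dipole_length(t) # 24
#' @export
dipole_length <- function(t) {
  er <- as.matrix(t[, c("er_x", "er_y", "er_z")])
  omm <- as.matrix(t[, c("omm_x", "omm_y", "omm_z")])
  check_finite_coords(er, "ER anchor coordinates")
  check_finite_coords(omm, "OMM anchor coordinates")
  unname(sqrt(rowSums((omm - er)^2)))
}

#' Convert dipoles to particles (centre, axis, length)
#'
#' For each dipole the particle centre is the midpoint of the two anchors,
#' the axis is the unit vector oriented from the ER anchor towards the OMM
#' anchor, and the length is the anchor-to-anchor distance. These are the
#' coordinates used for subvolume extraction in subtomogram averaging
#' workflows.
#'
#' @param t a \code{particle_table} of dipoles.
#' @return The table with columns \code{cx, cy, cz, ax, ay, az, length_nm}
#'   filled in and \code{length_class} initialised to \code{"unassigned"}
#'   when absent.
#' @export
dipole_to_particle <- function(t) {
  len <- dipole_length(t)
  if (any(len == 0)) {
    stop_mcsarch("zero-length dipole", "degenerate_geometry_error")
  }
  er <- as.matrix(t[, c("er_x", "er_y", "er_z")])
  omm <- as.matrix(t[, c("omm_x", "omm_y", "omm_z")])
  ctr <- (er + omm) / 2
  ax <- (omm - er) / len
  t$cx <- ctr[, 1]; t$cy <- ctr[, 2]; t$cz <- ctr[, 3]
  t$ax <- ax[, 1]; t$ay <- ax[, 2]; t$az <- ax[, 3]
  t$length_nm <- len
  if (is.null(t$length_class)) t$length_class <- "unassigned"
  add_provenance(t, list(step = "dipole_to_particle", n = nrow(t)))
}

#' Filter particles by bookkeeping flags
#'
#' Removes records carrying any of the dropped flags, e.g. bridges whose
#' subtomograms migrated onto a membrane during alignment
#' (\code{"misaligned"}) or bridges belonging to ER-peroxisome rather than
#' ER-mitochondria contact sites (\code{"peroxisome_mcs"}). Counts removed
#' per flag are appended to the table provenance.
#'
#' @param t a \code{particle_table}.
#' @param drop character vector of flags to drop, from
#'   \code{c("misaligned", "peroxisome_mcs")}.
#' @return The filtered table; surviving rows are unchanged.
#' @export
filter_particles <- function(t, drop = character()) {
  unknown <- setdiff(drop, flag_vocabulary)
  if (length(unknown) > 0) {
    stop_mcsarch(sprintf("unknown flag(s): %s",
                         paste(unknown, collapse = ", ")),
                 "configuration_error")
  }
  fl <- split_flags(t$flags)
  removed_per_flag <- vapply(
    drop, function(f) sum(vapply(fl, function(x) f %in% x, logical(1))),
    integer(1))
  keep <- !vapply(fl, function(x) any(x %in% drop), logical(1))
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(t, "provenance")
  class(out) <- class(t)
  add_provenance(out, list(step = "filter_particles",
                           dropped_flags = as.list(removed_per_flag),
                           n_in = nrow(t), n_out = nrow(out)))
}

#' Split bridges into equal short and long classes
#'
#' Sorts bridges ascending by length (ties broken by
#' \code{(tomogram_id, bridge_id)} so classes are reproducible across runs)
#' and labels the first half \code{"short"} and the second half
#' \code{"long"}. For odd N the short class receives the extra bridge.
#'
#' @param t a \code{particle_table}; lengths are computed if absent.
#' @return The table with \code{length_class} set; per-class summaries
#'   (n, min, max, median, unscaled MAD) are attached as
#'   \code{attr(, "class_summary")} and recorded in provenance.
#' @export
classify_by_length <- function(t) {
  if (nrow(t) < 2) {
    stop_mcsarch("need at least 2 particles to classify",
                 "insufficient_data_error")
  }
  if (is.null(t$length_nm)) t$length_nm <- dipole_length(t)
  ord <- order(t$length_nm, as.character(t$tomogram_id),
               as.character(t$bridge_id))
  n <- nrow(t)
  n_short <- ceiling(n / 2)
  cls <- character(n)
  cls[ord[seq_len(n_short)]] <- "short"
  cls[ord[seq.int(n_short + 1, n)]] <- "long"
  t$length_class <- cls
  summ <- lapply(c(short = "short", long = "long"), function(k) {
    x <- t$length_nm[t$length_class == k]
    list(n = length(x), min = min(x), max = max(x),
         median = stats::median(x), mad = mad_unscaled(x))
  })
  attr(t, "class_summary") <- summ
  add_provenance(t, list(step = "classify_by_length",
                         n_short = n_short, n_long = n - n_short))
}

#' Convert a unit axis to zenith/azimuth angles and back
#'
#' \code{axis_to_angles} returns the zenith angle (from the +z axis,
#' degrees in [0, 180]) and azimuth (atan2 of y over x, degrees in
#' (-180, 180]); \code{angles_to_axis} is the inverse mapping. This is the
#' export convention used for subtomogram-averaging style orientation
#' tables.
#'
#' @param axis unit 3-vector.
#' @param zenith,azimuth angles in degrees.
#' @return \code{axis_to_angles}: named numeric vector
#'   \code{c(zenith, azimuth)}; \code{angles_to_axis}: a unit 3-vector.
#' @export
axis_to_angles <- function(axis) {
  check_unit_vector(axis, tol = 1e-6, what = "axis")
  zenith <- acos(max(-1, min(1, axis[3]))) * 180 / pi
  azimuth <- atan2(axis[2], axis[1]) * 180 / pi
  if (azimuth <= -180) azimuth <- azimuth + 360
  c(zenith = zenith, azimuth = azimuth)
}

#' @rdname axis_to_angles
#' @export
angles_to_axis <- function(zenith, azimuth) {
  zr <- unname(zenith) * pi / 180
  ar <- unname(azimuth) * pi / 180
  c(sin(zr) * cos(ar), sin(zr) * sin(ar), cos(zr))
}

#' Read and write particle tables
#'
#' Two text dialects are supported. \code{"native-csv"} is a CSV with the
#' header columns documented in \code{\link{particle_table}}; unknown
#' columns are preserved on round-trip. \code{"dynamo-dipole-like"} is a
#' headerless whitespace-separated table with one dipole per row:
#' \code{tomogram_id bridge_id er_x er_y er_z omm_x omm_y omm_z}, the
#' minimal content of a two-anchor dipole picking model.
#'
#' @param path file path.
#' @param dialect \code{"native-csv"} or \code{"dynamo-dipole-like"}.
#' @param pixel_size_nm multiply coordinates on read by this factor to
#'   convert picked voxel coordinates to nm (default 1: already nm).
#' @param t a \code{particle_table} (write only).
#' @return \code{read_particle_table}: a \code{particle_table};
#'   \code{write_particle_table}: the path, invisibly.
#' @export
read_particle_table <- function(path, dialect = c("native-csv",
                                                  "dynamo-dipole-like"),
                                pixel_size_nm = 1) {
  dialect <- match.arg(dialect)
  if (dialect == "native-csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 8) {
      stop_mcsarch("dynamo-dipole-like table needs 8 columns", "format_error")
    }
    df <- df[, 1:8]
    names(df) <- c("tomogram_id", "bridge_id",
                   "er_x", "er_y", "er_z", "omm_x", "omm_y", "omm_z")
  }
  coord_cols <- c("er_x", "er_y", "er_z", "omm_x", "omm_y", "omm_z",
                  "cx", "cy", "cz", "length_nm")
  for (cc in intersect(coord_cols, names(df))) {
    df[[cc]] <- as.numeric(df[[cc]]) * pixel_size_nm
  }
  particle_table(df, provenance = list(list(step = "read",
                                            source = path,
                                            dialect = dialect,
                                            pixel_size_nm = pixel_size_nm)))
}

#' @rdname read_particle_table
#' @export
write_particle_table <- function(t, path, dialect = c("native-csv",
                                                      "dynamo-dipole-like")) {
  dialect <- match.arg(dialect)
  if (dialect == "native-csv") {
    utils::write.csv(as.data.frame(t), path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(
      as.data.frame(t)[, c("tomogram_id", "bridge_id", "er_x", "er_y",
                           "er_z", "omm_x", "omm_y", "omm_z")],
      path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
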