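# The eight acromial shape parameters, measured on a shoulder model in its
# scapular frame: AHI, AAP, AIP, AC angle, and the four anterolateral
# protrusion (AALP) parameters a, b, c, c+d (plus the ratio c/(c+d)*100).
# All operators work in frame-local coordinates (x lateral, y superior,
# z anterior).

#' Shoulder model container
#'
#' @param scapula `tri_mesh` with per-vertex labels; vertices labeled
#'   `"acromion"` form the acromion sub-mesh.
#' @param clavicle `tri_mesh`; vertices labeled `"distal"` mark the distal
#'   quarter used for the AAP/AIP reference lines (an unlabeled clavicle is
#'   used whole).
#' @param humerus `tri_mesh` of the proximal humerus.
#' @param landmarks a [scapular_landmarks()] object.
#' @param side `"left"` or `"right"`.
#' @return object of class `shoulder_model`.
#' @export
shoulder_model <- function(scapula, clavicle, humerus, landmarks,
                           side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(scapula, "tri_mesh"), inherits(clavicle, "tri_mesh"),
            inherits(humerus, "tri_mesh"),
            inherits(landmarks, "scapular_landmarks"))
  if (is.null(scapula$labels) || !any(scapula$labels == "acromion"))
    stop("scapula mesh must label an 'acromion' sub-mesh")
  structure(list(scapula = scapula, clavicle = clavicle, humerus = humerus,
                 landmarks = landmarks, side = side),
            class = "shoulder_model")
}

#' @export
print.shoulder_model <- function(x, ...) {
  cat(sprintf("shoulder_model (%s side)\n", x$side))
  cat("  scapula: "); print(x$scapula)
  cat("  clavicle:"); print(x$clavicle)
  cat("  humerus: "); print(x$humerus)
  invisible(x)
}

# Sub-mesh of vertices with the given label; faces whose three vertices all
# carry the label. Vertex indices are remapped; `orig_index` keeps the map.
submesh_by_label <- function(mesh, label) {
  if (is.null(mesh$labels)) stop("mesh has no labels")
  keep <- which(mesh$labels == label)
  if (length(keep) == 0L) stop("no vertices labeled '", label, "'")
  inset <- logical(nrow(mesh$vertices))
  inset[keep] <- TRUE
  fkeep <- inset[mesh$faces[, 1L]] & inset[mesh$faces[, 2L]] &
           inset[mesh$faces[, 3L]]
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  f <- mesh$faces[fkeep, , drop = FALSE]
  f[] <- remap[f]
  out <- tri_mesh(mesh$vertices[keep, , drop = FALSE], f,
                  labels = mesh$labels[keep], validate = FALSE)
  out$orig_index <- keep
  out
}

acromion_submesh <- function(model) submesh_by_label(model$scapula, "acromion")

distal_clavicle_points <- function(model) {
  cl <- model$clavicle
  if (!is.null(cl$labels) && any(cl$labels == "distal"))
    cl$vertices[cl$labels == "distal", , drop = FALSE]
  else cl$vertices
}

#' Most lateral point of the acromion (MLPA)
#'
#' The acromion vertex with maximal x in frame coordinates; ties (within
#' 1e-9 mm) are broken by smallest y, then smallest z.
#'
#' @param model a `shoulder_model`.
#' @param frame its `scapular_frame`.
#' @return list with `point` (3-vector, frame coords) and `index` into the
#'   acromion sub-mesh vertices.
#' @export
find_MLPA <- function(model, frame) {
  acr <- acromion_submesh(model)
  loc <- to_frame_coords(acr$vertices, frame)
  xmax <- max(loc[, 1L])
  cand <- which(loc[, 1L] > xmax - 1e-9)
  if (length(cand) > 1L) {
    cand <- cand[order(loc[cand, 2L], loc[cand, 3L])]
  }
  i <- cand[1L]
  list(point = loc[i, ], index = i, orig_index = acr$orig_index[i])
}

# TLS line fit in 2D: returns unit direction and a point on the line.
fit_line_2d <- function(xy) {
  ctr <- colMeans(xy)
  x <- sweep(xy, 2L, ctr)
  sv <- svd(x, nu = 0L)
  dir <- sv$v[, 1L]
  list(point = ctr, dir = dir / sqrt(sum(dir^2)))
}

# Extreme points of a projected point cloud per 1-mm bin along the abscissa.
# A bin whose extreme exceeds the envelope of its adjacent bins by more than
# `edge_tol` is dropped: bins straddling a tessellation grid line can
# otherwise capture an interior vertex instead of the edge (which would make
# the fitted reference line unstable under rigid motion).
bin_extremes <- function(xy, bin = 1, which = c("max", "min"),
                         edge_tol = 1.5) {
  which <- match.arg(which)
  sgn <- if (which == "max") -1 else 1  # work in min-convention
  y <- sgn * xy[, 2L]
  b <- floor(xy[, 1L] / bin)
  ub <- sort(unique(b))
  idx <- vapply(ub, function(bb) {
    i <- which(b == bb)
    i[which.min(y[i])]
  }, 0L)
  ey <- y[idx]
  keep <- vapply(seq_along(ub), function(k) {
    nb <- which(abs(ub - ub[k]) == 1L)
    length(nb) == 0L || ey[k] <= min(ey[nb]) + edge_tol
  }, TRUE)
  xy[idx[keep], , drop = FALSE]
}

#' Acromiohumeral interval (AHI)
#'
#' Outlet-view distance: the most superior humeral head point H (max-y
#' humeral vertex) and the acromial undersurface (vertices whose outward
#' normal has y-component below `-0.2`) are projected along x onto the y-z
#' plane; AHI is the minimum planar distance from H to the undersurface
#' vertex set.
#'
#' @param model a `shoulder_model`.
#' @param frame its `scapular_frame`.
#' @return list with `value` (mm) and flag `no_overhang` (set when H lies
#'   outside the undersurface z-range so no roof overhang exists).
#' @export
measure_AHI <- function(model, frame) {
  hum <- to_frame_coords(model$humerus$vertices, frame)
  H <- hum[which.max(hum[, 2L]), ]
  acr <- acromion_submesh(model)
  vn <- vertex_normals(acr)
  # rotate normals into the frame (directions: no translation)
  vn_loc <- vn %*% frame$axes
  under <- which(vn_loc[, 2L] < -0.2)
  if (length(under) == 0L) stop("acromion has no undersurface vertices")
  uv <- to_frame_coords(acr$vertices[under, , drop = FALSE], frame)
  dyz <- sqrt((uv[, 2L] - H[2L])^2 + (uv[, 3L] - H[3L])^2)
  no_overhang <- H[3L] < min(uv[, 3L]) || H[3L] > max(uv[, 3L])
  list(value = min(dyz), no_overhang = no_overhang)
}

# Shared AAP/AIP machinery: perpendicular distance from an extreme point to a
# TLS reference line along the distal clavicle, clamped at 0.
protrusion_vs_line <- function(line_pts, probe, positive_toward) {
  ln <- fit_line_2d(line_pts)
  nrm <- c(-ln$dir[2L], ln$dir[1L])
  if (sum(nrm * positive_toward) < 0) nrm <- -nrm
  d <- sum((probe - ln$point) * nrm)
  list(value = max(d, 0), clamped = d < 0, raw = d)
}

#' Acromial anterior protrusion (AAP)
#'
#' In the x-z projection, a total-least-squares line through the per-x-bin
#' most-anterior (max-z) points of the distal clavicle stands in for "the
#' anterior aspect of the distal clavicle"; AAP is the perpendicular distance
#' from the most anterior acromion vertex to that line, clamped at 0 when the
#' acromion does not protrude.
#'
#' @param model a `shoulder_model`.
#' @param frame its `scapular_frame`.
#' @param bin abscissa bin width (mm) for the clavicle edge points.
#' @return list with `value` (mm) and flag `clamped`.
#' @export
measure_AAP <- function(model, frame, bin = 1) {
  cl <- to_frame_coords(distal_clavicle_points(model), frame)
  cl_xz <- cl[, c(1L, 3L), drop = FALSE]
  edge <- bin_extremes(cl_xz, bin = bin, which = "max")
  if (nrow(edge) < 2L) stop("distal clavicle too small to fit a line")
  acr <- acromion_submesh(model)
  av <- to_frame_coords(acr$vertices, frame)
  probe <- av[which.max(av[, 3L]), c(1L, 3L)]
  protrusion_vs_line(edge, probe, positive_toward = c(0, 1))
}

#' Acromial inferior protrusion (AIP)
#'
#' In the x-y projection, a TLS line through the per-x-bin most-inferior
#' (min-y) points of the distal clavicle stands in for "the inferior aspect
#' of the distal clavicle"; AIP is the perpendicular distance from the most
#' inferior vertex of the anterior acromion half to that line, positive below
#' the line and clamped at 0 otherwise.
#'
#' @inheritParams measure_AAP
#' @param mlpa result of [find_MLPA()]; computed if missing.
#' @return list with `value` (mm) and flag `clamped`.
#' @export
measure_AIP <- function(model, frame, mlpa = NULL, bin = 1) {
  if (is.null(mlpa)) mlpa <- find_MLPA(model, frame)
  cl <- to_frame_coords(distal_clavicle_points(model), frame)
  cl_xy <- cl[, c(1L, 2L), drop = FALSE]
  edge <- bin_extremes(cl_xy, bin = bin, which = "min")
  if (nrow(edge) < 2L) stop("distal clavicle too small to fit a line")
  acr <- acromion_submesh(model)
  av <- to_frame_coords(acr$vertices, frame)
  ant <- av[av[, 3L] >= mlpa$point[3L], , drop = FALSE]
  if (nrow(ant) == 0L) stop("anterior acromion half is empty")
  probe <- ant[which.min(ant[, 2L]), c(1L, 2L)]
  protrusion_vs_line(edge, probe, positive_toward = c(0, -1))
}

#' Acromioclavicular (AC) angle
#'
#' AM, PM and the MLPA are projected onto the x-y plane; the AC angle is the
#' angle at the MLPA between the rays toward AM and PM, in degrees.
#'
#' @inheritParams measure_AIP
#' @return angle in degrees, in (0, 180).
#' @export
measure_AC_angle <- function(model, frame, mlpa = NULL) {
  if (is.null(mlpa)) mlpa <- find_MLPA(model, frame)
  am <- to_frame_coords(model$landmarks$AM, frame)[1L, c(1L, 2L)]
  pm <- to_frame_coords(model$landmarks$PM, frame)[1L, c(1L, 2L)]
  v0 <- mlpa$point[c(1L, 2L)]
  r1 <- am - v0; r2 <- pm - v0
  l1 <- sqrt(sum(r1^2)); l2 <- sqrt(sum(r2^2))
  if (l1 < 1e-9 || l2 < 1e-9)
    stop("AM or PM coincides with the MLPA in the x-y projection")
  ang <- acos(pmin(pmax(sum(r1 * r2) / (l1 * l2), -1), 1)) * 180 / pi
  ang
}

#' Split the acromion into anterior and posterior halves at the MLPA
#'
#' Cut plane z = z(MLPA), normal to the z-axis; vertices exactly on the plane
#' are assigned to the anterior half.
#'
#' @inheritParams measure_AIP
#' @return list with `anterior` and `posterior` logical vertex masks over the
#'   acromion sub-mesh, plus the sub-mesh itself (`acromion`) and its
#'   frame-local vertices (`local`).
#' @export
split_acromion <- function(model, frame, mlpa = NULL) {
  if (is.null(mlpa)) mlpa <- find_MLPA(model, frame)
  acr <- acromion_submesh(model)
  loc <- to_frame_coords(acr$vertices, frame)
  anterior <- loc[, 3L] >= mlpa$point[3L]
  if (!any(anterior)) stop("malformed acromion: empty anterior half")
  list(acromion = acr, local = loc, anterior = anterior,
       posterior = !anterior, z_cut = mlpa$point[3L])
}

#' Localize the acromial anterolateral protrusion (AALP)
#'
#' Slices the acromion with axial planes (normal to y) at `slice_step`
#' spacing. On each closed slice contour (CCW in the (z, x) basis) the
#' "inner edge" is the arc whose outward normal points medially
#' (x-component < 0); the crease between the anterolateral lobe and the main
#' acromion is the concave extremum there, i.e. the point of most negative
#' signed curvature with `|kappa| >= curvature_min`, restricted to the
#' anterior half (z >= z(MLPA)). Marked points ordered by y form the medial
#' border of the AALP; member points are the anterior-half vertices lateral
#' or anterior of the border.
#'
#' @param model a `shoulder_model`.
#' @param frame its `scapular_frame`.
#' @param split result of [split_acromion()]; computed if missing.
#' @param config measurement configuration, see [default_config()].
#' @return object of class `aalp_region`: `border` (`k x 3` matrix of frame
#'   coords ordered by y), `member_mask` (logical over acromion vertices),
#'   `slice_count`, and `empty` flag ("no distinct protrusion").
#' @export
localize_AALP <- function(model, frame, split = NULL,
                          config = default_config()) {
  if (is.null(split)) split <- split_acromion(model, frame)
  acr <- split$acromion
  loc <- split$local
  # slice in frame-local coordinates: plane normal +y, basis (z, x) so that
  # u x v = z x x = y and contours are CCW loops
  lmesh <- acr
  lmesh$vertices <- loc
  basis <- list(u = c(0, 0, 1), v = c(1, 0, 0))
  ys <- seq(min(loc[, 2L]) + config$slice_step / 2,
            max(loc[, 2L]) - config$slice_step / 4,
            by = config$slice_step)
  border <- list()
  for (y0 in ys) {
    cont <- slice_mesh(lmesh, normal = c(0, 1, 0), offset = y0, basis = basis,
                       min_perimeter = config$min_perimeter)
    best <- NULL
    for (cc in cont) {
      if (!cc$closed) next
      cur <- contour_curvature(cc$points, closed = TRUE,
                               resample_step = config$resample_step,
                               smooth_window = config$smooth_window)
      # contour 2D coords are (z, x)
      zc <- cur$points[, 1L]; xc <- cur$points[, 2L]
      medial <- cur$normals[, 2L] < -0.05
      ant <- zc >= split$z_cut
      cand <- which(medial & ant & !is.na(cur$curvature) &
                    cur$curvature <= -config$curvature_min)
      if (length(cand) == 0L) next
      k <- cur$curvature[cand]
      top <- cand[k <= min(k) + 1e-12]
      pick <- top[which.min(cur$arc[top])]  # tie-break: smallest arc length
      score <- cur$curvature[pick]
      if (is.null(best) || score < best$score)
        best <- list(score = score, point = c(xc[pick], y0, zc[pick]))
    }
    if (!is.null(best)) border[[length(border) + 1L]] <- best$point
  }
  slice_count <- length(ys)
  if (length(border) < config$min_slices) {
    return(structure(list(border = NULL, member_mask = NULL,
                          slice_count = slice_count, empty = TRUE),
                     class = "aalp_region"))
  }
  B <- do.call(rbind, border)
  B <- B[order(B[, 2L]), , drop = FALSE]
  # member points: anterior-half vertices lateral (x) or anterior (z) of the
  # border interpolated at the vertex's height
  bx <- stats::approxfun(B[, 2L], B[, 1L], rule = 2)
  bz <- stats::approxfun(B[, 2L], B[, 3L], rule = 2)
  tol <- 1e-6
  member <- split$anterior &
    (loc[, 1L] >= bx(loc[, 2L]) - tol | loc[, 3L] >= bz(loc[, 2L]) - tol)
  structure(list(border = B, member_mask = member,
                 slice_count = slice_count, empty = FALSE),
            class = "aalp_region")
}

#' @export
print.aalp_region <- function(x, ...) {
  if (x$empty) {
    cat("aalp_region: no distinct protrusion detected\n")
  } else {
    cat(sprintf("aalp_region: border of %d points over %d slices, %d member vertices\n",
                nrow(x$border), x$slice_count, sum(x$member_mask)))
  }
  invisible(x)
}

#' AALP width and extent parameters
#'
#' In the x-z projection: `a` is the planar distance from the most medial
#' border point (minimal x) to the MLPA; `b` from the most posteromedial
#' border point (minimal x among the posterior-most `posteromedial_frac` of
#' border points by z) to the MLPA. In the y-z projection: `c` is the
#' z-extent of the member points, `c_plus_d` the z-extent of the whole
#' acromion; `ratio_percent = 100 c / (c + d)`.
#'
#' @param region an `aalp_region`.
#' @param split result of [split_acromion()].
#' @param mlpa result of [find_MLPA()].
#' @param posteromedial_frac posterior fraction of the border's z-range used
#'   for `b` (default 0.2).
#' @return list with `a`, `b`, `c`, `c_plus_d`, `ratio_percent` (all `NA`
#'   when the region is empty).
#' @export
measure_AALP_params <- function(region, split, mlpa,
                                posteromedial_frac = 0.2) {
  cpd <- diff(range(split$local[, 3L]))
  if (region$empty) {
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                c_plus_d = cpd, ratio_percent = NA_real_))
  }
  B <- region$border
  ml <- mlpa$point[c(1L, 3L)]
  dxz <- function(p) sqrt(sum((p - ml)^2))
  a_pt <- B[which.min(B[, 1L]), c(1L, 3L)]
  zr <- range(B[, 3L])
  band <- B[, 3L] <= zr[1L] + posteromedial_frac * (zr[2L] - zr[1L]) + 1e-9
  Bb <- B[band, , drop = FALSE]
  b_pt <- Bb[which.min(Bb[, 1L]), c(1L, 3L)]
  memz <- split$local[region$member_mask, 3L]
  cc <- diff(range(memz))
  list(a = dxz(a_pt), b = dxz(b_pt), c = cc, c_plus_d = cpd,
       ratio_percent = 100 * cc / cpd)
}

#' Measure all eight acromial parameters
#'
#' Runs the full pipeline: side normalization, scapular frame construction,
#' MLPA detection, AHI/AAP/AIP/AC angle, AALP localization and parameters.
#'
#' @param model a `shoulder_model`.
#' @param config measurement configuration, see [default_config()].
#' @return object of class `measurement_set` with fields `AHI`, `AAP`, `AIP`,
#'   `AC_angle`, `a`, `b`, `c`, `c_plus_d`, `ratio_percent`, plus `flags` and
#'   `provenance` (config and frame used).
#' @export
measure_all <- function(model, config = default_config()) {
  model <- normalize_side(model)
  frame <- build_frame(model$landmarks)
  mlpa <- find_MLPA(model, frame)
  ahi <- measure_AHI(model, frame)
  aap <- measure_AAP(model, frame, bin = config$line_bin)
  aip <- measure_AIP(model, frame, mlpa = mlpa, bin = config$line_bin)
  ac <- measure_AC_angle(model, frame, mlpa = mlpa)
  split <- split_acromion(model, frame, mlpa = mlpa)
  region <- localize_AALP(model, frame, split = split, config = config)
  aalp <- measure_AALP_params(region, split, mlpa,
                              posteromedial_frac = config$posteromedial_frac)
  structure(list(AHI = ahi$value, AAP = aap$value, AIP = aip$value,
                 AC_angle = ac, a = aalp$a, b = aalp$b, c = aalp$c,
                 c_plus_d = aalp$c_plus_d, ratio_percent = aalp$ratio_percent,
                 flags = list(no_overhang = ahi$no_overhang,
                              aap_clamped = aap$clamped,
                              aip_clamped = aip$clamped,
                              aalp_empty = region$empty,
                              mirrored = isTRUE(attr(model, "mirrored"))),
                 provenance = list(config = config,
                                   glenoid_radius = frame$glenoid_radius)),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("Acromial measurement set\n")
  fmt <- function(v, unit) if (is.na(v)) "   --" else sprintf("%6.2f %s", v, unit)
  cat(sprintf("  AHI      %s\n", fmt(x$AHI, "mm")))
  cat(sprintf("  AAP      %s\n", fmt(x$AAP, "mm")))
  cat(sprintf("  AIP      %s\n", fmt(x$AIP, "mm")))
  cat(sprintf("  AC angle %s\n", fmt(x$AC_angle, "deg")))
  cat(sprintf("  (a)      %s\n", fmt(x$a, "mm")))
  cat(sprintf("  (b)      %s\n", fmt(x$b, "mm")))
  cat(sprintf("  (c)      %s\n", fmt(x$c, "mm")))
  cat(sprintf("  (c+d)    %s\n", fmt(x$c_plus_d, "mm")))
  cat(sprintf("  ratio    %s\n", fmt(x$ratio_percent, "%")))
  fl <- x$flags[vapply(x$flags, isTRUE, logical(1L))]
  if (length(fl)) cat("  flags:", paste(names(fl), collapse = ", "), "\n")
  invisible(x)
}

#' Coerce a measurement set to a one-row data frame
#' @param x a `measurement_set`.
#' @param ... unused.
#' @return data.frame with the eight parameter columns.
#' @export
as.data.frame.measurement_set <- function(x, ...) {
  data.frame(AHI = x$AHI, AAP = x$AAP, AIP = x$AIP, AC_angle = x$AC_angle,
             a = x$a, b = x$b, c = x$c, c_plus_d = x$c_plus_d,
             ratio_percent = x$ratio_percent)
}

#' Default measurement configuration
#'
#' @param slice_step axial slice spacing for AALP localization (mm); default
#'   0.625, the CT slice thickness the method emulates.
#' @param resample_step contour arc-length resampling step (mm).
#' @param smooth_window curvature half-window in samples.
#' @param curvature_min minimum |curvature| (1/mm) accepted as a crease.
#' @param min_slices minimum number of marked slices for a non-empty AALP.
#' @param min_perimeter minimum slice contour perimeter kept (mm).
#' @param posteromedial_frac posterior z-fraction of the border used for `b`.
#' @param line_bin abscissa bin (mm) for clavicle reference lines.
#' @return named list of configuration values.
#' @export
default_config <- function(slice_step = 0.625, resample_step = 0.5,
                           smooth_window = 5L, curvature_min = 0.15,
                           min_slices = 3L, min_perimeter = 2,
                           posteromedial_frac = 0.2, line_bin = 1) {
  stopifnot(slice_step > 0, resample_step > 0, smooth_window >= 1,
            curvature_min > 0, min_slices >= 1, min_perimeter >= 0,
            posteromedial_frac > 0, posteromedial_frac <= 1, line_bin > 0)
  list(slice_step = slice_step, resample_step = resample_step,
       smooth_window = as.integer(smooth_window),
       curvature_min = curvature_min, min_slices = as.integer(min_slices),
       min_perimeter = min_perimeter, posteromedial_frac = posteromedial_frac,
       line_bin = line_bin)
}
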