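# Low-level 3D/2D geometric primitives: plane/circle fitting, projections,
# mesh slicing, contour curvature, rigid transforms. All lengths are mm.

#' Construct a triangle mesh
#'
#' Vertices are stored as an `n x 3` numeric matrix, faces as an `m x 3`
#' integer matrix of 1-based vertex indices, with an optional per-vertex
#' character label vector (used to mark bone sub-regions such as the acromion).
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param labels optional character vector, one label per vertex.
#' @param validate check invariants (finite coordinates, indices in range,
#'   no zero-area faces).
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, labels = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (validate) {
    if (nrow(vertices) < 4L) stop("mesh must have at least 4 vertices")
    if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
    if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
      stop("face index out of range")
    a <- face_areas(vertices, faces)
    if (any(a <= 1e-12))
      stop("mesh contains degenerate (zero-area) faces")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(vertices))
      stop("labels must have one entry per vertex")
  }
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(" | labels: ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

face_areas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  p1 <- vertices[faces[, 1L], , drop = FALSE]
  p2 <- vertices[faces[, 2L], , drop = FALSE]
  p3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(vertices, faces) {
  p1 <- vertices[faces[, 1L], , drop = FALSE]
  p2 <- vertices[faces[, 2L], , drop = FALSE]
  p3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Area-weighted outward vertex normals
#'
#' Assumes consistently outward-oriented faces (the synthetic generator and the
#' mesh readers enforce this for closed components).
#'
#' @param mesh a `tri_mesh`.
#' @return numeric matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(v, f)
  fa <- face_areas(v, f)
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    s <- rowsum(fn * fa, group = f[, k])
    rows <- as.integer(rownames(s))
    n[rows, ] <- n[rows, ] + s
  }
  len <- sqrt(rowSums(n^2))
  ok <- len > 1e-12
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n
}

#' Total-least-squares plane fit
#'
#' Fits the orthogonal-distance regression plane through three or more points
#' via SVD of the centered coordinates.
#'
#' @param points numeric matrix (`n x 3`) of points, n >= 3.
#' @return list with `normal` (unit 3-vector), `offset` (scalar d with
#'   `normal . p = offset` on the plane), `centroid`, and `rms` residual.
#' @export
fit_plane_lsq <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  sv <- svd(x, nu = 0L)
  # collinear (or all-duplicate) points: second singular value ~ 0
  if (sv$d[2L] <= max(sv$d[1L], 1) * 1e-9)
    stop("degenerate geometry: points are collinear or coincident")
  normal <- sv$v[, 3L]
  normal <- normal / sqrt(sum(normal^2))
  list(normal = normal, offset = sum(normal * ctr), centroid = ctr,
       rms = sv$d[3L] / sqrt(nrow(points)))
}

# Any orthonormal in-plane basis (u, v) with u x v = normal.
plane_basis <- function(normal) {
  a <- if (abs(normal[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- cross3(normal, u)
  list(u = u, v = v)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Least-squares circle fit to 3D points
#'
#' Fits the total-least-squares plane, projects the points into it, runs the
#' algebraic Kasa circle fit followed by one geometric Gauss-Newton refinement
#' step, and lifts the center back to 3D. Deterministic: no random
#' initialization.
#'
#' @param points numeric matrix (`n x 3`), n >= 3, not collinear.
#' @param min_radius radii below this (mm) set the `small_radius` flag.
#' @return list with `center` (3-vector), `radius`, `normal` (plane normal),
#'   `rms` radial residual and logical `small_radius`.
#' @export
fit_circle_in_plane <- function(points, min_radius = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("circle fit needs at least 3 points")
  pl <- fit_plane_lsq(points)
  b <- plane_basis(pl$normal)
  rel <- sweep(points, 2L, pl$centroid)
  xy <- cbind(rel %*% b$u, rel %*% b$v)
  fit <- kasa_gauss_newton(xy)
  center <- pl$centroid + fit$center[1L] * b$u + fit$center[2L] * b$v
  list(center = as.numeric(center), radius = fit$radius, normal = pl$normal,
       rms = fit$rms, small_radius = fit$radius < min_radius)
}

# Kasa algebraic circle fit + one Gauss-Newton step on (cx, cy, r).
kasa_gauss_newton <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, rhs), error = function(e)
    stop("degenerate geometry: circle fit is singular"))
  cx <- sol[1L]; cy <- sol[2L]
  r <- sqrt(max(sol[3L] + cx^2 + cy^2, 0))
  if (r <= 0) stop("degenerate geometry: zero-radius circle")
  # one geometric refinement step: minimize sum (|p - c| - r)^2
  for (it in 1L) {
    dx <- x - cx; dy <- y - cy
    d <- sqrt(dx^2 + dy^2)
    if (any(d < 1e-12)) break
    J <- cbind(-dx / d, -dy / d, rep(-1, length(d)))
    res <- d - r
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    cx <- cx + step[1L]; cy <- cy + step[2L]; r <- r + step[3L]
  }
  dx <- x - cx; dy <- y - cy
  res <- sqrt(dx^2 + dy^2) - r
  list(center = c(cx, cy), radius = r, rms = sqrt(mean(res^2)))
}

#' Orthonormal coordinate frame
#'
#' @param origin 3-vector origin.
#' @param x_axis,y_axis,z_axis unit, mutually orthogonal, right-handed axes.
#' @param tol orthonormality tolerance.
#' @return object of class `ortho_frame`; `$axes` is the 3x3 matrix with the
#'   axes as columns.
#' @export
ortho_frame <- function(origin, x_axis, y_axis, z_axis, tol = 1e-9) {
  R <- cbind(as.numeric(x_axis), as.numeric(y_axis), as.numeric(z_axis))
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("frame axes are not orthonormal")
  if (det(R) < 0) stop("frame is not right-handed")
  structure(list(origin = as.numeric(origin), axes = R), class = "ortho_frame")
}

#' @export
print.ortho_frame <- function(x, ...) {
  cat("ortho_frame\n  origin:", sprintf("%.3f", x$origin), "\n")
  lab <- c("x", "y", "z")
  for (k in 1:3)
    cat(sprintf("  %s-axis: %s\n", lab[k],
                paste(sprintf("% .4f", x$axes[, k]), collapse = " ")))
  invisible(x)
}

# World -> frame-local coordinates (rows of `points`).
to_frame_coords <- function(points, frame) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  sweep(points, 2L, frame$origin) %*% frame$axes
}

#' Project points into a named coordinate plane of a frame
#'
#' Expresses the entity in frame coordinates and keeps the named axis pair
#' (first named axis = abscissa), dropping the third coordinate.
#'
#' @param entity a 3-vector, an `n x 3` matrix, or a `tri_mesh`.
#' @param frame an `ortho_frame`.
#' @param plane one of `"xy"`, `"xz"`, `"yz"` (separators `-`/`_` accepted).
#' @return an `n x 2` matrix of planar coordinates.
#' @export
project_to_plane <- function(entity, frame, plane = c("xy", "xz", "yz")) {
  plane <- gsub("[-_ ]", "", plane[1L])
  cols <- switch(plane,
                 xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L),
                 stop("unknown plane: ", plane))
  pts <- if (inherits(entity, "tri_mesh")) entity$vertices else entity
  loc <- to_frame_coords(pts, frame)
  loc[, cols, drop = FALSE]
}

#' Rigidly transform a mesh, point set, or shoulder model
#'
#' @param x a `tri_mesh`, numeric points, or `shoulder_model`.
#' @param rotation proper orthonormal 3x3 matrix (checked to 1e-8).
#' @param translation 3-vector.
#' @return the transformed object, same type, labels preserved.
#' @export
rigid_transform <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("rotation must be proper orthonormal")
  tr <- function(p) {
    p <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
    sweep(p %*% t(rotation), 2L, as.numeric(translation), `+`)
  }
  if (inherits(x, "tri_mesh")) {
    out <- x
    out$vertices <- tr(x$vertices)
    return(out)
  }
  if (inherits(x, "shoulder_model")) return(transform_model(x, tr))
  if (is.numeric(x)) {
    out <- tr(x)
    if (!is.matrix(x)) out <- as.numeric(out)
    return(out)
  }
  stop("unsupported type for rigid_transform")
}

# Apply a point-map fn (matrix -> matrix) to every mesh and landmark of a model.
transform_model <- function(model, fn) {
  out <- model
  for (m in c("scapula", "clavicle", "humerus")) {
    if (!is.null(model[[m]])) {
      out[[m]]$vertices <- fn(model[[m]]$vertices)
    }
  }
  lm <- model$landmarks
  lm$glenoid_rim <- fn(lm$glenoid_rim)
  for (p in c("B", "C", "AM", "PM", "anterior_witness"))
    lm[[p]] <- as.numeric(fn(lm[[p]]))
  out$landmarks <- lm
  out
}

#' Slice a mesh with a plane
#'
#' Intersects the mesh with the plane `normal . p = offset` and chains the
#' intersection segments into contours. Closed contours are oriented
#' counterclockwise in the plane's 2D basis `(u, v)` (`u x v = normal`);
#' contours with perimeter below `min_perimeter` are discarded.
#'
#' @param mesh a `tri_mesh`.
#' @param normal unit plane normal.
#' @param offset plane offset (mm).
#' @param basis optional list with in-plane unit vectors `u`, `v`; defaults to
#'   [plane_basis()] of the normal.
#' @param min_perimeter minimum contour perimeter kept (mm).
#' @return list of contours; each is a list with `points` (`k x 2` matrix of
#'   (u, v) coordinates), `closed` flag, and `origin`/`u`/`v` describing the
#'   embedding so 2D points can be lifted back to 3D.
#' @export
slice_mesh <- function(mesh, normal, offset, basis = NULL, min_perimeter = 2) {
  normal <- as.numeric(normal); normal <- normal / sqrt(sum(normal^2))
  if (is.null(basis)) basis <- plane_basis(normal)
  v <- mesh$vertices
  d <- as.numeric(v %*% normal) - offset
  f <- mesh$faces
  s1 <- d[f[, 1L]]; s2 <- d[f[, 2L]]; s3 <- d[f[, 3L]]
  crossed <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossed)) return(list())
  segs <- vector("list", sum(crossed))
  fi <- which(crossed)
  k <- 0L
  # canonical operand order: the two faces sharing a cut edge must compute a
  # bitwise-identical intersection point or contour chaining can break
  edge_pt <- function(ia, ib) {
    if (ia > ib) { tmp <- ia; ia <- ib; ib <- tmp }
    da <- d[ia]; db <- d[ib]
    t <- da / (da - db)
    v[ia, ] + t * (v[ib, ] - v[ia, ])
  }
  for (i in fi) {
    ids <- f[i, ]
    dd <- d[ids]
    pts <- list()
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      da <- dd[e[1L]]; db <- dd[e[2L]]
      if ((da > 0 && db < 0) || (da < 0 && db > 0)) {
        pts[[length(pts) + 1L]] <- edge_pt(ids[e[1L]], ids[e[2L]])
      } else if (da == 0 && db != 0) {
        pts[[length(pts) + 1L]] <- v[ids[e[1L]], ]
      }
    }
    if (length(pts) >= 2L) {
      k <- k + 1L
      segs[[k]] <- rbind(pts[[1L]], pts[[2L]])
    }
  }
  if (k == 0L) return(list())
  segs <- segs[seq_len(k)]
  # project segment endpoints to 2D plane coords
  origin3 <- offset * normal
  u <- basis$u; vv <- basis$v
  to2d <- function(p) {
    rel <- sweep(p, 2L, origin3)
    cbind(rel %*% u, rel %*% vv)
  }
  segs2 <- lapply(segs, to2d)
  chains <- chain_segments(segs2)
  out <- list()
  for (ch in chains) {
    pts <- ch$points
    # drop consecutive duplicates
    keep <- c(TRUE, rowSums((pts[-1L, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 1e-16)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 3L) next
    per <- contour_length(pts, ch$closed)
    if (per < min_perimeter) next
    if (ch$closed && polygon_area(pts) < 0) pts <- pts[nrow(pts):1L, , drop = FALSE]
    out[[length(out) + 1L]] <- list(points = pts, closed = ch$closed,
                                    origin = origin3, u = u, v = vv,
                                    normal = normal, offset = offset)
  }
  out
}

# Chain 2-point segments into polylines/loops by matching quantized endpoints.
chain_segments <- function(segs2, tol = 1e-6) {
  n <- length(segs2)
  key <- function(p) paste(round(p[1L] / tol), round(p[2L] / tol))
  ends <- matrix("", n, 2L)
  for (i in seq_len(n)) {
    ends[i, 1L] <- key(segs2[[i]][1L, ])
    ends[i, 2L] <- key(segs2[[i]][2L, ])
  }
  # adjacency: endpoint key -> list of (segment, end)
  adj <- new.env(parent = emptyenv())
  addk <- function(k, i, e) {
    cur <- if (is.null(adj[[k]])) list() else adj[[k]]
    cur[[length(cur) + 1L]] <- c(i, e)
    adj[[k]] <- cur
  }
  for (i in seq_len(n)) { addk(ends[i, 1L], i, 1L); addk(ends[i, 2L], i, 2L) }
  used <- logical(n)
  chains <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- list(segs2[[start]][1L, ], segs2[[start]][2L, ])
    headk <- ends[start, 1L]; tailk <- ends[start, 2L]
    # extend forward from tail, then backward from head
    repeat {
      nxt <- NULL
      for (cand in adj[[tailk]]) {
        i <- cand[1L]
        if (!used[i]) { nxt <- cand; break }
      }
      if (is.null(nxt)) break
      i <- nxt[1L]; e <- nxt[2L]
      used[i] <- TRUE
      other <- if (e == 1L) 2L else 1L
      pts[[length(pts) + 1L]] <- segs2[[i]][other, ]
      tailk <- ends[i, other]
      if (tailk == headk) break
    }
    closed <- identical(tailk, headk) && length(pts) > 3L
    if (closed) pts <- pts[-length(pts)]  # first != last in storage
    if (!closed) {
      repeat {
        nxt <- NULL
        for (cand in adj[[headk]]) {
          i <- cand[1L]
          if (!used[i]) { nxt <- cand; break }
        }
        if (is.null(nxt)) break
        i <- nxt[1L]; e <- nxt[2L]
        used[i] <- TRUE
        other <- if (e == 1L) 2L else 1L
        pts <- c(list(segs2[[i]][other, ]), pts)
        headk <- ends[i, other]
      }
    }
    chains[[length(chains) + 1L]] <-
      list(points = do.call(rbind, pts), closed = closed)
  }
  chains
}

contour_length <- function(pts, closed) {
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  L <- sum(d)
  if (closed) L <- L + sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2))
  L
}

#' Signed area of a planar polygon (shoelace; CCW positive)
#' @param pts `k x 2` matrix of polygon vertices (first vertex not repeated).
#' @return signed area.
#' @export
polygon_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

# Arc-length resampling of a contour at (approximately) `step` mm.
resample_contour <- function(pts, closed, step) {
  if (closed) pts <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  L <- sum(seg)
  if (L <= 0) stop("empty contour")
  n <- max(if (closed) 4L else 2L, round(L / step))
  s_at <- c(0, cumsum(seg))
  s_new <- if (closed) seq(0, L, length.out = n + 1L)[-(n + 1L)]
           else seq(0, L, length.out = n + 1L)
  idx <- findInterval(s_new, s_at, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(seg))
  t <- (s_new - s_at[idx]) / seg[idx]
  out <- pts[idx, , drop = FALSE] +
    (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE]) * t
  list(points = out, step = L / n, arc = s_new)
}

#' Signed curvature along a planar contour
#'
#' Resamples the contour by arc length and estimates curvature at each sample
#' from the circumscribed circle of the sample and its neighbors at
#' `+/- smooth_window` samples. For counterclockwise contours convex features
#' are positive. Open contours get `NA` at the ends where the window does not
#' fit.
#'
#' @param pts `k x 2` contour points.
#' @param closed logical; whether the contour is a closed loop.
#' @param resample_step arc-length resampling step (mm).
#' @param smooth_window half-window in samples for the circumscribed circle.
#' @return list with `points` (resampled), `curvature` (1/mm, signed), `arc`
#'   (arc-length positions), and `normals` (outward unit normals, CCW
#'   convention).
#' @export
contour_curvature <- function(pts, closed = TRUE, resample_step = 0.5,
                              smooth_window = 5L) {
  pts <- as.matrix(pts)
  rs <- resample_contour(pts, closed, resample_step)
  p <- rs$points
  n <- nrow(p)
  if (n < 5L) stop("contour too short for curvature estimation")
  w <- as.integer(smooth_window)
  idx <- seq_len(n)
  if (closed) {
    im <- ((idx - 1L - w) %% n) + 1L
    ip <- ((idx - 1L + w) %% n) + 1L
    valid <- rep(TRUE, n)
  } else {
    im <- pmax(idx - w, 1L)
    ip <- pmin(idx + w, n)
    valid <- (idx - w >= 1L) & (idx + w <= n)
  }
  a <- p[im, , drop = FALSE]; b <- p; c <- p[ip, , drop = FALSE]
  ab <- b - a; bc <- c - b; ac <- c - a
  la <- sqrt(rowSums(bc^2)); lb <- sqrt(rowSums(ac^2)); lc <- sqrt(rowSums(ab^2))
  cross <- ab[, 1L] * bc[, 2L] - ab[, 2L] * bc[, 1L]
  area2 <- abs(cross)  # = 2 * triangle area
  kappa <- ifelse(area2 < 1e-12, 0, 2 * area2 / pmax(la * lb * lc, 1e-300))
  kappa <- kappa * sign(cross)
  kappa[!valid] <- NA_real_
  # outward normals (right of travel for CCW): tangent from central difference
  tp <- if (closed) p[c(2:n, 1L), ] - p[c(n, 1:(n - 1L)), ]
        else rbind(p[2L, ] - p[1L, ],
                   p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE],
                   p[n, ] - p[n - 1L, ])
  tl <- pmax(sqrt(rowSums(tp^2)), 1e-300)
  tp <- tp / tl
  normals <- cbind(tp[, 2L], -tp[, 1L])
  list(points = p, curvature = kappa, arc = rs$arc, normals = normals,
       step = rs$step, closed = closed)
}

#' Random rotation matrix (uniform over SO(3))
#' @param n ignored; one matrix is returned.
#' @return 3x3 proper orthonormal matrix.
#' @export
random_rotation <- function(n = 1L) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}
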