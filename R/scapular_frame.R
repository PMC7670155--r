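# Scapular coordinate frame from three landmark constructs: the best-fit
# circle center of the inferior glenoid rim (A, the origin), the junction of
# the scapular spine with the medial border (B), and the inferior scapular
# angle (C). Axes: x medial->lateral, y inferior->superior, z posterior->
# anterior, right-handed. An annotated anterior witness point (any point on
# the coracoid or anterior clavicle) fixes the sign of z.

#' Scapular landmark set
#'
#' @param glenoid_rim `n x 3` matrix (n >= 5) of points on the inferior
#'   glenoid rim.
#' @param B 3-vector: scapular spine / medial border junction.
#' @param C 3-vector: most inferior point of the inferior scapular angle.
#' @param AM,PM 3-vectors: anterior / posterior acromioclavicular joint-line
#'   margins.
#' @param anterior_witness 3-vector on the anterior side of the scapular
#'   plane (coracoid or anterior clavicle); disambiguates the z direction.
#' @param side `"left"` or `"right"`.
#' @return object of class `scapular_landmarks`.
#' @export
scapular_landmarks <- function(glenoid_rim, B, C, AM, PM, anterior_witness,
                               side = c("right", "left")) {
  side <- match.arg(side)
  glenoid_rim <- as.matrix(glenoid_rim)
  if (nrow(glenoid_rim) < 5L)
    stop("at least 5 glenoid rim points are required")
  if (anyDuplicated(round(glenoid_rim, 9L)))
    stop("glenoid rim points must be pairwise distinct")
  B <- as.numeric(B); C <- as.numeric(C)
  AM <- as.numeric(AM); PM <- as.numeric(PM)
  anterior_witness <- as.numeric(anterior_witness)
  if (isTRUE(all.equal(B, C))) stop("landmarks B and C must differ")
  if (isTRUE(all.equal(AM, PM))) stop("landmarks AM and PM must differ")
  structure(list(glenoid_rim = glenoid_rim, B = B, C = C, AM = AM, PM = PM,
                 anterior_witness = anterior_witness, side = side),
            class = "scapular_landmarks")
}

#' Best-fit circle of the inferior glenoid rim
#'
#' @param glenoid_rim `n x 3` matrix, n >= 5.
#' @return list with `center` (point A), `radius`, and the fitted plane
#'   `normal`.
#' @export
fit_glenoid_circle <- function(glenoid_rim) {
  glenoid_rim <- as.matrix(glenoid_rim)
  if (nrow(glenoid_rim) < 5L)
    stop("at least 5 glenoid rim points are required")
  fit <- fit_circle_in_plane(glenoid_rim)
  list(center = fit$center, radius = fit$radius, normal = fit$normal)
}

#' Build the scapular coordinate frame
#'
#' The scapular plane is the plane through A (glenoid circle center), B and C.
#' x is the in-plane unit vector from B toward A (medial to lateral); z is the
#' plane normal signed so the anterior witness has positive z; y = z x x.
#' C is required to fall below the origin (negative y) — otherwise the
#' annotation is inconsistent with the anterior witness.
#'
#' @param landmarks a `scapular_landmarks` object.
#' @return object of class `scapular_frame` (an [ortho_frame()] with extra
#'   fields `A` and `glenoid_radius`).
#' @export
build_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "scapular_landmarks"))
  gc <- fit_glenoid_circle(landmarks$glenoid_rim)
  A <- gc$center
  B <- landmarks$B; C <- landmarks$C
  n <- cross3(B - A, C - A)
  nl <- sqrt(sum(n^2))
  if (nl < 1e-9 * max(sqrt(sum((B - A)^2)), 1))
    stop("degenerate geometry: A, B, C are collinear")
  z <- n / nl
  if (sum(z * (landmarks$anterior_witness - A)) < 0) z <- -z
  x <- (A - B) - sum((A - B) * z) * z
  x <- x / sqrt(sum(x^2))
  y <- cross3(z, x)
  # re-orthonormalize (x already unit and orthogonal to z by construction)
  y <- y / sqrt(sum(y^2))
  if (sum(y * (C - A)) > 0)
    stop(paste("inconsistent landmarks: inferior angle C lies above the",
               "origin for the given anterior witness"))
  fr <- ortho_frame(A, x, y, z, tol = 1e-9)
  fr$A <- A
  fr$glenoid_radius <- gc$radius
  class(fr) <- c("scapular_frame", class(fr))
  fr
}

#' Mirror a model across its scapular plane
#'
#' Reflects every mesh vertex and landmark across the plane through A
#' (glenoid circle center), B and C. In-plane landmarks (rim, B, C) are fixed
#' points; the reflection converts a left shoulder into its right-handed
#' mirror twin (and vice versa).
#'
#' @param model a `shoulder_model`.
#' @return the reflected model with the side flag flipped.
#' @export
mirror_model <- function(model) {
  lm <- model$landmarks
  A <- fit_glenoid_circle(lm$glenoid_rim)$center
  pl <- fit_plane_lsq(rbind(A, lm$B, lm$C))
  n <- pl$normal
  refl <- function(p) {
    p <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
    dd <- as.numeric(sweep(p, 2L, A) %*% n)
    p - 2 * outer(dd, n)
  }
  out <- transform_model(model, refl)
  out$side <- if (model$side == "left") "right" else "left"
  out$landmarks$side <- out$side
  # reflection flips triangle orientation; restore outward winding
  for (m in c("scapula", "clavicle", "humerus")) {
    if (!is.null(out[[m]]))
      out[[m]]$faces <- out[[m]]$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  out
}

#' Normalize shoulder side
#'
#' Left shoulders are mirrored across the scapular plane so every downstream
#' measurement uses one right-handed convention; right shoulders pass through
#' unchanged.
#'
#' @param model a `shoulder_model`.
#' @return a right-side `shoulder_model` (attribute `mirrored` records
#'   whether a reflection was applied).
#' @export
normalize_side <- function(model) {
  if (is.null(model$side) || !model$side %in% c("left", "right"))
    stop("unknown shoulder side; expected 'left' or 'right'")
  if (model$side == "right") {
    attr(model, "mirrored") <- FALSE
    return(model)
  }
  out <- mirror_model(model)
  attr(out, "mirrored") <- TRUE
  out
}
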