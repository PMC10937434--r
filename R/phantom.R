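# Synthetic head-and-neck phantom: multi-OAR structure sets with known
# anatomy-like topology (nested, abutting and paired lateral organs),
# patient-to-patient geometric variation, synthetic CT intensities per
# tissue class, and a four-category contour error injector with ground
# truth. The phantom emulates the topology and adjacency of a clinical
# head-and-neck structure set, not anatomical realism.

#' Default phantom OAR roster
#'
#' Nineteen head-and-neck OAR types of varied shape: ellipsoids (brain,
#' eyes, glands), tubes (cord, esophagus, larynx), a box-union mandible, a
#' two-lobed thyroid (two disconnected parts by construction), paired
#' lateral organs mirrored in x, a nested pair (lens inside eye, brainstem
#' partially inside brain) and an abutting pair (cord touching brainstem).
#' Offsets are mm relative to the brainstem center (positive x lateral,
#' y vertical, z longitudinal); the cord and lenses are placed relative to
#' their parent structure so the declared touching/nesting holds for every
#' generated set.
#'
#' @return named list of organ specifications, in CT paint order.
#' @export
defaultRoster <- function() {
  org <- function(shape, offset, ..., hu, hu_sd, paired = FALSE,
                  relative_to = NULL, rot = TRUE, parts = 1L)
    c(list(shape = shape, offset = offset, hu = hu, hu_sd = hu_sd,
           paired = paired, relative_to = relative_to, rot = rot,
           parts = parts), list(...))
  list(
    oral_cavity = org("ellipsoid", c(0, -26, -8), radii = c(20, 16, 10), hu = -150, hu_sd = 80),
    mandible = org("box_union", c(0, 0, 0), boxes = list(
      list(center = c(0, -34, -20), half = c(14, 6, 10)),
      list(center = c(-20, -22, -18), half = c(6, 14, 12)),
      list(center = c(20, -22, -18), half = c(6, 14, 12))),
      hu = 700, hu_sd = 150, rot = FALSE),
    larynx = org("tube", c(0, -18, -52), radius = 12, halfLen = 14, hu = -300, hu_sd = 120),
    esophagus = org("tube", c(0, 12, -62), radius = 4.5, halfLen = 21, hu = 45, hu_sd = 15),
    thyroid = org("paired_ellipsoid", c(0, -16, -72), radii = c(7, 5, 10),
                  pairDx = 11, hu = 90, hu_sd = 20, parts = 2L),
    brain = org("ellipsoid", c(0, -6, 32), radii = c(44, 36, 28), hu = 38, hu_sd = 6),
    brainstem = org("ellipsoid", c(0, 0, 0), radii = c(9, 7.5, 24), hu = 36, hu_sd = 6),
    cord = org("tube", c(0, 0, NA), radius = 4.5, halfLen = 35, hu = 40, hu_sd = 6,
               relative_to = "brainstem", rot = FALSE),
    pituitary = org("ellipsoid", c(0, -14, 24), radii = c(4.5, 3.5, 2.6), hu = 45, hu_sd = 8),
    eye_l = org("ellipsoid", c(29, -34, 24), radii = c(10, 12, 8),
                hu = 20, hu_sd = 8, paired = TRUE, rot = FALSE),
    eye_r = org("ellipsoid", c(-29, -34, 24), radii = c(10, 12, 8),
                hu = 20, hu_sd = 8, paired = TRUE, rot = FALSE),
    lens_l = org("ellipsoid", c(0, -6, 0), radii = c(3.6, 2.2, 2.8), hu = 70, hu_sd = 8,
                 paired = TRUE, relative_to = "eye_l", rot = FALSE),
    lens_r = org("ellipsoid", c(0, -6, 0), radii = c(3.6, 2.2, 2.8), hu = 70, hu_sd = 8,
                 paired = TRUE, relative_to = "eye_r", rot = FALSE),
    cochlea_l = org("ellipsoid", c(31, 2, 16), radii = c(3.6, 2.8, 2.1), hu = 250,
                    hu_sd = 60, paired = TRUE, rot = FALSE),
    cochlea_r = org("ellipsoid", c(-31, 2, 16), radii = c(3.6, 2.8, 2.1), hu = 250,
                    hu_sd = 60, paired = TRUE, rot = FALSE),
    parotid_l = org("ellipsoid", c(33, 4, -4), radii = c(10.5, 9, 15), hu = -10,
                    hu_sd = 12, paired = TRUE),
    parotid_r = org("ellipsoid", c(-33, 4, -4), radii = c(10.5, 9, 15), hu = -10,
                    hu_sd = 12, paired = TRUE),
    submandibular_l = org("ellipsoid", c(19, -14, -28), radii = c(8, 9.5, 6),
                          hu = 30, hu_sd = 10, paired = TRUE),
    submandibular_r = org("ellipsoid", c(-19, -14, -28), radii = c(8, 9.5, 6),
                          hu = 30, hu_sd = 10, paired = TRUE))
}

#' Phantom configuration
#'
#' @param gridDim grid shape in voxels (default 96 x 96 x 96).
#' @param spacing voxel spacing in mm (default 1.27 x 1.27 x 2, typical for
#'   head-and-neck planning CT).
#' @param roster organ roster (see \code{\link{defaultRoster}}); must
#'   include \code{brainstem} and \code{pituitary} (centroid references).
#' @param variation list: \code{global_scale} (per-set uniform scale range),
#'   \code{organ_scale} (per-organ scale range), \code{jitter_sd} /
#'   \code{jitter_max} translation jitter in mm, \code{rel_jitter_sd} for
#'   organs placed relative to a parent, \code{rot_sd_deg} rotation jitter
#'   about z.
#' @param huBackground background (air) HU.
#' @param noiseSd background CT noise standard deviation.
#' @return a PhantomConfig list.
#' @export
phantomConfig <- function(gridDim = c(96, 96, 96),
                          spacing = c(1.27, 1.27, 2),
                          roster = defaultRoster(),
                          variation = list(global_scale = c(0.9, 1.1),
                                           organ_scale = c(0.88, 1.12),
                                           aspect = c(0.92, 1.08),
                                           aspect_z = c(0.85, 1.15),
                                           jitter_sd = 2.5, jitter_max = 5,
                                           rel_jitter_sd = 0.3,
                                           rot_sd_deg = 5,
                                           tube_tilt_sd_deg = 2),
                          huBackground = -1000, noiseSd = 10) {
  stopifnot(all(c("brainstem", "pituitary") %in% names(roster)))
  structure(list(gridDim = gridDim, spacing = spacing, roster = roster,
                 variation = variation, huBackground = huBackground,
                 noiseSd = noiseSd),
            class = "PhantomConfig")
}

# ---- shape rasterizers ------------------------------------------------

subgridArrays <- function(axes, ix, iy, iz) {
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  list(X = array(axes$x[ix], c(nx, ny, nz)),
       Y = array(rep(axes$y[iy], each = nx), c(nx, ny, nz)),
       Z = array(rep(axes$z[iz], each = nx * ny), c(nx, ny, nz)),
       ix = ix, iy = iy, iz = iz)
}

clampRange <- function(lo, hi, n) {
  lo <- max(1L, lo); hi <- min(n, hi)
  if (lo > hi) integer() else lo:hi
}

boundingIdx <- function(axes, center, halfwidth, dim) {
  list(ix = clampRange(findInterval(center[1] - halfwidth[1], axes$x),
                       findInterval(center[1] + halfwidth[1], axes$x) + 1L, dim[1]),
       iy = clampRange(findInterval(center[2] - halfwidth[2], axes$y),
                       findInterval(center[2] + halfwidth[2], axes$y) + 1L, dim[2]),
       iz = clampRange(findInterval(center[3] - halfwidth[3], axes$z),
                       findInterval(center[3] + halfwidth[3], axes$z) + 1L, dim[3]))
}

placeSub <- function(dim, sub, predicate) {
  out <- array(FALSE, dim)
  if (!length(sub$ix) || !length(sub$iy) || !length(sub$iz)) return(out)
  out[sub$ix, sub$iy, sub$iz] <- predicate
  out
}

# small rigid rotation from per-axis angles (radians)
rotationMatrix <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# coordinates of the subgrid in the organ frame (columns qx, qy, qz)
organFrame <- function(g, center, R) {
  dx <- g$X - center[1]; dy <- g$Y - center[2]; dz <- g$Z - center[3]
  list(qx = R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz,
       qy = R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz,
       qz = R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz)
}

rasterEllipsoid <- function(dim, axes, center, radii, rot = diag(3)) {
  hw <- rep(max(radii) + 1, 3)
  bi <- boundingIdx(axes, center, hw, dim)
  g <- subgridArrays(axes, bi$ix, bi$iy, bi$iz)
  q <- organFrame(g, center, rot)
  pred <- (q$qx / radii[1])^2 + (q$qy / radii[2])^2 +
    (q$qz / radii[3])^2 <= 1
  placeSub(dim, g, pred)
}

rasterTube <- function(dim, axes, center, radius, halfLen, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  hw <- abs(axis) * halfLen + radius + 1
  bi <- boundingIdx(axes, center, hw, dim)
  g <- subgridArrays(axes, bi$ix, bi$iy, bi$iz)
  dx <- g$X - center[1]; dy <- g$Y - center[2]; dz <- g$Z - center[3]
  t <- dx * axis[1] + dy * axis[2] + dz * axis[3]
  r2 <- (dx - t * axis[1])^2 + (dy - t * axis[2])^2 + (dz - t * axis[3])^2
  pred <- abs(t) <= halfLen & r2 <= radius^2
  placeSub(dim, g, pred)
}

rasterBoxes <- function(dim, axes, center, boxes, scale = 1, rot = diag(3)) {
  out <- array(FALSE, dim)
  reach <- max(vapply(boxes, function(b)
    sqrt(sum((abs(b$center) + b$half)^2)), numeric(1))) * scale + 1
  bi <- boundingIdx(axes, center, rep(reach, 3), dim)
  g <- subgridArrays(axes, bi$ix, bi$iy, bi$iz)
  q <- organFrame(g, center, rot)
  pred <- array(FALSE, dim(q$qx))
  for (b in boxes) {
    c0 <- b$center * scale
    h <- b$half * scale
    pred <- pred | (abs(q$qx - c0[1]) <= h[1] & abs(q$qy - c0[2]) <= h[2] &
                    abs(q$qz - c0[3]) <= h[3])
  }
  out[g$ix, g$iy, g$iz] <- pred
  out
}

rasterOrgan <- function(spec, dim, axes, center, scale, rot = diag(3),
                        aspect = c(1, 1, 1), axis = c(0, 0, 1)) {
  switch(spec$shape,
    ellipsoid = rasterEllipsoid(dim, axes, center, spec$radii * scale * aspect,
                                rot),
    tube = rasterTube(dim, axes, center,
                      spec$radius * scale * mean(aspect[1:2]),
                      spec$halfLen * scale * aspect[3], axis = axis),
    box_union = rasterBoxes(dim, axes, center, spec$boxes,
                            scale * mean(aspect), rot),
    paired_ellipsoid = {
      dx <- spec$pairDx * scale
      lobe <- spec$radii * scale * aspect
      rasterEllipsoid(dim, axes, center + rot %*% c(dx, 0, 0), lobe, rot) |
        rasterEllipsoid(dim, axes, center - rot %*% c(dx, 0, 0), lobe, rot)
    },
    stop("unknown shape: ", spec$shape))
}

touchesBorder <- function(m) {
  d <- dim(m)
  any(m[1, , ]) || any(m[d[1], , ]) || any(m[, 1, ]) || any(m[, d[2], ]) ||
    any(m[, , 1]) || any(m[, , d[3]])
}

# ---- structure-set generation ----------------------------------------

#' Generate one synthetic structure set
#'
#' Rasterizes every roster organ with per-set and per-organ geometric
#' variation, builds the body contour and a synthetic CT (organ HU mean plus
#' Gaussian noise painted over a noisy air background), and returns a
#' complete \linkS4class{StructureSet}. Deterministic given \code{seed}.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param seed RNG seed.
#' @param setId identifier stored on the set and its contours.
#' @return a \linkS4class{StructureSet} with an attached image and body
#'   contour.
#' @export
generateStructureSet <- function(config, seed = 1, setId = sprintf("set%04d", seed)) {
  set.seed(seed)
  dim <- config$gridDim; sp <- config$spacing
  axes <- gridAxes(dim, sp)
  va <- config$variation
  g <- runif(1, va$global_scale[1], va$global_scale[2])
  base <- c((dim[1] - 1) * sp[1] / 2, (dim[2] - 1) * sp[2] / 2,
            (dim[3] - 1) * sp[3] * 0.59)
  jit <- function(sd = va$jitter_sd, mx = va$jitter_max)
    pmin(pmax(rnorm(3, 0, sd), -mx), mx)
  bsCenter <- base + jit()

  centers <- list()
  masks <- list()
  scales <- list()
  for (nm in names(config$roster)) {
    spec <- config$roster[[nm]]
    s <- g * runif(1, va$organ_scale[1], va$organ_scale[2])
    asp <- if (is.null(va$aspect)) c(1, 1, 1)
           else runif(3, va$aspect[1], va$aspect[2])
    # longitudinal extent varies more than in-plane shape: observers
    # disagree most on the first and last contoured slice of an organ
    if (!is.null(va$aspect_z))
      asp[3] <- runif(1, va$aspect_z[1], va$aspect_z[2])
    # every organ carries a small 3D orientation jitter: anatomy is never
    # exactly grid-aligned, so no eigenvector component is variance-free
    rot <- rotationMatrix(rnorm(3, 0, va$rot_sd_deg) * pi / 180)
    tubeAxis <- c(0, 0, 1)
    if (spec$shape == "tube" && !is.null(va$tube_tilt_sd_deg)) {
      # necks flex: tubular organs are never perfectly slice-aligned
      th <- abs(rnorm(1, 0, va$tube_tilt_sd_deg)) * pi / 180
      az <- runif(1, 0, 2 * pi)
      tubeAxis <- c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
    }
    if (!is.null(spec$relative_to)) {
      parent <- centers[[spec$relative_to]]
      if (is.null(parent)) stop("parent '", spec$relative_to, "' not yet placed")
      # nested/abutting organs scale with their parent (a lens scales with
      # its eye), with only a small independent factor
      s <- scales[[spec$relative_to]] * runif(1, 0.95, 1.05)
      if (nm == "cord" || (spec$shape == "tube" && anyNA(spec$offset))) {
        # abutting pair: tube top overlaps the parent's inferior tip by 4 mm
        pm <- masks[[spec$relative_to]]
        zBottom <- axes$z[min(which(apply(pm, 3, any)))]
        halfLen <- spec$halfLen * s
        topZ <- zBottom + 4
        cz <- topZ - halfLen
        if (cz - halfLen < axes$z[2]) {  # clamp inside the grid
          halfLen <- (topZ - axes$z[2]) / 2
          cz <- topZ - halfLen
        }
        center <- c(parent[1:2] + rnorm(2, 0, va$rel_jitter_sd), cz)
        m <- rasterTube(dim, axes, center, spec$radius * s, halfLen,
                        axis = tubeAxis)
      } else {
        # nested organ: placed relative to the parent center, small jitter
        center <- parent + spec$offset * scales[[spec$relative_to]] +
          rnorm(3, 0, va$rel_jitter_sd)
        m <- rasterOrgan(spec, dim, axes, center, s, rot, asp, tubeAxis)
      }
    } else {
      center <- bsCenter + spec$offset * g + jit()
      m <- rasterOrgan(spec, dim, axes, center, s, rot, asp, tubeAxis)
      if (!sum(m) || touchesBorder(m)) {
        warning("organ '", nm, "' left the grid; regenerating with clamped jitter")
        center <- bsCenter + spec$offset * g
        m <- rasterOrgan(spec, dim, axes, center, s, rot, asp, tubeAxis)
      }
    }
    if (!sum(m)) stop("organ '", nm, "' rasterized empty")
    centers[[nm]] <- center
    scales[[nm]] <- s
    masks[[nm]] <- m
  }

  # body: elliptical cylinder enclosing all organs (fixed envelope so no
  # organ surface ever mixes with air, as eyelids and skin ensure in vivo)
  bodyCenter <- c(bsCenter[1], bsCenter[2] - 12, (dim[3] - 1) * sp[3] / 2)
  bodyR <- c(58, 56)
  bi <- boundingIdx(axes, bodyCenter, c(bodyR + 1, (dim[3] - 1) * sp[3] / 2), dim)
  gsub <- subgridArrays(axes, bi$ix, bi$iy, 2:(dim[3] - 1))
  bodyPred <- ((gsub$X - bodyCenter[1]) / bodyR[1])^2 +
    ((gsub$Y - bodyCenter[2]) / bodyR[2])^2 <= 1
  bodyMask <- placeSub(dim, gsub, bodyPred)
  for (nm in names(masks)) bodyMask <- bodyMask | masks[[nm]]

  # synthetic CT: tissue-class means with texture, a per-scan calibration
  # shift and per-organ composition variability (real HU vary between
  # scans and patients), blurred by the scanner point-spread function
  # (partial-volume mixing at every boundary), plus detector noise
  img <- array(rnorm(prod(dim), config$huBackground, config$noiseSd), dim)
  huShift <- rnorm(1, 0, 6)
  nb <- sum(bodyMask)
  img[bodyMask] <- rnorm(nb, 35 + huShift, 12 * runif(1, 0.85, 1.25))
  for (nm in names(config$roster)) {
    spec <- config$roster[[nm]]
    n <- sum(masks[[nm]])
    img[masks[[nm]]] <- rnorm(n, spec$hu + huShift + rnorm(1, 0, 3),
                              spec$hu_sd * runif(1, 0.85, 1.25))
  }
  # spatially correlated texture: real tissue is not white noise, and the
  # texture a contour samples varies from scan to scan
  txt <- .cq_smooth3(rnorm(prod(dim)), as.integer(dim), rep(2, 3))
  img <- img + txt / stats::sd(txt) * 8
  img <- array(.cq_smooth3(as.numeric(img), as.integer(dim), rep(0.8, 3)), dim)
  img <- img + rnorm(prod(dim), 0, 5)

  cts <- lapply(names(masks), function(nm)
    Contour(masks[[nm]], nm, setId = setId, truthLabel = "acceptable"))
  names(cts) <- names(masks)
  StructureSet(contours = cts,
               image = ImageVolume(img, spacing = sp),
               body = Contour(bodyMask, "body", setId = setId,
                              truthLabel = "acceptable"),
               setId = setId)
}

# ---- error injection --------------------------------------------------

#' Specify a contour error to inject
#'
#' Default magnitudes: moderate = boundary +/-2 mm, volume 10-20%, one
#' ditzel with >= 5 mm gap, position 10-15 mm; major = boundary 4-6 mm,
#' volume 30-50%, two ditzels with >= 10 mm gap, position 25-35 mm (or a
#' label swap when \code{swap_mask} is supplied). Major magnitudes are
#' chosen to be relevant in nearly all clinical contexts; moderate ones may
#' or may not be, depending on context.
#'
#' @param category one of \code{boundary}, \code{volume},
#'   \code{nonadjacent_slice}, \code{position}.
#' @param severity \code{moderate} or \code{major}.
#' @param seed RNG seed for the injection.
#' @param params optional list overriding magnitudes: \code{radius_mm},
#'   \code{direction} (\code{dilate}/\code{erode}) for boundary;
#'   \code{fraction}, \code{mode} (\code{add}/\code{remove}/\code{truncate})
#'   for volume; \code{gap_mm}, \code{n_ditzels}, \code{mode}
#'   (\code{ditzel}/\code{jag}) for nonadjacent_slice; \code{offset_mm}
#'   (scalar magnitude or length-3 vector) or \code{swap_mask} for position.
#' @return an ErrorSpec list.
#' @export
errorSpec <- function(category = c("boundary", "volume", "nonadjacent_slice",
                                   "position"),
                      severity = c("moderate", "major"),
                      seed = 1, params = list()) {
  category <- match.arg(category)
  severity <- match.arg(severity)
  structure(list(category = category, severity = severity, seed = seed,
                 params = params), class = "ErrorSpec")
}

#' Inject a contour error
#'
#' Applies the four error-category semantics to a contour mask: boundary
#' (isotropic dilation/erosion in mm), volume (attach or carve a convex blob,
#' or truncate terminal slices), non-adjacent slice (disconnected single-slice
#' "ditzel" at a configured gap, or jagged per-slice shifts), position
#' (whole-mask translation, or mask swap). The image is never modified: an
#' erroneous contour covers tissue it should not, as in clinical failures.
#' Deterministic given \code{spec$seed}.
#'
#' @param contour a \linkS4class{Contour}.
#' @param image the set's \linkS4class{ImageVolume} (geometry reference; may
#'   be NULL for mask-only grids).
#' @param spec an \code{\link{errorSpec}}.
#' @param spacing voxel spacing in mm (taken from \code{image} when given).
#' @return a new \linkS4class{Contour} with \code{truthLabel = "erroneous"}
#'   and \code{errorMeta} describing the applied operator.
#' @export
injectError <- function(contour, image = NULL, spec = errorSpec(),
                        spacing = NULL) {
  if (is.null(spacing))
    spacing <- if (!is.null(image)) voxelSpacing(image) else c(1, 1, 1)
  m <- mask(contour)
  if (!sum(m)) stop("cannot inject an error into an empty contour")
  set.seed(spec$seed)
  p <- spec$params
  meta <- list(category = spec$category, severity = spec$severity)
  newMask <- switch(spec$category,
    boundary = {
      r <- p$radius_mm %||%
        if (spec$severity == "moderate") 2 else runif(1, 4, 6)
      dir <- p$direction %||% sample(c("dilate", "erode"), 1)
      out <- if (dir == "dilate") dilateMask(m, spacing, r)
             else erodeMask(m, spacing, r)
      if (!sum(out)) stop("boundary erosion emptied the mask; magnitude too large")
      meta$radius_mm <- r; meta$direction <- dir
      out
    },
    volume = {
      frac <- p$fraction %||%
        if (spec$severity == "moderate") runif(1, 0.10, 0.20) else runif(1, 0.30, 0.50)
      mode <- p$mode %||% sample(c("add", "remove", "truncate"), 1)
      meta$fraction <- frac; meta$mode <- mode
      injectVolumeError(m, spacing, frac, mode)
    },
    nonadjacent_slice = {
      # moderate: a stray disconnected single-slice "ditzel"; major:
      # jagged slice-to-slice misalignment of the whole contour
      mode <- p$mode %||% if (spec$severity == "moderate") "ditzel" else "jag"
      if (mode == "jag") {
        meta$mode <- "jag"
        injectJag(m, p$shift_vox %||% 2L)
      } else {
        gap <- p$gap_mm %||% 5
        nd <- p$n_ditzels %||% 1L
        meta$mode <- "ditzel"; meta$gap_mm <- gap; meta$n_ditzels <- nd
        img <- if (!is.null(image)) voxels(image) else NULL
        out <- m
        for (i in seq_len(nd)) out <- addDitzel(out, spacing, gap, img)
        out
      }
    },
    position = {
      if (!is.null(p$swap_mask)) {
        meta$mode <- "swap"
        p$swap_mask
      } else {
        off <- p$offset_mm
        if (is.null(off)) {
          mag <- if (spec$severity == "moderate") runif(1, 10, 15) else runif(1, 25, 35)
          u <- rnorm(3); u[3] <- 0.3 * u[3]
          off <- mag * u / sqrt(sum(u^2))
        } else if (length(off) == 1) {
          u <- rnorm(3); u[3] <- 0.3 * u[3]
          off <- off * u / sqrt(sum(u^2))
        }
        meta$mode <- "translate"
        translateInGrid(m, spacing, off, meta)
      }
    })
  if (spec$category == "position" && is.null(p$swap_mask)) {
    meta <- attr(newMask, "meta") %||% meta
    attr(newMask, "meta") <- NULL
  }
  if (identical(newMask, m)) stop("error injection left the mask unchanged")
  Contour(newMask, oarType(contour), setId = setId(contour),
          truthLabel = "erroneous", errorMeta = meta)
}

translateInGrid <- function(m, spacing, off, meta) {
  shift <- as.integer(round(off / spacing))
  out <- shiftMask(m, shift)
  if (sum(out) < sum(m)) {          # part fell off the grid: flip direction
    shift <- -shift
    out <- shiftMask(m, shift)
  }
  if (sum(out) < sum(m)) {          # still clipped: clamp to stay on-grid
    idx <- which(m, arr.ind = TRUE)
    lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
    shift <- pmin(pmax(shift, -(lo - 1L)), dim(m) - hi)
    out <- shiftMask(m, as.integer(shift))
  }
  meta$offset_mm <- shift * spacing
  attr(out, "meta") <- meta
  out
}

injectVolumeError <- function(m, spacing, frac, mode) {
  V <- sum(m)
  if (mode == "truncate") {
    zs <- which(apply(m, 3, any))
    k <- max(1L, as.integer(ceiling(frac * length(zs))))
    if (k >= length(zs)) k <- length(zs) - 1L
    if (k < 1L) return(injectVolumeError(m, spacing, frac, "add"))
    drop <- if (runif(1) < 0.5) utils::tail(zs, k) else utils::head(zs, k)
    out <- m
    out[, , drop] <- FALSE
    return(out)
  }
  bIdx <- which(boundaryMask(m) & m, arr.ind = TRUE)
  pick <- bIdx[sample(nrow(bIdx), 1), ]
  center <- (pick - 1) * spacing
  # blob volume ~ 2 * frac * V voxels: roughly half lands on the target
  # side; never smaller than a voxel so the operator always has an effect
  r <- max((3 * (2 * frac * V * prod(spacing)) / (4 * pi))^(1 / 3),
           1.1 * max(spacing))
  for (try in 1:4) {
    blob <- rasterEllipsoid(dim(m), gridAxes(dim(m), spacing), center,
                            rep(r, 3))
    out <- if (mode == "add") m | blob else m & !blob
    if (sum(out) != V) break
    r <- 1.5 * r
  }
  if (mode == "remove" && (sum(out) < 0.2 * V || !sum(out)))
    stop("volume removal left too little of the mask; magnitude too large")
  out
}

placeDisc <- function(m, center, spacing, rd = 1.8) {
  d <- dim(m)
  cx <- center[1]; cy <- center[2]; z <- center[3]
  rvox <- pmax(1L, as.integer(round(rd / spacing[1:2])))
  ix <- clampRange(cx - rvox[1], cx + rvox[1], d[1])
  iy <- clampRange(cy - rvox[2], cy + rvox[2], d[2])
  disc <- outer(((ix - cx) * spacing[1])^2, ((iy - cy) * spacing[2])^2, "+") <= rd^2
  m[ix, iy, z] <- m[ix, iy, z] | disc
  m
}

addDitzel <- function(m, spacing, gap, img = NULL) {
  # a clinical misclick is a stray single-slice contour near the organ:
  # place the disc at a random location in the organ's (slightly expanded)
  # bounding box that keeps at least `gap` mm clearance from the mask and,
  # when a CT is available, lies on soft tissue (misclicks happen on
  # anatomy, not in air), so single-contour features barely react and only
  # the parts count changes; fall back to a slice beyond the organ's ends
  # when no such spot exists
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  rd <- 1.8
  pad <- ceiling((gap + 2 * rd) / spacing)
  lo0 <- pmax(2L, apply(idx, 2, min)); hi0 <- pmin(d - 1L, apply(idx, 2, max))
  lo <- pmax(2L, lo0 - as.integer(pad))
  hi <- pmin(d - 1L, hi0 + as.integer(pad))
  bnd <- voxelCoords(boundaryMask(m), spacing)
  minC <- gap + rd + 1   # center clearance guaranteeing surface gap >= gap
  maxC <- gap + rd + 6
  # prefer spots inside the organ's own bounding box (concavities,
  # corners), then directly above/below within the organ's xy footprint
  # (small relative change of the longitudinal extent), then anywhere in
  # the padded box -- always on soft tissue; a fourth pass accepts any
  # in-body location before giving up on tissue altogether
  for (phase in 1:5) {
    l <- switch(phase, lo0, c(lo0[1:2], lo[3]), lo, lo, lo)
    h <- switch(phase, hi0, c(hi0[1:2], hi[3]), hi, hi, hi)
    for (t in seq_len(200)) {
      cand <- c(sample(l[1]:h[1], 1), sample(l[2]:h[2], 1),
                sample(l[3]:h[3], 1))
      if (m[cand[1], cand[2], cand[3]]) next   # inside the organ
      if (!is.null(img) && phase < 5) {
        # the whole disc footprint must satisfy the tissue constraint,
        # not just its center voxel
        rvox <- pmax(1L, as.integer(round(rd / spacing[1:2])))
        ix <- clampRange(cand[1] - rvox[1], cand[1] + rvox[1], d[1])
        iy <- clampRange(cand[2] - rvox[2], cand[2] + rvox[2], d[2])
        hu <- range(img[ix, iy, cand[3]])
        if (phase < 4 && (hu[1] < -100 || hu[2] > 150)) next  # soft tissue
        if (phase == 4 && hu[1] < -350) next                  # in-body
      }
      p <- matrix((cand - 1) * spacing, 1)
      dist <- .cq_min_dist(p, bnd)
      if (dist >= minC && dist <= maxC)
        return(placeDisc(m, cand, spacing, rd))
    }
  }
  zs <- which(apply(m, 3, any))
  gapSlices <- as.integer(ceiling((gap + 1) / spacing[3]))
  cx <- round(mean(idx[, 1])); cy <- round(mean(idx[, 2]))
  zAbove <- max(zs) + gapSlices + 1L
  zBelow <- min(zs) - gapSlices - 1L
  if (zAbove <= d[3] - 1) z <- zAbove
  else if (zBelow >= 2) z <- zBelow
  else stop("no room for a ditzel on this grid")
  placeDisc(m, c(cx, cy, z), spacing, rd)
}

injectJag <- function(m, shiftVox) {
  zs <- which(apply(m, 3, any))
  out <- m
  for (i in seq_along(zs)) {
    if (i %% 2 == 0) next
    s <- if ((i %/% 2) %% 2 == 0) shiftVox else -shiftVox
    sl <- m[, , zs[i]]
    d <- dim(sl)
    ns <- matrix(FALSE, d[1], d[2])
    if (s > 0) ns[(1 + s):d[1], ] <- sl[1:(d[1] - s), ]
    else ns[1:(d[1] + s), ] <- sl[(1 - s):d[1], ]
    out[, , zs[i]] <- ns
  }
  out
}

#' Default CCR pairs for the phantom roster
#'
#' Nested, abutting and near pairs among the default roster, directional
#' (selected, comparison); combined with a body column by
#' \code{\link{ccrMatrix}}.
#'
#' @return two-column character matrix.
#' @export
defaultCcrPairs <- function() {
  rbind(c("brainstem", "brain"), c("brain", "brainstem"),
        c("cord", "brainstem"), c("brainstem", "cord"),
        c("pituitary", "brainstem"),
        c("lens_l", "eye_l"), c("eye_l", "lens_l"),
        c("lens_r", "eye_r"), c("eye_r", "lens_r"),
        c("parotid_l", "mandible"),
        c("parotid_r", "mandible"),
        c("submandibular_l", "mandible"),
        c("submandibular_r", "mandible"),
        c("oral_cavity", "mandible"), c("mandible", "oral_cavity"),
        c("thyroid", "larynx"), c("larynx", "thyroid"),
        c("esophagus", "cord"), c("cord", "esophagus"))
}

#' Default CCR matrix for the phantom roster
#' @param roster organ roster.
#' @return logical matrix (see \code{\link{ccrMatrix}}).
#' @export
defaultCcrMatrix <- function(roster = defaultRoster()) {
  ccrMatrix(names(roster), pairs = defaultCcrPairs(), body = TRUE)
}
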