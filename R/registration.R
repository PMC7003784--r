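# Landmark-based registration into a common reference space.  Right facial
# sides are mirrored onto the left; the reference shape is the mean landmark
# configuration; each face is warped onto it with a thin-plate spline (TPS)
# interpolant, which is landmark-exact and reproduces affine maps, with a
# fold-over (non-diffeomorphism) diagnostic on the Jacobian.
#
# Coordinate convention: 0-based, origin top-left, x rightward, y downward,
# pixel centres at integer coordinates.  Matrix element [r, c] (1-based)
# holds pixel (x = c - 1, y = r - 1).

#' Landmark set container
#'
#' @param points `n x 2` matrix of (x, y) pixel coordinates (0-based,
#'   origin top-left).  Studies in this package use 60 anatomical points in
#'   a consistent ordering across all images.
#' @param image_id identifier of the image the landmarks belong to.
#' @param n_required required number of points (default 60).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, image_id = "", n_required = 60L) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, all(is.finite(points)))
  if (!is.null(n_required) && nrow(points) != n_required)
    stop("landmark_set: expected ", n_required, " points, got ", nrow(points))
  colnames(points) <- c("x", "y")
  structure(list(points = points, image_id = as.character(image_id)),
            class = "landmark_set")
}

#' Read landmarks from a JSON file
#'
#' Format: `{"image_id": str, "points": [[x, y], ...]}`.
#'
#' @param path JSON file path.
#' @param n_required required number of points (default 60).
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path, n_required = 60L) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(j$points, image_id = j$image_id %||% "", n_required = n_required)
}

#' Write landmarks to a JSON file
#' @param lm a [landmark_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  jsonlite::write_json(list(image_id = lm$image_id,
                            points = unname(lm$points)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mirror a right-side image and its landmarks
#'
#' Flips the image about the vertical axis (`x <- width - 1 - x` for the
#' landmarks) and remaps the anatomical ordering with `mirror_index` so
#' that mirrored right-side landmarks correspond index-wise to left-side
#' landmarks.  Applying the operation twice returns the input bit-exactly
#' when `mirror_index` is an involution (the identity included).
#'
#' @param img an [rgb_image] or [lab_image].
#' @param lm the matching [landmark_set].
#' @param mirror_index integer permutation mapping mirrored indices to
#'   left-side anatomical order; the default identity is appropriate when
#'   right-side landmark files are already stored in mirror-corresponding
#'   order.
#' @return `list(image = , landmarks = )`.
#' @export
mirror_right_side <- function(img, lm, mirror_index = seq_len(nrow(lm$points))) {
  px <- if (inherits(img, "rgb_image") || inherits(img, "lab_image")) img$pixels
        else stop("img must be rgb_image or lab_image")
  d <- dim(px)
  W <- d[2]
  flipped <- px[, W:1, , drop = FALSE]
  out <- if (inherits(img, "rgb_image")) rgb_image(flipped)
         else lab_image(flipped, mask = img$mask[, W:1, drop = FALSE])
  p <- lm$points
  p[, 1] <- (W - 1) - p[, 1]
  p <- p[mirror_index, , drop = FALSE]
  list(image = out,
       landmarks = landmark_set(p, image_id = lm$image_id,
                                n_required = nrow(p)))
}

#' Estimate the common reference shape
#'
#' The reference space is the coordinate-wise mean of the landmark sets
#' (faces are position-normalized at acquisition, so no Procrustes
#' alignment is applied), together with the output raster dimensions.
#'
#' @param landmarks list of [landmark_set]s with consistent ordering.
#' @param width,height reference raster dimensions in pixels.
#' @return An object of class `reference_space` with fields `mean_points`,
#'   `width`, `height`.
#' @export
estimate_reference_shape <- function(landmarks, width, height) {
  stopifnot(length(landmarks) >= 2L)
  n <- nrow(landmarks[[1]]$points)
  for (lm in landmarks)
    if (nrow(lm$points) != n)
      stop("inconsistent landmark point counts across images")
  mp <- Reduce(`+`, lapply(landmarks, function(l) l$points)) / length(landmarks)
  structure(list(mean_points = mp, width = as.integer(width),
                 height = as.integer(height)),
            class = "reference_space")
}

# Thin-plate spline radial kernel U(r) = r^2 log r, as 0.5 r^2 log r^2
# evaluated from squared distances; U(0) = 0.
.tps_kernel_sq <- function(r2) {
  out <- 0.5 * r2 * log(r2)
  out[r2 == 0] <- 0
  out
}

# Solve one TPS channel: f(p) = a0 + a1 x + a2 y + sum_i w_i U(|p - c_i|)
# interpolating f(ctrl[i, ]) = val[i].  Returns list(w, a).
.tps_solve <- function(ctrl, val, lambda = 0) {
  n <- nrow(ctrl)
  d2 <- outer(ctrl[, 1], ctrl[, 1], `-`)^2 + outer(ctrl[, 2], ctrl[, 2], `-`)^2
  if (any(d2[upper.tri(d2)] == 0))
    stop("coincident duplicate landmarks: TPS system is singular")
  K <- .tps_kernel_sq(d2) + diag(lambda, n)
  P <- cbind(1, ctrl)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(val, 0, 0, 0)
  sol <- solve(L, rhs)
  list(w = sol[1:n], a = sol[n + 1:3])
}

.tps_eval <- function(fit, ctrl, x, y) {
  d2 <- outer(x, ctrl[, 1], `-`)^2 + outer(y, ctrl[, 2], `-`)^2
  as.numeric(.tps_kernel_sq(d2) %*% fit$w + fit$a[1] + fit$a[2] * x + fit$a[3] * y)
}

#' Build the warp from reference space into a source image
#'
#' Fits a thin-plate spline mapping the reference landmarks onto the source
#' landmarks and evaluates it on the full reference raster, yielding for
#' each reference pixel the source coordinate to sample.  With
#' `lambda = 0` the warp is an exact interpolant: every reference landmark
#' maps onto its source landmark to numerical precision, and pure affine
#' landmark displacements (translations included) are reproduced exactly
#' everywhere.  The Jacobian determinant is probed on a 16 x 16 grid; any
#' non-positive value (a fold, i.e. local loss of diffeomorphism) raises a
#' warning and is recorded in the `folded` field.
#'
#' @param source_lm [landmark_set] of the source image.
#' @param ref a `reference_space`.
#' @param lambda non-negative TPS regularization weight (0 = exact
#'   interpolation).
#' @return An object of class `warp_field` with `map_x`, `map_y`
#'   (`height x width` matrices of source coordinates) and `folded`
#'   (logical).
#' @export
build_warp <- function(source_lm, ref, lambda = 0) {
  stopifnot(inherits(source_lm, "landmark_set"), inherits(ref, "reference_space"))
  ctrl <- ref$mean_points
  if (nrow(ctrl) != nrow(source_lm$points))
    stop("landmark count mismatch between source and reference")
  fx <- .tps_solve(ctrl, source_lm$points[, 1], lambda)
  fy <- .tps_solve(ctrl, source_lm$points[, 2], lambda)
  W <- ref$width; H <- ref$height
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), times = W)
  map_x <- matrix(.tps_eval(fx, ctrl, gx, gy), H, W)
  map_y <- matrix(.tps_eval(fy, ctrl, gx, gy), H, W)
  # fold-over probe: central-difference Jacobian on a 16 x 16 grid
  px <- seq(0, W - 1, length.out = 16)
  py <- seq(0, H - 1, length.out = 16)
  g <- expand.grid(x = px, y = py)
  h <- 0.5
  dxdx <- (.tps_eval(fx, ctrl, g$x + h, g$y) - .tps_eval(fx, ctrl, g$x - h, g$y)) / (2 * h)
  dxdy <- (.tps_eval(fx, ctrl, g$x, g$y + h) - .tps_eval(fx, ctrl, g$x, g$y - h)) / (2 * h)
  dydx <- (.tps_eval(fy, ctrl, g$x + h, g$y) - .tps_eval(fy, ctrl, g$x - h, g$y)) / (2 * h)
  dydy <- (.tps_eval(fy, ctrl, g$x, g$y + h) - .tps_eval(fy, ctrl, g$x, g$y - h)) / (2 * h)
  detJ <- dxdx * dydy - dxdy * dydx
  folded <- any(detJ <= 0)
  if (folded) warning("warp field folds over (Jacobian <= 0 on probe grid)")
  structure(list(map_x = map_x, map_y = map_y, folded = folded,
                 width = W, height = H),
            class = "warp_field")
}

#' Map reference-space points through the landmark warp
#'
#' Evaluates the fitted thin-plate spline at arbitrary reference
#' coordinates (not just the pixel grid), e.g. to verify that every
#' reference landmark maps exactly onto its source landmark.
#'
#' @param source_lm,ref,lambda as in [build_warp()].
#' @param points `n x 2` matrix of reference-space (x, y) coordinates;
#'   default the reference landmarks themselves.
#' @return `n x 2` matrix of source-image coordinates.
#' @export
warp_points <- function(source_lm, ref, points = ref$mean_points, lambda = 0) {
  ctrl <- ref$mean_points
  fx <- .tps_solve(ctrl, source_lm$points[, 1], lambda)
  fy <- .tps_solve(ctrl, source_lm$points[, 2], lambda)
  cbind(.tps_eval(fx, ctrl, points[, 1], points[, 2]),
        .tps_eval(fy, ctrl, points[, 1], points[, 2]))
}

# Bilinear sampling of matrix `m` (H x W, 0-based pixel coords) at (x, y)
# vectors.  Returns list(values, valid); invalid outside [0, W-1] x
# [0, H-1].  Samples exactly on the right/bottom edge fall into the last
# interior cell with fractional weight 1.
.bilinear <- function(m, x, y) {
  H <- nrow(m); W <- ncol(m)
  valid <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1 & is.finite(x) & is.finite(y)
  xs <- pmin(pmax(floor(x), 0), W - 2)
  ys <- pmin(pmax(floor(y), 0), H - 2)
  fx <- pmin(pmax(x - xs, 0), 1); fy <- pmin(pmax(y - ys, 0), 1)
  fx[!valid] <- 0; fy[!valid] <- 0; xs[!valid] <- 0; ys[!valid] <- 0
  i00 <- cbind(ys + 1, xs + 1); i01 <- cbind(ys + 1, xs + 2)
  i10 <- cbind(ys + 2, xs + 1); i11 <- cbind(ys + 2, xs + 2)
  v <- (1 - fy) * ((1 - fx) * m[i00] + fx * m[i01]) +
       fy * ((1 - fx) * m[i10] + fx * m[i11])
  list(values = v, valid = valid)
}

#' Warp an image into the reference space
#'
#' Bilinear sampling at the warp-field coordinates.  Samples falling
#' outside the source image are masked out (never extrapolated); for Lab
#' images a sample is valid only if all four bilinear neighbours are valid
#' in the source mask.
#'
#' @param img an [lab_image] or [rgb_image].
#' @param field a `warp_field` from [build_warp()].
#' @return Image of the same class in reference-raster dimensions; for
#'   `rgb_image` input the validity mask is attached as attribute `mask`.
#' @export
warp_image <- function(img, field) {
  stopifnot(inherits(field, "warp_field"))
  x <- as.numeric(field$map_x); y <- as.numeric(field$map_y)
  H <- field$height; W <- field$width
  px <- img$pixels
  ch <- vector("list", 3)
  valid <- NULL
  for (k in 1:3) {
    s <- .bilinear(px[, , k], x, y)
    ch[[k]] <- s$values
    valid <- if (is.null(valid)) s$valid else valid & s$valid
  }
  if (inherits(img, "lab_image") && !all(img$mask)) {
    mnum <- .bilinear(img$mask * 1, x, y)
    valid <- valid & (mnum$values >= 1 - 1e-12)   # all 4 neighbours masked TRUE
  }
  out <- array(0, c(H, W, 3))
  for (k in 1:3) {
    v <- ch[[k]]; v[!valid] <- 0
    out[, , k] <- matrix(v, H, W)
  }
  mask <- matrix(valid, H, W)
  if (inherits(img, "lab_image")) return(lab_image(out, mask = mask))
  r <- rgb_image(pmin(pmax(out, 0), 255))
  attr(r, "mask") <- mask
  r
}
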