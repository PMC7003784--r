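# Synthetic two-group, two-timepoint facial study generator.  Faces are
# schematic (ellipse + template landmarks): the correctness of the method
# is geometric and statistical, not perceptual.  Everything is
# deterministic under the study seed; the generator emits the same file
# dialects the pipeline reads (PNG images, JSON landmarks, CSV charts and
# manifest).

#' Synthetic study configuration
#'
#' Defaults emulate the study design the package targets: a blinded,
#' vehicle-controlled, parallel-group trial with imaging at baseline (T0)
#' and day 28 (T28), two facial sides per subject, 27 subjects per group,
#' and a base skin tone with an individual typology angle near 0.7 degrees
#' (intermediate skin).
#'
#' @param n_per_group subjects per group (default 27).
#' @param width,height image raster in pixels (default 128 x 128, a
#'   scaled-down stand-in for the high-resolution clinical photographs).
#' @param base_lab length-3 base skin colour L*, a*, b* (default
#'   `c(50.2, 13, 16)`, ITA about 0.7 degrees).
#' @param landmark_jitter SD (px) of per-image landmark jitter (default 1.5).
#' @param noise_sigma SD (Lab units) of independent per-pixel, per-subject,
#'   per-timepoint Gaussian colour noise (default 1.0).
#' @param noise_smooth if `> 0`, the noise field is smoothed with a
#'   Gaussian kernel of this SD in pixels (mimics spatially correlated
#'   registration residuals); default 0 = independent noise.
#' @param effects list of effects from [study_effect()].
#' @param chart_distortion if `TRUE`, each image gets a random affine
#'   colour distortion together with a matching measured-chart file, so
#'   the calibration stage is exercised end-to-end.
#' @param seed integer study seed; the same seed reproduces the study
#'   bit-identically.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = 27L, width = 128L, height = 128L,
                             base_lab = c(50.2, 13, 16),
                             landmark_jitter = 1.5, noise_sigma = 1.0,
                             noise_smooth = 0, effects = list(),
                             chart_distortion = FALSE, seed = 1L) {
  stopifnot(n_per_group >= 1, width >= 16, height >= 16,
            landmark_jitter >= 0, noise_sigma >= 0, noise_smooth >= 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 width = as.integer(width), height = as.integer(height),
                 base_lab = base_lab, landmark_jitter = landmark_jitter,
                 noise_sigma = noise_sigma, noise_smooth = noise_smooth,
                 effects = effects, chart_distortion = chart_distortion,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Localized colour effect for the synthetic study
#'
#' A circular region (unit face coordinates) in which one Lab channel is
#' shifted for one group at one time point.  `effect_sd` draws the
#' per-subject effect magnitude from `N(delta, effect_sd)` (constant
#' across the region for a given subject), emulating between-subject
#' response variability.
#'
#' @param channel `"L"`, `"a"` or `"b"`.
#' @param delta mean shift in Lab units.
#' @param cx,cy,r circle centre and radius in unit image coordinates.
#' @param group,timepoint which images carry the effect.
#' @param effect_sd between-subject SD of the shift (default 0).
#' @return A `study_effect` list.
#' @export
study_effect <- function(channel = c("L", "a", "b"), delta, cx, cy, r,
                         group = "active", timepoint = "T28",
                         effect_sd = 0) {
  structure(list(channel = match.arg(channel), delta = delta,
                 cx = cx, cy = cy, r = r,
                 group = match.arg(group, c("vehicle", "active")),
                 timepoint = match.arg(timepoint, c("T0", "T28")),
                 effect_sd = effect_sd),
            class = "study_effect")
}

#' The 60-point landmark template
#'
#' Unit-square coordinates (x rightward, y downward), left-right symmetric
#' about x = 0.5: 24 points on the face outline ellipse, 8 per eye, 4 brow
#' points, 6 nose points and 10 mouth points.  The attribute `mirror_map`
#' is the index permutation that maps the template onto itself under
#' `x -> 1 - x`.
#'
#' @return `60 x 2` matrix with attribute `mirror_map`.
#' @export
landmark_template <- function() {
  ell <- function(cx, cy, rx, ry, n, phase = 0) {
    th <- phase + 2 * pi * (0:(n - 1)) / n
    cbind(cx + rx * cos(th), cy + ry * sin(th))
  }
  pts <- rbind(
    ell(0.50, 0.54, 0.36, 0.420, 24),          # face outline
    ell(0.32, 0.42, 0.09, 0.045, 8),           # left eye
    ell(0.68, 0.42, 0.09, 0.045, 8),           # right eye
    c(0.24, 0.33), c(0.40, 0.33),              # left brow
    c(0.60, 0.33), c(0.76, 0.33),              # right brow
    c(0.50, 0.48), c(0.46, 0.58), c(0.54, 0.58),
    c(0.42, 0.62), c(0.58, 0.62), c(0.50, 0.64),   # nose
    ell(0.50, 0.76, 0.14, 0.050, 10)           # mouth
  )
  stopifnot(nrow(pts) == 60L)
  mirrored <- cbind(1 - pts[, 1], pts[, 2])
  d2 <- outer(mirrored[, 1], pts[, 1], `-`)^2 +
        outer(mirrored[, 2], pts[, 2], `-`)^2
  mm <- apply(d2, 1, which.min)
  stopifnot(max(apply(d2, 1, min)) < 1e-12, !anyDuplicated(mm))
  attr(pts, "mirror_map") <- as.integer(mm)
  pts
}

# per-(subject, side, timepoint) reproducible sub-seed, kept well below 2^31
.sub_seed <- function(seed, subject, side, timepoint) {
  s <- (as.integer(seed) %% 100000L) * 17000L +
    subject * 29L + (if (side == "right") 7L else 0L) +
    (if (timepoint == "T28") 13L else 0L)
  s %% 2147483647L
}

# separable Gaussian smoothing of a matrix (reflecting boundaries)
.gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(v) v[pmin(pmax(seq_along(v) - r, 1), length(v))]
  conv1 <- function(v) stats::filter(c(rep(v[1], r), v, rep(v[length(v)], r)),
                                     k, sides = 2)[(r + 1):(r + length(v))]
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

# Build one face in Lab, left-side layout, plus its landmark set.
# `offsets` = per-channel noise fields (list of H x W matrices or NULL);
# `eff` = list of study_effects with per-subject magnitudes already drawn.
.face_lab <- function(config, offsets = NULL, eff = list()) {
  W <- config$width; H <- config$height
  x <- matrix(rep(0:(W - 1), each = H), H, W) / (W - 1)
  y <- matrix(rep(0:(H - 1), times = W), H, W) / (H - 1)
  ex <- (x - 0.5) / 0.36; ey <- (y - 0.54) / 0.42
  r2 <- ex^2 + ey^2
  face <- r2 <= 1
  L <- config$base_lab[1] - 4 * r2          # gentle radial shading
  a <- config$base_lab[2] + 1.5 * (y - 0.5)
  b <- config$base_lab[3] + 1.0 * (x - 0.5)
  inside <- function(cx, cy, rx, ry) ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
  eyes <- inside(0.32, 0.42, 0.09, 0.045) | inside(0.68, 0.42, 0.09, 0.045)
  mouth <- inside(0.50, 0.76, 0.14, 0.050)
  L[eyes] <- L[eyes] - 25
  L[mouth] <- L[mouth] - 10; a[mouth] <- a[mouth] + 18
  for (e in eff) {
    sel <- ((x - e$cx)^2 + (y - e$cy)^2) <= e$r^2
    if (e$channel == "L") L[sel] <- L[sel] + e$value
    else if (e$channel == "a") a[sel] <- a[sel] + e$value
    else b[sel] <- b[sel] + e$value
  }
  if (!is.null(offsets)) {
    L <- L + offsets[[1]]; a <- a + offsets[[2]]; b <- b + offsets[[3]]
  }
  # dark neutral background
  L[!face] <- 7; a[!face] <- 0; b[!face] <- 0
  L <- pmin(pmax(L, 0), 100)
  lab_image(array(c(L, a, b), c(H, W, 3)), mask = face)
}

#' Generate one synthetic face image with landmarks
#'
#' Deterministic for a given `subject_seed`.  The face is an ellipse with
#' a smooth skin-tone gradient at the configured base colour, darker eye,
#' brow and mouth features, and 60 template landmarks jittered per
#' subject.  For `side = "right"` the whole layout is mirrored and the
#' landmarks are stored in mirror-corresponding order, so that a plain
#' horizontal flip restores index-wise correspondence with left sides.
#'
#' @param config a [synthetic_config()].
#' @param subject_seed integer seed for this image's random draws.
#' @param side `"left"` or `"right"`.
#' @param group,timepoint labels controlling which configured effects
#'   apply.
#' @param image_id identifier stored in the landmark set.
#' @param effect_values optional numeric vector of pre-drawn per-subject
#'   effect magnitudes (one per configured effect); used by
#'   [generate_study()] so both sides of a subject carry the same effect.
#' @return `list(image = rgb_image, landmarks = landmark_set,
#'   lab = lab_image, distortion = colour distortion or NULL)`.
#' @export
generate_face <- function(config, subject_seed, side = c("left", "right"),
                          group = "vehicle", timepoint = "T0",
                          image_id = "", effect_values = NULL) {
  side <- match.arg(side)
  set.seed(subject_seed %% 2147483647L)
  W <- config$width; H <- config$height
  # draws, in fixed order: landmark jitter, noise field, effect magnitudes,
  # chart distortion
  jit <- matrix(rnorm(120, 0, config$landmark_jitter), 60, 2)
  offsets <- NULL
  if (config$noise_sigma > 0) {
    offsets <- lapply(1:3, function(k) {
      f <- matrix(rnorm(H * W, 0, config$noise_sigma), H, W)
      if (config$noise_smooth > 0) f <- .gauss_smooth(f, config$noise_smooth)
      f
    })
  }
  eff <- list()
  for (j in seq_along(config$effects)) {
    e <- config$effects[[j]]
    val <- if (!is.null(effect_values)) effect_values[j]
           else e$delta + if (e$effect_sd > 0) rnorm(1, 0, e$effect_sd) else 0
    if (e$group == group && e$timepoint == timepoint)
      eff[[length(eff) + 1L]] <- c(e, list(value = val))
  }
  lab <- .face_lab(config, offsets, eff)
  tpl <- landmark_template()
  pts <- cbind(tpl[, 1] * (W - 1), tpl[, 2] * (H - 1)) + jit
  pts[, 1] <- pmin(pmax(pts[, 1], 0), W - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), H - 1)
  img <- lab_to_srgb(lab_image(lab$pixels))   # background kept, no masking
  distortion <- NULL
  if (isTRUE(config$chart_distortion)) {
    M <- diag(1 + rnorm(3, 0, 0.05))
    M[row(M) != col(M)] <- rnorm(6, 0, 0.015)
    off <- rnorm(3, 0, 4)
    distortion <- list(matrix = M, offset = off)
    m <- matrix(img$pixels, ncol = 3) %*% t(M)
    m <- sweep(m, 2, off, `+`)
    img <- rgb_image(array(pmin(pmax(round(m), 0), 255), dim(img$pixels)))
  }
  if (side == "right") {
    flip <- mirror_right_side(img, landmark_set(pts, image_id))
    img <- flip$image
    pts <- flip$landmarks$points
    lab <- lab_image(lab$pixels[, W:1, , drop = FALSE],
                     mask = lab$mask[, W:1, drop = FALSE])
  }
  list(image = img, landmarks = landmark_set(pts, image_id),
       lab = lab, distortion = distortion)
}

#' Reference values of the synthetic 48-patch colour chart
#'
#' A fixed, deterministic set of 48 sRGB triples: a 4 x 3 x 3 RGB level
#' grid plus a 12-step grey ramp.
#'
#' @return `48 x 3` matrix of sRGB values.
#' @export
reference_chart_values <- function() {
  g <- as.matrix(expand.grid(R = c(30, 105, 180, 255),
                             G = c(30, 140, 255), B = c(30, 140, 255)))
  grey <- round(seq(15, 255, length.out = 12))
  rbind(g, cbind(grey, grey, grey))
}

#' Generate a complete synthetic study on disk
#'
#' Writes, under `dir`: `images/` (PNG, one per subject x side x time
#' point), `landmarks/` (JSON), optionally `charts/` (CSV, measured =
#' distorted reference), and `manifest.csv` listing every row with md5
#' checksums.  Vehicle subjects are `S001..`, active subjects follow.
#' Identical `config` (seed included) reproduces every file byte for
#' byte.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return The manifest `data.frame`, invisibly; written as
#'   `manifest.csv`.
#' @export
generate_study <- function(config, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "landmarks"), showWarnings = FALSE)
  if (config$chart_distortion)
    dir.create(file.path(dir, "charts"), showWarnings = FALSE)
  ref <- reference_chart_values()
  n <- config$n_per_group
  rows <- list()
  for (g in c("vehicle", "active")) {
    for (i in seq_len(n)) {
      sid <- sprintf("S%03d", if (g == "vehicle") i else n + i)
      subj_no <- if (g == "vehicle") i else n + i
      for (tp in c("T0", "T28")) {
        # per-subject effect magnitudes, shared by both sides
        effect_values <- NULL
        if (length(config$effects)) {
          set.seed((.sub_seed(config$seed, subj_no, "left", tp) + 104729L) %%
                     2147483647L)
          effect_values <- vapply(config$effects, function(e)
            e$delta + if (e$effect_sd > 0) rnorm(1, 0, e$effect_sd) else 0, 0)
        }
        for (side in c("left", "right")) {
          id <- paste(sid, side, tp, sep = "_")
          sub_seed <- .sub_seed(config$seed, subj_no, side, tp)
          f <- generate_face(config, sub_seed, side, group = g,
                             timepoint = tp, image_id = id,
                             effect_values = effect_values)
          img_path <- file.path("images", paste0(id, ".png"))
          lm_path <- file.path("landmarks", paste0(id, ".json"))
          png::writePNG(f$image$pixels / 255, file.path(dir, img_path))
          write_landmarks(f$landmarks, file.path(dir, lm_path))
          chart_path <- NA_character_
          if (config$chart_distortion) {
            meas <- ref %*% t(f$distortion$matrix)
            meas <- sweep(meas, 2, f$distortion$offset, `+`)
            chart_path <- file.path("charts", paste0(id, ".csv"))
            write_colour_chart(colour_chart(ref, meas),
                               file.path(dir, chart_path))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sid, group = g, timepoint = tp, side = side,
            image_path = img_path, landmark_path = lm_path,
            chart_path = chart_path,
            md5 = unname(tools::md5sum(file.path(dir, img_path))))
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
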