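# The classical comparator: mean L*a*b* over four predefined facial
# regions (forehead, upper/middle/lower cheek), per-subject change between
# time points, paired t-test and exact Wilcoxon signed-rank test.  ROIs
# are fixed polygons in the shared reference space (registration already
# aligns anatomy, so no per-subject template matching is needed).

#' Region-of-interest polygon
#'
#' @param name one of `"forehead"`, `"upper_cheek"`, `"middle_cheek"`,
#'   `"lower_cheek"` (other names are allowed for custom regions).
#' @param polygon `k x 2` matrix of (x, y) vertices in reference-space
#'   pixel coordinates (0-based), `k >= 3`, simple (non-self-intersecting).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(nrow(polygon) >= 3L, ncol(polygon) == 2L, all(is.finite(polygon)))
  structure(list(name = as.character(name), polygon = polygon),
            class = "roi_spec")
}

#' Even-odd point-in-polygon test
#'
#' Ray-crossing test, vectorized over query points.  Points exactly on a
#' boundary follow the half-open edge convention of the crossing rule.
#'
#' @param px,py query coordinates.
#' @param polygon `k x 2` vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, polygon) {
  n <- nrow(polygon)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# H x W logical matrix of pixel centres inside the polygon
.roi_raster_mask <- function(height, width, polygon) {
  px <- rep(0:(width - 1), each = height)
  py <- rep(0:(height - 1), times = width)
  matrix(point_in_polygon(px, py, polygon), height, width)
}

#' Mean L*a*b* over a region of interest
#'
#' Mean over masked pixels whose centres fall inside the ROI polygon
#' (even-odd rule).
#'
#' @param img a [lab_image] in reference space.
#' @param roi an [roi_spec].
#' @return Named numeric vector `c(L=, a=, b=)`.
#' @export
roi_mean <- function(img, roi) {
  d <- dim(img$pixels)
  sel <- .roi_raster_mask(d[1], d[2], roi$polygon) & img$mask
  if (!any(sel)) stop("ROI '", roi$name, "' does not overlap the image mask")
  c(L = mean(img$pixels[, , 1][sel]),
    a = mean(img$pixels[, , 2][sel]),
    b = mean(img$pixels[, , 3][sel]))
}

#' Default facial ROI polygons
#'
#' Four rectangles approximating the classical regions (forehead and
#' upper, middle, lower cheek) placed relative to the reference raster.
#' They ship as a convenience and are user-replaceable via [read_rois()].
#'
#' @param width,height reference raster dimensions.
#' @return List of four [roi_spec]s.
#' @export
default_rois <- function(width, height) {
  rect <- function(x0, y0, x1, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)) *
      rep(c(width - 1, height - 1), each = 4)
  list(
    roi_spec("forehead",     rect(0.35, 0.10, 0.65, 0.24)),
    roi_spec("upper_cheek",  rect(0.22, 0.42, 0.44, 0.54)),
    roi_spec("middle_cheek", rect(0.22, 0.56, 0.44, 0.68)),
    roi_spec("lower_cheek",  rect(0.28, 0.70, 0.48, 0.80))
  )
}

#' Read ROI polygons from a JSON file
#'
#' Format: a JSON list of `{"name": str, "polygon": [[x, y], ...]}`.
#'
#' @param path JSON file path.
#' @return List of [roi_spec]s.
#' @export
read_rois <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(j)), function(i)
    roi_spec(j$name[i], j$polygon[[i]]))
}

#' Write ROI polygons to a JSON file
#' @param rois list of [roi_spec]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(
    lapply(rois, function(r) list(name = r$name, polygon = unname(r$polygon))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# per-subject lab_image from one stack slice
.stack_subject_image <- function(stack, i) {
  d <- dim(stack$lab_values)
  px <- stack$lab_values[i, , , , drop = FALSE]
  dim(px) <- d[2:4]
  lab_image(px, mask = stack$mask)
}

#' Classical ROI change table
#'
#' For every group, ROI and colour channel: per-subject change in the ROI
#' mean between the two time points, its mean and SD, the two-sided paired
#' Student's t-test p-value and the exact Wilcoxon signed-rank p-value
#' (both always reported; the significance flag uses the t-test).
#' P-values below `alpha` are flagged significant.
#'
#' @param stacks named list of groups; each element a list with
#'   [registered_stack]s `T0` and `T28` (identical subject order).
#' @param rois list of [roi_spec]s.
#' @param alpha significance level, default 0.05.
#' @return `data.frame` with columns `roi`, `group`, `channel`,
#'   `delta_mean`, `delta_sd`, `p_t`, `p_wilcoxon`, `n`, `significant`.
#' @export
roi_change_table <- function(stacks, rois, alpha = 0.05) {
  rows <- list()
  for (g in names(stacks)) {
    s0 <- stacks[[g]]$T0; s1 <- stacks[[g]]$T28
    stopifnot(inherits(s0, "registered_stack"), inherits(s1, "registered_stack"))
    if (!identical(s0$subject_ids, s1$subject_ids))
      stop("pairing error in group ", g)
    n <- length(s0$subject_ids)
    if (n < 2L) stop("group ", g, ": need at least 2 paired subjects")
    for (roi in rois) {
      m0 <- t(vapply(seq_len(n), function(i)
        roi_mean(.stack_subject_image(s0, i), roi), c(L = 0, a = 0, b = 0)))
      m1 <- t(vapply(seq_len(n), function(i)
        roi_mean(.stack_subject_image(s1, i), roi), c(L = 0, a = 0, b = 0)))
      for (ch in c("L", "a", "b")) {
        delta <- m1[, ch] - m0[, ch]
        p_t <- if (sd(delta) == 0) {
          if (all(delta == 0)) 1 else .Machine$double.xmin
        } else t.test(delta)$p.value
        p_w <- if (all(delta == 0)) 1
               else suppressWarnings(
                 wilcox.test(delta, exact = n <= 25)$p.value)
        rows[[length(rows) + 1L]] <- data.frame(
          roi = roi$name, group = g, channel = ch,
          delta_mean = mean(delta), delta_sd = sd(delta),
          p_t = p_t, p_wilcoxon = p_w, n = n,
          significant = p_t < alpha)
      }
    }
  }
  do.call(rbind, rows)
}
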