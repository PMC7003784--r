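# Average-face reconstruction: per-subject merge of left and mirrored
# right registered sides, stacking per group x time point, per-pixel mean
# and SD, and rendering of the average face.

#' Registered image stack for one group at one time point
#'
#' @param lab_values numeric `n x H x W x 3` array of registered L*a*b*
#'   values (subjects first).
#' @param subject_ids character vector of length `n`, in stack order.
#' @param group `"vehicle"` or `"active"`.
#' @param timepoint `"T0"` or `"T28"`.
#' @param mask `H x W` logical; `TRUE` where the pixel is valid in ALL
#'   subjects.
#' @return An object of class `registered_stack`.
#' @export
registered_stack <- function(lab_values, subject_ids, group, timepoint, mask) {
  stopifnot(length(dim(lab_values)) == 4L, dim(lab_values)[4] == 3L,
            dim(lab_values)[1] == length(subject_ids),
            all(dim(mask) == dim(lab_values)[2:3]))
  structure(list(lab_values = lab_values,
                 subject_ids = as.character(subject_ids),
                 group = match.arg(group, c("vehicle", "active")),
                 timepoint = match.arg(timepoint, c("T0", "T28")),
                 mask = mask),
            class = "registered_stack")
}

#' Merge the two registered facial sides of one subject
#'
#' Pixels valid in both sides are averaged; pixels valid in only one side
#' take that side's value; the merged mask is the union.
#'
#' @param left,right_mirrored registered [lab_image]s of the left side and
#'   the mirrored right side, same raster.
#' @return A merged [lab_image].
#' @export
merge_sides <- function(left, right_mirrored) {
  stopifnot(all(dim(left$pixels) == dim(right_mirrored$pixels)))
  both <- left$mask & right_mirrored$mask
  only_r <- right_mirrored$mask & !left$mask
  out <- left$pixels
  for (k in 1:3) {
    lk <- out[, , k]; rk <- right_mirrored$pixels[, , k]
    lk[both] <- (lk[both] + rk[both]) / 2
    lk[only_r] <- rk[only_r]
    out[, , k] <- lk
  }
  lab_image(out, mask = left$mask | right_mirrored$mask)
}

#' Build a registered stack from per-subject side images
#'
#' @param sides named list (names = subject ids); each element a list with
#'   components `left` and `right` holding registered [lab_image]s (the
#'   right side already mirrored).  A missing side may be `NULL`.
#' @param group,timepoint stack labels.
#' @return A [registered_stack]; subjects are stacked in sorted id order
#'   and the stack mask is the conjunction of the per-subject merged masks.
#' @export
build_stack <- function(sides, group, timepoint) {
  ids <- sort(names(sides))
  stopifnot(length(ids) >= 1L)
  merged <- lapply(ids, function(id) {
    s <- sides[[id]]
    if (!is.null(s$left) && !is.null(s$right)) merge_sides(s$left, s$right)
    else if (!is.null(s$left)) s$left
    else if (!is.null(s$right)) s$right
    else stop("subject ", id, " has no sides")
  })
  d <- dim(merged[[1]]$pixels)
  vals <- array(0, c(length(ids), d))
  mask <- matrix(TRUE, d[1], d[2])
  for (i in seq_along(merged)) {
    vals[i, , , ] <- merged[[i]]$pixels
    mask <- mask & merged[[i]]$mask
  }
  registered_stack(vals, ids, group, timepoint, mask)
}

#' Per-pixel mean and standard deviation over a stack
#'
#' @param stack a [registered_stack] with at least 2 subjects.
#' @param trim trimming fraction in `[0, 0.5)` for the per-pixel mean
#'   (default 0 = plain mean; the SD is always the untrimmed sample SD).
#' @return An object of class `pixel_stats` with `mean` and `sd`
#'   (`H x W x 3`, sample SD with denominator n - 1), `n`, `mask`, and the
#'   stack labels.
#' @export
pixel_stats <- function(stack, trim = 0) {
  stopifnot(inherits(stack, "registered_stack"), trim >= 0, trim < 0.5)
  n <- dim(stack$lab_values)[1]
  if (n < 2L) stop("pixel_stats: need at least 2 subjects (SD undefined)")
  mu0 <- colMeans(stack$lab_values)                     # H x W x 3
  mu <- if (trim > 0) apply(stack$lab_values, 2:4, mean, trim = trim)
        else mu0
  ss <- colSums(stack$lab_values^2) - n * mu0^2
  ss[ss < 0] <- 0                                       # guard rounding
  structure(list(mean = mu, sd = sqrt(ss / (n - 1)), n = n,
                 mask = stack$mask, group = stack$group,
                 timepoint = stack$timepoint),
            class = "pixel_stats")
}

#' Render the average face as an sRGB image
#'
#' Converts the per-pixel mean L*a*b* back to sRGB; pixels outside the
#' stack mask are black.
#'
#' @param stats a `pixel_stats` object.
#' @return An [rgb_image].
#' @export
render_average_face <- function(stats) {
  lab_to_srgb(lab_image(stats$mean, mask = stats$mask))
}

#' @export
print.registered_stack <- function(x, ...) {
  d <- dim(x$lab_values)
  cat(sprintf("registered_stack: %s %s, %d subjects, %d x %d raster, %d masked px\n",
              x$group, x$timepoint, d[1], d[3], d[2], sum(x$mask)))
  invisible(x)
}

#' Write a registered stack to disk
#'
#' Multi-page 32-bit float TIFF (pages = subject x channel, channel
#' fastest) plus a JSON sidecar recording subject order, labels and mask.
#'
#' @param stack a [registered_stack].
#' @param tiff_path output TIFF path; the sidecar is written next to it
#'   with extension `.json`.
#' @return `tiff_path`, invisibly.
#' @export
write_stack <- function(stack, tiff_path, lo = -200, hi = 200) {
  d <- dim(stack$lab_values)
  pages <- list()
  for (i in seq_len(d[1])) for (k in 1:3)
    pages[[length(pages) + 1L]] <-
      pmin(pmax((stack$lab_values[i, , , k] - lo) / (hi - lo), 0), 1)
  pages[[length(pages) + 1L]] <- stack$mask * 1
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(subject_ids = stack$subject_ids,
                            group = stack$group, timepoint = stack$timepoint,
                            height = d[2], width = d[3], lo = lo, hi = hi),
                       sub("\\.tiff?$", ".json", tiff_path), auto_unbox = TRUE)
  invisible(tiff_path)
}

#' Read a registered stack written by [write_stack()]
#' @param tiff_path path to the stack TIFF.
#' @return A [registered_stack].
#' @export
read_stack <- function(tiff_path) {
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", tiff_path),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = FALSE)
  n <- length(meta$subject_ids)
  vals <- array(0, c(n, meta$height, meta$width, 3))
  for (i in seq_len(n)) for (k in 1:3)
    vals[i, , , k] <- pages[[(i - 1) * 3 + k]] * (meta$hi - meta$lo) + meta$lo
  mask <- pages[[n * 3 + 1]] >= 0.5
  registered_stack(vals, meta$subject_ids, meta$group, meta$timepoint, mask)
}
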