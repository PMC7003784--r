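# Colour-consistency correction against the in-frame 48-patch reference
# chart.  The correction is an affine map (3x3 matrix + offset) in sRGB,
# fitted by least squares from the measured patch values to the known
# reference values.  Chart localization is out of scope: measured patch
# means are supplied in the chart file.

#' Colour chart container
#'
#' Reference and measured values for the 48-patch colour chart included in
#' every photograph.
#'
#' @param reference `48 x 3` matrix of known patch values.
#' @param measured `48 x 3` matrix of mean pixel values of each patch as
#'   photographed, in the same colour space as `reference`.
#' @param colour_space `"sRGB"` (default) or `"Lab"`.
#' @return An object of class `colour_chart`.
#' @export
colour_chart <- function(reference, measured, colour_space = c("sRGB", "Lab")) {
  colour_space <- match.arg(colour_space)
  reference <- as.matrix(reference); measured <- as.matrix(measured)
  if (nrow(reference) != 48L || nrow(measured) != 48L ||
      ncol(reference) != 3L || ncol(measured) != 3L)
    stop("colour_chart: reference and measured must both be 48 x 3")
  structure(list(reference = reference, measured = measured,
                 colour_space = colour_space), class = "colour_chart")
}

#' Read a colour chart file
#'
#' CSV with header `patch_id, ref_R, ref_G, ref_B, meas_R, meas_G, meas_B`.
#'
#' @param path file path.
#' @return A [colour_chart].
#' @export
read_colour_chart <- function(path) {
  d <- read.csv(path)
  need <- c("patch_id", "ref_R", "ref_G", "ref_B", "meas_R", "meas_G", "meas_B")
  if (!all(need %in% names(d)))
    stop("chart file must have columns: ", paste(need, collapse = ", "))
  colour_chart(as.matrix(d[, c("ref_R", "ref_G", "ref_B")]),
               as.matrix(d[, c("meas_R", "meas_G", "meas_B")]))
}

#' Write a colour chart file
#'
#' @param chart a [colour_chart].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_colour_chart <- function(chart, path) {
  d <- data.frame(patch_id = seq_len(48),
                  ref_R = chart$reference[, 1], ref_G = chart$reference[, 2],
                  ref_B = chart$reference[, 3],
                  meas_R = chart$measured[, 1], meas_G = chart$measured[, 2],
                  meas_B = chart$measured[, 3])
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Fit an affine colour correction from a chart
#'
#' Least-squares fit of `reference ~ matrix %*% measured + offset` over the
#' 48 patches.  The residual is reported as the mean CIE76 dE between the
#' corrected and reference patches (patches converted to Lab first when the
#' chart is in sRGB).
#'
#' @param chart a [colour_chart].
#' @return An object of class `colour_correction` with fields `matrix`
#'   (3x3), `offset` (length 3) and `fit_residual` (mean patch dE after
#'   correction).
#' @export
fit_colour_correction <- function(chart) {
  stopifnot(inherits(chart, "colour_chart"))
  X <- cbind(1, chart$measured)
  qrX <- qr(X)
  if (qrX$rank < 4L)
    stop("degenerate chart: measured patch values are rank-deficient")
  B <- qr.coef(qrX, chart$reference)      # 4 x 3: row 1 offset, rows 2-4 t(matrix)
  M <- unname(t(B[2:4, , drop = FALSE]))
  off <- as.numeric(B[1, ])
  corrected <- chart$measured %*% t(M) + rep(off, each = 48L)
  if (chart$colour_space == "sRGB") {
    res <- mean(delta_e(srgb_to_lab(pmin(pmax(corrected, 0), 255)),
                        srgb_to_lab(chart$reference)))
  } else {
    res <- mean(delta_e(corrected, chart$reference))
  }
  structure(list(matrix = M, offset = off, fit_residual = res),
            class = "colour_correction")
}

#' Identity colour correction
#' @return A `colour_correction` that leaves images unchanged.
#' @export
identity_correction <- function() {
  structure(list(matrix = diag(3), offset = c(0, 0, 0), fit_residual = 0),
            class = "colour_correction")
}

#' Apply a colour correction to an image
#'
#' Per-pixel affine map in sRGB, clipped to `[0, 255]` and rounded.  An
#' exact identity correction returns the input bit-exactly.
#'
#' @param img an [rgb_image].
#' @param corr a `colour_correction` from [fit_colour_correction()].
#' @return Corrected [rgb_image].
#' @export
apply_colour_correction <- function(img, corr) {
  stopifnot(inherits(img, "rgb_image"), inherits(corr, "colour_correction"))
  if (identical(corr$matrix, diag(3)) && all(corr$offset == 0)) return(img)
  d <- dim(img$pixels)
  m <- matrix(img$pixels, ncol = 3) %*% t(corr$matrix)
  m <- sweep(m, 2, corr$offset, `+`)
  rgb_image(array(pmin(pmax(round(m), 0), 255), d))
}

#' @export
print.colour_correction <- function(x, ...) {
  cat("Affine colour correction (sRGB)\n")
  cat("  gain matrix diag:", paste(signif(diag(x$matrix), 4), collapse = ", "), "\n")
  cat("  offset:", paste(signif(x$offset, 4), collapse = ", "), "\n")
  cat("  mean patch dE after fit:", signif(x$fit_residual, 4), "\n")
  invisible(x)
}
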