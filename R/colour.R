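# CIELAB colour mathematics: sRGB <-> L*a*b* (D65, 2 deg observer),
# colour difference dE, and the individual typology angle ITA.

# sRGB -> XYZ matrix derived from the IEC 61966-2-1 primaries and the D65
# white chromaticity (x, y) = (0.3127, 0.3290); columns scaled so that
# (1,1,1) maps exactly onto the white point, hence white -> L* = 100, a* =
# b* = 0 with no residual.
.SRGB_XYZ <- matrix(c(
  0.41239079926595934, 0.35758433938387796, 0.18048078840183430,
  0.21263900587151030, 0.71516867876775590, 0.07219231536073371,
  0.01933081871559182, 0.11919477979462596, 0.95053215224966070
), nrow = 3, byrow = TRUE)
.XYZ_SRGB <- solve(.SRGB_XYZ)
.WP_D65 <- rowSums(.SRGB_XYZ)

#' RGB image container
#'
#' An 8-bit sRGB image stored as an `H x W x 3` integer array (R, G, B),
#' values in `[0, 255]`.
#'
#' @param pixels numeric `H x W x 3` array, values in `[0, 255]`.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (any(pixels < -0.5 | pixels > 255.5)) stop("rgb_image: values outside [0, 255]")
  structure(list(pixels = round(pixels)), class = "rgb_image")
}

#' CIELAB image container
#'
#' Per-pixel L*a*b* values (`H x W x 3` array: L* in 0--100, a*, b*
#' unbounded) with a logical mask marking valid (facial skin) pixels.
#'
#' @param pixels numeric `H x W x 3` array of L*, a*, b*.
#' @param mask logical `H x W` matrix; `TRUE` = valid pixel.  Defaults to
#'   all `TRUE`.
#' @return An object of class `lab_image`.
#' @export
lab_image <- function(pixels, mask = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  d <- dim(pixels)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  L <- pixels[, , 1][mask]
  if (length(L) && (min(L) < -1e-9 || max(L) > 100 + 1e-9))
    stop("lab_image: masked L* values outside [0, 100]")
  structure(list(pixels = pixels, mask = mask), class = "lab_image")
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)
#' @export
dim.lab_image <- function(x) dim(x$pixels)

.srgb_linearize <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}
.srgb_delinearize <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}
.lab_f <- function(t) {
  d3 <- (6 / 29)^3
  ifelse(t > d3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}
.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

# N x 3 matrix of sRGB in [0,255] -> N x 3 matrix of Lab
.srgb_mat_to_lab <- function(m) {
  xyz <- .srgb_linearize(m / 255) %*% t(.SRGB_XYZ)
  fx <- .lab_f(xyz[, 1] / .WP_D65[1])
  fy <- .lab_f(xyz[, 2] / .WP_D65[2])
  fz <- .lab_f(xyz[, 3] / .WP_D65[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# N x 3 matrix of Lab -> N x 3 matrix of sRGB in [0,255] (clipped, unrounded)
.lab_mat_to_srgb <- function(m) {
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.lab_finv(fx) * .WP_D65[1],
               .lab_finv(fy) * .WP_D65[2],
               .lab_finv(fz) * .WP_D65[3])
  255 * .srgb_delinearize(xyz %*% t(.XYZ_SRGB))
}

#' Convert an sRGB image (or colour matrix) to CIELAB
#'
#' Standard sRGB decoding, D65 white point, 2 degree observer.  The white
#' point is the image of (255, 255, 255), so white maps exactly to
#' (100, 0, 0).
#'
#' @param img an [rgb_image], or an `N x 3` matrix / length-3 vector of
#'   sRGB values in `[0, 255]`.
#' @param mask optional logical mask forwarded to the resulting
#'   [lab_image].
#' @return A [lab_image] when `img` is an `rgb_image`; otherwise an
#'   `N x 3` matrix of L*, a*, b*.
#' @export
srgb_to_lab <- function(img, mask = NULL) {
  if (inherits(img, "rgb_image")) {
    d <- dim(img$pixels)
    m <- .srgb_mat_to_lab(matrix(img$pixels, ncol = 3))
    return(lab_image(array(m, d), mask = mask))
  }
  if (is.null(dim(img))) img <- matrix(img, ncol = 3)
  .srgb_mat_to_lab(img)
}

#' Convert a CIELAB image (or colour matrix) back to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()] up to 8-bit quantization; out-of-gamut
#' values are clipped to `[0, 255]`.
#'
#' @param img a [lab_image], or an `N x 3` matrix / length-3 vector of
#'   L*, a*, b* values.
#' @return An [rgb_image] (masked-out pixels set to black) or an `N x 3`
#'   matrix of rounded 8-bit values.
#' @export
lab_to_srgb <- function(img) {
  if (inherits(img, "lab_image")) {
    d <- dim(img$pixels)
    m <- .lab_mat_to_srgb(matrix(img$pixels, ncol = 3))
    a <- array(round(m), d)
    if (!all(img$mask)) for (k in 1:3) a[, , k][!img$mask] <- 0
    return(rgb_image(a))
  }
  if (is.null(dim(img))) img <- matrix(img, ncol = 3)
  round(.lab_mat_to_srgb(img))
}

#' CIE colour difference between L*a*b* colours
#'
#' Default is the CIE76 Euclidean distance
#' `sqrt(dL^2 + da^2 + db^2)`, under which dE = 1 is the conventional
#' just-noticeable difference used as the visibility threshold in the
#' relevance maps.  CIEDE2000 is available as an alternative but is never
#' the default.
#'
#' @param lab1,lab2 length-3 vectors or `N x 3` matrices of L*, a*, b*.
#' @param method `"cie76"` (default) or `"ciede2000"`.
#' @return Non-negative colour difference(s).
#' @export
delta_e <- function(lab1, lab2, method = c("cie76", "ciede2000")) {
  method <- match.arg(method)
  if (is.null(dim(lab1))) lab1 <- matrix(lab1, ncol = 3)
  if (is.null(dim(lab2))) lab2 <- matrix(lab2, ncol = 3)
  if (method == "cie76") {
    d <- lab1 - lab2
    return(sqrt(rowSums(d * d)))
  }
  .ciede2000(lab1, lab2)
}

# CIEDE2000 with the standard kL = kC = kH = 1 weights.
.ciede2000 <- function(lab1, lab2) {
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- h2p - h1p
  dhp <- ifelse(abs(dhp) > 180, dhp - sign(dhp) * 360, dhp)
  dhp <- ifelse(C1p * C2p == 0, 0, dhp)
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))
  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) + 0.24 * cos(2 * hbp * pi / 180) +
        0.32 * cos((3 * hbp + 6) * pi / 180) - 0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta * pi / 180) * RC
  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
       RT * (dCp / SC) * (dHp / SH))
}

#' Per-pixel CIE76 dE between two Lab pixel arrays
#'
#' @param lab1,lab2 `H x W x 3` arrays of L*, a*, b*.
#' @return `H x W` matrix of colour differences.
#' @keywords internal
delta_e_map <- function(lab1, lab2) {
  d <- lab1 - lab2
  sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
}

#' Individual typology angle (ITA, degrees)
#'
#' `ITA = atan2(L* - 50, b*) * 180 / pi`, the standard skin colour
#' classification angle.  Using the two-argument arctangent keeps the
#' function defined at `b* = 0` (+/-90 when L* != 50; 0 when both L* = 50
#' and b* = 0).
#'
#' @param L,b L* and b* values (vectorized).
#' @return Angle(s) in degrees, in `(-180, 180]`.
#' @export
ita_degrees <- function(L, b) {
  atan2(L - 50, b) * 180 / pi
}
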