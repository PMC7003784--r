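# Per-pixel change analysis between two time points of one group:
# mean channel differences, the CIE76 dE relevance map with its dE > 1
# visibility threshold, and per-channel paired t-test significance maps
# with the blue/red direction convention (blue = desired anti-ageing
# direction: lighter L*, less red a*, less yellow b*).

#' Per-pixel paired change maps between two time points
#'
#' For each masked pixel and each of L*, a*, b*: the mean paired
#' difference (T28 - T0), its sign, and the two-sided p-value of the
#' paired Student's t-test on the per-subject differences; plus the CIE76
#' dE computed from the three mean differences.  This is the central
#' fitted object of the package.
#'
#' Degenerate pixels (zero variance of the differences) get p = 1 when all
#' differences are exactly 0; when the differences are constant but
#' non-zero the p-value is set from the limit of the t-test as the
#' variance vanishes (the smallest positive double, never exactly 0) and
#' the pixel is counted in `qc$constant_nonzero`.
#'
#' @param stack_t0,stack_t28 [registered_stack]s of the same group with
#'   identical subject order and raster.
#' @param fdr if `TRUE`, p-values are Benjamini-Hochberg adjusted across
#'   the masked pixels of each channel (off by default: the method reports
#'   raw per-pixel p-values).
#' @return An object of class `change_maps` with fields `dL`, `da`, `db`,
#'   `dE` (`H x W` matrices), `p` and `sign` (named lists over channels
#'   `L`, `a`, `b`), `mask`, `n`, `df`, `group`, `qc`.
#' @export
change_maps <- function(stack_t0, stack_t28, fdr = FALSE) {
  stopifnot(inherits(stack_t0, "registered_stack"),
            inherits(stack_t28, "registered_stack"))
  if (stack_t0$group != stack_t28$group)
    stop("stacks belong to different groups")
  if (!identical(stack_t0$subject_ids, stack_t28$subject_ids))
    stop("pairing error: subject order differs between time points")
  d0 <- dim(stack_t0$lab_values); d1 <- dim(stack_t28$lab_values)
  if (!all(d0 == d1)) stop("stack raster dimensions differ")
  n <- d0[1]
  if (n < 2L) stop("need at least 2 subjects for a paired test")
  mask <- stack_t0$mask & stack_t28$mask
  diffs <- stack_t28$lab_values - stack_t0$lab_values   # n x H x W x 3
  p <- list(); sgn <- list(); dmean <- list()
  qc_const <- 0L
  for (k in 1:3) {
    Dk <- diffs[, , , k, drop = FALSE]
    dim(Dk) <- d0[1:3]
    md <- colMeans(Dk)
    ss <- colSums(Dk^2) - n * md^2
    ss[ss < 0] <- 0
    sdd <- sqrt(ss / (n - 1))
    tval <- md / (sdd / sqrt(n))
    pk <- 2 * pt(-abs(tval), df = n - 1)
    zerovar <- sdd == 0
    pk[zerovar & md == 0] <- 1
    cn <- zerovar & md != 0
    pk[cn] <- .Machine$double.xmin
    qc_const <- qc_const + sum(cn & mask)
    if (fdr) pk[mask] <- p.adjust(pk[mask], method = "BH")
    ch <- c("L", "a", "b")[k]
    p[[ch]] <- pk
    sgn[[ch]] <- sign(md)
    dmean[[ch]] <- md
  }
  dE <- sqrt(dmean$L^2 + dmean$a^2 + dmean$b^2)
  structure(list(dL = dmean$L, da = dmean$a, db = dmean$b, dE = dE,
                 p = p, sign = sgn, mask = mask, n = n, df = n - 1,
                 group = stack_t0$group, fdr = fdr,
                 qc = list(constant_nonzero = qc_const)),
            class = "change_maps")
}

#' @export
print.change_maps <- function(x, ...) {
  cat(sprintf("change_maps: group %s, n = %d paired subjects, %d masked pixels\n",
              x$group, x$n, sum(x$mask)))
  cat(sprintf("  mean dE over mask: %.3f (max %.3f)\n",
              mean(x$dE[x$mask]), max(x$dE[x$mask])))
  for (ch in c("L", "a", "b"))
    cat(sprintf("  %s*: significant fraction at 0.05 = %.3f\n",
                ch, mean(x$p[[ch]][x$mask] < 0.05)))
  invisible(x)
}

#' @export
summary.change_maps <- function(object, alpha = 0.05, ...) {
  m <- object$mask
  out <- data.frame(
    channel = c("L", "a", "b"),
    mean_delta = c(mean(object$dL[m]), mean(object$da[m]), mean(object$db[m])),
    sig_fraction = vapply(object$p, function(p) mean(p[m] < alpha), 0),
    row.names = NULL)
  attr(out, "dE_mean") <- mean(object$dE[m])
  attr(out, "visible_fraction") <- mean(object$dE[m] > 1)
  class(out) <- c("summary.change_maps", "data.frame")
  out
}

#' @export
print.summary.change_maps <- function(x, ...) {
  cat("Per-pixel paired change summary\n")
  print.data.frame(x)
  cat(sprintf("mean dE = %.3f; fraction dE > 1 = %.3f\n",
              attr(x, "dE_mean"), attr(x, "visible_fraction")))
  invisible(x)
}

#' @export
plot.change_maps <- function(x, what = c("dE", "p_L", "p_a", "p_b"), ...) {
  what <- match.arg(what)
  m <- if (what == "dE") x$dE else x$p[[sub("p_", "", what)]]
  m[!x$mask] <- NA
  image(t(m)[, nrow(m):1], col = gray(seq(0, 1, length.out = 64)),
        axes = FALSE, main = paste0(what, " (", x$group, ")"), ...)
  invisible(x)
}

#' Relevance map: visible colour change (dE over threshold)
#'
#' Pixels whose dE strictly exceeds the threshold (default 1, the
#' conventional just-noticeable colour difference) form the visible mask.
#' The rendering overlays those pixels on the average face as a grey
#' ramp scaled linearly from the threshold (darkest visible grey) to the
#' 99th percentile of dE under the mask (white); everything else shows the
#' face unaltered.
#'
#' @param cm a [change_maps] object.
#' @param threshold visibility threshold on dE (strict `>`), default 1.
#' @param face optional [rgb_image] average face for rendering.
#' @return An object of class `relevance_map` with `dE`, `visible_mask`,
#'   `threshold` and (if `face` given) `rendering`.
#' @export
relevance_map <- function(cm, threshold = 1, face = NULL) {
  stopifnot(inherits(cm, "change_maps"))
  visible <- cm$dE > threshold & cm$mask
  out <- list(dE = cm$dE, visible_mask = visible, threshold = threshold,
              group = cm$group)
  if (!is.null(face)) {
    stopifnot(all(dim(face$pixels)[1:2] == dim(cm$dE)))
    hi <- if (any(visible)) quantile(cm$dE[visible], 0.99, names = FALSE)
          else threshold + 1
    if (hi <= threshold) hi <- threshold + 1e-9
    w <- pmin(pmax((cm$dE - threshold) / (hi - threshold), 0), 1)
    grey <- round(64 + 191 * w)           # darkest visible grey -> white
    px <- face$pixels
    for (k in 1:3) {
      fk <- px[, , k]
      fk[visible] <- grey[visible]
      px[, , k] <- fk
    }
    out$rendering <- rgb_image(px)
  }
  structure(out, class = "relevance_map")
}

#' Significance map for one colour channel
#'
#' Pixels with p strictly below `alpha` are hue-coded by direction of
#' change: blue marks the desired anti-ageing direction (increased L* =
#' lighter; decreased a* = less red; decreased b* = less yellow), red the
#' opposite.  Colour intensity is proportional to `min(-log10(p), 4)`
#' rescaled to `[0, 1]`.  Non-significant pixels show the average face.
#'
#' @param cm a [change_maps] object.
#' @param channel `"L"`, `"a"` or `"b"`.
#' @param alpha significance level (strict `<`), default 0.05.
#' @param face optional [rgb_image] average face for rendering.
#' @return An object of class `significance_map` with `p`,
#'   `significant_mask`, `direction` (`H x W` character: `"blue"`,
#'   `"red"`, `"none"`), `alpha`, `channel` and (if `face` given)
#'   `rendering`.
#' @export
significance_map <- function(cm, channel = c("L", "a", "b"), alpha = 0.05,
                             face = NULL) {
  stopifnot(inherits(cm, "change_maps"), alpha > 0, alpha < 1)
  channel <- match.arg(channel)
  p <- cm$p[[channel]]
  s <- cm$sign[[channel]]
  sig <- p < alpha & cm$mask
  improved <- if (channel == "L") s > 0 else s < 0
  direction <- matrix("none", nrow(p), ncol(p))
  direction[sig & improved] <- "blue"
  direction[sig & !improved] <- "red"
  out <- list(p = p, significant_mask = sig, direction = direction,
              alpha = alpha, channel = channel, group = cm$group)
  if (!is.null(face)) {
    stopifnot(all(dim(face$pixels)[1:2] == dim(p)))
    w <- pmin(-log10(pmax(p, .Machine$double.xmin)), 4) / 4
    px <- face$pixels
    blue <- c(40, 60, 255); red <- c(255, 50, 40)
    for (k in 1:3) {
      fk <- px[, , k]
      bsel <- direction == "blue"; rsel <- direction == "red"
      fk[bsel] <- (1 - w[bsel]) * fk[bsel] + w[bsel] * blue[k]
      fk[rsel] <- (1 - w[rsel]) * fk[rsel] + w[rsel] * red[k]
      px[, , k] <- fk
    }
    out$rendering <- rgb_image(px)
  }
  structure(out, class = "significance_map")
}

#' QC summary of a change-maps analysis
#'
#' @param cm a [change_maps] object.
#' @param alpha significance level used for the per-channel fractions.
#' @return Named list: per-channel significant-pixel fraction, visible
#'   (dE > 1) fraction, degenerate-pixel count, n, masked pixel count.
#' @export
qc_summary <- function(cm, alpha = 0.05) {
  m <- cm$mask
  list(group = cm$group,
       n_subjects = cm$n,
       masked_pixels = sum(m),
       sig_fraction_L = mean(cm$p$L[m] < alpha),
       sig_fraction_a = mean(cm$p$a[m] < alpha),
       sig_fraction_b = mean(cm$p$b[m] < alpha),
       visible_fraction = mean(cm$dE[m] > 1),
       degenerate_pixels = cm$qc$constant_nonzero)
}
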