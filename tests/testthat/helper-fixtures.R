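# Shared fixture builders: constant-geometry registered stacks so that
# statistical behaviour can be tested without the imaging stages.

const_lab <- function(H, W, L = 50, a = 10, b = 12, mask = NULL) {
  lab_image(array(rep(c(L, a, b), each = H * W), c(H, W, 3)), mask = mask)
}

# stack of n subjects on an H x W raster; `base` length-3 Lab; `noise`
# per-pixel iid Gaussian SD; `shift` length-3 added to every subject;
# `subject_shifts` optional n x 3 per-subject offsets
make_stack <- function(n, H, W, base = c(55, 10, 12), noise = 0,
                       shift = c(0, 0, 0), subject_shifts = NULL,
                       group = "active", timepoint = "T0",
                       ids = sprintf("s%03d", seq_len(n))) {
  a <- array(0, c(n, H, W, 3))
  for (k in 1:3) {
    a[, , , k] <- base[k] + shift[k]
    if (!is.null(subject_shifts))
      a[, , , k] <- a[, , , k] + subject_shifts[, k]
    if (noise > 0)
      a[, , , k] <- a[, , , k] + array(rnorm(n * H * W, 0, noise), c(n, H, W))
  }
  registered_stack(a, ids, group, timepoint, matrix(TRUE, H, W))
}

# closed-form power of the two-sided one-sample/paired t-test
paired_t_power <- function(d, sigma, n, alpha = 0.05) {
  ncp <- d * sqrt(n) / sigma
  tc <- qt(1 - alpha / 2, n - 1)
  1 - pt(tc, n - 1, ncp) + pt(-tc, n - 1, ncp)
}

# exact two-sided Wilcoxon signed-rank p-value by enumeration of all 2^n
# sign assignments (independent oracle; no ties/zeros expected)
wilcoxon_exact_enum <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
}
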