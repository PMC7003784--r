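# The study pipeline tying the stages together: manifest validation,
# chart calibration, mirroring, registration, stacking, average faces,
# relevance and significance maps, the classical ROI table, and QC.
# Each stage is exposed on its own (stage_* functions) so the
# command-line subcommands in scripts/facemap compose to exactly the
# pipeline outputs.

#' Pipeline configuration
#'
#' All analysis thresholds with their method-faithful defaults.
#'
#' @param delta_e_threshold visibility threshold on dE (strict `>`),
#'   default 1.
#' @param alpha per-pixel significance level (strict `<`), default 0.05.
#' @param delta_e_method `"cie76"` (default) or `"ciede2000"` (affects
#'   chart residual reporting only; the per-pixel dE map follows the
#'   CIE76 definition used by the visibility threshold).
#' @param tps_lambda thin-plate-spline regularization weight, default 0
#'   (exact landmark interpolation).
#' @param fdr apply Benjamini-Hochberg correction to the per-pixel
#'   p-values (default `FALSE`: raw per-pixel p-values, as the method
#'   defines).
#' @param trim trimming fraction for the per-pixel mean (default 0 =
#'   plain mean).
#' @param mask_l_threshold L* value below which pixels are treated as
#'   background (default 20; set to `-Inf` to disable).
#' @param reference_width,reference_height reference raster override;
#'   default `NULL` = median input image size.
#' @param mirror_index landmark permutation applied when mirroring right
#'   sides; default `NULL` = identity (right-side landmark files already
#'   stored in mirror-corresponding order).
#' @return A `facemap_config` list.
#' @export
facemap_config <- function(delta_e_threshold = 1, alpha = 0.05,
                           delta_e_method = c("cie76", "ciede2000"),
                           tps_lambda = 0, fdr = FALSE, trim = 0,
                           mask_l_threshold = 20,
                           reference_width = NULL, reference_height = NULL,
                           mirror_index = NULL) {
  structure(list(delta_e_threshold = delta_e_threshold, alpha = alpha,
                 delta_e_method = match.arg(delta_e_method),
                 tps_lambda = tps_lambda, fdr = fdr, trim = trim,
                 mask_l_threshold = mask_l_threshold,
                 reference_width = reference_width,
                 reference_height = reference_height,
                 mirror_index = mirror_index),
            class = "facemap_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file path.
#' @return A [facemap_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(facemap_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(facemap_config, y)
}

#' Read a study manifest CSV
#'
#' Columns: `subject_id, group, timepoint, side, image_path,
#' landmark_path` and optional `chart_path`.  Paths are taken relative to
#' the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return A `data.frame` with attribute `root` (the manifest directory).
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  attr(m, "root") <- dirname(normalizePath(path))
  m
}

#' Validate a study manifest
#'
#' Checks column presence, factor levels, uniqueness of
#' (subject, timepoint, side), complete T0/T28 pairing per subject and
#' existence of every referenced file.  All offending rows are reported
#' together before aborting.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param root directory paths are relative to.
#' @return The validated manifest, invisibly; errors otherwise.
#' @export
validate_manifest <- function(manifest, root = attr(manifest, "root") %||% ".") {
  need <- c("subject_id", "group", "timepoint", "side",
            "image_path", "landmark_path")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  probs <- character()
  bad <- function(rows, what)
    if (length(rows)) probs <<- c(probs, paste0("rows ",
      paste(rows, collapse = ","), ": ", what))
  bad(which(!manifest$group %in% c("vehicle", "active")), "bad group")
  bad(which(!manifest$timepoint %in% c("T0", "T28")), "bad timepoint")
  bad(which(!manifest$side %in% c("left", "right")), "bad side")
  key <- paste(manifest$subject_id, manifest$timepoint, manifest$side)
  bad(which(duplicated(key)), "duplicate (subject, timepoint, side)")
  for (s in unique(manifest$subject_id)) {
    tps <- unique(manifest$timepoint[manifest$subject_id == s])
    if (!all(c("T0", "T28") %in% tps))
      probs <- c(probs, paste0("subject ", s, ": missing time point"))
  }
  for (col in c("image_path", "landmark_path", "chart_path")) {
    if (!col %in% names(manifest)) next
    p <- manifest[[col]]
    idx <- which(!is.na(p) & p != "" &
                 !file.exists(file.path(root, p)))
    bad(idx, paste("missing", col))
  }
  if (length(probs))
    stop("manifest validation failed:\n  ", paste(probs, collapse = "\n  "))
  invisible(manifest)
}

.read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  rgb_image(round(a[, , 1:3, drop = FALSE] * 255))
}

#' Write an [rgb_image] as PNG
#' @param img an [rgb_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

# write a real-valued matrix (or list of them) as 32-bit float TIFF,
# shifted/scaled into [0,1] with the transform recorded in a JSON sidecar
.write_float_tiff <- function(mats, path, lo = -200, hi = 200) {
  if (!is.list(mats)) mats <- list(mats)
  pages <- lapply(mats, function(m) {
    m[!is.finite(m)] <- lo
    pmin(pmax((m - lo) / (hi - lo), 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(lo = lo, hi = hi),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

.read_float_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) p * (meta$hi - meta$lo) + meta$lo)
}

# stages 1-5: read, calibrate, mirror, register, stack.
# Returns list(reference, stacks, faces, lms, log_lines).
.register_all <- function(manifest, config, out_dir = NULL,
                          write_intermediates = FALSE) {
  root <- attr(manifest, "root") %||% "."
  validate_manifest(manifest, root)
  log_lines <- character()
  has_chart <- "chart_path" %in% names(manifest) &&
    any(!is.na(manifest$chart_path) & manifest$chart_path != "")
  faces <- vector("list", nrow(manifest))
  lms <- vector("list", nrow(manifest))
  sizes <- matrix(0L, nrow(manifest), 2)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- .read_rgb_png(file.path(root, row$image_path))
    if (has_chart && !is.na(row$chart_path) && row$chart_path != "") {
      chart <- read_colour_chart(file.path(root, row$chart_path))
      corr <- fit_colour_correction(chart)
      img <- apply_colour_correction(img, corr)
      log_lines <- c(log_lines, sprintf(
        "calibrated %s: mean patch dE %.4f", row$image_path,
        corr$fit_residual))
    }
    lm <- read_landmarks(file.path(root, row$landmark_path))
    if (row$side == "right") {
      mi <- config$mirror_index %||% seq_len(nrow(lm$points))
      fl <- mirror_right_side(img, lm, mirror_index = mi)
      img <- fl$image; lm <- fl$landmarks
    }
    if (write_intermediates && !is.null(out_dir))
      write_rgb_png(img, file.path(out_dir, "calibrated",
                                   basename(row$image_path)))
    faces[[i]] <- img; lms[[i]] <- lm
    sizes[i, ] <- dim(img$pixels)[2:1]
  }
  W <- config$reference_width %||% as.integer(median(sizes[, 1]))
  H <- config$reference_height %||% as.integer(median(sizes[, 2]))
  ref <- estimate_reference_shape(lms, W, H)
  registered <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    lab <- srgb_to_lab(faces[[i]])
    if (is.finite(config$mask_l_threshold))
      lab$mask <- lab$pixels[, , 1] > config$mask_l_threshold
    field <- build_warp(lms[[i]], ref, lambda = config$tps_lambda)
    registered[[i]] <- warp_image(lab, field)
  }
  stacks <- list()
  for (g in intersect(c("vehicle", "active"), unique(manifest$group))) {
    stacks[[g]] <- list()
    for (tp in c("T0", "T28")) {
      idx <- which(manifest$group == g & manifest$timepoint == tp)
      if (!length(idx)) next
      sides <- list()
      for (i in idx) {
        sid <- manifest$subject_id[i]
        if (is.null(sides[[sid]])) sides[[sid]] <- list()
        sides[[sid]][[manifest$side[i]]] <- registered[[i]]
      }
      stacks[[g]][[tp]] <- build_stack(sides, g, tp)
    }
  }
  list(reference = ref, stacks = stacks, log_lines = log_lines)
}

# stage 6 for one group pair; writes averages + maps, returns
# list(change_maps, qc)
.emit_maps_group <- function(g, stack_pair, out_dir, config) {
  st0 <- pixel_stats(stack_pair$T0, trim = config$trim)
  st1 <- pixel_stats(stack_pair$T28, trim = config$trim)
  face0 <- render_average_face(st0)
  write_rgb_png(face0, file.path(out_dir, "averages", paste0(g, "_T0.png")))
  write_rgb_png(render_average_face(st1),
                file.path(out_dir, "averages", paste0(g, "_T28.png")))
  cm <- change_maps(stack_pair$T0, stack_pair$T28, fdr = config$fdr)
  rel <- relevance_map(cm, threshold = config$delta_e_threshold, face = face0)
  write_rgb_png(rel$rendering,
                file.path(out_dir, "maps", paste0(g, "_relevance.png")))
  .write_float_tiff(cm$dE, file.path(out_dir, "maps", paste0(g, "_dE.tiff")),
                    lo = 0, hi = 200)
  for (ch in c("L", "a", "b")) {
    sm <- significance_map(cm, ch, alpha = config$alpha, face = face0)
    write_rgb_png(sm$rendering, file.path(out_dir, "maps",
      paste0(g, "_significance_", ch, ".png")))
    .write_float_tiff(list(cm$p[[ch]], cm$sign[[ch]]),
      file.path(out_dir, "maps", paste0(g, "_p_", ch, ".tiff")),
      lo = -1, hi = 1)
  }
  list(cm = cm, qc = qc_summary(cm, alpha = config$alpha))
}

#' Registration stage: manifest to registered stack files
#'
#' Runs calibration, mirroring and TPS registration, and writes one stack
#' TIFF (+ JSON sidecar) per group and time point under
#' `out_dir/registered/`, plus the reference shape as
#' `reference.json`.
#'
#' @param manifest manifest path or data.frame.
#' @param out_dir output directory.
#' @param config a [facemap_config()].
#' @return Invisibly, the list of stacks.
#' @export
stage_register <- function(manifest, out_dir, config = facemap_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(file.path(out_dir, "registered"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "calibrated"), showWarnings = FALSE)
  reg <- .register_all(manifest, config, out_dir, write_intermediates = TRUE)
  for (g in names(reg$stacks))
    for (tp in names(reg$stacks[[g]]))
      write_stack(reg$stacks[[g]][[tp]],
                  file.path(out_dir, "registered", paste0(g, "_", tp, ".tiff")))
  jsonlite::write_json(list(mean_points = unname(reg$reference$mean_points),
                            width = reg$reference$width,
                            height = reg$reference$height),
                       file.path(out_dir, "reference.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(reg$stacks)
}

# read all stacks previously written under dir/registered
.load_stacks <- function(dir) {
  files <- list.files(file.path(dir, "registered"), pattern = "\\.tiff$",
                      full.names = TRUE)
  stacks <- list()
  for (f in files) {
    st <- read_stack(f)
    stacks[[st$group]][[st$timepoint]] <- st
  }
  # keep the pipeline's group convention (vehicle first)
  stacks[intersect(c("vehicle", "active"), names(stacks))]
}

#' Averaging stage: registered stacks to average-face images
#'
#' @param dir directory holding `registered/` stacks (from
#'   [stage_register()]).
#' @param out_dir output directory (`averages/` is created inside).
#' @param config a [facemap_config()].
#' @return Invisibly, the list of `pixel_stats` per group and time point.
#' @export
stage_average <- function(dir, out_dir = dir, config = facemap_config()) {
  dir.create(file.path(out_dir, "averages"), recursive = TRUE,
             showWarnings = FALSE)
  stacks <- .load_stacks(dir)
  out <- list()
  for (g in names(stacks)) for (tp in names(stacks[[g]])) {
    ps <- pixel_stats(stacks[[g]][[tp]], trim = config$trim)
    write_rgb_png(render_average_face(ps),
                  file.path(out_dir, "averages", paste0(g, "_", tp, ".png")))
    out[[g]][[tp]] <- ps
  }
  invisible(out)
}

#' Maps stage: registered stacks to relevance/significance maps and QC
#'
#' @param dir directory holding `registered/` stacks.
#' @param out_dir output directory (`maps/`, `averages/`, `qc.json`).
#' @param config a [facemap_config()].
#' @return Invisibly, the list of [change_maps] per group.
#' @export
stage_maps <- function(dir, out_dir = dir, config = facemap_config()) {
  for (d in c("averages", "maps"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  stacks <- .load_stacks(dir)
  cms <- list(); qc <- list()
  for (g in names(stacks)) {
    if (is.null(stacks[[g]]$T0) || is.null(stacks[[g]]$T28)) next
    r <- .emit_maps_group(g, stacks[[g]], out_dir, config)
    cms[[g]] <- r$cm; qc[[g]] <- r$qc
  }
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cms)
}

#' ROI stage: registered stacks to the classical ROI change table
#'
#' @param dir directory holding `registered/` stacks.
#' @param out_dir output directory (`roi/roi_changes.csv`).
#' @param config a [facemap_config()].
#' @param rois list of [roi_spec()]s; default [default_rois()] on the
#'   stack raster.
#' @return Invisibly, the ROI table.
#' @export
stage_roi <- function(dir, out_dir = dir, config = facemap_config(),
                      rois = NULL) {
  dir.create(file.path(out_dir, "roi"), recursive = TRUE, showWarnings = FALSE)
  stacks <- .load_stacks(dir)
  pairs <- Filter(function(s) !is.null(s$T0) && !is.null(s$T28), stacks)
  if (is.null(rois)) {
    d <- dim(pairs[[1]]$T0$lab_values)
    rois <- default_rois(d[3], d[2])
  }
  tab <- roi_change_table(pairs, rois, alpha = config$alpha)
  write.csv(tab, file.path(out_dir, "roi", "roi_changes.csv"),
            row.names = FALSE)
  invisible(tab)
}

#' Run the full study pipeline
#'
#' Stages: (1) read and colour-correct every image against its chart;
#' (2) mirror right sides; (3) estimate the reference shape from all
#' landmark sets; (4) TPS-warp every image into reference space;
#' (5) build per-group, per-timepoint registered stacks (left and
#' mirrored-right sides merged per subject); (6) average faces, per-pixel
#' change maps, relevance map and three significance maps per group;
#' (7) classical ROI table; (8) QC JSON and run log.
#'
#' The output directory layout is deterministic: `calibrated/`,
#' `registered/`, `averages/`, `maps/`, `roi/`, `qc.json`, `run.log`.
#' Reruns with identical inputs and config produce byte-identical TIFF
#' and PNG outputs.
#'
#' @param manifest path to a manifest CSV or a data.frame from
#'   [read_manifest()].
#' @param out_dir output directory.
#' @param config a [facemap_config()].
#' @param rois list of [roi_spec()]s; default [default_rois()] on the
#'   reference raster.
#' @param write_intermediates write calibrated PNGs and registered stack
#'   TIFFs (default `TRUE`).
#' @return Invisibly, a list with the reference space, stacks, change
#'   maps, ROI table and QC summary.
#' @export
run_pipeline <- function(manifest, out_dir, config = facemap_config(),
                         rois = NULL, write_intermediates = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  for (d in c("", "calibrated", "registered", "averages", "maps", "roi"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  reg <- .register_all(manifest, config, out_dir,
                       write_intermediates = write_intermediates)
  stacks <- reg$stacks
  if (write_intermediates)
    for (g in names(stacks)) for (tp in names(stacks[[g]]))
      write_stack(stacks[[g]][[tp]],
                  file.path(out_dir, "registered", paste0(g, "_", tp, ".tiff")))
  cms <- list(); qc <- list()
  for (g in names(stacks)) {
    if (is.null(stacks[[g]]$T0) || is.null(stacks[[g]]$T28)) next
    r <- .emit_maps_group(g, stacks[[g]], out_dir, config)
    cms[[g]] <- r$cm; qc[[g]] <- r$qc
  }
  W <- reg$reference$width; H <- reg$reference$height
  if (is.null(rois)) rois <- default_rois(W, H)
  pairs <- Filter(function(s) !is.null(s$T0) && !is.null(s$T28), stacks)
  roi_table <- roi_change_table(pairs, rois, alpha = config$alpha)
  write.csv(roi_table, file.path(out_dir, "roi", "roi_changes.csv"),
            row.names = FALSE)
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- c(
    paste("facemap", as.character(packageVersion("facemap"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("config:", jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      null = "null")),
    paste("images:", nrow(manifest)),
    reg$log_lines,
    sprintf("reference raster: %d x %d", W, H),
    sprintf("groups analysed: %s", paste(names(pairs), collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(reference = reg$reference, stacks = stacks,
                 change_maps = cms, roi_table = roi_table, qc = qc))
}
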