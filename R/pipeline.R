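#' Run configuration for an end-to-end quantification
#'
#' Groups experimental fields with their matched isotype-control fields,
#' mirroring the usual acquisition layout (several experimental images per
#' replicate plus 1-3 isotype images per staining run).
#'
#' @param groups named list: condition -> list of [field()] objects.
#' @param isotype named list: condition -> list of isotype [field()] objects
#'   (at least one per group), or a single list shared by all groups.
#' @param channels channels to quantify.
#' @param mode per-channel quantification mode (`"nearest"` or `"nuclear"`).
#' @param segmentation,stain [segmentation_config()] lists.
#' @param fallback_rule see [assign_nearest_stain()].
#' @param neighbor_radius_um spatial classification radius.
#' @param seed seed recorded in the manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(groups, isotype, channels = c("green", "red"),
                       mode = "nearest",
                       segmentation = segmentation_config(),
                       stain = segmentation_config(min_area_px = 5),
                       fallback_rule = "other_nucleus",
                       neighbor_radius_um = 50, seed = 1L) {
  stopifnot(is.list(groups), !is.null(names(groups)), length(groups) >= 1)
  if (!is.null(names(isotype)) && all(names(groups) %in% names(isotype))) {
    iso <- isotype[names(groups)]
  } else {
    iso <- stats::setNames(rep(list(isotype), length(groups)), names(groups))
  }
  for (g in names(groups)) {
    if (length(iso[[g]]) < 1)
      stop(sprintf("group '%s' references no isotype field", g))
  }
  structure(list(groups = groups, isotype = iso, channels = channels,
                 mode = mode, segmentation = segmentation, stain = stain,
                 fallback_rule = fallback_rule,
                 neighbor_radius_um = neighbor_radius_um, seed = seed),
            class = "run_config")
}

#' Run the full per-cell quantification
#'
#' For every group: segment the isotype fields, pool their per-cell raw
#' intensities into the isotype reference per channel, then quantify each
#' experimental field against those references and classify cells spatially.
#' The manifest records package version, configuration, per-field DAPI
#' thresholds, per-field fallback rates, and the isotype references.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes `cells.csv` and
#'   `manifest.json` there.
#' @return list with `cells` (tidy per-cell data frame) and `manifest`.
#' @export
run_quantification <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  qc <- list(segmentation = config$segmentation, stain = config$stain,
             fallback_rule = config$fallback_rule)
  all_cells <- list()
  manifest_fields <- list()
  refs_log <- list()
  for (g in names(config$groups)) {
    iso_vals <- stats::setNames(
      lapply(config$channels, function(ch) list()), config$channels)
    for (fi in seq_along(config$isotype[[g]])) {
      f <- config$isotype[[g]][[fi]]
      nuc <- segment_field(f, config$segmentation)
      if (nrow(nuc$table) == 0)
        stop(sprintf("isotype field '%s' of group '%s' contains no cells", f$field_id, g))
      for (ch in config$channels) {
        md <- if (length(config$mode) > 1) config$mode[[ch]] else config$mode
        vals <- if (md == "nuclear")
          nuclear_intensity(nuc, f, ch)$raw
        else {
          st <- build_stain_mask(f, ch, config$stain)
          # isotype fields carry no specific stain: use nuclear-region means as
          # the nonspecific per-cell baseline when no stain component exists
          if (length(st$comp_mean) == 0) nuclear_intensity(nuc, f, ch)$raw
          else assign_nearest_stain(nuc, st, fallback_value = 0,
                                    rule = config$fallback_rule)$raw
        }
        iso_vals[[ch]] <- c(iso_vals[[ch]], list(vals))
      }
    }
    refs <- lapply(iso_vals, isotype_reference)
    refs_log[[g]] <- lapply(refs, function(r) r$mean)
    for (f in config$groups[[g]]) {
      nuc <- segment_field(f, config$segmentation)
      cells <- quantify_field(f, references = refs, mode = config$mode,
                              config = qc, nuclei = nuc)
      cells$group_id <- g
      if (nrow(cells) > 0)
        cells <- classify_colony_single(cells, um_per_px = f$um_per_px,
                                        neighbor_radius_um = config$neighbor_radius_um)
      all_cells[[length(all_cells) + 1]] <- cells
      fb_cols <- grep("^fallback_", names(cells), value = TRUE)
      manifest_fields[[f$field_id]] <- list(
        group = g, n_cells = nrow(cells),
        dapi_threshold = attr(nuc, "threshold"),
        fallback_rate = if (nrow(cells) > 0)
          vapply(fb_cols, function(cn) mean(cells[[cn]]), numeric(1))
        else stats::setNames(numeric(length(fb_cols)), fb_cols))
    }
  }
  cells <- do.call(rbind, all_cells)
  manifest <- list(
    package = "trophoquant",
    version = as.character(utils::packageVersion("trophoquant")),
    seed = config$seed,
    channels = config$channels, mode = config$mode,
    segmentation = config$segmentation, stain = config$stain,
    fallback_rule = config$fallback_rule,
    neighbor_radius_um = config$neighbor_radius_um,
    isotype_references = refs_log,
    fields = manifest_fields)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(cells = cells, manifest = manifest)
}

#' Compare groups on a quantified channel
#'
#' For each requested contrast: group sizes, means, medians, the large-sample
#' Mann-Whitney p-value, and the raw-p significance marker (`ns`/`*`/`**`/
#' `***` at 0.05 / 0.005 / 0.0005).
#'
#' @param cells per-cell data frame from [run_quantification()].
#' @param contrasts list of 2-element character vectors of `group_id`s, or a
#'   2-row character matrix; `NULL` compares all pairs.
#' @param channel channel to compare (uses `norm_<channel>`).
#' @param group_col grouping column (default `"group_id"`; use
#'   `"spatial_class"` or `"quartile_label"` for the within-condition
#'   breakdowns).
#' @return data frame, one row per contrast.
#' @export
run_comparison <- function(cells, contrasts = NULL, channel = "green",
                           group_col = "group_id") {
  vcol <- paste0("norm_", channel)
  stopifnot(vcol %in% names(cells), group_col %in% names(cells))
  groups <- unique(as.character(cells[[group_col]]))
  if (is.null(contrasts)) {
    cm <- utils::combn(groups, 2)
    contrasts <- lapply(seq_len(ncol(cm)), function(j) cm[, j])
  }
  if (is.matrix(contrasts))
    contrasts <- lapply(seq_len(ncol(contrasts)), function(j) contrasts[, j])
  do.call(rbind, lapply(contrasts, function(ct) {
    if (!all(ct %in% groups))
      stop("contrast references unknown group: ",
           paste(setdiff(ct, groups), collapse = ", "))
    a <- cells[[vcol]][cells[[group_col]] == ct[1]]
    b <- cells[[vcol]][cells[[group_col]] == ct[2]]
    tr <- mann_whitney_large_sample(a, b)
    data.frame(group1 = ct[1], group2 = ct[2],
               n1 = length(a), n2 = length(b),
               mean1 = mean(a), mean2 = mean(b),
               median1 = stats::median(a), median2 = stats::median(b),
               U = tr$statistic, p_value = tr$p_value,
               marker = significance_marker(tr$p_value))
  }))
}

#' Violin-style diagnostic plot of per-cell intensities
#'
#' Draws the per-group intensity distributions with a white circle at the
#' mean and a black bar at the median. Diagnostic only; requires ggplot2.
#'
#' @inheritParams run_comparison
#' @return a ggplot object.
#' @export
plot_group_violin <- function(cells, channel = "green", group_col = "group_id") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for diagnostic plots")
  vcol <- paste0("norm_", channel)
  df <- data.frame(group = factor(cells[[group_col]]), value = cells[[vcol]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.25, linewidth = 0.6, colour = "black") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 21,
                          size = 3, fill = "white") +
    ggplot2::labs(x = NULL, y = sprintf("normalized %s intensity", channel)) +
    ggplot2::theme_classic()
}

#' Write the canonical synthetic fixture suite
#'
#' Deterministically regenerates, from a single seed, the fixture set used to
#' exercise every pipeline stage: counting fields (1, 5, 50 nuclei),
#' a stain-offset field that triggers the fallback rule, a two-population
#' field, membrane fields at fusion indices 0 / 0.4 / 0.9, and a Ct table —
#' each with its ground truth.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; identical seeds give bit-identical fixtures.
#' @return invisibly, a named list of the generated objects.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  out <- list()
  for (k in c(1L, 5L, 50L)) {
    sp <- field_spec(n_colonies = 0, n_single_cells = k, colony_radius_um = 12,
                     noise_sd = 0, background = 0, seed = seed + k)
    g <- generate_field(sp)
    pre <- file.path(out_dir, sprintf("count_%03d", k))
    write_field(g$field, pre)
    write_ground_truth(g$truth, paste0(pre, "_truth.csv"))
    write_field_spec(sp, paste0(pre, "_spec.yaml"))
    out[[sprintf("count_%03d", k)]] <- g
  }
  sp_fb <- field_spec(n_colonies = 2, cells_per_colony = c(3, 5),
                      n_single_cells = 3, stain_offset_px = 30,
                      noise_sd = 0, seed = seed + 101L)
  g <- generate_field(sp_fb)
  write_field(g$field, file.path(out_dir, "fallback"))
  write_ground_truth(g$truth, file.path(out_dir, "fallback_truth.csv"))
  out$fallback <- g
  sp_2p <- field_spec(n_colonies = 3, n_single_cells = 4, noise_sd = 0,
                      seed = seed + 202L)
  g <- generate_field(sp_2p)
  write_field(g$field, file.path(out_dir, "two_population"))
  write_ground_truth(g$truth, file.path(out_dir, "two_population_truth.csv"))
  out$two_population <- g
  for (fi in c(0, 0.4, 0.9)) {
    sp <- field_spec(n_colonies = 0, n_single_cells = 20, noise_sd = 0,
                     seed = seed + 300L + round(10 * fi))
    m <- generate_membrane_field(sp, fi)
    pre <- file.path(out_dir, sprintf("membrane_fi%02d", round(100 * fi)))
    write_field(m$field, pre)
    write_ground_truth(m$truth, paste0(pre, "_truth.csv"))
    out[[sprintf("membrane_fi%02d", round(100 * fi))]] <- m
  }
  ct <- generate_ct_table(
    genes = c("CYP19A1", "ERVW1", "TP63"), conditions = c("day0", "day4", "day6"),
    replicates = 3,
    true_log2fc = cbind(day0 = c(0, 0, 0), day4 = c(2, 1.5, -1.5),
                        day6 = c(3, 2.5, -2.5)),
    ct_noise_sd = 0.2, seed = seed + 400L)
  utils::write.csv(as.data.frame(ct), file.path(out_dir, "ct_table.csv"),
                   row.names = FALSE)
  out$ct_table <- ct
  invisible(out)
}
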