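#' Specification for a synthetic fluorescence field
#'
#' Describes the layout and intensity model of a simulated multichannel
#' immunofluorescence field: DAPI-stained nuclei arranged as epithelial
#' colonies plus isolated single cells, and red/green marker channels whose
#' per-cell intensities are drawn from a population mixture (by default two
#' anti-correlated populations, emulating HLA-G-high/Notch1-low mesenchymal
#' cells versus HLA-G-low/Notch1-high colony cells).
#'
#' Construction guarantees of the generator:
#' * every nucleus disk lies fully inside the image;
#' * nuclei are non-overlapping (center separation > 2 x max radius), unless
#'   `touching = TRUE`, which places a twin next to each single cell at
#'   1.5 x radius spacing to exercise watershed splitting;
#' * single cells have no other nucleus centroid within `colony_radius_um`;
#'   colony members have at least one.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param um_per_px micrometres per pixel (default 0.62, a typical 20x
#'   confocal export; the acquisition scale is an assumption of the model).
#' @param n_colonies number of colonies.
#' @param cells_per_colony integer range `c(min, max)`, `min >= 2`.
#' @param n_single_cells number of isolated cells.
#' @param colony_spacing_um minimum distance between colony centers.
#' @param colony_radius_um neighbor radius defining colony membership
#'   (default 50, matching the single-cell/colony classification rule).
#' @param nucleus_radius_px integer range of nucleus disk radii.
#' @param populations population mixture: a data frame with columns `name`,
#'   `prob`, and `<channel>_mean` / `<channel>_sd` per stain channel; see
#'   [default_populations()].
#' @param stain_radius_px radius of the stain blob rendered per cell.
#' @param stain_offset_px distance of the stain blob center from the nucleus
#'   centroid (0 = stain over the nucleus; > 0 triggers the fallback rule
#'   deliberately when it exceeds the inter-nucleus spacing).
#' @param dapi_intensity rendered DAPI value of nucleus pixels.
#' @param background additive background level on all channels.
#' @param noise_sd standard deviation of Gaussian pixel noise (8-bit scale).
#' @param max_intensity intensity ceiling (default 255, 8-bit).
#' @param quantize round pixel values to integers (default `FALSE` so that
#'   intensity-recovery checks are exact).
#' @param touching place sub-diameter twins next to single cells.
#' @param seed RNG seed; a fixed seed makes generation bit-identical.
#'
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(image_height_px = 512, image_width_px = 512,
                       um_per_px = 0.62,
                       n_colonies = 3, cells_per_colony = c(4, 8),
                       n_single_cells = 5,
                       colony_spacing_um = 150, colony_radius_um = 50,
                       nucleus_radius_px = c(4, 6),
                       populations = default_populations(),
                       stain_radius_px = 4, stain_offset_px = 0,
                       dapi_intensity = 200, background = 2, noise_sd = 2,
                       max_intensity = 255, quantize = FALSE,
                       touching = FALSE, seed = 1L) {
  stopifnot(image_height_px >= 16, image_width_px >= 16, um_per_px > 0,
            n_colonies >= 0, n_single_cells >= 0,
            length(cells_per_colony) == 2, cells_per_colony[1] >= 2,
            cells_per_colony[2] >= cells_per_colony[1],
            length(nucleus_radius_px) == 2, nucleus_radius_px[1] >= 1,
            colony_spacing_um > 0, colony_radius_um > 0,
            stain_radius_px >= 1, stain_offset_px >= 0,
            background >= 0, noise_sd >= 0, max_intensity > 0)
  if (!is.null(populations)) {
    stopifnot(is.data.frame(populations), all(c("name", "prob") %in% names(populations)),
              abs(sum(populations$prob) - 1) < 1e-8)
  }
  structure(as.list(environment()), class = "field_spec")
}

#' Default two-population marker model
#'
#' Green carries an HLA-G-like marker, red a Notch1-like marker; the two
#' populations are anti-correlated (high in one marker, low in the other),
#' emulating the heterogeneity of day-6 extravillous trophoblast cultures.
#'
#' @return a data frame usable as `populations` in [field_spec()].
#' @export
default_populations <- function() {
  data.frame(
    name = c("green_high", "green_low"),
    prob = c(0.5, 0.5),
    green_mean = c(200, 50), green_sd = c(10, 8),
    red_mean = c(50, 200), red_sd = c(8, 10)
  )
}

# stain channels implied by a populations table ("green_mean" -> "green")
.pop_channels <- function(populations) {
  if (is.null(populations)) return(character(0))
  nm <- names(populations)
  sub("_mean$", "", nm[grepl("_mean$", nm)])
}

# sample integers uniformly from [lo, hi] (safe for degenerate lo == hi,
# where sample() would treat the scalar as a range length)
.sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq.int(lo, hi), n, replace = TRUE)
}

# pixel index matrix of a filled disk clipped to the image
.disk_pixels <- function(nr, nc, r0, c0, rad) {
  rows <- max(1L, floor(r0 - rad)):min(nr, ceiling(r0 + rad))
  cols <- max(1L, floor(c0 - rad)):min(nc, ceiling(c0 + rad))
  d2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
  idx <- which(d2 <= rad^2, arr.ind = TRUE)
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}

# rejection-sample nucleus centroids honoring the field_spec layout invariants
.place_nuclei <- function(spec, max_tries = 4000L) {
  nr <- spec$image_height_px; nc <- spec$image_width_px
  rmax <- spec$nucleus_radius_px[2]
  sep <- 2 * rmax + 2                      # non-overlap center separation
  col_rad <- spec$colony_radius_um / spec$um_per_px
  margin <- rmax + 2
  pts <- matrix(numeric(0), 0, 2)
  colony_of <- integer(0)

  draw <- function(ok, what) {
    for (t in seq_len(max_tries)) {
      p <- c(stats::runif(1, margin, nr - margin), stats::runif(1, margin, nc - margin))
      if (ok(p)) return(p)
    }
    stop(sprintf("infeasible packing: could not place %s within %d tries (image too small for the requested layout)",
                 what, max_tries))
  }
  min_dist <- function(p, q = pts) if (nrow(q) == 0) Inf else
    sqrt(min((q[, 1] - p[1])^2 + (q[, 2] - p[2])^2))

  centers <- matrix(numeric(0), 0, 2)
  spread <- 0.45 * col_rad
  if (spec$n_colonies > 0) {
    spacing <- spec$colony_spacing_um / spec$um_per_px
    for (k in seq_len(spec$n_colonies)) {
      ctr <- draw(function(p) {
        p[1] > margin + spread && p[1] < nr - margin - spread &&
        p[2] > margin + spread && p[2] < nc - margin - spread &&
        min_dist(p, centers) >= spacing
      }, sprintf("colony center %d (spacing %.0f um)", k, spec$colony_spacing_um))
      centers <- rbind(centers, ctr)
      m <- .sample_range(spec$cells_per_colony[1], spec$cells_per_colony[2], 1)
      for (j in seq_len(m)) {
        p <- draw(function(p) {
          sqrt(sum((p - ctr)^2)) <= spread && min_dist(p) > sep
        }, sprintf("colony %d member %d", k, j))
        pts <- rbind(pts, p)
        colony_of <- c(colony_of, k)
      }
    }
  }
  for (k in seq_len(spec$n_single_cells)) {
    p <- draw(function(p) min_dist(p) > max(sep, col_rad),
              sprintf("single cell %d (exclusion radius %.0f um)", k, spec$colony_radius_um))
    pts <- rbind(pts, p)
    colony_of <- c(colony_of, 0L)
  }
  radii <- .sample_range(spec$nucleus_radius_px[1], spec$nucleus_radius_px[2],
                         nrow(pts))
  pair_of <- rep(NA_integer_, nrow(pts))

  if (isTRUE(spec$touching)) {
    singles <- which(colony_of == 0L)
    for (i in singles) {
      r <- radii[i]
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        a <- stats::runif(1, 0, 2 * pi)
        q <- pts[i, ] + 1.5 * r * c(cos(a), sin(a))
        others <- pts[-i, , drop = FALSE]
        if (q[1] > margin && q[1] < nr - margin && q[2] > margin && q[2] < nc - margin &&
            (nrow(others) == 0 || min_dist(q, others) > sep)) {
          pts <- rbind(pts, q); radii <- c(radii, r)
          colony_of <- c(colony_of, 0L)
          pair_of[i] <- nrow(pts); pair_of <- c(pair_of, i)
          placed <- TRUE; break
        }
      }
      if (!placed) stop("infeasible packing: could not place touching twin")
    }
  }
  data.frame(row = pts[, 1], col = pts[, 2], radius_px = radii,
             colony_id = colony_of, pair_of = pair_of)
}

# shared renderer for experimental and isotype fields
.generate_field_impl <- function(spec, render_stain) {
  set.seed(spec$seed)
  layout <- .place_nuclei(spec)
  n <- nrow(layout)
  nr <- spec$image_height_px; nc <- spec$image_width_px
  channels <- .pop_channels(spec$populations)

  if (n > 0 && length(channels) > 0) {
    pop_idx <- sample.int(nrow(spec$populations), n, replace = TRUE,
                          prob = spec$populations$prob)
  } else pop_idx <- integer(n)
  true_int <- matrix(spec$background, n, length(channels),
                     dimnames = list(NULL, channels))
  if (render_stain && n > 0) {
    for (ch in channels) {
      mu <- spec$populations[[paste0(ch, "_mean")]][pop_idx]
      sdv <- spec$populations[[paste0(ch, "_sd")]][pop_idx]
      v <- stats::rnorm(n, mu, sdv)
      true_int[, ch] <- pmin(pmax(v, 0), spec$max_intensity)
    }
  }

  blue <- matrix(spec$background, nr, nc)
  for (i in seq_len(n))
    blue[.disk_pixels(nr, nc, layout$row[i], layout$col[i], layout$radius_px[i])] <-
      spec$dapi_intensity

  stain <- stats::setNames(
    lapply(channels, function(ch) matrix(spec$background, nr, nc)), channels)
  if (render_stain && n > 0 && length(channels) > 0) {
    if (spec$stain_offset_px > 0) {
      ang <- stats::runif(n, 0, 2 * pi)
      sr <- layout$row + spec$stain_offset_px * cos(ang)
      sc <- layout$col + spec$stain_offset_px * sin(ang)
    } else { sr <- layout$row; sc <- layout$col }
    for (ch in channels) for (i in seq_len(n)) {
      px <- .disk_pixels(nr, nc, sr[i], sc[i], spec$stain_radius_px)
      if (nrow(px) > 0) stain[[ch]][px] <- true_int[i, ch]
    }
  }

  finish <- function(m) {
    if (spec$noise_sd > 0) m <- m + stats::rnorm(length(m), 0, spec$noise_sd)
    m <- pmin(pmax(m, 0), spec$max_intensity)
    if (isTRUE(spec$quantize)) m <- round(m)
    m
  }
  chans <- c(list(blue = finish(blue)), lapply(stain, finish))

  truth <- data.frame(
    cell_id = seq_len(n),
    true_row = layout$row, true_col = layout$col,
    radius_px = layout$radius_px,
    population = if (n > 0 && length(channels) > 0 && nrow(spec$populations) > 0)
      spec$populations$name[pop_idx] else rep(NA_character_, n),
    true_spatial_class = ifelse(layout$colony_id > 0 | !is.na(layout$pair_of),
                                "colony", "single"),
    true_syncytium_id = rep(NA_integer_, n)
  )
  for (ch in channels) truth[[paste0("true_", ch)]] <- true_int[, ch]

  list(field = field(chans, spec$um_per_px,
                     field_id = sprintf("synth_seed%d", spec$seed),
                     is_isotype = !render_stain),
       truth = truth)
}

#' Generate a ground-truthed synthetic fluorescence field
#'
#' Renders nuclei as filled DAPI disks and per-cell stain blobs carrying each
#' cell's true marker intensity, plus background and Gaussian noise clipped to
#' `[0, max_intensity]`. The accompanying ground-truth table has one row per
#' nucleus (unique `cell_id`, true centroid, population label, true per-channel
#' intensity, spatial class).
#'
#' @param spec a [field_spec()].
#' @return a list with elements `field` (a [field()]) and `truth` (data frame).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  .generate_field_impl(spec, render_stain = TRUE)
}

#' Generate a matched isotype-control field
#'
#' Nuclei are rendered exactly as in [generate_field()] (same seed gives the
#' same layout), but the stain channels contain only background and noise —
#' the nonspecific-signal baseline an isotype-control antibody defines. The
#' ground truth records the background level as each cell's true intensity.
#'
#' @inheritParams generate_field
#' @return a list with elements `field` (with `is_isotype = TRUE`) and `truth`.
#' @export
generate_isotype_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  .generate_field_impl(spec, render_stain = FALSE)
}

#' Generate a membrane-stained field with a known fusion index
#'
#' Partitions the plane into closed membrane-bounded regions, places nuclei so
#' that the resulting syncytium assignments reproduce a requested fusion index
#' `(N - S)/T` to within the attainable granularity `1/T`, where `N` is the
#' number of nuclei inside syncytia, `S` the number of syncytia (each holding
#' at least 2 nuclei), and `T` the total nucleus count. The nucleus count is
#' taken from `spec$n_single_cells` (set `n_colonies = 0`).
#'
#' @param spec a [field_spec()] with `n_colonies = 0`.
#' @param target_fusion_index requested fusion index in `[0, 1)`.
#' @return list with `field` (channels `blue` and `membrane`), `truth`
#'   (with `true_syncytium_id` set for nuclei inside syncytia),
#'   `region_labels` (integer matrix mapping pixels to regions, 0 = membrane),
#'   and `counts` (a [syncytium_counts()] with the true N, S, T).
#' @export
generate_membrane_field <- function(spec, target_fusion_index) {
  stopifnot(inherits(spec, "field_spec"),
            target_fusion_index >= 0, target_fusion_index < 1)
  if (spec$n_colonies > 0)
    stop("membrane fields place nuclei per region; use n_colonies = 0 and n_single_cells as the total nucleus count")
  tot <- spec$n_single_cells
  if (tot < 1) stop("at least one nucleus required")
  k <- round(target_fusion_index * tot)    # N - S
  if (k > tot - 1)
    stop(sprintf("fusion index %.3g unreachable with %d nuclei (granularity 1/%d)",
                 target_fusion_index, tot, tot))
  if (k == 0) { S <- 0L; N <- 0L } else {
    S <- as.integer(min(max(1, k %/% 4), tot - k))
    N <- as.integer(k + S)
  }
  sizes <- if (S > 0) {
    base <- rep(N %/% S, S)
    extra <- N %% S
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  } else integer(0)
  stopifnot(all(sizes >= 2))
  occupancy <- c(sizes, rep(1L, tot - N))
  G <- length(occupancy)

  set.seed(spec$seed)
  nr <- spec$image_height_px; nc <- spec$image_width_px
  gr <- max(1L, floor(sqrt(G)))
  gc <- as.integer(ceiling(G / gr))
  redges <- round(seq(1, nr, length.out = gr + 1))
  cedges <- round(seq(1, nc, length.out = gc + 1))

  region <- matrix(0L, nr, nc)
  for (ri in seq_len(gr)) for (ci in seq_len(gc)) {
    rows <- (redges[ri] + 1):(redges[ri + 1] - 1)
    cols <- (cedges[ci] + 1):(cedges[ci + 1] - 1)
    id <- (ri - 1L) * gc + ci
    region[rows, cols] <- min(id, G)        # surplus grid cells merge into region G
  }
  membrane <- matrix(spec$background, nr, nc)
  membrane[region == 0L] <- 180

  rmax <- spec$nucleus_radius_px[2]
  sep <- 2 * rmax + 2
  rows_out <- cols_out <- numeric(0); reg_out <- integer(0)
  for (g in seq_len(G)) {
    m <- occupancy[g]
    if (m == 0) next
    ri <- (g - 1L) %/% gc + 1L; ci <- (g - 1L) %% gc + 1L
    rlo <- redges[ri] + rmax + 2; rhi <- redges[ri + 1] - rmax - 2
    clo <- cedges[ci] + rmax + 2; chi <- cedges[ci + 1] - rmax - 2
    if (rhi <= rlo || chi <= clo)
      stop("infeasible packing: membrane region too small for nuclei; enlarge the image or reduce n_single_cells")
    placed <- matrix(numeric(0), 0, 2)
    for (j in seq_len(m)) {
      ok <- FALSE
      for (t in 1:4000) {
        p <- c(stats::runif(1, rlo, rhi), stats::runif(1, clo, chi))
        if (nrow(placed) == 0 ||
            min(sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2)) > sep) {
          placed <- rbind(placed, p); ok <- TRUE; break
        }
      }
      if (!ok) stop("infeasible packing: membrane region too crowded; enlarge the image or reduce the target")
    }
    rows_out <- c(rows_out, placed[, 1]); cols_out <- c(cols_out, placed[, 2])
    reg_out <- c(reg_out, rep(g, m))
  }
  n <- length(rows_out)
  radii <- .sample_range(spec$nucleus_radius_px[1], rmax, n)
  blue <- matrix(spec$background, nr, nc)
  for (i in seq_len(n))
    blue[.disk_pixels(nr, nc, rows_out[i], cols_out[i], radii[i])] <- spec$dapi_intensity
  finish <- function(m) {
    if (spec$noise_sd > 0) m <- m + stats::rnorm(length(m), 0, spec$noise_sd)
    m <- pmin(pmax(m, 0), spec$max_intensity)
    if (isTRUE(spec$quantize)) m <- round(m)
    m
  }
  syn_regions <- which(occupancy >= 2L)
  col_rad_px <- spec$colony_radius_um / spec$um_per_px
  spat <- vapply(seq_len(n), function(i) {
    d <- sqrt((rows_out - rows_out[i])^2 + (cols_out - cols_out[i])^2)
    if (any(d[-i] <= col_rad_px)) "colony" else "single"
  }, character(1))
  truth <- data.frame(
    cell_id = seq_len(n), true_row = rows_out, true_col = cols_out,
    radius_px = radii, population = NA_character_,
    true_spatial_class = spat,
    true_syncytium_id = ifelse(reg_out %in% syn_regions, reg_out, NA_integer_)
  )
  list(field = field(list(blue = finish(blue), membrane = finish(membrane)),
                     spec$um_per_px,
                     field_id = sprintf("membrane_seed%d", spec$seed)),
       truth = truth,
       region_labels = region,
       counts = syncytium_counts(N = N, S = S, T = as.integer(tot)))
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Constructs Ct values so the delta-delta-Ct pipeline recovers the requested
#' log2 fold changes exactly when `ct_noise_sd = 0`: for each target gene,
#' `Ct(condition) = base_ct - true_log2fc(condition)` (an upregulated gene
#' amplifies earlier), while housekeeping genes are constant across
#' conditions.
#'
#' @param genes character vector of target gene names.
#' @param conditions character vector of conditions; the first is the
#'   reference (e.g. `"day0"`).
#' @param replicates number of replicates per condition.
#' @param true_log2fc numeric matrix `genes x conditions` of true log2 fold
#'   changes relative to the reference (the reference column must be 0).
#' @param ct_noise_sd Gaussian noise added to every Ct value.
#' @param seed RNG seed.
#' @param housekeeping names of the housekeeping genes (true fold change 0).
#' @param base_ct optional named vector of baseline Cts per gene.
#' @return a `ct_table` data frame (`gene`, `condition`, `replicate`, `ct`,
#'   `role`) with attributes `housekeeping` and `reference`.
#' @export
generate_ct_table <- function(genes, conditions, replicates = 3,
                              true_log2fc, ct_noise_sd = 0, seed = 1L,
                              housekeeping = c("GAPDH", "ACTB"),
                              base_ct = NULL) {
  if (length(conditions) < 1) stop("missing reference condition")
  reference <- conditions[1]
  true_log2fc <- as.matrix(true_log2fc)
  if (is.null(rownames(true_log2fc))) rownames(true_log2fc) <- genes
  if (is.null(colnames(true_log2fc))) colnames(true_log2fc) <- conditions
  if (any(abs(true_log2fc[, reference]) > 1e-12))
    stop("true_log2fc of the reference condition must be 0")
  all_genes <- c(genes, setdiff(housekeeping, genes))
  if (is.null(base_ct))
    base_ct <- stats::setNames(
      ifelse(all_genes %in% housekeeping, 15, 22 + seq_along(all_genes) %% 5),
      all_genes)
  set.seed(seed)
  rows <- expand.grid(gene = all_genes, condition = conditions,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  lfc <- mapply(function(g, cond) {
    if (g %in% housekeeping) 0
    else if (g %in% rownames(true_log2fc)) true_log2fc[g, cond] else 0
  }, rows$gene, rows$condition)
  rows$ct <- base_ct[rows$gene] - lfc +
    if (ct_noise_sd > 0) stats::rnorm(nrow(rows), 0, ct_noise_sd) else 0
  rows$role <- ifelse(rows$gene %in% housekeeping, "housekeeping", "target")
  rownames(rows) <- NULL
  structure(rows, class = c("ct_table", "data.frame"),
            housekeeping = housekeeping, reference = reference)
}

#' Write a ground-truth table to CSV
#'
#' Header: `cell_id, true_row, true_col, radius_px, population,
#' true_spatial_class, true_syncytium_id, true_<channel>...`.
#'
#' @param truth ground-truth data frame from a generator.
#' @param path output CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Write a field spec as YAML
#' @param spec a [field_spec()].
#' @param path output path.
#' @export
write_field_spec <- function(spec, path) {
  stopifnot(inherits(spec, "field_spec"))
  x <- unclass(spec)
  x$populations <- if (!is.null(x$populations)) as.list(x$populations) else NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a field spec written by [write_field_spec()]
#' @param path YAML path.
#' @return a [field_spec()].
#' @export
read_field_spec <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$populations)) x$populations <- as.data.frame(x$populations)
  for (nm in c("cells_per_colony", "nucleus_radius_px"))
    x[[nm]] <- as.numeric(unlist(x[[nm]]))
  do.call(field_spec, x)
}
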