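#' Build a stain mask for a marker channel
#'
#' Binarizes and cleans a stain channel with the same operator family used
#' for the DAPI channel, labels its 8-connected components, and attaches each
#' component's mean intensity computed over the ORIGINAL (pre-binarization)
#' channel values.
#'
#' @param x a [field()].
#' @param channel channel name (e.g. `"green"`).
#' @param config segmentation settings ([segmentation_config()]); stain masks
#'   default to a smaller `min_area_px` than nuclei.
#' @return an object of class `stain_mask`: list with `channel`, `mask`
#'   (logical), `labels` (integer matrix), `comp_mean` (numeric vector indexed
#'   by component label), and `threshold`.
#' @export
build_stain_mask <- function(x, channel,
                             config = segmentation_config(min_area_px = 5)) {
  stopifnot(inherits(x, "field"))
  if (!channel %in% names(x$channels))
    stop(sprintf("channel '%s' not present in field '%s'", channel, x$field_id))
  ch <- x$channels[[channel]]
  mask <- suppressWarnings(
    binarize_channel(ch, method = config$method, threshold = config$threshold))
  thr <- attr(mask, "threshold")
  mask <- clean_mask(mask, min_area_px = config$min_area_px,
                     fill_holes = config$fill_holes, split_touching = FALSE)
  lab <- .label8(mask)
  K <- max(lab)
  comp_mean <- if (K > 0)
    as.numeric(tapply(ch[lab > 0], lab[lab > 0], mean)) else numeric(0)
  structure(list(channel = channel, mask = mask, labels = lab,
                 comp_mean = comp_mean, threshold = thr),
            class = "stain_mask")
}

#' @export
print.stain_mask <- function(x, ...) {
  cat(sprintf("<stain_mask '%s'> %d components\n", x$channel, length(x$comp_mean)))
  invisible(x)
}

#' Assign each cell the intensity of its nearest stain component
#'
#' Implements the nearest-stain ownership rule: each nucleus receives the mean
#' intensity of the stain component containing its nearest stain-positive
#' pixel, unless that pixel is farther away than the nearest DAPI-positive
#' pixel belonging to a *different* nucleus — in which case the stain likely
#' belongs to a neighbor and the cell falls back to the isotype-control value.
#'
#' Distances are Euclidean, in pixels, from the nucleus centroid to the
#' nearest mask pixel. Ties (`d_stain == d_other`) resolve to no fallback;
#' among equidistant stain pixels the one with the smallest `(row, col)` wins.
#' With `rule = "any_blue"` the literal reading — distance to any DAPI pixel,
#' including the cell's own nucleus — is used instead (it degenerates to
#' near-certain fallback and exists for sensitivity analysis only).
#'
#' @param nuclei a `nucleus_set` from [label_nuclei()] / [segment_field()].
#' @param stain a [build_stain_mask()] result from the same field.
#' @param fallback_value isotype-control reference intensity (>= 0).
#' @param rule `"other_nucleus"` (default) or `"any_blue"`.
#' @return data frame with one row per nucleus: `cell_id`, `raw`, `fallback`,
#'   `d_stain`, `d_other`.
#' @export
assign_nearest_stain <- function(nuclei, stain, fallback_value,
                                 rule = c("other_nucleus", "any_blue")) {
  rule <- match.arg(rule)
  stopifnot(inherits(nuclei, "nucleus_set"), inherits(stain, "stain_mask"),
            fallback_value >= 0)
  tab <- nuclei$table
  K <- nrow(tab)
  if (K == 0)
    return(data.frame(cell_id = integer(0), raw = numeric(0),
                      fallback = logical(0), d_stain = numeric(0),
                      d_other = numeric(0)))
  nrL <- nrow(stain$labels)
  sidx <- which(stain$labels > 0)
  srow <- (sidx - 1L) %% nrL + 1L
  scol <- (sidx - 1L) %/% nrL + 1L
  slab <- stain$labels[sidx]

  bidx <- which(nuclei$labels > 0)
  brow <- (bidx - 1L) %% nrow(nuclei$labels) + 1L
  bcol <- (bidx - 1L) %/% nrow(nuclei$labels) + 1L
  bown <- nuclei$labels[bidx]

  raw <- d_stain <- d_other <- numeric(K)
  fb <- logical(K)
  for (i in seq_len(K)) {
    r0 <- tab$centroid_row[i]; c0 <- tab$centroid_col[i]
    if (length(sidx) == 0) {
      d_stain[i] <- Inf; comp <- NA_integer_
    } else {
      d2 <- (srow - r0)^2 + (scol - c0)^2
      dmin <- min(d2)
      cand <- which(d2 == dmin)
      if (length(cand) > 1)
        cand <- cand[order(srow[cand], scol[cand])][1]
      d_stain[i] <- sqrt(dmin)
      comp <- slab[cand]
    }
    sel <- if (rule == "other_nucleus") bown != tab$label[i] else rep(TRUE, length(bown))
    d_other[i] <- if (any(sel))
      sqrt(min((brow[sel] - r0)^2 + (bcol[sel] - c0)^2)) else Inf
    fb[i] <- length(sidx) == 0 || d_stain[i] > d_other[i]
    raw[i] <- if (fb[i]) fallback_value else stain$comp_mean[comp]
  }
  data.frame(cell_id = tab$label, raw = raw, fallback = fb,
             d_stain = d_stain, d_other = d_other)
}

#' Nuclear-restricted intensity
#'
#' For analyses labeled "nuclear" (HIF1-alpha / HIF2-alpha), only pixels that
#' overlap the cell's own DAPI mask contribute: each cell's value is the mean
#' of the ORIGINAL channel values over its nucleus pixel set. The nearest-stain
#' fallback rule cannot trigger here (the nucleus is its own region).
#'
#' @param nuclei a `nucleus_set`.
#' @param x the [field()] the nuclei came from.
#' @param channel channel name.
#' @param fallback_value kept for interface symmetry; used only if a nucleus
#'   has an empty pixel set (impossible for detected nuclei).
#' @return data frame `cell_id`, `raw`, `fallback`.
#' @export
nuclear_intensity <- function(nuclei, x, channel, fallback_value = 0) {
  stopifnot(inherits(nuclei, "nucleus_set"), inherits(x, "field"))
  if (!channel %in% names(x$channels))
    stop(sprintf("channel '%s' not present", channel))
  tab <- nuclei$table
  ch <- x$channels[[channel]]
  lab <- nuclei$labels
  means <- rep(NA_real_, nrow(tab))
  if (any(lab > 0)) {
    mm <- tapply(ch[lab > 0], lab[lab > 0], mean)
    means[match(as.integer(names(mm)), tab$label)] <- as.numeric(mm)
  }
  fb <- is.na(means)
  means[fb] <- fallback_value
  data.frame(cell_id = tab$label, raw = means, fallback = fb)
}

#' Isotype-control reference intensity
#'
#' Pools per-cell raw intensities across 1-3 (or more) isotype-control fields
#' processed in the same mode as the experimental fields, and returns their
#' arithmetic mean — the baseline used both as the fallback value and as the
#' normalization denominator. Pooling weights each field by its cell count;
#' `method = "per_field"` averages per-field means instead.
#'
#' @param isotype_values numeric vector, or list of numeric vectors (one per
#'   isotype field), of per-cell raw intensities.
#' @param method `"pooled"` (default) or `"per_field"`.
#' @return object of class `isotype_reference`: list with `mean`, `n`, and
#'   `per_field` (data frame of per-field n and mean).
#' @export
isotype_reference <- function(isotype_values, method = c("pooled", "per_field")) {
  method <- match.arg(method)
  if (is.numeric(isotype_values)) isotype_values <- list(isotype_values)
  stopifnot(is.list(isotype_values))
  ns <- vapply(isotype_values, length, integer(1))
  if (sum(ns) == 0) stop("zero isotype cells: normalization undefined")
  per_field <- data.frame(
    field = seq_along(isotype_values), n = ns,
    mean = vapply(isotype_values, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)))
  m <- if (method == "pooled") mean(unlist(isotype_values))
       else mean(per_field$mean[per_field$n > 0])
  structure(list(mean = m, n = sum(ns), per_field = per_field, method = method),
            class = "isotype_reference")
}

#' @export
print.isotype_reference <- function(x, ...) {
  cat(sprintf("<isotype_reference> mean %.4g over %d cells (%d field(s), %s)\n",
              x$mean, x$n, nrow(x$per_field), x$method))
  invisible(x)
}

.ref_value <- function(ref) {
  if (inherits(ref, "isotype_reference")) ref$mean else as.numeric(ref)
}

#' Quantify all cells of a field
#'
#' Runs the full per-cell assignment for one field: DAPI segmentation, then
#' per-channel intensity assignment (nearest-stain or nuclear mode) with the
#' isotype reference as the fallback value, then normalization to the
#' reference (`normalized = raw / reference`, so fallback cells normalize to
#' exactly 1).
#'
#' @param x a [field()].
#' @param references named list/vector of isotype references per quantified
#'   channel (numbers or [isotype_reference()] objects); all must be > 0.
#' @param mode per-channel mode, `"nearest"` or `"nuclear"`; a single value
#'   recycles to all channels. Surface markers (HLA-G, Notch1) use
#'   nearest-stain; HIF-alpha analyses use nuclear.
#' @param config list of settings: `segmentation` and `stain`
#'   ([segmentation_config()]) and `fallback_rule` (see
#'   [assign_nearest_stain()]).
#' @param nuclei optional pre-computed `nucleus_set` (skips segmentation).
#' @return data frame, one row per detected nucleus: `field_id`, `group_id`,
#'   `cell_id`, `centroid_row`, `centroid_col`, `area_px`, and per channel
#'   `raw_<ch>`, `fallback_<ch>`, `norm_<ch>`, `mode_<ch>`; plus
#'   `spatial_class` and `quartile_label` initialized to `"unset"`.
#' @export
quantify_field <- function(x, references, mode = "nearest",
                           config = list(), nuclei = NULL) {
  stopifnot(inherits(x, "field"))
  seg_cfg <- config$segmentation %||% segmentation_config()
  stain_cfg <- config$stain %||% segmentation_config(min_area_px = 5)
  rule <- config$fallback_rule %||% "other_nucleus"
  chans <- names(references)
  if (is.null(chans) || any(!nzchar(chans)))
    stop("`references` must be named by channel")
  if (length(mode) == 1) mode <- stats::setNames(rep(mode, length(chans)), chans)
  if (is.null(nuclei)) nuclei <- segment_field(x, seg_cfg)
  tab <- nuclei$table
  out <- data.frame(field_id = rep(x$field_id, nrow(tab)),
                    group_id = rep(x$group_id, nrow(tab)),
                    cell_id = tab$label,
                    centroid_row = tab$centroid_row,
                    centroid_col = tab$centroid_col,
                    area_px = tab$area_px)
  for (ch in chans) {
    ref <- .ref_value(references[[ch]])
    if (!is.finite(ref) || ref <= 0)
      stop(sprintf("isotype reference for channel '%s' must be > 0", ch))
    res <- if (mode[[ch]] == "nuclear")
      nuclear_intensity(nuclei, x, ch, fallback_value = ref)
    else
      assign_nearest_stain(nuclei, build_stain_mask(x, ch, stain_cfg),
                           fallback_value = ref, rule = rule)
    out[[paste0("raw_", ch)]] <- res$raw
    out[[paste0("fallback_", ch)]] <- res$fallback
    out[[paste0("norm_", ch)]] <- res$raw / ref
    out[[paste0("mode_", ch)]] <- mode[[ch]]
  }
  out$spatial_class <- rep("unset", nrow(out))
  out$quartile_label <- rep("unset", nrow(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
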