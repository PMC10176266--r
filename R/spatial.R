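#' Classify cells as colony members or isolated single cells
#'
#' A cell is `single` iff no other cell's centroid lies within the neighbor
#' radius (inclusive at exactly the boundary); otherwise `colony`. Distances
#' are centroid-to-centroid in micrometres; classification runs within each
#' field independently when a `field_id` column is present.
#'
#' @param cells data frame with `centroid_row`, `centroid_col` (px) and
#'   optionally `field_id`.
#' @param um_per_px micrometres per pixel.
#' @param neighbor_radius_um neighbor radius in micrometres (default 50).
#' @return `cells` with `spatial_class` set to `"single"` or `"colony"`.
#' @export
classify_colony_single <- function(cells, um_per_px, neighbor_radius_um = 50) {
  stopifnot(nrow(cells) >= 1, um_per_px > 0, neighbor_radius_um > 0)
  radius_px <- neighbor_radius_um / um_per_px
  fid <- if ("field_id" %in% names(cells)) cells$field_id else rep(1L, nrow(cells))
  cls <- character(nrow(cells))
  for (f in unique(fid)) {
    sel <- which(fid == f)
    r <- cells$centroid_row[sel]; c <- cells$centroid_col[sel]
    if (length(sel) == 1) { cls[sel] <- "single"; next }
    d <- as.matrix(stats::dist(cbind(r, c)))
    diag(d) <- Inf
    has_nb <- apply(d, 1, min) <= radius_px
    cls[sel] <- ifelse(has_nb, "colony", "single")
  }
  cells$spatial_class <- cls
  cells
}

#' Stratify cells into expression quartiles with double-negative exclusion
#'
#' Cells negative for BOTH markers are excluded (by default, "negative" means
#' fallback-assigned, i.e. normalized intensity exactly 1; alternatively an
#' explicit normalized-intensity threshold). The remaining n cells are sorted
#' ascending by the primary marker (ties broken by `cell_id` for
#' determinism) and labeled Q1..Q4; the extracted bottom and top groups each
#' contain exactly `floor(n/4)` cells, so they are equal-sized by
#' construction.
#'
#' @param cells data frame from [quantify_field()].
#' @param primary_channel channel whose intensity defines the quartiles
#'   (e.g. `"green"` for HLA-G).
#' @param secondary_channel second marker of the double-negative rule
#'   (e.g. `"red"` for Notch1).
#' @param negativity_rule `"fallback"` (default) or `"threshold"`.
#' @param threshold normalized-intensity cutoff when
#'   `negativity_rule = "threshold"` (negative means `norm <= threshold`).
#' @return list with `cells` (the input with `quartile_label` in
#'   `Q1..Q4`/`excluded`), `bottom` and `top` (the extracted 25% groups),
#'   and `n_included`.
#' @export
quartile_stratify <- function(cells, primary_channel, secondary_channel,
                              negativity_rule = c("fallback", "threshold"),
                              threshold = 1.0) {
  negativity_rule <- match.arg(negativity_rule)
  pn <- paste0("norm_", primary_channel)
  sn <- paste0("norm_", secondary_channel)
  stopifnot(pn %in% names(cells), sn %in% names(cells))
  neg <- if (negativity_rule == "fallback") {
    cells[[paste0("fallback_", primary_channel)]] &
      cells[[paste0("fallback_", secondary_channel)]]
  } else {
    cells[[pn]] <= threshold & cells[[sn]] <= threshold
  }
  cells$quartile_label <- ifelse(neg, "excluded", NA_character_)
  inc <- which(!neg)
  n <- length(inc)
  if (n < 4) stop(sprintf("only %d cells after double-negative exclusion: quartiles undefined", n))
  ord <- inc[order(cells[[pn]][inc], cells$cell_id[inc])]
  k <- n %/% 4
  ranks <- seq_len(n)
  lab <- character(n)
  lab[ranks <= k] <- "Q1"
  lab[ranks > n - k] <- "Q4"
  mid <- which(lab == "")
  if (length(mid) > 0) {
    half <- ceiling(length(mid) / 2)
    lab[mid[seq_len(half)]] <- "Q2"
    if (half < length(mid)) lab[mid[(half + 1):length(mid)]] <- "Q3"
  }
  cells$quartile_label[ord] <- lab
  list(cells = cells,
       bottom = cells[ord[seq_len(k)], , drop = FALSE],
       top = cells[ord[(n - k + 1):n], , drop = FALSE],
       n_included = n)
}

#' Syncytium counts
#'
#' @param N nuclei inside syncytia.
#' @param S number of syncytia (each holds >= 2 nuclei, so `N >= 2 S`).
#' @param T total nuclei counted.
#' @return object of class `syncytium_counts`.
#' @export
syncytium_counts <- function(N, S, T) {
  stopifnot(N >= 0, S >= 0, T >= 1, N <= T)
  if ((S == 0) != (N == 0)) stop("S = 0 if and only if N = 0")
  if (S > 0 && N < 2 * S) stop("each syncytium holds >= 2 nuclei, so N >= 2 S")
  structure(list(N = as.integer(N), S = as.integer(S), T = as.integer(T)),
            class = "syncytium_counts")
}

#' @export
print.syncytium_counts <- function(x, ...) {
  cat(sprintf("<syncytium_counts> N=%d S=%d T=%d (FI=%.3f)\n",
              x$N, x$S, x$T, fusion_index(x)))
  invisible(x)
}

#' Syncytial fusion index
#'
#' `FI = (N - S)/T`: the fraction of nuclei that have been gained by fusion,
#' where `N` is the number of nuclei in syncytia, `S` the number of syncytia,
#' and `T` the total number of nuclei counted. 0 for an unfused culture;
#' approaches 1 as all nuclei merge into a single syncytium.
#'
#' @param counts a [syncytium_counts()] (or list with `N`, `S`, `T`).
#' @return fusion index in `[0, 1)`.
#' @export
fusion_index <- function(counts) {
  if (!inherits(counts, "syncytium_counts"))
    counts <- syncytium_counts(counts$N, counts$S, counts$T)
  if (counts$T == 0) stop("T = 0: fusion index undefined")
  (counts$N - counts$S) / counts$T
}

#' Derive syncytium counts from a region labeling
#'
#' Automated stand-in for manual counting: each nucleus is assigned to the
#' membrane-bounded region containing its centroid (centroids falling on a
#' membrane/background pixel are assigned to the nearest region and reported
#' via the `"reassigned"` attribute); regions holding >= 2 nuclei are
#' syncytia.
#'
#' @param nuclei a `nucleus_set`, or a data frame with `centroid_row`,
#'   `centroid_col`.
#' @param region_labels integer matrix mapping each pixel to a region id
#'   (0 = membrane/background).
#' @return a [syncytium_counts()]; per-region occupancies in attribute
#'   `"occupancy"`, number of boundary reassignments in `"reassigned"`.
#' @export
syncytium_counts_from_labels <- function(nuclei, region_labels) {
  tab <- if (inherits(nuclei, "nucleus_set")) nuclei$table else nuclei
  T <- nrow(tab)
  if (T == 0) stop("no nuclei")
  ridx <- which(region_labels > 0)
  rrow <- (ridx - 1L) %% nrow(region_labels) + 1L
  rcol <- (ridx - 1L) %/% nrow(region_labels) + 1L
  reassigned <- 0L
  reg <- integer(T)
  for (i in seq_len(T)) {
    r <- round(tab$centroid_row[i]); c <- round(tab$centroid_col[i])
    r <- min(max(r, 1L), nrow(region_labels))
    c <- min(max(c, 1L), ncol(region_labels))
    id <- region_labels[r, c]
    if (id == 0L) {
      j <- which.min((rrow - tab$centroid_row[i])^2 + (rcol - tab$centroid_col[i])^2)
      id <- region_labels[ridx[j]]
      reassigned <- reassigned + 1L
    }
    reg[i] <- id
  }
  occ <- table(reg)
  syn <- occ[occ >= 2]
  out <- syncytium_counts(N = sum(syn), S = length(syn), T = T)
  attr(out, "occupancy") <- occ
  attr(out, "reassigned") <- reassigned
  out
}

#' Summarize fusion indices per condition with pairwise tests
#'
#' @param groups named list: condition -> list of [syncytium_counts()] (one
#'   per measurement).
#' @return list with `summary` (condition, n, mean, sd) and `tests`
#'   (pairwise F-test-gated t tests on the per-measurement fusion indices,
#'   with significance markers).
#' @export
fusion_index_summary <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  fis <- lapply(groups, function(g) vapply(g, fusion_index, numeric(1)))
  summ <- data.frame(
    condition = names(groups),
    n = vapply(fis, length, integer(1)),
    mean = vapply(fis, mean, numeric(1)),
    sd = vapply(fis, stats::sd, numeric(1))
  )
  rownames(summ) <- NULL
  combs <- if (length(fis) >= 2) utils::combn(names(fis), 2) else
    matrix(character(0), 2, 0)
  tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
    a <- combs[1, j]; b <- combs[2, j]
    tr <- variance_gated_t_test(fis[[a]], fis[[b]])
    data.frame(group1 = a, group2 = b, statistic = tr$statistic,
               p_value = tr$p_value, method = tr$method,
               marker = significance_marker(tr$p_value))
  }))
  list(summary = summ, tests = tests)
}
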