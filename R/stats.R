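#' Large-sample Mann-Whitney U test
#'
#' Nonparametric comparison of two samples via the normal approximation used
#' for large sample sizes: `U` is computed from midranks, the null variance
#' carries the standard tie correction, and the two-sided p-value comes from
#' the standard normal. No continuity correction is applied by default (the
#' induced error is bounded in the test suite against an exact enumeration
#' oracle).
#'
#' @param x,y numeric sample vectors.
#' @param continuity apply a 0.5 continuity correction (default `FALSE`).
#' @return object of class `test_result`: `statistic` (U for `x`), `z`,
#'   `p_value`, `method`, `n1`, `n2`, `notes`.
#' @export
mann_whitney_large_sample <- function(x, y, continuity = FALSE) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)                              # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- if (N > 1)
    n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1))) else 0
  notes <- character(0)
  if (tie_term > 0) notes <- c(notes, "tie correction applied")
  if (sigma2 <= 0) {
    return(structure(list(statistic = U, z = 0, p_value = 1,
                          method = "Mann-Whitney U (large-sample normal approximation)",
                          n1 = n1, n2 = n2,
                          notes = c(notes, "degenerate: all values identical")),
                     class = "test_result"))
  }
  dev <- U - mu
  if (continuity) {
    dev <- sign(dev) * max(abs(dev) - 0.5, 0)
    notes <- c(notes, "continuity correction applied")
  }
  z <- dev / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  structure(list(statistic = U, z = z, p_value = p,
                 method = "Mann-Whitney U (large-sample normal approximation)",
                 n1 = n1, n2 = n2, notes = notes),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Exact Mann-Whitney p-value by complete enumeration
#'
#' Enumerates all `choose(n1 + n2, n1)` assignments of the pooled values to
#' the two groups, computes the midrank U for each, and returns the exact
#' two-sided p-value `P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|)`. Intended as
#' a test oracle; guarded to `n1 + n2 <= 20`.
#'
#' @param x,y numeric sample vectors with `length(x) + length(y) <= 20`.
#' @return list with `U` (observed, midranks) and `p_value` (exact two-sided).
#' @export
exact_mann_whitney_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (N > 20) stop("enumeration guard: n1 + n2 must be <= 20")
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(N, n1)
  Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
  list(U = U_obs, p_value = p)
}

#' F-test-gated two-sample t test
#'
#' Two-tailed Student's t test with equal or unequal variance, the choice
#' gated by a two-sided F test for equality of variances: if the F test
#' rejects at `alpha_f`, Welch's unequal-variance t test is used, otherwise
#' the pooled equal-variance test.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param alpha_f significance level of the variance gate (default 0.05).
#' @return a `test_result` with the variance decision in `notes`.
#' @export
variance_gated_t_test <- function(x, y, alpha_f = 0.05) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(structure(list(
      statistic = if (equal) 0 else Inf, z = NA_real_,
      p_value = if (equal) 1 else 0,
      method = "two-sample t test (degenerate: zero variance)",
      n1 = n1, n2 = n2, notes = "degenerate: zero variance in both samples"),
      class = "test_result"))
  }
  f <- stats::var.test(x, y)
  welch <- f$p.value < alpha_f
  tt <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
  structure(list(
    statistic = unname(tt$statistic), z = NA_real_,
    p_value = tt$p.value,
    method = if (welch) "Welch two-sample t test (unequal variance)"
             else "Student two-sample t test (pooled variance)",
    n1 = n1, n2 = n2,
    notes = sprintf("F test p = %.4g -> %s variance", f$p.value,
                    if (welch) "unequal" else "equal")),
    class = "test_result")
}

#' Significance marker
#'
#' Raw-p markers: `***` below 0.0005, `**` below 0.005, `*` below 0.05,
#' `ns` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of markers.
#' @export
significance_marker <- function(p) {
  ifelse(p < 0.0005, "***", ifelse(p < 0.005, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Delta-delta-Ct relative quantification
#'
#' For every sample, each target gene's Ct is normalized against the
#' geometric mean of the housekeeping Cts (`dCt = Ct - geomean(Ct_hk)`,
#' geometric mean taken over the Ct values themselves); per condition,
#' `ddCt = mean dCt(condition) - mean dCt(reference)` over replicates, and
#' `log2FC = -ddCt`. The standard error is across replicates, and each
#' condition is compared to the reference by a two-tailed t test on the
#' per-replicate dCt values.
#'
#' @param table a `ct_table` (see [generate_ct_table()]) or data frame with
#'   columns `gene`, `condition`, `replicate`, `ct`.
#' @param housekeeping housekeeping gene names (default GAPDH and ACTB).
#' @param reference reference condition (default from the table attribute,
#'   else the first condition).
#' @return data frame, one row per target gene x condition: `gene`,
#'   `condition`, `n_rep`, `delta_ct_mean`, `delta_delta_ct`, `log2fc`, `se`,
#'   `p_value`, `marker`. The reference condition's `log2fc` is identically 0.
#' @export
delta_delta_ct <- function(table, housekeeping = NULL, reference = NULL) {
  housekeeping <- housekeeping %||% attr(table, "housekeeping") %||%
    c("GAPDH", "ACTB")
  reference <- reference %||% attr(table, "reference") %||%
    as.character(table$condition[1])
  tab <- as.data.frame(table)
  if (!reference %in% tab$condition)
    stop(sprintf("reference condition '%s' absent from table", reference))
  if (!all(housekeeping %in% tab$gene))
    stop("housekeeping gene(s) missing from table: ",
         paste(setdiff(housekeeping, tab$gene), collapse = ", "))

  sample_key <- interaction(tab$condition, tab$replicate, drop = TRUE)
  hk <- tab[tab$gene %in% housekeeping, ]
  hk_key <- interaction(hk$condition, hk$replicate, drop = TRUE)
  hk_gm <- tapply(hk$ct, hk_key, function(v) exp(mean(log(v))))
  hk_n <- tapply(hk$ct, hk_key, length)
  if (any(hk_n < length(housekeeping))) {
    bad <- names(hk_n)[hk_n < length(housekeeping)]
    stop("missing housekeeping Ct for sample(s): ", paste(bad, collapse = ", "))
  }
  if (any(!levels(sample_key) %in% names(hk_gm)))
    stop("missing housekeeping Ct for sample(s): ",
         paste(setdiff(levels(sample_key), names(hk_gm)), collapse = ", "))

  targ <- tab[!tab$gene %in% housekeeping, ]
  targ$dct <- targ$ct - as.numeric(hk_gm[as.character(
    interaction(targ$condition, targ$replicate, drop = TRUE))])

  genes <- unique(targ$gene)
  conditions <- unique(as.character(tab$condition))
  out <- do.call(rbind, lapply(genes, function(g) {
    dref <- targ$dct[targ$gene == g & targ$condition == reference]
    do.call(rbind, lapply(conditions, function(cond) {
      d <- targ$dct[targ$gene == g & targ$condition == cond]
      ddct <- mean(d) - mean(dref)
      p <- if (cond == reference) 1
        else if (length(d) >= 2 && length(dref) >= 2)
          variance_gated_t_test(d, dref)$p_value
        else NA_real_
      data.frame(gene = g, condition = cond, n_rep = length(d),
                 delta_ct_mean = mean(d), delta_delta_ct = ddct,
                 log2fc = -ddct,
                 se = if (length(d) >= 2) stats::sd(d) / sqrt(length(d)) else NA_real_,
                 p_value = p)
    }))
  }))
  out$marker <- significance_marker(out$p_value)
  rownames(out) <- NULL
  out
}
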