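#' Subjects-by-raters measurement matrix
#'
#' @param values numeric matrix, one row per subject, one column per
#'   rater/observer; no missing cells.
#' @param subject_ids,rater_ids optional identifiers.
#' @param label,units measurement description.
#' @return An object of class `rater_matrix`.
#' @export
rater_matrix <- function(values, subject_ids = NULL, rater_ids = NULL,
                         label = "", units = "") {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 2L || ncol(values) < 2L)
    stopf("`values` must be a numeric matrix with >= 2 subjects and >= 2 raters")
  if (anyNA(values)) stopf("`values` must have no missing cells")
  structure(list(values = unname(values),
                 subject_ids = subject_ids %||% as.character(seq_len(nrow(values))),
                 rater_ids = rater_ids %||% paste0("rater", seq_len(ncol(values))),
                 label = label, units = units),
            class = "rater_matrix")
}

as_rater_matrix <- function(m) {
  if (inherits(m, "rater_matrix")) m else rater_matrix(m)
}

#' Two-way random-effects average-measures ICC
#'
#' ICC(2,k) from the two-way ANOVA decomposition of a subjects x raters
#' matrix: `ICC = (MSR - MSE) / (MSR + (MSC - MSE) / n)` with MSR, MSC,
#' MSE the between-subject, between-rater and residual mean squares, `n`
#' subjects and `k` raters. Mean squares are retained in the result for
#' audit. Negative estimates are reported as computed, not clipped.
#'
#' @param m a [rater_matrix()] or bare numeric matrix.
#' @return List of class `icc_result`: `icc`, `MSR`, `MSC`, `MSE`, `n`, `k`.
#' @export
icc_2k <- function(m) {
  m <- as_rater_matrix(m)
  x <- m$values
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  if (all(x == grand)) stopf("total variance is zero; ICC undefined")
  mi <- rowMeans(x); cj <- colMeans(x)
  MSR <- k * sum((mi - grand)^2) / (n - 1)
  MSC <- n * sum((cj - grand)^2) / (k - 1)
  MSE <- sum((x - outer(mi, rep(1, k)) - outer(rep(1, n), cj) + grand)^2) /
    ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  structure(list(icc = icc, MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,k) = %.4f  [n = %d subjects, k = %d raters; MSR %.4g, MSC %.4g, MSE %.4g]\n",
              x$icc, x$n, x$k, x$MSR, x$MSC, x$MSE))
  invisible(x)
}

#' Interobserver coefficient of variation
#'
#' Per subject, the SD of the rater values (n - 1 divisor; for two raters
#' `SD = |difference| / sqrt(2)`) divided by the mean of the rater
#' values. Reported as the across-subject mean, in percent (default), or
#' as the root-mean-square pooling of the per-subject CoVs.
#'
#' @param m a [rater_matrix()] or numeric matrix.
#' @param pooling `"mean"` (default) or `"rms"`.
#' @return CoV in percent.
#' @export
cov_interobserver <- function(m, pooling = c("mean", "rms")) {
  pooling <- match.arg(pooling)
  m <- as_rater_matrix(m)
  x <- m$values
  mi <- rowMeans(x)
  if (any(mi == 0)) stopf("subject mean of zero; CoV undefined")
  cv <- apply(x, 1L, stats::sd) / mi
  100 * switch(pooling, mean = mean(cv), rms = sqrt(mean(cv^2)))
}

#' Bland-Altman agreement analysis for two raters
#'
#' Differences are rater 1 minus rater 2 (fixed by column order); bias is
#' the mean difference and the 95% limits of agreement are
#' `bias +/- 1.96 SD(diff)` (n - 1 divisor).
#'
#' @param m a [rater_matrix()] or numeric matrix with exactly 2 columns.
#' @return List: `bias`, `loa_low`, `loa_high`, `pairs` (tibble of
#'   per-subject mean and difference), `n_subjects`.
#' @export
bland_altman <- function(m) {
  m <- as_rater_matrix(m)
  x <- m$values
  if (ncol(x) != 2L) stopf("Bland-Altman requires exactly 2 raters, got %d", ncol(x))
  d <- x[, 1L] - x[, 2L]
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       pairs = tibble::tibble(mean = rowMeans(x), diff = d),
       n_subjects = nrow(x))
}

#' Conventional hypothesis tests
#'
#' Thin wrappers over the standard implementations in `stats`, returning
#' the statistic and the two-sided p-value. The 0.05 significance
#' convention is applied only at the reporting layer, never inside these
#' functions.
#'
#' @param a,b,x,y numeric vectors.
#' @param values numeric vector of observations (ANOVA).
#' @param groups group labels, same length as `values`.
#' @return A list with `statistic`, `p_value` and test-specific extras.
#' @name hypothesis_tests
NULL

#' @rdname hypothesis_tests
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stopf("paired t-test needs two equal-length vectors with n >= 2")
  if (stats::sd(a - b) == 0 && !all(a == b))
    stopf("degenerate paired differences")
  tt <- if (all(a == b)) list(statistic = 0, p.value = 1)
        else stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = mean(a - b))
}

#' @rdname hypothesis_tests
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stopf("two-sample t-test needs n >= 2 per group")
  tt <- stats::t.test(a, b)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = mean(a) - mean(b))
}

#' @rdname hypothesis_tests
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stopf("Pearson correlation needs two equal-length vectors with n >= 3")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(statistic = unname(ct$statistic), r = unname(ct$estimate),
       p_value = ct$p.value)
}

#' @rdname hypothesis_tests
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("ANOVA needs at least 2 groups")
  if (any(table(groups) < 2L)) stopf("ANOVA needs n >= 2 per group")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1L]]
  list(statistic = s[["F value"]][1L], p_value = s[["Pr(>F)"]][1L],
       df = unname(s[["Df"]]))
}

#' Pairwise group mean differences
#'
#' For each sequence x ROI kind, reports the group means and every
#' pairwise difference of group means with a two-sample t-test p-value.
#' Groups with fewer than 2 subjects are excluded with a warning.
#'
#' @param subject_table data frame with columns `subject`, `group`,
#'   `value`, and optionally `sequence` and `roi_kind`.
#' @return Tibble with one row per (sequence, roi_kind, group pair).
#' @export
group_difference_report <- function(subject_table) {
  d <- as.data.frame(subject_table)
  need <- c("subject", "group", "value")
  if (!all(need %in% names(d)))
    stopf("`subject_table` must have columns %s", paste(need, collapse = ", "))
  if (!"sequence" %in% names(d)) d$sequence <- "all"
  if (!"roi_kind" %in% names(d)) d$roi_kind <- "all"
  small <- names(which(table(unique(d[c("subject", "group")])$group) < 2L))
  if (length(small)) {
    warning(sprintf("excluding group(s) with < 2 subjects: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    d <- d[!d$group %in% small, , drop = FALSE]
  }
  rows <- lapply(split(d, interaction(d$sequence, d$roi_kind, drop = TRUE)),
                 function(dd) {
    gs <- split(dd$value, dd$group)
    gn <- names(gs)
    if (length(gn) < 2L) return(NULL)
    prs <- utils::combn(gn, 2L)
    do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      g1 <- prs[1L, i]; g2 <- prs[2L, i]
      tt <- two_sample_ttest(gs[[g1]], gs[[g2]])
      data.frame(sequence = dd$sequence[1L], roi_kind = dd$roi_kind[1L],
                 group1 = g1, group2 = g2,
                 mean1 = mean(gs[[g1]]), mean2 = mean(gs[[g2]]),
                 mean_difference = mean(gs[[g1]]) - mean(gs[[g2]]),
                 p_value = tt$p_value)
    }))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  tibble::as_tibble(res)
}

#' Interobserver reproducibility report
#'
#' Joins two observers' tidy result tables on subject, sequence and ROI
#' kind, and reports per sequence x ROI: the across-observer mean value,
#' ICC(2,k), CoV (%), and Bland-Altman bias with 95% limits of
#' agreement (observer A minus observer B).
#'
#' @param a,b data frames with columns `subject`, `sequence`, `roi_kind`,
#'   `value` for observers A and B; subjects must match.
#' @return Tibble ordered by (sequence, roi_kind) with columns
#'   `mean_value`, `icc`, `cov_pct`, `bias`, `loa_low`, `loa_high`,
#'   `n_subjects`.
#' @export
repro_report <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  need <- c("subject", "sequence", "roi_kind", "value")
  for (nm in c("a", "b"))
    if (!all(need %in% names(get(nm))))
      stopf("`%s` must have columns %s", nm, paste(need, collapse = ", "))
  if (nrow(a) == 0L || nrow(b) == 0L) stopf("observer tables must be non-empty")
  key <- function(d) paste(d$subject, d$sequence, d$roi_kind, sep = "\r")
  unmatched <- c(setdiff(key(a), key(b)), setdiff(key(b), key(a)))
  if (length(unmatched))
    stopf("observers disagree on %d (subject, sequence, ROI) cells, e.g. %s",
          length(unmatched), gsub("\r", "/", unmatched[1L]))
  mrg <- merge(a, b, by = c("subject", "sequence", "roi_kind"),
               suffixes = c("_a", "_b"))
  rows <- lapply(split(mrg, interaction(mrg$sequence, mrg$roi_kind, drop = TRUE)),
                 function(dd) {
    x <- cbind(dd$value_a, dd$value_b)
    identical_obs <- all(dd$value_a == dd$value_b)
    icc <- if (identical_obs) 1 else icc_2k(x)$icc
    covp <- cov_interobserver(x)
    ba <- bland_altman(x)
    data.frame(sequence = dd$sequence[1L], roi_kind = dd$roi_kind[1L],
               mean_value = mean(x), icc = icc, cov_pct = covp,
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               n_subjects = nrow(dd))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$sequence, res$roi_kind), , drop = FALSE]
  rownames(res) <- NULL
  tibble::as_tibble(res)
}
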