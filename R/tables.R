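#' Reference cohort summary tables
#'
#' Bundled summary statistics from a published multi-parametric renal MRI
#' reproducibility cohort (healthy volunteers HV, heart failure HF and
#' renal transplant Tx), used as worked-example inputs for the reporting
#' and group-comparison layers: per-group mean and between-subject SD of
#' each ROI kind for kidney volume, T1, pCASL perfusion and ADC, and the
#' cohort-mean within-ROI SD per sequence and ROI kind.
#'
#' @return `reference_group_means()`: tibble with columns `sequence`,
#'   `roi_kind`, `group`, `n`, `mean`, `sd`, `units`.
#'   `reference_roi_sd()`: tibble with columns `sequence`, `roi_kind`,
#'   `mean_roi_sd`, `units`.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
reference_group_means <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "cohort_group_means.csv", package = "renalqmap"),
    stringsAsFactors = FALSE))
}

#' @rdname reference_tables
#' @export
reference_roi_sd <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "cohort_roi_sd.csv", package = "renalqmap"),
    stringsAsFactors = FALSE))
}

#' Corticomedullary ratios from a group-means table
#'
#' Recomputes the cortex:medulla ratio of group means per sequence and
#' group via [cortex_medulla_ratio()].
#'
#' @param gm a group-means table as from [reference_group_means()].
#' @return Tibble with `sequence`, `group`, `ratio`.
#' @export
cortex_medulla_ratio_table <- function(gm = reference_group_means()) {
  gm <- as.data.frame(gm)
  gm <- gm[gm$roi_kind %in% c("Cx", "Med"), , drop = FALSE]
  rows <- lapply(split(gm, interaction(gm$sequence, gm$group, drop = TRUE)),
                 function(d) {
    if (!all(c("Cx", "Med") %in% d$roi_kind)) return(NULL)
    data.frame(sequence = d$sequence[1L], group = d$group[1L],
               ratio = cortex_medulla_ratio(d$mean[d$roi_kind == "Cx"],
                                            d$mean[d$roi_kind == "Med"]))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$sequence, res$group), , drop = FALSE]
  rownames(res) <- NULL
  tibble::as_tibble(res)
}

#' Within-ROI spread as a proportion of the cohort mean
#'
#' Joins the cohort-mean within-ROI SD table to the all-group means and
#' expresses the spread as a percentage of the mean value (1 dp).
#'
#' @param gm group-means table; only the "All" group rows are used.
#' @param rsd within-ROI SD table as from [reference_roi_sd()].
#' @return Tibble with `sequence`, `roi_kind`, `mean_roi_sd`,
#'   `sd_fraction_pct`.
#' @export
sd_fraction_reference <- function(gm = reference_group_means(),
                                  rsd = reference_roi_sd()) {
  gm <- as.data.frame(gm)
  gm <- gm[gm$group == "All", c("sequence", "roi_kind", "mean")]
  mrg <- merge(as.data.frame(rsd), gm, by = c("sequence", "roi_kind"))
  mrg$sd_fraction_pct <- round(100 * mrg$mean_roi_sd / mrg$mean, 1L)
  mrg <- mrg[order(mrg$sequence, mrg$roi_kind),
             c("sequence", "roi_kind", "mean_roi_sd", "sd_fraction_pct")]
  rownames(mrg) <- NULL
  tibble::as_tibble(mrg)
}

#' Difference of two group means from a summary table
#'
#' @param gm group-means table.
#' @param sequence,roi_kind cell selector.
#' @param g1,g2 group names; returns mean(g1) - mean(g2).
#' @return Numeric difference in the table's units.
#' @export
group_mean_difference <- function(gm, sequence, roi_kind, g1, g2) {
  gm <- as.data.frame(gm)
  pick <- function(g) {
    r <- gm[gm$sequence == sequence & gm$roi_kind == roi_kind & gm$group == g, ]
    if (nrow(r) != 1L) stopf("no unique row for %s/%s/%s", sequence, roi_kind, g)
    r$mean
  }
  pick(g1) - pick(g2)
}
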