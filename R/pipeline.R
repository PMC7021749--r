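# Between-subject variability of the tissue priors used when drawing
# per-subject ground truth (means come from tissue_params() defaults).
subject_tissue_draw <- function(seed) {
  base <- tissue_params()
  with_seed(seed, {
    draw <- function(mean, sd, floor) max(rnorm(1, mean, sd), floor)
    tissue_params(
      cortex = list(
        t1_ms = draw(base$cortex$t1_ms, 100, 800),
        adc_mm2_per_s = draw(base$cortex$adc_mm2_per_s, 1.1e-4, 5e-4),
        perfusion_ml_per_100g_min = draw(base$cortex$perfusion_ml_per_100g_min, 80, 20),
        m0 = base$cortex$m0),
      medulla = list(
        t1_ms = draw(base$medulla$t1_ms, 75, 900),
        adc_mm2_per_s = draw(base$medulla$adc_mm2_per_s, 8e-5, 5e-4),
        perfusion_ml_per_100g_min = draw(base$medulla$perfusion_ml_per_100g_min, 42, 10),
        m0 = base$medulla$m0),
      pelvis = base$pelvis)
  })
}

# Derive stage seeds from the config seed; kept well below 2^31.
stage_seed <- function(seed, subject, stage) {
  (seed * 1000L + subject * 101L + stage) %% 2000000000L
}

analysis_mask <- function(labelmap, slice_index) {
  m <- array(FALSE, dim(labelmap$labels))
  m[slice_index, , ] <- labelmap$labels[slice_index, , ] %in% c(1L, 2L, 3L)
  m
}

observer_summaries <- function(maps, rois, labelmap, subject_id, group,
                               observer_label, sd_divisor) {
  rows <- list()
  for (seqname in names(maps)) {
    map <- maps[[seqname]]
    for (kind in ROI_KINDS) {
      mask <- rasterize_roi(rois, labelmap, kind)
      s <- roi_summary(map, mask, sd_divisor = sd_divisor)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject_id, group = group, observer = observer_label,
        sequence = seqname, roi_kind = kind,
        mean = s$mean, sd = s$sd, n = s$n_voxels,
        sd_fraction = s$sd_fraction, units = s$units)
    }
  }
  do.call(rbind, rows)
}

# Build an observer's ROI set: anatomy contours perturbed by the observer
# model, plus an observer-specific repCx placement.
observer_rois <- function(labelmap, slice_index, cfg, obs_seed) {
  truth <- define_standard_rois(labelmap, slice_index,
                                kinds = setdiff(ROI_KINDS, "repCx"),
                                rep_cx_radius_mm = cfg$rep_cx_radius_mm)
  model <- observer_model(cfg$observer_jitter_mm, cfg$observer_bias_mm,
                          seed = obs_seed)
  pert <- perturb_contours(truth, model)
  # a zero-variability observer reproduces the analysis exactly, including
  # the representative-cortex placement
  rep_seed <- if (cfg$observer_jitter_mm == 0 && cfg$observer_bias_mm == 0)
    1L else obs_seed + 1L
  rep_set <- define_standard_rois(labelmap, slice_index, kinds = "repCx",
                                  seed = rep_seed,
                                  rep_cx_radius_mm = cfg$rep_cx_radius_mm)
  roi_set(c(pert$contours, rep_set$contours), spacing = labelmap$spacing,
          observer_id = pert$observer_id, slice_count = pert$slice_count)
}

#' Run the end-to-end synthetic study pipeline
#'
#' For each simulated subject: generate a kidney phantom and ground-truth
#' tissue parameters, simulate the MOLLI, DWI and pCASL acquisitions, fit
#' the three quantitative maps on the analysis slice (the slice of
#' maximal kidney area), derive the six standard ROIs for two simulated
#' observers (contour jitter plus observer-specific representative-cortex
#' placement), summarise every map over every ROI, and contour the kidney
#' across slices for alternate-slice and every-slice volumetry per
#' observer. Finally assemble interobserver reproducibility reports. The
#' run is fully deterministic for a fixed config seed; all derived stage
#' seeds are recorded in the returned seed manifest.
#'
#' @param config a [study_config()].
#' @return A list: `summaries` (tidy per subject x observer x sequence x
#'   ROI), `volumes` (per subject x observer x protocol), `repro_maps`,
#'   `repro_volume`, `subjects`, `seed_manifest`, `config`.
#' @export
run_pipeline <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  groups <- cfg$groups %||% rep("A", cfg$n_subjects)
  asl_const <- do.call(asl_constants, cfg$asl)

  all_summaries <- list(); all_volumes <- list(); subj_rows <- list()
  manifest <- list()
  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", i)
    seeds <- list(
      phantom = stage_seed(cfg$seed, i, 1L), tissue = stage_seed(cfg$seed, i, 2L),
      molli = stage_seed(cfg$seed, i, 3L), dwi = stage_seed(cfg$seed, i, 4L),
      asl = stage_seed(cfg$seed, i, 5L), obs_a = stage_seed(cfg$seed, i, 6L),
      obs_b = stage_seed(cfg$seed, i, 7L))
    manifest[[sid]] <- seeds

    step <- function(stage, expr) {
      tryCatch(expr, error = function(e)
        stopf("pipeline stage '%s' failed for subject %s: %s",
              stage, sid, conditionMessage(e)))
    }
    lm <- step("phantom", make_kidney_labelmap(cfg$shape, cfg$spacing,
                                               seed = seeds$phantom))
    pars <- step("tissue", subject_tissue_draw(seeds$tissue))
    molli <- step("simulate-molli",
                  simulate_molli_series(lm, pars, cfg$ti_ms,
                                        noise_sd = cfg$noise_sd$molli,
                                        seed = seeds$molli))
    dwi <- step("simulate-dwi",
                simulate_dwi_series(lm, pars, cfg$b_values,
                                    noise_sd = cfg$noise_sd$dwi,
                                    seed = seeds$dwi))
    asl <- step("simulate-asl",
                simulate_asl_set(lm, pars, asl_const,
                                 noise_sd = cfg$noise_sd$asl,
                                 seed = seeds$asl))

    slice_index <- which.max(apply(lm$labels == 1L | lm$labels == 2L, 1L, sum))
    fit_mask <- analysis_mask(lm, slice_index)
    maps <- step("fit-maps", list(
      T1 = fit_t1_map(molli, fit_mask),
      ADC = {
        m <- fit_adc_map(dwi, fit_mask)
        m$values <- m$values * 1e6          # table convention
        m$units <- "1e-6 mm^2/s"
        m
      },
      pCASL = perfusion_map(asl, fit_mask)))

    wk_truth <- step("volumetry-contours", labelmap_contours(lm))
    for (obs in c("A", "B")) {
      obs_seed <- if (obs == "A") seeds$obs_a else seeds$obs_b
      rois <- step(paste0("rois-", obs),
                   observer_rois(lm, slice_index, cfg, obs_seed))
      all_summaries[[paste(sid, obs)]] <- step(
        paste0("summaries-", obs),
        observer_summaries(maps, rois, lm, sid, groups[i], obs,
                           cfg$sd_divisor))
      model <- observer_model(cfg$observer_jitter_mm, cfg$observer_bias_mm,
                              seed = obs_seed + 2L)
      wk_obs <- step(paste0("volume-contours-", obs),
                     perturb_contours(wk_truth, model))
      contoured <- sort(unique(vapply(wk_obs$contours, `[[`, 1L, "slice")))
      alt_keep <- contoured[c(TRUE, rep(c(FALSE, TRUE),
                                        length.out = length(contoured) - 1L))]
      alt_keep <- union(alt_keep, range(contoured))
      wk_alt <- roi_set(Filter(function(c) c$slice %in% alt_keep,
                               wk_obs$contours),
                        spacing = wk_obs$spacing, observer_id = wk_obs$observer_id,
                        slice_count = wk_obs$slice_count)
      all_volumes[[paste(sid, obs)]] <- step(
        paste0("volume-", obs),
        data.frame(subject = sid, group = groups[i], observer = obs,
                   method = c("every", "alternate"),
                   volume_ml = c(volume_every_slice(wk_obs),
                                 volume_alternate_slice(wk_alt))))
    }
    subj_rows[[sid]] <- data.frame(
      subject = sid, group = groups[i], analysis_slice = slice_index,
      t1_cortex = pars$cortex$t1_ms, t1_medulla = pars$medulla$t1_ms,
      adc_cortex = pars$cortex$adc_mm2_per_s,
      adc_medulla = pars$medulla$adc_mm2_per_s,
      perf_cortex = pars$cortex$perfusion_ml_per_100g_min,
      perf_medulla = pars$medulla$perfusion_ml_per_100g_min)
  }

  summaries <- do.call(rbind, all_summaries)
  volumes <- do.call(rbind, all_volumes)
  rownames(summaries) <- rownames(volumes) <- NULL
  ord <- order(summaries$subject, summaries$sequence, summaries$roi_kind,
               summaries$observer)
  summaries <- tibble::as_tibble(summaries[ord, , drop = FALSE])
  volumes <- tibble::as_tibble(volumes[order(volumes$subject, volumes$method,
                                             volumes$observer), , drop = FALSE])

  obs_tbl <- function(tab, o) {
    d <- tab[tab$observer == o, c("subject", "sequence", "roi_kind", "mean")]
    names(d)[names(d) == "mean"] <- "value"
    d
  }
  repro_maps <- if (cfg$n_subjects >= 2L)
    repro_report(obs_tbl(summaries, "A"), obs_tbl(summaries, "B"))
  else NULL
  vol_tbl <- function(o) {
    d <- volumes[volumes$observer == o, ]
    data.frame(subject = d$subject, sequence = paste0("volume_", d$method),
               roi_kind = "WK", value = d$volume_ml)
  }
  repro_volume <- if (cfg$n_subjects >= 2L)
    repro_report(vol_tbl("A"), vol_tbl("B"))
  else NULL

  list(summaries = summaries, volumes = volumes,
       repro_maps = repro_maps, repro_volume = repro_volume,
       subjects = tibble::as_tibble(do.call(rbind, subj_rows)),
       seed_manifest = manifest, config = cfg)
}

#' Write pipeline outputs as stable-ordered CSV files
#'
#' Writes `summaries.csv`, `volumes.csv`, `repro_maps.csv`,
#' `repro_volume.csv`, `subjects.csv` and a JSON seed manifest (plus the
#' effective config) into `dir`. Row order is fixed (subject, sequence,
#' ROI) so repeated runs with the same seed are byte-identical.
#'
#' @param result a [run_pipeline()] result bundle.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) if (!is.null(d))
    utils::write.csv(as.data.frame(d), file.path(dir, f), row.names = FALSE)
  wr(result$summaries, "summaries.csv")
  wr(result$volumes, "volumes.csv")
  wr(result$repro_maps, "repro_maps.csv")
  wr(result$repro_volume, "repro_volume.csv")
  wr(result$subjects, "subjects.csv")
  jsonlite::write_json(list(package_version = as.character(utils::packageVersion("renalqmap")),
                            seeds = result$seed_manifest,
                            config = unclass(result$config)),
                       file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
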