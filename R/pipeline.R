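#' Default pipeline configuration
#'
#' A complete synthetic-study configuration emulating the duration-tuning
#' experiment: 13 subjects and seven ROIs laid out occipital to frontal on
#' one hemisphere's lattice patch, planting the preference regimes the
#' analyses are built to detect: smooth long-skewed maps in occipital
#' visual ROIs, full-range chronotopic gradients in parietal ROIs, a
#' short-skewed motor-somatosensory map, and boundary-tuned fields
#' (preferences near the 0.5 s reference) frontally. One frontal ROI's
#' boundary center tracks each subject's planted PSE, planting the
#' preference-perception link.
#' Analysis constants are the study's: 999 permutations, alpha 0.05,
#' 2 mm variogram bins, 12 nearest neighbors for the global statistic, and
#' a local neighborhood of one-fourth the smallest ROI.
#'
#' @param seed master seed; every stage derives its own recorded sub-seed.
#' @param n_subjects number of simulated subjects.
#' @param n_rows lattice rows per ROI column band.
#' @param cols_per_roi lattice columns per ROI.
#' @param noise_sd beta noise, psc.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L, n_subjects = 13L,
                                    n_rows = 12L, cols_per_roi = 6L,
                                    noise_sd = 0.05) {
  rois <- list(
    ## occipital visual streams: smooth, long-skewed preference maps
    list(roi = "occ1", stream = "visual", kind = "grf",
         params = list(correlation_length_mm = 6, nugget_fraction = 0.3,
                       mu_center = 0.63, mu_sd = 0.08)),
    list(roi = "occ2", stream = "visual", kind = "grf",
         params = list(correlation_length_mm = 5, nugget_fraction = 0.3,
                       mu_center = 0.60, mu_sd = 0.08)),
    ## parietal streams: chronotopic gradients spanning the full range
    list(roi = "par1", stream = "parietal", kind = "gradient",
         params = list(axis = "row")),
    list(roi = "par2", stream = "parietal", kind = "gradient",
         params = list(axis = "row")),
    ## motor-somatosensory: smooth, short-skewed
    list(roi = "motsom", stream = "motor", kind = "grf",
         params = list(correlation_length_mm = 5, nugget_fraction = 0.3,
                       mu_center = 0.35, mu_sd = 0.08)),
    ## medial/inferior frontal: tuned to the 0.5 s category boundary
    list(roi = "sma", stream = "frontal", kind = "boundary",
         params = list(center = 0.5, spread = 0.03)),
    list(roi = "front", stream = "frontal", kind = "boundary",
         params = list(spread = 0.03), link_pse = TRUE)
  )
  structure(list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    patch = list(n_rows = as.integer(n_rows),
                 cols_per_roi = as.integer(cols_per_roi), spacing_mm = 2),
    rois = rois,
    ordering = vapply(rois, `[[`, "", "roi"),
    prf = list(noise_sd = noise_sd, r2_threshold = 0.10),
    moran = list(n_perm = 999L, alpha = 0.05, local_k = "quarter_smallest_roi",
                 global_k = 12L, local_center = "hemisphere_mean"),
    variogram = list(bin_width_mm = 2),
    categories = list(edges = c(0.2, 0.32, 0.44, 0.56, 0.68, 0.8)),
    behavior = list(pse_mean = 0.5, pse_sd = 0.05, slope = 20,
                    n_per_duration = 80L)
  ), class = "pipeline_config")
}

pipeline_patch <- function(config) {
  blocks <- data.frame(
    roi = vapply(config$rois, `[[`, "", "roi"),
    cols = config$patch$cols_per_roi,
    stream = vapply(config$rois, `[[`, "", "stream"),
    stringsAsFactors = FALSE)
  make_patch(config$patch$n_rows,
             config$patch$cols_per_roi * length(config$rois),
             config$patch$spacing_mm, roi_blocks = blocks)
}

## Plant each ROI's field kind on its own sub-lattice and reassemble
## (column bands are contiguous in vertex order, so blocks concatenate).
pipeline_truth <- function(config, patch, subject_pse, subj_seed) {
  pieces <- lapply(seq_along(config$rois), function(ri) {
    spec <- config$rois[[ri]]
    sub <- make_patch(config$patch$n_rows, config$patch$cols_per_roi,
                      config$patch$spacing_mm,
                      roi_blocks = data.frame(roi = spec$roi,
                                              cols = config$patch$cols_per_roi,
                                              stream = spec$stream))
    params <- spec$params
    if (isTRUE(spec$link_pse)) params$center <- subject_pse
    plant_field(sub, spec$kind, params, seed = derive_seed(subj_seed, ri))
  })
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  out$vertex_id <- patch$vertex_id
  structure(out, mu_range = c(0.2, 0.8), support = c(0.2, 0.8),
            class = c("ground_truth_field", "data.frame"))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the chain simulate -> pRF fit -> local/global Moran ->
#' variogram -> categorization and ROI summaries -> behavior link ->
#' long-range correlation/dendrogram, per subject and at the group level,
#' writing every stage output as headered TSV (plus JSON sidecars) under
#' `out_dir` and a manifest with content hashes. Reruns with the same
#' config reproduce the hashes.
#'
#' If `config$behavior` is `NULL` the behavior and preference-perception
#' stages are skipped with a notice; all upstream outputs are still
#' produced.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory results: `patch`,
#'   `subjects` (per-subject fits and summaries), `medians`, `pse`,
#'   `roi_summary` (group means), `global_moran`, `variograms`,
#'   `corr_matrix`, `hclust`, `pse_link`, `gradients`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("chronotopo_run_"),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stim <- stimulus_spec()
  patch <- pipeline_patch(config)
  write_tsv(patch, file.path(out_dir, "patch.tsv"))
  write_sidecar(unclass(config), file.path(out_dir, "config.json"))

  do_behavior <- !is.null(config$behavior)
  if (!do_behavior) say("behavior config missing: behavior-link stage will be skipped")
  subject_pse <- if (do_behavior) {
    with_seed(derive_seed(config$seed, 900L),
              stats::rnorm(config$n_subjects, config$behavior$pse_mean,
                           config$behavior$pse_sd))
  } else rep(0.5, config$n_subjects)

  local_k <- if (identical(config$moran$local_k, "quarter_smallest_roi")) {
    local_k_rule(patch)
  } else as.integer(config$moran$local_k)

  subjects <- vector("list", config$n_subjects)
  sub_dir <- file.path(out_dir, "subjects")
  dir.create(sub_dir, showWarnings = FALSE)
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("s%02d", s)
    s_seed <- derive_seed(config$seed, s)
    truth <- pipeline_truth(config, patch, subject_pse[s], s_seed)
    betas <- simulate_betas(truth, stim, config$prf$noise_sd,
                            seed = derive_seed(s_seed, 101L))
    field <- fit_field(betas, patch, stim,
                       r2_threshold = config$prf$r2_threshold)
    ok <- field$valid
    vpatch <- patch[ok, , drop = FALSE]
    w_local <- knn_weights(vpatch, local_k, restrict = "hemisphere")
    moran <- local_morans_i(field$mu_d[ok], w_local,
                            center = config$moran$local_center,
                            n_perm = config$moran$n_perm,
                            alpha = config$moran$alpha,
                            seed = derive_seed(s_seed, 202L))
    quad <- summarize_quadrants(moran, vpatch)
    scheme <- category_scheme(config$categories$edges)
    roi_sum <- summarize_roi(field, scheme, quadrants = quad,
                             ordering = config$ordering)

    roi_stats <- lapply(config$ordering, function(r) {
      sel <- vpatch$roi == r
      rp <- vpatch[sel, , drop = FALSE]
      mu <- field$mu_d[ok][sel]
      gm <- global_morans_i(mu, knn_weights(rp, config$moran$global_k),
                            center = "roi_mean",
                            n_perm = config$moran$n_perm,
                            seed = derive_seed(s_seed, 303L))
      vg <- empirical_variogram(mu, rp, config$variogram$bin_width_mm)
      rng <- extract_range(vg)
      data.frame(roi = r, global_i = gm$global_i, global_p = gm$global_p,
                 nugget = extract_nugget(vg), range = rng$range,
                 reached_sill = rng$reached_sill, stringsAsFactors = FALSE)
    })
    roi_stats <- do.call(rbind, roi_stats)

    behav <- pse_fit <- NULL
    if (do_behavior) {
      behav <- simulate_behavior(subject_pse[s], config$behavior$slope,
                                 config$behavior$n_per_duration,
                                 subject_id = sid,
                                 seed = derive_seed(s_seed, 404L))
      pse_fit <- fit_psychometric(behav)
      write_tsv(behav, file.path(sub_dir, paste0(sid, "_behavior.tsv")))
    }
    write_tsv(as.data.frame(field), file.path(sub_dir, paste0(sid, "_field.tsv")))
    write_tsv(moran, file.path(sub_dir, paste0(sid, "_moran.tsv")))
    write_tsv(roi_sum, file.path(sub_dir, paste0(sid, "_roi_summary.tsv")))
    write_tsv(roi_stats, file.path(sub_dir, paste0(sid, "_roi_stats.tsv")))
    subjects[[s]] <- list(id = sid, truth = truth, field = field,
                          moran = moran, quadrants = quad,
                          roi_summary = roi_sum, roi_stats = roi_stats,
                          behavior = behav, psychometric = pse_fit,
                          pse_true = if (do_behavior) subject_pse[s] else NA)
    say("subject %s: %d/%d vertices valid", sid, sum(ok), nrow(patch))
  }

  ## group level -------------------------------------------------------
  medians <- do.call(rbind, lapply(subjects, function(su) {
    su$roi_summary$median_mu[match(config$ordering, su$roi_summary$roi)]
  }))
  dimnames(medians) <- list(vapply(subjects, `[[`, "", "id"), config$ordering)
  write_tsv(data.frame(subject = rownames(medians), medians,
                       check.names = FALSE),
            file.path(out_dir, "medians.tsv"))

  ll_hh <- colMeans(do.call(rbind, lapply(subjects, function(su) {
    su$roi_summary$ll_minus_hh[match(config$ordering, su$roi_summary$roi)]
  })))
  gradients <- list(
    ll_minus_hh = hierarchy_regression(ll_hh),
    median_mu = hierarchy_regression(colMeans(medians))
  )

  cm <- hc <- NULL
  if (config$n_subjects >= 3) {
    cm <- preference_corr_matrix(medians)
    hc <- hierarchical_cluster(corr_to_distance(cm))
    write_tsv(data.frame(region = rownames(cm), unclass(cm),
                         check.names = FALSE),
              file.path(out_dir, "corr_matrix.tsv"))
    writeLines(dendrogram_newick(hc), file.path(out_dir, "dendrogram.newick"))
  } else {
    say("fewer than 3 subjects: long-range correlation stage skipped")
  }

  pse_link <- NULL
  if (do_behavior && config$n_subjects >= 3) {
    pse <- vapply(subjects, function(su) su$psychometric$pse, 0)
    names(pse) <- rownames(medians)
    write_tsv(data.frame(subject = names(pse), pse = pse,
                         pse_true = subject_pse),
              file.path(out_dir, "pse.tsv"))
    pse_link <- pse_preference_link(pse, medians, config$ordering,
                                    clamp = TRUE)
    write_tsv(pse_link$table, file.path(out_dir, "pse_link.tsv"))
    gradients$z_tau <- pse_link$gradient
  }
  write_sidecar(gradients, file.path(out_dir, "gradients.json"))

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  write_sidecar(list(config_seed = config$seed, files = manifest),
                file.path(out_dir, "manifest.json"))
  say("pipeline complete: %d files in %s", nrow(manifest) + 1L, out_dir)

  invisible(list(config = config, out_dir = out_dir, patch = patch,
                 subjects = subjects, medians = medians,
                 gradients = gradients, corr_matrix = cm, hclust = hc,
                 pse_link = pse_link, manifest = manifest))
}
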