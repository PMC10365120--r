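#' Pipeline configuration
#'
#' A plain, YAML-serializable container for every tunable the pipeline
#' uses: tracking parameters, profile node count, bundle-cleaning
#' thresholds and group-statistics settings.
#'
#' @param tracking a [tracking_params()].
#' @param n_nodes profile node count (default 100).
#' @param score_quantile,length_z_max cleaning thresholds, see
#'   [clean_bundle()].
#' @param fwe_method,n_perm,alpha,min_sig_nodes group-statistics settings,
#'   see [fwe_correct()] and [summarize_table()].
#' @param weighting node-averaging scheme, see [compute_tract_profile()].
#' @param rng_seed master seed for the stochastic stages.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(tracking = tracking_params(), n_nodes = 100L,
                            score_quantile = 0.05, length_z_max = 3,
                            fwe_method = "maxT", n_perm = 10000L,
                            alpha = 0.05, min_sig_nodes = 10L,
                            weighting = "uniform", rng_seed = 1L) {
  structure(list(tracking = tracking, n_nodes = as.integer(n_nodes),
                 score_quantile = score_quantile,
                 length_z_max = length_z_max, fwe_method = fwe_method,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 min_sig_nodes = as.integer(min_sig_nodes),
                 weighting = weighting, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$tracking <- unclass(lst$tracking)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  lst <- yaml::read_yaml(path)
  tr <- do.call(tracking_params, lst$tracking)
  lst$tracking <- NULL
  do.call(pipeline_config, c(list(tracking = tr), lst))
}

# The three SLF-family bundles and their ROI pairs for one hemisphere.
.slf_bundle_defs <- function(h) {
  list(
    list(tract = "SLF", anterior = paste0(h, "_SLF_anterior")),
    list(tract = "SLF_II", anterior = paste0(h, "_SLF_II_anterior")),
    list(tract = "SLF_III", anterior = paste0(h, "_SLF_III_anterior"))
  )
}

#' Subject-level pipeline: fit, track, segment, clean, profile
#'
#' Runs the full per-subject chain on a diffusion dataset: tensor fit,
#' scalar maps, whole-brain FACT tractography, waypoint dissection of SLF,
#' SLF II and SLF III per hemisphere, probability-map scoring and
#' cleaning, anterior-posterior orientation and 100-node profiling.
#' Deterministic given the inputs and config.
#'
#' @param dwi a [dwi_dataset()].
#' @param rois named list of waypoint ROIs in the subject's space, with
#'   names `<hemi>_SLF_anterior`, `<hemi>_SLF_II_anterior`,
#'   `<hemi>_SLF_III_anterior` and `<hemi>_posterior` (see
#'   [define_slf_rois()]); hemispheres are inferred from the names.
#' @param config a [pipeline_config()].
#' @param subject_id,group labels recorded on the profiles.
#' @param prob_maps optional named list of probability arrays (same grid),
#'   one per tract name ("SLF", "SLF_II", "SLF_III") or a single array
#'   under "union" used for all; enables score-based cleaning.
#' @param output_dir optional directory; when given, writes the profile
#'   CSV, one .trk per bundle, a QC JSON and an md5-checksummed manifest
#'   of every artifact.
#' @return list with `profiles` (named list of [compute_tract_profile()]
#'   results, names "tract|hemisphere"), `profile_df` (long table),
#'   `bundles`, `tractogram`, and `qc` (streamline counts, clamped
#'   eigenvalue count, empty-bundle flags).
#' @export
run_subject <- function(dwi, rois, config = pipeline_config(),
                        subject_id = "subject", group = NA_character_,
                        prob_maps = NULL, output_dir = NULL) {
  stopifnot(inherits(dwi, "dwi_dataset"), inherits(config, "pipeline_config"))
  tf <- fit_tensor(dwi)
  maps <- compute_scalar_maps(tf)
  tg <- track_whole_brain(tf, maps, config$tracking)
  hemis <- unique(sub("_.*$", "", names(rois)))
  hemis <- hemis[hemis %in% c("L", "R")]
  profiles <- list()
  bundles <- list()
  qc <- list(subject_id = subject_id,
             n_streamlines_total = length(tg),
             n_clamped_eigenvalues = tf$n_clamped,
             empty_bundles = character(0L))
  for (h in hemis) {
    post <- rois[[paste0(h, "_posterior")]]
    for (def in .slf_bundle_defs(h)) {
      ant <- rois[[def$anterior]]
      if (is.null(ant) || is.null(post)) next
      key <- paste0(def$tract, "|", h)
      bundle <- assign_by_waypoints(tg, ant, post, def$tract, h)
      if (length(bundle) == 0L) {
        qc$empty_bundles <- c(qc$empty_bundles, key)
        next
      }
      scores <- NULL
      if (!is.null(prob_maps)) {
        pm <- prob_maps[[def$tract]]
        if (is.null(pm)) pm <- prob_maps[["union"]]
        if (!is.null(pm))
          scores <- score_against_probability_map(bundle, pm, tf$affine)
      }
      bundle <- clean_bundle(bundle, scores,
                             score_quantile = if (is.null(scores)) 0
                                              else config$score_quantile,
                             length_z_max = config$length_z_max)
      if (length(bundle) == 0L) {
        qc$empty_bundles <- c(qc$empty_bundles, key)
        next
      }
      ant_centroid <- c(mean(ant$x_range), ant$y_mm, mean(ant$z_range))
      bundle <- orient_bundle(bundle, ant_centroid)
      profiles[[key]] <- compute_tract_profile(
        bundle, maps, n_nodes = config$n_nodes,
        weighting = config$weighting,
        subject_id = subject_id, group = group)
      bundles[[key]] <- bundle
      qc[[paste0("n_streamlines_", key)]] <- length(bundle)
    }
  }
  profile_df <- if (length(profiles)) profiles_to_df(profiles) else NULL
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    if (!is.null(profile_df))
      save_profiles(profile_df,
                    file.path(output_dir,
                              paste0(subject_id, "_profiles.csv")))
    for (key in names(bundles)) {
      b <- bundles[[key]]
      sub_tg <- tractogram(bundle_streamlines(b), tg$reference_affine,
                           tg$reference_shape, validate = FALSE)
      save_tractogram(sub_tg,
                      file.path(output_dir,
                                paste0(subject_id, "_",
                                       gsub("\\|", "_", key), ".trk")))
    }
    jsonlite::write_json(qc, file.path(output_dir,
                                       paste0(subject_id, "_qc.json")),
                         auto_unbox = TRUE)
    arts <- list.files(output_dir, pattern = paste0("^", subject_id, "_"),
                       full.names = TRUE)
    manifest <- data.frame(file = basename(arts),
                           md5 = unname(tools::md5sum(arts)),
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest,
                     file.path(output_dir,
                               paste0(subject_id, "_manifest.csv")),
                     row.names = FALSE)
  }
  list(profiles = profiles, profile_df = profile_df, bundles = bundles,
       tractogram = tg, qc = qc)
}

#' Group-level pipeline: node-wise statistics and summary table
#'
#' For every (tract, hemisphere, metric) present in the profile table,
#' compares the two groups node by node with [fwe_correct()] and builds
#' the star-marked summary table of tract-mean values.
#'
#' @param profile_df long-format profile table for all subjects (see
#'   [profile_schema]); must contain exactly two groups.
#' @param config a [pipeline_config()].
#' @param metrics metrics to test (default all four).
#' @return list with `stats` (named list of `group_stats_result`, names
#'   "tract|hemisphere|metric"), `table` (from [summarize_table()]) and
#'   `groups` (the two labels, patients first when recognizable).
#' @export
run_group <- function(profile_df, config = pipeline_config(),
                      metrics = c("fa", "md", "ad", "rd")) {
  groups <- unique(profile_df$group)
  if (length(groups) != 2L)
    stop("stats_error: expected exactly 2 groups, got ", length(groups),
         call. = FALSE)
  combos <- unique(profile_df[, c("tract", "hemisphere")])
  stats_results <- list()
  for (i in seq_len(nrow(combos))) {
    tr <- combos$tract[i]; h <- combos$hemisphere[i]
    sub <- profile_df[profile_df$tract == tr &
                        profile_df$hemisphere == h, ]
    a <- sub[sub$group == groups[1L], ]
    b <- sub[sub$group == groups[2L], ]
    if (length(unique(a$subject_id)) < 2L ||
        length(unique(b$subject_id)) < 2L) next
    for (metric in metrics) {
      key <- paste(tr, h, metric, sep = "|")
      stats_results[[key]] <- fwe_correct(
        a, b, metric, method = config$fwe_method, n_perm = config$n_perm,
        rng_seed = config$rng_seed, alpha = config$alpha)
    }
  }
  tab <- summarize_table(profile_df, stats_results,
                         min_sig_nodes = config$min_sig_nodes)
  list(stats = stats_results, table = tab, groups = groups)
}

#' Plot group mean +/- SE tract profiles with significance marks
#'
#' Renders, for one tract/hemisphere/metric, the two group mean curves
#' with standard-error ribbons and asterisks at FWE-significant nodes.
#' Requires ggplot2.
#'
#' @param profile_df long-format profile table.
#' @param tract,hemisphere,metric what to plot.
#' @param stats optional `group_stats_result` for the same selection.
#' @return a ggplot object.
#' @export
plot_profile_comparison <- function(profile_df, tract, hemisphere, metric,
                                    stats = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  sub <- profile_df[profile_df$tract == tract &
                      profile_df$hemisphere == hemisphere, ]
  agg <- do.call(rbind, lapply(split(sub, list(sub$group, sub$node),
                                     drop = TRUE), function(d) {
    data.frame(group = d$group[1L], node = d$node[1L],
               mean = mean(d[[metric]], na.rm = TRUE),
               se = stats::sd(d[[metric]], na.rm = TRUE) /
                 sqrt(sum(is.finite(d[[metric]]))))
  }))
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$node, y = .data$mean,
                                         color = .data$group,
                                         fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "node (anterior to posterior)", y = metric,
                  title = sprintf("%s (%s)", tract, hemisphere)) +
    ggplot2::theme_minimal()
  if (!is.null(stats) && any(stats$sig)) {
    ymax <- max(agg$mean + agg$se, na.rm = TRUE)
    p <- p + ggplot2::annotate("text", x = which(stats$sig), y = ymax,
                               label = "*", size = 5)
  }
  p
}
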