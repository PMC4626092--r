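#' Pipeline run configuration
#'
#' Bundles every tunable of the batch pipeline so a run is fully
#' reproducible from its config echo. Serializes to/from YAML.
#'
#' @param vessel_channel channel segmented for vessel area (NULL skips).
#' @param pericyte_channel channel for coverage (NULL skips coverage).
#' @param area_channels channels quantified by fixed-threshold percent
#'   area.
#' @param count_channels channels counted by blob detection.
#' @param coloc a list `list(a=, b=)` of channels for double-positive
#'   counting, or NULL.
#' @param params [filter_params()] for segmentation.
#' @param min_area,max_area particle-size filter in px^2.
#' @param area_threshold `"otsu_control"` (pooled Otsu on the control
#'   group, frozen for the whole experiment) or a fixed 0..255 value.
#' @param detection list of [detect_cells()] arguments.
#' @param tolerance_radius coverage apposition tolerance, px.
#' @param pairing_radius double-positive pairing radius, px.
#' @param control_group control group label.
#' @param seed integer seed recorded with the run.
#' @return a `run_config` list.
#' @export
run_config <- function(vessel_channel = "COL4",
                       pericyte_channel = "PDGFRB",
                       area_channels = character(),
                       count_channels = c("IBA1"),
                       coloc = list(a = "C1QA", b = "IBA1"),
                       params = filter_params(),
                       min_area = 25, max_area = Inf,
                       area_threshold = "otsu_control",
                       detection = list(min_scale = 3, max_scale = 8,
                                        score_threshold = 0.05,
                                        min_distance = 6),
                       tolerance_radius = 2, pairing_radius = 5,
                       control_group = "young", seed = 0L) {
  structure(list(vessel_channel = vessel_channel,
                 pericyte_channel = pericyte_channel,
                 area_channels = area_channels,
                 count_channels = count_channels, coloc = coloc,
                 params = params, min_area = min_area, max_area = max_area,
                 area_threshold = area_threshold, detection = detection,
                 tolerance_radius = tolerance_radius,
                 pairing_radius = pairing_radius,
                 control_group = control_group, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  x$max_area <- if (is.infinite(x$max_area)) "Inf" else x$max_area
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$params <- do.call(filter_params, x$params)
  if (identical(x$max_area, "Inf")) x$max_area <- Inf
  x$area_channels <- as.character(x$area_channels)
  x$count_channels <- as.character(x$count_channels)
  do.call(run_config, x)
}

# per-scene measurement given frozen thresholds; returns a one-row df
measure_scene <- function(img, config, thresholds) {
  out <- list()
  det <- function(ch) do.call(detect_cells,
                              c(list(img = img, channel = ch),
                                config$detection))
  if (!is.null(config$vessel_channel) &&
      config$vessel_channel %in% names(img$channels)) {
    seg <- segment_vessels(img, config$params, min_area = config$min_area,
                           max_area = config$max_area,
                           channel = config$vessel_channel)
    out$vessel_area_fraction <- seg$area_fraction
    out$vessel_particle_count <- seg$particles$particle_count
    out$sigma_used <- seg$params_used$sigma_used
    if (!is.null(config$pericyte_channel) &&
        config$pericyte_channel %in% names(img$channels)) {
      pm <- get_channel(img, config$pericyte_channel) >
        thresholds[[config$pericyte_channel]]
      cov <- tryCatch(
        pericyte_coverage(seg$mask, pm,
                          tolerance_radius = config$tolerance_radius,
                          pixel_size = img$pixel_size),
        error = function(e) {
          warning("coverage undefined for a scene: ", conditionMessage(e))
          list(vessel_length = NA_real_, covered_length = NA_real_,
               coverage_fraction = NA_real_)
        })
      out$vessel_length_um <- cov$vessel_length
      out$coverage_fraction <- cov$coverage_fraction
    }
  }
  for (ch in config$area_channels)
    if (ch %in% names(img$channels))
      out[[paste0("percent_area_", ch)]] <-
        percent_area(img, thresholds[[ch]], channel = ch)
  for (ch in config$count_channels)
    if (ch %in% names(img$channels))
      out[[paste0("count_", ch)]] <- nrow(det(ch)$points)
  if (!is.null(config$coloc) &&
      all(unlist(config$coloc) %in% names(img$channels))) {
    dp <- double_positive(det(config$coloc$a), det(config$coloc$b),
                          pairing_radius = config$pairing_radius)
    out[[paste0("count_", config$coloc$a, "_", config$coloc$b)]] <-
      dp$count_ab
  }
  as.data.frame(out)
}

# freeze per-channel thresholds from the control group's pooled histogram
freeze_thresholds <- function(images, groups, config) {
  chans <- unique(c(config$pericyte_channel, config$area_channels))
  chans <- chans[!vapply(chans, is.null, TRUE)]
  thresholds <- list()
  for (ch in chans) {
    if (is.numeric(config$area_threshold)) {
      thresholds[[ch]] <- config$area_threshold
      next
    }
    ctrl <- which(groups == config$control_group)
    if (length(ctrl) == 0L)
      stop("no control-group images to freeze the threshold on")
    mats <- lapply(images[ctrl], function(im)
      if (ch %in% names(im$channels)) get_channel(im, ch) else NULL)
    mats <- Filter(Negate(is.null), mats)
    if (length(mats) == 0L) next
    thresholds[[ch]] <- pooled_otsu(mats)
  }
  thresholds
}

#' Run the full quantification pipeline on a set of scenes
#'
#' Measures every scene (vessel segmentation, percent area at a frozen
#' experiment-wide threshold, coverage, cell and double-positive counts),
#' aggregates per animal, normalizes to the control group and tests
#' group differences: unpaired t for two groups, one-way ANOVA with
#' Tukey HSD for three or more.
#'
#' @param scenes list of [micrograph()]s (or of `generate_scene()`
#'   results, whose `$image` is used).
#' @param manifest data.frame with one row per scene: `animal_id`,
#'   `group` (order matches `scenes`).
#' @param config a [run_config()].
#' @param out_dir optional directory: writes per_image.csv,
#'   per_animal.csv, stats.csv and config.yaml.
#' @return list with `per_image`, `per_animal`, `relative`, `stats`,
#'   `thresholds`, `config`.
#' @export
run_pipeline <- function(scenes, manifest, config = run_config(),
                         out_dir = NULL) {
  stopifnot(length(scenes) == nrow(manifest),
            all(c("animal_id", "group") %in% names(manifest)))
  if (any(is.na(manifest$animal_id)) || any(is.na(manifest$group)))
    stop("missing group/animal metadata")
  scenes <- lapply(scenes, function(s)
    if (inherits(s, "micrograph")) s else s$image)
  thresholds <- freeze_thresholds(scenes, manifest$group, config)
  per_image <- do.call(rbind, lapply(seq_along(scenes), function(i)
    cbind(manifest[i, c("animal_id", "group"), drop = FALSE],
          measure_scene(scenes[[i]], config, thresholds))))
  rownames(per_image) <- NULL

  metric_cols <- setdiff(names(per_image),
                         c("animal_id", "group", "sigma_used"))
  long <- do.call(rbind, lapply(metric_cols, function(mc)
    data.frame(animal_id = per_image$animal_id, group = per_image$group,
               metric = mc, value = per_image[[mc]],
               stringsAsFactors = FALSE)))
  long <- long[!is.na(long$value), ]
  per_animal <- aggregate_per_animal(long)

  stats_rows <- list(); relative <- list()
  for (mc in unique(per_animal$metric)) {
    sub <- per_animal[per_animal$metric == mc, ]
    rel <- tryCatch(relative_to_control(sub, config$control_group),
                    error = function(e) NULL)
    if (!is.null(rel)) {
      rel$summary$metric <- mc
      relative[[mc]] <- rel$summary
    }
    gl <- split(sub$value, sub$group)
    gl <- gl[vapply(gl, length, 0L) >= 2L]
    if (length(gl) < 2L) next
    if (length(gl) == 2L) {
      tt <- unpaired_t(gl[[1L]], gl[[2L]])
      stats_rows[[mc]] <- data.frame(
        metric = mc, test = "unpaired_t",
        comparison = paste(names(gl), collapse = " vs "),
        statistic = tt$t, p = tt$p, stringsAsFactors = FALSE)
    } else {
      at <- anova_tukey(gl)
      stats_rows[[mc]] <- rbind(
        data.frame(metric = mc, test = "anova_F", comparison = "omnibus",
                   statistic = at$F, p = at$p, stringsAsFactors = FALSE),
        data.frame(metric = mc, test = "tukey_hsd",
                   comparison = paste(at$pairwise$group1, "vs",
                                      at$pairwise$group2),
                   statistic = at$pairwise$diff, p = at$pairwise$p_adj,
                   stringsAsFactors = FALSE))
    }
  }
  res <- list(per_image = per_image, per_animal = per_animal,
              relative = do.call(rbind, unname(relative)),
              stats = do.call(rbind, unname(stats_rows)),
              thresholds = thresholds, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$per_image, file.path(out_dir, "per_image.csv"),
                     row.names = FALSE)
    utils::write.csv(res$per_animal, file.path(out_dir, "per_animal.csv"),
                     row.names = FALSE)
    if (!is.null(res$stats))
      utils::write.csv(res$stats, file.path(out_dir, "stats.csv"),
                       row.names = FALSE)
    if (!is.null(res$relative))
      utils::write.csv(res$relative, file.path(out_dir, "relative.csv"),
                       row.names = FALSE)
    save_config(config, file.path(out_dir, "config.yaml"))
  }
  res
}
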