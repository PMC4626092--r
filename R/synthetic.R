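# Seeded generator of multi-channel neurovascular scenes with exact
# ground truth: curvilinear vessels, pericyte coverage bands and somata,
# soma-like cells (with double-positive pairing), fibrin-like puncta,
# background gradient and Poisson + Gaussian camera noise.

# run expr under a pinned, seeded RNG; restores the caller's RNG state
with_scene_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

# deterministic per-scene sub-seed, kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %%
               2147483587)
}

#' Scene specification for the synthetic micrograph generator
#'
#' Defaults describe a 20x cortical field: 512 x 512 px at 0.6 um/px,
#' bright curvilinear vessels 3-10 px wide, pericyte somata and coverage
#' bands on the vessel wall, soma-like microglia (IBA1-like) of which a
#' subset carries an in-situ (C1qa-like) signal, fibrin-like puncta
#' partly on vessels, a shallow background gradient, and Poisson followed
#' by Gaussian noise. Ground truth is captured pre-noise.
#'
#' @param image_size c(rows, cols) in px.
#' @param pixel_size um/px (0.6 approximates a 20x field).
#' @param n_vessels number of vessels to draw (ignored when
#'   `target_vessel_fraction` is set).
#' @param target_vessel_fraction if non-NULL, vessels are added until the
#'   truth-mask fraction reaches this value (the realized fraction is
#'   recorded exactly).
#' @param vessel_width_range min/max tube width in px.
#' @param vessel_length_range min/max centerline length in px.
#' @param vessel_intensity peak vessel intensity (8-bit scale).
#' @param vessel_channel name of the vessel channel.
#' @param pericyte_per_100um somata per 100 um of vessel length.
#' @param pericyte_coverage_frac fraction of each vessel's length covered
#'   by pericyte processes (somata are placed on covered stretches).
#' @param pericyte_intensity process-band intensity; somata render 60
#'   units brighter.
#' @param cells named list of expected counts per field for soma-like
#'   channels (`IBA1`, `NEUN`, ...); counts are Poisson-drawn.
#' @param c1qa_fraction fraction of IBA1-like cells that also carry the
#'   C1qa-like signal (double positives).
#' @param soma_sigma soma Gaussian radius in px.
#' @param soma_intensity soma peak amplitude.
#' @param fibrin_count expected number of fibrin-like puncta.
#' @param fibrin_size_range min/max punctum radius in px.
#' @param fibrin_intensity punctum amplitude.
#' @param background constant background level.
#' @param gradient_amplitude amplitude of the linear background gradient.
#' @param poisson_scale photon scaling for shot noise (0 disables).
#' @param gaussian_sd read-noise standard deviation (0 disables).
#' @param seed integer RNG seed.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = c(512L, 512L), pixel_size = 0.6,
                       n_vessels = 8, target_vessel_fraction = NULL,
                       vessel_width_range = c(3, 10),
                       vessel_length_range = c(150, 400),
                       vessel_intensity = 180, vessel_channel = "COL4",
                       pericyte_per_100um = 1.2,
                       pericyte_coverage_frac = 0.6,
                       pericyte_intensity = 110,
                       cells = list(IBA1 = 60),
                       c1qa_fraction = 0.5,
                       soma_sigma = 4, soma_intensity = 160,
                       fibrin_count = 0, fibrin_size_range = c(2, 4),
                       fibrin_intensity = 220,
                       background = 20, gradient_amplitude = 10,
                       poisson_scale = 1, gaussian_sd = 5, seed = 0L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 64),
            pixel_size > 0, n_vessels >= 0,
            vessel_width_range[1L] >= 1,
            vessel_width_range[2L] >= vessel_width_range[1L],
            pericyte_per_100um >= 0,
            pericyte_coverage_frac >= 0, pericyte_coverage_frac <= 1,
            c1qa_fraction >= 0, c1qa_fraction <= 1,
            poisson_scale >= 0, gaussian_sd >= 0)
  if (!is.null(target_vessel_fraction))
    stopifnot(target_vessel_fraction > 0, target_vessel_fraction < 0.5)
  spec <- as.list(environment())
  structure(spec, class = "scene_spec")
}

# random-walk centerline with unit (1 px) steps, reflected into bounds
walk_centerline <- function(nr, nc, n_steps, margin = 8) {
  r <- stats::runif(1, margin, nr - margin)
  c <- stats::runif(1, margin, nc - margin)
  theta <- stats::runif(1, 0, 2 * pi)
  path <- matrix(0, n_steps, 2L)
  path[1L, ] <- c(r, c)
  for (t in 2L:n_steps) {
    theta <- theta + stats::rnorm(1, 0, 0.08)
    nrp <- r + sin(theta); ncp <- c + cos(theta)
    if (nrp < margin || nrp > nr - margin || ncp < margin ||
        ncp > nc - margin) {
      # steer back toward the field centre
      theta <- atan2(nr / 2 - r, nc / 2 - c) + stats::rnorm(1, 0, 0.2)
      nrp <- r + sin(theta); ncp <- c + cos(theta)
    }
    r <- nrp; c <- ncp
    path[t, ] <- c(r, c)
  }
  path
}

#' Generate one synthetic multi-channel micrograph with ground truth
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (a [micrograph()]) and `truth` (pre-noise
#'   masks, centerline polylines and exact total length, object
#'   coordinates, double-positive pairing, and exact per-channel area
#'   fractions).
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_rng(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
  px <- spec$pixel_size
  blank <- function() matrix(0, nr, nc)
  channels <- list()
  truth <- list(pixel_size = px)

  ## --- vessels -------------------------------------------------------
  centerlines <- list()
  widths <- numeric()
  vmask <- matrix(FALSE, nr, nc)
  draw_one <- function() {
    len <- round(stats::runif(1, spec$vessel_length_range[1L],
                              spec$vessel_length_range[2L]))
    w <- stats::runif(1, spec$vessel_width_range[1L],
                      spec$vessel_width_range[2L])
    path <- walk_centerline(nr, nc, len)
    list(path = path, width = w,
         mask = cpp_draw_tube(nr, nc, path[, 1L] - 1, path[, 2L] - 1,
                              w / 2))
  }
  if (!is.null(spec$target_vessel_fraction)) {
    i <- 0L
    while (mean(vmask) < spec$target_vessel_fraction && i < 200L) {
      v <- draw_one()
      centerlines[[length(centerlines) + 1L]] <- v$path
      widths <- c(widths, v$width)
      vmask <- vmask | v$mask
      i <- i + 1L
    }
  } else if (spec$n_vessels > 0) {
    for (i in seq_len(spec$n_vessels)) {
      v <- draw_one()
      centerlines[[length(centerlines) + 1L]] <- v$path
      widths <- c(widths, v$width)
      vmask <- vmask | v$mask
    }
  }
  per_vessel_len <- vapply(centerlines, function(p) (nrow(p) - 1) * px, 0)
  truth$centerlines <- centerlines
  truth$vessel_widths <- widths
  truth$vessel_length_um <- sum(per_vessel_len)
  truth$vessel_mask <- vmask
  truth$vessel_fraction <- mean(vmask)
  vimg <- blank()
  vimg[vmask] <- spec$vessel_intensity
  vimg <- cpp_gaussian_blur_sep(vimg, 1.0)  # soft vessel edge
  channels[[spec$vessel_channel]] <- vimg

  ## --- pericytes (somata + coverage bands on the vessel wall) --------
  if (spec$pericyte_coverage_frac > 0 && length(centerlines) > 0) {
    pmask <- matrix(FALSE, nr, nc)
    covered <- list()  # covered sub-polylines, for exact truth
    covered_len <- 0
    soma_r <- numeric(); soma_c <- numeric()
    for (k in seq_along(centerlines)) {
      path <- centerlines[[k]]
      n <- nrow(path)
      ncov <- round(spec$pericyte_coverage_frac * (n - 1))
      if (ncov < 1) next
      start <- sample.int(n - ncov, 1L)
      seg <- path[start:(start + ncov), , drop = FALSE]
      covered[[length(covered) + 1L]] <- seg
      covered_len <- covered_len + (nrow(seg) - 1) * px
      pmask <- pmask | cpp_draw_tube(nr, nc, seg[, 1L] - 1, seg[, 2L] - 1,
                                     widths[k] / 2 + 1)
      n_somata <- stats::rpois(1, (nrow(seg) - 1) * px / 100 *
                                 spec$pericyte_per_100um /
                                 max(spec$pericyte_coverage_frac, 1e-9))
      if (n_somata > 0) {
        at <- sample.int(nrow(seg), min(n_somata, nrow(seg)))
        soma_r <- c(soma_r, seg[at, 1L]); soma_c <- c(soma_c, seg[at, 2L])
      }
    }
    pimg <- blank()
    pimg[pmask] <- spec$pericyte_intensity
    if (length(soma_r)) {
      pimg <- cpp_add_blobs(pimg, soma_r - 1, soma_c - 1,
                            rep(spec$soma_intensity, length(soma_r)),
                            rep(spec$soma_sigma * 0.75, length(soma_r)))
      pmask <- pmask | cpp_draw_tube(nr, nc, soma_r - 1, soma_c - 1,
                                     spec$soma_sigma)
    }
    channels$PDGFRB <- pimg
    truth$pericyte_mask <- pmask
    truth$pericyte_somata <- data.frame(row = soma_r, col = soma_c)
    truth$covered_length_um <- covered_len
    truth$coverage_fraction <- if (truth$vessel_length_um > 0)
      covered_len / truth$vessel_length_um else 0
  }

  ## --- soma-like cell channels ---------------------------------------
  place_cells <- function(n, min_sep = 3 * spec$soma_sigma) {
    pts <- matrix(0, 0L, 2L)
    tries <- 0L
    margin <- 2 * spec$soma_sigma
    while (nrow(pts) < n && tries < 50L * n) {
      p <- c(stats::runif(1, margin, nr - margin),
             stats::runif(1, margin, nc - margin))
      if (nrow(pts) == 0L ||
          min((pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2) >= min_sep^2)
        pts <- rbind(pts, p)
      tries <- tries + 1L
    }
    pts
  }
  render_cells <- function(pts) {
    img <- blank()
    if (nrow(pts) == 0L) return(img)
    cpp_add_blobs(img, pts[, 1L] - 1, pts[, 2L] - 1,
                  spec$soma_intensity *
                    stats::runif(nrow(pts), 0.8, 1.2),
                  rep(spec$soma_sigma, nrow(pts)))
  }
  truth$cells <- list()
  for (ch in names(spec$cells)) {
    dens <- spec$cells[[ch]]
    if (dens <= 0) next
    n <- stats::rpois(1, dens)
    pts <- place_cells(n)
    channels[[ch]] <- render_cells(pts)
    truth$cells[[ch]] <- data.frame(row = pts[, 1L], col = pts[, 2L])
  }
  # C1qa-like signal on a subset of the IBA1-like population
  if (!is.null(truth$cells$IBA1) && spec$c1qa_fraction > 0 &&
      nrow(truth$cells$IBA1) > 0) {
    ni <- nrow(truth$cells$IBA1)
    ndp <- round(spec$c1qa_fraction * ni)
    if (ndp > 0) {
      which_dp <- sort(sample.int(ni, ndp))
      dp <- as.matrix(truth$cells$IBA1[which_dp, c("row", "col")])
      dp <- dp + matrix(stats::runif(2 * ndp, -1, 1), ncol = 2L)
      channels$C1QA <- render_cells(dp)
      truth$cells$C1QA <- data.frame(row = dp[, 1L], col = dp[, 2L])
      truth$dp_pairing <- data.frame(iba1_index = which_dp,
                                     c1qa_index = seq_len(ndp))
    }
  }

  ## --- fibrin-like puncta --------------------------------------------
  if (spec$fibrin_count > 0) {
    n <- stats::rpois(1, spec$fibrin_count)
    fmask <- matrix(FALSE, nr, nc)
    coords <- matrix(0, 0L, 2L)
    if (n > 0) {
      on_vessel <- stats::runif(n) < 0.5 & length(centerlines) > 0
      for (t in seq_len(n)) {
        if (on_vessel[t]) {
          k <- sample.int(length(centerlines), 1L)
          at <- sample.int(nrow(centerlines[[k]]), 1L)
          p <- centerlines[[k]][at, ]
        } else {
          p <- c(stats::runif(1, 5, nr - 5), stats::runif(1, 5, nc - 5))
        }
        rad <- stats::runif(1, spec$fibrin_size_range[1L],
                            spec$fibrin_size_range[2L])
        fmask <- fmask | cpp_draw_tube(nr, nc, p[1L] - 1, p[2L] - 1, rad)
        coords <- rbind(coords, p)
      }
    }
    fimg <- blank()
    fimg[fmask] <- spec$fibrin_intensity
    fimg <- cpp_gaussian_blur_sep(fimg, 1.0)
    channels$FIBRIN <- fimg
    truth$fibrin_mask <- fmask
    truth$fibrin_fraction <- mean(fmask)
    truth$fibrin_coords <- data.frame(row = coords[, 1L],
                                      col = coords[, 2L])
  }

  ## --- background, gradient, noise -----------------------------------
  phi <- stats::runif(1, 0, 2 * pi)
  gr <- outer(seq_len(nr) / nr - 0.5, rep(1, nc)) * sin(phi) +
    outer(rep(1, nr), seq_len(nc) / nc - 0.5) * cos(phi)
  bg <- spec$background + spec$gradient_amplitude * gr
  channels <- lapply(channels, function(m) {
    m <- m + bg
    if (spec$poisson_scale > 0) {
      lam <- pmax(m, 0) / spec$poisson_scale
      m <- matrix(stats::rpois(length(lam), lam) * spec$poisson_scale,
                  nr, nc)
    }
    if (spec$gaussian_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, spec$gaussian_sd), nr, nc)
    round_clamp8(m)
  })

  # per-channel true area fractions (pre-noise structure masks)
  truth$true_fractions <- c(
    stats::setNames(truth$vessel_fraction, spec$vessel_channel),
    if (!is.null(truth$pericyte_mask))
      c(PDGFRB = mean(truth$pericyte_mask)),
    if (!is.null(truth$fibrin_mask))
      c(FIBRIN = truth$fibrin_fraction))

  list(image = micrograph(channels, pixel_size = px, bit_depth = 8L),
       truth = truth)
}

#' Cohort specification with planted group effects
#'
#' Describes a multi-group imaging cohort: a base [scene_spec()] and, per
#' group, effect multipliers applied to generator fields. Default
#' multipliers reproduce the magnitudes reported for the aged mouse
#' cortex: fibrin-stained area x3, pericyte numbers x0.8, pericyte
#' coverage x0.5, microglial/C1qa-positive cells x3 in aged sedentary
#' animals, with voluntary running reducing the C1qa-positive population
#' to 0.65 of the sedentary level.
#'
#' @param base a [scene_spec()] used for the control group.
#' @param groups named list of multiplier lists; recognized multiplier
#'   names: `fibrin`, `pericyte_count`, `coverage`, `iba1`, `c1qa`.
#' @param n_animals animals per group.
#' @param images_per_animal fields imaged per animal (4 or 6 typical).
#' @param animal_cv lognormal coefficient of biological variation between
#'   animals (default 0.1).
#' @param seed cohort-level seed; every scene derives its own sub-seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(base = scene_spec(),
                        groups = list(
                          young = list(),
                          aging = list(fibrin = 1.5, pericyte_count = 0.9,
                                       coverage = 0.8, iba1 = 1.5,
                                       c1qa = 1.5),
                          aged_sd = list(fibrin = 3, pericyte_count = 0.8,
                                         coverage = 0.5, iba1 = 3,
                                         c1qa = 3),
                          aged_rn = list(fibrin = 3, pericyte_count = 0.8,
                                         coverage = 0.75,
                                         iba1 = 3 * 0.65,
                                         c1qa = 3 * 0.65)),
                        n_animals = 6L, images_per_animal = 6L,
                        animal_cv = 0.1, seed = 0L) {
  stopifnot(inherits(base, "scene_spec"), length(groups) >= 1L,
            !is.null(names(groups)), !anyDuplicated(names(groups)),
            n_animals >= 1L, images_per_animal >= 1L, animal_cv >= 0)
  for (g in groups)
    if (length(g) && any(unlist(g) <= 0))
      stop("effect multipliers must be positive")
  if (n_animals < 2L)
    warning("fewer than 2 animals per group: downstream inference impossible")
  structure(list(base = base, groups = groups, n_animals = n_animals,
                 images_per_animal = images_per_animal,
                 animal_cv = animal_cv, seed = seed),
            class = "cohort_spec")
}

apply_multipliers <- function(spec, mult, animal_effect = 1) {
  m <- function(name, default = 1) {
    v <- mult[[name]]
    if (is.null(v)) default else v
  }
  spec$fibrin_count <- spec$fibrin_count * m("fibrin") * animal_effect
  spec$pericyte_per_100um <-
    spec$pericyte_per_100um * m("pericyte_count") * animal_effect
  spec$pericyte_coverage_frac <-
    min(spec$pericyte_coverage_frac * m("coverage") * animal_effect, 0.95)
  if (!is.null(spec$cells$IBA1))
    spec$cells$IBA1 <- spec$cells$IBA1 * m("iba1") * animal_effect
  # c1qa multiplier acts on the double-positive fraction relative to the
  # (already scaled) IBA1 population
  spec$c1qa_fraction <-
    min(spec$c1qa_fraction * m("c1qa") / m("iba1"), 1)
  spec
}

#' Generate a cohort of synthetic scenes with planted group effects
#'
#' For each group x animal x image a scene is drawn from the base spec
#' with the group's multipliers and a lognormal per-animal biological
#' effect applied; every scene carries its own derived seed, so results
#' do not depend on generation order. Planted per-scene expectations are
#' recorded in the truth table.
#'
#' @param cs a [cohort_spec()].
#' @param process optional `function(scene, meta)` returning a one-row
#'   data.frame of per-image metrics; when supplied, images are discarded
#'   after processing (memory-friendly) and the bound rows are returned
#'   as `$metrics`.
#' @param keep_scenes keep full scene objects in the result (default
#'   `is.null(process)`).
#' @return list with `manifest` (scene_id, animal_id, group, image_index,
#'   seed), `truth` (per-scene planted values), and `scenes` and/or
#'   `metrics`.
#' @export
generate_cohort <- function(cs = cohort_spec(), process = NULL,
                            keep_scenes = is.null(process)) {
  stopifnot(inherits(cs, "cohort_spec"))
  manifest <- list(); truth <- list(); scenes <- list(); metrics <- list()
  scene_id <- 0L
  for (gi in seq_along(cs$groups)) {
    gname <- names(cs$groups)[gi]
    for (ai in seq_len(cs$n_animals)) {
      animal <- sprintf("%s_%02d", gname, ai)
      aseed <- derive_seed(cs$seed, gi * 1000L + ai)
      aeff <- with_scene_rng(aseed,
                             exp(stats::rnorm(1, 0, cs$animal_cv)))
      for (ii in seq_len(cs$images_per_animal)) {
        scene_id <- scene_id + 1L
        sspec <- apply_multipliers(cs$base, cs$groups[[gi]], aeff)
        sspec$seed <- derive_seed(cs$seed,
                                  gi * 1000000L + ai * 1000L + ii)
        sc <- generate_scene(sspec)
        meta <- data.frame(scene_id = scene_id, animal_id = animal,
                           group = gname, image_index = ii,
                           seed = sspec$seed, stringsAsFactors = FALSE)
        manifest[[scene_id]] <- meta
        truth[[scene_id]] <- data.frame(
          scene_id = scene_id, animal_id = animal, group = gname,
          vessel_fraction = sc$truth$vessel_fraction,
          vessel_length_um = sc$truth$vessel_length_um,
          coverage_fraction = sc$truth$coverage_fraction %||% NA_real_,
          n_pericyte_somata = if (is.null(sc$truth$pericyte_somata)) NA_integer_
                              else nrow(sc$truth$pericyte_somata),
          n_iba1 = if (is.null(sc$truth$cells$IBA1)) NA_integer_
                   else nrow(sc$truth$cells$IBA1),
          n_c1qa = if (is.null(sc$truth$cells$C1QA)) NA_integer_
                   else nrow(sc$truth$cells$C1QA),
          fibrin_fraction = sc$truth$fibrin_fraction %||% NA_real_,
          stringsAsFactors = FALSE)
        if (!is.null(process))
          metrics[[scene_id]] <- cbind(meta, process(sc, meta))
        if (keep_scenes) scenes[[scene_id]] <- sc
      }
    }
  }
  out <- list(manifest = do.call(rbind, manifest),
              truth = do.call(rbind, truth))
  if (keep_scenes) out$scenes <- scenes
  if (!is.null(process)) out$metrics <- do.call(rbind, metrics)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to disk
#'
#' Writes one 8-bit grayscale PNG per scene channel plus `manifest.csv`
#' (file, animal_id, group, channel) and `truth.csv`.
#'
#' @param cohort result of [generate_cohort()] with scenes kept.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$scenes)) stop("cohort was generated without scenes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(cohort$scenes)) {
    sc <- cohort$scenes[[i]]
    meta <- cohort$manifest[i, ]
    for (ch in names(sc$image$channels)) {
      fn <- sprintf("scene%04d_%s.png", meta$scene_id, ch)
      write_micrograph(sc$image, file.path(dir, fn), channel = ch)
      rows[[length(rows) + 1L]] <- data.frame(
        file = fn, animal_id = meta$animal_id, group = meta$group,
        channel = ch, scene_id = meta$scene_id, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
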