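#' Configuration for the synthetic microscopy scene generator
#'
#' Describes one paired fluorescence/phase frame: a grid of nanowells, each
#' holding a few elliptical nuclei. The fluorescence channel renders each
#' nucleus as a bright, blurred footprint that systematically over-extends the
#' true boundary by `fluor_halo` pixels (the behaviour of a stained-channel
#' blob that motivates eroding generated labels). The phase channel renders
#' nuclei as low-contrast textured regions with a faint edge ring, optional
#' protruding cell-body lobes, additive sensor noise and a per-image
#' multiplicative illumination gain.
#'
#' @param image_size integer (H, W) in pixels.
#' @param nanowell_size nanowell side length in pixels; wells tile the frame.
#' @param n_nuclei integer range (min, max) of nuclei per well.
#' @param diameter_range full nucleus diameter range (2 x semi-major axis), px.
#' @param fluor_halo extra apparent radius of the fluorescence footprint beyond
#'   the true nucleus boundary, px (>= 0).
#' @param noise_sd Gaussian sensor noise standard deviation (intensity units,
#'   images live in `[0, 1]`).
#' @param illumination_gain multiplicative gain range (min, max) drawn once per
#'   image, emulating light-source fluctuation.
#' @param touching_fraction fraction of wells in which two nuclei are placed in
#'   contact (their masks share a boundary but never pixels).
#' @param extension_fraction fraction of nuclei given a protruding low-contrast
#'   cell-body lobe in the phase channel (a known false-positive motif).
#' @param fluor_contrast foreground-minus-background intensity of the
#'   fluorescence footprint before blur and noise.
#' @param phase_texture_sd amplitude of the band-passed intra-nucleus texture
#'   in the phase channel.
#' @param phase_edge_depth intensity drop of the faint ring at the nucleus
#'   boundary in the phase channel.
#' @param seed integer seed; scenes are deterministic functions of the config.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = c(512, 512), nanowell_size = 250,
                         n_nuclei = c(1, 3), diameter_range = c(20, 60),
                         fluor_halo = 3, noise_sd = 0.02,
                         illumination_gain = c(0.9, 1.1),
                         touching_fraction = 0.15, extension_fraction = 0.1,
                         fluor_contrast = 0.6, phase_texture_sd = 0.13,
                         phase_edge_depth = 0.1, seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              nanowell_size = as.integer(nanowell_size),
              n_nuclei = as.integer(n_nuclei),
              diameter_range = as.numeric(diameter_range),
              fluor_halo = as.numeric(fluor_halo),
              noise_sd = as.numeric(noise_sd),
              illumination_gain = as.numeric(illumination_gain),
              touching_fraction = as.numeric(touching_fraction),
              extension_fraction = as.numeric(extension_fraction),
              fluor_contrast = as.numeric(fluor_contrast),
              phase_texture_sd = as.numeric(phase_texture_sd),
              phase_edge_depth = as.numeric(phase_edge_depth),
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot(length(cfg$image_size) == 2, all(cfg$image_size >= 32),
            cfg$nanowell_size >= 32,
            length(cfg$n_nuclei) == 2, cfg$n_nuclei[1] >= 0,
            cfg$n_nuclei[2] >= cfg$n_nuclei[1],
            cfg$diameter_range[1] > 0,
            cfg$diameter_range[2] >= cfg$diameter_range[1],
            cfg$fluor_halo >= 0, cfg$noise_sd >= 0)
  for (f in c("touching_fraction", "extension_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("scene_config: %s must lie in [0, 1]", f))
  invisible(cfg)
}

#' Canonical configuration for desk-scale 128 x 128 training patches
#'
#' One nanowell per patch, 1-3 nuclei of 20-44 px diameter: the conditions
#' used throughout the package's detector tests so a compact model is
#' trainable on a single CPU.
#'
#' @param seed integer seed.
#' @param ... overrides forwarded to [scene_config()].
#' @return a `scene_config`.
#' @export
patch_scene_config <- function(seed = 1L, ...) {
  args <- list(image_size = c(128, 128), nanowell_size = 128,
               n_nuclei = c(1, 3), diameter_range = c(20, 44),
               touching_fraction = 0.1, extension_fraction = 0.1, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_config, args)
}

# Normalized elliptical radius of pixels (r, c) w.r.t. a nucleus spec row.
ellipse_dist <- function(r, c, nu) {
  dr <- r - nu$center_r; dc <- c - nu$center_c
  u <- dr * cos(nu$theta) + dc * sin(nu$theta)
  v <- -dr * sin(nu$theta) + dc * cos(nu$theta)
  sqrt((u / nu$a)^2 + (v / nu$b)^2)
}

# Place nuclei inside one well; returns a data.frame of nucleus specs.
place_nuclei <- function(cfg, well_r0, well_c0, well_size, touching) {
  n <- if (cfg$n_nuclei[2] == cfg$n_nuclei[1]) cfg$n_nuclei[1] else
    sample(seq(cfg$n_nuclei[1], cfg$n_nuclei[2]), 1)
  if (n == 0) return(NULL)
  dmin <- cfg$diameter_range[1]; dmax <- cfg$diameter_range[2]
  # keep sampled sizes off the range edges so discretized bounding boxes of
  # rotated ellipses still fall inside the configured diameter range
  inset <- min(2, (dmax - dmin) / 4)
  out <- NULL
  for (i in seq_len(n)) {
    a <- runif(1, (dmin + 2 * inset) / 2, (dmax - inset) / 2)
    b <- a * runif(1, 0.8, 1)
    theta <- runif(1, 0, pi)
    margin <- a + cfg$fluor_halo + 3
    if (2 * margin >= well_size)
      stop("simulate_scene: nanowell_size too small for the configured ",
           "diameter_range and fluor_halo")
    placed <- FALSE
    for (try in 1:300) {
      if (touching && i == 2) {
        ref <- out[1, ]
        phi <- runif(1, 0, 2 * pi)
        d <- 0.97 * (sqrt(ref$a * ref$b) + sqrt(a * b))
        cr <- ref$center_r + d * cos(phi); cc <- ref$center_c + d * sin(phi)
      } else {
        cr <- runif(1, well_r0 + margin, well_r0 + well_size - margin)
        cc <- runif(1, well_c0 + margin, well_c0 + well_size - margin)
      }
      if (cr < well_r0 + margin || cr > well_r0 + well_size - margin ||
          cc < well_c0 + margin || cc > well_c0 + well_size - margin) next
      ok <- TRUE
      if (!is.null(out)) {
        for (j in seq_len(nrow(out))) {
          want_touch <- touching && i == 2 && j == 1
          dist <- sqrt((cr - out$center_r[j])^2 + (cc - out$center_c[j])^2)
          sep <- out$a[j] + a + 4
          if (!want_touch && dist < sep) { ok <- FALSE; break }
        }
      }
      if (ok) {
        out <- rbind(out, data.frame(
          center_r = cr, center_c = cc, a = a, b = b, theta = theta,
          fluor_halo = cfg$fluor_halo,
          extension = runif(1) < cfg$extension_fraction,
          texture_seed = sample.int(.Machine$integer.max, 1)))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("simulate_scene: could not place ", n, " nuclei in a ",
           well_size, " px nanowell; reduce n_nuclei or diameter_range")
  }
  out
}

# Band-passed noise texture over a full image, seeded per nucleus.
texture_field <- function(H, W, seed, sd_out) {
  with_seed(seed, {
    z <- matrix(stats::rnorm(H * W), H, W)
    t <- gauss_blur(z, 1.2) - gauss_blur(z, 3)
    t * (sd_out / max(stats::sd(t), 1e-12))
  })
}

#' Simulate one paired fluorescence/phase scene with exact ground truth
#'
#' Deterministic in `config$seed`. Nuclei are placed per nanowell; truth masks
#' are the exact ellipse interiors, made pairwise disjoint by assigning
#' contested pixels to the nucleus with the smallest normalized elliptical
#' distance (touching pairs therefore share a boundary, never pixels).
#'
#' @param config a [scene_config()].
#' @return a `synthetic_scene`: list with `config`, `nuclei` (data.frame of
#'   nucleus parameters), `fluor` and `phase` (numeric matrices in `[0, 1]`)
#'   and `truth` (an [instance_mask_set()] of exact nucleus masks, no halo).
#' @export
simulate_scene <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, simulate_scene_impl(config))
}

simulate_scene_impl <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  ws <- cfg$nanowell_size
  wells_r <- max(1, H %/% ws); wells_c <- max(1, W %/% ws)
  nuclei <- NULL
  for (wr in seq_len(wells_r) - 1) for (wc in seq_len(wells_c) - 1) {
    touching <- runif(1) < cfg$touching_fraction && cfg$n_nuclei[2] >= 2
    nn <- place_nuclei(cfg, wr * ws, wc * ws, ws, touching)
    nuclei <- rbind(nuclei, nn)
  }
  rows <- matrix(seq_len(H) - 1, H, W)
  cols <- matrix(rep(seq_len(W) - 1, each = H), H, W)

  fluor <- matrix(0.08, H, W)
  phase <- matrix(0.55, H, W)
  masks <- list()
  if (!is.null(nuclei) && nrow(nuclei) > 0) {
    n <- nrow(nuclei)
    # normalized ellipse distance per nucleus, evaluated on its padded bbox
    dist_all <- vector("list", n)
    owner <- matrix(0L, H, W); best <- matrix(Inf, H, W)
    for (i in seq_len(n)) {
      nu <- nuclei[i, ]
      d <- ellipse_dist(rows, cols, nu)
      dist_all[[i]] <- d
      upd <- d <= 1 & d < best
      owner[upd] <- i; best[upd] <- d[upd]
    }
    for (i in seq_len(n)) {
      px <- which(owner == i)
      if (length(px) == 0)
        stop("simulate_scene: a nucleus rendered to an empty mask; ",
             "diameter_range too small for the pixel grid")
      masks[[i]] <- px

      nu <- nuclei[i, ]
      # fluorescence footprint: true ellipse enlarged by the halo, domed profile
      dh <- ellipse_dist(rows, cols, within(nu, {
        a <- a + fluor_halo; b <- b + fluor_halo }))
      inside <- dh <= 1
      fluor[inside] <- fluor[inside] +
        cfg$fluor_contrast * (1 - 0.35 * dh[inside]^2)

      # phase: textured, slightly darker interior + faint edge ring
      d <- dist_all[[i]]
      core <- d <= 1
      tex <- texture_field(H, W, nu$texture_seed, cfg$phase_texture_sd)
      phase[core] <- phase[core] - 0.06 + tex[core]
      ring <- d > 0.85 & d < 1.12
      phase[ring] <- phase[ring] -
        cfg$phase_edge_depth * (1 - abs(d[ring] - 1) / 0.15)

      if (isTRUE(nu$extension)) {
        # low-contrast cell-body lobe protruding from the nucleus (phase only)
        phi <- runif(1, 0, 2 * pi)
        lr <- runif(1, 4, 7)
        rad <- 1 / sqrt((cos(phi) / nu$a)^2 + (sin(phi) / nu$b)^2)
        lc_r <- nu$center_r + (rad + 0.7 * lr) * cos(phi)
        lc_c <- nu$center_c + (rad + 0.7 * lr) * sin(phi)
        dl <- sqrt((rows - lc_r)^2 + (cols - lc_c)^2) / lr
        lobe <- dl <= 1
        phase[lobe] <- phase[lobe] - 0.05 * (1 - dl[lobe]^2)
      }
    }
  }
  fluor <- gauss_blur(fluor, 1.0)
  gain <- runif(1, cfg$illumination_gain[1], cfg$illumination_gain[2])
  fluor <- clamp01(gain * fluor + matrix(stats::rnorm(H * W, 0, cfg$noise_sd), H, W))
  phase <- clamp01(gain * phase + matrix(stats::rnorm(H * W, 0, cfg$noise_sd), H, W))

  truth <- instance_mask_set(c(H, W), masks)
  structure(list(config = cfg,
                 nuclei = if (is.null(nuclei)) data.frame() else nuclei,
                 fluor = fluor, phase = phase, truth = truth),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene: %d x %d px, %d nuclei, seed %d>\n",
              nrow(x$fluor), ncol(x$fluor), length(x$truth$masks),
              x$config$seed))
  invisible(x)
}

#' Simulate a batch of scenes from a root seed
#'
#' Scene `i` uses a child seed derived deterministically from `seed` and `i`.
#'
#' @param n_scenes number of scenes.
#' @param config template [scene_config()]; its own seed field is ignored.
#' @param seed root seed.
#' @return list of `synthetic_scene`.
#' @export
simulate_scenes <- function(n_scenes, config, seed = 1L) {
  lapply(seq_len(n_scenes), function(i) {
    cfg <- config
    cfg$seed <- child_seed(seed, i)
    simulate_scene(cfg)
  })
}

#' Write scenes to disk as 16-bit TIFFs plus a JSON manifest
#'
#' Per scene: a fluorescence image, a phase image (16-bit grayscale TIFF) and
#' the truth instance masks as an integer label-map TIFF (0 = background,
#' k = instance k). A `manifest.json` lists files, seeds and the config.
#'
#' @param scenes list of `synthetic_scene`.
#' @param directory output directory (created if missing).
#' @param overwrite if `FALSE` (default), refuse to write into an existing
#'   non-empty directory.
#' @return the manifest, invisibly (a list; also written as JSON).
#' @export
write_dataset <- function(scenes, directory, overwrite = FALSE) {
  if (dir.exists(directory) && length(list.files(directory)) > 0 && !overwrite)
    stop("write_dataset: directory ", directory,
         " is not empty; pass overwrite = TRUE to replace it")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    fl <- sprintf("scene%03d_fluor.tif", i)
    ph <- sprintf("scene%03d_phase.tif", i)
    tr <- sprintf("scene%03d_truth.tif", i)
    tiff::writeTIFF(sc$fluor, file.path(directory, fl), bits.per.sample = 16)
    tiff::writeTIFF(sc$phase, file.path(directory, ph), bits.per.sample = 16)
    write_label_map(as_label_map(sc$truth), file.path(directory, tr))
    list(id = i, fluor = fl, phase = ph, truth = tr,
         seed = sc$config$seed, n_nuclei = length(sc$truth$masks))
  })
  manifest <- list(
    n_scenes = length(scenes), files = entries,
    config = if (length(scenes)) unclass(scenes[[1]]$config) else NULL)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Label maps are stored as 16-bit TIFF with value k/65535 for instance k.
write_label_map <- function(lab, path) {
  if (max(lab) > 65535) stop("write_label_map: more than 65535 instances")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16)
}

#' Read an integer label map written by [write_dataset()]
#' @param path TIFF path.
#' @return integer matrix (0 = background).
#' @export
read_label_map <- function(path) {
  x <- tiff::readTIFF(path)
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

#' Read a dataset directory written by [write_dataset()]
#' @param directory dataset directory containing `manifest.json`.
#' @return list with `manifest` and per-scene `fluor`, `phase`, `truth`.
#' @export
read_dataset <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  scenes <- lapply(seq_len(manifest$n_scenes), function(i) {
    f <- manifest$files[i, ]
    list(fluor = tiff::readTIFF(file.path(directory, f$fluor)),
         phase = tiff::readTIFF(file.path(directory, f$phase)),
         truth = mask_set_from_label_map(
           read_label_map(file.path(directory, f$truth))))
  })
  list(manifest = manifest, scenes = scenes)
}
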