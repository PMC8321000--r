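#' Configuration of the synthetic chest phantom
#'
#' The phantom emulates the four-region structure of a PNG-exported axial
#' chest CT slice: black background, a dark-gray circular body rim, a bright
#' chest wall carrying darker patches, and two dark lung fields. Bright
#' spheres (nodules) keep their in-plane center across adjacent slices while
#' bright oblique cylinders (vessels) drift between slices, so the
#' across-slice consistency feature separates them by construction.
#'
#' Intensity defaults reproduce the expected histogram peak layout
#' (background 0, rim about 60, lungs about 50, wall near 255) and keep the
#' lung level below the background-removal valley and the structure/wall
#' levels well above it.
#'
#' @param M,N Slice size in pixels.
#' @param n_slices Stack depth.
#' @param intensities Named per-region mean levels: `background`, `rim`,
#'   `wall`, `patch`, `lung`, `nodule`, `vessel`.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units); intensities are clipped to `[0, 255]` after perturbation.
#' @param n_nodules,nodule_radius_range Number of planted nodules and their
#'   sphere radius range in pixels.
#' @param n_vessels,vessel_radius_range Number of vessels and their
#'   cross-section radius range in pixels.
#' @param vessel_obliqueness In-plane drift of a vessel center per slice
#'   (pixels); the default exceeds the candidate match radius so vessels fail
#'   the consistency test.
#' @param n_patches Number of darker patches in the chest wall.
#' @param slice_dz Through-plane distance between adjacent slices in pixel
#'   units (converts a sphere radius into its per-slice cross-sections).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(M = 320L, N = 320L, n_slices = 9L,
                           intensities = c(background = 0, rim = 60, wall = 235,
                                           patch = 170, lung = 50,
                                           nodule = 210, vessel = 200),
                           noise_sd = 3, n_nodules = 2L,
                           nodule_radius_range = c(4, 6), n_vessels = 3L,
                           vessel_radius_range = c(2, 4),
                           vessel_obliqueness = 6, n_patches = 5L,
                           slice_dz = 2, seed = 1L) {
  cfg <- list(M = as.integer(M), N = as.integer(N),
              n_slices = as.integer(n_slices), intensities = intensities,
              noise_sd = noise_sd, n_nodules = as.integer(n_nodules),
              nodule_radius_range = nodule_radius_range,
              n_vessels = as.integer(n_vessels),
              vessel_radius_range = vessel_radius_range,
              vessel_obliqueness = vessel_obliqueness,
              n_patches = as.integer(n_patches), slice_dz = slice_dz,
              seed = as.integer(seed))
  req <- c("background", "rim", "wall", "patch", "lung", "nodule", "vessel")
  if (!all(req %in% names(intensities)))
    stop("intensities must name: ", paste(req, collapse = ", "), call. = FALSE)
  if (cfg$M < 64L || cfg$N < 64L || cfg$n_slices < 1L)
    stop("phantom must be at least 64 x 64 with >= 1 slice", call. = FALSE)
  i <- intensities
  if (!(i["lung"] < i["rim"] + 15 && i["rim"] < i["patch"] &&
        i["patch"] < max(i["nodule"], i["vessel"], i["wall"])))
    stop("region levels must be ordered lung/rim < patch < structures/wall",
         call. = FALSE)
  geom <- phantom_geometry(cfg)
  if (max(cfg$nodule_radius_range) + 4 > 0.45 * min(geom$lung_ar, geom$lung_ac))
    stop("config error: nodule radius does not fit inside the phantom lungs",
         call. = FALSE)
  structure(cfg, class = "phantom_config")
}

phantom_geometry <- function(cfg) {
  s <- min(cfg$M, cfg$N)
  list(center_r = (cfg$M + 1) / 2, center_c = (cfg$N + 1) / 2,
       body_radius = 0.47 * s, wall_radius = 0.42 * s,
       lung_offset = 0.1625 * s, lung_ar = 0.275 * s, lung_ac = 0.13 * s,
       lung_wobble_amp = 0.06, lung_wobble_freq = 5)
}

ellipse_mask <- function(rr, cc, r0, c0, ar, ac, amp = 0, freq = 0, phase = 0) {
  dr <- (rr - r0) / ar
  dc <- (cc - c0) / ac
  rho <- sqrt(dr^2 + dc^2)
  if (amp == 0) return(rho <= 1)
  theta <- atan2(dr, dc)
  rho <= 1 + amp * sin(freq * theta + phase)
}

disc_mask <- function(rr, cc, r0, c0, radius) {
  (rr - r0)^2 + (cc - c0)^2 <= radius^2
}

#' Generate a seeded synthetic chest-CT stack with ground truth
#'
#' @param config A [phantom_config()].
#' @param exam_id Opaque identifier stamped on the stack and truth.
#' @return List with `stack` (a `slice_stack`) and `truth`: `lung_masks`
#'   (per-slice logical matrices covering the planted lung fields, internal
#'   structures included), `nodules` and `vessels` (data frames with one row
#'   per slice occurrence: `id`, `slice_index`, `center_r`, `center_c`,
#'   `radius_px`).
#' @export
generate_stack <- function(config = phantom_config(), exam_id = "phantom") {
  cfg <- config
  g <- phantom_geometry(cfg)
  lev <- cfg$intensities
  with_seed(cfg$seed, {
    rr <- matrix(seq_len(cfg$M), cfg$M, cfg$N)
    cc <- matrix(rep(seq_len(cfg$N), each = cfg$M), cfg$M, cfg$N)

    base <- matrix(lev[["background"]], cfg$M, cfg$N)
    body <- disc_mask(rr, cc, g$center_r, g$center_c, g$body_radius)
    wall <- disc_mask(rr, cc, g$center_r, g$center_c, g$wall_radius)
    base[body] <- lev[["rim"]]
    base[wall] <- lev[["wall"]]

    lungs <- vector("list", 2L)
    for (side in 1:2) {
      c0 <- g$center_c + c(-1, 1)[side] * g$lung_offset
      lungs[[side]] <- ellipse_mask(rr, cc, g$center_r, c0, g$lung_ar,
                                    g$lung_ac, g$lung_wobble_amp,
                                    g$lung_wobble_freq, runif(1, 0, 2 * pi))
    }
    lung_mask <- lungs[[1]] | lungs[[2]]
    base[lung_mask] <- lev[["lung"]]

    # darker patches inside the chest wall (between rim and lungs)
    wall_only <- wall & !lung_mask
    placed <- 0L
    tries <- 0L
    while (placed < cfg$n_patches && tries < 200L) {
      tries <- tries + 1L
      pr <- runif(1, g$center_r - g$wall_radius, g$center_r + g$wall_radius)
      pc <- runif(1, g$center_c - g$wall_radius, g$center_c + g$wall_radius)
      prad <- runif(1, 2, 4)
      d <- disc_mask(rr, cc, pr, pc, prad)
      if (all(wall_only[d]) && any(d)) {
        base[d] <- lev[["patch"]]
        placed <- placed + 1L
      }
    }

    sample_in_lung <- function(scale) {
      repeat {
        side <- sample(1:2, 1)
        c0 <- g$center_c + c(-1, 1)[side] * g$lung_offset
        a <- runif(1, 0, 2 * pi)
        rho <- sqrt(runif(1)) * scale
        r <- g$center_r + rho * g$lung_ar * sin(a)
        c <- c0 + rho * g$lung_ac * cos(a)
        return(c(r, c))
      }
    }
    fits_in_lungs <- function(r, c, radius) {
      d <- disc_mask(rr, cc, r, c, radius)
      any(d) && all(lung_mask[d])
    }

    # nodules: spheres with fixed in-plane center; cross-section radius on
    # slice offset dj is sqrt(R^2 - (dz*dj)^2), drawn when it rounds to >= 2 px
    nodules <- NULL
    nod_centers <- NULL
    for (i in seq_len(cfg$n_nodules)) {
      R <- runif(1, cfg$nodule_radius_range[1], cfg$nodule_radius_range[2])
      smax <- 0L
      while (cfg$slice_dz^2 * (smax + 1)^2 < R^2 &&
             round(sqrt(R^2 - cfg$slice_dz^2 * (smax + 1)^2)) >= 2) smax <- smax + 1L
      jc <- if (cfg$n_slices >= 2L * smax + 1L)
        sample(seq(1L + smax, cfg$n_slices - smax), 1)
      else sample(seq_len(cfg$n_slices), 1)
      ok <- FALSE
      for (try in 1:200) {
        ctr <- sample_in_lung(0.55)
        if (!fits_in_lungs(ctr[1], ctr[2], R + 3)) next
        if (!is.null(nod_centers) &&
            any(sqrt(colSums((t(nod_centers) - ctr)^2)) < 3 * R + 10)) next
        ok <- TRUE
        break
      }
      if (!ok) next
      nod_centers <- rbind(nod_centers, ctr)
      for (dj in -smax:smax) {
        j <- jc + dj
        if (j < 1L || j > cfg$n_slices) next
        rj <- round(sqrt(max(R^2 - (cfg$slice_dz * dj)^2, 0)))
        if (rj < 2) next
        nodules <- rbind(nodules, data.frame(
          id = i, slice_index = j, center_r = round(ctr[1]),
          center_c = round(ctr[2]), radius_px = rj))
      }
    }

    # vessels: cylinders whose cross-section center drifts between slices
    vessels <- NULL
    for (i in seq_len(cfg$n_vessels)) {
      best <- NULL
      for (try in 1:200) {
        rv <- runif(1, cfg$vessel_radius_range[1], cfg$vessel_radius_range[2])
        j0 <- sample(seq_len(cfg$n_slices), 1)
        start <- sample_in_lung(0.55)
        phi <- runif(1, 0, 2 * pi)
        dir <- c(sin(phi), cos(phi))
        rows <- NULL
        clash <- FALSE
        for (j in seq_len(cfg$n_slices)) {
          ctr <- start + (j - j0) * cfg$vessel_obliqueness * dir
          if (!fits_in_lungs(ctr[1], ctr[2], rv + 1)) next
          near <- function(df) {
            !is.null(df) && any(df$slice_index == j &
              sqrt((df$center_r - ctr[1])^2 + (df$center_c - ctr[2])^2) <
                df$radius_px + rv + 4)
          }
          if (near(nodules) || near(vessels)) { clash <- TRUE; break }
          rows <- rbind(rows, data.frame(
            id = i, slice_index = j, center_r = round(ctr[1]),
            center_c = round(ctr[2]), radius_px = round(rv)))
        }
        if (!clash && !is.null(rows) && nrow(rows) >= 2L) { best <- rows; break }
      }
      vessels <- rbind(vessels, best)
    }

    slices <- vector("list", cfg$n_slices)
    for (j in seq_len(cfg$n_slices)) {
      img <- base
      draw <- function(df, level) {
        if (is.null(df)) return(invisible(NULL))
        sel <- df[df$slice_index == j, , drop = FALSE]
        for (k in seq_len(nrow(sel))) {
          d <- disc_mask(rr, cc, sel$center_r[k], sel$center_c[k],
                         sel$radius_px[k])
          img[d] <<- level
        }
      }
      draw(nodules, lev[["nodule"]])
      draw(vessels, lev[["vessel"]])
      if (cfg$noise_sd > 0)
        img <- img + rnorm(length(img), sd = cfg$noise_sd)
      px <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), cfg$M, cfg$N)
      slices[[j]] <- grayscale_slice(px, j, sprintf("%s_%03d", exam_id, j))
    }
    empty_df <- data.frame(id = integer(0), slice_index = integer(0),
                           center_r = numeric(0), center_c = numeric(0),
                           radius_px = numeric(0))
    list(stack = slice_stack(slices, exam_id = exam_id),
         truth = list(lung_masks = rep(list(lung_mask), cfg$n_slices),
                      nodules = if (is.null(nodules)) empty_df else nodules,
                      vessels = if (is.null(vessels)) empty_df else vessels))
  })
}

#' Export a phantom exam to disk
#'
#' Writes the slices as loss-less grayscale PNGs (`slice_001.png`, ...), the
#' per-slice lung masks under `masks/`, and the planted nodule/vessel ground
#' truth as JSON lines in the evaluation module's format (`nodules.jsonl`,
#' `vessels.jsonl`).
#'
#' @param stack A `slice_stack`.
#' @param truth The matching ground-truth list from [generate_stack()].
#' @param dir Output directory (created if missing).
#' @export
export_phantom <- function(stack, truth, dir) {
  if (length(stack$slices) == 0L)
    stop("config error: empty stack", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  for (s in stack$slices) {
    write_slice_image(s, file.path(dir, sprintf("slice_%03d.png", s$slice_index)))
  }
  for (j in seq_along(truth$lung_masks)) {
    write_mask_image(truth$lung_masks[[j]],
                     file.path(dir, "masks", sprintf("lung_%03d.png", j)))
  }
  for (what in c("nodules", "vessels")) {
    df <- truth[[what]]
    df$exam_id <- stack$exam_id
    write_ground_truth(df, file.path(dir, paste0(what, ".jsonl")))
  }
  invisible(NULL)
}
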