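#' Fluorescence localization model for synthetic cells
#'
#' Describes how fluorophores are laid out in a synthetic cell. `polar_foci`
#' places two Gaussian foci at the spine ends; `septal_accumulation` places a
#' Gaussian band across the cell middle; `mixed` shifts weight from the polar
#' foci to the septal band as the cell widens (a logistic function of width),
#' emulating division proteins that sit at the poles of young cells and
#' accumulate medially in constricting ones. Fluorophore density is constant
#' per unit volume by default, so total signal scales with the rod-model
#' volume.
#'
#' @param pattern `"mixed"`, `"polar_foci"` or `"septal_accumulation"`.
#' @param focus_sd_um Gaussian focus / band standard deviation (um).
#' @param density Fluorophores (a.u.) per cubic micrometre.
#' @param background_level Scalar camera background added to the image.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param septal_midpoint_um Width at which polar and septal weights are
#'   equal (`mixed` pattern).
#' @param septal_steepness Logistic steepness (per um) of the polar-to-septal
#'   handover.
#' @return An object of class `localization_model`.
#' @export
localization_model <- function(pattern = c("mixed", "polar_foci",
                                           "septal_accumulation"),
                               focus_sd_um = 0.15, density = 5000,
                               background_level = 100, noise_sd = 3,
                               septal_midpoint_um = 1.08,
                               septal_steepness = 20) {
  pattern <- match.arg(pattern)
  if (density < 0) stop("density must be >= 0")
  structure(list(pattern = pattern, focus_sd_um = focus_sd_um,
                 density = density, background_level = background_level,
                 noise_sd = noise_sd,
                 septal_midpoint_um = septal_midpoint_um,
                 septal_steepness = septal_steepness),
            class = "localization_model")
}

# septal weight in [0,1] as a function of width
.septal_weight <- function(model, width_um) {
  switch(model$pattern,
         polar_foci = 0,
         septal_accumulation = 1,
         mixed = 1 / (1 + exp(-model$septal_steepness *
                                (width_um - model$septal_midpoint_um))))
}

# shortest distance between two segments given as endpoint pairs (2-col mats)
.seg_dist <- function(p1, p2, q1, q2) {
  pts <- function(a, b) {  # sample points along a segment
    tt <- seq(0, 1, length.out = 9)
    cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  A <- pts(p1, p2); B <- pts(q1, q2)
  min(sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2))
}

#' Generate synthetic phase/fluorescence cell image pairs
#'
#' Places capsule-shaped (rod-model) cells at random positions and
#' orientations, without overlap and away from image borders, filling as many
#' images as needed. Phase images show dark cells on a light background;
#' fluorescence images render the localization model (polar foci and/or a
#' medial septal band) with total per-cell signal equal to `density x
#' rod-model volume`, plus background and Gaussian noise. Cell widths follow
#' a right-skewed population (piecewise-linear quantile anchors mimicking a
#' population in which most cells are young and thin), rescaled to
#' `width_range_um`.
#'
#' @param n_cells Number of cells to place (0 gives one background-only
#'   pair).
#' @param width_range_um Width range (um) spanned by the population.
#' @param length_um Mean cell length (um); each cell's length is jittered by
#'   `length_jitter` relative.
#' @param model A [localization_model()].
#' @param pixel_size_um Pixel size (um).
#' @param image_size Image dimensions `c(rows, cols)`.
#' @param length_jitter Relative length jitter.
#' @param max_attempts Placement attempts per cell within one image before a
#'   new image is started.
#' @param seed Integer seed.
#' @return A list of class `cell_image_sim`: `images` (list of
#'   `list(phase, fluor)` matrices), `truth` (per-cell data.frame: image,
#'   center, angle, length/width um, volume, total_signal, septal_weight),
#'   `model`, `pixel_size_um`.
#' @export
gen_cell_images <- function(n_cells, width_range_um = c(0.66, 1.50),
                            length_um = 2.4,
                            model = localization_model(),
                            pixel_size_um = 0.0645,
                            image_size = c(512, 512),
                            length_jitter = 0.1,
                            max_attempts = 200, seed = 1) {
  set.seed(seed)
  nr <- image_size[1]; nc <- image_size[2]
  ps <- pixel_size_um

  # width population: right-skewed quantile anchors rescaled to the range
  qu <- c(0, 0.6, 0.8, 0.9, 1)
  qw <- c(0.66, 1.03, 1.14, 1.27, 1.50)
  draw_width <- function(n) {
    w0 <- stats::approx(qu, qw, stats::runif(n))$y
    width_range_um[1] + (w0 - qw[1]) *
      diff(width_range_um) / (qw[5] - qw[1])
  }

  widths <- if (n_cells > 0) draw_width(n_cells) else numeric(0)
  lengths <- if (n_cells > 0)
    pmax(length_um * (1 + stats::runif(n_cells, -length_jitter,
                                       length_jitter)),
         widths + 3 * ps) else numeric(0)

  blank_pair <- function() {
    list(phase = matrix(30000, nr, nc) +
           matrix(stats::rnorm(nr * nc, 0, 300), nr, nc),
         fluor = matrix(model$background_level, nr, nc) +
           matrix(stats::rnorm(nr * nc, 0, model$noise_sd), nr, nc))
  }

  placed <- list()   # per image: list of spine endpoint pairs + widths
  sig <- list()      # per image: noiseless signal accumulator
  phase_mask <- list()
  truth <- list()

  new_image <- function() {
    placed[[length(placed) + 1L]] <<- list()
    sig[[length(sig) + 1L]] <<- matrix(0, nr, nc)
    phase_mask[[length(phase_mask) + 1L]] <<- matrix(FALSE, nr, nc)
  }
  new_image()

  for (i in seq_len(n_cells)) {
    l_px <- lengths[i] / ps; w_px <- widths[i] / ps
    half_spine <- (l_px - w_px) / 2
    margin <- l_px / 2 + 2
    if (2 * margin >= min(nr, nc))
      stop("cell longer than the image; enlarge image_size")
    done <- FALSE
    img <- length(placed)
    attempts_left <- max_attempts
    while (!done) {
      r0 <- stats::runif(1, margin, nr - margin)
      c0 <- stats::runif(1, margin, nc - margin)
      th <- stats::runif(1, 0, pi)
      u <- c(cos(th), sin(th))
      p1 <- c(r0, c0) - u * half_spine
      p2 <- c(r0, c0) + u * half_spine
      ok <- TRUE
      for (pl in placed[[img]]) {
        if (.seg_dist(p1, p2, pl$p1, pl$p2) <
            (w_px + pl$w_px) / 2 + 2) { ok <- FALSE; break }
      }
      if (ok) {
        placed[[img]][[length(placed[[img]]) + 1L]] <-
          list(p1 = p1, p2 = p2, w_px = w_px)
        res <- .render_cell(nr, nc, r0, c0, u, half_spine, w_px, ps,
                            lengths[i], widths[i], model)
        sig[[img]] <- sig[[img]] + res$fluor
        phase_mask[[img]] <- phase_mask[[img]] | res$mask
        sw <- .septal_weight(model, widths[i])
        vol <- rod_volume(lengths[i], widths[i])
        truth[[length(truth) + 1L]] <- data.frame(
          image = img, row = r0, col = c0, angle = th,
          length_um = lengths[i], width_um = widths[i],
          volume_um3 = vol, total_signal = model$density * vol,
          septal_weight = sw)
        done <- TRUE
      } else {
        attempts_left <- attempts_left - 1
        if (attempts_left == 0) {
          if (length(placed[[img]]) == 0)
            stop("cannot place cell even in an empty image")
          new_image()
          img <- length(placed)
          attempts_left <- max_attempts
        }
      }
    }
  }

  out_images <- lapply(seq_along(placed), function(im) {
    pair <- blank_pair()
    pair$phase[phase_mask[[im]]] <- pair$phase[phase_mask[[im]]] - 18000
    pair$fluor <- pair$fluor + sig[[im]]
    pair
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(image = integer(0), row = numeric(0), col = numeric(0),
               angle = numeric(0), length_um = numeric(0),
               width_um = numeric(0), volume_um3 = numeric(0),
               total_signal = numeric(0), septal_weight = numeric(0))
  structure(list(images = out_images, truth = truth, model = model,
                 pixel_size_um = ps, seed = seed),
            class = "cell_image_sim")
}

# render one capsule cell: returns its boolean mask and noiseless
# fluorescence contribution on the full image grid
.render_cell <- function(nr, nc, r0, c0, u, half_spine, w_px, ps,
                         length_um, width_um, model) {
  v <- c(-u[2], u[1])
  sd_px <- model$focus_sd_um / ps
  pad <- w_px / 2 + 3 * sd_px + 2
  reach <- half_spine + pad
  rmin <- max(1L, floor(r0 - reach)); rmax <- min(nr, ceiling(r0 + reach))
  cmin <- max(1L, floor(c0 - reach)); cmax <- min(nc, ceiling(c0 + reach))
  rr <- rmin:rmax; cc <- cmin:cmax
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  a <- (R - r0) * u[1] + (C - c0) * u[2]
  d <- (R - r0) * v[1] + (C - c0) * v[2]
  da <- pmax(abs(a) - half_spine, 0)
  inside <- sqrt(da^2 + d^2) <= w_px / 2

  sw <- .septal_weight(model, width_um)
  total <- model$density * rod_volume(length_um, width_um)
  comp <- matrix(0, length(rr), length(cc))
  if (sw < 1) {
    # polar foci sit at the centers of the hemispherical pole caps
    pole <- (2 * half_spine + w_px) / 2 - w_px / 4
    p1 <- c(r0, c0) - u * pole
    p2 <- c(r0, c0) + u * pole
    g1 <- exp(-((R - p1[1])^2 + (C - p1[2])^2) / (2 * sd_px^2))
    g2 <- exp(-((R - p2[1])^2 + (C - p2[2])^2) / (2 * sd_px^2))
    comp <- comp + (1 - sw) / 2 * (g1 / sum(g1) + g2 / sum(g2))
  }
  if (sw > 0) {
    band <- exp(-a^2 / (2 * sd_px^2)) * inside
    comp <- comp + sw * band / sum(band)
  }
  fluor_box <- total * comp

  mask <- matrix(FALSE, nr, nc)
  fluor <- matrix(0, nr, nc)
  mask[rr, cc] <- inside
  fluor[rr, cc] <- fluor_box
  list(mask = mask, fluor = fluor)
}

#' Write a synthetic image set to TIFF + CSV
#'
#' Writes each image pair as 16-bit grayscale TIFFs (`phase_##.tif`,
#' `fluor_##.tif`), the ground truth as `truth.csv`, and a `manifest.csv`
#' (`phase_path`, `fluor_path`, `pixel_size_um`) next to them.
#'
#' @param sim A [gen_cell_images()] result.
#' @param dir Output directory (created if needed).
#' @param scale Intensity divisor mapping a.u. to the 16-bit range.
#' @return The manifest data.frame, invisibly.
#' @export
write_cell_images <- function(sim, dir, scale = 65535) {
  stopifnot(inherits(sim, "cell_image_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(sim$images), function(i) {
    pp <- file.path(dir, sprintf("phase_%02d.tif", i))
    fp <- file.path(dir, sprintf("fluor_%02d.tif", i))
    clip <- function(m) pmin(pmax(m / scale, 0), 1)
    tiff::writeTIFF(clip(sim$images[[i]]$phase), pp, bits.per.sample = 16)
    tiff::writeTIFF(clip(sim$images[[i]]$fluor), fp, bits.per.sample = 16)
    data.frame(phase_path = pp, fluor_path = fp,
               pixel_size_um = sim$pixel_size_um, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read and analyze an image-pair manifest
#'
#' Runs [analyze_image_pair()] over every row of a manifest CSV
#' (`phase_path`, `fluor_path`, `pixel_size_um`) and pools the results.
#'
#' @param manifest_path Manifest CSV path.
#' @param ... Passed to [analyze_image_pair()].
#' @return List with pooled `cells` and `profiles` plus per-image results.
#' @export
analyze_manifest <- function(manifest_path, ...) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("phase_path", "fluor_path", "pixel_size_um")
  if (!all(needed %in% names(man)))
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  per_image <- lapply(seq_len(nrow(man)), function(i) {
    ph <- tiff::readTIFF(man$phase_path[i])
    fl <- tiff::readTIFF(man$fluor_path[i])
    analyze_image_pair(ph, fl, man$pixel_size_um[i], ...)
  })
  list(cells = do.call(c, lapply(per_image, `[[`, "cells")),
       profiles = do.call(c, lapply(per_image, `[[`, "profiles")),
       per_image = per_image)
}
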