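#' Segment cells from a phase-contrast image
#'
#' Global Otsu threshold for dark-on-light cells, connected components with
#' 8-connectivity, removal of components smaller than `min_area_px` or
#' touching the image border. Labels are dense from 1, ordered by the
#' component's topmost (then leftmost) pixel.
#'
#' @param phase_image 2-D numeric matrix (row, col), higher = brighter.
#' @param pixel_size_um Physical pixel size in micrometres (> 0), attached to
#'   each mask.
#' @param min_area_px Minimum component area in pixels.
#' @return A list of `cell_mask` objects (`label`, `pixels` = integer matrix
#'   of (row, col), `pixel_size_um`); empty list if nothing is found.
#' @export
segment_cells <- function(phase_image, pixel_size_um, min_area_px = 50) {
  stopifnot(is.matrix(phase_image), pixel_size_um > 0)
  rng <- range(phase_image)
  if (diff(rng) == 0) return(list())
  norm <- (phase_image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm < thr  # cells are dark
  if (!any(bw)) return(list())
  lab <- .label8(bw)
  if (max(lab) == 0) return(list())

  nr <- nrow(lab); nc <- ncol(lab)
  keep <- list()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) next
    if (any(idx[, 1] %in% c(1L, nr)) || any(idx[, 2] %in% c(1L, nc))) next
    keep[[length(keep) + 1L]] <- idx
  }
  if (length(keep) == 0) return(list())
  ord <- order(vapply(keep, function(p) min(p[, 1]), numeric(1)),
               vapply(keep, function(p) min(p[, 2]), numeric(1)))
  keep <- keep[ord]
  lapply(seq_along(keep), function(i) {
    structure(list(label = i, pixels = keep[[i]],
                   pixel_size_um = pixel_size_um),
              class = "cell_mask")
  })
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels touching
# only diagonally are merged through the label adjacency graph.
.label8 <- function(bw) {
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- matrix(as.integer(lab), nrow = nrow(bw))
  nmax <- max(lab)
  if (nmax <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # (r,c) vs (r+1,c+1)
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # (r+1,c) vs (r,c+1)
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  g <- igraph::graph_from_edgelist(apply(unique(pairs), 2, as.character),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(nmax)),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  map <- integer(nmax)
  map[as.integer(names(comp))] <- comp
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

# principal axes of a pixel set: list(center, major, minor) unit vectors in
# (row, col) coordinates
.principal_axes <- function(pixels) {
  cv <- stats::cov(pixels)
  eig <- eigen(cv, symmetric = TRUE)
  list(center = colMeans(pixels),
       major = eig$vectors[, 1],
       minor = eig$vectors[, 2],
       var = eig$values)
}

#' Measure a single cell
#'
#' Principal axes from the second moments of the mask pixel coordinates;
#' length and width are the full extents of the pixel projections onto the
#' major and minor axes (projection span plus one pixel footprint) scaled by
#' pixel size, with length assigned to the larger extent. Total fluorescence
#' is the background-subtracted sum over the mask (each pixel clipped at 0).
#' Volume uses the rod model: cylinder of diameter w and height l - w with
#' hemispherical caps, falling back to a sphere of diameter w when l < w.
#'
#' @param mask A `cell_mask` (>= 5 pixels).
#' @param fluor_image Fluorescence matrix, same frame as the phase image.
#' @param background Scalar background level subtracted per pixel.
#' @return An object of class `cell_geometry`: `label`, `length_um`,
#'   `width_um`, `area_um2`, `volume_um3`, `total_fluor`, `concentration`,
#'   plus the fitted `axes`.
#' @export
measure_cell <- function(mask, fluor_image, background = 0) {
  stopifnot(inherits(mask, "cell_mask"))
  px <- mask$pixels
  if (nrow(px) < 5) stop("mask has fewer than 5 pixels")
  ps <- mask$pixel_size_um
  ax <- .principal_axes(px)
  ext <- function(v) diff(range(px %*% v)) + 1
  e1 <- ext(ax$major); e2 <- ext(ax$minor)
  len <- max(e1, e2) * ps
  wid <- min(e1, e2) * ps
  f <- fluor_image[px]
  total <- sum(pmax(f - background, 0))
  vol <- rod_volume(len, wid)
  structure(
    list(label = mask$label, length_um = len, width_um = wid,
         area_um2 = nrow(px) * ps^2, volume_um3 = vol,
         total_fluor = total, concentration = total / vol,
         axes = ax, n_px = nrow(px)),
    class = "cell_geometry"
  )
}

#' Rod-model cell volume
#'
#' Cylinder with hemispherical caps: `pi (w/2)^2 (l - w) + (4/3) pi (w/2)^3`
#' for `l >= w`, else a sphere of diameter `w`.
#'
#' @param length_um,width_um Cell length and width in micrometres.
#' @return Volume in cubic micrometres.
#' @export
rod_volume <- function(length_um, width_um) {
  r <- width_um / 2
  ifelse(length_um >= width_um,
         pi * r^2 * (length_um - width_um) + 4 / 3 * pi * r^3,
         4 / 3 * pi * r^3)
}

#' Normalized-axis fluorescence profile of a cell
#'
#' Projects each mask pixel onto the chosen principal axis, min-max
#' normalizes the coordinate to \[0, 1\], bins it, sums background-subtracted
#' fluorescence per bin, and normalizes the profile to unit sum. The axis is
#' oriented deterministically: the end with the lower mean image row is
#' position 0 (ties broken by column).
#'
#' @param mask A `cell_mask`.
#' @param fluor_image Fluorescence matrix.
#' @param background Scalar background level.
#' @param axis `"long"` (major principal axis) or `"short"` (minor).
#' @param n_bins Number of bins (default 100).
#' @return An object of class `axis_profile`: `axis`, `n_bins`, `positions`
#'   (bin centers), `values` (unit-sum).
#' @export
axis_profile <- function(mask, fluor_image, background = 0,
                         axis = c("long", "short"), n_bins = 100) {
  axis <- match.arg(axis)
  stopifnot(inherits(mask, "cell_mask"))
  px <- mask$pixels
  if (nrow(px) < 5) stop("mask has fewer than 5 pixels")
  ax <- .principal_axes(px)
  v <- if (axis == "long") ax$major else ax$minor
  proj <- as.numeric(px %*% v)
  rng <- range(proj)
  if (diff(rng) == 0) stop("degenerate axis: zero variance along projection")
  t <- (proj - rng[1]) / diff(rng)
  # orient: position 0 at the end with the lower mean row (then column)
  s <- sum((t - mean(t)) * (px[, 1] - mean(px[, 1])))
  if (s == 0) s <- sum((t - mean(t)) * (px[, 2] - mean(px[, 2])))
  if (s < 0) t <- 1 - t
  bins <- pmin(floor(t * n_bins) + 1L, n_bins)
  f <- pmax(fluor_image[px] - background, 0)
  vals <- numeric(n_bins)
  agg <- rowsum(f, bins)
  vals[as.integer(rownames(agg))] <- agg[, 1]
  total <- sum(vals)
  if (total <= 0) stop("no fluorescence signal above background in mask")
  structure(
    list(axis = axis, n_bins = n_bins,
         positions = (seq_len(n_bins) - 0.5) / n_bins,
         values = vals / total),
    class = "axis_profile"
  )
}

#' @export
plot.axis_profile <- function(x, ...) {
  graphics::plot(x$positions, x$values, type = "l",
                 xlab = sprintf("normalized %s axis", x$axis),
                 ylab = "normalized fluorescence", ...)
  invisible(x)
}

#' Group sizes for a fractional population split
#'
#' Converts group fractions into integer group sizes for a population of `n`
#' cells: each size is the half-up rounding of its quota `fraction * n`, and
#' the final group absorbs the rounding residual so the sizes total `n`.
#'
#' @param n Population size.
#' @param fractions Positive fractions summing to 1 (within 1e-9).
#' @return Integer vector of group sizes summing to `n`.
#' @examples
#' group_sizes(1258, c(0.6, 0.2, 0.1, 0.1))
#' @export
group_sizes <- function(n, fractions) {
  if (any(fractions <= 0)) stop("fractions must be > 0")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (length(fractions) > n) stop("more groups than cells")
  k <- length(fractions)
  sizes <- floor(fractions * n + 0.5)
  sizes[k] <- n - sum(sizes[-k])
  if (any(sizes < 1))
    stop("fractions produce an empty group for this population size")
  as.integer(sizes)
}

#' Group cells and average their axis profiles
#'
#' Sorts cells ascending by the sort key (width or area), splits them into
#' consecutive groups sized by [group_sizes()], and averages the member
#' profiles per group (arithmetic mean, renormalized to unit sum). Groups are
#' ordered thinnest/smallest first.
#'
#' @param cells List of `cell_geometry` objects.
#' @param profiles List of `axis_profile` objects, parallel to `cells`.
#' @param sort_key `"width"` or `"area"`.
#' @param fractions Group fractions (positive, sum 1).
#' @return An object of class `grouped_profiles`: `sort_key`, `fractions`,
#'   and `groups`, each with `n_cells`, `key_range`, `profile`.
#' @export
group_cells <- function(cells, profiles, sort_key = c("width", "area"),
                        fractions = c(0.6, 0.2, 0.1, 0.1)) {
  sort_key <- match.arg(sort_key)
  if (length(cells) == 0) stop("no cells to group")
  stopifnot(length(cells) == length(profiles))
  key <- vapply(cells, function(g)
    if (sort_key == "width") g$width_um else g$area_um2, numeric(1))
  sizes <- group_sizes(length(cells), fractions)
  ord <- order(key)
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  groups <- lapply(seq_along(sizes), function(gi) {
    members <- ord[starts[gi]:ends[gi]]
    vals <- colMeans(do.call(rbind,
      lapply(profiles[members], function(p) p$values)))
    vals <- vals / sum(vals)
    list(n_cells = sizes[gi],
         key_range = range(key[members]),
         profile = structure(
           list(axis = profiles[[members[1]]]$axis,
                n_bins = profiles[[members[1]]]$n_bins,
                positions = profiles[[members[1]]]$positions,
                values = vals),
           class = "axis_profile"))
  })
  structure(list(sort_key = sort_key, fractions = fractions, groups = groups),
            class = "grouped_profiles")
}

#' @export
print.grouped_profiles <- function(x, ...) {
  cat(sprintf("Grouped profiles by %s (%d groups):\n", x$sort_key,
              length(x$groups)))
  for (i in seq_along(x$groups)) {
    g <- x$groups[[i]]
    cat(sprintf("  group %d: %d cells, %s %.3f-%.3f\n", i, g$n_cells,
                x$sort_key, g$key_range[1], g$key_range[2]))
  }
  invisible(x)
}

#' @export
plot.grouped_profiles <- function(x, ...) {
  k <- length(x$groups)
  old <- graphics::par(mfrow = c(k, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(k)) {
    g <- x$groups[[i]]
    plot(g$profile,
         main = sprintf("group %d (n = %d)", i, g$n_cells), ...)
  }
  invisible(x)
}

#' Total-fluorescence-versus-width regression
#'
#' Ordinary least squares of total cell fluorescence on cell width, with the
#' Pearson correlation — the check that fluorescence rises linearly as these
#' cells widen through their division cycle.
#'
#' @param cells List of `cell_geometry` objects (>= 3, non-zero width
#'   variance).
#' @return A `linear_fit` list: `slope`, `intercept`, `pearson_r`, `n`.
#' @export
fluor_vs_width_fit <- function(cells) {
  if (length(cells) < 3) stop("at least 3 cells are required")
  w <- vapply(cells, `[[`, numeric(1), "width_um")
  f <- vapply(cells, `[[`, numeric(1), "total_fluor")
  if (stats::var(w) == 0) stop("zero variance in cell width")
  linearity_check(data.frame(amount = w, intensity = f))
}

#' Count prominent peaks in an axis profile
#'
#' Smooths the profile with a 3-bin moving average, finds local maxima
#' (plateaus count once; profile ends may be maxima), computes each maximum's
#' topographic prominence, and counts those with prominence at least
#' `min_prominence` times the smoothed maximum. An exactly flat profile has
#' no local maxima and returns 0.
#'
#' @param profile An `axis_profile`.
#' @param min_prominence Prominence threshold as a fraction of the smoothed
#'   profile maximum (default 0.2).
#' @return Integer peak count.
#' @export
count_profile_peaks <- function(profile, min_prominence = 0.2) {
  stopifnot(inherits(profile, "axis_profile"))
  v <- profile$values
  n <- length(v)
  vs <- vapply(seq_len(n), function(i)
    mean(v[max(1, i - 1):min(n, i + 1)]), numeric(1))
  r <- rle(vs)
  k <- length(r$values)
  if (k == 1) return(0L)
  thr <- min_prominence * max(vs)
  count <- 0L
  for (j in seq_len(k)) {
    h <- r$values[j]
    left_ok <- j == 1 || h > r$values[j - 1]
    right_ok <- j == k || h > r$values[j + 1]
    if (!(left_ok && right_ok)) next
    base <- function(side) {
      idx <- if (side < 0) rev(seq_len(j - 1)) else
        if (j < k) (j + 1):k else integer(0)
      if (length(idx) == 0) return(NA_real_)
      m <- Inf
      for (jj in idx) {
        if (r$values[jj] > h) break
        m <- min(m, r$values[jj])
      }
      if (is.finite(m)) m else NA_real_
    }
    bases <- c(base(-1), base(1))
    prom <- h - max(bases, na.rm = TRUE)
    if (prom >= thr) count <- count + 1L
  }
  count
}

#' Background level from non-cell pixels
#'
#' Mode (kernel density peak) of the pixels outside all cell masks.
#'
#' @param image Fluorescence matrix.
#' @param masks List of `cell_mask` objects to exclude (may be empty).
#' @return Scalar background estimate.
#' @export
estimate_background <- function(image, masks = list()) {
  excl <- matrix(FALSE, nrow(image), ncol(image))
  for (m in masks) excl[m$pixels] <- TRUE
  pix <- image[!excl]
  if (length(unique(pix)) == 1) return(pix[1])
  d <- stats::density(pix)
  d$x[which.max(d$y)]
}

#' Analyze one phase/fluorescence image pair
#'
#' Convenience pipeline: segment the phase image, estimate (or accept) the
#' fluorescence background, measure every cell and compute its axis profile.
#'
#' @param phase_image,fluor_image Matched image matrices.
#' @param pixel_size_um Pixel size in micrometres.
#' @param min_area_px Minimum cell area in pixels.
#' @param background Scalar background; estimated from non-cell pixels when
#'   `NULL`.
#' @param n_bins Profile bins.
#' @param axis Profile axis, `"long"` or `"short"`.
#' @return List with `masks`, `background`, `cells` (geometries), `profiles`.
#' @export
analyze_image_pair <- function(phase_image, fluor_image, pixel_size_um,
                               min_area_px = 50, background = NULL,
                               n_bins = 100, axis = "long") {
  masks <- segment_cells(phase_image, pixel_size_um, min_area_px)
  if (is.null(background))
    background <- estimate_background(fluor_image, masks)
  cells <- lapply(masks, measure_cell, fluor_image = fluor_image,
                  background = background)
  profiles <- lapply(masks, axis_profile, fluor_image = fluor_image,
                     background = background, axis = axis, n_bins = n_bins)
  list(masks = masks, background = background, cells = cells,
       profiles = profiles)
}

#' Per-cell measurement table
#'
#' @param cells List of `cell_geometry` objects.
#' @return data.frame with one row per cell: `label`, `length_um`,
#'   `width_um`, `area_um2`, `volume_um3`, `total_fluor`, `concentration`.
#' @export
geometry_table <- function(cells) {
  do.call(rbind, lapply(cells, function(g)
    data.frame(label = g$label, length_um = g$length_um,
               width_um = g$width_um, area_um2 = g$area_um2,
               volume_um3 = g$volume_um3, total_fluor = g$total_fluor,
               concentration = g$concentration)))
}
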