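#' Centroided LC-MS run
#'
#' Container for a centroided acquisition: an ordered set of spectra (scans),
#' each a list of (m/z, intensity) centroids. Internally stored as flat
#' vectors with a scan index for fast extracted-ion-chromatogram queries.
#'
#' @param rt Retention time (minutes) of each centroid, or of each scan when
#'   `scan` is given.
#' @param mz m/z of each centroid (Da).
#' @param intensity Intensity of each centroid (arbitrary units, >= 0).
#' @param scan_rt Optional vector of all scan times; scans with no centroid
#'   are kept as empty spectra (they contribute zeros to every EIC).
#' @return An object of class `centroided_run` with fields `scan_rt` (strictly
#'   increasing scan times), `scan` (scan index per centroid), `mz`,
#'   `intensity`.
#' @export
centroided_run <- function(rt, mz, intensity, scan_rt = NULL) {
  stopifnot(length(rt) == length(mz), length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (is.null(scan_rt)) scan_rt <- sort(unique(rt))
  if (length(scan_rt) == 0) stop("empty run: no spectra")
  if (is.unsorted(scan_rt, strictly = TRUE))
    stop("scan retention times must be strictly increasing")
  scan <- match(rt, scan_rt)
  if (anyNA(scan)) stop("centroid retention times must appear in scan_rt")
  o <- order(scan, mz)
  structure(
    list(scan_rt = as.numeric(scan_rt), scan = scan[o],
         mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o]),
    class = "centroided_run"
  )
}

#' @export
print.centroided_run <- function(x, ...) {
  cat(sprintf("Centroided run: %d spectra over %.2f-%.2f min, %d centroids\n",
              length(x$scan_rt), min(x$scan_rt), max(x$scan_rt), length(x$mz)))
  invisible(x)
}

#' Read a peak table CSV as a centroided run
#'
#' Expects columns `rt_min`, `mz`, `intensity`; rows sharing an `rt_min` value
#' form one spectrum.
#'
#' @param path CSV file path.
#' @return A [centroided_run()].
#' @export
read_peak_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("rt_min", "mz", "intensity")
  if (!all(needed %in% names(tab)))
    stop("peak table must have columns rt_min, mz, intensity")
  centroided_run(tab$rt_min, tab$mz, tab$intensity)
}

#' Read a centroided mzML file
#'
#' Thin reader over the mzR backend. Profile-mode files are rejected (this
#' package does not centroid internally); a file is considered profile-mode
#' when its header flags say so or when spectra are implausibly dense.
#'
#' @param path mzML file path.
#' @return A [centroided_run()].
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package; use read_peak_table() for CSV input")
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1)
  if (length(ms1) == 0) stop("no MS1 spectra in file")
  if ("centroided" %in% names(hdr) && any(!is.na(hdr$centroided[ms1])) &&
      !all(hdr$centroided[ms1], na.rm = TRUE))
    stop("profile-mode spectra detected; supply centroided data")
  pk <- mzR::peaks(handle, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  rt_min <- hdr$retentionTime[ms1] / 60  # mzR reports seconds
  n <- vapply(pk, nrow, integer(1))
  centroided_run(rep(rt_min, n),
                 unlist(lapply(pk, function(m) m[, 1])),
                 unlist(lapply(pk, function(m) m[, 2])),
                 scan_rt = rt_min)
}

#' Extract an ion chromatogram
#'
#' For each spectrum, sums the intensities of all centroids whose m/z lies
#' within `target_mz * (1 +/- tolerance_ppm * 1e-6)`; spectra with no matching
#' centroid contribute zero.
#'
#' @param run A [centroided_run()].
#' @param target_mz Target m/z (Da).
#' @param tolerance_ppm Half-width of the extraction window in ppm (> 0).
#' @return An object of class `eic_trace`: fields `target_mz`,
#'   `tolerance_ppm`, `rt`, `intensity` (one sample per spectrum).
#' @export
extract_eic <- function(run, target_mz, tolerance_ppm = 10) {
  stopifnot(inherits(run, "centroided_run"))
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  lo <- target_mz * (1 - tolerance_ppm * 1e-6)
  hi <- target_mz * (1 + tolerance_ppm * 1e-6)
  sel <- run$mz >= lo & run$mz <= hi
  inten <- numeric(length(run$scan_rt))
  if (any(sel)) {
    s <- rowsum(run$intensity[sel], run$scan[sel])
    inten[as.integer(rownames(s))] <- s[, 1]
  }
  structure(
    list(target_mz = target_mz, tolerance_ppm = tolerance_ppm,
         rt = run$scan_rt, intensity = inten),
    class = "eic_trace"
  )
}

#' Integrate an EIC peak
#'
#' Trapezoidal integral of the trace over the retention-time window after
#' subtracting a baseline equal to the minimum intensity inside the window.
#' A flat trace therefore integrates to zero.
#'
#' @param trace An [extract_eic()] result.
#' @param rt_window Numeric length-2 `(start, end)` in minutes, `start < end`.
#' @return Non-negative area (intensity x minutes).
#' @export
integrate_peak <- function(trace, rt_window) {
  stopifnot(inherits(trace, "eic_trace"), length(rt_window) == 2)
  if (rt_window[1] >= rt_window[2]) stop("rt_window start must precede end")
  if (rt_window[2] < min(trace$rt) || rt_window[1] > max(trace$rt))
    stop("rt_window lies outside the trace retention-time range")
  sel <- trace$rt >= rt_window[1] & trace$rt <= rt_window[2]
  if (sum(sel) < 2) return(0)
  y <- trace$intensity[sel] - min(trace$intensity[sel])
  max(pracma::trapz(trace$rt[sel], y), 0)
}

#' Match a run against a muropeptide library
#'
#' For each library species and each charge state z = 1..3, extracts the EIC
#' at the species m/z, locates the apex (global maximum; restricted to
#' `+/- rt_window_min` around the library retention time when one is
#' recorded), takes the contiguous region around the apex above 5% of the
#' apex intensity as the peak window, and integrates it. Per species the best
#' charge state by area is kept; identifications with area below `min_area`
#' are dropped, so each species yields at most one identification.
#'
#' @param run A [centroided_run()].
#' @param library A `muro_library` (see [build_library()]).
#' @param tolerance_ppm EIC window half-width in ppm.
#' @param min_area Minimum integrated area to keep an identification.
#' @param rt_window_min Half-width (minutes) of the retention-time search
#'   window, used only for species whose library `rt` is not `NA`.
#' @param boundary_frac Peak boundary threshold as a fraction of apex
#'   intensity.
#' @param max_gap_scans Number of consecutive sub-threshold scans the
#'   boundary walk may step over. Centroided traces have occasional
#'   single-scan dropouts (a centroid pushed just outside the m/z window by
#'   mass noise); without gap tolerance such holes would truncate the peak.
#' @return A data.frame of class `identification_table`: `name`, `charge`,
#'   `apex_rt`, `rt_start`, `rt_end`, `area`, `matched_mz`, `mass_error_ppm`.
#'   Zero identifications is a valid (empty) result.
#' @export
match_run <- function(run, library, tolerance_ppm = 10, min_area = 0,
                      rt_window_min = 0.5, boundary_frac = 0.05,
                      max_gap_scans = 2) {
  stopifnot(inherits(run, "centroided_run"))
  if (nrow(library) == 0) stop("library must be non-empty")
  out <- list()
  for (i in seq_len(nrow(library))) {
    best <- NULL
    for (z in 1:3) {
      target <- library[[paste0("mz_z", z)]][i]
      trace <- extract_eic(run, target, tolerance_ppm)
      look <- rep(TRUE, length(trace$rt))
      if (!is.na(library$rt[i]))
        look <- abs(trace$rt - library$rt[i]) <= rt_window_min
      if (!any(look) || all(trace$intensity[look] <= 0)) next
      apex <- which(look)[which.max(trace$intensity[look])]
      apex_int <- trace$intensity[apex]
      thr <- boundary_frac * apex_int
      n <- length(trace$intensity)
      expand <- function(step) {
        pos <- apex; gap <- 0; j <- apex + step
        while (j >= 1 && j <= n) {
          if (trace$intensity[j] >= thr) { pos <- j; gap <- 0 }
          else { gap <- gap + 1; if (gap > max_gap_scans) break }
          j <- j + step
        }
        pos
      }
      left <- expand(-1L)
      right <- expand(1L)
      if (right == left) next
      area <- integrate_peak(trace, c(trace$rt[left], trace$rt[right]))
      # closest centroid to the target in the apex scan, for the mass error
      in_scan <- run$scan == apex &
        abs(run$mz - target) <= target * tolerance_ppm * 1e-6
      matched_mz <- if (any(in_scan)) {
        mzs <- run$mz[in_scan]
        mzs[which.min(abs(mzs - target))]
      } else NA_real_
      cand <- data.frame(
        name = library$name[i], charge = z,
        apex_rt = trace$rt[apex],
        rt_start = trace$rt[left], rt_end = trace$rt[right],
        area = area, matched_mz = matched_mz,
        mass_error_ppm = if (is.na(matched_mz)) NA_real_ else
          (matched_mz - target) / target * 1e6,
        stringsAsFactors = FALSE
      )
      if (is.null(best) || cand$area > best$area) best <- cand
    }
    if (!is.null(best) && best$area >= min_area && best$area > 0)
      out[[length(out) + 1L]] <- best
  }
  ids <- if (length(out)) do.call(rbind, out) else
    data.frame(name = character(0), charge = integer(0), apex_rt = numeric(0),
               rt_start = numeric(0), rt_end = numeric(0), area = numeric(0),
               matched_mz = numeric(0), mass_error_ppm = numeric(0),
               stringsAsFactors = FALSE)
  rownames(ids) <- NULL
  class(ids) <- c("identification_table", "data.frame")
  ids
}

#' Normalize identifications to molar percentages
#'
#' Divides each integrated area by the total and scales to 100. Equimolar
#' detector response across muropeptides is assumed, so area fractions are
#' interpreted directly as molar fractions.
#'
#' @param identifications An [match_run()] result, or any data.frame with
#'   `name` and `area` columns.
#' @return A data.frame of class `quant_table` with columns `name`, `area`,
#'   `molar_percent`, sorted by name; percentages sum to 100.
#' @export
normalize_molar <- function(identifications) {
  if (!all(c("name", "area") %in% names(identifications)))
    stop("identifications must have 'name' and 'area' columns")
  if (nrow(identifications) == 0 || all(identifications$area <= 0))
    stop("no identification with positive area; cannot normalize")
  if (any(identifications$area < 0)) stop("areas must be >= 0")
  q <- data.frame(name = identifications$name,
                  area = identifications$area,
                  stringsAsFactors = FALSE)
  q$molar_percent <- 100 * q$area / sum(q$area)
  q <- q[order(q$name), , drop = FALSE]
  rownames(q) <- NULL
  class(q) <- c("quant_table", "data.frame")
  q
}

#' Assemble a quant table directly from molar percentages
#'
#' Convenience constructor used when abundances are known (e.g. from a
#' published composition table or a simulation) rather than measured.
#'
#' @param name Species names.
#' @param molar_percent Molar percentages (will be renormalized to sum 100).
#' @return A `quant_table`.
#' @export
quant_table <- function(name, molar_percent) {
  if (any(molar_percent < 0)) stop("molar percentages must be >= 0")
  normalize_molar(data.frame(name = name, area = molar_percent,
                             stringsAsFactors = FALSE))
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("Quant table: %d species, molar percentages sum to %.4f\n",
              nrow(x), sum(x$molar_percent)))
  print.data.frame(as.data.frame(x), digits = 6)
  invisible(x)
}
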