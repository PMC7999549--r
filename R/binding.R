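#' Relative Bocillin-FL binding curve
#'
#' Normalizes gel-densitometry lane intensities of one antibiotic titration to
#' the untreated (zero-concentration) control of each replicate, then averages
#' across replicates. The relative binding at concentration zero is 1 by
#' construction. Standard deviations use denominator n - 1; with a single
#' replicate the sd is reported as 0 and flagged.
#'
#' @param lanes A data.frame with columns `antibiotic`, `concentration`,
#'   `replicate`, `intensity` (one zero-concentration control lane per
#'   replicate; intensities >= 0). An optional `unit` column is carried
#'   through.
#' @return An object of class `titration_result`: fields `antibiotic`, `unit`,
#'   `curve` (data.frame `concentration`, `mean_rel`, `sd`, `n_rep`) and
#'   `single_replicate` flag. Classification and IC50 fields are filled by
#'   [classify_response()] / [ic50_interpolate()] or by the [titrate()]
#'   wrapper.
#' @export
relative_binding <- function(lanes) {
  needed <- c("antibiotic", "concentration", "replicate", "intensity")
  if (!all(needed %in% names(lanes)))
    stop("lanes must have columns: ", paste(needed, collapse = ", "))
  if (length(unique(lanes$antibiotic)) != 1)
    stop("relative_binding expects lanes of a single antibiotic; see titrate()")
  if (any(lanes$intensity < 0)) stop("intensities must be >= 0")
  if (any(lanes$concentration < 0)) stop("concentrations must be >= 0")

  reps <- sort(unique(lanes$replicate))
  rel <- lapply(reps, function(r) {
    sub <- lanes[lanes$replicate == r, ]
    ctrl <- sub$intensity[sub$concentration == 0]
    if (length(ctrl) != 1)
      stop(sprintf("replicate %s needs exactly one zero-concentration control lane", r))
    if (ctrl <= 0) stop("control lane intensity must be > 0")
    data.frame(concentration = sub$concentration,
               rel = sub$intensity / ctrl)
  })
  rel <- do.call(rbind, rel)
  concs <- sort(unique(rel$concentration))
  curve <- do.call(rbind, lapply(concs, function(cc) {
    v <- rel$rel[rel$concentration == cc]
    data.frame(concentration = cc,
               mean_rel = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n_rep = length(v))
  }))
  structure(
    list(antibiotic = lanes$antibiotic[1],
         unit = if ("unit" %in% names(lanes)) lanes$unit[1] else NA_character_,
         curve = curve,
         single_replicate = length(reps) == 1,
         response_class = NA_character_,
         ic50 = NA_real_),
    class = "titration_result"
  )
}

#' Classify a titration response
#'
#' `enhancement` if the mean relative binding at the highest concentration is
#' at or above `enhancement_threshold` (the behaviour of beta-lactams that
#' improve Bocillin-FL labelling at high dose, consistent with an allosteric
#' binding site); otherwise `inhibition` if any mean relative binding falls to
#' `inhibition_threshold` or below; otherwise `weak`.
#'
#' @param tr A [relative_binding()] result.
#' @param inhibition_threshold Relative binding at or below which the compound
#'   is called inhibitory (default 0.5).
#' @param enhancement_threshold Relative binding at the top concentration at
#'   or above which the compound is called enhancing (default 1.2).
#' @return One of `"inhibition"`, `"weak"`, `"enhancement"`.
#' @export
classify_response <- function(tr, inhibition_threshold = 0.5,
                              enhancement_threshold = 1.2) {
  stopifnot(inherits(tr, "titration_result"))
  cv <- tr$curve[tr$curve$concentration > 0, ]
  if (nrow(cv) < 2)
    stop("classification needs at least 2 nonzero concentrations")
  cv <- cv[order(cv$concentration), ]
  if (cv$mean_rel[nrow(cv)] >= enhancement_threshold) return("enhancement")
  if (any(cv$mean_rel <= inhibition_threshold)) return("inhibition")
  "weak"
}

#' Interpolated IC50
#'
#' The smallest concentration at which the mean relative binding crosses 0.5,
#' located by linear interpolation on log-concentration between the two
#' bracketing measured points. Returns `NA` when the curve never reaches 0.5.
#' If the first nonzero concentration is already at or below 0.5, that
#' concentration is returned (an upper bound; no bracket exists on the log
#' scale).
#'
#' @param tr A [relative_binding()] result.
#' @param level Crossing level (default 0.5).
#' @return Concentration, or `NA_real_` if never crossed.
#' @export
ic50_interpolate <- function(tr, level = 0.5) {
  stopifnot(inherits(tr, "titration_result"))
  cv <- tr$curve[tr$curve$concentration > 0, ]
  cv <- cv[order(cv$concentration), ]
  if (nrow(cv) == 0) return(NA_real_)
  if (cv$mean_rel[1] <= level) return(cv$concentration[1])
  below <- which(cv$mean_rel <= level)
  if (length(below) == 0) return(NA_real_)
  j <- below[1]
  i <- j - 1
  lx <- log10(cv$concentration[c(i, j)])
  ly <- cv$mean_rel[c(i, j)]
  10^(lx[1] + (level - ly[1]) * (lx[2] - lx[1]) / (ly[2] - ly[1]))
}

#' Bocillin-FL / protein-amount linearity check
#'
#' Ordinary least squares of band intensity on protein amount, with the
#' Pearson correlation, used to verify that gel fluorescence responds
#' linearly to the amount of penicillin-binding protein loaded.
#'
#' @param points A data.frame with columns `amount` and `intensity`
#'   (>= 3 rows, non-zero variance in `amount`).
#' @return A list of class `linear_fit`: `slope`, `intercept`, `pearson_r`,
#'   `n`.
#' @export
linearity_check <- function(points) {
  if (!all(c("amount", "intensity") %in% names(points)))
    stop("points must have 'amount' and 'intensity' columns")
  if (nrow(points) < 3) stop("at least 3 points are required")
  if (stats::var(points$amount) == 0)
    stop("zero variance in protein amount")
  fit <- stats::lm(intensity ~ amount, data = points)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = if (stats::var(points$intensity) == 0) 0 else
           unname(stats::cor(points$amount, points$intensity)),
         n = nrow(points)),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): slope %.4g, intercept %.4g, Pearson r %.4f\n",
              x$n, x$slope, x$intercept, x$pearson_r))
  invisible(x)
}

#' Full titration analysis of a lane table
#'
#' Splits a lane table by antibiotic and runs [relative_binding()],
#' [classify_response()] and [ic50_interpolate()] on each.
#'
#' @param lanes Lane table (see [relative_binding()]), possibly covering
#'   several antibiotics.
#' @param ... Thresholds passed to [classify_response()].
#' @return A named list of `titration_result` objects with `response_class`
#'   and `ic50` filled in.
#' @export
titrate <- function(lanes, ...) {
  out <- lapply(split(lanes, lanes$antibiotic), function(sub) {
    tr <- relative_binding(sub)
    tr$response_class <- classify_response(tr, ...)
    tr$ic50 <- ic50_interpolate(tr)
    tr
  })
  out[order(names(out))]
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("Titration of %s%s\n", x$antibiotic,
              if (!is.na(x$unit)) sprintf(" (%s)", x$unit) else ""))
  if (!is.na(x$response_class))
    cat(sprintf("  response class: %s\n", x$response_class))
  if (!is.na(x$ic50)) cat(sprintf("  IC50 (interpolated): %.4g\n", x$ic50))
  if (x$single_replicate)
    cat("  note: single replicate; sd reported as 0\n")
  print.data.frame(x$curve, digits = 4)
  invisible(x)
}

#' @export
plot.titration_result <- function(x, ...) {
  cv <- x$curve[x$curve$concentration > 0, ]
  graphics::plot(cv$concentration, cv$mean_rel, log = "x", type = "b",
                 xlab = sprintf("concentration%s",
                                if (!is.na(x$unit)) sprintf(" (%s)", x$unit) else ""),
                 ylab = "relative Bocillin-FL binding",
                 main = x$antibiotic,
                 ylim = range(0, 1, cv$mean_rel + cv$sd), ...)
  graphics::arrows(cv$concentration, cv$mean_rel - cv$sd,
                   cv$concentration, cv$mean_rel + cv$sd,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
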