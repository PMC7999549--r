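# Synthetic-data generators with known ground truth. Every generator takes an
# explicit seed and is fully deterministic under it; ground-truth tables are
# returned alongside the data.

#' Generate a glycan strand population
#'
#' Strand lengths (disaccharide units) are drawn from a geometric distribution
#' with the given mean (support >= 1; memoryless chain termination is the
#' simplest model consistent with exactly one 1,6-anhydro terminus per
#' strand).
#'
#' @param n_strands Number of strands.
#' @param mean_length Mean strand length in disaccharide units (> 1).
#' @param seed Integer seed.
#' @return An object of class `strand_population`: `lengths`, `mean_length`,
#'   `seed`.
#' @examples
#' pop <- gen_strands(1000, 12.58, seed = 1)
#' mean(pop$lengths)
#' @export
gen_strands <- function(n_strands, mean_length, seed) {
  if (mean_length <= 1) stop("mean_length must be > 1")
  set.seed(seed)
  lengths <- stats::rgeom(n_strands, prob = 1 / mean_length) + 1L
  structure(list(lengths = lengths, mean_length = mean_length, seed = seed),
            class = "strand_population")
}

#' Digest a strand population into muropeptide species
#'
#' Muramidase digestion releases every disaccharide unit; units are assigned
#' to oligomer species (monomer to tetramer, all-tetrapeptide stems) by
#' drawing species orders from `oligomer_probs` until the unit pool is
#' exhausted (a final partial draw is downgraded to fit). The population's
#' anhydro termini (one per strand) are distributed uniformly over all units.
#' The realized species counts become the quant table; the ground truth
#' carries directly counted crosslinks per 100 species — the independent
#' oracle for the crosslink formula — plus anhydro percentages on both the
#' species and the unit basis.
#'
#' @param pop A [gen_strands()] population.
#' @param oligomer_probs Probabilities for orders 1-4, summing to 1.
#' @param seed Integer seed.
#' @return A list of class `digestion`: `quant` (a `quant_table` of realized
#'   molar percentages), `truth` (list: `crosslinks_per_100`,
#'   `anhydro_species_pct`, `anhydro_unit_pct`, `mean_strand_length`,
#'   `n_species`, `n_units`), `species` (count table).
#' @export
digest_strands <- function(pop, oligomer_probs = c(1, 0, 0, 0), seed = 1) {
  stopifnot(inherits(pop, "strand_population"))
  if (length(oligomer_probs) != 4 || any(oligomer_probs < 0) ||
      abs(sum(oligomer_probs) - 1) > 1e-9)
    stop("oligomer_probs must be 4 non-negative values summing to 1")
  set.seed(seed)
  U <- sum(pop$lengths)
  n_strands <- length(pop$lengths)

  draws <- sample.int(4L, U, replace = TRUE, prob = oligomer_probs)
  cum <- cumsum(draws)
  k <- findInterval(U, cum)
  orders <- draws[seq_len(k)]
  left <- U - (if (k > 0) cum[k] else 0L)
  if (left > 0) orders <- c(orders, left)  # downgraded final species

  species_of_unit <- rep(seq_along(orders), orders)
  anh_units <- sample.int(U, n_strands)
  anh_per_species <- integer(length(orders))
  tb <- table(species_of_unit[anh_units])
  anh_per_species[as.integer(names(tb))] <- as.integer(tb)

  key <- paste(orders, anh_per_species, sep = "_")
  counts <- table(key)
  parts <- strsplit(names(counts), "_", fixed = TRUE)
  ords <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  anhs <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  names_out <- vapply(seq_along(ords), function(i)
    .muro_name(muro_composition(rep(4L, ords[i]), n_anhydro = anhs[i])),
    character(1))

  sp <- data.frame(name = names_out, order = ords, n_anhydro = anhs,
                   count = as.integer(counts), stringsAsFactors = FALSE)
  N <- sum(sp$count)
  quant <- quant_table(sp$name, 100 * sp$count / N)
  truth <- list(
    crosslinks_per_100 = 100 * sum((sp$order - 1) * sp$count) / N,
    anhydro_species_pct = 100 * sum(sp$count[sp$n_anhydro >= 1]) / N,
    anhydro_unit_pct = 100 * n_strands / U,
    mean_strand_length = U / n_strands,
    n_species = N, n_units = U
  )
  structure(list(quant = quant, truth = truth, species = sp),
            class = "digestion")
}

#' Simulate a centroided LC-MS run from known molar percentages
#'
#' Renders one Gaussian elution peak per species at its assigned retention
#' time, sampled at a fixed scan interval. Each scan's centroid m/z is the
#' theoretical m/z perturbed multiplicatively by Normal ppm noise; the total
#' injected amount of each species is its molar percentage perturbed by a
#' Normal coefficient of variation. Optional uniform noise centroids can be
#' added.
#'
#' @param quant A `quant_table` of species and molar percentages.
#' @param library A `muro_library` containing every quant species.
#' @param ppm_noise_sd Centroid m/z noise (ppm standard deviation).
#' @param peak_cv Coefficient of variation of species amounts.
#' @param rt_assignment Named vector of retention times (minutes) per
#'   species; defaults to the library `rt` when present, else species are
#'   spread evenly over the run.
#' @param peak_sd_min Gaussian elution peak standard deviation (minutes).
#' @param scan_interval_min Scan spacing (minutes); default 0.25 s.
#' @param rt_range Run start/end (minutes).
#' @param charge Charge state rendered (1-3).
#' @param n_noise_peaks Number of random noise centroids over the whole run.
#' @param seed Integer seed.
#' @return A list of class `lcms_sim`: `run` (a [centroided_run()]),
#'   `library` (with `rt` filled in), `truth` (data.frame `name`, `rt`,
#'   `amount`).
#' @export
gen_lcms_run <- function(quant, library, ppm_noise_sd = 5, peak_cv = 0.05,
                         rt_assignment = NULL, peak_sd_min = 0.05,
                         scan_interval_min = 0.25 / 60, rt_range = c(0, 18),
                         charge = 1, n_noise_peaks = 0, seed = 1) {
  stopifnot(inherits(quant, "quant_table"))
  idx <- match(quant$name, library$name)
  if (anyNA(idx))
    stop("quant species missing from library: ",
         paste(quant$name[is.na(idx)], collapse = ", "))
  set.seed(seed)
  n_sp <- nrow(quant)
  rts <- if (!is.null(rt_assignment)) {
    unname(rt_assignment[quant$name])
  } else if (!all(is.na(library$rt[idx]))) {
    library$rt[idx]
  } else {
    seq(rt_range[1] + 1.5, rt_range[2] - 1.5, length.out = n_sp)
  }
  if (anyNA(rts)) stop("retention time missing for some species")
  gap <- if (n_sp > 1) min(diff(sort(rts))) else Inf
  if (gap < 4 * peak_sd_min)
    warning("assigned retention times closer than the peak width; peaks will overlap")

  scan_rt <- seq(rt_range[1], rt_range[2], by = scan_interval_min)
  mz_col <- paste0("mz_z", charge)
  rt_v <- list(); mz_v <- list(); in_v <- list()
  amounts <- numeric(n_sp)
  for (i in seq_len(n_sp)) {
    amounts[i] <- max(quant$molar_percent[i] * (1 + stats::rnorm(1) * peak_cv), 0)
    sel <- which(abs(scan_rt - rts[i]) <= 4 * peak_sd_min)
    if (length(sel) == 0 || amounts[i] == 0) next
    h <- amounts[i] * stats::dnorm(scan_rt[sel], rts[i], peak_sd_min)
    mz0 <- library[[mz_col]][idx[i]]
    mzs <- mz0 * (1 + stats::rnorm(length(sel)) * ppm_noise_sd * 1e-6)
    rt_v[[i]] <- scan_rt[sel]; mz_v[[i]] <- mzs; in_v[[i]] <- h
  }
  if (n_noise_peaks > 0) {
    j <- length(rt_v) + 1L
    rt_v[[j]] <- sample(scan_rt, n_noise_peaks, replace = TRUE)
    mz_v[[j]] <- stats::runif(n_noise_peaks, 300, 2000)
    in_v[[j]] <- stats::rexp(n_noise_peaks, 1)
  }
  run <- centroided_run(unlist(rt_v), unlist(mz_v), unlist(in_v),
                        scan_rt = scan_rt)
  lib_out <- library
  lib_out$rt[idx] <- rts
  structure(
    list(run = run, library = lib_out,
         truth = data.frame(name = quant$name, rt = rts, amount = amounts,
                            stringsAsFactors = FALSE)),
    class = "lcms_sim"
  )
}

#' Simulate an antibiotic titration lane table
#'
#' Inhibitory compounds follow `1 / (1 + (c / ic50)^hill)`; enhancing
#' compounds follow `1 + amplitude * c / (c + half_max_conc)` (saturating
#' binding improvement, the behaviour seen for some beta-lactams at high
#' dose). Noise is multiplicative on each treated lane; one
#' zero-concentration control lane per replicate is included.
#'
#' @param antibiotic Compound name.
#' @param ic50 Half-inhibition concentration (inhibitory mode; > 0).
#' @param hill Hill coefficient of the inhibition curve.
#' @param enhancement Logical; simulate a binding-enhancement response.
#' @param amplitude Saturating fractional increase for enhancement mode.
#' @param half_max_conc Half-saturation concentration of the enhancement term
#'   (defaults to `ic50`).
#' @param concentrations Nonzero concentrations tested (default 7 points over
#'   4 decades).
#' @param replicates Number of replicates.
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param control_intensity Mean control band intensity (a.u.).
#' @param seed Integer seed.
#' @return A list of class `titration_sim`: `lanes` (data.frame `antibiotic`,
#'   `concentration`, `replicate`, `intensity`), `truth` (list with the
#'   generating parameters and the noiseless relative curve).
#' @export
gen_titration <- function(antibiotic = "compound", ic50 = 1, hill = 1,
                          enhancement = FALSE, amplitude = 0.5,
                          half_max_conc = ic50,
                          concentrations = 10^seq(-2, 2, length.out = 7),
                          replicates = 2, noise_cv = 0.05,
                          control_intensity = 1000, seed = 1) {
  if (!enhancement && ic50 <= 0) stop("ic50 must be > 0 for inhibitory curves")
  set.seed(seed)
  rel <- if (enhancement) {
    function(cc) 1 + amplitude * cc / (cc + half_max_conc)
  } else {
    function(cc) 1 / (1 + (cc / ic50)^hill)
  }
  rows <- list()
  for (r in seq_len(replicates)) {
    ctrl <- control_intensity * (1 + stats::rnorm(1) * noise_cv)
    rows[[length(rows) + 1L]] <- data.frame(
      antibiotic = antibiotic, concentration = 0, replicate = r,
      intensity = ctrl, stringsAsFactors = FALSE)
    for (cc in concentrations) {
      rows[[length(rows) + 1L]] <- data.frame(
        antibiotic = antibiotic, concentration = cc, replicate = r,
        intensity = ctrl * rel(cc) * (1 + stats::rnorm(1) * noise_cv),
        stringsAsFactors = FALSE)
    }
  }
  lanes <- do.call(rbind, rows)
  lanes$intensity <- pmax(lanes$intensity, 0)
  structure(
    list(lanes = lanes,
         truth = list(antibiotic = antibiotic, ic50 = ic50, hill = hill,
                      enhancement = enhancement, amplitude = amplitude,
                      half_max_conc = half_max_conc,
                      relative = data.frame(concentration = concentrations,
                                            rel = rel(concentrations)))),
    class = "titration_sim"
  )
}
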