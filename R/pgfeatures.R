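#' Oligomer abundance set
#'
#' Holds the molar percentages of the four oligomer classes plus the molar
#' percentage of anhydro-containing species — the inputs to every
#' peptidoglycan summary statistic.
#'
#' @param monomers,dimers,trimers,tetramers Molar percentages by oligomer
#'   order; must be non-negative and sum to 100 within `tol`.
#' @param anhydro Molar percentage of species carrying at least one
#'   1,6-anhydro-MurNAc terminus.
#' @param tol Tolerance on the oligomer percentage sum (default 0.05,
#'   accommodating rounded published inputs).
#' @return An object of class `oligomer_abundance`.
#' @examples
#' oligomer_abundance(45.16, 43.29, 10.54, 1.01, anhydro = 7.95)
#' @export
oligomer_abundance <- function(monomers, dimers, trimers, tetramers,
                               anhydro = NA_real_, tol = 0.05) {
  vals <- c(monomers, dimers, trimers, tetramers)
  if (any(vals < 0)) stop("oligomer percentages must be >= 0")
  if (!is.na(anhydro) && anhydro < 0) stop("anhydro percentage must be >= 0")
  total <- sum(vals)
  if (abs(total - 100) > tol)
    stop(sprintf("oligomer percentages sum to %.4f, not 100 within %.2f", total, tol))
  structure(
    list(monomers_pct = monomers, dimers_pct = dimers, trimers_pct = trimers,
         tetramers_pct = tetramers, anhydro_pct = anhydro),
    class = "oligomer_abundance"
  )
}

#' @export
print.oligomer_abundance <- function(x, ...) {
  cat("Oligomer molar percentages:\n")
  cat(sprintf("  monomers %8.2f\n  dimers   %8.2f\n  trimers  %8.2f\n  tetramers%8.2f\n",
              x$monomers_pct, x$dimers_pct, x$trimers_pct, x$tetramers_pct))
  if (!is.na(x$anhydro_pct))
    cat(sprintf("  anhydro species %.2f\n", x$anhydro_pct))
  invisible(x)
}

#' Aggregate a quant table into oligomer percentages
#'
#' Each oligomer percentage is the sum of molar percentages over species of
#' that order; the anhydro percentage is the sum over species carrying at
#' least one anhydro terminus, each such species counted once regardless of
#' how many anhydro termini it has (set `count_termini = TRUE` to weight by
#' the terminus count instead).
#'
#' @param quant A `quant_table`.
#' @param library A `muro_library` resolving each species name to its oligomer
#'   order and anhydro status.
#' @param count_termini Weight anhydro species by their number of anhydro
#'   termini rather than counting each species once.
#' @param tol Passed to [oligomer_abundance()].
#' @return An [oligomer_abundance()].
#' @export
oligomer_percentages <- function(quant, library, count_termini = FALSE,
                                 tol = 0.05) {
  stopifnot(inherits(quant, "quant_table"))
  idx <- match(quant$name, library$name)
  if (anyNA(idx))
    stop("species not in library: ",
         paste(quant$name[is.na(idx)], collapse = ", "))
  ord <- library$order[idx]
  anh <- library$n_anhydro[idx]
  by_order <- vapply(1:4, function(o) sum(quant$molar_percent[ord == o]),
                     numeric(1))
  anhydro <- if (count_termini) sum(quant$molar_percent * anh) else
    sum(quant$molar_percent[anh >= 1])
  oligomer_abundance(by_order[1], by_order[2], by_order[3], by_order[4],
                     anhydro = anhydro, tol = tol)
}

#' Overall crosslink percentage
#'
#' Crosslinked bonds per 100 muropeptide species:
#' `dimers + 2 * trimers + 3 * tetramers` (a linear n-mer carries n - 1
#' crosslinks). No conversion to a crosslinked-peptide fraction is applied.
#'
#' @param ab An [oligomer_abundance()].
#' @return Crosslink percentage.
#' @examples
#' crosslink_percentage(oligomer_abundance(45.16, 43.29, 10.54, 1.01))
#' @export
crosslink_percentage <- function(ab) {
  stopifnot(inherits(ab, "oligomer_abundance"))
  ab$dimers_pct + 2 * ab$trimers_pct + 3 * ab$tetramers_pct
}

#' Mean glycan chain length
#'
#' `100 / anhydro_pct` disaccharide units: every glycan strand terminates in
#' exactly one 1,6-anhydro-MurNAc, so the molar percentage of anhydro
#' muropeptides is the reciprocal of the mean number of disaccharide units
#' per strand.
#'
#' @param anhydro_pct Molar percentage of anhydro muropeptides (> 0).
#' @return Mean chain length in disaccharide units.
#' @examples
#' mean_chain_length(7.95)
#' @export
mean_chain_length <- function(anhydro_pct) {
  if (!is.numeric(anhydro_pct) || is.na(anhydro_pct) || anhydro_pct <= 0)
    stop("chain length is undefined for anhydro percentage <= 0")
  100 / anhydro_pct
}

#' Peptidoglycan feature summary
#'
#' Computes the full summary statistic set from either an
#' [oligomer_abundance()] or a `quant_table` plus library: oligomer
#' percentages, overall crosslink percentage, higher-order percentage
#' (trimers + tetramers), and mean glycan chain length.
#'
#' @param x An `oligomer_abundance` or a `quant_table`.
#' @param ... Passed on to methods; for `quant_table` input, `library` (a
#'   `muro_library`) is required and `count_termini`/`tol` are honoured.
#' @return An object of class `pg_summary` with fields `abundance`,
#'   `crosslink_pct`, `higher_order_pct`, `chain_length`.
#' @examples
#' pg_summary(oligomer_abundance(45.16, 43.29, 10.54, 1.01, anhydro = 7.95))
#' @export
pg_summary <- function(x, ...) UseMethod("pg_summary")

#' @rdname pg_summary
#' @export
pg_summary.oligomer_abundance <- function(x, ...) {
  structure(
    list(abundance = x,
         crosslink_pct = crosslink_percentage(x),
         higher_order_pct = x$trimers_pct + x$tetramers_pct,
         chain_length = if (is.na(x$anhydro_pct) || x$anhydro_pct <= 0)
           NA_real_ else mean_chain_length(x$anhydro_pct)),
    class = "pg_summary"
  )
}

#' @rdname pg_summary
#' @export
pg_summary.quant_table <- function(x, library, ...) {
  pg_summary(oligomer_percentages(x, library, ...))
}

#' Half-up rounding
#'
#' Report-style rounding (0.5 always rounds away from zero), as used for the
#' two-decimal composition tables; R's own `round()` is round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.pg_summary <- function(x, digits = 2, ...) {
  ab <- x$abundance
  cat("Peptidoglycan composition summary (molar %):\n")
  rows <- c(Monomers = ab$monomers_pct, Dimers = ab$dimers_pct,
            Trimers = ab$trimers_pct, Tetramers = ab$tetramers_pct,
            Crosslinks = x$crosslink_pct,
            `Anhydro muropeptide` = ab$anhydro_pct)
  for (nm in names(rows))
    cat(sprintf("  %-20s %8.*f\n", nm, digits, round_half_up(rows[[nm]], digits)))
  if (!is.na(x$chain_length))
    cat(sprintf("  %-20s %8.*f disaccharide units\n", "Chain length",
                digits, round_half_up(x$chain_length, digits)))
  invisible(x)
}

#' @export
as.data.frame.pg_summary <- function(x, ...) {
  ab <- x$abundance
  data.frame(
    feature = c("monomers_pct", "dimers_pct", "trimers_pct", "tetramers_pct",
                "crosslink_pct", "higher_order_pct", "anhydro_pct",
                "chain_length"),
    value = c(ab$monomers_pct, ab$dimers_pct, ab$trimers_pct, ab$tetramers_pct,
              x$crosslink_pct, x$higher_order_pct, ab$anhydro_pct,
              x$chain_length),
    stringsAsFactors = FALSE
  )
}

#' Read an oligomer abundance table from CSV
#'
#' Expects two columns, `feature` and `value`, with features `monomers`,
#' `dimers`, `trimers`, `tetramers` and optionally `anhydro` (case- and
#' punctuation-insensitive; "Anhydro muropeptide" is accepted).
#'
#' @param path CSV file path.
#' @param tol Passed to [oligomer_abundance()].
#' @return An [oligomer_abundance()].
#' @export
read_abundance <- function(path, tol = 0.05) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("feature", "value") %in% names(tab)))
    stop("abundance CSV must have 'feature' and 'value' columns")
  key <- tolower(gsub("[^a-z]", "", tolower(tab$feature)))
  pick <- function(what, required = TRUE) {
    i <- which(startsWith(key, what))
    if (length(i) == 0) {
      if (required) stop("abundance CSV is missing feature: ", what)
      return(NA_real_)
    }
    tab$value[i[1]]
  }
  oligomer_abundance(pick("monomer"), pick("dimer"), pick("trimer"),
                     pick("tetramer"), anhydro = pick("anhydro", FALSE),
                     tol = tol)
}
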