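#' Define a muropeptide composition
#'
#' A composition describes one theoretical muramidase digestion product: a
#' linear oligomer of 1-4 disaccharide-peptide subunits (monomer, dimer,
#' trimer, tetramer) joined by D,D (4-3) peptide crosslinks, with optional
#' 1,6-anhydro-MurNAc chain termini and optional borohydride reduction of the
#' free reducing ends.
#'
#' Invariants enforced: `n_crosslinks = n_subunits - 1` (linear oligomers
#' only), one GlcNAc and one MurNAc per subunit, `0 <= n_anhydro <=
#' n_subunits`, stem lengths in 2-5 residues. When `reduced = TRUE`, the
#' `n_subunits - n_anhydro` non-anhydro termini each gain 2 H; anhydro termini
#' carry no free reducing end and are never reduced.
#'
#' @param stem_lengths Integer vector, one entry per subunit, each in 2:5
#'   (di/tri/tetra/pentapeptide stems). Its length sets the oligomer order.
#' @param n_anhydro Number of 1,6-anhydro-MurNAc termini (0 to order).
#' @param reduced Logical; sodium-borohydride reduction of free reducing ends.
#' @return An object of class `muro_composition`.
#' @examples
#' muro_composition(c(4, 4), n_anhydro = 1)  # anhydro dimer of tetrapeptides
#' @export
muro_composition <- function(stem_lengths, n_anhydro = 0L, reduced = TRUE) {
  if (length(stem_lengths) == 0)
    stop("empty composition: at least one subunit is required")
  if (!all(stem_lengths %in% 2:5))
    stop("stem lengths must be in 2..5 (di- to pentapeptide)")
  n <- length(stem_lengths)
  if (n > 4)
    stop("oligomers beyond tetramers are not modeled")
  n_anhydro <- as.integer(n_anhydro)
  if (n_anhydro < 0 || n_anhydro > n)
    stop("n_anhydro must be between 0 and the number of subunits")
  structure(
    list(
      n_subunits   = n,
      stem_lengths = as.integer(stem_lengths),
      n_anhydro    = n_anhydro,
      n_crosslinks = n - 1L,
      reduced      = isTRUE(reduced)
    ),
    class = "muro_composition"
  )
}

#' Neutral monoisotopic mass of a muropeptide
#'
#' Sums condensed-residue masses over all glycan and amino-acid residues, adds
#' one water per subunit (each subunit is a complete condensation product),
#' removes one water per crosslink, removes one water per 1,6-anhydro terminus
#' (carried by the anhydro-MurNAc residue formula), and adds 2 H per reduced
#' free reducing end.
#'
#' @param composition A [muro_composition()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' m4 <- muro_composition(4)
#' neutral_mass(m4)
#' @export
neutral_mass <- function(composition) {
  stopifnot(inherits(composition, "muro_composition"))
  n <- composition$n_subunits
  res <- character(0)
  for (s in composition$stem_lengths)
    res <- c(res, "GlcNAc", "MurNAc", .stem_residues(s))
  # swap MurNAc -> anhMurNAc for the anhydro termini
  if (composition$n_anhydro > 0) {
    idx <- which(res == "MurNAc")[seq_len(composition$n_anhydro)]
    res[idx] <- "anhMurNAc"
  }
  mass <- sum(vapply(res, function(r) .formula_mass(.residue_formulas[[r]]),
                     numeric(1)))
  mass <- mass + n * WATER_MASS - composition$n_crosslinks * WATER_MASS
  if (composition$reduced) {
    n_red <- n - composition$n_anhydro
    mass <- mass + n_red * 2 * .atomic_mass[["H"]]
  }
  mass
}

#' m/z of a protonated species
#'
#' Positive-mode m/z for charge state `z`: `(neutral_mass + z * m_proton) / z`
#' with the proton mass taken as 1.007276 Da.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param z Charge state, a positive integer.
#' @return m/z in Da per unit charge.
#' @examples
#' mz_for_charge(1000, 1:3)
#' @export
mz_for_charge <- function(neutral_mass, z) {
  z <- as.integer(z)
  if (any(z < 1)) stop("charge must be a positive integer")
  (neutral_mass + z * PROTON_MASS) / z
}

# Canonical name: order letter (M/D/T/Q) + stem digits (descending) + one "N"
# per anhydro terminus. The naming scheme is a package convention.
.muro_name <- function(composition) {
  letter <- c("M", "D", "T", "Q")[composition$n_subunits]
  stems <- paste(sort(composition$stem_lengths, decreasing = TRUE), collapse = "")
  paste0(letter, stems, strrep("N", composition$n_anhydro))
}

#' Build a theoretical muropeptide library
#'
#' Enumerates every distinct composition in the cartesian product of oligomer
#' order (1 to `max_order`), multiset of stem lengths, and anhydro-terminus
#' count (0 to order when `allow_anhydro`), computes neutral masses and
#' charge-state m/z values (z = 1-3), and returns them as a library table.
#' This reconstructs the kind of in-house compound library that vendor
#' software uses for muropeptide identification; the exact species list of any
#' particular instrument library is not published, so the scope here (linear
#' D,D-crosslinked oligomers of canonical Gram-negative residues) is a
#' deliberate, documented reconstruction.
#'
#' @param max_order Highest oligomer order to enumerate (1-4).
#' @param stem_lengths Set of stem peptide lengths to combine (subset of 2:5).
#' @param allow_anhydro Include 1,6-anhydro-terminated variants.
#' @param reduced Treat free reducing ends as borohydride-reduced.
#' @return A data.frame of class `muro_library` with columns `name`, `order`,
#'   `stems` (comma-separated), `n_anhydro`, `reduced`, `neutral_mass`,
#'   `mz_z1`, `mz_z2`, `mz_z3`, `rt` (NA until assigned).
#' @examples
#' lib <- build_library(max_order = 2, stem_lengths = c(3, 4))
#' head(lib)
#' @export
build_library <- function(max_order = 4, stem_lengths = c(3, 4, 5),
                          allow_anhydro = TRUE, reduced = TRUE) {
  if (max_order < 1 || max_order > 4) stop("max_order must be in 1..4")
  if (length(stem_lengths) == 0) stop("stem_lengths must be non-empty")
  stem_lengths <- sort(unique(as.integer(stem_lengths)))
  if (!all(stem_lengths %in% 2:5)) stop("stem lengths must be in 2..5")

  rows <- list()
  for (ord in seq_len(max_order)) {
    # multisets of size ord from stem_lengths (combinations with repetition)
    combs <- .multisets(stem_lengths, ord)
    anh_max <- if (allow_anhydro) ord else 0L
    for (i in seq_len(nrow(combs))) {
      for (k in 0:anh_max) {
        comp <- muro_composition(combs[i, ], n_anhydro = k, reduced = reduced)
        mass <- neutral_mass(comp)
        rows[[length(rows) + 1L]] <- data.frame(
          name = .muro_name(comp),
          order = ord,
          stems = paste(sort(combs[i, ], decreasing = TRUE), collapse = ","),
          n_anhydro = k,
          reduced = comp$reduced,
          neutral_mass = mass,
          mz_z1 = mz_for_charge(mass, 1L),
          mz_z2 = mz_for_charge(mass, 2L),
          mz_z3 = mz_for_charge(mass, 3L),
          rt = NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  lib <- do.call(rbind, rows)
  lib <- lib[order(lib$name), , drop = FALSE]
  rownames(lib) <- NULL
  stopifnot(!anyDuplicated(lib$name))
  class(lib) <- c("muro_library", "data.frame")
  lib
}

# all multisets of size k from sorted vector v, as a matrix (one row each)
.multisets <- function(v, k) {
  if (k == 1) return(matrix(v, ncol = 1))
  sub <- .multisets(v, k - 1)
  out <- list()
  for (i in seq_along(v)) {
    keep <- sub[sub[, 1] >= v[i], , drop = FALSE]
    if (nrow(keep))
      out[[length(out) + 1L]] <- cbind(v[i], keep)
  }
  do.call(rbind, out)
}

#' @export
print.muro_library <- function(x, ...) {
  cat(sprintf("Muropeptide library: %d species (orders %s; %s; %s)\n",
              nrow(x), paste(sort(unique(x$order)), collapse = ","),
              if (any(x$n_anhydro > 0)) "with anhydro variants" else "no anhydro variants",
              if (all(x$reduced)) "reduced" else "non-reduced"))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Write / read a muropeptide library as CSV
#'
#' @param library A `muro_library`.
#' @param path File path.
#' @return `read_library` returns a `muro_library`; `write_library` returns
#'   `path` invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "muro_library"))
  utils::write.csv(as.data.frame(library), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "order", "stems", "n_anhydro", "neutral_mass",
              "mz_z1", "mz_z2", "mz_z3")
  if (!all(needed %in% names(lib)))
    stop("library CSV is missing columns: ",
         paste(setdiff(needed, names(lib)), collapse = ", "))
  if (!"rt" %in% names(lib)) lib$rt <- NA_real_
  if (!"reduced" %in% names(lib)) lib$reduced <- NA
  if (anyDuplicated(lib$name)) stop("duplicate species names in library")
  class(lib) <- c("muro_library", "data.frame")
  lib
}
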