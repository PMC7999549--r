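# Independent oracles, kept deliberately separate from the package internals.

# Elemental-formula mass oracle: assembles the FULL molecular formula of a
# muropeptide from free (unbound) building-block formulas and condensation
# bookkeeping, then converts to mass once. Atomic masses are NIST values
# entered independently of the package's table.
oracle_atomic <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196)

oracle_free_formulas <- list(
  GlcNAc = c(C = 8,  H = 15, N = 1, O = 6),
  MurNAc = c(C = 11, H = 19, N = 1, O = 8),
  Ala    = c(C = 3,  H = 7,  N = 1, O = 2),
  iGlu   = c(C = 5,  H = 9,  N = 1, O = 4),
  mDAP   = c(C = 7,  H = 14, N = 2, O = 4)
)

# stems: integer vector of stem lengths (one per subunit)
oracle_formula <- function(stems, n_anhydro = 0, reduced = TRUE) {
  stem_aa <- function(k) c("Ala", "iGlu", "mDAP", "Ala", "Ala")[seq_len(k)]
  total <- c(C = 0, H = 0, N = 0, O = 0)
  n_bonds <- 0
  for (s in stems) {
    for (res in c("GlcNAc", "MurNAc", stem_aa(s)))
      total <- total + oracle_free_formulas[[res]]
    n_bonds <- n_bonds + (s + 1)  # glycosidic + lactyl amide + peptide bonds
  }
  n_bonds <- n_bonds + (length(stems) - 1)  # crosslinks
  total <- total - n_bonds * c(C = 0, H = 2, N = 0, O = 1)
  total <- total - n_anhydro * c(C = 0, H = 2, N = 0, O = 1)  # 1,6-anhydro rings
  if (reduced)
    total <- total + (length(stems) - n_anhydro) * c(C = 0, H = 2, N = 0, O = 0)
  total
}

oracle_mass <- function(stems, n_anhydro = 0, reduced = TRUE) {
  f <- oracle_formula(stems, n_anhydro, reduced)
  sum(f * oracle_atomic[names(f)])
}

# brute-force count of distinct library compositions
oracle_library_count <- function(max_order, stems, allow_anhydro) {
  seen <- character(0)
  grids <- list()
  for (ord in seq_len(max_order)) {
    combos <- do.call(expand.grid, rep(list(stems), ord))
    for (i in seq_len(nrow(combos))) {
      key_stems <- paste(sort(as.numeric(combos[i, ])), collapse = ",")
      for (k in 0:(if (allow_anhydro) ord else 0)) {
        seen <- c(seen, paste(ord, key_stems, k, sep = "|"))
      }
    }
  }
  length(unique(seen))
}

# rebuild a muro_composition from a library row (for property tests)
composition_from_row <- function(row) {
  stems <- as.integer(strsplit(row$stems, ",", fixed = TRUE)[[1]])
  muro_composition(stems, n_anhydro = row$n_anhydro, reduced = row$reduced)
}

# simple capsule mask builder for geometry tests (axis-aligned rectangle)
make_rect_mask <- function(nrow_px, ncol_px, offset = c(10, 10),
                           pixel_size_um = 0.1, label = 1) {
  px <- as.matrix(expand.grid(row = offset[1] + seq_len(nrow_px) - 1,
                              col = offset[2] + seq_len(ncol_px) - 1))
  structure(list(label = label, pixels = px, pixel_size_um = pixel_size_um),
            class = "cell_mask")
}

# rotate a matrix 90 degrees clockwise
rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
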