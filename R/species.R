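#' Theoretical oxygen demand from elemental composition
#'
#' Computes the theoretical oxygen demand (ThOD) of a compound
#' \eqn{C_nH_mO_p} as \eqn{32 (n + m/4 - p/2)} g O2 per mole, the oxygen
#' required for complete oxidation to CO2 and H2O.  ThOD is the conversion
#' factor used throughout the package to express concentrations and rates on
#' a g COD basis, the common currency for substrates and fermentation
#' products.
#'
#' The arithmetic is carried out as `32*n_C + 8*n_H - 16*n_O`, a sum of
#' exact integer products, so registry constants are bit-stable.
#'
#' @param n_C,n_H,n_O Non-negative integer atom counts (vectorised,
#'   recycled to a common length).
#' @return ThOD in g COD/mol (g O2/mol), numeric.
#' @examples
#' thod(2, 6, 1)  # ethanol, 96
#' thod(8, 16, 2) # n-caprylate, 352
#' thod(0, 2, 0)  # hydrogen, 16
#' @export
thod <- function(n_C, n_H, n_O) {
  counts <- vctrs_recycle(n_C, n_H, n_O)
  n_C <- counts[[1]]; n_H <- counts[[2]]; n_O <- counts[[3]]
  if (any(is.na(n_C) | is.na(n_H) | is.na(n_O))) {
    stop("invalid composition: atom counts must not be NA", call. = FALSE)
  }
  if (any(n_C < 0 | n_H < 0 | n_O < 0)) {
    stop("invalid composition: atom counts must be non-negative", call. = FALSE)
  }
  if (any(n_C != round(n_C) | n_H != round(n_H) | n_O != round(n_O))) {
    stop("invalid composition: atom counts must be integers", call. = FALSE)
  }
  32 * n_C + 8 * n_H - 16 * n_O
}

# recycle scalars against vectors without pulling in vctrs
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x else rep_len(x, n)
  })
}

#' Default carboxylate and ethanol species registry
#'
#' One row per registered species: elemental composition, molar mass of the
#' free acid (or alcohol), ThOD-derived COD conversion factor, and the acid
#' dissociation constant.  The registry covers ethanol (the electron donor
#' for chain elongation) and the straight-chain C2-C8 carboxylates.
#' pKa values are literature values for the free acids at 25 degrees C with
#' no temperature or ionic-strength correction; ethanol carries none.
#' COD factors are identical for the dissociated carboxylate and the
#' undissociated acid (the oxygen demand of a proton is zero).
#'
#' @param path Optional path to a registry CSV with columns
#'   `name, n_C, n_H, n_O, molar_mass, pKa, carbon_number` to override the
#'   packaged default; `cod_factor` is always recomputed from composition.
#' @return A tibble with columns `name`, `n_C`, `n_H`, `n_O`, `molar_mass`
#'   (g/mol), `cod_factor` (g COD/mol), `pKa`, `carbon_number`.
#' @examples
#' species_registry()
#' @export
species_registry <- function(path = NULL) {
  if (is.null(path)) {
    reg <- tibble::tribble(
      ~name,           ~n_C, ~n_H, ~n_O, ~molar_mass, ~pKa, ~carbon_number,
      "ethanol",          2L,   6L,   1L,       46.07,   NA,             2L,
      "acetate",          2L,   4L,   2L,       60.05, 4.76,             2L,
      "propionate",       3L,   6L,   2L,       74.08, 4.87,             3L,
      "n-butyrate",       4L,   8L,   2L,       88.11, 4.82,             4L,
      "n-valerate",       5L,  10L,   2L,      102.13, 4.84,             5L,
      "n-caproate",       6L,  12L,   2L,      116.16, 4.88,             6L,
      "n-heptanoate",     7L,  14L,   2L,      130.18, 4.89,             7L,
      "n-caprylate",      8L,  16L,   2L,      144.21, 4.89,             8L
    )
  } else {
    reg <- readr::read_csv(path, show_col_types = FALSE)
    needed <- c("name", "n_C", "n_H", "n_O", "molar_mass", "pKa", "carbon_number")
    missing <- setdiff(needed, names(reg))
    if (length(missing) > 0) {
      stop("registry file is missing columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  reg$cod_factor <- thod(reg$n_C, reg$n_H, reg$n_O)
  bad_pka <- !is.na(reg$pKa) & (reg$pKa <= 3 | reg$pKa >= 6)
  if (any(bad_pka)) {
    stop("registry pKa outside (3, 6) for: ",
         paste(reg$name[bad_pka], collapse = ", "), call. = FALSE)
  }
  reg[, c("name", "n_C", "n_H", "n_O", "molar_mass", "cod_factor", "pKa",
          "carbon_number")]
}

# normalised alias -> canonical registry name
species_alias_table <- function() {
  alias <- c(
    ethanol = "ethanol", etoh = "ethanol",
    acetate = "acetate", aceticacid = "acetate", c2 = "acetate",
    propionate = "propionate", propionicacid = "propionate", c3 = "propionate",
    butyrate = "n-butyrate", nbutyrate = "n-butyrate",
    butyricacid = "n-butyrate", nbutyricacid = "n-butyrate", c4 = "n-butyrate",
    valerate = "n-valerate", nvalerate = "n-valerate",
    valericacid = "n-valerate", nvalericacid = "n-valerate",
    pentanoate = "n-valerate", c5 = "n-valerate",
    caproate = "n-caproate", ncaproate = "n-caproate",
    caproicacid = "n-caproate", ncaproicacid = "n-caproate",
    hexanoate = "n-caproate", nhexanoate = "n-caproate",
    hexanoicacid = "n-caproate", c6 = "n-caproate",
    heptanoate = "n-heptanoate", nheptanoate = "n-heptanoate",
    heptanoicacid = "n-heptanoate", nheptanoicacid = "n-heptanoate",
    enanthate = "n-heptanoate", c7 = "n-heptanoate",
    caprylate = "n-caprylate", ncaprylate = "n-caprylate",
    caprylicacid = "n-caprylate", ncaprylicacid = "n-caprylate",
    octanoate = "n-caprylate", noctanoate = "n-caprylate",
    octanoicacid = "n-caprylate", c8 = "n-caprylate"
  )
  stopifnot(!anyDuplicated(names(alias)))
  alias
}

normalize_species_name <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

#' Resolve a species name against the registry
#'
#' Lookup is case-insensitive and alias-tolerant: `"C8"`, `"n-caprylate"`,
#' `"caprylic acid"` and `"octanoate"` all resolve to the same registry row.
#'
#' @param species Character vector of species names or aliases.
#' @param registry A registry tibble, by default [species_registry()].
#' @return The matching registry rows, in the order requested.
#' @examples
#' lookup_species(c("C8", "n-caproic acid"))
#' @export
lookup_species <- function(species, registry = species_registry()) {
  key <- normalize_species_name(species)
  alias <- species_alias_table()
  canonical <- unname(alias[key])
  # names already canonical in a custom registry resolve directly
  direct <- match(key, normalize_species_name(registry$name))
  idx <- ifelse(!is.na(canonical), match(canonical, registry$name), direct)
  idx[is.na(idx)] <- direct[is.na(idx)]
  if (any(is.na(idx))) {
    stop("unknown species: ", paste(unique(species[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  registry[idx, ]
}

#' Convert a concentration to a COD basis
#'
#' @param concentration Non-negative concentration, in the given `unit`.
#' @param unit `"g_L"` (mass concentration) or `"mol_L"` (molarity).
#' @param species Species name or alias (see [lookup_species()]).
#' @param registry Species registry tibble.
#' @return Concentration in g COD/L.
#' @examples
#' to_cod(1.88, "mol_L", "ethanol")  # ~180.5 g COD/L
#' @export
to_cod <- function(concentration, unit = c("g_L", "mol_L"), species,
                   registry = species_registry()) {
  unit <- match.arg(unit)
  if (any(concentration < 0, na.rm = TRUE)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  sp <- lookup_species(species, registry)
  switch(unit,
    mol_L = concentration * sp$cod_factor,
    g_L   = concentration / sp$molar_mass * sp$cod_factor
  )
}

#' Convert a COD-basis concentration to molarity
#'
#' Inverse of [to_cod()] on the molar scale, returned in mmol/L as broth
#' concentrations are usually quoted.
#'
#' @inheritParams to_cod
#' @param concentration Concentration in g COD/L.
#' @return Concentration in mM.
#' @examples
#' from_cod(2.7, "n-caproate")   # 10.5 mM
#' from_cod(0.11, "n-caprylate") # 0.31 mM
#' @export
from_cod <- function(concentration, species, registry = species_registry()) {
  if (any(concentration < 0, na.rm = TRUE)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  sp <- lookup_species(species, registry)
  concentration / sp$cod_factor * 1000
}

#' Undissociated fraction of a weak acid at a given pH
#'
#' Henderson-Hasselbalch speciation: the fraction of a monoprotic acid in
#' its protonated (undissociated) form is \eqn{1 / (1 + 10^{pH - pKa})}.
#' Only the undissociated acid crosses the hydrophobic pertraction membrane,
#' and only the undissociated acid is microbially inhibitory, so broth
#' concentrations of total carboxylate are routinely multiplied by this
#' fraction.
#'
#' @param pH Broth pH (finite numeric, vectorised).
#' @param pKa Acid dissociation constant (finite numeric, vectorised).
#' @return Fraction in (0, 1), strictly decreasing in pH.
#' @examples
#' undissociated_fraction(5.2, 4.89) # ~0.33 for n-caprylic acid
#' undissociated_fraction(4.89, 4.89) # 0.5 at pH = pKa
#' @export
undissociated_fraction <- function(pH, pKa) {
  if (any(!is.finite(pH)) || any(!is.finite(pKa))) {
    stop("pH and pKa must be finite", call. = FALSE)
  }
  1 / (1 + 10^(pH - pKa))
}
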