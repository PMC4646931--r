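#' Monoisotopic mass constants
#'
#' CODATA/IUPAC monoisotopic masses (Da) used throughout the package. Only
#' C, H and O occur in FAHFA lipids and their fragments, and no isotope
#' abundance is modelled: all masses are monoisotopic.
#'
#' @format A named list of masses in Da:
#' \describe{
#'   \item{H}{1.007825032 — hydrogen atom}
#'   \item{C}{12.0 — carbon-12}
#'   \item{O}{15.994914620 — oxygen-16}
#'   \item{proton}{1.007276467}
#'   \item{electron}{0.000548580}
#'   \item{H2O}{18.010564684 — water loss}
#'   \item{CH2}{14.015650064 — methylene homology step}
#' }
#' @examples
#' fahfa_masses$H2O - (2 * fahfa_masses$H + fahfa_masses$O) # ~0
#' @export
fahfa_masses <- list(
  H        = 1.007825032,
  C        = 12.0,
  O        = 15.994914620,
  proton   = 1.007276467,
  electron = 0.000548580,
  H2O      = 18.010564684,
  CH2      = 14.015650064
)

#' Elemental formulas as tibbles
#'
#' An elemental formula is a tibble with integer columns `c`, `h`, `o`
#' (one row per formula; all functions are vectorised over rows). Addition
#' and subtraction are element-wise; subtraction below zero is an error.
#'
#' @param c,h,o Non-negative integer element counts (recycled to a common
#'   length).
#' @return A tibble with columns `c`, `h`, `o`.
#' @examples
#' elemental_formula(34, 66, 4) # 9-PAHSA neutral, C34H66O4
#' @export
elemental_formula <- function(c = 0L, h = 0L, o = 0L) {
  n <- max(length(c), length(h), length(o))
  out <- tibble::tibble(
    c = vctrs::vec_recycle(as.integer(c), n),
    h = vctrs::vec_recycle(as.integer(h), n),
    o = vctrs::vec_recycle(as.integer(o), n)
  )
  if (anyNA(out) || any(out$c < 0 | out$h < 0 | out$o < 0)) {
    rlang::abort("element counts must be non-negative integers")
  }
  out
}

#' @rdname elemental_formula
#' @param x,y Formula tibbles of compatible length.
#' @export
formula_add <- function(x, y) {
  elemental_formula(x$c + y$c, x$h + y$h, x$o + y$o)
}

#' @rdname elemental_formula
#' @export
formula_subtract <- function(x, y) {
  cc <- x$c - y$c; hh <- x$h - y$h; oo <- x$o - y$o
  if (any(cc < 0 | hh < 0 | oo < 0)) {
    rlang::abort("formula subtraction yields a negative element count")
  }
  elemental_formula(cc, hh, oo)
}

#' @rdname elemental_formula
#' @param formula A formula tibble.
#' @export
formula_string <- function(formula) {
  paste0(
    ifelse(formula$c > 0, paste0("C", formula$c), ""),
    ifelse(formula$h > 0, paste0("H", formula$h), ""),
    ifelse(formula$o > 0, paste0("O", formula$o), "")
  )
}

#' Monoisotopic mass and deprotonated m/z
#'
#' `monoisotopic_mass()` sums element counts times monoisotopic element
#' masses. `deprotonated_mz()` gives the m/z of the \eqn{[M-H]^-} anion,
#' i.e. neutral mass minus the proton mass (the electron stays on the ion,
#' so this equals neutral − H + electron).
#'
#' @param formula A formula tibble (see [elemental_formula()]).
#' @return Numeric vector of masses (Da) or m/z values.
#' @examples
#' monoisotopic_mass(elemental_formula(16, 32, 2)) # palmitic acid, 256.24023
#' deprotonated_mz(elemental_formula(34, 66, 4))   # 9-PAHSA [M-H]-, 537.48883
#' @export
monoisotopic_mass <- function(formula) {
  formula$c * fahfa_masses$C + formula$h * fahfa_masses$H +
    formula$o * fahfa_masses$O
}

#' @rdname monoisotopic_mass
#' @export
deprotonated_mz <- function(formula) {
  if (any(formula$h < 1)) {
    rlang::abort("cannot deprotonate a formula without hydrogen")
  }
  monoisotopic_mass(formula) - fahfa_masses$proton
}

# ---- acyl chains and hydroxy backbones --------------------------------------

#' Validate and build fatty acyl / hydroxy fatty acid chain formulas
#'
#' A fatty acyl chain `n:d` (n carbons, d double bonds) has neutral formula
#' \eqn{C_n H_{2n-2d} O_2}; a hydroxy fatty acid backbone `O-n:d` carries one
#' extra oxygen, \eqn{C_n H_{2n-2d} O_3}. Chain-length bounds
#' (4 <= n <= 40, d <= (n-2)/2) are sanity rails for plausible lipids.
#'
#' @param carbons Integer vector of chain lengths.
#' @param double_bonds Integer vector of double-bond counts.
#' @return A formula tibble.
#' @examples
#' acyl_formula(16, 0)     # C16H32O2
#' backbone_formula(18, 1) # C18H34O3
#' @export
acyl_formula <- function(carbons, double_bonds = 0L) {
  validate_chain(carbons, double_bonds)
  elemental_formula(carbons, 2L * carbons - 2L * double_bonds, 2L)
}

#' @rdname acyl_formula
#' @export
backbone_formula <- function(carbons, double_bonds = 0L) {
  validate_chain(carbons, double_bonds)
  elemental_formula(carbons, 2L * carbons - 2L * double_bonds, 3L)
}

validate_chain <- function(carbons, double_bonds) {
  if (anyNA(carbons) || anyNA(double_bonds)) {
    rlang::abort("chain descriptors must not be NA")
  }
  if (any(carbons != as.integer(carbons)) ||
      any(double_bonds != as.integer(double_bonds))) {
    rlang::abort("carbons and double_bonds must be integers")
  }
  if (any(carbons < 4) || any(carbons > 40)) {
    rlang::abort("chain length must be between 4 and 40 carbons")
  }
  if (any(double_bonds < 0) || any(double_bonds > (carbons - 2) / 2)) {
    rlang::abort("double-bond count must satisfy 0 <= d <= (n - 2)/2")
  }
  invisible(TRUE)
}

#' Fragment-ion m/z for FAHFA moieties
#'
#' `fa_anion_mz()` is the deprotonated fatty acid fragment ion;
#' `hfa_anion_mz()` returns the intact deprotonated hydroxy fatty acid ion
#' and its dehydration product (intact − H2O). These, together with the
#' precursor, are the four major negative-mode CID fragments of a FAHFA.
#'
#' @inheritParams acyl_formula
#' @return `fa_anion_mz()`: numeric m/z. `hfa_anion_mz()`: a tibble with
#'   columns `intact` and `dehydrated`.
#' @examples
#' fa_anion_mz(16, 0)  # palmitate, 255.23295
#' hfa_anion_mz(18, 0) # hydroxy-stearate 299.25917 and 281.24860
#' @export
fa_anion_mz <- function(carbons, double_bonds = 0L) {
  deprotonated_mz(acyl_formula(carbons, double_bonds))
}

#' @rdname fa_anion_mz
#' @export
hfa_anion_mz <- function(carbons, double_bonds = 0L) {
  intact <- deprotonated_mz(backbone_formula(carbons, double_bonds))
  tibble::tibble(intact = intact, dehydrated = intact - fahfa_masses$H2O)
}

#' Neutral formula of a FAHFA ester
#'
#' Esterification of the acyl carboxyl onto the backbone hydroxyl loses one
#' water: \eqn{C_{na+nb} H_{2na+2nb-2da-2db-2} O_4}.
#'
#' @param acyl_carbons,acyl_db Acyl chain descriptor.
#' @param backbone_carbons,backbone_db Hydroxy backbone descriptor.
#' @return A formula tibble.
#' @examples
#' formula_string(fahfa_formula(16, 0, 18, 0)) # "C34H66O4" (PAHSA)
#' @export
fahfa_formula <- function(acyl_carbons, acyl_db, backbone_carbons, backbone_db) {
  formula_subtract(
    formula_add(
      acyl_formula(acyl_carbons, acyl_db),
      backbone_formula(backbone_carbons, backbone_db)
    ),
    elemental_formula(0L, 2L, 1L)
  )
}
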