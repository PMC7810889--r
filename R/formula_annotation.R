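# Monoisotopic masses of the supported elements (Da). C is exact by
# definition of the unified atomic mass scale.
ELEMENT_MASSES <- c(
  C = 12,
  H = 1.007825,
  N = 14.003074,
  O = 15.994915,
  P = 30.973762,
  S = 31.972071
)

# Mass added to the neutral molecule under the two [M+H]+ conventions.
# The hydrogen-atom convention (neutral H, electron mass ignored) matches
# the lock-mass reference value printed by the instrument vendor for
# leucine enkephalin (556.2771); the proton convention is the physically
# strict one.
ADDUCT_DELTAS <- c(
  M_plus_H_atom = 1.007825,
  M_plus_H_proton = 1.007276
)

#' Parse an elemental formula string
#'
#' Accepts Hill-style formula strings over the element alphabet C, H, N, O,
#' P, S (e.g. `"C28H37N5O7"`). An omitted count means 1.
#'
#' @param x A single formula string.
#' @return A named integer vector over `c("C","H","N","O","P","S")`.
#' @export
#' @examples
#' parse_formula("C28H37N5O7")
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  counts <- stats::setNames(integer(length(ELEMENT_MASSES)), names(ELEMENT_MASSES))
  if (nzchar(x)) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    tokens <- regmatches(x, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(x)) {
      validation_error(sprintf("cannot parse formula string '%s'", x))
    }
    for (tok in tokens) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(counts)) {
        validation_error(sprintf("unknown element symbol '%s' (supported: %s)",
                                 el, paste(names(counts), collapse = ", ")))
      }
      counts[el] <- counts[el] + n
    }
  }
  counts
}

as_formula_counts <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (is.null(names(formula)) || !all(names(formula) %in% names(ELEMENT_MASSES))) {
    bad <- setdiff(names(formula), names(ELEMENT_MASSES))
    validation_error(sprintf("unknown element symbol(s): %s",
                             paste(bad, collapse = ", ")))
  }
  if (any(is.na(formula)) || any(formula < 0) || any(formula != floor(formula))) {
    validation_error("element counts must be non-negative integers")
  }
  counts <- stats::setNames(integer(length(ELEMENT_MASSES)), names(ELEMENT_MASSES))
  counts[names(formula)] <- as.integer(formula)
  counts
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula A formula string (see [parse_formula()]) or a named vector
#'   of element counts over C, H, N, O, P, S.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
monoisotopic_mass <- function(formula) {
  counts <- as_formula_counts(formula)
  sum(counts * ELEMENT_MASSES[names(counts)])
}

#' Theoretical m/z of a formula under an [M+H]+ convention
#'
#' `M_plus_H_atom` adds the mass of a neutral hydrogen atom (1.007825 Da,
#' electron mass ignored), the convention under which leucine enkephalin's
#' [M+H]+ reference mass is 556.2771; `M_plus_H_proton` adds the proton mass
#' (1.007276 Da).
#'
#' @inheritParams monoisotopic_mass
#' @param adduct One of `"M_plus_H_atom"` (default) or `"M_plus_H_proton"`.
#' @return Theoretical m/z in Da.
#' @export
adduct_mz <- function(formula, adduct = c("M_plus_H_atom", "M_plus_H_proton")) {
  adduct <- match.arg(adduct)
  monoisotopic_mass(formula) + ADDUCT_DELTAS[[adduct]]
}

#' Ring and double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + P/2 + 1, with O and S contributing nothing and P
#' treated as trivalent.
#'
#' @inheritParams monoisotopic_mass
#' @return RDBE (may be half-integer).
#' @export
#' @examples
#' rdbe("C6H6") # 4
rdbe <- function(formula) {
  counts <- as_formula_counts(formula)
  unname(counts["C"] - counts["H"] / 2 + counts["N"] / 2 + counts["P"] / 2 + 1)
}

#' Element-count bounds for formula enumeration
#'
#' @param C,H,N,O,P,S Maximum count per element.
#' @param rdbe_min Minimum RDBE a candidate must reach; use `-Inf` to lift
#'   the filter.
#' @param nitrogen_rule Apply the nitrogen parity rule (for the neutral
#'   molecule: even nominal mass iff even nitrogen count). Off by default:
#'   for even-electron [M+H]+ ions the textbook rule inverts and silently
#'   discards valid formulas.
#' @return An object of class `enumeration_bounds`.
#' @export
enumeration_bounds <- function(C = 50, H = 100, N = 10, O = 20, P = 3, S = 3,
                               rdbe_min = 0, nitrogen_rule = FALSE) {
  max_counts <- c(C = C, H = H, N = N, O = O, P = P, S = S)
  if (any(is.na(max_counts)) || any(max_counts < 0)) {
    validation_error("element maxima must be non-negative")
  }
  structure(
    list(max_counts = max_counts, rdbe_min = rdbe_min,
         nitrogen_rule = isTRUE(nitrogen_rule)),
    class = "enumeration_bounds"
  )
}

formula_string <- function(counts_mat) {
  # Hill system over CHNOPS: C, H, then alphabetical
  order_el <- c("C", "H", "N", "O", "P", "S")
  apply(counts_mat[, order_el, drop = FALSE], 1L, function(cc) {
    parts <- vapply(order_el, function(el) {
      n <- cc[[el]]
      if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
    }, character(1))
    paste0(parts, collapse = "")
  })
}

#' Enumerate candidate elemental formulas for an observed m/z
#'
#' Exhaustive search over the bounded CHNOPS lattice, pruned by partial mass:
#' the heteroatom skeleton (C, N, O, P, S) is enumerated first and the
#' hydrogen count is solved from the residual mass window, so only
#' mass-feasible lattice points are visited. Candidates must place the
#' theoretical adduct m/z within `ppm` of the query and pass the RDBE floor
#' and (optionally) the nitrogen rule.
#'
#' @param mz Observed m/z (Da), positive.
#' @param ppm Mass tolerance in parts per million, positive.
#' @param adduct Ion convention, see [adduct_mz()].
#' @param bounds An [enumeration_bounds()] object.
#' @return A data frame of candidates sorted by `|error_ppm|` (ties broken by
#'   formula string): columns `formula`, the six element counts,
#'   `theoretical_mz`, `error_ppm`, `rdbe`, `adduct`.
#' @export
#' @examples
#' enumerate_formulas(556.2771, ppm = 5)
enumerate_formulas <- function(mz, ppm,
                               adduct = c("M_plus_H_atom", "M_plus_H_proton"),
                               bounds = enumeration_bounds()) {
  adduct <- match.arg(adduct)
  if (!is.numeric(mz) || length(mz) != 1L || mz <= 0) {
    validation_error("mz must be a single positive number")
  }
  if (!is.numeric(ppm) || length(ppm) != 1L || ppm <= 0) {
    validation_error("ppm must be a single positive number")
  }
  stopifnot(inherits(bounds, "enumeration_bounds"))
  lattice <- prod(bounds$max_counts + 1)
  if (lattice > 1e8) {
    rd_stop(sprintf(paste0(
      "enumeration bounds admit %.3g lattice points (> 1e8); ",
      "tighten the per-element maxima (see enumeration_bounds()) ",
      "or split the query"), lattice), "residomics_bounds_error")
  }

  delta <- ADDUCT_DELTAS[[adduct]]
  m_lo <- mz * (1 - ppm * 1e-6) - delta
  m_hi <- mz * (1 + ppm * 1e-6) - delta
  if (m_hi < 0) return(empty_candidates(adduct))

  mx <- bounds$max_counts
  cap <- function(el) min(mx[[el]], floor(m_hi / ELEMENT_MASSES[[el]]))
  skeleton <- expand.grid(
    C = 0:cap("C"), N = 0:cap("N"), O = 0:cap("O"),
    P = 0:cap("P"), S = 0:cap("S"),
    KEEP.OUT.ATTRS = FALSE
  )
  base_mass <- as.matrix(skeleton) %*% ELEMENT_MASSES[c("C", "N", "O", "P", "S")]
  base_mass <- as.numeric(base_mass)
  keep <- base_mass <= m_hi
  skeleton <- skeleton[keep, , drop = FALSE]
  base_mass <- base_mass[keep]
  if (nrow(skeleton) == 0L) return(empty_candidates(adduct))

  mH <- ELEMENT_MASSES[["H"]]
  h_lo <- pmax(0L, as.integer(ceiling((m_lo - base_mass) / mH - 1e-9)))
  h_hi <- pmin(mx[["H"]], as.integer(floor((m_hi - base_mass) / mH + 1e-9)))
  n_h <- pmax(0L, h_hi - h_lo + 1L)
  if (sum(n_h) == 0L) return(empty_candidates(adduct))

  idx <- rep.int(seq_len(nrow(skeleton)), n_h)
  H <- unlist(lapply(which(n_h > 0L), function(i) h_lo[i]:h_hi[i]),
              use.names = FALSE)
  cand <- cbind(
    C = skeleton$C[idx], H = H, N = skeleton$N[idx],
    O = skeleton$O[idx], P = skeleton$P[idx], S = skeleton$S[idx]
  )
  neutral_mass <- base_mass[idx] + H * mH
  theo <- neutral_mass + delta
  err <- (theo - mz) / mz * 1e6
  rdbe_val <- cand[, "C"] - cand[, "H"] / 2 + cand[, "N"] / 2 + cand[, "P"] / 2 + 1

  ok <- abs(err) <= ppm & rdbe_val >= bounds$rdbe_min
  if (bounds$nitrogen_rule) {
    # neutral-molecule parity: nominal mass parity is set by H + P (the only
    # odd nominal element masses); even nominal mass iff even N
    nominal_parity <- (cand[, "H"] + cand[, "P"]) %% 2L
    ok <- ok & (nominal_parity == cand[, "N"] %% 2L)
  }
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_candidates(adduct))
  theo <- theo[ok]; err <- err[ok]; rdbe_val <- rdbe_val[ok]

  fstr <- formula_string(cand)
  ord <- order(abs(err), fstr)
  out <- data.frame(
    formula = fstr[ord],
    cand[ord, , drop = FALSE],
    theoretical_mz = theo[ord],
    error_ppm = err[ord],
    rdbe = rdbe_val[ord],
    adduct = adduct,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out
}

empty_candidates <- function(adduct) {
  data.frame(
    formula = character(0), C = integer(0), H = integer(0), N = integer(0),
    O = integer(0), P = integer(0), S = integer(0),
    theoretical_mz = numeric(0), error_ppm = numeric(0), rdbe = numeric(0),
    adduct = character(0), stringsAsFactors = FALSE
  )
}
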