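#' Two-point complete-basis-set extrapolation of correlation energy
#'
#' For correlation energies converging as `E(X) = E_inf + A X^-3` in the
#' basis-set cardinal number X, the two-point formula
#' `E_inf = (X^3 E_X - (X-1)^3 E_{X-1}) / (X^3 - (X-1)^3)` eliminates the
#' `A X^-3` term exactly.
#'
#' @param e_x Correlation energy at cardinal `x`.
#' @param e_xm1 Correlation energy at cardinal `x - 1`.
#' @param x Larger cardinal number (integer `>= 3`; T/Q extrapolation uses
#'   `x = 4`).
#' @return Extrapolated basis-set-limit correlation energy, same units as
#'   the inputs.
#' @export
extrapolate_two_point <- function(e_x, e_xm1, x = 4L) {
  if (length(x) != 1L || is.na(x) || x != round(x) || x < 3) {
    nbi_stop("invalid-cardinal",
             "cardinal number x must be an integer >= 3")
  }
  (x^3 * e_x - (x - 1)^3 * e_xm1) / (x^3 - (x - 1)^3)
}

#' Correlation-energy series over basis-set cardinals
#'
#' @param cardinals Integer cardinal numbers (strictly increasing, `>= 2`).
#' @param energies Correlation energies matching `cardinals`.
#' @param label Basis family name (e.g. `"cc-pVXZ"`).
#' @return Data frame of class `nbi_corr_series` with columns `cardinal`,
#'   `e_corr`.
#' @export
correlation_series <- function(cardinals, energies, label = "cc-pVXZ") {
  if (length(cardinals) < 2L) {
    nbi_stop("invalid-cardinal", "need at least two cardinals")
  }
  if (any(diff(cardinals) <= 0) || any(cardinals < 2)) {
    nbi_stop("invalid-cardinal",
             "cardinals must be strictly increasing and >= 2")
  }
  structure(data.frame(cardinal = as.integer(cardinals),
                       e_corr = energies),
            label = label, class = c("nbi_corr_series", "data.frame"))
}

#' Total MP2/CBS energy from HF reference plus extrapolated correlation
#'
#' The Hartree-Fock part converges much faster than correlation and is
#' taken unextrapolated at the larger basis; only the correlation part is
#' extrapolated from the (T, Q) pair.
#'
#' @param hf_large HF energy at the larger basis (cardinal `x`).
#' @param corr_t Correlation energy at cardinal `x - 1` (triple zeta).
#' @param corr_q Correlation energy at cardinal `x` (quadruple zeta).
#' @param x Larger cardinal (default 4).
#' @return Total energy at the extrapolated basis-set limit.
#' @export
mp2_cbs_total <- function(hf_large, corr_t, corr_q, x = 4L) {
  hf_large + extrapolate_two_point(corr_q, corr_t, x)
}

#' Composite components of a coupled-cluster/CBS interaction energy
#'
#' @param mp2_cbs Interaction energy at MP2/CBS.
#' @param ccsdt_small Interaction energy at CCSD(T) in the small basis.
#' @param mp2_small Interaction energy at MP2 in the same small basis.
#' @param small_basis_ccsdt,small_basis_mp2 Basis labels of the two
#'   small-basis components; they must agree.
#' @return List of class `nbi_composite`.
#' @export
composite_components <- function(mp2_cbs, ccsdt_small, mp2_small,
                                 small_basis_ccsdt = "aug-cc-pVDZ",
                                 small_basis_mp2 = small_basis_ccsdt) {
  if (!identical(small_basis_ccsdt, small_basis_mp2)) {
    nbi_stop("basis-mismatch",
             sprintf("coupled-cluster correction components use different small bases: '%s' vs '%s'",
                     small_basis_ccsdt, small_basis_mp2))
  }
  structure(list(mp2_cbs = mp2_cbs, ccsdt_small = ccsdt_small,
                 mp2_small = mp2_small,
                 small_basis_label = small_basis_ccsdt),
            class = "nbi_composite")
}

#' Composite CCSD(T)/CBS interaction energy
#'
#' Adds the small-basis coupled-cluster correction to the MP2/CBS value:
#' `dE_CCSD(T)/CBS = dE_MP2/CBS + (dE_CCSD(T) - dE_MP2)|small basis`.
#'
#' @param components A [composite_components()] object, or the `mp2_cbs`
#'   value when the remaining pieces are passed positionally.
#' @param ccsdt_small,mp2_small Small-basis components (used when
#'   `components` is numeric).
#' @return The composite interaction energy, same units as the inputs.
#' @export
ccsdt_cbs <- function(components, ccsdt_small = NULL, mp2_small = NULL) {
  if (is.numeric(components)) {
    components <- composite_components(components, ccsdt_small, mp2_small)
  }
  stopifnot(inherits(components, "nbi_composite"))
  components$mp2_cbs + (components$ccsdt_small - components$mp2_small)
}

#' Read a delimited CBS component table
#'
#' Expected columns: `motif_id`, `role`, `hf_q`, `corr_t`, `corr_q`,
#' `ccsdt_small`, `mp2_small` (energies in hartree, one row per
#' counterpoise fragment role), plus optionally `small_basis`.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return Data frame.
#' @export
read_component_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("motif_id", "role", "hf_q", "corr_t", "corr_q",
            "ccsdt_small", "mp2_small")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    nbi_stop("schema-mismatch",
             sprintf("component table lacks column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  tab
}

#' Assemble composite interaction energies from a component table
#'
#' For each motif, forms fragment totals `HF(Q) + extrapolated correlation`,
#' takes counterpoise differences (`dimer_AB - monoA_ghostB -
#' monoB_ghostA`) at the MP2/CBS, CCSD(T)/small and MP2/small levels, and
#' composes the coupled-cluster-corrected interaction energy.
#'
#' @param components Data frame from [read_component_table()].
#' @return Data frame with one row per motif: `motif_id`, `mp2_cbs`,
#'   `ccsdt_small`, `mp2_small`, `dE_ccsdt_cbs` (all kcal/mol).
#' @export
compose_ccsdt_cbs <- function(components) {
  cp_roles <- c("dimer_AB", "monoA_ghostB", "monoB_ghostA")
  out <- lapply(split(components, components$motif_id), function(tab) {
    rows <- match(cp_roles, tab$role)
    if (anyNA(rows)) {
      nbi_stop("incomplete-ledger",
               sprintf("motif %s lacks role(s): %s", tab$motif_id[1],
                       paste(cp_roles[is.na(rows)], collapse = ", ")))
    }
    tot <- mp2_cbs_total(tab$hf_q[rows], tab$corr_t[rows],
                         tab$corr_q[rows])
    d_mp2_cbs <- supramolecular_delta(tot[1], tot[2], tot[3]) *
      HARTREE_TO_KCAL
    d_cc <- supramolecular_delta(tab$ccsdt_small[rows[1]],
                                 tab$ccsdt_small[rows[2]],
                                 tab$ccsdt_small[rows[3]]) * HARTREE_TO_KCAL
    d_mp2 <- supramolecular_delta(tab$mp2_small[rows[1]],
                                  tab$mp2_small[rows[2]],
                                  tab$mp2_small[rows[3]]) * HARTREE_TO_KCAL
    data.frame(motif_id = tab$motif_id[1], mp2_cbs = d_mp2_cbs,
               ccsdt_small = d_cc, mp2_small = d_mp2,
               dE_ccsdt_cbs = ccsdt_cbs(d_mp2_cbs, d_cc, d_mp2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
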