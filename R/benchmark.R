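#' Benchmark error metrics against reference energies
#'
#' Errors are signed as calculated minus reference, so a positive average
#' means the tested method is less attractive than the reference.
#'
#' @param calc Calculated interaction energies (kcal/mol).
#' @param ref Reference interaction energies of equal length; no reference
#'   value may be exactly zero (the percentage error would be undefined).
#' @return List with `rmsd` (root-mean-square deviation), `mae` (mean
#'   absolute error), `avg` (mean signed error) and `max_pct` (largest
#'   absolute percentage error relative to the reference).
#' @export
error_metrics <- function(calc, ref) {
  if (length(calc) != length(ref) || length(calc) < 1L) {
    nbi_stop("shape-mismatch",
             "calc and ref must have equal length >= 1")
  }
  if (any(ref == 0)) {
    nbi_stop("undefined-percentage",
             "reference values of exactly zero make MAX% undefined")
  }
  e <- calc - ref
  list(rmsd = sqrt(mean(e^2)), mae = mean(abs(e)), avg = mean(e),
       max_pct = max(100 * abs(e) / abs(ref)))
}

#' Stratified error summaries by interaction mode
#'
#' Computes [error_metrics()] within each interaction mode and over the
#' full set (`stratum = "overall"`).
#'
#' @param calc,ref Calculated and reference energies (kcal/mol).
#' @param modes Mode label per entry; must be one of
#'   [interaction_modes()].
#' @param method_label,basis_label Labels carried into the output.
#' @return Data frame with one row per stratum: `method_label`,
#'   `basis_label`, `stratum`, `n`, `rmsd`, `mae`, `avg`, `max_pct`.
#' @export
stratified_errors <- function(calc, ref, modes, method_label = "method",
                              basis_label = "basis") {
  if (length(modes) != length(calc)) {
    nbi_stop("shape-mismatch", "modes must match the energy vectors")
  }
  unknown <- setdiff(unique(modes), interaction_modes())
  if (length(unknown)) {
    nbi_stop("unknown-mode",
             sprintf("unknown mode label(s): %s",
                     paste(unknown, collapse = ", ")))
  }
  strata <- c(intersect(interaction_modes(), unique(modes)), "overall")
  rows <- lapply(strata, function(s) {
    sel <- if (s == "overall") rep(TRUE, length(calc)) else modes == s
    m <- error_metrics(calc[sel], ref[sel])
    data.frame(method_label = method_label, basis_label = basis_label,
               stratum = s, n = sum(sel), rmsd = m$rmsd, mae = m$mae,
               avg = m$avg, max_pct = m$max_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-mode energy summaries of a reference interaction table
#'
#' Summarizes the gas-phase, dehydration and solution-phase energies of a
#' 49-motif reference table (columns `mode`, `dE_gas`, `dE_deh`, `dE_aq`)
#' by interaction mode: mean, min, max and count per mode and phase, plus
#' the mean rounded to one decimal for reporting.
#'
#' @param ref_table Data frame with columns `mode`, `dE_gas`, `dE_deh`,
#'   `dE_aq` (kcal/mol).
#' @return Data frame with columns `mode`, `phase` (gas, dehydration,
#'   aqueous), `mean`, `mean_1dp`, `min`, `max`, `n`.
#' @export
mode_summary <- function(ref_table) {
  phases <- c(gas = "dE_gas", dehydration = "dE_deh", aqueous = "dE_aq")
  modes <- intersect(interaction_modes(), unique(ref_table$mode))
  rows <- list()
  for (m in modes) {
    sub <- ref_table[ref_table$mode == m, , drop = FALSE]
    for (p in names(phases)) {
      v <- sub[[phases[[p]]]]
      rows[[length(rows) + 1L]] <- data.frame(
        mode = m, phase = p, mean = mean(v),
        mean_1dp = round(mean(v), 1), min = min(v), max = max(v),
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pareto front of accuracy versus computational cost
#'
#' Returns the methods not dominated in (RMSD, CPU time): a point dominates
#' another when it is no worse in both coordinates and strictly better in
#' at least one. The front is the set a user would choose from when
#' trading accuracy against cost.
#'
#' @param points Data frame with columns `rmsd` (kcal/mol) and
#'   `cpu_minutes` (> 0); other columns (labels) are carried through.
#' @return The non-dominated subset, sorted by ascending `cpu_minutes`.
#' @export
pareto_front <- function(points) {
  if (nrow(points) < 1L) {
    nbi_stop("shape-mismatch", "at least one cost point required")
  }
  if (any(points$cpu_minutes <= 0)) {
    nbi_stop("invalid-parameters", "cpu_minutes must be positive")
  }
  n <- nrow(points)
  dominated <- vapply(seq_len(n), function(i) {
    any(points$rmsd <= points$rmsd[i] &
          points$cpu_minutes <= points$cpu_minutes[i] &
          (points$rmsd < points$rmsd[i] |
             points$cpu_minutes < points$cpu_minutes[i]))
  }, logical(1))
  out <- points[!dominated, , drop = FALSE]
  out <- out[order(out$cpu_minutes, out$rmsd), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benchmark a table of per-motif method energies against a reference
#'
#' Convenience wrapper producing the error-summary grid for every method
#' column of a per-motif energy matrix.
#'
#' @param energies Data frame with columns `motif_id`, `mode`, `ref`, and
#'   one column per method/basis combination (kcal/mol).
#' @param by_mode When `TRUE`, stratify each method by interaction mode;
#'   otherwise only overall rows are produced.
#' @return Data frame of stratified error summaries for all methods.
#' @export
benchmark_methods <- function(energies, by_mode = TRUE) {
  fixed <- c("motif_id", "mode", "ref")
  missing_cols <- setdiff(fixed, names(energies))
  if (length(missing_cols)) {
    nbi_stop("schema-mismatch",
             sprintf("energy table lacks column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  methods <- setdiff(names(energies), fixed)
  rows <- lapply(methods, function(mcol) {
    parts <- strsplit(mcol, "/", fixed = TRUE)[[1]]
    meth <- parts[1]
    bas <- if (length(parts) > 1L) parts[2] else NA_character_
    full <- stratified_errors(energies[[mcol]], energies$ref,
                              energies$mode, meth, bas)
    if (by_mode) full else full[full$stratum == "overall", , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
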