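#' Per-frame MM-GBSA component deltas of a dimer
#'
#' For each frame and each energy component, the delta is the complex value
#' minus the sum of the two monomer values. The internal term is later formed
#' as the combined change in bond, angle, dihedral and improper energies.
#' The three series must cover identical frame indices.
#'
#' @param complex,mon_a,mon_b `energy_series` for the dimer and the two
#'   monomers.
#' @return an `energy_series` of deltas, labelled `"delta"`. `nonpolar_sa` is
#'   kept only when present in all three inputs; derive it from SASA with
#'   [nonpolar_from_sasa()] otherwise.
#' @export
frame_component_deltas <- function(complex, mon_a, mon_b) {
  series <- list(complex = complex, mon_a = mon_a, mon_b = mon_b)
  frames <- lapply(series, function(s) sort(s$frame))
  for (nm in c("mon_a", "mon_b")) {
    miss <- setdiff(frames$complex, frames[[nm]])
    extra <- setdiff(frames[[nm]], frames$complex)
    if (length(miss) > 0 || length(extra) > 0) {
      bad <- c(miss, extra)[1]
      abort(sprintf("frame mismatch between complex and %s: first differing frame %d", nm, bad))
    }
  }
  comps <- Reduce(intersect, lapply(series, function(s) intersect(ENERGY_COMPONENTS, names(s))))
  ord <- lapply(series, function(s) s[order(s$frame), , drop = FALSE])
  out <- tibble(frame = ord$complex$frame)
  for (cc in comps) {
    out[[cc]] <- ord$complex[[cc]] - ord$mon_a[[cc]] - ord$mon_b[[cc]]
  }
  energy_series(out, system_label = "delta")
}

#' Nonpolar solvation energy from SASA
#'
#' The nonpolar solvation component is proportional to the solvent-accessible
#' surface area: `energy = gamma * sasa`. Used when an energy log lacks a
#' nonpolar column.
#'
#' @param sasa numeric SASA series (A^2).
#' @param gamma surface-tension coefficient, kcal/(mol A^2); must be > 0.
#'   A common choice is 0.00542.
#' @return numeric energy series (kcal/mol).
#' @export
nonpolar_from_sasa <- function(sasa, gamma = 0.00542) {
  if (is.null(sasa) || length(sasa) == 0) abort("SASA series is absent")
  if (!is.numeric(gamma) || gamma <= 0) abort("gamma must be > 0")
  gamma * sasa
}

#' Aggregate MM-GBSA deltas into a binding-energy summary
#'
#' Over the frames of the analysis window, each component's mean and standard
#' error (sample SD / sqrt(n), no autocorrelation correction) are computed.
#' The internal term is the per-frame sum of the bond, angle, dihedral and
#' improper deltas; the total binding energy per frame is
#' `dG = dE_int + dE_ele + dG_sol_pb + dG_sol_sa + dE_vdW`, so the total mean
#' equals the sum of the component means exactly. Binding energies of this
#' kind are scoring values, not absolute affinities.
#'
#' @param deltas an `energy_series` of deltas (see
#'   [frame_component_deltas()]); must carry `nonpolar_sa`.
#' @param window a [frame_window()] in the series' `frame` numbering, or
#'   `NULL` for all frames; at least 2 frames.
#' @param n_residues residue count of the dimer, for the per-residue value.
#' @return object of class `mmgbsa_summary`.
#' @export
aggregate_mmgbsa <- function(deltas, window = NULL, n_residues) {
  if (missing(n_residues) || n_residues <= 0) abort("n_residues must be > 0")
  if (!"nonpolar_sa" %in% names(deltas)) {
    abort("deltas lack nonpolar_sa; derive it with nonpolar_from_sasa() first")
  }
  df <- as_tibble(deltas)
  if (!is.null(window)) {
    if (!inherits(window, "frame_window")) abort("window must be a frame_window or NULL")
    if (window$start_frame < min(df$frame) || window$end_frame > max(df$frame)) {
      abort("window not contained in delta frames")
    }
    df <- df[df$frame >= window$start_frame & df$frame <= window$end_frame, , drop = FALSE]
  } else {
    window <- frame_window(min(df$frame), max(df$frame))
  }
  n <- nrow(df)
  if (n < 2) abort("analysis window must contain at least 2 frames")

  per_frame <- tibble(
    dE_int = df$bond + df$angle + df$dihedral + df$improper,
    dE_ele = df$elec,
    dG_sol_pb = df$gb_polar,
    dG_sol_sa = df$nonpolar_sa,
    dE_vdw = df$vdw
  )
  per_frame$dG_total <- rowSums(per_frame)
  comp <- tibble(
    term = names(per_frame),
    estimate = vapply(per_frame, mean, 0),
    se = vapply(per_frame, function(v) sd(v) / sqrt(n), 0)
  )
  total <- unname(comp$estimate[comp$term == "dG_total"])
  structure(
    list(
      components = comp,
      dg_total = total,
      dg_se = unname(comp$se[comp$term == "dG_total"]),
      n_residues = as.integer(n_residues),
      dg_per_aa = total / n_residues,
      window = window,
      n_frames = n
    ),
    class = "mmgbsa_summary"
  )
}

#' Binding-energy summary from component means
#'
#' Convenience wrapper for working from already-averaged component values
#' (e.g. a published component table): builds a constant two-frame delta
#' series carrying the given means and aggregates it, so the total is the
#' plain component sum. The internal term is supplied whole (as `bond`; the
#' other internal channels are zero).
#'
#' @param de_int,de_ele,dg_sol_pb,dg_sol_sa,de_vdw component means, kcal/mol.
#' @param n_residues residue count of the dimer.
#' @return an `mmgbsa_summary` (standard errors are zero by construction).
#' @export
mmgbsa_from_components <- function(de_int, de_ele, dg_sol_pb, dg_sol_sa, de_vdw,
                                   n_residues) {
  deltas <- energy_series(tibble(
    frame = 0:1,
    bond = de_int, angle = 0, dihedral = 0, improper = 0,
    elec = de_ele, vdw = de_vdw, gb_polar = dg_sol_pb, nonpolar_sa = dg_sol_sa
  ), system_label = "delta")
  aggregate_mmgbsa(deltas, NULL, n_residues)
}

#' Combine duplicate-run summaries
#'
#' Means are combined as the unweighted mean of means; standard errors in
#' quadrature (`sqrt(sum(se^2)) / k`).
#'
#' @param summaries list of `mmgbsa_summary` objects from duplicate runs
#'   (same dimer, same residue count).
#' @return a combined `mmgbsa_summary`; its window is the first run's window
#'   and `n_frames` the total.
#' @export
combine_mmgbsa_runs <- function(summaries) {
  if (length(summaries) < 1) abort("need at least one summary")
  if (length(summaries) == 1) return(summaries[[1]])
  k <- length(summaries)
  nres <- unique(vapply(summaries, function(s) s$n_residues, 0L))
  if (length(nres) != 1) abort("summaries disagree on n_residues")
  comps <- lapply(summaries, function(s) s$components)
  comb <- comps[[1]]
  comb$estimate <- Reduce(`+`, lapply(comps, function(c) c$estimate)) / k
  comb$se <- sqrt(Reduce(`+`, lapply(comps, function(c) c$se^2))) / k
  total <- unname(comb$estimate[comb$term == "dG_total"])
  structure(
    list(
      components = comb,
      dg_total = total,
      dg_se = unname(comb$se[comb$term == "dG_total"]),
      n_residues = nres,
      dg_per_aa = total / nres,
      window = summaries[[1]]$window,
      n_frames = sum(vapply(summaries, function(s) s$n_frames, 0L))
    ),
    class = "mmgbsa_summary"
  )
}

#' @export
print.mmgbsa_summary <- function(x, ...) {
  cat(sprintf(
    "MM-GBSA binding-energy summary (%d frames, window [%d, %d])\n",
    x$n_frames, x$window$start_frame, x$window$end_frame
  ))
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf(
      "  %-10s %8.1f +/- %.1f kcal/mol\n",
      comp$term[i], round_half_away(comp$estimate[i]), comp$se[i]
    ))
  }
  cat(sprintf(
    "  dG/AA      %8.1f kcal/mol per residue (%d residues)\n",
    round_half_away(x$dg_per_aa), x$n_residues
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mmgbsa_summary <- function(x, ...) x$components

#' @exportS3Method generics::glance
glance.mmgbsa_summary <- function(x, ...) {
  tibble(
    dg_total = x$dg_total, dg_se = x$dg_se,
    dg_per_aa = x$dg_per_aa, n_residues = x$n_residues,
    n_frames = x$n_frames,
    window_start = x$window$start_frame, window_end = x$window$end_frame
  )
}

#' Expected heterodimer binding energy
#'
#' Under additivity the binding energy expected for a heterodimer A-B is the
#' arithmetic mean of the two homodimer binding energies.
#'
#' @param dg_homo_a,dg_homo_b homodimer binding energies, kcal/mol.
#' @return the mean, kcal/mol (vectorized).
#' @export
#' @examples
#' expected_heterodimer_dg(-529.1, -485.4) # -507.25, printed -507.3
expected_heterodimer_dg <- function(dg_homo_a, dg_homo_b) {
  if (!all(is.finite(dg_homo_a)) || !all(is.finite(dg_homo_b))) {
    abort("homodimer binding energies must be finite")
  }
  (dg_homo_a + dg_homo_b) / 2
}

#' Score heterodimer preference against the homodimer expectation
#'
#' The excess stabilization is `ddg = dg_het - dg_expected`. A heterodimer is
#' called favored when `ddg < -neutrality_band`, homodimer-favored when
#' `ddg > +neutrality_band`, and neutral otherwise. The default band of
#' 10 kcal/mol separates differences of a few kcal/mol (within the noise of
#' this kind of scoring) from the tens-of-kcal/mol scale that marks a real
#' preference.
#'
#' @param dg_het measured heterodimer binding energy, kcal/mol.
#' @param dg_expected expectation from [expected_heterodimer_dg()].
#' @param neutrality_band half-width of the neutral zone, kcal/mol.
#' @return tibble (one row per input): `dg_het`, `dg_expected`, `ddg`,
#'   `verdict` (`"heterodimer-favored"`, `"neutral"`, `"homodimer-favored"`),
#'   `neutrality_band`.
#' @export
#' @examples
#' heterodimer_preference(-529.5, -507.3) # ddg -22.2, heterodimer-favored
heterodimer_preference <- function(dg_het, dg_expected, neutrality_band = 10) {
  if (!all(is.finite(dg_het)) || !all(is.finite(dg_expected))) {
    abort("binding energies must be finite")
  }
  if (neutrality_band < 0) abort("neutrality_band must be >= 0")
  ddg <- dg_het - dg_expected
  tibble(
    dg_het = dg_het,
    dg_expected = dg_expected,
    ddg = ddg,
    verdict = dplyr::case_when(
      ddg < -neutrality_band ~ "heterodimer-favored",
      ddg > neutrality_band ~ "homodimer-favored",
      TRUE ~ "neutral"
    ),
    neutrality_band = neutrality_band
  )
}
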