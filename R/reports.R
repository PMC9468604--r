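# Deterministic TSV report writers. All writers emit a fixed column order,
# '#' metadata lines carrying the effective parameters, and the display
# precisions used throughout: energies at one decimal, occupancies at two,
# RMSD at one.

write_report <- function(df, path, header_lines) {
  tmp <- paste0(path, ".tmp")
  writeLines(header_lines, tmp)
  readr::write_tsv(df, tmp, append = TRUE, col_names = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a salt-bridge barcode table
#'
#' One row per retained pair: label, residue identities, occupancy (two
#' decimals) and the presence vector as run-length encoding
#' (`state x length` segments).
#'
#' @param barcode a [bridge_barcode()] result.
#' @param path output path.
#' @param config optional [run_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_barcode_table <- function(barcode, path, config = NULL) {
  rle_string <- function(p) {
    r <- rle(as.integer(p))
    paste(sprintf("%dx%d", r$values, r$lengths), collapse = ",")
  }
  df <- as_tibble(barcode) %>%
    mutate(
      occupancy = sprintf("%.2f", .data$occupancy),
      presence_rle = vapply(.data$presence, rle_string, "")
    ) %>%
    select(-"presence")
  write_report(df, path, c("# salt-bridge barcode", config_header_lines(config)))
}

#' Write an RMSD series table
#'
#' @param series an [rmsd_series()] tibble.
#' @param path output path.
#' @param config optional [run_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_rmsd_table <- function(series, path, config = NULL) {
  df <- as_tibble(series) %>% mutate(rmsd = sprintf("%.1f", .data$rmsd))
  write_report(df, path, c("# Calpha RMSD series", config_header_lines(config)))
}

#' Write a per-frame SASA/BSA table
#'
#' @param bsa a [bsa_series()] result.
#' @param path output path.
#' @param config optional [run_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_bsa_table <- function(bsa, path, config = NULL) {
  df <- bsa$per_frame %>%
    mutate(across(c("sasa_complex", "sasa_a", "sasa_b", "bsa"), ~ sprintf("%.1f", .x)))
  write_report(df, path, c(
    sprintf("# BSA min %.1f max %.1f mean %.1f", bsa$min, bsa$max, bsa$mean),
    config_header_lines(config)
  ))
}

#' Write MM-GBSA summaries as a component table
#'
#' One row per dimer in the column order used for binding-energy component
#' tables; energies at one decimal.
#'
#' @param summaries named list of `mmgbsa_summary` objects (names label the
#'   dimers).
#' @param path output path.
#' @param config optional [run_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_mmgbsa_table <- function(summaries, path, config = NULL) {
  rows <- purrr::imap(summaries, function(s, nm) {
    comp <- s$components
    get <- function(term) round_half_away(comp$estimate[comp$term == term])
    tibble(
      dimer = nm,
      dg_total = round_half_away(s$dg_total),
      de_int = get("dE_int"), de_ele = get("dE_ele"),
      dg_sol_pb = get("dG_sol_pb"), dg_sol_sa = get("dG_sol_sa"),
      de_vdw = get("dE_vdw"),
      n_residues = s$n_residues,
      dg_per_aa = round_half_away(s$dg_per_aa),
      window_start = s$window$start_frame, window_end = s$window$end_frame,
      n_frames = s$n_frames
    )
  })
  write_report(bind_rows(rows), path, c("# MM-GBSA component summary (kcal/mol)",
    config_header_lines(config)))
}

#' Reference binding-energy component table for BTB dimers
#'
#' The bundled per-dimer MM-GBSA component values (kcal/mol), residue
#' counts, buried surface areas and interface statistics for five ZBTB
#' homodimers and four heterodimers, as printed in the source analyses of
#' 500-ns dimer trajectories. Used to exercise the aggregation arithmetic
#' and the heterodimer-preference comparison at desk scale.
#'
#' @return tibble: `dimer`, `kind`, `window_ns`, `dg_total`, `dg_expected`
#'   (heterodimers only), `de_int`, `de_ele`, `dg_sol_pb`, `dg_sol_sa`,
#'   `de_vdw`, `n_residues`, `dg_per_aa`, `avg_bsa`, `pct_interface`,
#'   `avg_salt_bridges`.
#' @export
btb_reference_energies <- function() {
  path <- system.file("extdata", "reference_dimer_energies.tsv", package = "btbdimer")
  if (path == "") abort("bundled reference table not found")
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Compare measured heterodimer energies with the homodimer expectation
#'
#' For each heterodimer row of a component table (see
#' [btb_reference_energies()] for the layout), looks up the two parent
#' homodimer binding energies, forms the expectation as their mean, and
#' scores the preference.
#'
#' @param energies tibble with columns `dimer`, `kind`
#'   (`"homodimer"`/`"heterodimer"`) and `dg_total`; heterodimer `dimer`
#'   names must be `"A-B"` with `A`, `B` matching homodimer rows.
#' @param neutrality_band passed to [heterodimer_preference()].
#' @return tibble: `dimer`, `dg_het`, `dg_expected`, `ddg`, `verdict`.
#' @export
compare_dimers <- function(energies, neutrality_band = 10) {
  energies <- as_tibble(energies)
  homo <- energies %>% filter(.data$kind == "homodimer")
  het <- energies %>% filter(.data$kind == "heterodimer")
  rows <- purrr::pmap(
    list(het$dimer, het$dg_total),
    function(dimer, dg_total) {
      parents <- strsplit(dimer, "-", fixed = TRUE)[[1]]
      if (length(parents) != 2 || !all(parents %in% homo$dimer)) {
        return(tibble(
          dimer = dimer, dg_het = dg_total, dg_expected = NA_real_,
          ddg = NA_real_, verdict = NA_character_
        ))
      }
      dg_a <- homo$dg_total[homo$dimer == parents[1]]
      dg_b <- homo$dg_total[homo$dimer == parents[2]]
      pref <- heterodimer_preference(
        dg_total, expected_heterodimer_dg(dg_a, dg_b), neutrality_band
      )
      tibble(
        dimer = dimer, dg_het = pref$dg_het, dg_expected = pref$dg_expected,
        ddg = pref$ddg, verdict = pref$verdict
      )
    }
  )
  bind_rows(rows)
}
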