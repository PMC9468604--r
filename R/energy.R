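# Canonical per-frame energy components (kcal/mol). nonpolar_sa is optional:
# when an energy log lacks it, it can be derived from SASA via
# nonpolar_from_sasa(); absence is represented by the column being missing,
# never by zeros.
ENERGY_COMPONENTS <- c(
  "bond", "angle", "dihedral", "improper", "elec", "vdw", "gb_polar", "nonpolar_sa"
)
ENERGY_REQUIRED <- setdiff(ENERGY_COMPONENTS, "nonpolar_sa")

# header-name aliases (upper-cased) -> canonical component
ENERGY_ALIASES <- c(
  TS = "frame", FRAME = "frame", STEP = "frame",
  BOND = "bond", ANGLE = "angle", DIHED = "dihedral", DIHEDRAL = "dihedral",
  IMPRP = "improper", IMPROPER = "improper",
  ELECT = "elec", ELEC = "elec",
  VDW = "vdw",
  GB = "gb_polar", GBIS = "gb_polar", GB_POLAR = "gb_polar",
  SASA_ENERGY = "nonpolar_sa", NONPOLAR_SA = "nonpolar_sa", SA = "nonpolar_sa"
)

#' Construct a per-frame energy series
#'
#' @param df data frame with a `frame` column and the energy components
#'   `bond`, `angle`, `dihedral`, `improper`, `elec`, `vdw`, `gb_polar` and
#'   optionally `nonpolar_sa`, all in kcal/mol.
#' @param system_label label of the molecular system (e.g. `"complex"`).
#' @return a tibble of class `energy_series`.
#' @export
energy_series <- function(df, system_label = "system") {
  df <- as_tibble(df)
  missing <- setdiff(c("frame", ENERGY_REQUIRED), names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "energy series lacks columns: ", paste(missing, collapse = ", "),
      "; found: ", paste(names(df), collapse = ", ")
    ))
  }
  keep <- intersect(c("frame", ENERGY_COMPONENTS), names(df))
  df <- df[, keep, drop = FALSE]
  df$frame <- as.integer(df$frame)
  attr(df, "system_label") <- system_label
  class(df) <- c("energy_series", class(tibble()))
  df
}

#' Parse a per-frame energy log
#'
#' Two dialects are read: `"tsv"` (a header line naming the components, then
#' one row per frame; `#` comments allowed) and `"namd-log"` (an
#' `ETITLE:` header naming the column order, followed by `ENERGY:` data
#' lines, as produced by MD engines of the NAMD family). In both dialects
#' columns are mapped by header name, never by position, so permuting columns
#' leaves the result unchanged.
#'
#' @param text path or character vector of lines.
#' @param dialect `"tsv"` or `"namd-log"`.
#' @param system_label label stored on the result.
#' @return an `energy_series` tibble.
#' @export
parse_energy_log <- function(text, dialect = c("tsv", "namd-log"),
                             system_label = "system") {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(text)
  if (dialect == "tsv") {
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) < 2) abort("energy log is empty: no data rows found")
    df <- readr::read_tsv(I(paste(lines, collapse = "\n")), show_col_types = FALSE)
    names(df) <- canonical_energy_names(names(df))
    energy_series(df, system_label)
  } else {
    parse_namd_log(lines, system_label)
  }
}

canonical_energy_names <- function(nm) {
  up <- toupper(trimws(nm))
  mapped <- ENERGY_ALIASES[up]
  ifelse(is.na(mapped), tolower(trimws(nm)), mapped)
}

parse_namd_log <- function(lines, system_label) {
  etitle <- grep("^ETITLE:", lines, value = TRUE)
  energy <- grep("^ENERGY:", lines, value = TRUE)
  if (length(energy) == 0) abort("energy log is empty: no ENERGY: lines found")
  if (length(etitle) == 0) abort("namd-log dialect requires an ETITLE: header before ENERGY: lines")
  header <- strsplit(trimws(sub("^ETITLE:", "", etitle[1])), "\\s+")[[1]]
  cols <- canonical_energy_names(header)
  rows <- lapply(energy, function(l) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(sub("^ENERGY:", "", l)), "\\s+")[[1]]))
    if (length(vals) != length(cols) || anyNA(vals)) {
      abort(sprintf("malformed ENERGY: line: %s", l))
    }
    vals
  })
  df <- as_tibble(setNames(as.data.frame(do.call(rbind, rows)), cols))
  missing <- setdiff(c("frame", ENERGY_REQUIRED), names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "namd-log header lacks required columns: ", paste(missing, collapse = ", "),
      "; found: ", paste(header, collapse = ", ")
    ))
  }
  energy_series(df, system_label)
}

#' Write an energy series as TSV
#'
#' @param es an `energy_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_tsv <- function(es, path) {
  writeLines(sprintf("# energy series: %s", attr(es, "system_label") %||% "system"), path)
  readr::write_tsv(as_tibble(es), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
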