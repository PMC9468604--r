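#' Parse a PDB-format structure into an atom table
#'
#' Reads the `ATOM` records of a PDB file into a tidy atom-level table, one
#' row per atom. `HETATM` records (including waters) are skipped, as are
#' alternate locations other than blank or `'A'`. Residue numbers follow the
#' author numbering of the file; insertion codes, when present, are appended
#' to the residue number in reports.
#'
#' @param text either a path to a PDB file or a character vector of PDB lines
#'   (a single string with embedded newlines is also accepted).
#' @param id structure identifier stored in the `id` attribute.
#' @return a tibble of class `btb_structure` with columns `serial`, `atom`,
#'   `element`, `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`
#'   (coordinates in Angstrom).
#' @export
#' @examples
#' pdb <- c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "END"
#' )
#' parse_pdb(pdb, id = "toy")
parse_pdb <- function(text, id = "structure") {
  lines <- read_text_lines(text)
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec == "ATOM  " | rec == "ATOM")
  if (length(atom_idx) == 0) {
    abort("no ATOM records found: input is empty or not PDB-format")
  }
  al <- lines[atom_idx]
  altloc <- substr(al, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  al <- al[keep]
  ln <- atom_idx[keep]

  xs <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  serial <- suppressWarnings(as.integer(substr(al, 7, 11)))
  resno <- suppressWarnings(as.integer(substr(al, 23, 26)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs) | is.na(resno))
  if (length(bad) > 0) {
    abort(sprintf("malformed ATOM record at line %d", ln[bad[1]]))
  }

  atom <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 20))
  element <- trimws(substr(al, 77, 78))
  element <- ifelse(element == "", guess_element(atom), toupper(element))

  out <- tibble(
    serial = serial,
    atom = atom,
    element = element,
    resname = resname,
    chain = substr(al, 22, 22),
    resno = resno,
    icode = trimws(substr(al, 27, 27)),
    x = xs, y = ys, z = zs
  )
  out <- out[!(out$resname %in% c("HOH", "WAT", "TIP3")), , drop = FALSE]
  if (nrow(out) == 0) abort("no ATOM records left after filtering waters")
  new_structure(out, id = id)
}

#' Construct a structure from an atom table
#'
#' @param df data frame with columns `atom`, `element`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z` (and optionally `serial`, `icode`).
#' @param id structure identifier.
#' @return a `btb_structure` tibble.
#' @export
new_structure <- function(df, id = "structure") {
  df <- as_tibble(df)
  needed <- c("atom", "element", "resname", "chain", "resno", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("structure table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("structure coordinates must be finite")
  }
  if (!"serial" %in% names(df)) df$serial <- seq_len(nrow(df))
  if (!"icode" %in% names(df)) df$icode <- ""
  attr(df, "id") <- id
  class(df) <- c("btb_structure", class(tibble()))
  df
}

read_text_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
}

guess_element <- function(atom_name) {
  first <- substr(gsub("[0-9']", "", atom_name), 1, 1)
  toupper(first)
}

#' Classify a residue by side-chain charge
#'
#' Aspartate and glutamate are acidic; lysine and arginine basic. Histidine is
#' neutral by default (its protonation state at physiological pH is
#' ambiguous); set `his_basic = TRUE` to count it as basic.
#'
#' @param resname character vector of 3-letter residue codes.
#' @param his_basic treat HIS as basic? Default `FALSE`.
#' @return character vector: `"acidic"`, `"basic"` or `"neutral"`.
#' @export
residue_charge_class <- function(resname, his_basic = FALSE) {
  basic <- c("LYS", "ARG", if (his_basic) "HIS")
  dplyr::case_when(
    resname %in% c("ASP", "GLU") ~ "acidic",
    resname %in% basic ~ "basic",
    TRUE ~ "neutral"
  )
}

#' Residue-level summary of a structure
#'
#' @param structure a `btb_structure`.
#' @param his_basic passed to [residue_charge_class()].
#' @return a tibble with one row per residue: `chain`, `resno`, `icode`,
#'   `resname`, `charge_class`, `n_atoms`.
#' @export
structure_residues <- function(structure, his_basic = FALSE) {
  structure %>%
    as_tibble() %>%
    group_by(.data$chain, .data$resno, .data$icode, .data$resname) %>%
    summarise(n_atoms = n(), .groups = "drop") %>%
    mutate(charge_class = residue_charge_class(.data$resname, his_basic)) %>%
    arrange(.data$chain, .data$resno)
}

#' Extract coordinates of selected atoms as a matrix
#'
#' @param structure a `btb_structure`.
#' @param atom atom-name selection, default `"CA"`; `NULL` keeps all atoms.
#' @return numeric matrix (n x 3).
#' @export
atom_coords <- function(structure, atom = "CA") {
  df <- as_tibble(structure)
  if (!is.null(atom)) df <- df[df$atom %in% atom, , drop = FALSE]
  as.matrix(df[, c("x", "y", "z")])
}

#' One-letter amino-acid sequence of a chain
#'
#' @param structure a `btb_structure`.
#' @param chain chain identifier; default first chain.
#' @return single string over the one-letter alphabet (`X` for non-standard).
#' @export
chain_sequence <- function(structure, chain = NULL) {
  df <- as_tibble(structure)
  if (is.null(chain)) chain <- df$chain[1]
  res <- df %>%
    filter(.data$chain == !!chain, .data$atom == "CA") %>%
    arrange(.data$resno)
  paste(aa_three_to_one(res$resname), collapse = "")
}

AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

aa_three_to_one <- function(resname) {
  out <- unname(AA3[resname])
  out[is.na(out)] <- "X"
  out
}

#' Write a structure (or trajectory) in PDB format
#'
#' Coordinates are written at the PDB's fixed 3-decimal precision; trajectory
#' frames become `MODEL`/`ENDMDL` blocks.
#'
#' @param x a `btb_structure` or `btb_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "btb_trajectory")) {
    top <- x$topology
    blocks <- purrr::imap(x$coords, function(m, i) {
      c(sprintf("MODEL     %4d", i), pdb_atom_lines(top, m), "ENDMDL")
    })
    lines <- c(unlist(blocks), "END")
  } else {
    lines <- c(pdb_atom_lines(x, as.matrix(x[, c("x", "y", "z")])), "END")
  }
  writeLines(lines, path)
  invisible(path)
}

pdb_atom_lines <- function(top, coords) {
  name4 <- ifelse(nchar(top$atom) < 4, paste0(" ", top$atom), top$atom)
  sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(top)), name4, " ", top$resname, top$chain, top$resno,
    ifelse(top$icode == "", " ", top$icode),
    coords[, 1], coords[, 2], coords[, 3], 1, 0, top$element
  )
}

#' @export
print.btb_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat(sprintf(
    "<btb_structure '%s': %d atoms, %d residues, chains %s>\n",
    attr(x, "id") %||% "?", nrow(x), nrow(res),
    paste(unique(x$chain), collapse = ",")
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
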