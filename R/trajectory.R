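#' Construct a trajectory from a topology and coordinate frames
#'
#' @param topology a `btb_structure` giving atom identities.
#' @param coords list of numeric matrices (n_atoms x 3), one per frame, in
#'   Angstrom.
#' @param times frame times in ns; strictly increasing. Default
#'   `0, dt, 2 dt, ...`.
#' @param dt_ns frame spacing used when `times` is absent.
#' @return an object of class `btb_trajectory`: a list with elements
#'   `topology`, `coords`, `times`.
#' @export
new_trajectory <- function(topology, coords, times = NULL, dt_ns = 1) {
  if (!inherits(topology, "btb_structure")) topology <- new_structure(topology)
  n_atoms <- nrow(topology)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  bad <- which(vapply(coords, nrow, 0L) != n_atoms)
  if (length(bad) > 0) {
    abort(sprintf(
      "frame %d has %d atoms; topology has %d",
      bad[1], nrow(coords[[bad[1]]]), n_atoms
    ))
  }
  if (is.null(times)) times <- (seq_along(coords) - 1) * dt_ns
  if (length(times) != length(coords)) abort("times must have one entry per frame")
  if (length(times) > 1 && any(diff(times) <= 0)) abort("times must be strictly increasing")
  structure(
    list(topology = topology, coords = coords, times = as.numeric(times)),
    class = "btb_trajectory"
  )
}

#' @export
print.btb_trajectory <- function(x, ...) {
  cat(sprintf(
    "<btb_trajectory: %d frames x %d atoms, %.3g-%.3g ns>\n",
    n_frames(x), nrow(x$topology), min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `btb_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Parse a multi-frame trajectory
#'
#' Two plain-text dialects are supported: a multi-model PDB (frames delimited
#' by `MODEL`/`ENDMDL`, all models sharing model 1's atom ordering) and a
#' tab-separated coordinate table with columns `frame`, `atom_index`, `x`,
#' `y`, `z` (Angstrom; `#` starts a comment; an optional `time_ns` column
#' carries frame times).
#'
#' @param source path or character vector of lines.
#' @param dialect `"multi-model-pdb"` or `"coord-tsv"`.
#' @param topology required for the `coord-tsv` dialect (the table carries no
#'   atom identities).
#' @param dt_ns frame spacing (ns) used when the source carries no times.
#' @return a `btb_trajectory`.
#' @export
parse_trajectory <- function(source, dialect = c("multi-model-pdb", "coord-tsv"),
                             topology = NULL, dt_ns = 1) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(source)
  if (dialect == "multi-model-pdb") {
    parse_traj_pdb(lines, dt_ns)
  } else {
    parse_traj_tsv(lines, topology, dt_ns)
  }
}

parse_traj_pdb <- function(lines, dt_ns) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    # single-model file: one frame
    s <- parse_pdb(lines)
    return(new_trajectory(s, list(as.matrix(s[, c("x", "y", "z")])), dt_ns = dt_ns))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) abort("unbalanced MODEL/ENDMDL records")
  first <- parse_pdb(lines[(starts[1] + 1):(ends[1] - 1)])
  coords <- vector("list", length(starts))
  coords[[1]] <- as.matrix(first[, c("x", "y", "z")])
  for (i in seq_along(starts)[-1]) {
    s <- parse_pdb(lines[(starts[i] + 1):(ends[i] - 1)])
    if (nrow(s) != nrow(first)) {
      abort(sprintf("model %d has %d atoms; model 1 has %d", i, nrow(s), nrow(first)))
    }
    coords[[i]] <- as.matrix(s[, c("x", "y", "z")])
  }
  new_trajectory(first, coords, dt_ns = dt_ns)
}

parse_traj_tsv <- function(lines, topology, dt_ns) {
  df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
    comment = "#", show_col_types = FALSE
  )
  needed <- c("frame", "atom_index", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("coord-tsv lacks columns: ", paste(missing, collapse = ", ")))
  }
  frames <- sort(unique(df$frame))
  n_atoms <- length(unique(df$atom_index))
  if (is.null(topology)) {
    # placeholder topology: one pseudo-CA per atom index
    topology <- new_structure(tibble(
      serial = seq_len(n_atoms), atom = "CA", element = "C", resname = "ALA",
      chain = "A", resno = seq_len(n_atoms), icode = "",
      x = 0, y = 0, z = 0
    ))
  }
  coords <- lapply(frames, function(f) {
    sub <- df[df$frame == f, , drop = FALSE]
    if (nrow(sub) != nrow(topology)) {
      abort(sprintf("frame %s has %d atoms; topology has %d", f, nrow(sub), nrow(topology)))
    }
    sub <- sub[order(sub$atom_index), , drop = FALSE]
    as.matrix(sub[, c("x", "y", "z")])
  })
  times <- if ("time_ns" %in% names(df)) {
    vapply(frames, function(f) df$time_ns[df$frame == f][1], 0)
  } else {
    (seq_along(frames) - 1) * dt_ns
  }
  new_trajectory(topology, coords, times = times)
}

#' Write a trajectory as a coordinate TSV
#'
#' Emits the `coord-tsv` dialect read by [parse_trajectory()]: columns
#' `frame`, `atom_index`, `x`, `y`, `z`, `time_ns`, with a `#` metadata
#' header. Deterministic row and column order.
#'
#' @param traj a `btb_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  rows <- purrr::imap(traj$coords, function(m, i) {
    tibble(
      frame = i - 1L, atom_index = seq_len(nrow(m)) - 1L,
      x = m[, 1], y = m[, 2], z = m[, 3], time_ns = traj$times[i]
    )
  })
  df <- bind_rows(rows)
  writeLines(sprintf("# coord-tsv: %d frames x %d atoms", n_frames(traj), nrow(traj$topology)), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
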