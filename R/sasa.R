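# van der Waals radii (Angstrom) by element, Bondi-style values commonly
# used for SASA. Unknown elements are an error, never silently defaulted.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

# Deterministic quasi-uniform unit-sphere points (Fibonacci spiral). No RNG:
# the same n gives bit-identical SASA on every run.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over each atom's van der Waals sphere, sampled with a
#' fixed Fibonacci-spiral point set: a surface point is accessible when it
#' lies outside every neighbouring atom's probe-expanded sphere. The per-atom
#' area is the accessible fraction of `4 pi (r + probe)^2`.
#'
#' @param topology a `btb_structure` (elements supply radii).
#' @param coords optional frame coordinates (n_atoms x 3); defaults to the
#'   topology's coordinates.
#' @param probe probe radius in Angstrom, default 1.4 (water).
#' @param n_points sphere sample points per atom, default 960.
#' @return atom-level tibble: topology identity columns plus `sasa` (A^2).
#' @seealso [residue_sasa()] to aggregate per residue.
#' @export
shrake_rupley_sasa <- function(topology, coords = NULL, probe = 1.4, n_points = 960) {
  df <- as_tibble(topology)
  if (is.null(coords)) coords <- as.matrix(df[, c("x", "y", "z")])
  coords <- as.matrix(coords)
  radii <- VDW_RADII[toupper(df$element)]
  if (anyNA(radii)) {
    bad <- which(is.na(radii))[1]
    abort(sprintf(
      "no van der Waals radius for element '%s' (atom %s %s%d)",
      df$element[bad], df$atom[bad], df$chain[bad], df$resno[bad]
    ))
  }
  n <- nrow(coords)
  pts <- fibonacci_sphere(n_points)
  ext <- unname(radii) + probe
  area <- numeric(n)
  # neighbour lists via squared-distance cutoff on expanded radii
  maxext <- max(ext)
  for (i in seq_len(n)) {
    ri <- ext[i]
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (ri + ext)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * ri^2
      next
    }
    sp <- pts * ri
    sp <- sweep(sp, 2, coords[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb[order(d2[nb])]) {
      if (!any(accessible)) break
      dj2 <- (sp[, 1] - coords[j, 1])^2 + (sp[, 2] - coords[j, 2])^2 +
        (sp[, 3] - coords[j, 3])^2
      accessible <- accessible & (dj2 >= ext[j]^2)
    }
    area[i] <- 4 * pi * ri^2 * sum(accessible) / n_points
  }
  df$sasa <- area
  df
}

#' Aggregate atom-level SASA per residue
#'
#' @param atom_sasa output of [shrake_rupley_sasa()].
#' @return tibble with `chain`, `resno`, `resname`, `sasa` (A^2).
#' @export
residue_sasa <- function(atom_sasa) {
  atom_sasa %>%
    group_by(.data$chain, .data$resno, .data$resname) %>%
    summarise(sasa = sum(.data$sasa), .groups = "drop") %>%
    arrange(.data$chain, .data$resno)
}

default_chain_split <- function(topology, chain_split) {
  chains <- unique(topology$chain)
  if (is.null(chain_split)) {
    if (length(chains) != 2) {
      abort(sprintf(
        "topology has %d chain(s); supply an explicit chain_split = list(a = ..., b = ...)",
        length(chains)
      ))
    }
    chain_split <- list(a = chains[1], b = chains[2])
  }
  if (!all(c("a", "b") %in% names(chain_split))) {
    abort("chain_split must be a list with elements 'a' and 'b'")
  }
  chain_split
}

#' Buried-surface-area series of a dimer trajectory
#'
#' At each frame the complex SASA and the SASA of each monomer in isolation
#' (at the same complex-frame coordinates, the single-trajectory convention)
#' are computed, and the buried surface area is
#' `BSA = SASA(a) + SASA(b) - SASA(complex)`, non-negative for bound dimers
#' up to numerical tolerance.
#'
#' @param traj a `btb_trajectory` of the complex.
#' @param chain_split list `list(a = chains, b = chains)` partitioning the
#'   topology; defaults to the two chains of a two-chain topology.
#' @param probe,n_points passed to [shrake_rupley_sasa()].
#' @param frames optional subset of 1-based frame indices to evaluate.
#' @return object of class `bsa_summary`: list with `per_frame` (tibble:
#'   `frame`, `time_ns`, `sasa_complex`, `sasa_a`, `sasa_b`, `bsa`, all A^2)
#'   and `min`, `max`, `mean` of BSA.
#' @export
bsa_series <- function(traj, chain_split = NULL, probe = 1.4, n_points = 960,
                       frames = NULL) {
  top <- as_tibble(traj$topology)
  chain_split <- default_chain_split(top, chain_split)
  ia <- which(top$chain %in% chain_split$a)
  ib <- which(top$chain %in% chain_split$b)
  if (length(ia) == 0 || length(ib) == 0) abort("chain_split selects no atoms for one side")
  if (length(intersect(ia, ib)) > 0) abort("chain_split sides overlap")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  top_a <- new_structure(top[ia, , drop = FALSE])
  top_b <- new_structure(top[ib, , drop = FALSE])
  rows <- lapply(frames, function(f) {
    m <- traj$coords[[f]]
    sc <- sum(shrake_rupley_sasa(traj$topology, m, probe, n_points)$sasa)
    sa <- sum(shrake_rupley_sasa(top_a, m[ia, , drop = FALSE], probe, n_points)$sasa)
    sb <- sum(shrake_rupley_sasa(top_b, m[ib, , drop = FALSE], probe, n_points)$sasa)
    tibble(
      frame = f, time_ns = traj$times[f],
      sasa_complex = sc, sasa_a = sa, sasa_b = sb, bsa = sa + sb - sc
    )
  })
  per_frame <- bind_rows(rows)
  structure(
    list(
      per_frame = per_frame,
      min = min(per_frame$bsa), max = max(per_frame$bsa), mean = mean(per_frame$bsa)
    ),
    class = "bsa_summary"
  )
}

#' @export
print.bsa_summary <- function(x, ...) {
  cat(sprintf(
    "<bsa_summary: %d frames; BSA min %.0f, max %.0f, mean %.0f A^2>\n",
    nrow(x$per_frame), x$min, x$max, x$mean
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bsa_summary <- function(x, ...) x$per_frame

#' @exportS3Method ggplot2::autoplot
autoplot.bsa_summary <- function(object, ...) {
  df <- object$per_frame %>%
    tidyr::pivot_longer(c("sasa_complex", "sasa_a", "sasa_b", "bsa"),
      names_to = "series", values_to = "area"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ns, .data$area, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(
      sasa_complex = "firebrick", sasa_a = "grey20", sasa_b = "grey60",
      bsa = "forestgreen"
    )) +
    ggplot2::labs(x = "time (ns)", y = expression("area (" * ring(A)^2 * ")")) +
    ggplot2::theme_classic()
}

#' Interface residues and interface percentage
#'
#' A residue belongs to the dimer interface when its window-mean buried area
#' (its SASA in the isolated monomer minus its SASA in the complex, at the
#' same coordinates) exceeds a small threshold. The interface percentage is
#' `100 x interface residues / total residues` of the dimer.
#'
#' @param traj a `btb_trajectory` of the complex.
#' @param window a [frame_window()] or `NULL` for all frames.
#' @param per_residue_bsa_threshold threshold in A^2, default 0.1.
#' @param chain_split,probe,n_points as in [bsa_series()].
#' @return list with `residues` (per-residue tibble with `mean_buried` and
#'   logical `interface`) and `pct_interface`.
#' @export
interface_residues <- function(traj, window = NULL, per_residue_bsa_threshold = 0.1,
                               chain_split = NULL, probe = 1.4, n_points = 960) {
  top <- as_tibble(traj$topology)
  chain_split <- default_chain_split(top, chain_split)
  ia <- which(top$chain %in% chain_split$a)
  ib <- which(top$chain %in% chain_split$b)
  top_a <- new_structure(top[ia, , drop = FALSE])
  top_b <- new_structure(top[ib, , drop = FALSE])
  frames <- window_frame_indices(window, n_frames(traj))
  acc <- NULL
  for (f in frames) {
    m <- traj$coords[[f]]
    rc <- residue_sasa(shrake_rupley_sasa(traj$topology, m, probe, n_points))
    rm_ <- bind_rows(
      residue_sasa(shrake_rupley_sasa(top_a, m[ia, , drop = FALSE], probe, n_points)),
      residue_sasa(shrake_rupley_sasa(top_b, m[ib, , drop = FALSE], probe, n_points))
    )
    joined <- left_join(rc, rename(rm_, sasa_mono = "sasa"),
      by = c("chain", "resno", "resname")
    ) %>%
      mutate(buried = .data$sasa_mono - .data$sasa)
    acc <- if (is.null(acc)) {
      joined %>% select("chain", "resno", "resname") %>% mutate(sum_buried = joined$buried)
    } else {
      mutate(acc, sum_buried = .data$sum_buried + joined$buried)
    }
  }
  residues <- acc %>%
    mutate(
      mean_buried = .data$sum_buried / length(frames),
      interface = .data$mean_buried > per_residue_bsa_threshold
    ) %>%
    select("chain", "resno", "resname", "mean_buried", "interface")
  list(
    residues = residues,
    pct_interface = 100 * sum(residues$interface) / nrow(residues)
  )
}
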