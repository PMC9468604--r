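# Side-chain heavy atoms that carry the formal charge. A salt bridge is an
# acidic carboxylate oxygen within the cutoff of a basic side-chain nitrogen;
# backbone termini are not counted.
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
HIS_ATOMS <- c("ND1", "NE2")

charged_atom_table <- function(topology, his_basic = FALSE) {
  df <- as_tibble(topology)
  basic_atoms <- BASIC_ATOMS
  if (his_basic) basic_atoms$HIS <- HIS_ATOMS
  pick <- function(sets) {
    keep <- rep(FALSE, nrow(df))
    for (rn in names(sets)) {
      keep <- keep | (df$resname == rn & df$atom %in% sets[[rn]])
    }
    out <- df[keep, , drop = FALSE]
    out$.row <- which(keep)
    out
  }
  list(acidic = pick(ACIDIC_ATOMS), basic = pick(basic_atoms))
}

# charged residues whose needed side-chain atoms are absent from the topology
missing_sidechain_residues <- function(topology, his_basic = FALSE) {
  res <- structure_residues(topology, his_basic = his_basic)
  charged <- res[res$charge_class != "neutral", , drop = FALSE]
  if (nrow(charged) == 0) return(charged)
  ch <- charged_atom_table(topology, his_basic)
  have <- bind_rows(ch$acidic, ch$basic) %>%
    distinct(.data$chain, .data$resno)
  dplyr::anti_join(charged, have, by = c("chain", "resno"))
}

#' Detect salt bridges in one coordinate frame
#'
#' A pair of residues forms a salt bridge when the minimum distance between
#' the acidic side-chain carboxylate oxygens (Asp OD1/OD2, Glu OE1/OE2) and
#' the basic side-chain nitrogens (Lys NZ, Arg NE/NH1/NH2; optionally His
#' ND1/NE2) is within the cutoff. Charged residues whose side-chain atoms are
#' absent from the topology are skipped with a note, never silently counted.
#'
#' @param topology a `btb_structure` carrying atom identities.
#' @param coords optional frame coordinates (n_atoms x 3); defaults to the
#'   topology's own coordinates.
#' @param cutoff_angstrom heavy-atom distance cutoff, default 3.0.
#' @param interchain_only keep only cross-chain pairs (default `TRUE`).
#' @param his_basic count histidine as basic? Default `FALSE`.
#' @return tibble with one row per bridged pair: acidic and basic residue
#'   identity, chains, and the minimum heavy-atom distance.
#' @export
detect_salt_bridges <- function(topology, coords = NULL, cutoff_angstrom = 3.0,
                                interchain_only = TRUE, his_basic = FALSE) {
  df <- as_tibble(topology)
  if (is.null(coords)) {
    coords <- as.matrix(df[, c("x", "y", "z")])
  }
  miss <- missing_sidechain_residues(topology, his_basic)
  if (nrow(miss) > 0) {
    inform(paste0(
      "charged residues without side-chain atoms skipped: ",
      paste(paste0(miss$resname, miss$resno, miss$chain), collapse = ", ")
    ))
  }
  ch <- charged_atom_table(topology, his_basic)
  empty <- tibble(
    acidic_chain = character(), acidic_resno = integer(), acidic_resname = character(),
    basic_chain = character(), basic_resno = integer(), basic_resname = character(),
    min_dist = numeric()
  )
  if (nrow(ch$acidic) == 0 || nrow(ch$basic) == 0) return(empty)
  pa <- coords[ch$acidic$.row, , drop = FALSE]
  pb <- coords[ch$basic$.row, , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  pairs <- tibble(
    acidic_chain = rep(ch$acidic$chain, times = nrow(ch$basic)),
    acidic_resno = rep(ch$acidic$resno, times = nrow(ch$basic)),
    acidic_resname = rep(ch$acidic$resname, times = nrow(ch$basic)),
    basic_chain = rep(ch$basic$chain, each = nrow(ch$acidic)),
    basic_resno = rep(ch$basic$resno, each = nrow(ch$acidic)),
    basic_resname = rep(ch$basic$resname, each = nrow(ch$acidic)),
    dist = sqrt(as.numeric(d2))
  )
  out <- pairs %>%
    group_by(across(c(
      "acidic_chain", "acidic_resno", "acidic_resname",
      "basic_chain", "basic_resno", "basic_resname"
    ))) %>%
    summarise(min_dist = min(.data$dist), .groups = "drop") %>%
    filter(.data$min_dist <= cutoff_angstrom)
  if (interchain_only) out <- filter(out, .data$acidic_chain != .data$basic_chain)
  arrange(out, .data$acidic_chain, .data$acidic_resno, .data$basic_chain, .data$basic_resno)
}

# Fig-style residue label: one-letter code + author number + chain tag, chain
# tags a, b, ... in topology chain order; pair printed chain-a residue first.
bridge_pair_label <- function(acidic_resname, acidic_resno, acidic_chain,
                              basic_resname, basic_resno, basic_chain,
                              chain_levels) {
  tag <- function(ch) letters[match(ch, chain_levels)]
  a_lab <- paste0(aa_three_to_one(acidic_resname), acidic_resno, tag(acidic_chain))
  b_lab <- paste0(aa_three_to_one(basic_resname), basic_resno, tag(basic_chain))
  ifelse(tag(acidic_chain) <= tag(basic_chain),
    paste0(a_lab, "-", b_lab), paste0(b_lab, "-", a_lab)
  )
}

#' Salt-bridge occupancy barcode over a trajectory
#'
#' Every interchain acidic-basic pair observed within the cutoff in any frame
#' gets a presence vector over all frames and an occupancy (the fraction of
#' frames in which it is formed). Occupancy is computed over the full
#' trajectory, not only an equilibrated window, and pairs below
#' `min_occupancy` (default 8 percent of the run) are dropped from the
#' report.
#'
#' @param traj a `btb_trajectory`.
#' @param cutoff_angstrom heavy-atom cutoff, default 3.0.
#' @param min_occupancy minimum reported occupancy fraction, default 0.08.
#' @param interchain_only,his_basic passed to [detect_salt_bridges()].
#' @return tibble of class `bridge_barcode`: one row per retained pair with
#'   `pair` label (e.g. `"R39a-D42b"`), residue identities, `occupancy`, and
#'   a `presence` list-column of logical vectors over frames.
#' @export
bridge_barcode <- function(traj, cutoff_angstrom = 3.0, min_occupancy = 0.08,
                           interchain_only = TRUE, his_basic = FALSE) {
  nf <- n_frames(traj)
  if (nf == 0) abort("trajectory has no frames")
  per_frame <- withCallingHandlers(
    lapply(traj$coords, function(m) {
      detect_salt_bridges(traj$topology, m, cutoff_angstrom, interchain_only, his_basic)
    }),
    message = function(m) invokeRestart("muffleMessage")
  )
  key_cols <- c(
    "acidic_chain", "acidic_resno", "acidic_resname",
    "basic_chain", "basic_resno", "basic_resname"
  )
  all_pairs <- distinct(bind_rows(per_frame)[, key_cols])
  chain_levels <- unique(traj$topology$chain)
  if (nrow(all_pairs) == 0) {
    out <- tibble(
      pair = character(), all_pairs[0, ],
      occupancy = numeric(), presence = list()
    )
  } else {
    keys <- do.call(paste, all_pairs)
    presence <- lapply(seq_len(nrow(all_pairs)), function(i) logical(nf))
    for (f in seq_len(nf)) {
      if (nrow(per_frame[[f]]) == 0) next
      hit <- match(do.call(paste, per_frame[[f]][, key_cols]), keys)
      for (h in hit) presence[[h]][f] <- TRUE
    }
    out <- all_pairs %>%
      mutate(
        pair = bridge_pair_label(
          .data$acidic_resname, .data$acidic_resno, .data$acidic_chain,
          .data$basic_resname, .data$basic_resno, .data$basic_chain,
          chain_levels
        ),
        occupancy = vapply(presence, mean, 0),
        presence = presence
      ) %>%
      select("pair", dplyr::all_of(key_cols), "occupancy", "presence") %>%
      filter(.data$occupancy >= min_occupancy) %>%
      arrange(dplyr::desc(.data$occupancy), .data$pair)
  }
  attr(out, "times") <- traj$times
  attr(out, "cutoff_angstrom") <- cutoff_angstrom
  attr(out, "min_occupancy") <- min_occupancy
  class(out) <- c("bridge_barcode", class(tibble()))
  out
}

#' Mean number of interchain salt bridges over a window
#'
#' Counts interchain acidic-basic pairs within the cutoff in each frame of
#' the window and reports mean and standard error (sample SD / sqrt(n)).
#'
#' @param traj a `btb_trajectory`.
#' @param window a [frame_window()] in 1-based frame numbering, or `NULL` for
#'   the full run.
#' @param cutoff_angstrom heavy-atom cutoff, default 3.0.
#' @param his_basic count histidine as basic? Default `FALSE`.
#' @return one-row tibble: `mean`, `se`, `n_frames`.
#' @export
avg_interface_salt_bridges <- function(traj, window = NULL, cutoff_angstrom = 3.0,
                                       his_basic = FALSE) {
  frames <- window_frame_indices(window, n_frames(traj))
  if (length(frames) == 0) abort("window contains no frames")
  counts <- vapply(frames, function(f) {
    nrow(suppressMessages(detect_salt_bridges(
      traj$topology, traj$coords[[f]], cutoff_angstrom,
      interchain_only = TRUE, his_basic = his_basic
    )))
  }, 0L)
  tibble(
    mean = mean(counts),
    se = if (length(counts) > 1) sd(counts) / sqrt(length(counts)) else 0,
    n_frames = length(counts)
  )
}

window_frame_indices <- function(window, n) {
  if (is.null(window)) return(seq_len(n))
  if (!inherits(window, "frame_window")) abort("window must be a frame_window or NULL")
  if (window$start_frame < 1 || window$end_frame > n) {
    abort(sprintf("window [%d, %d] outside trajectory bounds [1, %d]",
                  window$start_frame, window$end_frame, n))
  }
  seq(window$start_frame, window$end_frame)
}

#' @exportS3Method ggplot2::autoplot
autoplot.bridge_barcode <- function(object, ...) {
  times <- attr(object, "times")
  df <- object %>%
    mutate(pair = factor(.data$pair, levels = rev(.data$pair))) %>%
    tidyr::unnest_longer(.data$presence, indices_to = "frame") %>%
    filter(.data$presence) %>%
    mutate(time_ns = times[.data$frame])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ns, .data$pair)) +
    ggplot2::geom_tile(width = diff(range(times)) / length(times), fill = "grey20") +
    ggplot2::labs(x = "time (ns)", y = NULL) +
    ggplot2::theme_classic()
}
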