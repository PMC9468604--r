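# Synthetic-data generators. Each generator is deterministic given its seed
# and returns the quantities it planted (the "truth") alongside the data, so
# downstream recovery tests read the truth from the generator, never from
# hard-coded numbers.

#' Build an idealized two-chain dimer with planted salt-bridge contacts
#'
#' Two parallel pseudo-backbones (chains A and B, one Calpha per 3.8
#' Angstrom) with minimal side-chain atoms. `n_contacts` acidic-basic pairs
#' (Asp/Glu on A, Lys/Arg on B) are placed so their charged side-chain atoms
#' face each other across the interface at 2.8 Angstrom; all other residues
#' are alanine with side chains pointing away from the interface, so no
#' accidental bridges arise.
#'
#' @param n_residues_per_chain residues per chain, >= 4.
#' @param n_contacts number of planted interchain salt bridges; must fit on
#'   the chain.
#' @param seed RNG seed (placement of contacts and residue identities).
#' @return a `btb_structure` with a `contacts` attribute: a tibble naming
#'   each planted pair's residues and charged atoms.
#' @export
make_toy_dimer <- function(n_residues_per_chain = 12, n_contacts = 2, seed = 1) {
  n <- n_residues_per_chain
  if (n < 4) abort("n_residues_per_chain must be >= 4")
  if (n_contacts < 0 || n_contacts > n) {
    abort(sprintf("cannot place %d contacts on chains of %d residues", n_contacts, n))
  }
  with_seed(seed, {
    pos <- sort(sample.int(n, n_contacts))
    acid <- sample(c("ASP", "GLU"), n_contacts, replace = TRUE)
    base <- sample(c("LYS", "ARG"), n_contacts, replace = TRUE)

    rows <- list()
    add <- function(chain, resno, resname, atom, x, y, z) {
      rows[[length(rows) + 1]] <<- tibble(
        atom = atom, element = guess_element(atom), resname = resname,
        chain = chain, resno = resno, icode = "", x = x, y = y, z = z
      )
    }
    acid_o <- c(ASP = "OD1", GLU = "OE1")
    base_n <- c(LYS = "NZ", ARG = "NH1")
    for (i in seq_len(n)) {
      xi <- 3.8 * (i - 1)
      zi <- 0.5 * (-1)^i # zig-zag so Calpha sets are not collinear
      k <- match(i, pos)
      if (!is.na(k)) {
        add("A", i, acid[k], "CA", xi, 0, zi)
        add("A", i, acid[k], "CB", xi, 1.5, zi)
        add("A", i, acid[k], acid_o[acid[k]], xi, 3.0, zi)
        add("B", i, base[k], "CA", xi, 9.0, zi)
        add("B", i, base[k], "CB", xi, 7.5, zi)
        add("B", i, base[k], base_n[base[k]], xi, 5.8, zi)
      } else {
        add("A", i, "ALA", "CA", xi, 0, zi)
        add("A", i, "ALA", "CB", xi, -1.5, zi)
        add("B", i, "ALA", "CA", xi, 9.0, zi)
        add("B", i, "ALA", "CB", xi, 10.5, zi)
      }
    }
    df <- bind_rows(rows)
    df$serial <- seq_len(nrow(df))
    s <- new_structure(df, id = sprintf("toy_dimer_seed%d", seed))
    attr(s, "contacts") <- tibble(
      position = pos,
      acidic_chain = "A", acidic_resno = pos, acidic_resname = acid,
      acidic_atom = unname(acid_o[acid]),
      basic_chain = "B", basic_resno = pos, basic_resname = base,
      basic_atom = unname(base_n[base])
    )
    s
  })
}

#' Simulate a dimer trajectory with planted bridge occupancies
#'
#' Each planted bridge toggles independently per frame (Bernoulli with its
#' occupancy) between a formed geometry (2.8 Angstrom) and a broken one
#' (4.5 Angstrom), realized by moving the basic side-chain nitrogen along
#' the interface normal. The neutral residues carry a deformation field
#' whose magnitude ramps linearly to a plateau and then stays, plus frame
#' noise, giving the drifting-then-stable Calpha RMSD profile typical of a
#' run that equilibrates.
#'
#' @param dimer output of [make_toy_dimer()].
#' @param occupancies per-contact occupancy in `[0, 1]`, recycled; default 1.
#' @param n_frames frames, default 500.
#' @param plateau_angstrom plateau deformation magnitude, default 3.
#' @param onset_frac fraction of the run over which the drift ramps,
#'   default 0.4.
#' @param noise_sd frame-to-frame magnitude noise (Angstrom), default 0.1.
#' @param dt_ns frame spacing (ns), default 1.
#' @param formed_dist,broken_dist bridge O-N distances (Angstrom).
#' @param seed RNG seed.
#' @return list: `trajectory` (a `btb_trajectory`) and `truth`. The truth's
#'   `bridges` table carries both the planted Bernoulli `occupancy` and the
#'   `realized_occupancy` actually written into the coordinates (their
#'   difference is the generator's own binomial noise, about
#'   `sqrt(p (1 - p) / n_frames)`); rmsd profile parameters and the seed are
#'   recorded alongside.
#' @export
simulate_trajectory <- function(dimer, occupancies = 1, n_frames = 500,
                                plateau_angstrom = 3, onset_frac = 0.4,
                                noise_sd = 0.1, dt_ns = 1,
                                formed_dist = 2.8, broken_dist = 4.5, seed = 1) {
  contacts <- attr(dimer, "contacts")
  if (is.null(contacts)) abort("dimer carries no contacts attribute; use make_toy_dimer()")
  nc <- nrow(contacts)
  occupancies <- rep_len(occupancies, max(nc, 1))[seq_len(nc)]
  if (nc > 0 && (any(occupancies < 0) || any(occupancies > 1))) {
    abort("occupancies must lie in [0, 1]")
  }
  top <- as_tibble(dimer)
  x0 <- as.matrix(top[, c("x", "y", "z")])
  onset <- max(2L, as.integer(round(onset_frac * n_frames)))

  acid_row <- integer(nc)
  base_row <- integer(nc)
  for (k in seq_len(nc)) {
    acid_row[k] <- which(top$chain == contacts$acidic_chain[k] &
      top$resno == contacts$acidic_resno[k] & top$atom == contacts$acidic_atom[k])
    base_row[k] <- which(top$chain == contacts$basic_chain[k] &
      top$resno == contacts$basic_resno[k] & top$atom == contacts$basic_atom[k])
  }
  deform_rows <- which(top$resname == "ALA")

  with_seed(seed, {
    dirs <- matrix(rnorm(length(deform_rows) * 3), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    formed <- if (nc > 0) {
      matrix(runif(n_frames * nc) < rep(occupancies, each = n_frames), nrow = n_frames)
    }
    mags <- plateau_angstrom * pmin((seq_len(n_frames) - 1) / (onset - 1), 1) +
      rnorm(n_frames, 0, noise_sd)
    mags <- pmax(mags, 0)
    coords <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      m <- x0
      m[deform_rows, ] <- m[deform_rows, ] + dirs * mags[t]
      for (k in seq_len(nc)) {
        d <- if (formed[t, k]) formed_dist else broken_dist
        m[base_row[k], ] <- m[acid_row[k], ] + c(0, d, 0)
      }
      coords[[t]] <- m
    }
    traj <- new_trajectory(dimer, coords, dt_ns = dt_ns)
    realized <- if (nc > 0) colMeans(formed) else numeric(0)
    truth <- list(
      bridges = contacts %>%
        mutate(occupancy = occupancies, realized_occupancy = realized),
      rmsd = list(
        onset_frame = onset, plateau_angstrom = plateau_angstrom,
        noise_sd = noise_sd
      ),
      n_frames = n_frames, dt_ns = dt_ns, seed = seed
    )
    list(trajectory = traj, truth = truth)
  })
}

#' Simulate complex/monomer energy-log triples with planted deltas
#'
#' Monomer components are i.i.d. normal around arbitrary fixed baselines;
#' the complex is the realized monomer sum plus the planted per-component
#' delta plus noise, so the recoverable delta of each component is exactly
#' the planted mean with standard error `delta_sd / sqrt(n)`.
#'
#' @param delta_means named numeric of planted component deltas (kcal/mol);
#'   defaults resemble a strongly bound BTB homodimer.
#' @param delta_sds per-frame delta noise SDs, recycled over components;
#'   default 5.
#' @param n_frames frames, default 1000.
#' @param monomer_sd monomer baseline noise SD, default 2.
#' @param seed RNG seed.
#' @return list: `complex`, `mon_a`, `mon_b` (`energy_series`) and `truth`.
#' @export
simulate_energy_logs <- function(delta_means = c(
                                   bond = -150, angle = -120, dihedral = -70,
                                   improper = -13.9, elec = -418, vdw = -194.3,
                                   gb_polar = 437.1, nonpolar_sa = 0
                                 ),
                                 delta_sds = 5, n_frames = 1000,
                                 monomer_sd = 2, seed = 1) {
  comps <- names(delta_means)
  if (is.null(comps) || !all(comps %in% ENERGY_COMPONENTS)) {
    abort(paste0("delta_means must be named with components among: ",
      paste(ENERGY_COMPONENTS, collapse = ", ")))
  }
  missing <- setdiff(ENERGY_REQUIRED, comps)
  if (length(missing) > 0) {
    abort(paste0("delta_means lacks components: ", paste(missing, collapse = ", ")))
  }
  delta_sds <- rep_len(delta_sds, length(comps))
  if (any(delta_sds < 0)) abort("delta_sds must be >= 0")
  with_seed(seed, {
    baseline_a <- round(runif(length(comps), -500, 500), 1)
    baseline_b <- round(runif(length(comps), -500, 500), 1)
    mk <- function() tibble(frame = seq_len(n_frames) - 1L)
    a <- mk()
    b <- mk()
    cx <- mk()
    for (i in seq_along(comps)) {
      cc <- comps[i]
      a[[cc]] <- baseline_a[i] + rnorm(n_frames, 0, monomer_sd)
      b[[cc]] <- baseline_b[i] + rnorm(n_frames, 0, monomer_sd)
      cx[[cc]] <- a[[cc]] + b[[cc]] + delta_means[i] + rnorm(n_frames, 0, delta_sds[i])
    }
    list(
      complex = energy_series(cx, "complex"),
      mon_a = energy_series(a, "monomer_a"),
      mon_b = energy_series(b, "monomer_b"),
      truth = list(
        delta_means = as.list(delta_means),
        delta_sds = as.list(setNames(delta_sds, comps)),
        n_frames = n_frames, monomer_sd = monomer_sd, seed = seed
      )
    )
  })
}

#' Simulate lineage-structured expression with planted correlations
#'
#' Baseline expression is i.i.d. log-normal; each planted pair's values in
#' its lineage are drawn from a bivariate normal on the log scale achieving
#' the stated population correlation.
#'
#' @param genes gene names.
#' @param lineages lineage names.
#' @param samples_per_lineage samples per lineage, >= 3.
#' @param planted optional tibble `gene_a`, `gene_b`, `lineage`, `r`
#'   (population correlation, `|r| < 1`).
#' @param log_mean,log_sd log-scale baseline parameters.
#' @param seed RNG seed.
#' @return list: `exprs` (genes x samples matrix), `samples` (tibble
#'   `sample`, `lineage`), `truth`.
#' @export
simulate_expression <- function(genes, lineages, samples_per_lineage = 10,
                                planted = NULL, log_mean = 5, log_sd = 1,
                                seed = 1) {
  if (samples_per_lineage < 3) abort("samples_per_lineage must be >= 3")
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (any(abs(planted$r) >= 1)) abort("planted correlations must satisfy |r| < 1")
    bad_g <- setdiff(c(planted$gene_a, planted$gene_b), genes)
    if (length(bad_g) > 0) abort(sprintf("planted names unknown gene: %s", bad_g[1]))
    bad_l <- setdiff(planted$lineage, lineages)
    if (length(bad_l) > 0) abort(sprintf("planted names unknown lineage: %s", bad_l[1]))
  }
  samples <- tidyr::expand_grid(lineage = lineages, i = seq_len(samples_per_lineage)) %>%
    mutate(sample = paste0(gsub("[^A-Za-z0-9]", "_", .data$lineage), "_", .data$i)) %>%
    select("sample", "lineage")
  with_seed(seed, {
    m <- matrix(
      exp(rnorm(length(genes) * nrow(samples), log_mean, log_sd)),
      nrow = length(genes),
      dimnames = list(genes, samples$sample)
    )
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        cols <- samples$sample[samples$lineage == planted$lineage[i]]
        z1 <- rnorm(length(cols))
        z2 <- planted$r[i] * z1 + sqrt(1 - planted$r[i]^2) * rnorm(length(cols))
        m[planted$gene_a[i], cols] <- exp(log_mean + log_sd * z1)
        m[planted$gene_b[i], cols] <- exp(log_mean + log_sd * z2)
      }
    }
    list(
      exprs = m, samples = samples,
      truth = list(
        planted = planted, samples_per_lineage = samples_per_lineage,
        log_mean = log_mean, log_sd = log_sd, seed = seed
      )
    )
  })
}

#' Random rooted tree with a planted ortholog clade
#'
#' Builds a random binary tree whose root splits into (a) the planted clade
#' - the query leaf (target taxon) plus `clade_size` non-target leaves - and
#' (b) an outgroup subtree containing a second target-taxon leaf, so the
#' planted clade is exactly the maximal query-containing subtree free of a
#' second target-taxon sequence.
#'
#' @param n_leaves total leaves; needs `n_leaves >= clade_size + 2`.
#' @param clade_size non-target leaves in the planted clade (0 allowed: the
#'   planted clade is the query alone).
#' @param taxon target taxon label, default `"Homo sapiens"`.
#' @param seed RNG seed.
#' @return list: `tree` (rooted `ape::phylo`, leaf labels `id|taxon` with
#'   underscored taxa), `truth` (planted clade labels, query label, seed).
#' @export
random_tree_with_clade <- function(n_leaves = 20, clade_size = 3,
                                   taxon = "Homo sapiens", seed = 1) {
  if (clade_size < 0 || n_leaves < clade_size + 2) {
    abort(sprintf(
      "infeasible sizes: n_leaves = %d needs at least clade_size + 2 = %d",
      n_leaves, clade_size + 2
    ))
  }
  taxon_us <- gsub(" ", "_", taxon)
  pool <- c(
    "Mus_musculus", "Rattus_norvegicus", "Danio_rerio", "Gallus_gallus",
    "Xenopus_laevis", "Canis_lupus", "Bos_taurus", "Monodelphis_domestica"
  )
  with_seed(seed, {
    query <- paste0("Q1|", taxon_us)
    clade_leaves <- if (clade_size > 0) {
      paste0("O", seq_len(clade_size), "|", sample(pool, clade_size, replace = TRUE))
    } else {
      character(0)
    }
    n_out <- n_leaves - 1 - clade_size
    out_leaves <- c(
      paste0("H2|", taxon_us),
      if (n_out > 1) paste0("X", seq_len(n_out - 1), "|", sample(pool, n_out - 1, replace = TRUE))
    )
    clade_nwk <- random_subtree(c(query, clade_leaves))
    out_nwk <- random_subtree(out_leaves)
    tree <- parse_newick(sprintf("(%s,%s);", clade_nwk, out_nwk))
    list(
      tree = tree,
      truth = list(
        clade = sort(c(query, clade_leaves)), query = query,
        taxon = taxon, n_leaves = n_leaves, clade_size = clade_size, seed = seed
      )
    )
  })
}

# random binary topology over labels via sequential random joins
random_subtree <- function(labels) {
  nodes <- as.list(labels)
  while (length(nodes) > 1) {
    i <- sample.int(length(nodes), 2)
    merged <- sprintf("(%s,%s)", nodes[[i[1]]], nodes[[i[2]]])
    nodes[[i[1]]] <- merged
    nodes[[i[2]]] <- NULL
  }
  nodes[[1]]
}

#' Write / read a simulation-truth record
#'
#' Truth records are serialized as JSON alongside generated datasets so
#' recovery tests read planted values from the record, not from constants.
#'
#' @param truth a truth list as returned by the generators.
#' @param path file path.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
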