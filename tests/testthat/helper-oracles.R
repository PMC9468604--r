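# Independent oracles used by the tests. Each is a deliberately naive
# re-derivation (exhaustive scan, closed form, or tiny-n enumeration) kept
# separate from the implementation it checks.

# Exhaustive stable-window search: terminal window first, else the longest
# window anywhere with max-min <= tol (ties -> latest end), else NULL.
oracle_equilibrated_window <- function(x, tol = 1, min_fraction = 0.2) {
  n <- length(x)
  spread_ok <- function(i, j) (max(x[i:j]) - min(x[i:j])) <= tol
  term_start <- NA
  for (i in 1:(n - 1)) {
    if (spread_ok(i, n)) {
      term_start <- i
      break
    }
  }
  if (!is.na(term_start) && (n - term_start + 1) >= min_fraction * n) {
    return(c(term_start, n))
  }
  best <- NULL
  best_len <- 1
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (spread_ok(i, j) && (j - i + 1) >= best_len) {
        best_len <- j - i + 1
        best <- c(i, j)
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (!is.na(term_start) && (n - term_start + 1) >= best_len) {
    return(c(term_start, n))
  }
  best
}

# All-pairs distance scan for salt bridges: nested loops over every acidic
# oxygen and basic nitrogen, no vectorization shared with the implementation.
oracle_salt_bridges <- function(topology, coords, cutoff = 3, interchain = TRUE) {
  df <- as.data.frame(topology)
  acid <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  base <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  hits <- list()
  for (i in seq_len(nrow(df))) {
    ai <- df[i, ]
    if (!(ai$resname %in% names(acid)) || !(ai$atom %in% acid[[ai$resname]])) next
    for (j in seq_len(nrow(df))) {
      bj <- df[j, ]
      if (!(bj$resname %in% names(base)) || !(bj$atom %in% base[[bj$resname]])) next
      if (interchain && ai$chain == bj$chain) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= cutoff) {
        hits[[length(hits) + 1]] <- paste(ai$chain, ai$resno, bj$chain, bj$resno)
      }
    }
  }
  sort(unique(unlist(hits)))
}

# Exhaustive global-alignment enumeration for short sequences: recursively
# explores every alignment and returns the maximum score.
oracle_alignment_score <- function(a, b, match, mismatch, gap) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(a)) return(gap * (length(b) - j + 1))
    if (j > length(b)) return(gap * (length(a) - i + 1))
    max(
      rec(i + 1, j + 1) + if (a[i] == b[j]) match else mismatch,
      rec(i + 1, j) + gap,
      rec(i, j + 1) + gap
    )
  }
  rec(1, 1)
}

# Accessible area of two intersecting spheres of expanded radii r1, r2 at
# centre separation d: each loses the spherical cap inside the other.
oracle_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  x2 <- d - x1
  a1 <- 4 * pi * r1^2 - 2 * pi * r1 * (r1 - x1)
  a2 <- 4 * pi * r2^2 - 2 * pi * r2 * (r2 - x2)
  a1 + a2
}

# Monte-Carlo SASA with uniformly random (seeded) sphere points; independent
# of the deterministic spiral sampling in the implementation.
oracle_sasa_total <- function(topology, coords, probe = 1.4, n_points = 4000, seed = 99) {
  radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8)
  df <- as.data.frame(topology)
  ext <- unname(radii[toupper(df$element)]) + probe
  set.seed(seed)
  z <- stats::runif(n_points, -1, 1)
  th <- stats::runif(n_points, 0, 2 * pi)
  pts <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  total <- 0
  for (i in seq_len(nrow(df))) {
    sp <- sweep(pts * ext[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(df))) {
      if (j == i) next
      dj2 <- rowSums(sweep(sp, 2, coords[j, ])^2)
      free <- free & dj2 >= ext[j]^2
    }
    total <- total + 4 * pi * ext[i]^2 * mean(free)
  }
  total
}

# Naive average-linkage agglomeration over distance 1 - r: scans every
# cluster pair each step and records merge heights.
oracle_average_linkage_heights <- function(r) {
  d <- 1 - r
  clusters <- as.list(seq_len(nrow(r)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Brute-force ortholog-clade selection: enumerates every ancestor of the
# query with phangorn machinery and applies the stopping rule directly.
oracle_ortholog_clade <- function(tree, query, taxon = "Homo sapiens") {
  taxa <- btbdimer::leaf_taxa(tree)
  q <- match(query, tree$tip.label)
  target <- which(!is.na(taxa) & taxa == taxon)
  anc <- phangorn::Ancestors(tree, q, type = "all")
  prev <- q
  for (node in anc) {
    tips <- phangorn::Descendants(tree, node, type = "tips")[[1]]
    if (sum(tips %in% target) >= 2) {
      prev_tips <- if (prev <= length(tree$tip.label)) prev else
        phangorn::Descendants(tree, prev, type = "tips")[[1]]
      return(sort(tree$tip.label[prev_tips]))
    }
    prev <- node
  }
  sort(tree$tip.label)
}

# Hand-written PDB fixture: 2 chains, 4 residues, plus decoys (water, altloc)
fixture_pdb_lines <- function() {
  c(
    "HEADER    TEST FIXTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.900   1.200   0.000  1.00  0.00           C",
    "ATOM      4  CA AASP B   1       0.000   5.000   0.000  1.00  0.00           C",
    "ATOM      5  CA BASP B   1       0.100   5.000   0.000  1.00  0.00           C",
    "ATOM      6  OD1 ASP B   1       1.000   6.500   0.000  1.00  0.00           O",
    "ATOM      7  CA  LYS B   2       3.800   5.000   0.000  1.00  0.00           C",
    "HETATM    8  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"
  )
}

# independent line scanner for the fixture (counts via regex only)
fixture_pdb_counts <- function(lines) {
  atom <- grep("^ATOM  ", lines, value = TRUE)
  atom <- atom[substr(atom, 17, 17) %in% c(" ", "A")]
  chains <- unique(substr(atom, 22, 22))
  res <- unique(paste(substr(atom, 22, 22), substr(atom, 23, 26)))
  list(n_atoms = length(atom), chains = sort(chains), n_residues = length(res))
}
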