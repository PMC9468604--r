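rigid_move <- function(m, angle, axis = c(0, 0, 1), shift = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle)
  s_ <- sin(angle)
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, byrow = TRUE)
  r <- diag(3) * c_ + s_ * k + (1 - c_) * (a %o% a)
  sweep(m %*% t(r), 2, shift, "+")
}

test_that("rmsd_series is zero for static and rigidly moved trajectories", {
  d <- make_toy_dimer(8, 1, seed = 5)
  m0 <- atom_coords(d, NULL)
  static <- new_trajectory(d, replicate(5, m0, simplify = FALSE))
  expect_equal(rmsd_series(static)$rmsd, rep(0, 5))

  moved <- new_trajectory(d, lapply(0:4, function(i) {
    rigid_move(m0, angle = i * 0.7, axis = c(1, 2, 3), shift = c(i, -i, 2 * i))
  }))
  expect_true(all(rmsd_series(moved)$rmsd < 1e-8))
})

test_that("rmsd_series matches an independent brute-force recomputation", {
  d <- make_toy_dimer(10, 2, seed = 9)
  sim <- simulate_trajectory(d, 0.5, n_frames = 20, seed = 10)
  series <- rmsd_series(sim$trajectory)
  sel <- which(sim$trajectory$topology$atom == "CA")
  ref <- sim$trajectory$coords[[1]][sel, ]
  # independent closed form: rmsd^2 = (E0 - 2 (s1 + s2 +/- s3)) / N from the
  # singular values of the centred covariance, sign by reflection test
  brute <- vapply(sim$trajectory$coords, function(m) {
    a0 <- scale(m[sel, ], scale = FALSE)
    b0 <- scale(ref, scale = FALSE)
    s <- svd(crossprod(a0, b0))
    sgn <- sign(det(s$u) * det(s$v))
    e0 <- sum(a0^2) + sum(b0^2)
    sqrt(max(0, e0 - 2 * (s$d[1] + s$d[2] + sgn * s$d[3])) / nrow(a0))
  }, 0)
  expect_equal(series$rmsd, brute, tolerance = 1e-6)
})

test_that("equilibration detection handles constant and step series", {
  w <- find_equilibrated_window(rep(2.5, 50))
  expect_equal(c(w$start_frame, w$end_frame), c(1, 50))

  # drift at 3 A for 60 frames then stable 1 A plateau for 40
  step <- c(rep(3, 60), rep(1, 40))
  w2 <- find_equilibrated_window(step)
  expect_equal(c(w2$start_frame, w2$end_frame), c(61, 100))

  expect_null(find_equilibrated_window(seq(0, 50, by = 1.5), tol_angstrom = 1))
})

test_that("equilibration detection agrees with exhaustive search on random series", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(5:500, 1)
    kind <- rep %% 3
    x <- if (kind == 0) {
      cumsum(rnorm(n, 0, 0.3)) # random walk
    } else if (kind == 1) {
      c(seq(0, 3, length.out = ceiling(n / 2)), rnorm(floor(n / 2), 3, 0.2))
    } else {
      rnorm(n, 2, 1.2) # noisy, may have no long window
    }
    got <- suppressWarnings(find_equilibrated_window(x, tol_angstrom = 1))
    want <- oracle_equilibrated_window(x, tol = 1)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(c(got$start_frame, got$end_frame), want, info = paste("rep", rep))
    }
  }
})

test_that("salt-bridge detection respects the distance cutoff exactly", {
  mk <- function(gap) {
    new_structure(tibble::tibble(
      atom = c("CA", "CB", "OD1", "CA", "CB", "NZ"),
      element = c("C", "C", "O", "C", "C", "N"),
      resname = c("ASP", "ASP", "ASP", "LYS", "LYS", "LYS"),
      chain = c("A", "A", "A", "B", "B", "B"),
      resno = c(1L, 1L, 1L, 1L, 1L, 1L), icode = "",
      x = 0, y = c(0, 1, 2, 2 + gap + 2, 2 + gap + 1, 2 + gap), z = 0
    ))
  }
  near <- detect_salt_bridges(mk(2.8))
  expect_equal(nrow(near), 1)
  expect_equal(near$min_dist, 2.8)
  expect_equal(nrow(detect_salt_bridges(mk(3.2))), 0)
})

test_that("salt-bridge detection equals an independent all-pairs scan", {
  set.seed(19)
  for (rep in 1:5) {
    d <- make_toy_dimer(12, 3, seed = rep)
    m <- atom_coords(d, NULL) + matrix(rnorm(nrow(d) * 3, sd = 0.5), ncol = 3)
    got <- suppressMessages(detect_salt_bridges(d, m))
    keys <- sort(paste(got$acidic_chain, got$acidic_resno, got$basic_chain, got$basic_resno))
    expect_equal(keys, oracle_salt_bridges(d, m))
  }
})

test_that("residues lacking charged side-chain atoms are skipped with a note", {
  df <- tibble::as_tibble(make_toy_dimer(6, 1, seed = 3))
  # strip the acidic oxygen: ASP/GLU residue now has no usable atoms
  df <- df[!(df$atom %in% c("OD1", "OE1")), ]
  s <- new_structure(df)
  expect_message(out <- detect_salt_bridges(s), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("barcode retains pairs at or above the occupancy floor and drops the rest", {
  d <- make_toy_dimer(12, 2, seed = 14)
  sim <- simulate_trajectory(d, occupancies = c(0.10, 0.05), n_frames = 500, seed = 15)
  bc <- bridge_barcode(sim$trajectory)
  truth <- sim$truth$bridges
  lab <- function(i) paste(truth$acidic_resno[i], truth$basic_resno[i])
  got <- paste(bc$acidic_resno, bc$basic_resno)
  measured_hi <- mean(vapply(seq_len(n_frames(sim$trajectory)), function(f) {
    s <- suppressMessages(detect_salt_bridges(d, sim$trajectory$coords[[f]]))
    any(s$acidic_resno == truth$acidic_resno[1])
  }, TRUE))
  # the 10 % bridge is retained with its measured occupancy, the 5 % one dropped
  expect_true(lab(1) %in% got)
  expect_false(lab(2) %in% got)
  expect_equal(bc$occupancy[got == lab(1)], measured_hi)
  expect_true(all(bc$occupancy >= 0.08))
})

test_that("barcode occupancy recovers planted occupancy within 2 binomial SE", {
  d <- make_toy_dimer(10, 1, seed = 20)
  p <- 0.30
  n <- 400
  sim <- simulate_trajectory(d, p, n_frames = n, seed = 21)
  bc <- bridge_barcode(sim$trajectory)
  expect_equal(nrow(bc), 1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(bc$occupancy - p), 2 * se)
  expect_equal(bc$occupancy, mean(bc$presence[[1]]))
})

test_that("trajectories without charged residues give an empty barcode", {
  d <- make_toy_dimer(6, 0, seed = 2)
  sim <- simulate_trajectory(d, n_frames = 10, seed = 2)
  bc <- bridge_barcode(sim$trajectory)
  expect_equal(nrow(bc), 0)
})

test_that("average interface bridge count is exact for permanent and half-time bridges", {
  d <- make_toy_dimer(8, 1, seed = 6)
  sim <- simulate_trajectory(d, 1.0, n_frames = 20, seed = 6)
  got <- avg_interface_salt_bridges(sim$trajectory)
  expect_equal(got$mean, 1)
  expect_equal(got$se, 0)

  # deterministic half-time bridge: alternate formed/broken by hand
  base <- atom_coords(d, NULL)
  contacts <- attr(d, "contacts")
  top <- tibble::as_tibble(d)
  nrow_basic <- which(top$chain == "B" & top$resno == contacts$basic_resno[1] &
    top$atom == contacts$basic_atom[1])
  acid <- which(top$chain == "A" & top$resno == contacts$acidic_resno[1] &
    top$atom == contacts$acidic_atom[1])
  coords <- lapply(1:10, function(f) {
    m <- base
    m[nrow_basic, ] <- m[acid, ] + c(0, if (f %% 2 == 0) 2.8 else 4.5, 0)
    m
  })
  half <- new_trajectory(d, coords)
  expect_equal(avg_interface_salt_bridges(half)$mean, 0.5)
  expect_error(avg_interface_salt_bridges(half, frame_window(11, 20)), "bounds")
})

test_that("window-mean bridge count recovers the sum of planted occupancies", {
  d <- make_toy_dimer(14, 2, seed = 25)
  p <- c(0.6, 0.3)
  n <- 500
  sim <- simulate_trajectory(d, p, n_frames = n, seed = 26)
  got <- avg_interface_salt_bridges(sim$trajectory)
  se <- sqrt(sum(p * (1 - p)) / n)
  expect_lt(abs(got$mean - sum(p)), 2 * se)
})

test_that("occupancy is stable under uniform frame subsampling", {
  d <- make_toy_dimer(10, 1, seed = 33)
  p <- 0.4
  sim <- simulate_trajectory(d, p, n_frames = 400, seed = 34)
  bc_full <- bridge_barcode(sim$trajectory)
  set.seed(35)
  keep <- sort(sample.int(400, 200))
  sub <- new_trajectory(d, sim$trajectory$coords[keep], times = sim$trajectory$times[keep])
  bc_sub <- bridge_barcode(sub)
  se <- sqrt(p * (1 - p) / 200)
  expect_lt(abs(bc_sub$occupancy - bc_full$occupancy), 2 * se)
})
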