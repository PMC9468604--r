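const_series <- function(vals, n = 4, label = "x") {
  df <- tibble::tibble(frame = seq_len(n) - 1L)
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  energy_series(df, label)
}

full_components <- function(bond = 0, angle = 0, dihedral = 0, improper = 0,
                            elec = 0, vdw = 0, gb_polar = 0, nonpolar_sa = 0) {
  list(
    bond = bond, angle = angle, dihedral = dihedral, improper = improper,
    elec = elec, vdw = vdw, gb_polar = gb_polar, nonpolar_sa = nonpolar_sa
  )
}

test_that("component deltas vanish when the complex is the exact monomer sum", {
  el <- simulate_energy_logs(n_frames = 50, seed = 61)
  # rebuild a complex equal to a + b component-wise
  ab <- tibble::as_tibble(el$mon_a)
  for (nm in setdiff(names(ab), "frame")) ab[[nm]] <- ab[[nm]] + el$mon_b[[nm]]
  deltas <- frame_component_deltas(energy_series(ab, "sum"), el$mon_a, el$mon_b)
  for (nm in setdiff(names(deltas), "frame")) {
    expect_equal(deltas[[nm]], rep(0, 50), tolerance = 1e-10)
  }
})

test_that("constant series give the constant delta on every frame", {
  cx <- const_series(full_components(elec = -10, vdw = -4, gb_polar = 3, bond = 1))
  a <- const_series(full_components(elec = -2, vdw = -1))
  b <- const_series(full_components(elec = -3, gb_polar = 1))
  d <- frame_component_deltas(cx, a, b)
  expect_equal(d$elec, rep(-5, 4))
  expect_equal(d$vdw, rep(-3, 4))
  expect_equal(d$gb_polar, rep(2, 4))
  expect_equal(d$bond, rep(1, 4))
})

test_that("deltas are antisymmetric under swapping the complex with the monomer sum", {
  el <- simulate_energy_logs(n_frames = 30, seed = 62)
  ab <- tibble::as_tibble(el$mon_a)
  for (nm in setdiff(names(ab), "frame")) ab[[nm]] <- ab[[nm]] + el$mon_b[[nm]]
  zero <- const_series(full_components(), n = 30)
  fwd <- frame_component_deltas(el$complex, el$mon_a, el$mon_b)
  bwd <- frame_component_deltas(energy_series(ab, "sum"), el$complex, zero)
  for (nm in setdiff(names(fwd), "frame")) {
    expect_equal(bwd[[nm]], -fwd[[nm]], tolerance = 1e-10)
  }
})

test_that("frame mismatches are rejected naming the offending frame", {
  el <- simulate_energy_logs(n_frames = 10, seed = 63)
  short <- energy_series(tibble::as_tibble(el$mon_b)[-4, ], "short")
  expect_error(frame_component_deltas(el$complex, el$mon_a, short), "frame 3")
})

test_that("planted component deltas are recovered within 2 SE with SE near sigma/sqrt(n)", {
  el <- simulate_energy_logs(n_frames = 1000, seed = 64)
  deltas <- frame_component_deltas(el$complex, el$mon_a, el$mon_b)
  s <- aggregate_mmgbsa(deltas, NULL, n_residues = 290)
  truth <- el$truth
  comp <- s$components
  planted <- c(
    dE_int = truth$delta_means$bond + truth$delta_means$angle +
      truth$delta_means$dihedral + truth$delta_means$improper,
    dE_ele = truth$delta_means$elec,
    dG_sol_pb = truth$delta_means$gb_polar,
    dG_sol_sa = truth$delta_means$nonpolar_sa,
    dE_vdw = truth$delta_means$vdw
  )
  for (term in names(planted)) {
    row <- comp[comp$term == term, ]
    expect_lt(abs(row$estimate - planted[[term]]), 2 * row$se)
  }
  # SE of a single-channel component ~ sigma / sqrt(n) within 20 %
  sigma <- truth$delta_sds$elec
  se_expected <- sigma / sqrt(truth$n_frames)
  se_got <- comp$se[comp$term == "dE_ele"]
  expect_lt(abs(se_got - se_expected) / se_expected, 0.2)
  # total is exactly the sum of component means
  expect_equal(s$dg_total, sum(comp$estimate[comp$term != "dG_total"]))
})

test_that("printed component rows reproduce their printed totals", {
  s <- mmgbsa_from_components(
    de_int = -353.9, de_ele = -418.0, dg_sol_pb = 437.1,
    dg_sol_sa = 0, de_vdw = -194.3, n_residues = 290
  )
  expect_equal(round_half_away(s$dg_total), -529.1)
  expect_equal(round_half_away(s$dg_per_aa), -1.8)

  zero <- mmgbsa_from_components(0, 0, 0, 0, 0, n_residues = 10)
  expect_equal(zero$dg_total, 0)
  expect_true(all(zero$components$se == 0))
})

test_that("aggregation honours the window and rejects degenerate ones", {
  vals <- full_components(elec = 1)
  df <- tibble::as_tibble(const_series(vals, n = 10))
  df$elec <- c(rep(100, 5), rep(2, 5))
  es <- energy_series(df, "delta")
  s <- aggregate_mmgbsa(es, frame_window(5, 9), n_residues = 5)
  expect_equal(s$dg_total, 2)
  expect_equal(s$n_frames, 5)
  expect_error(aggregate_mmgbsa(es, frame_window(9, 9), n_residues = 5), "at least 2")
  expect_error(aggregate_mmgbsa(es, frame_window(5, 20), n_residues = 5), "not contained")
  expect_error(aggregate_mmgbsa(es, NULL, n_residues = 0), "n_residues")
})

test_that("nonpolar energy is linear in SASA and reproduces -gamma * BSA for deltas", {
  expect_equal(nonpolar_from_sasa(0, gamma = 0.005), 0)
  expect_equal(nonpolar_from_sasa(1000, gamma = 0.005), 5)
  expect_error(nonpolar_from_sasa(numeric(0)), "absent")
  expect_error(nonpolar_from_sasa(10, gamma = -1), "gamma")

  d <- make_toy_dimer(6, 1, seed = 71)
  sim <- simulate_trajectory(d, 0.8, n_frames = 3, seed = 72)
  b <- bsa_series(sim$trajectory, n_points = 480)
  gamma <- 0.00542
  delta_np <- nonpolar_from_sasa(b$per_frame$sasa_complex, gamma) -
    nonpolar_from_sasa(b$per_frame$sasa_a, gamma) -
    nonpolar_from_sasa(b$per_frame$sasa_b, gamma)
  expect_equal(delta_np, -gamma * b$per_frame$bsa)
})

test_that("duplicate runs combine as mean of means with SEs in quadrature", {
  e1 <- simulate_energy_logs(n_frames = 200, seed = 73)
  e2 <- simulate_energy_logs(n_frames = 200, seed = 74)
  s1 <- aggregate_mmgbsa(frame_component_deltas(e1$complex, e1$mon_a, e1$mon_b), NULL, 290)
  s2 <- aggregate_mmgbsa(frame_component_deltas(e2$complex, e2$mon_a, e2$mon_b), NULL, 290)
  comb <- combine_mmgbsa_runs(list(s1, s2))
  expect_equal(comb$dg_total, (s1$dg_total + s2$dg_total) / 2)
  expect_equal(comb$dg_se, sqrt(s1$dg_se^2 + s2$dg_se^2) / 2)
  expect_equal(comb$n_frames, 400)
})

test_that("expected heterodimer energy is the homodimer mean", {
  expect_equal(expected_heterodimer_dg(-529.1, -485.4), -507.25)
  expect_equal(round_half_away(expected_heterodimer_dg(-529.1, -485.4)), -507.3)
  expect_equal(round_half_away(expected_heterodimer_dg(-529.1, -401.6)), -465.4)
  expect_equal(expected_heterodimer_dg(-3, -3), -3)
  expect_error(expected_heterodimer_dg(NA_real_, 1), "finite")
})

test_that("heterodimer preference verdicts follow the neutrality band", {
  p1 <- heterodimer_preference(-529.5, -507.3)
  expect_equal(p1$ddg, -22.2)
  expect_equal(p1$verdict, "heterodimer-favored")
  p2 <- heterodimer_preference(-470.9, -465.4)
  expect_equal(p2$ddg, -5.5)
  expect_equal(p2$verdict, "neutral")
  p3 <- heterodimer_preference(-400, -400)
  expect_equal(p3$ddg, 0)
  expect_equal(p3$verdict, "neutral")
  p4 <- heterodimer_preference(-380, -400)
  expect_equal(p4$verdict, "homodimer-favored")
})

test_that("tidy and glance expose the summary as tibbles", {
  s <- mmgbsa_from_components(-353.9, -418.0, 437.1, 0, -194.3, 290)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("dE_int", "dE_ele", "dG_sol_pb", "dG_sol_sa", "dE_vdw", "dG_total"))
  g <- glance(s)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_residues, 290L)
})
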