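test_that("pseudorotation inverts the generating cosine series exactly", {
  # oracle: nu_j = nu_max * cos(P + 144 (j - 2)) generates the torsions;
  # recovery must be a fixed point
  for (P in c(0, 18, 47, 90, 162, 181, 270, 342)) {
    for (vm in c(20, 38, 40, 45)) {
      ps <- pseudorotation(nu_series(P, vm))
      expect_false(ps$degenerate)
      expect_equal(ps$P, P, tolerance = 1e-6)
      expect_equal(ps$nu_max, vm, tolerance = 1e-6)
      # re-generate from the recovered state: fixed point to 1e-6 degrees
      ps2 <- pseudorotation(nu_series(ps$P, ps$nu_max))
      expect_equal(ps2$P, ps$P, tolerance = 1e-6)
      expect_equal(ps2$nu_max, ps$nu_max, tolerance = 1e-6)
    }
  }
})

test_that("nu2 equals nu_max cos(P) and flat rings are degenerate", {
  nu <- nu_series(18, 38)
  expect_equal(nu[3], 38 * cos(18 * pi / 180), tolerance = 0.5)
  expect_true(pseudorotation(rep(0, 5))$degenerate)
  expect_true(pseudorotation(nu_series(90, 3))$degenerate)
  expect_error(classify_pucker(NA, 3), "refused")
})

test_that("conformer bins and quadrants follow the wheel convention", {
  cases <- list(
    list(P = 18, conf = "C3'-endo", quad = "north"),
    list(P = 47, conf = "C4'-exo", quad = "east"),
    list(P = 54, conf = "C4'-exo", quad = "east"),
    list(P = 90, conf = "O4'-endo", quad = "east"),
    list(P = 162, conf = "C2'-endo", quad = "south"),
    list(P = 170, conf = "C2'-endo", quad = "south"),
    # 181 sits in the C2'-endo/C3'-exo twist bin of the 18-degree wheel,
    # within the southern B-form family
    list(P = 181, conf = "C2'-endo/C3'-exo-twist", quad = "south"),
    list(P = 342, conf = "C2'-exo", quad = "north"),
    list(P = 0, conf = "C3'-endo/C2'-exo-twist", quad = "north")
  )
  for (cs in cases) {
    got <- classify_pucker(cs$P, 38)
    expect_equal(got$conformer, cs$conf)
    expect_equal(got$quadrant, cs$quad)
  }
  # the coarse envelope-family label used in prose descriptions
  expect_equal(classify_pucker(175, 38)$envelope, "C2'-endo")
  expect_equal(classify_pucker(30, 38)$envelope, "C3'-endo")
})

test_that("ring torsions are rigid-transform invariant", {
  ring <- xnageom:::embed_ring(nu_series(162, 38))
  ref <- ring_torsions(ring)
  set.seed(5)
  for (i in 1:10) {
    R <- random_proper_rotation()
    t <- rnorm(3, sd = 20)
    moved <- sweep(ring %*% t(R), 2, -t)
    expect_equal(ring_torsions(moved), ref, tolerance = 1e-6)
  }
})

test_that("mirror reflection negates every endocyclic torsion", {
  ring <- xnageom:::embed_ring(nu_series(47, 38))
  ref <- ring_torsions(ring)
  mirrored <- ring %*% diag(c(1, 1, -1))
  expect_equal(ring_torsions(mirrored), -ref, tolerance = 1e-9)
  # negating every nu shifts the cosine series by half a cycle: P -> P + 180
  ps <- pseudorotation(ring_torsions(mirrored))
  ps0 <- pseudorotation(ref)
  expect_equal(ps$P, (ps0$P + 180) %% 360, tolerance = 1e-6)
  expect_equal(ps$nu_max, ps0$nu_max, tolerance = 1e-6)
})

test_that("generated rings recover their prescribed pucker through analysis", {
  fr <- make_furanose(P = 162, nu_max = 40, base = "A")
  ann <- annotate_chemistry(fr)
  nu <- endocyclic_torsions(ann, 1)
  # achieved torsions (the generator's oracle) match the measured ones
  expect_equal(unname(nu), unname(attr(fr, "achieved_nu")), tolerance = 1e-6)
  # and targets were hit within the embedding guarantee
  expect_lt(max(abs(nu - attr(fr, "target_nu"))), 0.5)
  pk <- sugar_pucker(ann)
  expect_equal(pk$P, 162, tolerance = 1)
  expect_equal(pk$conformer, "C2'-endo")
  expect_equal(pk$quadrant, "south")
})

test_that("an incomplete ring names its missing atom", {
  fr <- make_furanose(P = 18, nu_max = 38)
  broken <- fr[fr$elety != "C2'", ]
  ann <- annotate_chemistry(broken)
  expect_error(endocyclic_torsions(ann, 1), "C2'")
})

test_that("pucker wheel coordinates are the polar projection", {
  ann <- bdna_annotated()
  pk <- pucker_wheel_coords(sugar_pucker(ann))
  expect_equal(pk$wheel_x, pk$nu_max * sin(pk$P * pi / 180))
  expect_equal(pk$wheel_y, pk$nu_max * cos(pk$P * pi / 180))
  expect_equal(sqrt(pk$wheel_x^2 + pk$wheel_y^2), pk$nu_max)
})
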