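test_that("idealized B-DNA residues measure B-form delta and classify B-like", {
  ann <- bdna_annotated()
  tor <- classify_form(backbone_torsions(ann))
  # generator builds C2'-endo sugars with anti chi; every interior residue
  # must land in the B-form chi/delta region
  expect_true(all(tor$form == "B-like"))
  expect_true(all(tor$delta_like > 110 & tor$delta_like < 175))
  expect_equal(tor$chi, rep(-105, nrow(tor)), tolerance = 1e-6)
})

test_that("terminal residues mark spanning torsions unmeasurable, never drop them", {
  ann <- bdna_annotated()
  res <- annotated_residues(ann)
  first <- which(res$chain == "A" & res$resno == 1)
  tor <- exocyclic_torsions(ann, first)
  # every declared torsion label is present
  expect_setequal(
    tor$torsion,
    c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
  )
  expect_match(tor$status[tor$torsion == "alpha"], "terminus|missing")
  expect_true(is.na(tor$value[tor$torsion == "alpha"]))
  last <- which(res$chain == "A" & res$resno == 10)
  tor_l <- exocyclic_torsions(ann, last)
  expect_match(tor_l$status[tor_l$torsion == "epsilon"], "terminus")
  expect_match(tor_l$status[tor_l$torsion == "zeta"], "terminus")
})

test_that("P-P spacings match coordinates placed at known separation", {
  # two residues with bridging phosphorus atoms placed 6.30 A apart
  dup <- bdna_duplex()
  ann <- bdna_annotated()
  res <- annotated_residues(ann)
  i <- which(res$chain == "A" & res$resno == 2)
  j <- which(res$chain == "A" & res$resno == 3)
  pi_ <- xnageom:::atom_coord(ann, i, "P")
  pj <- xnageom:::atom_coord(ann, j, "P")
  expected <- sqrt(sum((pi_ - pj)^2))
  tbl <- p_p_distances(ann)
  got <- tbl$p_p_distance[tbl$chain == "A" & tbl$resno_i == 2]
  expect_equal(got, expected, tolerance = 1e-9)
  # symmetric in residue order by definition of Euclidean distance
  expect_equal(got, sqrt(sum((pj - pi_)^2)), tolerance = 1e-12)
})

test_that("B-DNA decamer spacing equals the rise/twist-derived helical value", {
  # on a homopolymer strand the build is exactly helically symmetric, so
  # every P-P spacing must equal sqrt(rise^2 + (2 r sin(twist/2))^2), with
  # r the phosphorus' distance from the helix axis (z through the pair
  # origins by construction)
  dup <- make_duplex(duplex_spec("AAAAAAAAAA"))
  ann <- annotate_chemistry(dup)
  p_atoms <- dup[dup$elety == "P" & dup$chain == "A", ]
  r <- sqrt(p_atoms$x^2 + p_atoms$y^2)
  expected <- sqrt(3.4^2 + (2 * r[1] * sin(18 * pi / 180))^2)
  tbl <- p_p_distances(ann)
  meas <- tbl$p_p_distance[tbl$chain == "A" & tbl$status == "measured"]
  expect_equal(meas, rep(expected, length(meas)), tolerance = 1e-9)
  # every residue of the idealized decamer classifies B-like
  tor <- classify_form(backbone_torsions(ann))
  expect_true(all(tor$form == "B-like"))
})

test_that("missing phosphorus is reported, not dropped", {
  dup <- bdna_duplex()
  nop <- dup[!(dup$chain == "A" & dup$resno == 3 & dup$elety == "P"), ]
  ann <- annotate_chemistry(nop)
  tbl <- p_p_distances(ann)
  row <- tbl[tbl$chain == "A" & tbl$resno_i == 2, ]
  expect_true(is.na(row$p_p_distance))
  expect_match(row$status, "missing phosphorus")
})

test_that("chi/delta classification follows the region rectangles and tie rule", {
  expect_equal(chi_delta_classify(-100, 140), "B-like")
  expect_equal(chi_delta_classify(-160, 82), "A-like")
  # shared boundary at delta = 110 goes to the B side
  expect_equal(chi_delta_classify(-139, 110), "B-like")
  expect_equal(chi_delta_classify(-60, 140), "intermediate")
  expect_equal(chi_delta_classify(-160, 130), "intermediate")
  # wraparound: chi = 175 equals -185, inside the A region [-190, -138]
  expect_equal(chi_delta_classify(175, 82), "A-like")
  expect_error(chi_delta_classify(NA, 100), "refused")
  # boundaries are configurable
  regions <- chi_delta_regions()
  regions$B$delta[2] <- 200
  expect_equal(chi_delta_classify(-100, 190, regions), "B-like")
})

test_that("all backbone torsions are rigid-transform invariant", {
  dup <- bdna_duplex()
  ann <- bdna_annotated()
  ref <- backbone_torsions(ann)
  set.seed(9)
  R <- random_proper_rotation()
  moved <- rigidly_move(dup, R, c(3, -7, 12))
  tor <- backbone_torsions(annotate_chemistry(moved))
  for (col in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")) {
    expect_equal(tor[[col]], ref[[col]], tolerance = 1e-6)
  }
})

test_that("threose chemistries report their declared torsion sets", {
  tna <- make_duplex(duplex_spec("AATT", chemistry1 = "TNA"))
  ann <- annotate_chemistry(tna)
  res <- annotated_residues(ann)
  i <- which(res$chain == "A" & res$resno == 2)
  tor <- exocyclic_torsions(ann, i)
  # TNA: five-atom repeat, no gamma-analog bond
  expect_setequal(
    tor$torsion, c("alpha", "beta", "delta", "epsilon", "zeta", "chi")
  )
  expect_true(all(tor$status[tor$torsion %in% c("alpha", "beta", "delta")] == "measured"))
  ptna <- make_duplex(duplex_spec("AATT", chemistry1 = "pTNA"))
  annp <- annotate_chemistry(ptna)
  resp <- annotated_residues(annp)
  ip <- which(resp$chain == "A" & resp$resno == 2)
  torp <- exocyclic_torsions(annp, ip)
  # pTNA: six-atom phosphonomethyl repeat restores a gamma-analog
  expect_setequal(
    torp$torsion, c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
  )
  expect_true(all(torp$status[torp$torsion != "chi"][2:5] == "measured"))
})
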