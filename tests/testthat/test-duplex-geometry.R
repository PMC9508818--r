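test_that("base frames recover planted placements", {
  # a base placed exactly at the standard geometry fits the identity frame
  std <- standard_base("A")
  f <- xnageom:::fit_base_frame(std, "A")
  expect_equal(f$R, diag(3), tolerance = 1e-9)
  expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(f$fit_rmsd, 1e-9)
  # a rotated/translated standard base yields exactly that transform
  set.seed(3)
  for (i in 1:5) {
    R <- random_proper_rotation()
    t <- rnorm(3, sd = 8)
    moved <- sweep(std %*% t(R), 2, -t)
    rownames(moved) <- rownames(std)
    f2 <- xnageom:::fit_base_frame(moved, "A")
    expect_equal(f2$R, R, tolerance = 1e-9)
    expect_equal(f2$origin, t, tolerance = 1e-9)
  }
  # missing base atoms refuse a frame
  expect_error(
    xnageom:::fit_base_frame(std[rownames(std) != "N7", ], "A"),
    "N7"
  )
})

test_that("the ideal duplex pairs at every position with built H-bond distances", {
  ann <- bdna_annotated()
  pairs <- find_basepairs(ann, "A", "B")
  expect_equal(nrow(pairs), 10)
  expect_equal(pairs$resno_i, 1:10)
  # distances as built from the standard frames: all in the canonical
  # hydrogen-bonding range
  hb <- hbond_distances(pairs)
  expect_true(all(hb$dist > 2.7 & hb$dist < 3.1))
  # A-T pairs report 2 bonds, G-C pairs 3
  counts <- table(pairs$base_i)
  nb <- vapply(pairs$hbonds, nrow, 1L)
  expect_true(all(nb[pairs$base_i %in% c("A", "T")] == 2))
  expect_true(all(nb[pairs$base_i %in% c("G", "C")] == 3))
})

test_that("parallel-oriented bases within distance are rejected", {
  # build a fake 'pair': two A-T bases at H-bond distance but with parallel
  # z-axes (no flip), which must fail the antiparallel test
  a <- make_furanose(18, 38, base = "A", chain = "A", resno = 1)
  t_ <- make_furanose(18, 38, base = "T", chain = "B", resno = 1)
  # translate T so its N3 sits near A's N1 without flipping
  sa <- standard_base("A")
  st <- standard_base("T")
  shift <- (sa["N1", ] - st["N3", ]) + c(0, -2.9, 0)
  t_$x <- t_$x + shift[1]
  t_$y <- t_$y + shift[2]
  t_$z <- t_$z + shift[3]
  both <- dplyr::bind_rows(a, t_)
  ann <- annotate_chemistry(both)
  pairs <- find_basepairs(ann, "A", "B", cutoff = 3.5)
  expect_equal(nrow(pairs), 0)
})

test_that("H-bond acceptance is monotone in the cutoff", {
  # stretch the pairs slightly so distances spread around the thresholds
  dup <- make_duplex(duplex_spec("ATGCAT",
    pair_params = data.frame(
      shear = 0, stretch = 0.45, stagger = 0,
      buckle = 0, propeller = 0, opening = 0
    )
  ))
  ann <- annotate_chemistry(dup)
  tight <- find_basepairs(ann, "A", "B", cutoff = 3.2)
  loose <- find_basepairs(ann, "A", "B", cutoff = 3.5)
  key <- function(p) paste(p$resno_i, p$resno_j)
  expect_true(all(key(tight) %in% key(loose)))
  expect_gte(nrow(loose), nrow(tight))
})

test_that("pair and step parameters round-trip the build values", {
  target_pair <- c(shear = 0.2, stretch = -0.1, stagger = 0.3,
    buckle = 5, propeller = -12, opening = 3)
  target_step <- c(shift = 0.4, slide = -0.8, rise = 3.2,
    tilt = -3, roll = 7, twist = 31)
  dup <- make_duplex(duplex_spec("ATGCA",
    step_params = as.data.frame(as.list(target_step)),
    pair_params = as.data.frame(as.list(target_pair))
  ))
  ann <- annotate_chemistry(dup)
  pairs <- find_basepairs(ann, "A", "B")
  ps <- pair_and_step_params(ann, pairs)
  for (k in seq_len(nrow(ps$pairs))) {
    expect_equal(
      unlist(ps$pairs[k, names(target_pair)]), target_pair,
      tolerance = 1e-3
    )
  }
  for (k in seq_len(nrow(ps$steps))) {
    expect_equal(
      unlist(ps$steps[k, names(target_step)]), target_step,
      tolerance = 1e-3
    )
  }
})

test_that("coincident frames give all-zero pair parameters", {
  f <- list(R = diag(3), origin = c(1, 2, 3))
  flipped <- list(R = xnageom:::flip_frame(diag(3)), origin = c(1, 2, 3))
  pp <- xnageom:::pair_params_frames(f, flipped)
  expect_equal(unname(pp$params), rep(0, 6), tolerance = 1e-12)
})

test_that("reversing strand order flips shear and buckle only", {
  dup <- make_duplex(duplex_spec("ATGCA",
    pair_params = data.frame(
      shear = 0.25, stretch = -0.15, stagger = 0.3,
      buckle = 6, propeller = -11, opening = 4
    )
  ))
  ann <- annotate_chemistry(dup)
  p12 <- pair_and_step_params(ann, find_basepairs(ann, "A", "B"))$pairs
  p21 <- pair_and_step_params(ann, find_basepairs(ann, "B", "A"))$pairs
  m12 <- p12[order(p12$resno_i), ]
  m21 <- p21[order(p21$resno_j), ]
  expect_equal(m21$shear, -m12$shear, tolerance = 1e-9)
  expect_equal(m21$buckle, -m12$buckle, tolerance = 1e-9)
  expect_equal(m21$stretch, m12$stretch, tolerance = 1e-9)
  expect_equal(m21$stagger, m12$stagger, tolerance = 1e-9)
  expect_equal(m21$propeller, m12$propeller, tolerance = 1e-9)
  expect_equal(m21$opening, m12$opening, tolerance = 1e-9)
})

test_that("pair and step parameters are rigid-transform invariant", {
  dup <- make_duplex(duplex_spec("ATGC",
    step_params = data.frame(
      shift = 0.2, slide = -0.5, rise = 3.3, tilt = 2, roll = 5, twist = 34
    )
  ))
  ann <- annotate_chemistry(dup)
  ref <- pair_and_step_params(ann, find_basepairs(ann, "A", "B"))
  set.seed(17)
  R <- random_proper_rotation()
  moved <- rigidly_move(dup, R, c(10, -4, 6))
  annm <- annotate_chemistry(moved)
  got <- pair_and_step_params(annm, find_basepairs(annm, "A", "B"))
  expect_equal(as.data.frame(got$pairs[, 7:12]), as.data.frame(ref$pairs[, 7:12]),
    tolerance = 1e-9
  )
  expect_equal(as.data.frame(got$steps[, 3:8]), as.data.frame(ref$steps[, 3:8]),
    tolerance = 1e-9
  )
})

test_that("a single pair yields parameters but no steps", {
  dup <- make_duplex(duplex_spec("G"))
  ann <- annotate_chemistry(dup)
  pairs <- find_basepairs(ann, "A", "B")
  expect_equal(nrow(pairs), 1)
  ps <- pair_and_step_params(ann, pairs)
  expect_equal(nrow(ps$pairs), 1)
  expect_equal(nrow(ps$steps), 0)
})
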