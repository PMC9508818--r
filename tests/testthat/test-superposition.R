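test_that("kabsch recovers identity on identical sets and planted transforms", {
  cloud <- make_ca_cloud(60, seed = 2)
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  f0 <- kabsch(xyz, xyz)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:10) {
    R <- random_proper_rotation()
    t <- rnorm(3, sd = 15)
    moved <- sweep(xyz %*% t(R), 2, -t)
    f <- kabsch(xyz, moved)
    expect_lt(f$rmsd, 1e-9)
    expect_equal(f$rotation, R, tolerance = 1e-9)
    expect_equal(f$translation, t, tolerance = 1e-9)
    expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  }
})

test_that("mirror images are not superposable (chirality preserved)", {
  cloud <- make_ca_cloud(40, seed = 4)
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  mirror <- xyz %*% diag(c(1, 1, -1))
  f <- kabsch(xyz, mirror)
  expect_gt(f$rmsd, 0.5)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch beats random rigid transforms (optimality spot-check)", {
  cloud <- make_ca_cloud(50, seed = 6)
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  set.seed(8)
  target <- xyz + matrix(rnorm(length(xyz), sd = 0.5), ncol = 3)
  best <- kabsch(xyz, target)$rmsd
  for (i in 1:25) {
    R <- random_proper_rotation()
    aR <- xyz %*% t(R)
    tv <- colMeans(target) - colMeans(aR) # optimal translation for this R
    rmsd <- sqrt(mean(rowSums((sweep(aR, 2, -tv) - target)^2)))
    expect_gte(rmsd + 1e-12, best)
  }
})

test_that("degenerate inputs are refused", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("alignment against itself is exact with zero rejections", {
  cloud <- make_ca_cloud(80, seed = 10)
  fit <- align_calpha(cloud, cloud)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$n_retained, 80)
  expect_equal(nrow(fit$rejection_rounds), 0)
})

test_that("iterative rejection removes exactly the planted outliers", {
  cloud <- make_ca_cloud(100, seed = 12)
  set.seed(13)
  hits <- 0
  for (trial in 1:20) {
    noisy <- cloud
    planted <- sample(100, 5)
    noisy$x[planted] <- noisy$x[planted] + rnorm(5, 0, 1)
    noisy$y[planted] <- noisy$y[planted] + rnorm(5, 0, 1)
    noisy$z[planted] <- noisy$z[planted] + rnorm(5, 0, 1)
    fit <- align_calpha(cloud, noisy)
    if (setequal(setdiff(1:100, fit$retained), planted)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("rejection lowers the final RMSD monotonically", {
  cloud <- make_ca_cloud(100, seed = 14)
  noisy <- perturb(cloud, 0.1, seed = 15)
  idx <- c(7, 33, 71)
  noisy$x[idx] <- noisy$x[idx] + 2.5
  fit <- align_calpha(cloud, noisy)
  rounds <- tidy(fit)
  expect_gt(nrow(rounds), 0)
  # non-increasing across rounds, and below the no-rejection fit
  expect_true(all(diff(rounds$rmsd) <= 1e-12))
  no_rej <- align_calpha(cloud, noisy, max_rounds = 0)
  expect_lt(fit$rmsd, no_rej$rmsd)
  expect_equal(no_rej$n_retained, no_rej$n_initial)
})

test_that("rejection disabled equals plain kabsch on the full pairing", {
  cloud <- make_ca_cloud(60, seed = 16)
  noisy <- perturb(cloud, 0.3, seed = 17)
  a <- align_calpha(cloud, noisy, max_rounds = 0)
  k <- kabsch(
    as.matrix(cloud[, c("x", "y", "z")]),
    as.matrix(noisy[, c("x", "y", "z")])
  )
  expect_equal(a$rmsd, k$rmsd, tolerance = 1e-12)
  expect_equal(a$rotation, k$rotation, tolerance = 1e-12)
})

test_that("pairing is by residue number and unshared residues drop out", {
  a <- make_ca_cloud(50, seed = 18)
  b <- perturb(a, 0.05, seed = 19)
  b <- b[b$resno != 25, ] # unbuilt residue in one model
  fit <- align_calpha(a, b)
  expect_equal(fit$n_initial, 49)
})

test_that("local alignment on a residue subset recovers planted transforms", {
  dup <- bdna_duplex()
  sel <- data.frame(chain = c("A", "A", "A", "B", "B", "B"),
    resno = c(4, 5, 6, 4, 5, 6))
  # whole structure against itself: identity
  self <- align_local(dup, dup, sel)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  set.seed(20)
  R <- random_proper_rotation()
  t <- c(4, -9, 2)
  moved <- rigidly_move(dup, R, t)
  fit <- align_local(dup, moved, sel)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, t, tolerance = 1e-9)
  # the transformed copy overlays the target structure
  expect_equal(
    as.matrix(fit$transformed[, c("x", "y", "z")]),
    as.matrix(moved[, c("x", "y", "z")]),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  # unresolvable selection entries are named
  bad <- rbind(sel, data.frame(chain = "Z", resno = 99))
  expect_error(align_local(dup, moved, bad), "Z:99")
})

test_that("tidy and glance summarize superposition fits", {
  cloud <- make_ca_cloud(50, seed = 22)
  noisy <- perturb(cloud, 0.1, seed = 23)
  noisy$x[10] <- noisy$x[10] + 3
  fit <- align_calpha(cloud, noisy)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(all(c("rmsd", "n_retained", "n_initial", "n_rounds") %in% names(g)))
  expect_equal(g$n_rounds, nrow(tidy(fit)))
})
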