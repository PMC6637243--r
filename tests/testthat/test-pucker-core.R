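test_that("planar hexagon has zero amplitude and undefined angles", {
  psi <- 2 * pi * (0:5) / 6
  hexagon <- ring_coords(cbind(1.5 * cos(psi), 1.5 * sin(psi), 0))
  p <- cremer_pople(hexagon)
  expect_lt(p$Q, 1e-12)
  expect_true(p$planar)
  expect_identical(classify_pucker(p)$conformer, "UNDEFINED")
})

test_that("alternating out-of-plane displacements give a pure chair component", {
  psi <- 2 * pi * (0:5) / 6
  pos <- cbind(1.5 * cos(psi), 1.5 * sin(psi), 0.25 * (-1)^(0:5))
  p <- cremer_pople(ring_coords(pos))
  expect_lt(abs(p$q2), 1e-12)
  expect_equal(p$q3, sqrt(6) * 0.25, tolerance = 1e-12)
  expect_equal(p$theta, 0, tolerance = 1e-9)
})

test_that("ideal-ring construction round-trips through the decomposition", {
  lib <- build_conformer_library()
  i <- match("1S3", lib$label)
  r <- ideal_ring(0.60, lib$theta_ref[i], lib$phi_ref[i])
  p <- cremer_pople(r)
  expect_equal(p$Q, 0.60, tolerance = 1e-6)
  expect_equal(p$theta, lib$theta_ref[i], tolerance = 1e-6)
  expect_equal(p$phi, lib$phi_ref[i], tolerance = 1e-6)
})

test_that("puckering coordinates are rigid-body invariant", {
  set.seed(11)
  ref <- cremer_pople(ideal_ring(0.62, 73, 211))
  for (i in 1:100) {
    moved <- random_rigid_transform(ideal_ring(0.62, 73, 211))
    p <- cremer_pople(ring_coords(moved))
    expect_lt(abs(p$Q - ref$Q), 1e-8)
    expect_lt(abs(p$theta - ref$theta), 1e-8)
    expect_lt(min(abs(p$phi - ref$phi), 360 - abs(p$phi - ref$phi)), 1e-8)
  }
})

test_that("amplitude decomposes exactly into its components", {
  set.seed(12)
  for (i in 1:25) {
    r <- ideal_ring(runif(1, 0.2, 0.9), runif(1, 0, 180), runif(1, 0, 360))
    p <- cremer_pople(ring_coords(random_rigid_transform(r)))
    expect_lt(abs(p$Q^2 - (p$q2^2 + p$q3^2)), 1e-9)
  }
})

test_that("decomposition matches a brute-force loop oracle on random rings", {
  set.seed(13)
  for (i in 1:20) {
    r <- random_rigid_transform(
      ideal_ring(runif(1, 0.3, 0.8), runif(1, 5, 175), runif(1, 0, 360)))
    p <- cremer_pople(ring_coords(r))
    o <- brute_force_cp(r)
    expect_equal(p$Q, o$Q, tolerance = 1e-9)
    expect_equal(p$theta, o$theta, tolerance = 1e-8)
    expect_equal(p$phi, o$phi, tolerance = 1e-8)
  }
})

test_that("degenerate geometry is rejected, not silently decomposed", {
  line <- cbind(seq(0, 5, length.out = 6) + 1, 0, 0)
  expect_error(cremer_pople(line), "degenerate|collinear")
  coincident <- matrix(1, 6, 3)
  expect_error(ring_coords(coincident), "distance")
})

test_that("library holds the 38 canonical conformers on the expected bands", {
  lib <- build_conformer_library()
  expect_identical(nrow(lib), 38L)
  expect_false(anyDuplicated(lib$label) > 0)
  expect_identical(sum(lib$family == "chair"), 2L)
  expect_identical(sum(lib$family == "boat"), 6L)
  expect_identical(sum(lib$family == "skew-boat"), 6L)
  expect_identical(sum(lib$family == "half-chair"), 12L)
  expect_identical(sum(lib$family == "envelope"), 12L)

  eq <- lib[lib$band == "equator", ]
  expect_true(all(abs(eq$theta_ref - 90) < 1e-9))
  # boats and skew-boats alternate every 30 degrees around the equator
  phis <- sort(eq$phi_ref)
  expect_equal(diff(phis), rep(30, 11), tolerance = 1e-9)
  fam_by_phi <- eq$family[order(eq$phi_ref)]
  expect_true(all(fam_by_phi == rep(c("boat", "skew-boat"), 6)))

  # the three itinerary anchors sit at distinct equatorial meridians
  anchors <- lib[lib$label %in% c("1S3", "1,4B", "1S5"), ]
  expect_identical(anchors$band, rep("equator", 3))
  expect_identical(anyDuplicated(anchors$phi_ref), 0L)
})

test_that("poles classify as the two chairs regardless of phi", {
  for (phi in c(0, 77, 191, 359)) {
    expect_identical(classify_pucker(pucker(0.57, 0, phi))$conformer, "4C1")
    expect_identical(classify_pucker(pucker(0.57, 180, phi))$conformer, "1C4")
  }
})

test_that("classification recovers every conformer under 5-degree jitter", {
  lib <- build_conformer_library()
  set.seed(14)
  for (i in seq_len(nrow(lib))) {
    for (k in 1:3) {
      # displacement of at most 5 degrees in a random tangent direction
      ang <- runif(1, 0, 2 * pi)
      mag <- runif(1, 0, 5)
      th <- min(180, max(0, lib$theta_ref[i] + mag * cos(ang)))
      s <- max(sin(th * pi / 180), 0.1)
      ph <- (lib$phi_ref[i] + mag * sin(ang) / s) %% 360
      got <- classify_pucker(pucker(0.6, th, ph), lib)$conformer
      # jitter across a pole can legitimately leave the label basin only
      # when theta clamps; the equator/tropic cases must be exact
      if (lib$band[i] != "pole") expect_identical(got, lib$label[i])
    }
  }
})

test_that("cyclic relabelling of the ring atoms moves the pucker predictably", {
  # advancing the atom origin by two positions (O5,C1..C5 -> C2,C3..C1)
  # advances the m=2 phase by 2 x 120 degrees and keeps chair parity:
  # phi shifts by +240, theta and Q are unchanged
  r <- ideal_ring(0.6, 90, 210)
  p0 <- cremer_pople(r)
  shifted <- unclass(r)[c(3:6, 1:2), ]
  p2 <- cremer_pople(ring_coords(shifted))
  expect_equal(p2$Q, p0$Q, tolerance = 1e-9)
  expect_equal(p2$theta, p0$theta, tolerance = 1e-8)
  expect_equal((p0$phi + 240) %% 360, p2$phi, tolerance = 1e-8)
  # odd shifts flip alternation parity: theta mirrors, phi advances 120
  r3 <- ideal_ring(0.6, 50.77, 210)
  q0 <- cremer_pople(r3)
  p1 <- cremer_pople(ring_coords(unclass(r3)[c(2:6, 1), ]))
  expect_equal(p1$theta, 180 - q0$theta, tolerance = 1e-6)
  expect_equal(p1$phi, (q0$phi + 120) %% 360, tolerance = 1e-6)
})

test_that("mercator projection preserves order, length and ranges", {
  expect_identical(nrow(mercator(list())), 0L)
  one <- mercator(list(pucker(0.6, 0, 123)))
  expect_identical(nrow(one), 1L)
  expect_equal(one$theta, 0)

  # a 1S3 -> 4H3 -> 4C1 relaxation path descends monotonically in theta
  lib <- build_conformer_library()
  waypoints <- c("1S3", "4H3", "4C1")
  thetas <- lib$theta_ref[match(waypoints, lib$label)]
  path <- lapply(seq_along(waypoints), function(i)
    pucker(0.6, thetas[i], 210))
  m <- mercator(path)
  expect_identical(nrow(m), 3L)
  expect_true(all(diff(m$theta) < 0))
  expect_equal(m$theta[3], 0)
})
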