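test_that("superposition removes rigid motion and flags atom mismatches", {
  ct <- basic_mock(n_frames = 5)
  ref <- ct$frames[[1]]

  # identical frame: identity transform
  sup <- superpose(ref, ref)
  expect_equal(sup$protein, ref$protein, tolerance = 1e-10)

  # rotated + translated copy comes back exactly
  set.seed(21)
  R <- random_rotation()
  moved <- complex_frame(ref$protein %*% t(R) + 3,
                         lapply(ref$ligand, function(m) m %*% t(R) + 3),
                         frame_index = 1L)
  sup <- superpose(moved, ref)
  expect_lt(rmsd(sup$protein, ref$protein), 1e-10)
  expect_lt(rmsd(sup$ligand[["1"]], ref$ligand[["1"]]), 1e-10)

  bad <- complex_frame(ref$protein[-1, ], ref$ligand)
  expect_error(superpose(bad, ref), "differ")
})

test_that("a single displaced ligand atom gives the closed-form RMSD", {
  ct <- basic_mock(n_frames = 3)
  ref <- ct$frames[[1]]
  frame <- ref
  frame$ligand[["2"]]["C3", ] <- frame$ligand[["2"]]["C3", ] + c(0.9, 0, 0)
  prof <- rmsd_series(list(ref, frame), ct$subsite_map)
  n_atoms <- nrow(ref$ligand[["2"]])
  expect_equal(prof[["+1"]][2], 0.9 / sqrt(n_atoms), tolerance = 1e-10)
  expect_equal(prof[["-1"]][2], 0, tolerance = 1e-10)
  expect_equal(prof$protein[2], 0, tolerance = 1e-10)
})

test_that("rigid trajectories profile to zero and frame 0 is always zero", {
  ct <- basic_mock(n_frames = 20)
  # apply a different random rigid motion to every frame
  set.seed(22)
  frames <- lapply(ct$frames, function(f) {
    R <- random_rotation(); t <- runif(3, -8, 8)
    complex_frame(sweep(f$protein %*% t(R), 2, t, "+"),
                  lapply(f$ligand, function(m) sweep(m %*% t(R), 2, t, "+")),
                  f$frame_index)
  })
  prof <- rmsd_series(frames, ct$subsite_map)
  expect_true(all(abs(as.matrix(prof[-1])) < 1e-8))

  flex <- build_mock_complex(mock_complex_spec(
    ligand_subsites = c("-1", "+1"),
    pucker_spec = pucker_path_spec(c("4C1", "1S3"), c(0.7, 0.3),
                                   n_frames = 15, seed = 3)))
  p2 <- rmsd_series(flex$frames, flex$subsite_map)
  expect_true(all(abs(as.matrix(p2[1, -1])) < 1e-10))
})

test_that("one global rigid transform of all frames changes nothing", {
  ct <- basic_mock(n_frames = 10, waypoints = c("4C1", "4H3"),
                   dwell = c(0.5, 0.5), noise = 2, seed = 9)
  prof <- rmsd_series(ct$frames, ct$subsite_map)
  set.seed(23)
  R <- random_rotation(); t <- runif(3, -10, 10)
  moved <- lapply(ct$frames, function(f)
    complex_frame(sweep(f$protein %*% t(R), 2, t, "+"),
                  lapply(f$ligand, function(m) sweep(m %*% t(R), 2, t, "+")),
                  f$frame_index))
  prof2 <- rmsd_series(moved, ct$subsite_map)
  expect_lt(max(abs(as.matrix(prof[-1]) - as.matrix(prof2[-1]))), 1e-8)
})

test_that("puckering -1 residue is more flexible than rigid +1", {
  ct <- build_mock_complex(mock_complex_spec(
    ligand_subsites = c("-1", "+1"),
    pucker_spec = pucker_path_spec(c("4C1", "1S3", "4H3"),
                                   c(0.6, 0.25, 0.15),
                                   n_frames = 40, angular_noise_sigma = 3,
                                   seed = 31),
    seed = 31))
  prof <- rmsd_series(ct$frames, ct$subsite_map)
  expect_gt(mean(prof[["-1"]]), mean(prof[["+1"]]))

  # doubling the angular noise weakly increases -1 flexibility
  quiet <- basic_mock(n_frames = 40, waypoints = "4C1", noise = 2, seed = 8)
  loud <- basic_mock(n_frames = 40, waypoints = "4C1", noise = 4, seed = 8)
  pq <- rmsd_series(quiet$frames, quiet$subsite_map)
  pl <- rmsd_series(loud$frames, loud$subsite_map)
  expect_gte(mean(pl[["-1"]]), mean(pq[["-1"]]))
})

test_that("five-residue ligand emits one series per subsite", {
  labels <- c("-1", "+1", "+2", "+3", "+2'")
  ct <- build_mock_complex(mock_complex_spec(
    ligand_subsites = labels,
    pucker_spec = pucker_path_spec("4C1", n_frames = 6, seed = 2)))
  prof <- rmsd_series(ct$frames, ct$subsite_map)
  expect_setequal(setdiff(names(prof), "frame"),
                  c("protein", "ligand", labels))
  expect_identical(nrow(prof), 6L)
  long <- flexibility_long(prof)
  expect_identical(nrow(long), 6L * (2L + length(labels)))

  expect_error(rmsd_series(ct$frames, character(0)), "empty subsite map")
  expect_error(rmsd_series(ct$frames, c("1" = "+1")), "-1")
})

test_that("series match the quaternion-method superposition oracle", {
  ct <- build_mock_complex(mock_complex_spec(
    ligand_subsites = c("-1", "+1"),
    pucker_spec = pucker_path_spec(c("4C1", "1,4B"), c(0.5, 0.5),
                                   n_frames = 10, angular_noise_sigma = 4,
                                   seed = 17),
    rigid_jitter_sigma = 0.1,
    seed = 17))
  # perturb protein too so the fit is non-trivial
  set.seed(24)
  frames <- lapply(ct$frames, function(f) {
    f$protein <- f$protein + matrix(rnorm(length(f$protein), 0, 0.05),
                                    nrow(f$protein))
    random_rigid_frame(f)
  })
  ref <- frames[[1]]
  prof <- rmsd_series(frames, ct$subsite_map, reference = ref)
  for (i in seq_along(frames)) {
    fit <- quaternion_superpose(frames[[i]]$protein, ref$protein)
    expect_equal(prof$protein[i],
                 sqrt(mean(rowSums((fit$apply(frames[[i]]$protein) -
                                      ref$protein)^2))),
                 tolerance = 1e-8)
    expect_equal(prof[["-1"]][i],
                 sqrt(mean(rowSums((fit$apply(frames[[i]]$ligand[["1"]]) -
                                      ref$ligand[["1"]])^2))),
                 tolerance = 1e-8)
  }
})
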