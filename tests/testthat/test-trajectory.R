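test_that("per-frame classification preserves order and flags bad frames", {
  traj <- simulate_pucker_path(
    pucker_path_spec("4C1", n_frames = 50, angular_noise_sigma = 0,
                     Q_noise_sigma = 0))
  pf <- per_frame_conformers(traj)
  expect_length(pf, 50)
  expect_true(all(conformer_labels(pf) == "4C1"))

  expect_error(per_frame_conformers(list()), "empty")

  bad <- traj$frames
  bad[[7]] <- matrix(1, 6, 3)  # coincident atoms
  expect_error(per_frame_conformers(bad), "frame 6")
})

test_that("generator mixtures come back with matching label inventory", {
  spec <- pucker_path_spec(c("4C1", "4H3"), c(0.9, 0.1), n_frames = 300,
                           angular_noise_sigma = 2, seed = 5)
  pf <- per_frame_conformers(simulate_pucker_path(spec))
  occ <- occupancy(pf)
  expect_identical(occ$dominant, "4C1")
  expect_gt(occ$percent[["4C1"]], 80)
  expect_true("4H3" %in% names(occ$percent))
})

test_that("occupancy arithmetic reproduces a published-style distribution row", {
  # 372 skew-boat + 344 boat frames among 1000 give 37.2% / 34.4%
  labels <- rep(c("1S3", "1,4B", "4E", "4H3", "4C1"),
                c(372, 344, 139, 81, 64))
  occ <- occupancy(labels)
  expect_identical(occ$n_frames, 1000L)
  expect_equal(occ$percent[["1S3"]], 37.2, tolerance = 1e-12)
  expect_equal(occ$percent[["1,4B"]], 34.4, tolerance = 1e-12)
  expect_identical(occ$dominant, "1S3")
  expect_equal(sum(occ$percent), 100, tolerance = 1e-6)
})

test_that("occupancy sums to 100 and omits unobserved conformers", {
  set.seed(6)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    labels <- sample(c("4C1", "4H3", "4E", "1S3", "1,4B", "E3")[1:k],
                     200, replace = TRUE)
    occ <- occupancy(labels)
    expect_equal(sum(occ$percent), 100, tolerance = 1e-6)
    expect_setequal(names(occ$percent), unique(labels))
    expect_equal(max(occ$percent), occ$percent[[occ$dominant]])
  }
  expect_error(occupancy(character(0)), "at least one")
})

test_that("excursion segmentation matches a run-length oracle", {
  expect_identical(nrow(excursions(rep("4C1", 25))), 0L)

  stream <- rep(c("4C1", "4H3", "1S3", "4C1"), c(10, 3, 2, 10))
  ex <- excursions(stream)
  expect_identical(nrow(ex), 1L)
  expect_identical(ex$start_frame, 10L)
  expect_identical(ex$end_frame, 14L)
  expect_true(ex$reached_equator)

  two <- rep(c("4C1", "4E", "4C1", "4H3", "1,4B", "4C1"),
             c(5, 2, 6, 1, 3, 5))
  ex2 <- excursions(two)
  expect_identical(nrow(ex2), 2L)
  expect_false(ex2$reached_equator[1])  # 4E burst never reaches equator
  expect_true(ex2$reached_equator[2])

  set.seed(7)
  for (i in 1:10) {
    labels <- sample(c("4C1", "4H3", "1S3"), 80, replace = TRUE,
                     prob = c(0.7, 0.2, 0.1))
    ex <- excursions(labels)
    oracle <- runs_oracle(labels)
    expect_identical(nrow(ex), length(oracle))
    if (length(oracle) > 0) {
      expect_identical(ex$start_frame, vapply(oracle, `[[`, integer(1), "start"))
      expect_identical(ex$end_frame, vapply(oracle, `[[`, integer(1), "end"))
    }
    # conservation: excursion frames plus ground-state frames cover the run
    expect_identical(sum(ex$n_frames) + sum(labels == "4C1"), 80L)
  }
})

test_that("itinerary assignment reads the equatorial anchors", {
  # inventory with a 1S3 excursion: the GH2-type skew-boat path
  gh2 <- occupancy(rep(c("4C1", "4H3", "1S3", "E3", "4E"),
                       c(980, 5, 13, 1, 1)))
  a <- assign_itinerary(gh2)
  expect_identical(a$itinerary, "GH2-type")
  expect_true(a$alph_compatible)
  expect_equal(unname(a$support[["GH2-type"]]), 1)

  # pure ground state: nothing ALPH-diagnostic
  none <- assign_itinerary(occupancy(rep("4C1", 100)))
  expect_identical(none$itinerary, "NONE")
  expect_false(none$alph_compatible)
  expect_true(all(none$support == 0))

  # two anchors present: both reported, argmax selected
  both <- assign_itinerary(occupancy(rep(c("4C1", "1S3", "1,4B"),
                                         c(284, 372, 344))))
  expect_setequal(both$supported, c("GH2-type", "GH1/GH35-type"))
  expect_identical(both$itinerary, "GH2-type")
  expect_equal(unname(both$support[["GH2-type"]]), 372 / (372 + 344))
  expect_equal(sum(both$support), 1)
})

test_that("itinerary assignment is a pure function of the table", {
  occ <- occupancy(rep(c("4C1", "1S5", "4E"), c(90, 8, 2)))
  a1 <- assign_itinerary(occ)
  a2 <- assign_itinerary(occ)
  expect_identical(a1, a2)
  expect_identical(a1$itinerary, "GH42-type")
})

test_that("adding 1S5 frames weakly increases GH42-type support", {
  base <- rep(c("4C1", "1S3", "4H3"), c(900, 60, 40))
  prev <- -1
  for (extra in c(0, 10, 50, 200)) {
    occ <- occupancy(c(base, rep("1S5", extra)))
    s <- assign_itinerary(occ)$support[["GH42-type"]]
    expect_gte(s, prev)
    prev <- s
  }
  expect_gt(prev, 0)
})

test_that("wide occupancy export renders absent conformers as a dash", {
  tabs <- list(runA = occupancy(rep(c("4C1", "1S3"), c(98, 2))),
               runB = occupancy(rep("4C1", 50)))
  wide <- occupancy_wide(tabs)
  expect_identical(wide[["1S3"]][1], "2.0")
  expect_identical(wide[["1S3"]][2], "—")
})

test_that("BED export writes excursions as 0-based half-open intervals", {
  stream <- rep(c("4C1", "4H3", "1S3", "4C1"), c(10, 3, 2, 10))
  f <- tempfile(fileext = ".tsv")
  bed <- write_excursions_bed(excursions(stream), f)
  expect_identical(bed$start, 10L)
  expect_identical(bed$end, 15L)          # exclusive end = inclusive + 1
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_identical(back$end - back$start, 5L)
})
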