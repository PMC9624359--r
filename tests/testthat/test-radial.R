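test_that("relative minima reproduce the toy worked values", {
  dom <- toy_domain()
  D <- distance_matrix(dom)
  S <- dom$labels
  # self-distance counts at rank 1 for every member
  for (x in S) expect_equal(relative_min(x, S, 1, D)$value, 0)
  expect_equal(relative_min(1, S, 2, D)$value, sqrt(5))
  expect_equal(relative_min(1, S, 3, D)$value, sqrt(10))
  expect_equal(relative_min(1, S, 4, D)$value, sqrt(13))
  # third-least distance from q is exactly 5, attained by p
  rq <- relative_min(4, S, 3, D)
  expect_equal(rq$value, 5)
  expect_identical(rq$achiever, 3L)
  expect_equal(relative_min(4, S, 4, D)$value, sqrt(34))
})

test_that("radial balls are the closed balls of the worked example", {
  dom <- toy_domain()
  D <- distance_matrix(dom)
  S <- dom$labels
  expect_identical(radial_ball(1, S, 1, D), 1L)
  expect_identical(radial_ball(1, S, 2, D), c(1L, 4L))
  expect_identical(radial_ball(1, S, 3, D), c(1L, 3L, 4L))
  expect_identical(radial_ball(1, S, 4, D), S)
  expect_identical(radial_ball(2, S, 3, D), c(1L, 2L, 3L))
  # center removed from the subset: ball around q within {x, y, p}
  expect_identical(radial_ball(4, c(1L, 2L, 3L), 3, D), c(1L, 2L, 3L))
})

test_that("radial levels outside the subset raise errors", {
  dom <- toy_domain()
  D <- distance_matrix(dom)
  expect_error(relative_min(1, dom$labels, 5, D), "exceeds subset size")
  expect_error(relative_min(1, dom$labels, 0, D), ">= 1")
  expect_error(relative_min(1, integer(0), 1, D), "nonempty")
})

test_that("relative minima match the explicit-sort oracle on random domains", {
  for (seed in 1:8) {
    n <- sample(4:12, 1)
    dom <- random_domain(n, seed + 100)
    D <- distance_matrix(dom)
    subset <- sort(sample(dom$labels, sample(2:n, 1)))
    centers <- c(subset[1], setdiff(dom$labels, subset)[1])
    for (center in centers[!is.na(centers)]) {
      for (k in seq_along(subset)) {
        expect_equal(relative_min(center, subset, k, D)$value,
                     oracle_relative_min(center, subset, k, D))
      }
    }
  }
})

test_that("relative minima are monotone in k and balls are nested", {
  dom <- random_domain(10, 7)
  D <- distance_matrix(dom)
  subset <- dom$labels[-c(2, 5)]
  vals <- vapply(seq_along(subset), function(k)
    relative_min(3, subset, k, D)$value, numeric(1))
  expect_true(all(diff(vals) >= 0))
  for (k in seq_len(length(subset) - 1)) {
    bk <- radial_ball(3, subset, k, D)
    expect_gte(length(bk), k)
    expect_true(all(bk %in% radial_ball(3, subset, k + 1, D)))
  }
  # membership of the center decides whether rank 1 is zero
  expect_equal(relative_min(3, subset, 1, D)$value, 0)
  expect_gt(relative_min(2, subset, 1, D)$value, 0)
})

test_that("achiever ties break by ascending label", {
  # foods 2 and 3 exactly equidistant from food 1
  dom <- food_domain(rbind(c(0, 0), c(1, 0), c(-1, 0)))
  D <- distance_matrix(dom)
  rm <- relative_min(1, c(2L, 3L), 1, D)
  expect_identical(rm$achiever, 2L)
})

test_that("depleted-domain query on the bundled positions matches the study", {
  dom <- load_fixture("table1_animal1")
  D <- distance_matrix(dom)
  rm <- relative_min(7, setdiff(dom$labels, 16L), 4, D)
  expect_equal(rm$value, 1.7417, tolerance = 2e-3)
  expect_identical(rm$achiever, 8L)
})
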