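test_that("LMRFT step resolves the toy tie to the lower label", {
  dom <- toy_domain()
  D <- distance_matrix(dom)
  # at k = 3, x and p tie at sqrt(10); the lower label (x = 1) is chosen
  st <- lmrft_step(dom$labels, 3, D)
  expect_identical(st$target, 1L)
  expect_equal(st$score, sqrt(10))
  p <- lmrft_path(dom, k = 3, N = 2)
  expect_identical(p$labels, c(1L, 3L))
  expect_equal(p$legs, sqrt(10))
  expect_equal(p$scores, c(sqrt(10), 5))
})

test_that("LMRFT at level 1 degenerates to zero scores, smallest label", {
  dom <- random_domain(8, 3)
  st <- lmrft_step(dom$labels, 1, distance_matrix(dom))
  expect_identical(st$target, 1L)
  expect_equal(st$score, 0)
})

test_that("single-step paths have no legs", {
  p <- lmrft_path(toy_domain(), k = 2, N = 1)
  expect_length(p$labels, 1)
  expect_length(p$legs, 0)
})

test_that("LMRFT on the bundled positions eats the reported first targets", {
  dom <- load_fixture("table1_animal1")
  p <- lmrft_path(dom, k = 4, N = 5, animal = "a1")
  expect_identical(p$labels, c(16L, 7L, 17L, 8L, 18L))
  expect_equal(p$scores[1], 1.4707, tolerance = 2e-3)
  expect_equal(p$scores[2], 1.7417, tolerance = 2e-3)
})

test_that("SMRFT step restricts candidates to the current radial ball", {
  dom <- toy_domain()
  D <- distance_matrix(dom)
  # from q over {x, y, p} at k = 3: scores sqrt(13), sqrt(13), sqrt(10) -> p
  st <- smrft_step(c(1L, 2L, 3L), current = 4L, k = 3, D = D)
  expect_identical(st$target, 3L)
  expect_equal(st$score, sqrt(10))
  p <- smrft_path(dom, start = 4, k = 3, N = 2)
  expect_identical(p$labels, c(4L, 3L))
  expect_error(smrft_step(c(1L, 2L), current = 1L, k = 1, D = D),
               "removed")
})

test_that("SMRFT at level 1 walks to the nearer of two candidates", {
  dom <- food_domain(rbind(c(0, 0), c(1, 0), c(5, 0)))
  D <- distance_matrix(dom)
  st <- smrft_step(c(2L, 3L), current = 1L, k = 1, D = D)
  expect_identical(st$target, 2L)
})

test_that("exactly tied SMRFT scores resolve to the candidate nearer the agent", {
  # bundled positions, first SMRFT move of agent 1 at level 2: foods 16 and
  # 11 share the identical score d(11,16); 16 is nearer to the start 7
  dom <- load_fixture("table1_animal1")
  D <- distance_matrix(dom)
  S <- setdiff(dom$labels, 7L)
  expect_identical(radial_ball(7, S, 2, D), c(11L, 16L))
  s16 <- relative_min(16, S, 2, D)$value
  s11 <- relative_min(11, S, 2, D)$value
  expect_identical(s16, s11)  # the tie is exact: the same pair distance
  st <- smrft_step(S, current = 7L, k = 2, D = D)
  expect_identical(st$target, 16L)
})

test_that("paths never repeat foods and deplete one food per step", {
  dom <- random_domain(20, 11)
  for (mode in c("lmrft", "smrft")) {
    p <- modelled_path(dom, mode, k = 3, N = 14, start = 5)
    expect_length(p$labels, 14)
    expect_identical(anyDuplicated(p$labels), 0L)
    expect_length(p$legs, 13)
    expect_true(all(p$legs > 0))
  }
})

test_that("recorded scores equal brute-force recomputation with depletion", {
  dom <- random_domain(10, 21)
  D <- distance_matrix(dom)
  k <- 3
  p <- lmrft_path(dom, k, N = 6)
  S <- dom$labels
  for (i in seq_along(p$labels)) {
    brute <- min(vapply(S, function(e) oracle_relative_min(e, S, k, D),
                        numeric(1)))
    expect_identical(p$scores[i], brute)
    S <- setdiff(S, p$labels[i])
  }
})

test_that("every SMRFT target lies in its predecessor's radial ball", {
  dom <- random_domain(20, 31)
  D <- distance_matrix(dom)
  k <- 4
  p <- smrft_path(dom, start = 2, k = k, N = 12)
  S <- setdiff(dom$labels, p$labels[1])
  for (i in 2:length(p$labels)) {
    expect_true(p$labels[i] %in% radial_ball(p$labels[i - 1], S, k, D))
    S <- setdiff(S, p$labels[i])
  }
})

test_that("SMRFT regenerated from its own first label is identical", {
  dom <- random_domain(20, 41)
  p1 <- smrft_path(dom, start = 9, k = 3, N = 14)
  p2 <- smrft_path(dom, start = p1$labels[1], k = 3, N = 14)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$legs, p2$legs)
})

test_that("LMRFT is equivariant under relabeling on a tie-free domain", {
  dom <- random_domain(12, 51)
  set.seed(52)
  perm <- sample(dom$labels)
  coords2 <- dom$coords
  coords2[perm, ] <- dom$coords  # food perm[i] now sits where food i was
  dom2 <- food_domain(coords2)
  p1 <- lmrft_path(dom, k = 3, N = 8)
  p2 <- lmrft_path(dom2, k = 3, N = 8)
  expect_identical(p2$labels, perm[p1$labels])
  expect_equal(p2$legs, p1$legs)
})

test_that("configuration errors are raised for impossible k and N", {
  dom <- toy_domain()
  expect_error(lmrft_path(dom, k = 4, N = 2), "too large")
  expect_error(lmrft_path(dom, k = 2, N = 9), "between 1 and")
  expect_error(smrft_path(dom, start = 9, k = 2, N = 2), "not in domain")
})
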