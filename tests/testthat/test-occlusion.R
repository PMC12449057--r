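test_that("neighbor index finds exactly the atoms within the cutoff", {
  two <- makeDimer(1.7, 3.0)
  idx <- buildNeighborIndex(two, dW = 2.8)
  expect_equal(queryNeighbors(idx, c(0, 0, -1.5), cutoff = 5, exclude = 1L),
               2L)
  one <- makeShell(1.7, 4, contact = FALSE, spacing = 50)  # scattered atoms
  idx1 <- buildNeighborIndex(one, dW = 2.8)
  expect_length(queryNeighbors(idx1, coords(one)[1, ], exclude = 1L), 0)

  # all-pairs oracle on a random box
  s <- makeRandomCluster(50, box = 20, seed = 5)
  idx <- buildNeighborIndex(s, dW = 2.8)
  xyz <- coords(s)
  set.seed(17)
  for (q in 1:100) {
    p <- runif(3, -2, 22)
    cutoff <- runif(1, 1, idx@cutoff)
    d <- sqrt(colSums((t(xyz) - p)^2))
    expect_identical(queryNeighbors(idx, p, cutoff), which(d <= cutoff))
  }
})

test_that("buried-dot removal matches the spherical-cap fraction on a dimer", {
  s <- makeDimer(1.7, 2.4)
  a <- atoms(s)
  n_dots <- 1000
  cloud <- scaleDots(fibonacciDots(n_dots), c(a$x[1], a$y[1], a$z[1]), 1.7)
  kept <- removeBuriedDots(cloud, data.frame(x = a$x[2], y = a$y[2],
                                             z = a$z[2], radius = 1.7))
  frac_removed <- 1 - nDots(kept) / n_dots
  cap <- (1 - 2.4 / 3.4) / 2          # analytic spherical-cap fraction
  se <- sqrt(cap * (1 - cap) / n_dots)
  expect_lt(abs(frac_removed - cap), 3 * se)
  expect_equal(dotAreas(kept), dotAreas(cloud)[attr(kept, "kept")])

  # no neighbors: everything kept; engulfing sphere: nothing kept
  expect_equal(nDots(removeBuriedDots(cloud, NULL)), n_dots)
  none <- removeBuriedDots(cloud, data.frame(x = a$x[1], y = a$y[1],
                                             z = a$z[1], radius = 2.9))
  expect_equal(nDots(none), 0L)
})

test_that("normal casting solves the first ray-sphere intersection", {
  # no neighbors -> vacuously non-occluded
  r0 <- castNormal(c(0, 0, 0), c(0, 0, 1),
                   data.frame(x = numeric(), y = numeric(), z = numeric(),
                              radius = numeric()), dW = 2.8)
  expect_false(r0$occluded)

  # collinear: length = center distance - radius
  r1 <- castNormal(c(0, 0, 0), c(0, 0, 1),
                   data.frame(x = 0, y = 0, z = 3.0, radius = 1.5), 2.8)
  expect_true(r1$occluded)
  expect_equal(r1$length, 1.5)

  # oblique: smaller root of t^2 - 4t + 3.56 = 0, solved independently
  roots <- sort(Re(polyroot(c(3.56, -4, 1))))
  r2 <- castNormal(c(0, 0, 0), c(0, 0, 1),
                   data.frame(x = 0, y = 1, z = 2, radius = 1.2), 2.8)
  expect_true(r2$occluded)
  expect_equal(r2$length, roots[1], tolerance = 1e-9)

  # origin strictly inside a neighbor: occluded at zero length
  r3 <- castNormal(c(0, 0, 0), c(0, 0, 1),
                   data.frame(x = 0, y = 0, z = 0.5, radius = 2), 2.8)
  expect_true(r3$occluded)
  expect_equal(r3$length, 0)

  # beyond the water diameter: disregarded
  r4 <- castNormal(c(0, 0, 0), c(0, 0, 1),
                   data.frame(x = 0, y = 0, z = 5, radius = 1.5), 2.8)
  expect_false(r4$occluded)

  expect_error(castNormal(c(0, 0, 0), c(0, 0, 1.01),
                          data.frame(x = 0, y = 0, z = 3, radius = 1), 2.8),
               "domain error")
})

test_that("an isolated atom has no occluded dots", {
  s <- makeShell(1.7, 4, contact = FALSE, spacing = 30)
  rec <- occludedSurface(s, density = 3)
  expect_equal(sum(rec$occluded), 0L)
  expect_true(all(is.na(rec$length)))
})

test_that("mirror-symmetric dimer atoms occlude identically under a mirrored lattice", {
  s <- makeDimer(1.7, 3.0)
  cl1 <- atomDots(c(0, 0, -1.5), 1.7, density = 5)
  P2 <- dotPoints(cl1)
  P2[, 3] <- -P2[, 3]                 # reflect through the contact plane
  cl2 <- new("DotCloud", points = P2, areas = dotAreas(cl1),
             method = "fibos", radius = 1.7, center = c(0, 0, 1.5),
             scaled = TRUE)
  rec <- occludedSurface(s, dotClouds = list(cl1, cl2))
  r1 <- rec[rec$atom_serial == 1, ]
  r2 <- rec[rec$atom_serial == 2, ]
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(sum(r1$occluded), sum(r2$occluded))
  expect_equal(sort(r1$length[r1$occluded]), sort(r2$length[r2$occluded]))
})

test_that("engine equals the brute-force oracle on random clusters", {
  for (seed in c(2, 9)) {
    s <- makeRandomCluster(12, box = 11, seed = seed)
    eng <- occludedSurface(s, density = 3)
    ora <- bruteForceOcclusion(s, density = 3)
    expect_equal(eng, ora)
  }
})

test_that("occlusion is invariant under a rigid motion of structure and lattice", {
  s <- makeRandomCluster(10, box = 10, seed = 21)
  clouds <- structure_clouds(s, density = 3)
  rec <- occludedSurface(s, dotClouds = clouds)
  R <- random_rotation(4)
  shift <- c(5, -3, 2)
  s2 <- transform_structure(s, R, shift)
  clouds2 <- lapply(clouds, transform_cloud, R = R, shift = shift)
  rec2 <- occludedSurface(s2, dotClouds = clouds2)
  expect_equal(rec$occluded, rec2$occluded)
  expect_equal(rec$length, rec2$length, tolerance = 1e-6)
  expect_equal(rec$occluder_serial, rec2$occluder_serial)
})

test_that("closer approach never reduces either atom's occluded-dot count", {
  counts <- sapply(seq(4.2, 3.4, by = -0.2), function(d) {
    rec <- occludedSurface(makeDimer(1.7, d), density = 5)
    c(sum(rec$occluded[rec$atom_serial == 1]),
      sum(rec$occluded[rec$atom_serial == 2]))
  })
  expect_true(all(diff(counts[1, ]) >= 0))
  expect_true(all(diff(counts[2, ]) >= 0))
})

test_that("every occluded normal length lies in [0, dW]", {
  for (dW in c(1.5, 2.8)) {
    rec <- occludedSurface(makeRandomCluster(15, box = 10, seed = 3),
                           density = 3, dW = dW)
    L <- rec$length[rec$occluded]
    expect_true(all(L >= 0 & L <= dW))
  }
})
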