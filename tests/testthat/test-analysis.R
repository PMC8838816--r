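test_that("kabschRMSD handles identity, rigid motion and the hand case", {
  X <- coords(buildChain(3))
  expect_lt(kabschRMSD(X, X), 1e-12)
  expect_equal(kabschRMSD(X, X + 5), 0, tolerance = 1e-10)
  # unit square with one corner lifted 1 A, no superposition: sqrt(1/4)
  sq <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3, byrow = TRUE)
  sq2 <- sq; sq2[4, 3] <- 1
  expect_equal(kabschRMSD(sq, sq2, superpose = FALSE), 0.5)
  expect_error(kabschRMSD(X, X[-1, ]), "equal size")
})

test_that("kabschRMSD agrees with the bio3d superposition oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    X <- matrix(rnorm(3 * n, sd = 4), n, 3)
    Y <- X + matrix(rnorm(3 * n, sd = 0.7), n, 3)
    ours <- kabschRMSD(X, Y)
    fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(X)),
                                           mobile = as.numeric(t(Y))))
    ref <- bio3d::rmsd(as.numeric(t(X)), fit)  # bio3d rounds to 3 digits
    expect_lt(abs(ours - ref), 1e-3)
  }
})

test_that("superposed RMSD is a pseudo-metric on small frame sets", {
  set.seed(13)
  n <- 8
  frames <- lapply(1:5, function(i) matrix(rnorm(3 * n, sd = 3), n, 3))
  for (i in 1:5) for (j in 1:5) {
    dij <- kabschRMSD(frames[[i]], frames[[j]])
    expect_gte(dij, 0)
    expect_equal(dij, kabschRMSD(frames[[j]], frames[[i]]),
                 tolerance = 1e-8)
    if (i == j) expect_lt(dij, 1e-10)
    for (k in 1:5)
      expect_lte(dij, kabschRMSD(frames[[i]], frames[[k]]) +
                      kabschRMSD(frames[[k]], frames[[j]]) + 1e-8)
  }
})

test_that("trajectory RMSD summarises per-frame deviations", {
  sys <- chain_system(4)
  X <- coords(sys$model)
  arr <- array(0, c(nrow(X), 3, 3))
  arr[, , 1] <- X
  arr[, , 2] <- X
  arr[, , 3] <- X
  tr <- new("CGTrajectory", coords = arr, times = 1:3, box = diag(3) * 100,
            seed = NA_integer_, config = list())
  st <- trajectoryRMSD(tr, X)
  expect_equal(st$mean, 0)
  expect_equal(st$sd, 0)
  # two frames at raw RMSD 1 and 3 give mean 2, sd sqrt(2)
  n <- nrow(X)
  arr2 <- array(0, c(n, 3, 2))
  arr2[, , 1] <- X + matrix(c(1, 0, 0), n, 3, byrow = TRUE)
  arr2[, , 2] <- X + matrix(c(3, 0, 0), n, 3, byrow = TRUE)
  tr2 <- new("CGTrajectory", coords = arr2, times = 1:2,
             box = diag(3) * 100, seed = NA_integer_, config = list())
  st2 <- trajectoryRMSD(tr2, X, superpose = FALSE)
  expect_equal(st2$mean, 2)
  expect_equal(st2$sd, sd(c(1, 3)))
  # langevin run stays near but not at the start structure
  tr3 <- runDynamics(sys$model, sys$topology, quick_cfg(), 2000, 100)
  st3 <- trajectoryRMSD(tr3, coords(sys$model))
  expect_gt(st3$mean, 0)
  expect_lt(st3$mean, 5)
  expect_error(trajectoryRMSD(tr3, X[-1, ]), "bead counts")
})

test_that("cross-RMSD counts pairs and respects rigid invariance", {
  X <- coords(buildChain(3))
  n <- nrow(X)
  mktraj <- function(flist) {
    arr <- array(0, c(n, 3, length(flist)))
    for (i in seq_along(flist)) arr[, , i] <- flist[[i]]
    new("CGTrajectory", coords = arr, times = seq_along(flist),
        box = diag(3) * 100, seed = NA_integer_, config = list())
  }
  A <- mktraj(list(X))
  expect_equal(crossRMSD(A, A)$mean, 0)
  expect_identical(crossRMSD(A, A)$n_pairs, 1L)
  A3 <- mktraj(list(X, X + 1, X + 2))
  B4 <- mktraj(list(X, X - 1, X + 3, X * 1))
  expect_identical(crossRMSD(A3, B4)$n_pairs, 12L)
  # rigid rotation leaves superposed cross-RMSD at zero
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  Brot <- mktraj(list(X %*% R, (X + 2) %*% R))
  A2 <- mktraj(list(X, X + 2))
  expect_lt(crossRMSD(A2, Brot)$mean, 1e-8)
})

test_that("twistAngle follows the atan2 dihedral convention", {
  expect_equal(twistAngle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               0)
  expect_equal(twistAngle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               -90)
  # reversing the quadruple preserves the signed value's magnitude
  set.seed(17)
  for (rep in 1:20) {
    p <- lapply(1:4, function(i) rnorm(3, sd = 2))
    a1 <- twistAngle(p[[1]], p[[2]], p[[3]], p[[4]])
    a2 <- twistAngle(p[[4]], p[[3]], p[[2]], p[[1]])
    expect_equal(abs(a1), abs(a2), tolerance = 1e-9)
  }
  expect_error(twistAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "collinear|undefined")
})

test_that("twistAngle matches independent oracles on random quadruples", {
  set.seed(19)
  for (rep in 1:1000) {
    p <- lapply(1:4, function(i) rnorm(3, sd = 3))
    a <- twistAngle(p[[1]], p[[2]], p[[3]], p[[4]])
    b <- dihedral_oracle(p[[1]], p[[2]], p[[3]], p[[4]])
    d <- (a - b) %% 360
    expect_lt(min(d, 360 - d), 1e-9)
  }
  # bio3d's torsion routine is a second oracle up to its opposite sign
  # convention (it reports +90 on the reference quadruple above)
  for (rep in 1:50) {
    p <- lapply(1:4, function(i) rnorm(3, sd = 3))
    a <- twistAngle(p[[1]], p[[2]], p[[3]], p[[4]])
    b <- bio3d::torsion.xyz(unlist(p))
    d <- abs(a + b) %% 360
    expect_lt(min(d, 360 - d), 1e-6)
  }
})

test_that("twist statistics pool junctions, chains and frames", {
  ch <- buildChain(6)
  st <- twistStats(NULL, ch)
  expect_equal(st$average, 0, tolerance = 1e-8)
  expect_equal(st$sd, 0, tolerance = 1e-8)
  expect_identical(st$n, 5L)
  expect_true(st$min <= st$average && st$average <= st$max)
  fib <- buildFibril(4, c(2, 2), 5, "Ibeta")
  expect_identical(twistStats(NULL, fib)$n, 4L * 4L)
  # chains with < 2 residues are skipped with a warning
  one <- buildChain(1)
  expect_error(suppressWarnings(twistStats(NULL, one)), "residue")
})

test_that("pair-distance statistics recover static and dynamic geometry", {
  ch <- buildChain(4)
  st <- pairDistanceStats(NULL, ch, "O2-O3")
  expect_equal(st$mean, 2.88, tolerance = 1e-9)
  expect_equal(st$sd, 0, tolerance = 1e-12)
  st2 <- pairDistanceStats(NULL, ch, "O2-O2", neighbours = "2nd")
  expect_equal(st2$mean, 10.44, tolerance = 1e-7)
  # histogram integrates to 1
  sys <- chain_system(5)
  tr <- runDynamics(sys$model, sys$topology, quick_cfg(), 2000, 50)
  st3 <- pairDistanceStats(tr, sys$model, "O2-O3")
  h <- st3$histogram
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-8)
  expect_error(pairDistanceStats(NULL, ch, "O5-O6"), "unknown pair")
  expect_error(pairDistanceStats(NULL, ch, "O2-O2"), "ambiguous")
})
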