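test_that("built chains satisfy every reference distance exactly", {
  tab <- bondedParameterTable()
  for (allo in c("Ialpha", "Ibeta", "II")) {
    ch <- buildChain(6, allo)
    co <- coords(ch)
    bt <- makeBondTerms(ch)
    d <- sqrt(rowSums((co[bt$i, ] - co[bt$j, ])^2))
    expect_lt(max(abs(d - bt$r0)), 1e-6)
  }
  # the printed spot checks
  ch1 <- buildChain(1, "Ibeta")
  co <- coords(ch1)
  b <- beads(ch1)
  d_ <- function(a1, a2) sqrt(sum((co[b$atom == a1, ] - co[b$atom == a2, ])^2))
  expect_equal(d_("O2", "O3"), 2.88, tolerance = 1e-9)
  expect_equal(d_("C6", "O6"), 1.43, tolerance = 1e-9)
  ch3 <- buildChain(3, "Ialpha")
  co3 <- coords(ch3)
  b3 <- beads(ch3)
  i0 <- which(b3$residue == 0 & b3$atom == "O2")
  i2 <- which(b3$residue == 2 & b3$atom == "O2")
  expect_equal(sqrt(sum((co3[i0, ] - co3[i2, ])^2)), 10.44,
               tolerance = 1e-7)
})

test_that("built chains are untwisted and reject bad arguments", {
  ch <- buildChain(5)
  tw <- twistStats(NULL, ch)
  expect_lt(abs(tw$average), 1e-8)
  expect_lt(tw$sd, 1e-8)
  expect_error(buildChain(0), "n_residues")
  expect_error(buildChain(-3), "n_residues")
})

test_that("connectivity matches brute-force enumeration and 12n-9", {
  for (n in c(1:6, 10)) {
    ch <- buildChain(n)
    conn <- schConnectivity(ch)
    expected <- if (n == 1) 6 else if (n == 2) 15 else 12 * n - 9
    expect_identical(nrow(conn), as.integer(expected))
    bf <- brute_force_pairs(ch)
    key <- function(df) sort(paste(pmin(df$i, df$j), pmax(df$i, df$j),
                                   df$class, df$label))
    expect_identical(key(conn), key(bf))
  }
  expect_identical(nrow(schConnectivity(buildChain(3))), 27L)
})

test_that("fibril lattices replicate chains without overlap", {
  fib <- buildFibril(4, c(2, 2), 5, "Ialpha")
  expect_identical(nBeads(fib), 80L)
  expect_identical(nChains(fib), 4L)
  # minimum interchain bead distance >= 2 A
  co <- coords(fib)
  chain_id <- beads(fib)$chain
  mind <- Inf
  for (a in 0:2) for (b2 in (a + 1):3) {
    A <- co[chain_id == a, ]; B <- co[chain_id == b2, ]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    mind <- min(mind, sqrt(max(min(d2), 0)))
  }
  expect_gte(mind, 2)
  # single-site lattice is exactly the single chain
  f1 <- buildFibril(1, c(1, 1), 10, "II")
  expect_equal(coords(f1), coords(buildChain(10, "II")), tolerance = 1e-12)
  # bead count arithmetic at scale
  f36 <- buildFibril(36, c(6, 6), 100, "Ibeta")
  expect_identical(nBeads(f36), 36L * 100L * 4L)
  # overlapping lattice is refused
  lat <- defaultLattice("Ibeta")
  lat$dx <- 0.5; lat$dy <- 0.5
  expect_error(buildFibril(4, c(2, 2), 5, "Ibeta", lattice = lat),
               "overlap")
  expect_error(buildFibril(3, c(2, 2), 5), "layout")
})

test_that("type II fibrils pack antiparallel sheets", {
  fib <- buildFibril(4, c(2, 2), 6, "II")
  b <- beads(fib)
  co <- coords(fib)
  zdir <- function(ch) {
    o2 <- co[b$chain == ch & b$atom == "O2", 3]
    sign(o2[length(o2)] - o2[1])
  }
  expect_identical(zdir(0), zdir(1))    # same sheet: parallel
  expect_identical(zdir(0), -zdir(2))   # next sheet: antiparallel
  # parallel allomorphs keep one polarity
  fb <- buildFibril(4, c(2, 2), 6, "Ibeta")
  bb <- beads(fb); cb <- coords(fb)
  zd <- vapply(0:3, function(ch) {
    o2 <- cb[bb$chain == ch & bb$atom == "O2", 3]
    sign(o2[length(o2)] - o2[1])
  }, 0)
  expect_true(all(zd == zd[1]))
})

test_that("atomistic mapping copies positions and validates residues", {
  # identity copy of explicit positions
  rec <- data.frame(chain = 0L, residue = 1L,
                    atom = c("O2", "O3", "C6", "O6"),
                    x = c(0, 2.88, 1, 1), y = c(0, 0, 4, 5),
                    z = c(0, 0, 2, 3))
  m <- mapAtomistic(rec)
  expect_equal(unname(coords(m)),
               matrix(c(0, 0, 0, 2.88, 0, 0, 1, 4, 2, 1, 5, 3), 4, 3,
                      byrow = TRUE))
  # extra atoms are ignored, the named four are picked
  rec2 <- rbind(rec, data.frame(chain = 0L, residue = 1L, atom = "C1",
                                x = 9, y = 9, z = 9))
  expect_equal(nBeads(mapAtomistic(rec2)), 4L)
  # a residue missing one of the four atoms names the culprit
  bad <- rec[rec$atom != "O6", ]
  expect_error(mapAtomistic(bad), "O6")
  expect_error(mapAtomistic(rec[0, ]), "empty")
  # 100-residue chain gives 400 beads
  ch <- buildChain(100)
  f <- tempfile(fileext = ".pdb")
  writeStructure(ch, f)
  expect_identical(nBeads(mapAtomistic(f)), 400L)
})

test_that("mapping round-trips through PDB at format precision", {
  ch <- buildChain(7, "Ialpha")
  f <- tempfile(fileext = ".pdb")
  writeStructure(ch, f)
  m <- mapAtomistic(f, allomorph = "Ialpha")
  expect_lt(max(abs(coords(m) - coords(ch))), 1e-3 + 1e-9)
  expect_identical(m@provenance, "mapped")
  expect_identical(nResidues(m), nResidues(ch))
})
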