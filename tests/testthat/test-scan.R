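test_that("the default grid reproduces the 18 x 3 selection protocol", {
  sp <- scanSpec()
  expect_identical(length(sp$candidate_types), 18L)
  expect_identical(sp$elastic_candidates, c(25, 250, 2500))
  expect_identical(length(sp$candidate_types) *
                   length(sp$elastic_candidates), 54L)
  expect_identical(sp$systems, c("Ialpha", "Ibeta", "II"))
})

test_that("candidates without parameters are marked, the scan continues", {
  sp <- scanSpec(candidate_types = c("SP6", "N1"), systems = "Ibeta",
                 n_residues = 4, n_steps = 200, report_every = 50)
  out <- beadTypeScan(sp)  # packaged table covers only SP6
  res <- out$results
  expect_identical(nrow(res), 6L)
  expect_true(all(res$status[res$type == "N1"] == "missing-parameters"))
  expect_true(all(res$status[res$type == "SP6"] == "ok"))
  expect_true(all(is.na(res$mean_rmsd[res$type == "N1"])))
  expect_false(any(out$ranking$type == "N1"))
})

test_that("unstable grid points are recorded as failed without rank", {
  # an absurd candidate: gigantic epsilon and overlapping sigma blows up
  params <- rbind(nonbondedParameterTable(),
                  data.frame(type_a = "XX", type_b = "XX",
                             sigma = 30, epsilon = 5e6),
                  data.frame(type_a = "XX", type_b = "TC1",
                             sigma = 30, epsilon = 5e6))
  sp <- scanSpec(candidate_types = c("SP6", "XX"), systems = "Ibeta",
                 n_residues = 6, n_steps = 500, report_every = 100)
  out <- beadTypeScan(sp, params)
  res <- out$results
  expect_true(all(res$status[res$type == "XX"] == "unstable"))
  expect_false(any(out$ranking$type == "XX"))
  expect_true(all(out$ranking$type == "SP6"))
})

test_that("the scan reproduces the published soft-spring selection", {
  sp <- scanSpec(candidate_types = "SP6", n_residues = 8, seed = 1L)
  out <- beadTypeScan(sp)
  expect_identical(out$selected$type, "SP6")
  expect_identical(out$selected$k, 2500)
  expect_true(all(diff(out$ranking$score) >= 0))
})

test_that("ranking is pure and monotone in per-system RMSD", {
  res <- data.frame(
    type = rep(c("A", "B"), each = 3),
    k = 2500,
    system = rep(c("Ialpha", "Ibeta", "II"), 2),
    mean_rmsd = c(1, 2, 3, 2, 2, 2),
    sd = 0.1, status = "ok", stringsAsFactors = FALSE)
  r1 <- rankScan(res)
  expect_identical(r1, rankScan(res))  # pure
  expect_identical(r1$type[1], "B")    # max(1,2,3)=3 > max(2,2,2)=2
  # lowering one of A's systems cannot worsen A's rank
  res2 <- res
  res2$mean_rmsd[3] <- 1.5
  r2 <- rankScan(res2)
  expect_identical(r2$type[1], "A")
  expect_identical(rankScan(res, aggregate = "mean")$type[1], "A")
})
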