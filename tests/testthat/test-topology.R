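test_that("bead typing follows the site assignment", {
  ch <- assignBeadTypes(buildChain(1))
  b <- beads(ch)
  expect_identical(b$type[match(c("CG1", "CG2", "CG3", "CG4"), b$site)],
                   c("SP6", "SP6", "TC1", "SP6"))
  expect_true(all(b$charge == 0))
  expect_equal(b$mass[b$type == "SP6"], rep(54, 3))
  expect_equal(b$mass[b$type == "TC1"], 36)
  ch100 <- assignBeadTypes(buildChain(100))
  expect_identical(as.integer(table(beads(ch100)$type)[c("TC1", "SP6")]),
                   c(100L, 300L))
  # unknown site label is an invalid model
  bad <- buildChain(1)
  expect_error(assignBeadTypes(bad, site_types = c(CG1 = "SP6")),
               "site label")
})

test_that("bond terms carry the printed (r0, k) per pair class", {
  ch <- buildChain(4)
  bt <- makeBondTerms(ch)
  look <- function(lab, cls) unique(bt[bt$label == lab & bt$class == cls,
                                       c("r0", "k")])
  expect_equal(look("O2-O6", "none"), data.frame(r0 = 6.42, k = 2500),
               ignore_attr = TRUE)
  expect_equal(look("O3-O6", "none"), data.frame(r0 = 5.76, k = 2500),
               ignore_attr = TRUE)
  expect_equal(look("O3-O3", "1st"), data.frame(r0 = 6.69, k = 30000),
               ignore_attr = TRUE)
  expect_equal(look("O2-O2", "2nd"), data.frame(r0 = 10.44, k = 30000),
               ignore_attr = TRUE)
  # soft springs only on the two flexible pairs
  expect_setequal(unique(bt$label[bt$k == 2500]), c("O2-O6", "O3-O6"))
  expect_true(all(bt$k[!bt$label %in% c("O2-O6", "O3-O6")] == 30000))
  expect_identical(nrow(makeBondTerms(buildChain(1))), 6L)
  # every (r0, k) appears in the reference table
  tab <- bondedParameterTable()
  expect_true(all(paste(bt$r0, bt$k) %in% paste(tab$r0, tab$k)))
  # a pair with no table entry is a missing parameter
  tab2 <- tab[tab$label != "O2-O3" | tab$neighbours != "none", ]
  expect_error(makeBondTerms(ch, bonded = tab2), "missing parameter")
})

test_that("the pair-label multiset per residue is allomorph-invariant", {
  sig <- function(allo) {
    bt <- makeBondTerms(buildChain(5, allo))
    sort(paste(bt$class, bt$label))
  }
  expect_identical(sig("Ialpha"), sig("Ibeta"))
  expect_identical(sig("Ialpha"), sig("II"))
})

test_that("nonbonded lookup is symmetric, exact, and closed", {
  expect_equal(nonbondedLookup("SP6", "SP6"),
               c(sigma = 4.100, epsilon = 4.290))
  expect_equal(nonbondedLookup("TC1", "SP6"),
               c(sigma = 4.840, epsilon = 0.890))
  expect_equal(nonbondedLookup("SP6", "TC1"),
               nonbondedLookup("TC1", "SP6"))
  expect_equal(nonbondedLookup("W", "SP6"),
               c(sigma = 4.250, epsilon = 4.530))
  expect_equal(nonbondedLookup("W", "TC1"),
               c(sigma = 4.150, epsilon = 0.550))
  expect_equal(nonbondedLookup("TC1", "TC1"),
               c(sigma = 3.400, epsilon = 1.510))
  tab <- nonbondedParameterTable()
  for (r in seq_len(nrow(tab)))
    expect_equal(nonbondedLookup(tab$type_b[r], tab$type_a[r], tab),
                 nonbondedLookup(tab$type_a[r], tab$type_b[r], tab))
  # no combining rules: absent pairs error
  expect_error(nonbondedLookup("SP6", "X9"), "missing parameter")
  expect_error(nonbondedLookup("W", "W"), "missing parameter")
})

test_that("bond-term count follows the 12n-9 closed form", {
  for (n in c(3, 5, 8, 10))
    expect_identical(nrow(makeBondTerms(buildChain(n))),
                     as.integer(12 * n - 9))
})

test_that("topology files round-trip and carry nm units", {
  sys <- chain_system(3)
  prefix <- tempfile()
  paths <- writeTopology(sys$model, sys$topology, prefix)
  expect_true(all(file.exists(paths)))
  itp <- readLines(paths["itp"])
  # the O2-O3 bond line carries 0.288 nm
  expect_true(any(grepl("0\\.288000", itp)))
  top <- readLines(paths["top"])
  expect_true(any(grepl("0\\.410000\\s+4\\.290000", top)))
  back <- readTopology(prefix)
  expect_equal(back@bonds$r0, sys$topology@bonds$r0, tolerance = 1e-5)
  expect_equal(back@bonds$k, sys$topology@bonds$k)
  expect_identical(back@bonds$i, sys$topology@bonds$i)
  expect_identical(back@bonds$class, sys$topology@bonds$class)
  expect_identical(back@bonds$label, sys$topology@bonds$label)
  expect_equal(back@nonbonded$sigma, sys$topology@nonbonded$sigma,
               tolerance = 1e-5)
  expect_equal(back@nonbonded$epsilon, sys$topology@nonbonded$epsilon,
               tolerance = 1e-5)
  expect_identical(back@types, sys$topology@types)
  expect_equal(back@masses, sys$topology@masses)
  # untyped model is refused
  top2 <- sys$topology
  top2@types <- rep(NA_character_, length(top2@types))
  expect_error(writeTopology(sys$model, top2, tempfile()), "types")
})
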