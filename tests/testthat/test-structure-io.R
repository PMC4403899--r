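test_that("toy structures round-trip through PDB format", {
  for (st in toyStructures()) {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeStructurePDB(st, f)
    back <- readPDB(f)
    expect_identical(residueSequence(back), residueSequence(st))
    expect_identical(back@residues$resno, st@residues$resno)
    expect_identical(back@residues$cb_virtual, st@residues$cb_virtual)
    for (col in c("ca_x", "ca_y", "ca_z", "cb_x", "cb_y", "cb_z"))
      expect_equal(back@residues[[col]], st@residues[[col]], tolerance = 2e-3)
  }
})

test_that("alternate locations resolve to highest occupancy and aliases map", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdbAtomLine(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.3, alt = "A"),
    pdbAtomLine(3, "CA", "ALA", "A", 1, 9.0, 0, 0, occ = 0.7, alt = "B"),
    pdbAtomLine(4, "C", "ALA", "A", 1, 2.0, 1.0, 0),
    pdbAtomLine(5, "CB", "ALA", "A", 1, 1.0, -1.5, 0),
    pdbAtomLine(6, "N", "MSE", "A", 2, 4, 0, 0, type = "HETATM"),
    pdbAtomLine(7, "CA", "MSE", "A", 2, 5, 0, 0, type = "HETATM"),
    pdbAtomLine(8, "C", "MSE", "A", 2, 6, 1, 0, type = "HETATM"),
    pdbAtomLine(9, "CB", "MSE", "A", 2, 5, -1.5, 0, type = "HETATM"),
    pdbAtomLine(10, "N", "XXX", "A", 3, 8, 0, 0),
    pdbAtomLine(11, "CA", "XXX", "A", 3, 9, 0, 0),
    "END"), f)
  expect_warning(st <- readPDB(f), "non-standard")
  expect_identical(residueSequence(st), c("A", "M"))
  ## highest-occupancy altloc wins
  expect_equal(st@residues$ca_x[1], 9.0)
})

test_that("multi-model entries split into per-model structures", {
  base <- makeToyStructure(10, "helix", sequence = strrep("A", 10))
  shifted <- base
  shifted@residues[, grep("_[xyz]$", names(shifted@residues))] <-
    shifted@residues[, grep("_[xyz]$", names(shifted@residues))] + 2.5
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(list(base, shifted, base), f)
  models <- readPDB(f, model = "all")
  expect_length(models, 3L)
  for (m in models) expect_identical(residueSequence(m), residueSequence(base))
  expect_equal(models[[2]]@residues$ca_x, base@residues$ca_x + 2.5,
               tolerance = 1e-3)
  one <- readPDB(f, model = 2L)
  expect_equal(one@residues$ca_y, models[[2]]@residues$ca_y)
  expect_error(readPDB(f, model = 7L), "model")
})

test_that("glycine receives an ideal virtual C-beta", {
  st <- makeToyStructure(8, "helix", sequence = "AAAGAAAA")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(st, f)
  back <- readPDB(f)
  i <- 4L
  expect_true(back@residues$cb_virtual[i])
  r <- back@residues[i, ]
  ca <- c(r$ca_x, r$ca_y, r$ca_z); cb <- c(r$cb_x, r$cb_y, r$cb_z)
  n <- c(r$n_x, r$n_y, r$n_z); cc <- c(r$c_x, r$c_y, r$c_z)
  expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 0.01)
  ## tetrahedral branch geometry, checked against direct vector arithmetic
  ang <- function(a, b) acos(sum(a * b) / sqrt(sum(a * a) * sum(b * b))) * 180 / pi
  expect_equal(ang(n - ca, cb - ca), 110.3, tolerance = 2)
  expect_equal(ang(cc - ca, cb - ca), 110.1, tolerance = 2)
})

test_that("virtualCbeta honours its geometric contract", {
  set.seed(42)
  for (k in 1:25) {
    ca <- rnorm(3); n <- ca + rnorm(3); cc <- ca + rnorm(3)
    if (sqrt(sum((n - ca)^2)) < 0.5 || sqrt(sum((cc - ca)^2)) < 0.5) next
    cb <- virtualCbeta(n, ca, cc)
    expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 1e-9)
  }
  ## hidden real C-beta is reconstructed from the backbone
  st <- makeToyStructure(6, "helix", sequence = "AAAAAA")
  r <- st@residues[3, ]
  rec <- virtualCbeta(c(r$n_x, r$n_y, r$n_z), c(r$ca_x, r$ca_y, r$ca_z),
                      c(r$c_x, r$c_y, r$c_z))
  expect_lt(sqrt(sum((rec - c(r$cb_x, r$cb_y, r$cb_z))^2)), 0.05)
  expect_error(virtualCbeta(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("every residue keeps |CB - CA| in the physical window", {
  for (st in toyStructures()) {
    r <- st@residues
    d <- sqrt((r$cb_x - r$ca_x)^2 + (r$cb_y - r$ca_y)^2 + (r$cb_z - r$ca_z)^2)
    expect_true(all(d >= 1.4 & d <= 1.7))
  }
})

test_that("mutation tokens parse and format canonically", {
  ms <- parseMutations("A:N25K")
  expect_identical(ms@mutations$wt, "N")
  expect_identical(ms@mutations$resno, 25L)
  expect_identical(ms@mutations$mut, "K")
  multi <- parseMutations("A:N25K;A:L30I")
  expect_identical(nrow(multi@mutations), 2L)
  expect_identical(formatMutations(multi), "A:N25K;A:L30I")
  ins <- parseMutations("B:G7AD")
  expect_identical(ins@mutations$icode, "A")
  expect_identical(ins@mutations$mut, "D")
  expect_error(parseMutations("A:?25K"), "malformed")
  expect_error(mutationSet(data.frame(chain = "A", resno = 1, icode = "",
                                      wt = "A", mut = "A")), "differ")
  expect_error(mutationSet(data.frame(chain = "A", resno = c(1, 1),
                                      icode = "", wt = c("A", "A"),
                                      mut = c("K", "R"))), "distinct")
})

test_that("applyMutations relabels types without touching coordinates", {
  st <- toyStructures()[[1]]
  expect_identical(applyMutations(st, emptyMutationSet()), st)
  wt <- st@residues$aa[7]
  mut <- setdiff(c("K", "R"), wt)[1]
  ms <- mutationSet(data.frame(chain = "A", resno = 7L, icode = "",
                               wt = wt, mut = mut))
  out <- applyMutations(st, ms)
  expect_identical(out@residues$aa[7], mut)
  expect_identical(out@residues$aa[-7], st@residues$aa[-7])
  coordCols <- grep("_[xyz]$", names(st@residues), value = TRUE)
  expect_identical(out@residues[, coordCols], st@residues[, coordCols])
  ## involution under the reverse set
  expect_identical(applyMutations(out, reverseMutations(ms)), st)
  wrong <- mutationSet(data.frame(chain = "A", resno = 7L, icode = "",
                                  wt = setdiff(c("W", "Y"), wt)[1], mut = "K"))
  expect_error(applyMutations(st, wrong), "mismatch")
})

test_that("biological-assembly transforms generate suffixed chain copies", {
  st <- makeToyStructure(6, "helix", sequence = "AAAAAA")
  f <- withr::local_tempfile(fileext = ".pdb")
  rot <- c("REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
           "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
           "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
           "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
           "REMARK 350   BIOMT1   2 -1.000000  0.000000  0.000000       10.00000",
           "REMARK 350   BIOMT2   2  0.000000 -1.000000  0.000000        0.00000",
           "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000")
  writeStructurePDB(st, f)
  txt <- readLines(f)
  writeLines(c(rot, txt), f)
  asm <- readPDB(f, assembly = TRUE)
  expect_identical(nResidues(asm), 12L)
  expect_setequal(unique(asm@residues$chain), c("A", "A.2"))
  orig <- asm@residues[asm@residues$chain == "A", ]
  copy <- asm@residues[asm@residues$chain == "A.2", ]
  expect_equal(copy$ca_x, 10 - orig$ca_x, tolerance = 1e-6)
  expect_equal(copy$ca_y, -orig$ca_y, tolerance = 1e-6)
  expect_equal(copy$ca_z, orig$ca_z, tolerance = 1e-6)
})
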