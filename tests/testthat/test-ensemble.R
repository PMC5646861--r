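# Kabsch superposition, ensemble statistics, RMSF, alignment-guided
# superposition and restraint classification.

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("kabsch handles identity and pure translation", {
  set.seed(1)
  x <- matrix(rnorm(15), 5, 3)
  s <- kabsch(x, x)
  expect_equal(s@rmsd, 0, tolerance = 1e-10)
  expect_equal(s@rotation, diag(3), tolerance = 1e-8)
  t <- kabsch(x, sweep(x, 2, c(5, 0, 0), "+"))
  expect_equal(t@rmsd, 0, tolerance = 1e-10)
  expect_equal(t@translation, c(5, 0, 0), tolerance = 1e-8)
})

test_that("kabsch matches the rotation-grid oracle on 5-point systems", {
  set.seed(3)
  for (rep in 1:5) {
    x <- matrix(rnorm(15, sd = 3), 5, 3)
    y <- x %*% t(randomRotation()) + matrix(rnorm(15, sd = 0.3), 5, 3)
    got <- kabsch(x, y)@rmsd
    oracle <- oracleSuperposeRmsd(x, y)
    expect_equal(got, oracle, tolerance = 1e-3)
    expect_lte(got, oracle + 1e-9) # kabsch is the minimiser
  }
})

test_that("kabsch always returns a proper rotation, even for reflections", {
  set.seed(5)
  x <- matrix(rnorm(15), 5, 3)
  y <- x %*% diag(c(1, 1, -1)) # mirrored target
  s <- kabsch(x, y)
  expect_equal(det(s@rotation), 1, tolerance = 1e-9)
  expect_equal(max(abs(crossprod(s@rotation) - diag(3))), 0,
               tolerance = 1e-9)
  expect_gt(s@rmsd, 0) # a reflection must NOT be matched exactly
})

test_that("kabsch rejects degenerate input", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), ">= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("ensemble statistics are exact on constructed cases", {
  # duplicated model: everything 0
  e0 <- simulateEnsemble(ensembleDesign(nModels = 3, nResidues = 10,
                                        coreNoiseSd = 0, tailNoiseSd = 0,
                                        seed = 1))
  st <- ensembleStats(e0, NULL, "backbone")
  expect_equal(st$mean, 0, tolerance = 1e-10)

  # two identical models except one CA moved 1 A in one model: the mean
  # sits halfway, so each model is 0.5 A off at that atom over n atoms
  coords <- modelCoords(e0)[, , 1:2]
  at <- atomTable(e0)
  i <- which(at$residueId == 5 & at$atomName == "CA")
  # displace along a direction orthogonal-ish to the structure spread;
  # superposition relaxes the analytic value slightly, so build a wide
  # flat structure and displace along z
  e2 <- new("StructureEnsemble", atoms = at,
            coords = array(coords, c(nrow(at), 3, 2)))
  e2@coords[i, 3, 2] <- e2@coords[i, 3, 2] + 1
  n <- sum(at$atomName %in% c("N", "CA", "C"))
  st2 <- ensembleStats(e2, NULL, "backbone")
  analytic <- sqrt(0.5^2 / n)
  # superposition can only reduce the deviation, and only slightly here
  expect_lte(st2$mean, analytic + 1e-9)
  expect_gt(st2$mean, 0.9 * analytic)
  expect_equal(st2$perModel[1], st2$perModel[2], tolerance = 1e-6)
})

test_that("heavy-atom RMSD >= backbone RMSD under uniform noise", {
  for (seed in 1:5) {
    e <- simulateEnsemble(ensembleDesign(nModels = 6, nResidues = 30,
                                         coreNoiseSd = 0.4,
                                         tailNoiseSd = 1.5, seed = seed))
    bb <- ensembleStats(e, c(10, 25), "backbone")$mean
    hv <- ensembleStats(e, c(10, 25), "heavy")$mean
    # noise is iid per atom here, so the two agree in expectation; allow
    # sampling slack and check the heavy set is not systematically tighter
    expect_gt(hv, 0.7 * bb)
  }
})

test_that("ensemble statistics ignore model order and rigid motions", {
  e <- simulateEnsemble(ensembleDesign(nModels = 5, nResidues = 20,
                                       seed = 11))
  st <- ensembleStats(e, NULL, "backbone")
  perm <- e
  perm@coords <- e@coords[, , c(3, 1, 5, 2, 4)]
  st2 <- ensembleStats(perm, NULL, "backbone")
  expect_equal(sort(st2$perModel), sort(st$perModel), tolerance = 1e-9)
  # rigidly move every model
  R <- randomRotation()
  mov <- e
  for (k in 1:5)
    mov@coords[, , k] <- e@coords[, , k] %*% t(R) +
      matrix(c(10, -3, 2), nrow(atomTable(e)), 3, byrow = TRUE)
  st3 <- ensembleStats(mov, NULL, "backbone")
  expect_equal(st3$mean, st$mean, tolerance = 1e-9)
})

test_that("pairwise RMSD method is available and consistent", {
  e <- simulateEnsemble(ensembleDesign(nModels = 4, nResidues = 15,
                                       seed = 2))
  pw <- ensembleStats(e, NULL, "backbone", method = "pairwise")
  expect_length(pw$perModel, choose(4, 2))
  expect_gt(pw$mean, 0)
})

test_that("RMSF is zero for identical models and localises displacement", {
  e0 <- simulateEnsemble(ensembleDesign(nModels = 4, nResidues = 12,
                                        coreNoiseSd = 0, tailNoiseSd = 0,
                                        seed = 1))
  r0 <- perResidueRmsf(e0, "backbone")
  expect_equal(r0$rmsf, rep(0, 12), tolerance = 1e-10)

  e1 <- e0
  i <- which(atomTable(e0)$residueId == 6)
  for (k in c(1, 3)) e1@coords[i, 1, k] <- e1@coords[i, 1, k] + 2
  r1 <- perResidueRmsf(e1, "backbone")
  expect_equal(which.max(r1$rmsf), 6)
  expect_gt(r1$rmsf[6], 5 * max(r1$rmsf[-6]))
})

test_that("alignSuperpose is exact for self and rigidly moved copies", {
  e <- simulateEnsemble(ensembleDesign(nModels = 2, nResidues = 25,
                                       seed = 6))
  s <- alignSuperpose(e, e)
  expect_equal(s@rmsd, 0, tolerance = 1e-8)
  expect_equal(s@nPairs, 25L)
  mov <- e
  R <- randomRotation()
  mov@coords[, , 1] <- e@coords[, , 1] %*% t(R) +
    matrix(c(4, 4, -8), nrow(atomTable(e)), 3, byrow = TRUE)
  s2 <- alignSuperpose(mov, e)
  expect_equal(s2@rmsd, 0, tolerance = 1e-8)
})

test_that("pruning removes a displaced loop and lowers the rmsd", {
  e <- simulateEnsemble(ensembleDesign(nModels = 2, nResidues = 30,
                                       coreNoiseSd = 0, tailNoiseSd = 0,
                                       seed = 8))
  bent <- e
  loop <- which(atomTable(e)$residueId %in% 14:17)
  bent@coords[loop, 1, 1] <- bent@coords[loop, 1, 1] + 12
  pruned <- alignSuperpose(bent, e, pruneCutoff = 2)
  unpruned <- alignSuperpose(bent, e, pruneCutoff = Inf)
  expect_lt(pruned@rmsd, unpruned@rmsd)
  expect_lt(pruned@nPairs, unpruned@nPairs)
  expect_equal(pruned@rmsd, 0, tolerance = 1e-8) # core is identical
  expect_equal(pruned@nPairs, 26L)
})

test_that("restraint classes follow the sequence-separation boundaries", {
  r <- data.frame(residue_i = c(4, 4, 4, 7), residue_j = c(5, 8, 9, 7))
  cls <- classifyRestraints(r)
  expect_equal(as.character(cls$class), c("short", "medium", "long", "short"))
  expect_equal(cls$short, 2)
  expect_equal(cls$medium, 1)
  expect_equal(cls$long, 1)
  expect_equal(cls$total, 4)
})

test_that("restraint class partition always sums to the total", {
  for (seed in 1:10) {
    r <- simulateRestraints(50, nResidues = 40, seed = seed)
    cls <- classifyRestraints(r)
    expect_equal(cls$short + cls$medium + cls$long, cls$total)
    # brute-force recount
    sep <- abs(r$residue_i - r$residue_j)
    expect_equal(cls$short, sum(sep <= 1))
    expect_equal(cls$medium, sum(sep > 1 & sep < 5))
    expect_equal(cls$long, sum(sep >= 5))
  }
  expect_error(classifyRestraints(data.frame(residue_i = 0,
                                             residue_j = 3)), "positive")
})
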