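# Fitness terms: closed-form identities, direct-summation oracles, rigid
# invariance, linearity, and the native-vs-random sanity property.

twoAtomComplex <- function(d, name = "CA", element = "C", resname = "ALA") {
  s1 <- makeBareSubunit(1, matrix(c(0, 0, 0), 1, 3), name, element, resname)
  s2 <- makeBareSubunit(2, matrix(c(d, 0, 0), 1, 3), name, element, resname)
  asComplex(list(s1, s2))
}

test_that("vdW term matches the Lennard-Jones closed forms", {
  params <- defaultScoreParams()
  expect_equal(vdwEnergy(twoAtomComplex(100), params), 0)
  # identical carbons at sigma * 2^(1/6): the pair minimum, -epsilon
  sig <- params$vdw$sigma[["C"]]
  eps <- params$vdw$epsilon[["C"]]
  expect_equal(vdwEnergy(twoAtomComplex(sig * 2^(1 / 6)), params), -eps,
               tolerance = 1e-12)
  # the clash cap continues linearly: finite and monotone as r -> 0
  eCap <- vdwEnergy(twoAtomComplex(0.6 * sig), params)
  eDeep <- vdwEnergy(twoAtomComplex(0.2 * sig), params)
  expect_true(is.finite(eDeep))
  expect_gt(eDeep, eCap)
  lin <- (vdwEnergy(twoAtomComplex(0.3 * sig), params) - eDeep) /
    (0.3 * sig - 0.2 * sig)
  lin2 <- (vdwEnergy(twoAtomComplex(0.5 * sig), params) -
             vdwEnergy(twoAtomComplex(0.4 * sig), params)) / (0.1 * sig)
  expect_equal(lin, lin2, tolerance = 1e-6)
})

test_that("vdW term equals a hand-summed pairwise oracle on a toy pair", {
  set.seed(31)
  params <- defaultScoreParams()
  c1 <- matrix(rnorm(15, sd = 2), 5, 3)
  c2 <- sweep(matrix(rnorm(15, sd = 2), 5, 3), 2, c(5, 0, 0), "+")
  s1 <- makeBareSubunit(1, c1)
  s2 <- makeBareSubunit(2, c2)
  cx <- asComplex(list(s1, s2))
  sig <- params$vdw$sigma[["C"]]; eps <- params$vdw$epsilon[["C"]]
  manual <- 0
  for (a in 1:5) for (b in 1:5) {
    r <- sqrt(sum((c1[a, ] - c2[b, ])^2))
    if (r > params$cutoffs[["vdw"]]) next
    rc <- params$clashCapFrac * sig
    lj <- function(d) 4 * eps * ((sig / d)^12 - (sig / d)^6)
    manual <- manual + if (r >= rc) lj(r) else
      lj(rc) + 4 * eps * (-12 * sig^12 / rc^13 + 6 * sig^6 / rc^7) * (r - rc)
  }
  expect_equal(vdwEnergy(cx, params), manual, tolerance = 1e-9)
})

test_that("electrostatic term matches its closed form and oracle", {
  params <- defaultScoreParams()
  # no charged residues -> 0
  expect_equal(elecEnergy(twoAtomComplex(3), params), 0)
  # one +1/-1 pair at 2 A: q1 q2 / (4 * 2 * 2) with the half-charge table
  s1 <- makeBareSubunit(1, matrix(0, 1, 3), name = "NZ", element = "N",
                        resname = "LYS")
  s2 <- makeBareSubunit(2, matrix(c(2, 0, 0), 1, 3), name = "OD1",
                        element = "O", resname = "ASP")
  expect_equal(elecEnergy(asComplex(list(s1, s2)), params),
               (1.0 * -0.5) / (4 * 2 * 2), tolerance = 1e-12)
  # three charged atoms across two subunits: hand summation
  a1 <- makeBareSubunit(1, rbind(c(0, 0, 0), c(0, 3, 0)), name = c("NZ", "OD1"),
                        element = c("N", "O"), resname = c("LYS", "ASP"))
  a2 <- makeBareSubunit(2, matrix(c(4, 0, 0), 1, 3), name = "NH1",
                        element = "N", resname = "ARG")
  r13 <- 4; r23 <- 5
  manual <- (1 * 0.5) / (4 * r13^2) + (-0.5 * 0.5) / (4 * r23^2)
  expect_equal(elecEnergy(asComplex(list(a1, a2)), params), manual,
               tolerance = 1e-12)
})

test_that("contact term picks the right matrix entries", {
  params <- defaultScoreParams()
  # beyond 4.5 A -> 0
  expect_equal(contactEnergy(twoAtomComplex(6), params), 0)
  # a single contacting Cn-Cn pair -> exactly that entry
  expect_equal(contactEnergy(twoAtomComplex(4, name = "CB"), params),
               params$contact["Cn", "Cn"])
  # CA is backbone-nonpolar? CA is side of backbone: classed Cn; carbonyl C is Cp
  expect_equal(contactEnergy(twoAtomComplex(4, name = "C"), params),
               params$contact["Cp", "Cp"])
  # random toy vs brute-force double loop over heavy atoms
  set.seed(32)
  fx <- smallFixture(seed = 32, nSubunits = 2)
  cx <- fx$native
  manual <- 0
  cls <- lapply(cx@atoms, function(df)
    TreeDock:::.atomClass(toupper(df$element), df$resname, df$name))
  A <- cx@atoms[[1]]; B <- cx@atoms[[2]]
  for (a in seq_len(nrow(A))) for (b in seq_len(nrow(B))) {
    r <- sqrt((A$x[a] - B$x[b])^2 + (A$y[a] - B$y[b])^2 + (A$z[a] - B$z[b])^2)
    if (r <= 4.5) manual <- manual + params$contact[cls[[1]][a], cls[[2]][b]]
  }
  expect_equal(contactEnergy(cx, params), manual, tolerance = 1e-9)
})

test_that("fitness is the weighted linear combination of its terms", {
  fx <- smallFixture(seed = 33, nSubunits = 3)
  cx <- fx$native
  params <- defaultScoreParams()
  v <- vdwEnergy(cx, params); e <- elecEnergy(cx, params)
  k <- contactEnergy(cx, params)
  br <- scoreComplex(cx, params, weights = c(vdw = 1, elec = 1, contact = 1))
  expect_equal(br@total, v + e + k, tolerance = 1e-9)
  expect_equal(br@vdw, v)
  # weights (1,0,0) -> total == vdw term; scaling a weight scales its share
  expect_equal(scoreComplex(cx, params, c(vdw = 1, elec = 0, contact = 0))@total,
               v, tolerance = 1e-12)
  expect_equal(scoreComplex(cx, params, c(vdw = 2, elec = 1, contact = 1))@total,
               2 * v + e + k, tolerance = 1e-9)
  # far-separated subunits -> all-zero total
  far <- twoAtomComplex(200)
  expect_equal(scoreComplex(far, params)@total, 0)
})

test_that("all terms are invariant under global rigid motion and relabeling", {
  fx <- smallFixture(seed = 34, nSubunits = 3)
  cx <- fx$native
  params <- defaultScoreParams()
  set.seed(35)
  t1 <- rigidTransform(randomRotation(), rnorm(3, sd = 30))
  moved <- cx
  moved@atoms <- lapply(cx@atoms, function(df) {
    xyz <- applyTransform(t1, cbind(df$x, df$y, df$z))
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df
  })
  expect_equal(vdwEnergy(moved, params), vdwEnergy(cx, params),
               tolerance = 1e-6)
  expect_equal(elecEnergy(moved, params), elecEnergy(cx, params),
               tolerance = 1e-6)
  expect_equal(contactEnergy(moved, params), contactEnergy(cx, params),
               tolerance = 1e-6)
  # subunit relabeling: reverse the subunit order
  flipped <- new("AssembledComplex", subunitIds = rev(cx@subunitIds),
                 labels = rev(cx@labels), atoms = rev(cx@atoms), genome = NULL)
  expect_equal(vdwEnergy(flipped, params), vdwEnergy(cx, params),
               tolerance = 1e-9)
  expect_equal(contactEnergy(flipped, params), contactEnergy(cx, params),
               tolerance = 1e-9)
})

test_that("the native scores better than nearly all random assemblies", {
  fx <- standardFixture(seed = 36, nSubunits = 4, atomsPerSubunit = 25,
                        poolSize = 30)
  params <- defaultScoreParams()
  nativeScore <- scoreComplex(fx$native, params)@total
  set.seed(37)
  rand <- replicate(500, {
    g <- randomGenome(4, fx$library)
    scoreComplex(assembleComplex(g, fx$subunits, fx$library), params)@total
  })
  expect_gte(mean(nativeScore < rand), 0.95)
})

test_that("oracle fitness equals the evaluation-module RMSD", {
  fx <- smallFixture(seed = 38)
  expect_lt(oracleFitness(fx$native, fx$native), 1e-6)
  set.seed(39)
  t1 <- rigidTransform(randomRotation(), rnorm(3, sd = 10))
  moved <- fx$native
  moved@atoms <- lapply(fx$native@atoms, function(df) {
    xyz <- applyTransform(t1, cbind(df$x, df$y, df$z))
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df
  })
  expect_lt(oracleFitness(moved, fx$native), 1e-6)
  # perturb one subunit: oracle == superposedCaRmsd by construction
  pert <- fx$native
  pert@atoms[[2]]$x <- pert@atoms[[2]]$x + 3
  expect_equal(oracleFitness(pert, fx$native),
               superposedCaRmsd(pert, fx$native))
  expect_gt(oracleFitness(pert, fx$native), 0.1)
})
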