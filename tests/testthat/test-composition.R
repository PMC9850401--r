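test_that("neutral mass matches elemental-formula arithmetic", {
  expect_equal(neutralMass(glycanComposition(hex = 1)), 180.0634,
               tolerance = 1e-6)
  expect_equal(neutralMass(glycanComposition(hex = 3, reduced = TRUE)),
               506.1847, tolerance = 1e-6)
  # property: residue-sum arithmetic equals summed elemental formulas
  set.seed(42)
  for (i in 1:50) {
    h <- sample(0:8, 1); p <- sample(0:8, 1); a <- sample(0:3, 1)
    n <- if (h + p + a == 0) sample(1:8, 1) else 0
    m <- if (a > 0) sample(0:a, 1) else 0
    red <- sample(c(TRUE, FALSE), 1)
    comp <- glycanComposition(h, p, a, n, m, red)
    expect_equal(neutralMass(comp), oracleMass(h, p, a, n, m, red),
                 tolerance = 1e-9)
  }
  expect_error(glycanComposition(), "polymerization")
  expect_error(glycanComposition(hex = -1), "non-negative")
  expect_error(glycanComposition(hex = 2, me = 1), "hexuronic")
})

test_that("composition text form round-trips and rejects garbage", {
  forms <- c("Hex3", "Pnt5", "Pnt4HxA1Me1", "Hex3-red", "HexNAc4-red",
             "Hex2Pnt3HxA2Me1-red", "Pnt4HxA1Me1-red")
  for (s in forms) {
    expect_identical(as.character(parseComposition(s)), s)
  }
  # canonical order is restored from scrambled token order
  expect_identical(as.character(parseComposition("Me1HxA1Pnt4")),
                   "Pnt4HxA1Me1")
  expect_error(parseComposition("Glc3"), "cannot parse")
  expect_error(parseComposition("Hex"), "cannot parse")
  expect_error(parseComposition("hex3"), "cannot parse")
  expect_error(parseComposition("Hex2Hex3"), "duplicated")
  expect_error(parseComposition("Me2"), "polymerization|hexuronic")
})

test_that("adducted m/z follows (M + z*cation)/z", {
  c3r <- glycanComposition(hex = 3, reduced = TRUE)
  expect_equal(mzOf(c3r, "sodium", 1), 529.1739, tolerance = 1e-6)
  expect_equal(mzOf(c3r, "proton", 1), 507.1920, tolerance = 1e-6)
  expect_equal(mzOf(c3r, "ammonium", 1),
               (oracleMass(hex = 3, reduced = TRUE) +
                  oracleCation[["ammonium"]]), tolerance = 1e-9)
  # doubly charged species
  expect_equal(mzOf(c3r, "sodium", 2),
               (oracleMass(hex = 3, reduced = TRUE) +
                  2 * oracleCation[["sodium"]]) / 2, tolerance = 1e-9)
  expect_error(mzOf(c3r, "sodium", 0), "charge")
  expect_error(mzOf(c3r, "potassium", 1), "adduct")
})

test_that("glycosidic condensation is mass-additive", {
  set.seed(7)
  masses <- residueMasses()
  water <- masses$constants[["water"]]
  for (i in 1:20) {
    a <- glycanComposition(sample(1:5, 1), sample(0:4, 1))
    b <- glycanComposition(sample(0:4, 1), sample(1:5, 1))
    ab <- glycanComposition(a@hex + b@hex, a@pnt + b@pnt)
    expect_equal(neutralMass(ab),
                 neutralMass(a) + neutralMass(b) - water,
                 tolerance = 1e-9)
  }
})
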