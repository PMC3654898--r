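test_that("overall composition counts residues in percent", {
  ds <- peptide_dataset("STVIIE", "amyloid")
  comp <- overall_composition(ds, "amyloid")
  expect_equal(comp[["I"]], 100 * 2 / 6)
  expect_equal(comp[["S"]], 100 / 6)
  expect_equal(sum(comp), 100)
  expect_equal(attr(comp, "n_total"), 6L)
  # duplication invariance: composition is a count ratio
  ds2 <- peptide_dataset(rep("STVIIE", 2), "amyloid",
                         allow_duplicates = TRUE)
  expect_equal(unclass(overall_composition(ds2, "amyloid")), unclass(comp),
               ignore_attr = TRUE)
  expect_error(overall_composition(ds, "non_amyloid"), "no 'non_amyloid'")
})

test_that("positional composition is per-position percent with N_j peptides", {
  ds <- peptide_dataset(c("STVIIE", "ATVIIE"), c("amyloid", "amyloid"))
  pos <- positional_composition(ds, "amyloid")
  expect_equal(pos["S", "P1"], 50)
  expect_equal(pos["A", "P1"], 50)
  expect_equal(pos["E", "P6"], 100)
  expect_equal(unname(colSums(unclass(pos))), rep(100, 6))
  expect_equal(unname(attr(pos, "n_per_position")), rep(2L, 6))
})

test_that("identity normalization gives an all-ones propensity matrix", {
  # a composition numerically equal to the reference maps to propensity 1
  ref <- globular_composition()
  pos <- structure(matrix(ref, 20, 6,
                          dimnames = list(aa_alphabet(), paste0("P", 1:6))),
                   observed = matrix(TRUE, 20, 6),
                   n_per_position = rep(1L, 6),
                   class = c("positional_composition", "matrix", "array"))
  prop <- positional_propensity(pos, ref)
  expect_equal(unclass(prop), matrix(1, 20, 6), ignore_attr = TRUE)
})

test_that("propensity columns satisfy the normalization identity", {
  ref <- globular_composition()
  for (seed in 1:5) {
    ds <- sample_dataset(n_amyloid = 50, n_nonamyloid = 50, seed = seed)
    for (lab in c("amyloid", "non_amyloid")) {
      prop <- positional_propensity(positional_composition(ds, lab), ref)
      expect_equal(unname(colSums(unclass(prop) * ref)), rep(100, 6),
                   tolerance = 1e-9)
    }
  }
})

test_that("Boltzmann conversion and its inverse round-trip observed cells", {
  ds <- sample_dataset(n_amyloid = 80, n_nonamyloid = 0, seed = 3)
  prop <- positional_propensity(positional_composition(ds, "amyloid"))
  pot <- propensity_to_potential(prop, rt = 0.6)
  expect_s3_class(pot, "potential_matrix")
  back <- potential_to_propensity(pot)
  obs <- attr(prop, "observed")
  expect_equal(unclass(back)[obs], unclass(prop)[obs], tolerance = 1e-9)
  # unobserved cells are exactly zero with the flag propagated
  expect_true(all(unclass(pot)[!obs] == 0))
  expect_identical(attr(pot, "observed"), obs)
  # monotonicity: higher propensity <=> strictly lower energy
  v <- unclass(prop)[obs]
  e <- unclass(pot)[obs]
  ord <- order(v)
  expect_true(all(diff(e[ord]) <= 0))
  # spot values: propensity 1 -> 0; propensity 1.2 at RT 0.6 -> -0.109
  expect_equal(-0.6 * log(1), 0)
  expect_equal(round(-0.6 * log(1.2), 3), -0.109)
})

test_that("pseudo-counts fill unobserved cells without breaking columns", {
  ds <- peptide_dataset(c("STVIIE", "ATVIIE"), "amyloid")
  pos <- positional_composition(ds, "amyloid", pseudocount = 0.5)
  expect_true(all(attr(pos, "observed")))
  expect_equal(unname(colSums(unclass(pos))), rep(100, 6))
  pot <- derive_potentials(ds, "amyloid", pseudocount = 0.5)
  expect_true(all(is.finite(unclass(pot))))
  expect_true(all(attr(pot, "observed")))
})

test_that("self normalization uses the class's own overall composition", {
  ds <- sample_dataset(n_amyloid = 100, n_nonamyloid = 0, seed = 8)
  pot <- derive_potentials(ds, "amyloid", normalization = "self")
  ref <- unclass(overall_composition(ds, "amyloid"))
  prop <- potential_to_propensity(pot, ref = ref)
  keep <- ref > 0
  expect_equal(unname(colSums(unclass(prop)[keep, ] * ref[keep])),
               rep(100, 6), tolerance = 1e-6)
})

test_that("preference classification applies thresholds to observed cells", {
  prop <- potential_to_propensity(amyloid_potentials())
  prefs <- classify_preferences(prop)
  expect_true("S" %in% prefs$preferred$P1)   # propensity exp(1.036/0.6) > 1.2
  expect_true("D" %in% prefs$avoided$P1)
  # unobserved residues count as avoided
  expect_true("P" %in% prefs$avoided$P3)
  # flat matrix: nothing preferred or avoided
  flat <- structure(matrix(1, 20, 6,
                           dimnames = list(aa_alphabet(), paste0("P", 1:6))),
                    observed = matrix(TRUE, 20, 6),
                    class = c("propensity_matrix", "matrix", "array"))
  p2 <- classify_preferences(flat)
  expect_true(all(lengths(p2$preferred) == 0))
  expect_true(all(lengths(p2$avoided) == 0))
  expect_error(classify_preferences(prop, preferred_min = 0.5),
               "preferred_min > avoided_max")
})

test_that("published preferred residues all clear the 1.2 threshold", {
  for (cls in c("amyloid", "non_amyloid")) {
    pot <- if (cls == "amyloid") amyloid_potentials() else
      nonamyloid_potentials()
    prop <- potential_to_propensity(pot)
    prefs <- classify_preferences(prop)
    for (j in paste0("P", 1:6)) {
      expect_true(all(published_preferences[[cls]]$preferred[[j]] %in%
                        prefs$preferred[[j]]),
                  label = sprintf("%s %s preferred subset", cls, j))
      expect_true(all(published_preferences[[cls]]$avoided[[j]] %in%
                        prefs$avoided[[j]]),
                  label = sprintf("%s %s avoided subset", cls, j))
    }
  }
})

test_that("derivation recovers generating potentials from a large sample", {
  rep5k <- recovery_experiment(n_per_class = 5000, seed = 71)
  expect_lt(rep5k$mad, 0.1)
  # unobserved-in-sample cells re-derive to exactly zero, flagged unobserved
  small <- sample_dataset(n_amyloid = 30, n_nonamyloid = 0, seed = 5)
  pot <- derive_potentials(small, "amyloid")
  obs <- attr(pot, "observed")
  expect_true(any(!obs))
  expect_true(all(unclass(pot)[!obs] == 0))
})
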