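test_that("worked scoring examples match the published potentials", {
  sc <- score_peptide(c("STVIIE", "VQIVYK"))
  expect_equal(sc$phi_amyloid[1], -6.975, tolerance = 1e-9)
  expect_equal(sc$phi_nonamyloid[1], -5.269, tolerance = 1e-9)
  expect_equal(sc$delta_phi[1], -1.706, tolerance = 1e-9)
  expect_identical(as.character(sc$call[1]), "amyloid")
  expect_equal(sc$phi_amyloid[2], 2.290, tolerance = 1e-9)
  expect_equal(sc$phi_nonamyloid[2], 1.668, tolerance = 1e-9)
  expect_equal(sc$delta_phi[2], 0.622, tolerance = 1e-9)
  expect_identical(as.character(sc$call[2]), "non_amyloid")
})

test_that("delta-phi is antisymmetric and ties resolve to non-amyloid", {
  seqs <- random_hexapeptides(200)
  amy <- amyloid_potentials()
  non <- nonamyloid_potentials()
  fwd <- score_peptide(seqs, amy, non)
  rev <- score_peptide(seqs, non, amy)
  expect_equal(rev$delta_phi, -fwd$delta_phi, tolerance = 1e-12)
  # same matrix on both sides: delta exactly zero, called non-amyloid
  same <- score_peptide(seqs, amy, amy)
  expect_true(all(same$delta_phi == 0))
  expect_true(all(same$call == "non_amyloid"))
  expect_equal(fwd$delta_phi, fwd$phi_amyloid - fwd$phi_nonamyloid,
               tolerance = 1e-12)
})

test_that("single-residue substitutions shift delta-phi additively", {
  amy <- amyloid_potentials()
  non <- nonamyloid_potentials()
  set.seed(10)
  for (i in 1:20) {
    s <- random_hexapeptides(1)
    j <- sample(6, 1)
    r_new <- sample(setdiff(aa_alphabet(), substr(s, j, j)), 1)
    s2 <- s
    substr(s2, j, j) <- r_new
    d1 <- score_peptide(s, amy, non)$delta_phi
    d2 <- score_peptide(s2, amy, non)$delta_phi
    expected_shift <- (amy[r_new, j] - non[r_new, j]) -
      (amy[substr(s, j, j), j] - non[substr(s, j, j), j])
    expect_equal(d2 - d1, expected_shift, tolerance = 1e-12)
  }
})

test_that("scoring equals brute-force per-position lookup", {
  seqs <- random_hexapeptides(500)
  sc <- score_peptide(seqs)
  brute <- vapply(seqs, naive_phi_total, numeric(1),
                  pot = amyloid_potentials())
  expect_equal(sc$phi_amyloid, unname(brute), tolerance = 1e-12)
})

test_that("dataset classification tallies the confusion table", {
  ds <- peptide_dataset(c("STVIIE", "VQIVYK"), c("amyloid", "amyloid"))
  cc <- classify_dataset(ds)
  expect_identical(cc$tp, 1L)   # STVIIE called amyloid
  expect_identical(cc$fn, 1L)   # VQIVYK called non-amyloid
  expect_identical(cc$fp + cc$tn, 0L)
  # swapping the matrices flips every call
  swapped <- classify_dataset(ds, nonamyloid_potentials(),
                              amyloid_potentials())
  expect_identical(swapped$tp, 1L)
  expect_identical(swapped$fn, 1L)
  expect_error(classify_dataset(peptide_dataset("STVIIE")), "unlabeled")
})

test_that("window scanning equals independent scoring of each slice", {
  expect_error(scan_sequence("STVIE"), "shorter than 6")
  one <- scan_sequence("STVIIE")
  expect_identical(nrow(one), 1L)
  expect_equal(one$delta_phi, score_peptide("STVIIE")$delta_phi)
  two <- scan_sequence("STVIIEK")
  expect_identical(two$start0, c(0L, 1L))
  expect_identical(two$sequence, c("STVIIE", "TVIIEK"))
  set.seed(2)
  prot <- paste(sample(aa_alphabet(), 50, replace = TRUE), collapse = "")
  wins <- scan_sequence(prot, id = "prot1")
  expect_identical(nrow(wins), 45L)
  for (i in seq_len(nrow(wins))) {
    slice <- substr(prot, wins$start1[i], wins$end1[i])
    expect_identical(wins$sequence[i], slice)
    expect_equal(wins$delta_phi[i], score_peptide(slice)$delta_phi,
                 tolerance = 1e-12)
  }
})

test_that("energy differentials bin per class with the cutoff as an edge", {
  ds <- peptide_dataset("STVIIE", "amyloid")
  d1 <- energy_differential_distribution(ds, position = 1)
  # S at position 1: -1.036 - (-0.827) = -0.209
  expect_equal(unname(d1$cutoff_fractions["amyloid"]), 1.0)
  expect_true(-0.2 %in% round(d1$bin_edges, 10))
  expect_equal(sum(d1$class_frequencies["amyloid", ]), 1)
  # a value exactly at the cutoff is counted (<= comparison)
  ds2 <- sample_dataset(n_amyloid = 100, n_nonamyloid = 100, seed = 12)
  for (pos in c(1, 4)) {
    d <- energy_differential_distribution(ds2, position = pos)
    expect_equal(unname(rowSums(d$class_frequencies)), c(1, 1),
                 tolerance = 1e-9)
  }
})

test_that("amyloid-sampled peptides accumulate below the cutoff", {
  # amyloid class drawn from the amyloid matrix vs a background class; the
  # ordering is asserted at informative positions, i.e. where the true
  # sampling laws separate the sub-cutoff mass by a clear margin
  ds <- sample_dataset(n_amyloid = 800, n_nonamyloid = 800, non = NULL,
                       seed = 19)
  dmat <- unclass(amyloid_potentials()) - unclass(nonamyloid_potentials())
  p_amy <- sampling_probabilities(amyloid_potentials())
  p_bg <- sampling_probabilities(NULL)
  informative <- which(vapply(1:6, function(j)
    sum(p_amy[, j] * (dmat[, j] <= -0.2)) -
      sum(p_bg[, j] * (dmat[, j] <= -0.2)) > 0.05, logical(1)))
  expect_gte(length(informative), 3)
  for (pos in informative) {
    d <- energy_differential_distribution(ds, position = pos)
    expect_gt(d$cutoff_fractions[["amyloid"]],
              d$cutoff_fractions[["non_amyloid"]])
  }
})
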