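test_that("closure rescales to 100, is idempotent, and rejects non-positive shares", {
  ref <- aa_ref_vec()
  closed <- close_composition(ref)
  expect_equal(sum(closed), 100, tolerance = 1e-12)
  expect_equal(closed[["LEU"]], 8.24 * 100 / 100.01, tolerance = 1e-6)
  expect_equal(close_composition(closed), closed)
  expect_equal(unname(close_composition(rep(1, 18))), rep(100 / 18, 18))
  # proportionality: ratios survive closure
  expect_equal(closed[["GLU"]] / closed[["ILE"]], ref[["GLU"]] / ref[["ILE"]])
  expect_error(close_composition(c(A = 1, B = 0)), "B")
  expect_error(close_composition(c(A = -1, B = 2)), "A")
})

test_that("clr has zero sum, closed forms, and closure invariance", {
  expect_equal(clr_transform(rep(5, 7)), rep(0, 7))
  expect_equal(clr_transform(c(75, 25)), c(log(3) / 2, -log(3) / 2))
  ref <- clr_transform(aa_ref_closed())
  expect_equal(sum(ref), 0, tolerance = 1e-10)
  expect_equal(names(which.max(ref)), "GLU")
  set.seed(1)
  for (i in 1:20) {
    x <- exp(rnorm(10))
    k <- runif(1, 0.01, 50)
    expect_equal(clr_transform(x), clr_transform(k * x), tolerance = 1e-12)
  }
})

test_that("pivot basis rows are orthonormal, zero-sum, with the documented first row", {
  comps <- names(aa_ref_closed())
  b <- pivot_basis(comps)
  expect_equal(b %*% t(b), diag(17), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(rowSums(b)), rep(0, 17), tolerance = 1e-10)
  first <- unname(b[1, ])
  expect_equal(first, -sqrt(17 / 18) * c(1, rep(-1 / 17, 17)), tolerance = 1e-12)
  b3 <- pivot_basis(c("A", "B", "C"))
  expect_equal(unname(b3[1, ]), -sqrt(2 / 3) * c(1, -0.5, -0.5), tolerance = 1e-12)
  expect_equal(b3 %*% t(b3), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  bs <- pivot_basis(c("A", "B", "C"), sign_convention = "standard")
  expect_equal(unname(bs), -unname(b3), ignore_attr = TRUE)
  expect_error(pivot_basis(c("A", "A", "B")), "duplicated")
  expect_error(pivot_basis(c("A", "B"), components = c("A", "C")), "permutation")
})

test_that("ilr is an isometry and basis change is a rotation", {
  comps <- names(aa_ref_closed())
  set.seed(7)
  x <- close_composition(setNames(exp(rnorm(18, log(aa_ref_vec()), 0.2)), comps))
  b1 <- pivot_basis(comps)
  b2 <- pivot_basis(sample(comps), components = comps)
  z1 <- ilr_transform(x, b1)
  z2 <- ilr_transform(x, b2)
  expect_equal(sqrt(sum(z1^2)), sqrt(sum(z2^2)), tolerance = 1e-10)
  expect_equal(unname(ilr_transform(rep(1, 18), pivot_basis(comps))),
               rep(0, 17))
  # explicit rotation: R = B2 B1' is orthogonal and maps z1 to z2
  r <- b2 %*% t(b1)
  expect_equal(r %*% t(r), diag(17), tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(r %*% z1 - z2)), 1e-9)
  # matrix input agrees with row-wise vector input
  xm <- rbind(x, x * 2)
  zm <- ilr_transform(xm, b1)
  expect_equal(unname(zm[1, ]), unname(z1), tolerance = 1e-12)
})

test_that("reversed first coordinate is negative iff the pivot exceeds the geometric mean of the rest", {
  ref <- aa_ref_closed()
  comps <- names(ref)
  b_leu <- pivot_basis(c("LEU", setdiff(comps, "LEU")), components = comps)
  z1 <- unname(ilr_transform(ref, b_leu)[1])
  gm_rest <- exp(mean(log(ref[setdiff(comps, "LEU")])))
  expect_true(ref[["LEU"]] > gm_rest)
  expect_lt(z1, 0)
  expect_equal(z1, -sqrt(17 / 18) * log(ref[["LEU"]] / gm_rest),
               tolerance = 1e-12)
})

test_that("perturbations shift shares as specified and conserve the total", {
  ref <- aa_ref_closed()
  p <- apply_perturbation(ref, perturbation("one_to_all", "LEU", delta = 0.1))
  expect_equal(p[["LEU"]], ref[["LEU"]] + 0.1)
  others <- setdiff(names(ref), "LEU")
  expect_equal(unname(p[others]), unname(ref[others] - 0.1 / 17))
  expect_equal(sum(p), 100, tolerance = 1e-10)
  q <- apply_perturbation(ref, perturbation("one_to_one", "LEU", "ILE", delta = 0.1))
  expect_equal(q[["LEU"]], ref[["LEU"]] + 0.1)
  expect_equal(q[["ILE"]], ref[["ILE"]] - 0.1)
  expect_equal(unname(q[setdiff(names(ref), c("LEU", "ILE"))]),
               unname(ref[setdiff(names(ref), c("LEU", "ILE"))]))
  expect_equal(apply_perturbation(ref, perturbation("one_to_all", "LEU", delta = 0)),
               ref)
  expect_error(
    apply_perturbation(ref, perturbation("one_to_one", "LEU", "TRP", delta = 1.3)),
    "TRP"
  )
  # full names accepted against abbreviation-named compositions
  p2 <- apply_perturbation(ref, perturbation("one_to_all", "leucine", delta = 0.1))
  expect_equal(p2, p)
})

test_that("perturbation JSON schema round-trips", {
  p <- perturbation("one_to_one", "LEU", "ILE", delta = 0.2)
  p2 <- perturbation_from_json(perturbation_to_json(p))
  expect_equal(p2, p)
  path <- system.file("extdata", "example_perturbation.json", package = "aacoda")
  p3 <- perturbation_from_json(path)
  expect_s3_class(p3, "aa_perturbation")
  expect_equal(p3$target, "LEU")
  expect_error(perturbation("one_to_one", "LEU"), "source")
  expect_error(perturbation("one_to_one", "LEU", "LEU"), "differ")
  expect_error(perturbation("one_to_all", "LEU", "ILE"), "one_to_one")
})
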