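test_that("reference composition is the closed geometric mean", {
  one <- aa_ref_closed()
  rows <- tibble::as_tibble(as.list(one))[rep(1, 5), ]
  expect_equal(reference_composition(rows), one, tolerance = 1e-12)
  toy <- matrix(c(50, 50, 98, 2), 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B")))
  expect_equal(
    reference_composition(toy),
    close_composition(c(A = sqrt(50 * 98), B = sqrt(50 * 2))),
    tolerance = 1e-12
  )
  # generator calibrated to the reference recovers it within sampling error
  comp <- generate_composition(20000, generator_config(), seed = 3)
  ref <- reference_composition(as.matrix(comp))
  expect_equal(ref[["GLU"]], 18.68, tolerance = 0.01 * 18.68)
})

test_that("contrast-based effect equals the brute-force prediction difference", {
  coh <- small_cohort(n = 220, seed = 12)
  fit <- fit_composition_model(coh, model_spec("glucose"))
  ref <- fit$reference
  for (p in list(perturbation("one_to_all", "LEU"),
                 perturbation("one_to_one", "LEU", "ILE"),
                 perturbation("one_to_one", "SER", "GLU", delta = 0.05))) {
    eff <- substitution_effect(fit, p)
    # independent route: full predictions at both compositions with the
    # covariate block held at arbitrary values
    pert <- apply_perturbation(ref, p)
    covs <- rnorm(length(fit$coefficients) - 1 - length(fit$ilr_terms))
    x_ref <- c(1, ilr_transform(ref, fit$basis), covs)
    x_per <- c(1, ilr_transform(pert, fit$basis), covs)
    brute <- sum(x_per * fit$coefficients) - sum(x_ref * fit$coefficients)
    expect_equal(eff$effect, brute, tolerance = 1e-10)
  }
  z <- substitution_effect(fit, perturbation("one_to_all", "LEU", delta = 0))
  expect_equal(z$effect, 0)
  expect_equal(z$se, 0)
})

test_that("effects match the analytic log-contrast gradient as delta -> 0", {
  a <- c(A = 2, B = -3, C = 1)
  fit <- toy_fit(a)
  ref <- fit$reference
  d <- 1e-6
  eff <- substitution_effect(fit, perturbation("one_to_one", "A", "B", delta = d))
  expect_equal(eff$effect / d, a[["A"]] / ref[["A"]] - a[["B"]] / ref[["B"]],
               tolerance = 1e-6)
  # exact log form at a finite delta
  d2 <- 0.5
  eff2 <- substitution_effect(fit, perturbation("one_to_one", "A", "B", delta = d2))
  expect_equal(eff2$effect,
               a[["A"]] * log(1 + d2 / ref[["A"]]) +
                 a[["B"]] * log(1 - d2 / ref[["B"]]),
               tolerance = 1e-10)
})

test_that("substitution effects are invariant to the pivot ordering of the fit", {
  coh <- small_cohort(n = 180, seed = 22)
  spec <- model_spec("glucose")
  f1 <- fit_composition_model(coh, spec, first = "ILE")
  f2 <- fit_composition_model(coh, spec, first = "SER")
  t1 <- one_to_all_table(f1)
  t2 <- one_to_all_table(f2)
  expect_equal(t1$effect, t2$effect, tolerance = 1e-10)
  expect_equal(t1$se, t2$se, tolerance = 1e-9)
  m1 <- one_to_one_matrix(f1, delta = 0.1)
  m2 <- one_to_one_matrix(f2, delta = 0.1)
  expect_equal(m1$effect, m2$effect, tolerance = 1e-10)
})

test_that("one-to-all table covers all components, CI width is 4 SE, signs anti-align with pivot coefficients", {
  coh <- small_cohort(n = 500, seed = 32)
  spec <- model_spec("glucose")
  fit <- fit_composition_model(coh, spec)
  tab <- one_to_all_table(fit)
  expect_equal(tab$target, aa_reference()$abbrev)
  expect_equal(tab$ci_high - tab$ci_low, 4 * tab$se, tolerance = 1e-12)
  expect_true(all(tab$ci_low <= tab$effect & tab$effect <= tab$ci_high))
  ps <- pivot_sweep(coh, spec)
  # where the first-pivot coefficient dominates (the three generated
  # signals), the one-to-all effect has the opposite sign (reversed
  # convention)
  strong <- ps$component[abs(ps$statistic) > 4]
  expect_true(length(strong) >= 2)
  for (cc in strong) {
    expect_lt(tab$effect[tab$target == cc] * ps$estimate[ps$component == cc], 0)
  }
})

test_that("one-to-all at D = 2 degenerates to one-to-one", {
  a <- c(A = 1.5, B = -1.5)
  fit <- toy_fit(a)
  all2 <- one_to_all_table(fit, delta = 0.2)
  one2 <- substitution_effect(fit, perturbation("one_to_one", "A", "B", delta = 0.2))
  expect_equal(all2$effect[all2$target == "A"], one2$effect, tolerance = 1e-12)
})

test_that("one-to-one matrix is first-order antisymmetric with O(delta^2) residual", {
  coh <- small_cohort(n = 260, seed = 42)
  fit <- fit_composition_model(coh, model_spec("glucose"))
  resid_at <- function(d) {
    m <- effect_matrix(one_to_one_matrix(fit, delta = d))
    max(abs(m + t(m)), na.rm = TRUE)
  }
  r <- vapply(c(0.1, 0.01, 0.001), resid_at, numeric(1))
  expect_gt(r[1], 0)  # exact asymmetry at the working delta
  expect_equal(r[1] / r[2], 100, tolerance = 0.1)
  expect_equal(r[2] / r[3], 100, tolerance = 0.1)
  m <- one_to_one_matrix(fit, delta = 0.1)
  expect_equal(nrow(m), 18 * 17)
  expect_true(all(m$target != m$source))
  wide <- effect_matrix(m)
  expect_true(all(is.na(diag(wide))))
})

test_that("delta-method SE scales as 1/sqrt(n)", {
  ses <- vapply(c(300, 1200, 4800), function(n) {
    coh <- small_cohort(n = n, seed = 52)
    fit <- fit_composition_model(coh, model_spec("glucose"))
    substitution_effect(fit, perturbation("one_to_all", "LEU"))$se
  }, numeric(1))
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.15)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.15)
})

test_that("relabeling components permutes the effect matrix identically", {
  a <- c(A = 2, B = -3, C = 1)
  set.seed(5)
  w <- matrix(exp(rnorm(40 * 3, sd = 0.2)), 40)
  colnames(w) <- names(a)
  comp <- close_composition(w)
  dat <- tibble::as_tibble(comp)
  dat$y <- drop(clr_transform(comp) %*% a)
  spec_for <- function(cols) {
    sp <- model_spec("glucose", covariates = character(),
                     composition_cols = cols)
    sp$outcome <- "y"; sp$outcome_label <- "y"; sp$log_transform <- FALSE
    sp
  }
  fit1 <- fit_composition_model(dat, spec_for(c("A", "B", "C")))
  # same data with components renamed A->P, B->Q, C->R
  dat2 <- dplyr::rename(dat, P = "A", Q = "B", R = "C")
  fit2 <- fit_composition_model(dat2, spec_for(c("P", "Q", "R")))
  m1 <- effect_matrix(one_to_one_matrix(fit1, delta = 0.2))
  m2 <- effect_matrix(one_to_one_matrix(fit2, delta = 0.2))
  dimnames(m2) <- dimnames(m1)  # P,Q,R correspond to A,B,C
  expect_equal(m2, m1, tolerance = 1e-10)
})
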