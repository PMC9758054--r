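test_that("collision competence matches a hand evaluation", {
  cc <- chamber_counts(
    pre = c(A20_dCas = 0.90, A20_only = 0.05, dCas_only = 0.03, Nak = 0.02),
    post = c(TEC_up_dCas = 0.10, TEC_up_only = 0.05, Coll = 0.40,
             dCas_rem = 0.05, TEC_dn = 0.10, Nak = 0.20, dCas_only = 0.10),
    counts = FALSE)
  expect_equal(collision_competence(cc, nuisance_params(0.10, 0)),
               1 - 0.15 / (0.95 * 0.90), tolerance = 1e-12)
  # all motors reached the site
  cc2 <- chamber_counts(
    pre = c(A20_dCas = 0.95, A20_only = 0.05, dCas_only = 0, Nak = 0),
    post = c(TEC_up_dCas = 0, TEC_up_only = 0, Coll = 0.5, dCas_rem = 0,
             TEC_dn = 0.2, Nak = 0.3, dCas_only = 0), counts = FALSE)
  expect_equal(collision_competence(cc2, nuisance_params()), 1)
})

test_that("read-through reduces correctly in degenerate limits", {
  # perfect co-occupancy, no nuisance dissociation, full competence
  cc <- chamber_counts(
    pre = c(A20_dCas = 1, A20_only = 0, dCas_only = 0, Nak = 0),
    post = c(TEC_up_dCas = 0, TEC_up_only = 0, Coll = 0.57, dCas_rem = 0,
             TEC_dn = 0, Nak = 0.43, dCas_only = 0), counts = FALSE)
  expect_equal(read_through(cc, nuisance_params(), 1), 0.43,
               tolerance = 1e-15)
  # no change in the naked pool and no subtraction terms: zero read-through
  cc0 <- chamber_counts(
    pre = c(A20_dCas = 0.9, A20_only = 0, dCas_only = 0, Nak = 0.1),
    post = c(TEC_up_dCas = 0.2, TEC_up_only = 0, Coll = 0.7, dCas_rem = 0,
             TEC_dn = 0, Nak = 0.1, dCas_only = 0), counts = FALSE)
  expect_equal(read_through(cc0, nuisance_params(), 0.8), 0)
})

test_that("removal adds the stalled-removal fraction and dominates", {
  nu <- nuisance_params(0.05, 0.05)
  cc <- chamber_counts(
    pre = c(A20_dCas = 0.9, A20_only = 0.04, dCas_only = 0.04, Nak = 0.02),
    post = c(TEC_up_dCas = 0.1, TEC_up_only = 0.02, Coll = 0.3,
             dCas_rem = 0.08, TEC_dn = 0.15, Nak = 0.3, dCas_only = 0.05),
    counts = FALSE)
  p_cc <- collision_competence(cc, nu)
  expect_gte(removal(cc, nu, p_cc), read_through(cc, nu, p_cc))
  # with no stalled removals the two coincide
  cc2 <- chamber_counts(
    pre = cc$pre,
    post = c(TEC_up_dCas = 0.1, TEC_up_only = 0.02, Coll = 0.38,
             dCas_rem = 0, TEC_dn = 0.15, Nak = 0.3, dCas_only = 0.05),
    counts = FALSE)
  expect_equal(removal(cc2, nu, p_cc), read_through(cc2, nu, p_cc))
})

test_that("the estimator inverts the generative tree exactly", {
  withr::with_seed(11, {
    for (i in 1:50) {
      cfg <- random_generator_config()
      est <- estimate_from_expected(cfg)
      expect_equal(unname(est["p_coll_comp"]), cfg$p_coll_comp,
                   tolerance = 1e-12)
      expect_equal(unname(est["p_read_through"]), cfg$p_read_through,
                   tolerance = 1e-12)
      expect_equal(unname(est["p_removal"]),
                   cfg$p_read_through + cfg$p_removal_stall,
                   tolerance = 1e-12)
    }
  })
})

test_that("aggregation computes mean and s.e.m. with n-1 denominator", {
  mk <- function(p_nak) chamber_counts(
    pre = c(A20_dCas = 1, A20_only = 0, dCas_only = 0, Nak = 0),
    post = c(TEC_up_dCas = 0, TEC_up_only = 0, Coll = 1 - p_nak,
             dCas_rem = 0, TEC_dn = 0, Nak = p_nak, dCas_only = 0),
    counts = FALSE)
  fit <- roadblock_model(list(mk(0.4), mk(0.5), mk(0.6)),
                         nuisance_params())
  a <- fit$aggregate
  expect_equal(a$mean[a$quantity == "p_read_through"], 0.5)
  expect_equal(a$sem[a$quantity == "p_read_through"], 0.1 / sqrt(3),
               tolerance = 1e-12)
  # identical chambers: s.e.m. 0
  fit2 <- roadblock_model(list(mk(0.5), mk(0.5)), nuisance_params())
  expect_equal(fit2$aggregate$sem[3], 0)
  # single chamber: mean defined, s.e.m. unavailable
  fit1 <- roadblock_model(list(mk(0.5)), nuisance_params())
  expect_equal(coef(fit1)[["p_read_through"]], 0.5)
  expect_true(is.na(fit1$aggregate$sem[2]))
})

test_that("undefined and out-of-range chambers are flagged, not hidden", {
  # no initial motor occupancy: undefined collision competence
  bad <- chamber_counts(
    pre = c(A20_dCas = 0, A20_only = 0, dCas_only = 0.5, Nak = 0.5),
    post = c(TEC_up_dCas = 0, TEC_up_only = 0, Coll = 0, dCas_rem = 0,
             TEC_dn = 0, Nak = 0.6, dCas_only = 0.4), counts = FALSE)
  expect_true(is.na(collision_competence(bad, nuisance_params())))
  ok <- chamber_counts(
    pre = c(A20_dCas = 1, A20_only = 0, dCas_only = 0, Nak = 0),
    post = c(TEC_up_dCas = 0, TEC_up_only = 0, Coll = 0.5, dCas_rem = 0,
             TEC_dn = 0, Nak = 0.5, dCas_only = 0), counts = FALSE)
  fit <- roadblock_model(list(bad, ok), nuisance_params())
  expect_equal(fit$n_invalid, 1)
  expect_equal(fit$aggregate$n[1], 1)
  # sampling noise can push estimates out of [0, 1]; they are reported raw
  hot <- chamber_counts(
    pre = c(A20_dCas = 0.5, A20_only = 0.5, dCas_only = 0, Nak = 0),
    post = c(TEC_up_dCas = 0, TEC_up_only = 0, Coll = 0, dCas_rem = 0,
             TEC_dn = 0.5, Nak = 0.5, dCas_only = 0), counts = FALSE)
  fit2 <- roadblock_model(list(hot), nuisance_params(0.3, 0))
  expect_gt(fit2$chambers$p_read_through, 1)
  expect_true(fit2$chambers$out_of_range)
})

test_that("read-through sensitivity to the dCas nuisance follows the algebra", {
  # independent derivative of the ratio N(pdd)/D(pdd), coded from the
  # printed equation, compared against a finite difference of the function
  cc <- chamber_counts(
    pre = c(A20_dCas = 0.88, A20_only = 0.05, dCas_only = 0.04, Nak = 0.03),
    post = c(TEC_up_dCas = 0.08, TEC_up_only = 0.04, Coll = 0.30,
             dCas_rem = 0.05, TEC_dn = 0.18, Nak = 0.30, dCas_only = 0.05),
    counts = FALSE)
  p_cc <- 0.85
  pmd <- 0.05
  for (pdd in seq(0.02, 0.3, by = 0.04)) {
    h <- 1e-6
    fd <- (read_through(cc, nuisance_params(pmd, pdd + h), p_cc) -
             read_through(cc, nuisance_params(pmd, pdd - h), p_cc)) / (2 * h)
    reached <- p_cc * (1 - pmd) + pmd
    num <- cc$post[["Nak"]] + cc$post[["TEC_dn"]] - cc$pre[["Nak"]] -
      cc$pre[["A20_dCas"]] * reached * pdd -
      cc$pre[["A20_only"]] * reached - cc$pre[["dCas_only"]] * pdd
    den <- cc$pre[["A20_dCas"]] * p_cc * (1 - pmd) * (1 - pdd)
    dnum <- -cc$pre[["A20_dCas"]] * reached - cc$pre[["dCas_only"]]
    dden <- -cc$pre[["A20_dCas"]] * p_cc * (1 - pmd)
    expect_equal(fd, unname((dnum * den - num * dden) / den^2),
                 tolerance = 1e-4)
  }
})

test_that("estimates converge to the truth as traces per chamber grow", {
  cfg_at <- function(n) generator_config(
    p_read_through = 0.43, p_removal_stall = 0.12, p_coll_comp = 0.85,
    p_motor_diss = 0.05, p_dcas_diss = 0.05,
    n_control = n, n_chase = n, n_chambers = 6, seed = 100 + n)
  errs <- sapply(c(50, 500, 5000), function(n) {
    counts <- count_categories(sample_outcomes(cfg_at(n)))
    fit <- roadblock_model(counts, nuisance_params(0.05, 0.05))
    abs(coef(fit)[["p_read_through"]] - 0.43)
  })
  expect_lt(errs[3], 0.02)
  expect_lt(errs[3], errs[1] + 0.02)
})

test_that("model methods are coherent", {
  cfg <- generator_config(p_read_through = 0.43, p_removal_stall = 0.1,
                          seed = 77)
  counts <- count_categories(sample_outcomes(cfg))
  fit <- roadblock_model(counts, nuisance_params(0.05, 0.05))
  expect_s3_class(fit, "roadblock_model")
  expect_named(coef(fit), c("p_coll_comp", "p_read_through", "p_removal"))
  expect_output(print(fit), "p_read_through")
  expect_output(print(summary(fit)), "Per-chamber")
  r <- residuals(fit)
  expect_equal(colMeans(r), c(p_coll_comp = 0, p_read_through = 0,
                              p_removal = 0), tolerance = 1e-12)
  # predict: forward tree at the fitted parameters sums to one
  pr <- predict(fit)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  # simulate: outcome tables at the fitted parameters, reproducible
  s1 <- simulate(fit, nsim = 1, seed = 5)
  s2 <- simulate(fit, nsim = 1, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sort(unique(s1[[1]]$phase)), c("chase", "control"))
})
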