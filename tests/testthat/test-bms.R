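space <- build_model_space()

test_that("the model space has the pinned structure", {
  expect_equal(nrow(space$nodes), 6)           # 5 cortical + hidden BG
  expect_equal(sum(space$nodes$hidden), 1)
  expect_equal(nrow(space$edges), 14)
  expect_length(space$models, 9)
  expect_length(space$families, 3)
  expect_true(all(lengths(space$families) == 3))
  expect_setequal(unlist(space$families), names(space$models))
  # every modulation mask touches only BG-involving edges
  bg_edges <- space$edges$id[space$edges$from == "BG" | space$edges$to == "BG"]
  for (m in space$models) expect_true(all(m %in% bg_edges))
  # MNI coordinates of the cortical sources
  expect_equal(space$nodes$x[space$nodes$name == "R_IFG"], 54)
  expect_equal(space$nodes$z[space$nodes$name == "preSMA_dACC"], 56)
  # inputs target IFG and DLPFC bilaterally
  expect_setequal(space$input_nodes, c("L_IFG", "R_IFG", "L_DLPFC", "R_DLPFC"))
})

test_that("the canonical YAML fixture matches the in-code space", {
  path <- system.file("extdata", "model_space.yaml", package = "stopsignal")
  expect_true(nzchar(path))
  expect_equal(yaml::yaml.load(model_space_to_yaml(space)),
               yaml::read_yaml(path))
})

test_that("symmetric evidences give the analytic posterior and flat exceedance", {
  lnE <- matrix(0, 12, 9,
                dimnames = list(sprintf("S%02d", 1:12), names(space$models)))
  res <- rfx_bms(lnE, prior_alpha = 1, n_samples = 1e5, seed = 1)
  expect_equal(unname(res$alpha), rep(1 + 12 / 9, 9), tolerance = 1e-8)
  expect_equal(sum(res$expected_freq), 1, tolerance = 1e-12)
  expect_equal(sum(res$exceedance), 1, tolerance = 1e-3)
  expect_true(all(abs(res$exceedance - 1 / 9) < 0.01))
  expect_true(res$converged)
})

test_that("the fixed point matches an independent high-precision solver", {
  lnE <- matrix(c(log(2), 0), 1, 2, dimnames = list("S1", c("m1", "m2")))
  res <- rfx_bms(lnE, prior_alpha = 1, n_samples = 1e4, seed = 1)
  oracle <- rfx_fixed_point_oracle(lnE, prior = 1)
  expect_equal(unname(res$alpha), unname(oracle), tolerance = 1e-5)

  lnE2 <- matrix(rnorm(36), 12, 3,
                 dimnames = list(sprintf("S%02d", 1:12), c("a", "b", "c")))
  res2 <- rfx_bms(lnE2, n_samples = 1e4, seed = 2)
  expect_equal(unname(res2$alpha), unname(rfx_fixed_point_oracle(lnE2)),
               tolerance = 1e-4)
})

test_that("two-model exceedance matches the closed-form Beta comparison", {
  # with K = 2 the Dirichlet marginal is Beta(a1, a2), so the exceedance of
  # model 1 is P(p1 > 1/2) = 1 - pbeta(0.5, a1, a2)
  set.seed(3)
  xp <- stopsignal:::dirichlet_argmax_freq(c(11, 3), 1e6)
  expect_equal(xp[1], 1 - pbeta(0.5, 11, 3), tolerance = 1e-3)
  set.seed(4)
  xp2 <- stopsignal:::dirichlet_argmax_freq(c(5, 7), 1e6)
  expect_equal(xp2[1], 1 - pbeta(0.5, 5, 7), tolerance = 1e-3)
})

test_that("posterior mass is conserved and evidence shifts are irrelevant", {
  lnE <- simulate_evidences(space, "IFG_both", effect_nats = 3,
                            noise_nats = 2, n_subjects = 10, seed = 6)
  res <- rfx_bms(lnE, prior_alpha = 1, n_samples = 1e4, seed = 1)
  expect_equal(sum(res$alpha), 9 * 1 + 10, tolerance = 1e-6)
  shifted <- lnE + rep(rnorm(10, 0, 50), ncol(lnE))
  res2 <- rfx_bms(shifted, prior_alpha = 1, n_samples = 1e4, seed = 1)
  expect_equal(res$alpha, res2$alpha, tolerance = 1e-6)
  expect_equal(res$exceedance, res2$exceedance, tolerance = 1e-12)
})

test_that("evidence simulation has the stated dimensions and degenerate limits", {
  lnE <- simulate_evidences(space, "both_efferent", n_subjects = 12, seed = 1)
  expect_equal(dim(lnE), c(12, 9))
  expect_equal(attr(lnE, "generating_model"), rep("both_efferent", 12))
  expect_error(simulate_evidences(space, "no_such_model"), "unknown")
  # zero effect: models are exchangeable, so exceedance averaged over
  # datasets is flat (any single noisy dataset may favor one model)
  xp <- rowMeans(vapply(1:10, function(sd) {
    lnE0 <- simulate_evidences(space, "both_efferent", effect_nats = 0,
                               noise_nats = 1, n_subjects = 12, seed = sd)
    rfx_bms(lnE0, n_samples = 2e4, seed = 1)$exceedance
  }, numeric(9)))
  expect_true(all(abs(xp - 1 / 9) < 0.1))
  # strong effect: the true model dominates
  lnE1 <- simulate_evidences(space, "preSMA_afferent", effect_nats = 10,
                             noise_nats = 1, n_subjects = 12, seed = 3)
  res1 <- rfx_bms(lnE1, n_samples = 1e5, seed = 1)
  expect_gt(res1$exceedance["preSMA_afferent"], 0.95)
})

test_that("family inference is symmetric under symmetry and decisive when driven", {
  lnE <- matrix(0, 12, 9,
                dimnames = list(sprintf("S%02d", 1:12), names(space$models)))
  fam <- family_bms(lnE, space$families, n_samples = 1e5, seed = 4)
  expect_true(all(abs(fam$family_exceedance - 1 / 3) < 0.02))
  expect_equal(sum(fam$family_exceedance), 1, tolerance = 1e-3)
  # per-subject weights on each family's models sum to the family posterior
  within <- fam$within_family
  for (w in within) expect_equal(sum(w), 1, tolerance = 1e-12)

  lnE2 <- simulate_evidences(space, "both_both", effect_nats = 10,
                             noise_nats = 1, n_subjects = 12, seed = 5)
  fam2 <- family_bms(lnE2, space$families, n_samples = 1e5, seed = 4)
  expect_gt(fam2$family_exceedance["both"], 0.9)
  expect_error(family_bms(lnE2, list(a = "both_both")), "cover")
})

test_that("BMA reduces correctly in degenerate cases", {
  lnE <- simulate_evidences(space, "IFG_afferent", effect_nats = 2,
                            noise_nats = 1, n_subjects = 4, seed = 7)
  pars <- simulate_dcm_params(space, n_subjects = 4, seed = 7)
  # single-model family returns that model's parameters unchanged
  one <- bma(pars, lnE, "IFG_afferent")
  sub <- pars[pars$model == "IFG_afferent", ]
  merged <- merge(one$subject_strengths, sub,
                  by = c("subject", "connection", "condition"))
  expect_equal(merged$strength.x, merged$strength.y, tolerance = 1e-12)
  # equal evidences and strengths theta, 3*theta average to 2*theta
  lnEq <- matrix(0, 2, 2, dimnames = list(c("S01", "S02"), c("mA", "mB")))
  theta <- data.frame(
    subject = rep(c("S01", "S02"), each = 4),
    model = rep(rep(c("mA", "mB"), each = 2), 2),
    connection = "c1", condition = rep(c("OFF", "ON"), 4),
    strength = rep(c(1, 1, 3, 3), 2))
  avg <- bma(theta, lnEq, c("mA", "mB"))
  expect_true(all(avg$subject_strengths$strength == 2))
  expect_error(bma(theta, lnEq, c("mA", "missing")), "missing")
})

test_that("BMA detects a simulated efferent-connection decrease", {
  lnE <- simulate_evidences(space, "both_efferent", effect_nats = 5,
                            noise_nats = 1, n_subjects = 12, seed = 8)
  pars <- simulate_dcm_params(space, n_subjects = 12,
                              target_connection = "BG->R_IFG",
                              on_scale = 0.7, seed = 8)
  res <- bma(pars, lnE, space$families$both)
  row <- res$tests[res$tests$measure == "BG->R_IFG", ]
  expect_lt(row$mean_on, row$mean_off)
  expect_lt(row$p_value, 0.05)
  # group summary is the exponential of the subject-mean log strength
  g <- res$group_summary
  on <- g$group_strength[g$connection == "BG->R_IFG" & g$condition == "ON"]
  off <- g$group_strength[g$connection == "BG->R_IFG" & g$condition == "OFF"]
  expect_equal(on / off, 0.7, tolerance = 0.15)
  # weights sum to 1 per subject
  expect_equal(unname(rowSums(res$weights)), rep(1, 12), tolerance = 1e-12)
})
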