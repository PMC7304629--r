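test_that("training-set simulation is seeded, saturating and well-calibrated", {
  a <- simulate_training_set(200, seed = 11)
  b <- simulate_training_set(200, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_training_set(200, seed = 12)))
  # logistic saturation: huge intercept forces every label to 1
  sat <- simulate_training_set(500, gamma = 50, seed = 13)
  expect_true(all(sat$label == 1))
  # empirical prevalence vs E[p] by numerical integration over the features
  lam <- c(2, -1, 0.5); gam <- -0.3
  sd <- c(0.2, 0.3, 1.5)
  # S_F ~ N(gam, s2): E[p] = E[plogis(S_F)] by 1-D quadrature
  s2 <- sum((lam * sd)^2)
  ep <- integrate(function(z) plogis(gam + sqrt(s2) * z) * dnorm(z),
                  -10, 10)$value
  big <- simulate_training_set(50000, lambda = lam, gamma = gam, sd = sd,
                               seed = 14)
  se <- sqrt(ep * (1 - ep) / 50000)
  expect_lt(abs(mean(big$label) - ep), 3 * se)
})

test_that("labels are Bernoulli draws at the model probability", {
  tr <- simulate_training_set(20000, seed = 15)
  # bin by p_true; observed label rate tracks the bin mean probability
  bins <- cut(tr$p_true, seq(0, 1, 0.2), include.lowest = TRUE)
  obs <- tapply(tr$label, bins, mean)
  expl <- tapply(tr$p_true, bins, mean)
  expect_true(all(abs(obs - expl) < 0.03, na.rm = TRUE))
})

test_that("correlated features are supported through the Cholesky factor", {
  R <- matrix(c(1, 0.6, 0, 0.6, 1, 0, 0, 0, 1), 3)
  tr <- simulate_training_set(20000, chol_corr = chol(R), seed = 16)
  expect_equal(cor(tr$delta_id, tr$delta_a), 0.6, tolerance = 0.03)
})

test_that("designed sequences realise their composition and disorder targets", {
  des <- data.frame(start = 41, end = 52, delta_h = 2.0, delta_a = -0.3,
                    delta_id = -0.25)
  ss <- synth_sequence(120, des, seed = 21)
  # recompute from the emitted sequence with the published KD values
  kd <- kyte_doolittle()
  chars <- strsplit(ss$seq$residues, "")[[1]]
  bg <- setdiff(seq_len(120), 41:52)
  dh <- mean(kd[chars[41:52]]) - mean(kd[chars[bg]])
  expect_lt(abs(dh - 2.0), 0.2 + 1e-12)
  expect_lt(abs(ss$truth$realised_delta_a - (-0.3)), 0.15 + 1e-12)
  expect_equal(ss$truth$realised_delta_id, -0.25, tolerance = 1e-9)
  # same design + seed -> identical sequence
  ss2 <- synth_sequence(120, des, seed = 21)
  expect_identical(ss2$seq$residues, ss$seq$residues)
  expect_identical(ss2$profile$scores, ss$profile$scores)
})

test_that("null designs give near-zero realised deltas", {
  des <- data.frame(start = 41, end = 49)  # no bias columns: targets 0
  ss <- synth_sequence(120, des, seed = 22)
  expect_lt(abs(ss$truth$realised_delta_h), 0.2)
  expect_lt(abs(ss$truth$realised_delta_a), 0.15)
  expect_lt(abs(ss$truth$realised_delta_id), 0.05)
})

test_that("invalid designs are rejected", {
  expect_error(synth_sequence(100, data.frame(start = 98, end = 104),
                              seed = 1))
  expect_error(synth_sequence(100, data.frame(start = 10, end = 12),
                              seed = 1))  # region < 5
  expect_error(synth_sequence(
    100, data.frame(start = c(10, 15), end = c(18, 22)), seed = 1),
    "overlap")
  expect_error(synth_sequence(
    100, data.frame(start = 10, end = 18, delta_h = 9), seed = 1),
    "achievable")
})

test_that("toy structure files realise their observed/missing plan", {
  d <- withr::local_tempdir()
  s <- synth_structures(45, c(18, 27), c("ordered_contact", "missing"),
                        dir = d)
  expect_true(file.exists(s$monomer))
  expect_length(s$complexes, 2)
  obs <- residue_order_states(s$complexes[2], "A", 45)
  expect_true(all(obs$states[18:27] == "M"))
  expect_equal(s$truth, "CDR")
  # plan validation
  expect_error(synth_structures(45, c(18, 21), "missing", dir = d))
  expect_error(synth_structures(45, c(18, 27), "bogus", dir = d), "unknown")
})

test_that("curation reproduces the truth table of every plan combination", {
  d <- withr::local_tempdir()
  plans <- list(c("ordered_contact"),
                c("missing", "missing", "missing"),
                c("ordered_contact", "ordered_contact"),
                c("missing", "ordered_contact"),
                c("ordered_nocontact", "missing"))
  for (k in seq_along(plans)) {
    s <- synth_structures(50, c(21, 30), plans[[k]], dir = d,
                          prefix = paste0("combo", k))
    expect_equal(curate_synth(s, 50)$label, s$truth,
                 info = paste(plans[[k]], collapse = "+"))
  }
})

test_that("coefficient recovery has near-nominal CI coverage across replicates", {
  lam <- c(2, -1, 0.5); gam <- -0.3
  truth <- c(gam, lam)
  hits <- matrix(0L, 100, 4)
  for (r in 1:100) {
    tr <- simulate_training_set(1000, lambda = lam, gamma = gam,
                                seed = 3000 + r)
    ci <- confint(fit_binding_model(data = tr))
    hits[r, ] <- as.integer(ci[, 1] <= truth & truth <= ci[, 2])
  }
  # each coefficient's nominal-95% CI covers its truth in >= 90/100 replicates
  expect_true(all(colSums(hits) >= 90L))
})
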