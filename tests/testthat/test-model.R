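test_that("region score is the stated linear form", {
  expect_equal(score_region(c(delta_id = 0, delta_a = 0, delta_h = 0),
                            toy_params(c(1, 1, 1), gamma = 0)), 0)
  expect_equal(score_region(c(delta_id = 0.2, delta_a = 0.3, delta_h = 0.5),
                            toy_params(c(1, 1, 1), gamma = 0)), 1.0)
  # hand computation: 2*0.1 - 1*0.2 + 0.5*0.4 - 0.3 = -0.1
  expect_equal(score_region(c(delta_id = 0.1, delta_a = 0.2, delta_h = 0.4),
                            toy_params(c(2, -1, 0.5), gamma = -0.3)),
               -0.1)
})

test_that("logistic transform is exact, antisymmetric and monotone", {
  expect_identical(pdo_from_score(0), 0.5)
  expect_equal(pdo_from_score(log(3)), 0.75)
  s <- c(-50, -3, -0.1, 0.2, 7, 60)
  expect_equal(pdo_from_score(s) + pdo_from_score(-s), rep(1, length(s)))
  expect_true(all(diff(pdo_from_score(seq(-30, 30, by = 0.5))) > 0))
  # stable at large |s|
  expect_equal(pdo_from_score(1000), 1)
  expect_equal(pdo_from_score(-1000), 0)
})

test_that("IRLS fit matches the glm oracle on a modest sample", {
  tr <- simulate_training_set(400, lambda = c(2, -1, 0.5), gamma = -0.3,
                              seed = 101)
  fit <- fit_binding_model(data = tr)
  ora <- glm(label ~ delta_id + delta_a + delta_h, family = binomial(),
             data = tr)
  expect_equal(unname(coef(fit)), unname(coef(ora)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ora)))),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ora)), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("fit rejects degenerate input and flags separation", {
  tr <- simulate_training_set(100, seed = 1)
  tr$label <- 1
  expect_error(fit_binding_model(data = tr), "both classes")
  tr2 <- simulate_training_set(100, seed = 2)
  tr2$label <- as.integer(tr2$delta_h > 0)  # perfectly separable
  expect_warning(fit <- fit_binding_model(data = tr2), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(coef(fit))))
  # non-finite features rejected
  tr3 <- simulate_training_set(100, seed = 3)
  tr3$delta_id[5] <- NaN
  expect_error(fit_binding_model(data = tr3), "non-finite")
  expect_error(fit_binding_model(data = simulate_training_set(12, seed = 4)),
               ">= 10")
})

test_that("true coefficients are recovered within their 95% CIs at n=5000", {
  tr <- simulate_training_set(5000, lambda = c(2, -1, 0.5), gamma = -0.3,
                              seed = 1)
  fit <- fit_binding_model(data = tr)
  ci <- confint(fit)
  truth <- c(-0.3, 2, -1, 0.5)  # intercept first, as in coef()
  expect_true(all(ci[, 1] <= truth & truth <= ci[, 2]))
  # and the point estimates are close in absolute terms at this n
  expect_equal(unname(coef(fit)), truth, tolerance = 0.15)
})

test_that("refits are deterministic and equivariant under feature rescaling", {
  tr <- simulate_training_set(600, seed = 55)
  f1 <- fit_binding_model(data = tr)
  f2 <- fit_binding_model(data = tr)
  expect_identical(coef(f1), coef(f2))
  trs <- tr; trs$delta_h <- trs$delta_h * 4
  f3 <- fit_binding_model(data = trs)
  expect_equal(coef(f3)[["delta_h"]], coef(f1)[["delta_h"]] / 4,
               tolerance = 1e-6)
})

test_that("model methods: summary, predict, residuals, simulate", {
  tr <- simulate_training_set(300, seed = 77)
  fit <- fit_binding_model(data = tr)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.binding_model")
  expect_equal(dim(sm$coefficients), c(4, 4))
  p <- predict(fit, newdata = tr)
  expect_equal(p, unname(fit$fitted), tolerance = 1e-12)
  eta <- predict(fit, newdata = tr, type = "link")
  expect_equal(plogis(eta), p, tolerance = 1e-12)
  r <- residuals(fit)
  expect_equal(sum(r^2), -2 * fit$loglik, tolerance = 1e-8)  # deviance identity
  s1 <- simulate(fit, nsim = 2, seed = 9)
  s2 <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(s1, s2)
})

test_that("model JSON round-trips bit-exactly and validates fields", {
  tr <- simulate_training_set(200, seed = 31)
  fit <- fit_binding_model(data = tr)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, f, provenance = list(note = "test"))
  back <- read_model_json(f)
  expect_identical(back$lambda, unname(coef(fit)[2:4]))
  expect_identical(back$gamma, unname(coef(fit)[1]))
  expect_equal(back$feature_config$composition_stat, "topidp")
  # missing mandatory field
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(lambda1 = 1), bad, auto_unbox = TRUE)
  expect_error(read_model_json(bad), "missing field")
})

test_that("packaged default model loads and matches its feature config", {
  m <- default_model()
  expect_s3_class(m, "binding_params")
  expect_length(m$lambda, 3)
  expect_true(is.finite(m$gamma))
  expect_equal(m$feature_config$flank_len, 20)
  expect_match(m$provenance$description, "[Nn]on-canonical")
})
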