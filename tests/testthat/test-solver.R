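test_that("initialization pseudo-labels well-separated targets perfectly", {
  for (s in 1:10) {
    b <- make_two_domain_blobs(n = 40, m = 40, d = 4, n_classes = 2,
                               class_separation = 8, shift_magnitude = 0,
                               seed = s)
    st <- cpddm_initialize(b$source$features, b$source$labels,
                           b$target$features, cpddm_control(seed = s))
    # source-classifier hot start recovers the target truth with no shift
    src_pred <- predict(st$source_fit,
                        st$Xa[!st$src, , drop = FALSE])$labels
    expect_equal(src_pred, b$target$labels)
  }
})

test_that("a target identical to the source reproduces self-predictions", {
  b <- toy_problem(seed = 31)
  st <- cpddm_initialize(b$source$features, b$source$labels,
                         b$source$features, cpddm_control(seed = 31))
  self_pred <- predict(st$source_fit, st$Xa[st$src, , drop = FALSE])$labels
  init_pseudo <- predict(st$source_fit,
                         st$Xa[!st$src, , drop = FALSE])$labels
  expect_equal(init_pseudo, self_pred)
})

test_that("delta = 1 makes class means independent of the target domain", {
  cm <- class_mean_coefficients(c(1L, 2L, 1L), c(1L, 2L, 2L), delta = 1)
  expect_true(all(cm$coefficients[4:6, 2:3] == 0))
  # whole-domain column too
  expect_true(all(cm$coefficients[4:6, 1] == 0))
})

test_that("stopping-rule extremes behave as documented", {
  b <- toy_problem(seed = 32)
  # huge epsilon: exactly one iteration runs
  st1 <- cpddm_fit(b$source$features, b$source$labels, b$target$features,
                   cpddm_control(epsilon = 1e9, seed = 32))
  expect_equal(st1$iterations, 1L)
  expect_true(st1$converged)
  # max_iter = 0: initialization returned unchanged
  st0 <- cpddm_fit(b$source$features, b$source$labels, b$target$features,
                   cpddm_control(max_iter = 0, seed = 32))
  expect_equal(st0$iterations, 0L)
  expect_equal(nrow(st0$trace), 1L)
})

test_that("the relaxed objective trace is non-increasing and the stopping
          rule fires", {
  for (s in 1:5) {
    b <- toy_problem(seed = s)
    st <- cpddm_fit(b$source$features, b$source$labels, b$target$features,
                    cpddm_control(seed = s))
    expect_true(all(diff(st$trace$theta_relaxed) <= 1e-9))
    expect_true(st$converged)
    expect_lt(st$iterations, 50)
  }
})

test_that("identical seeds and configs give identical runs", {
  b <- toy_problem(seed = 33)
  run <- function() {
    st <- cpddm_fit(b$source$features, b$source$labels, b$target$features,
                    cpddm_control(seed = 33))
    list(trace = st$trace, pred = cpddm_predict(st)$labels)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$pred, r2$pred)
})

test_that("fusion weight limits recover the two component classifiers", {
  b <- toy_problem(seed = 34, shift_magnitude = 2)
  st <- cpddm_fit(b$source$features, b$source$labels, b$target$features,
                  cpddm_control(seed = 34))
  p1 <- cpddm_predict(st, upsilon = 1)
  p0 <- cpddm_predict(st, upsilon = 0)
  Xt <- st$Xa[!st$src, , drop = FALSE]
  expect_equal(p1$labels, predict(p1$fit_source, Xt)$labels)
  expect_equal(p0$labels, predict(p0$fit_target, Xt)$labels)
  # where the two classifiers agree, the fusion cannot disagree
  agree <- p1$labels == p0$labels
  p9 <- cpddm_predict(st, upsilon = 0.9)
  expect_equal(p9$labels[agree], p1$labels[agree])
})

test_that("accuracy and confusion matrices are counted correctly", {
  ev <- evaluate_predictions(c(1, 2, 2, 2), c(1, 1, 2, 2))
  expect_equal(ev$accuracy, 0.75)
  expect_equal(unname(ev$confusion),
               matrix(c(1L, 0L, 1L, 2L), 2, 2))
  expect_equal(evaluate_predictions(1:4, 1:4)$accuracy, 1)
  expect_equal(evaluate_predictions(c(1, 1), c(2, 2))$accuracy, 0)
  expect_error(evaluate_predictions(c(1, 5), c(1, 2), n_classes = 2), "1..2")
  expect_error(evaluate_predictions(1:3, 1:2), "length")
})

test_that("frozen pseudo-labels are honored by the ablation flag", {
  b <- toy_problem(seed = 35, shift_magnitude = 2)
  st <- cpddm_fit(b$source$features, b$source$labels, b$target$features,
                  cpddm_control(seed = 35, refresh_pseudo_labels = FALSE))
  st_init <- cpddm_initialize(b$source$features, b$source$labels,
                              b$target$features,
                              cpddm_control(seed = 35,
                                            refresh_pseudo_labels = FALSE))
  expect_equal(st$pseudo, st_init$pseudo)
})

test_that("memberships downweight far outliers in the source domain", {
  b <- toy_problem(seed = 36, outlier_fraction = 0.2, outlier_scale = 10)
  st <- cpddm_fit(b$source$features, b$source$labels, b$target$features,
                  cpddm_control(seed = 36))
  l2 <- st$lam[seq_len(st$n), 1]^2
  expect_lt(mean(l2[b$source$outlier]), 0.5 * mean(l2[!b$source$outlier]))
})

test_that("solver rejects inconsistent inputs", {
  b <- toy_problem(seed = 37)
  expect_error(cpddm_initialize(b$source$features, b$source$labels,
                                b$target$features[, 1:3],
                                cpddm_control()), "dimension")
  expect_error(cpddm_initialize(b$source$features,
                                rep(1L, nrow(b$source$features)),
                                b$target$features, cpddm_control()),
               "two classes")
  bad <- b$source$labels
  bad[bad == 2L] <- 3L
  expect_error(cpddm_initialize(b$source$features, bad, b$target$features,
                                cpddm_control()), "must appear")
})

test_that("random Fourier mode runs end to end", {
  b <- make_two_domain_blobs(n = 40, m = 40, d = 4, n_classes = 2, seed = 38)
  st <- cpddm_fit(b$source$features, b$source$labels, b$target$features,
                  cpddm_control(seed = 38, map_type = "random_fourier",
                                rf_dimension = 100))
  acc <- evaluate_predictions(cpddm_predict(st)$labels,
                              b$target$labels)$accuracy
  expect_gt(acc, 0.8)
})
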