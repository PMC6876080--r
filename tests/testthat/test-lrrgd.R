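test_that("bag sizing and expected selections follow the sqrt rule", {
  expect_equal(feature_subset_size(1608), 40)
  expect_equal(feature_subset_size(1), 1)
  expect_equal(feature_subset_size(100), 10)
  expect_equal(expected_selections(400, 40, 1608), 400 * 40 / 1608)
  expect_equal(round(expected_selections(400, 40, 1608), 2), 9.95)
  expect_equal(expected_selections(37, 12, 12), 37)
  expect_error(expected_selections(10, 20, 5), "exceed")
})

test_that("feature sampling is uniform, distinct and seed-reproducible", {
  set.seed(1)
  full <- sample_features(7, 7)
  expect_setequal(full, 1:7)
  set.seed(42); a <- sample_features(100, 10)
  set.seed(42); b <- sample_features(100, 10)
  expect_identical(a, b)
  expect_false(anyDuplicated(a) > 0)
  expect_error(sample_features(5, 6), "exceed")

  # frequency of each index over 10,000 draws of 2 from 5: binomial with
  # p = 2/5, so each count should sit within 3 sigma of 4,000
  set.seed(7)
  counts <- integer(5)
  for (i in 1:10000) {
    s <- sample_features(5, 2)
    counts[s] <- counts[s] + 1L
  }
  sigma <- sqrt(10000 * 0.4 * 0.6)
  expect_true(all(abs(counts - 4000) < 3 * sigma))

  # empirical selections match the expectation within 3 sigma
  set.seed(8)
  hits <- integer(50)
  for (i in 1:100) {
    s <- sample_features(50, 5)
    hits[s] <- hits[s] + 1L
  }
  expect_equal(mean(hits), expected_selections(100, 5, 50))
  sig <- sqrt(100 * 0.1 * 0.9)
  expect_true(all(abs(hits - 10) <= 3.5 * sig))
})

test_that("Newton logistic fit recovers closed forms and the GD oracle", {
  # all-zero features, constant fractional label: intercept = logit(c)
  X <- matrix(0, 5, 1, dimnames = list(NULL, "p1"))
  fit <- fit_logistic_newton(X, rep(0.3, 5), ridge = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$theta[[1]]), qlogis(0.3), tolerance = 1e-6)
  expect_equal(unname(fit$theta[[2]]), 0, tolerance = 1e-8)

  # a perfectly aligned feature lowers the loss below intercept-only
  X2 <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "p1"))
  y2 <- c(0, 0, 1, 1)
  fit2 <- fit_logistic_newton(X2, y2, ridge = 0.1)
  h0 <- mean(y2)
  loss0 <- -mean(y2 * log(h0) + (1 - y2) * log(1 - h0))
  expect_lt(fit2$final_loss, loss0)
  expect_gt(unname(fit2$theta[["p1"]]), 0)

  # small dense problem: match a long-run plain gradient descent on the
  # identical penalized objective
  set.seed(3)
  X3 <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y3 <- c(0.1, 0.9, 0.4, 0.6, 0.8)
  lam <- 0.5
  fit3 <- fit_logistic_newton(X3, y3, ridge = lam, tol = 1e-12)
  Xd <- cbind(1, X3)
  theta <- numeric(4)
  for (i in 1:200000) {
    h <- 1 / (1 + exp(-drop(Xd %*% theta)))
    g <- drop(crossprod(Xd, h - y3)) / 5 + (lam / 5) * c(0, theta[-1])
    theta <- theta - 0.5 * g
  }
  expect_equal(unname(fit3$theta), unname(theta), tolerance = 1e-4)

  expect_error(fit_logistic_newton(matrix(NA_real_, 2, 1), c(0, 1)),
               "non-finite")
  expect_error(fit_logistic_newton(matrix(0, 2, 1), c(0, 2)), "\\[0, 1\\]")
})

test_that("indicator refinement respects fixed points and stationarity", {
  mod <- structure(list(theta = c(`(intercept)` = 0, a = 1, b = 2, c = 0.5),
                        feature_ids = c("a", "b", "c"),
                        converged = TRUE, final_loss = 0, n_iter = 1),
                   class = "logistic_model")
  # all-positive weights, already at the constrained optimum
  out <- gd_refine_indicator(mod, c(1, 1, 1), tol = 1e-12)
  expect_equal(out$values, c(1, 1, 1))
  expect_identical(out$binarized, c(1L, 1L, 1L))

  # zero weights: gradient is zero, initialization is returned unchanged
  zero <- structure(list(theta = c(0, 0, 0, 0),
                         feature_ids = c("a", "b", "c"),
                         converged = TRUE, final_loss = 0, n_iter = 1),
                    class = "logistic_model")
  out0 <- gd_refine_indicator(zero, c(1, 0, 1))
  expect_equal(out0$values, c(1, 0, 1))

  expect_error(gd_refine_indicator(mod, c(1, 1, 1), step = -1), "step")
  expect_error(gd_refine_indicator(mod, c(1, 1)), "length")
})

test_that("as tolerance vanishes, calls converge to the weight signs", {
  # constrained optimum of the monotone sigmoid objective: each
  # coordinate at the bound matching its weight's sign
  set.seed(123)
  for (k in 1:200) {
    p <- sample(3:6, 1)
    w <- sample(c(-1, 1), p, replace = TRUE) * runif(p, 0.5, 1.5)
    # keep the attainable sigmoid away from full saturation so the
    # constrained optimum is reached within the iteration budget
    pos <- sum(pmax(w, 0))
    if (pos > 2.5) w <- w * 2.5 / pos
    b <- runif(1, -0.5, 0)
    mod <- structure(list(theta = c(b, w), feature_ids = paste0("f", 1:p),
                          converged = TRUE, final_loss = 0, n_iter = 1),
                     class = "logistic_model")
    x0 <- sample(0:1, p, replace = TRUE)
    out <- gd_refine_indicator(mod, x0, step = 0.2, tol = 1e-12,
                               max_iter = 100000)
    expect_identical(out$binarized, as.integer(w > 0))
  }
})

test_that("the GD objective is non-increasing along the iteration path", {
  set.seed(9)
  sig <- function(z) 1 / (1 + exp(-z))
  for (k in 1:20) {
    w <- rnorm(5); b <- rnorm(1)
    x <- sample(0:1, 5, replace = TRUE)
    f <- function(x) (sig(b + sum(w * x)) - 1)^2
    prev <- f(x)
    for (i in 1:500) {
      h <- sig(b + sum(w * x))
      x <- pmin(1, pmax(0, x - 0.1 * 2 * (h - 1) * h * (1 - h) * w))
      cur <- f(x)
      expect_lte(cur, prev + 1e-12)
      prev <- cur
    }
  }
})

test_that("the ensemble is deterministic, conservative and signal-seeking", {
  b <- default_bundle()
  tab <- load_associations(b$paths$associations)
  labs <- stats::setNames(
    pmin(1, 0.1 + 0.9 * b$ranking$closeness[match(tab$diseases,
                                                  b$ranking$disease_id)]),
    tab$diseases)
  fm <- build_feature_matrix(tab, labs)

  # one round with the full pool selects every protein exactly once
  t1 <- run_ensemble(fm, b$target_id, b$seed_proteins, n_rounds = 1,
                     bag_size = length(fm$protein_index), rng_seed = 5)
  expect_true(all(t1$times_selected == 1L))

  ta <- run_ensemble(fm, b$target_id, b$seed_proteins, n_rounds = 40,
                     rng_seed = 11)
  tb <- run_ensemble(fm, b$target_id, b$seed_proteins, n_rounds = 40,
                     rng_seed = 11)
  expect_identical(ta, tb)

  # vote conservation: selections sum to rounds x bag size
  expect_equal(sum(ta$times_selected), 40 * attr(ta, "bag_size"))
  expect_true(all(ta$times_called_related <= ta$times_selected))

  # planted proteins are called more often than the background median
  # (full 400-round run, shared with the acceptance suite)
  run <- default_pipeline_run()
  tal <- run$tally
  planted <- tal$protein_accession %in% b$planted
  frac <- ifelse(tal$times_selected > 0,
                 tal$times_called_related / tal$times_selected, 0)
  expect_gt(min(frac[planted]), stats::median(frac[!planted]))

  expect_warning(
    run_ensemble(fm, b$target_id, c(b$seed_proteins, "NOSUCH"),
                 n_rounds = 1, rng_seed = 1),
    "seed protein")
  expect_error(run_ensemble(fm, "missing-disease", character()),
               "target disease")
})

test_that("vote-threshold selection is ordered, inclusive and monotone", {
  tally <- structure(
    data.frame(protein_accession = c("p1", "p2", "p3", "p4"),
               times_selected = c(10L, 10L, 10L, 0L),
               times_called_related = c(10L, 7L, 6L, 0L)),
    class = c("vote_tally", "data.frame"))
  expect_identical(select_related(tally, 7), c("p1", "p2"))
  expect_identical(select_related(tally, 0), c("p1", "p2", "p3"))
  prev <- select_related(tally, 0)
  for (th in 1:12) {
    cur <- select_related(tally, th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("the known fraction reproduces the published split", {
  expect_equal(round(known_fraction(376, 308)), 18)
  expect_equal(known_fraction(10, 0), 100)
  expect_equal(known_fraction(10, 4), 60)
  expect_error(known_fraction(0, 0), "positive")
  expect_error(known_fraction(5, 6), "n_novel")
})
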