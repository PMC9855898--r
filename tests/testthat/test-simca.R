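# simulate new samples from a fitted class model: training-score spread on
# the inner components plus full-dimension residual noise at s0, mapped back
# to the raw variable space
simulate_from_model <- function(model, n, seed = 1) {
  set.seed(seed)
  T_ <- sapply(seq_len(model$A), function(a)
    rnorm(n, 0, sqrt(model$score_var[a])))
  if (model$A == 1) T_ <- matrix(T_, ncol = 1)
  E <- matrix(rnorm(n * model$p, 0, model$s0), n, model$p)
  Xs <- T_ %*% t(model$pca$loadings) + E
  sweep(sweep(Xs, 2, model$scale, "*"), 2, model$center, "+")
}

test_that("the acceptance limit reproduces tabulated F quantiles", {
  # alpha = 0.05, nu1 = 1, nu2 = 10: F table gives 4.9646
  # p = 2, A = 1 -> nu1 = 1; n = 12 -> nu2 = (12 - 1 - 1) * 1 = 10
  lat <- latent_matrix(12, 2, 1, noise_sd = 0.4, seed = 2)
  m <- fit_simca_class(lat, A = 1, alpha = 0.05)
  expect_equal(unname(m$df["nu1"]), 1)
  expect_equal(unname(m$df["nu2"]), 10)
  expect_equal(m$crit_distance, sqrt(4.9646), tolerance = 1e-4)
})

test_that("s0 recovers the generating noise scale", {
  X <- latent_matrix(200, 12, 3, noise_sd = 0, seed = 3)
  X <- scale(X)                    # unit total variance per column
  noise <- 0.25
  Xn <- X + matrix(rnorm(200 * 12, 0, noise), 200, 12)
  m <- fit_simca_class(Xn, A = 3)
  # residual sd in the autoscaled metric, compared to the injected noise
  # rescaled by the per-column autoscaling factors
  expected <- noise * sqrt(mean(1 / m$scale^2))
  expect_equal(m$s0, expected, tolerance = 0.2)
})

test_that("distances behave at the centroid and far off-subspace", {
  X <- latent_matrix(60, 8, 2, noise_sd = 0.2, seed = 5)
  m <- fit_simca_class(X, A = 2)
  d0 <- distance_to_model(m, m$center)
  expect_equal(d0$distance, 0, tolerance = 1e-9)
  expect_true(d0$accepted)
  # a sample displaced 10 s0 along every residual direction
  far <- m$center + 10 * m$s0 * m$scale
  dfar <- distance_to_model(m, far)
  expect_false(dfar$accepted)
})

test_that("acceptance coverage converges to the confidence level", {
  X <- latent_matrix(120, 10, 3, noise_sd = 0.3, seed = 7)
  m05 <- fit_simca_class(X, A = 3, alpha = 0.05)
  new <- simulate_from_model(m05, 1000, seed = 8)
  frac <- mean(distance_to_model(m05, new)$accepted)
  ci <- 2.58 * sqrt(0.05 * 0.95 / 1000)
  expect_equal(frac, 0.95, tolerance = (ci + 0.015) / 0.95)
  m01 <- fit_simca_class(X, A = 3, alpha = 0.01)
  frac01 <- mean(distance_to_model(m01, new)$accepted)
  expect_equal(frac01, 0.99, tolerance = (2.58 * sqrt(0.01 * 0.99 / 1000) + 0.008) / 0.99)
})

test_that("four-way assignment covers own/both/none and forced classes", {
  set.seed(11)
  X1 <- matrix(rnorm(40 * 5), 40, 5)
  X2 <- matrix(rnorm(40 * 5), 40, 5) + 12     # far-separated
  m1 <- fit_simca_class(X1, A = 2, class_label = "C1")
  m2 <- fit_simca_class(X2, A = 2, class_label = "C2")
  a <- simca_assign(list(m1, m2), rbind(colMeans(X1), colMeans(X2)))
  expect_equal(a$membership, c("C1", "C2"))
  expect_equal(a$forced_class, c("C1", "C2"))
  # overlapping classes: the shared centroid is accepted by both
  X3 <- matrix(rnorm(40 * 5), 40, 5) + 0.1
  m3 <- fit_simca_class(X3, A = 2, class_label = "C3")
  amid <- simca_assign(list(m1, m3), matrix(colMeans(rbind(X1, X3)), 1))
  expect_equal(amid$membership, "both")
  # a point far from everything belongs to none
  anone <- simca_assign(list(m1, m3), matrix(50, 1, 5))
  expect_equal(anone$membership, "none")
})

test_that("forced SIMCA assignment concords with LDA on separated classes", {
  mk <- two_class_matrix(60, 60, 6, p_info = 6, effect = 4, seed = 13)
  m1 <- fit_simca_class(mk$X[mk$labels == "A", ], A = 2, class_label = "A")
  m2 <- fit_simca_class(mk$X[mk$labels == "B", ], A = 2, class_label = "B")
  forced <- simca_assign(list(m1, m2), mk$X)$forced_class
  lda_pred <- predict(fit_lda(mk$X, mk$labels), mk$X)
  expect_gte(mean(forced == lda_pred), 0.95)
})

test_that("modelling power separates structure from noise", {
  # variables fully reconstructed by the inner components reach MP = 1
  lat <- latent_matrix(30, 6, 2, noise_sd = 0, seed = 17)
  m <- fit_simca_class(lat, A = 2)
  expect_equal(modelling_power(m), rep(1, 6), tolerance = 1e-6)
  # a pure-noise variable orthogonal to the structure stays low
  set.seed(18)
  lat2 <- latent_matrix(500, 5, 2, noise_sd = 0.05, seed = 18)
  X <- cbind(lat2, rnorm(500))
  m2 <- fit_simca_class(X, A = 2)
  mp <- modelling_power(m2)
  expect_lt(mp[6], 0.15)
  expect_true(all(mp >= 0 & mp <= 1))
})

test_that("strongly modelled variables reach MP >= 0.99 in both classes", {
  # within-class variation dominated by one latent factor: every variable is
  # almost fully reconstructed by the single inner component
  set.seed(20)
  make_block <- function(n, shift) {
    f <- rnorm(n)
    outer(f, rep(20, 6)) + matrix(rnorm(n * 6, 0, 0.2), n, 6) + shift
  }
  m1 <- fit_simca_class(make_block(100, 0), A = 1, class_label = "A")
  m2 <- fit_simca_class(make_block(100, 6), A = 1, class_label = "B")
  expect_true(all(modelling_power(m1) >= 0.99))
  expect_true(all(modelling_power(m2) >= 0.99))
})

test_that("discriminant power is ~1 under the null and large for shifts", {
  set.seed(23)
  n <- 500
  shared <- function() {
    f <- rnorm(n)
    outer(f, rep(1, 4)) * 0.8 + matrix(rnorm(n * 4, 0, 0.5), n, 4)
  }
  # fully null: identically distributed classes -> every DP near 1
  m1n <- fit_simca_class(shared(), A = 1, class_label = "C1")
  m2n <- fit_simca_class(shared(), A = 1, class_label = "C2")
  dp_null <- discriminant_power(m1n, m2n)
  expect_true(all(dp_null > 0.8 & dp_null < 1.25))
  # one variable shifted by 5 within-class sd dominates the DP ranking
  X1 <- shared(); X2 <- shared()
  X2[, 4] <- X2[, 4] + 5 * 0.5             # 5 sd of the noise part
  m1 <- fit_simca_class(X1, A = 1, class_label = "C1")
  m2 <- fit_simca_class(X2, A = 1, class_label = "C2")
  dp <- discriminant_power(m1, m2)
  expect_gt(dp[4], max(dp[1:3]))
  expect_gt(dp[4], 2)
  # symmetric under class swap
  expect_equal(discriminant_power(m2, m1), dp, tolerance = 1e-10)
})

test_that("interclass distance is 1 against itself and grows with shift", {
  X <- latent_matrix(50, 6, 2, noise_sd = 0.3, seed = 29)
  m <- fit_simca_class(X, A = 2)
  expect_equal(class_distance(m, m, X, X), 1, tolerance = 1e-12)
  dist_at <- function(shift) {
    set.seed(31)
    X1 <- matrix(rnorm(60 * 5), 60, 5)
    X2 <- matrix(rnorm(60 * 5), 60, 5) + shift
    class_distance(fit_simca_class(X1, A = 2, class_label = "a"),
                   fit_simca_class(X2, A = 2, class_label = "b"))
  }
  d <- vapply(c(0, 1, 2, 4), dist_at, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_gt(dist_at(8), 3)
})

test_that("Cooman coordinates are consistent with the assignments", {
  mk <- two_class_matrix(40, 50, 5, p_info = 5, effect = 5, seed = 37)
  m1 <- suppressWarnings(          # near-tied noise eigenvalues stall NIPALS
    fit_simca_class(mk$X[mk$labels == "A", ], A = 2, class_label = "A"))
  m2 <- fit_simca_class(mk$X[mk$labels == "B", ], A = 2, class_label = "B")
  cc <- coomans_coordinates(list(m1, m2), mk$X, mk$labels)
  expect_equal(attr(cc, "crit1"), m1$crit_distance)
  # class-A centroid: (0, large)
  c0 <- coomans_coordinates(list(m1, m2), matrix(m1$center, 1))
  expect_equal(c0$d1, 0, tolerance = 1e-9)
  expect_gt(c0$d2, m2$crit_distance)
  # quadrant membership from the coordinates reproduces simca_assign
  a <- simca_assign(list(m1, m2), mk$X)
  mem <- ifelse(cc$d1 <= attr(cc, "crit1") & cc$d2 <= attr(cc, "crit2"), "both",
         ifelse(cc$d1 <= attr(cc, "crit1"), "A",
         ifelse(cc$d2 <= attr(cc, "crit2"), "B", "none")))
  expect_equal(mem, a$membership)
  expect_error(coomans_coordinates(list(m1), mk$X), "exactly two")
})

test_that("augmented distances fold in score-space leverage", {
  X <- latent_matrix(80, 8, 2, noise_sd = 0.3, seed = 41)
  m <- fit_simca_class(X, A = 2)
  plain <- distance_to_model(m, X)$distance
  aug <- distance_to_model(m, X, augmented = TRUE)$distance
  expect_true(all(aug >= plain - 1e-12))
  # a sample far out in score space but on the subspace: caught only by
  # the augmented rule
  far_score <- m$center + 20 * (m$pca$loadings[, 1] * m$scale)
  expect_true(distance_to_model(m, far_score)$accepted)
  expect_false(distance_to_model(m, far_score, augmented = TRUE)$accepted)
})

test_that("serialized models reproduce every statistic after reload", {
  mk <- two_class_matrix(30, 35, 6, p_info = 3, effect = 3, seed = 43)
  m1 <- fit_simca_class(mk$X[mk$labels == "A", ], A = 2, class_label = "A")
  f <- withr::local_tempfile(fileext = ".json")
  write_simca_model(m1, f)
  back <- read_simca_model(f)
  expect_equal(back$s0, m1$s0, tolerance = 1e-12)
  expect_equal(back$crit_distance, m1$crit_distance, tolerance = 1e-12)
  d_orig <- distance_to_model(m1, mk$X)
  d_back <- distance_to_model(back, mk$X)
  expect_equal(d_back$distance, d_orig$distance, tolerance = 1e-10)
  expect_identical(d_back$accepted, d_orig$accepted)
  expect_equal(modelling_power(back), modelling_power(m1), tolerance = 1e-10)
})

test_that("the SIMCA report summarises a strong-signal problem at 100%", {
  mk <- two_class_matrix(19, 76, 10, p_info = 10, effect = 6, seed = 47)
  te <- two_class_matrix(2, 8, 10, p_info = 10, effect = 6, seed = 48)
  rep <- simca_report(mk$X, mk$labels, te$X, te$labels, A = 2)
  tot <- rep$summary[rep$summary$class == "Total", ]
  expect_equal(tot$efficiency_forced, 100)
  expect_equal(tot$total_rate, 100)
  expect_gt(rep$class_distance, 3)
  # percentages recompute from the stored LOO table exactly
  expect_equal(tot$loo, 100 * mean(rep$loo$own_accepted))
  a_row <- rep$summary[rep$summary$class == "A", ]
  own <- mk$labels == "A"
  expect_equal(a_row$cv_efficiency,
               100 * sqrt(mean(rep$loo$own_accepted[own]) *
                            mean(!rep$loo$other_accepted[!own])))
})

test_that("null-signal SIMCA efficiency falls to chance", {
  mk <- two_class_matrix(25, 25, 6, p_info = 0, seed = 53)
  rep <- simca_report(mk$X, mk$labels, A = 2)
  tot <- rep$summary[rep$summary$class == "Total", ]
  # forced assignment on indistinguishable classes: near the 50% floor
  expect_lt(tot$efficiency_forced, 70)
  expect_lt(rep$class_distance, 1.5)
})

test_that("recognition-guided truncation returns the requested size", {
  mk <- two_class_matrix(40, 50, 14, p_info = 6, effect = 4, seed = 59)
  sel <- run_select(mk$X, mk$labels, k_max = 14, min_ratio = 3)
  tr <- truncate_for_simca(mk$X, mk$labels, sel$selected, sel$weights,
                           k_target = 6, A = 2)
  expect_length(tr$selected, 6)
  expect_true(all(tr$selected %in% sel$selected))
  expect_gte(tr$recognition, 0.8)
  # the informative columns survive the truncation
  expect_gte(sum(tr$selected %in% 1:6), 4)
})
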