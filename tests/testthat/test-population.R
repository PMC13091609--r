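# Feature matrices, GMM clustering, KS tests, JS divergence

test_that("feature matrices are (statistic x offset) rectangular and labeled", {
  exs <- std_extractions()
  f <- build_features(exs, stats = c("median", "std"), offsets = -1:1)
  expect_identical(ncol(f$x), 6L)
  expect_identical(colnames(f$x),
                   c("median@-1", "median@0", "median@1",
                     "std@-1", "std@0", "std@1"))
  expect_identical(nrow(f$x),
                   sum(vapply(exs, function(e) length(e$reads), integer(1))))
  expect_true(all(is.finite(f$x)))
  # condition rows differ at the shifted position
  m_ctrl <- mean(f$x[f$condition == "control", "median@0"])
  m_mod <- mean(f$x[f$condition == "modified", "median@0"])
  expect_gt(m_mod - m_ctrl, 5)
  expect_lt(abs(mean(f$x[f$condition == "modified", "median@-1"]) -
                mean(f$x[f$condition == "control", "median@-1"])), 2)
  expect_error(build_features(exs, offsets = -8:0), "outside the K=13 window")

  # single read, single stat, single offset equals the raw statistic
  ex1 <- exs$control
  ex1$reads <- ex1$reads[1]
  f1 <- build_features(ex1, stats = "mean", offsets = 0L)
  expect_identical(dim(f1$x), c(1L, 1L))
  expect_equal(unname(f1$x[1, 1]), mean(ex1$reads[[1]]$samples[[7]]))
})

test_that("GMM recovers a well-separated synthetic mixture", {
  set.seed(501)
  n <- 1000L
  x <- rbind(cbind(rnorm(n / 2, 80), rnorm(n / 2, 2)),
             cbind(rnorm(n / 2, 95), rnorm(n / 2, 4)))
  g <- fit_gmm(x, n_components = 2L, seed = 3L)
  truth <- rbind(c(80, 2), c(95, 4))
  # order-free matching of components to truth
  ord <- order(g$means[, 1])
  expect_lt(max(abs(g$means[ord, ] - truth)), 0.5)
  expect_lt(max(abs(sort(g$weights) - 0.5)), 0.05)
  expect_equal(sum(g$weights), 1, tolerance = 1e-8)
  for (k in 1:2) {
    S <- g$covariances[, , k]
    expect_equal(S, t(S))
    expect_true(all(eigen(S, only.values = TRUE)$values > 0))
  }
  expect_true(all(g$assignments %in% 1:2))
})

test_that("single-component fits collapse to sample moments", {
  set.seed(502)
  x <- cbind(rnorm(100, 10, 2), rnorm(100, -3, 0.5))
  g <- fit_gmm(x, n_components = 1L, seed = 1L)
  expect_equal(g$weights, 1)
  expect_equal(as.numeric(g$means), colMeans(x), tolerance = 1e-6)
})

test_that("degenerate inputs produce the singularity error", {
  x <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2,
                1, 2, 1, 2, 1, 2, 1, 2, 1, 2), ncol = 2, byrow = TRUE)
  expect_error(fit_gmm(x, n_components = 2L), "singular|jitter")
  expect_error(fit_gmm(cbind(1:20, 1:20, 1:20), 2L), "exactly 2 feature")
  expect_error(fit_gmm(cbind(1:5, 1:5), 2L), "at least 5 reads per component")
})

test_that("log-likelihood is invariant under component relabeling", {
  set.seed(503)
  x <- rbind(cbind(rnorm(100, 0), rnorm(100, 0)),
             cbind(rnorm(100, 6), rnorm(100, 6)))
  g <- fit_gmm(x, 2L, seed = 1L)
  swapped <- g
  swapped$weights <- rev(g$weights)
  swapped$means <- g$means[2:1, ]
  swapped$covariances <- g$covariances[, , 2:1]
  ll <- function(m) sum(nanotrace:::gmm_log_density(m, x))
  expect_equal(ll(g), ll(swapped))
})

test_that("KS tests compare per-feature condition distributions", {
  exs <- std_extractions()
  f <- build_features(exs, stats = "median", offsets = -2:2)
  ks <- ks_pairwise(f)
  expect_named(ks, c("feature", "n_a", "n_b", "D", "p"))
  expect_true(all(ks$D >= 0 & ks$D <= 1))
  expect_true(all(ks$p >= 0 & ks$p <= 1))
  # the shifted center position separates maximally; flanks do not
  expect_gt(ks$D[ks$feature == "median@0"], 0.9)
  expect_lt(ks$D[ks$feature == "median@-2"], 0.5)

  # identical and disjoint samples give the trivial extremes
  tab <- data.frame(condition = rep(c("a", "b"), each = 50),
                    ref_pos = 0L, offset = 0L, statistic = "mean",
                    read_id = "r", value = c(1:50, 1:50) / 10)
  class(tab) <- c("position_stat_table", "data.frame")
  k0 <- ks_pairwise(tab)
  expect_equal(k0$D, 0)
  expect_equal(k0$p, 1)
  tab$value <- c(1:50, 101:150) / 10
  expect_equal(ks_pairwise(tab)$D, 1)
  tab2 <- tab[c(1:3, 51:53), ]
  expect_error(ks_pairwise(tab2), "at least 5 values")
})

test_that("JS estimator is calibrated against oracles and bounded", {
  a <- manual_gmm(c(0, 0))
  # identical models: divergence ~ 0
  expect_lt(js_divergence_gmm(a, manual_gmm(c(0, 0)), 10000L,
                              seed = 404L)$divergence, 0.01)
  # far-separated models saturate at 1 (base 2)
  far <- js_divergence_gmm(a, manual_gmm(c(100, 0)), 10000L, seed = 404L)
  expect_equal(far$divergence, 1, tolerance = 0.02)
  expect_equal(far$distance, sqrt(far$divergence))
  # N((0,0),I) vs N((3,0),I) against dense-grid quadrature
  mc <- js_divergence_gmm(a, manual_gmm(c(3, 0)), 10000L, seed = 404L)
  expect_equal(mc$divergence, js_quadrature(c(0, 0), c(3, 0)),
               tolerance = 0.02)
  expect_error(js_divergence_gmm(a, a, 50L), "mc_samples")
})

test_that("JS is symmetric and in [0, 1] across random model pairs", {
  set.seed(505)
  for (i in 1:10) {
    a <- manual_gmm(runif(2, -3, 3), sd = runif(2, 0.5, 2))
    b <- manual_gmm(runif(2, -3, 3), sd = runif(2, 0.5, 2))
    # swapped-seed averaging: each direction averaged over both seeds
    ab <- mean(c(js_divergence_gmm(a, b, 20000L, seed = i)$divergence,
                 js_divergence_gmm(a, b, 20000L, seed = i + 100L)$divergence))
    ba <- mean(c(js_divergence_gmm(b, a, 20000L, seed = i)$divergence,
                 js_divergence_gmm(b, a, 20000L, seed = i + 100L)$divergence))
    expect_gte(ab, 0); expect_lte(ab, 1 + 1e-9)
    expect_lt(abs(ab - ba), 0.01)
  }
})

test_that("population results export to JSON with reproducibility metadata", {
  set.seed(506)
  x <- rbind(cbind(rnorm(50, 0), rnorm(50, 0)),
             cbind(rnorm(50, 8), rnorm(50, 8)))
  g <- fit_gmm(x, 2L, seed = 9L)
  js <- js_divergence_gmm(manual_gmm(c(0, 0)), manual_gmm(c(1, 0)),
                          1000L, seed = 2L)
  path <- tempfile(fileext = ".json")
  export_population_json(path, gmm = g, js = js)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$gmm$n_components, 2L)
  expect_equal(back$js$seed, 2L)
  expect_equal(back$js$mc_samples, 1000L)
})
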