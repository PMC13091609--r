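# Summary statistics, KDE and histogram conventions

test_that("builtin statistics use the stated closed forms", {
  v <- c(1, 2, 3)
  fns <- nanotrace:::resolve_stats(c("mean", "median", "std", "duration",
                                     "min", "max", "skewness", "kurtosis"))
  expect_equal(fns$mean(v), 2)
  expect_equal(fns$median(v), 2)
  expect_equal(fns$std(v), sqrt(2 / 3))      # population sd
  expect_equal(fns$duration(v), 3)
  expect_equal(fns$min(v), 1)
  expect_equal(fns$max(v), 3)
  expect_equal(fns$skewness(v), 0)
  # excess kurtosis of a symmetric 3-point set: m4/m2^2 - 3 = 1.5 - 3
  expect_equal(fns$kurtosis(v), -1.5)
  # zero-variance convention
  k <- c(5, 5, 5, 5)
  expect_equal(fns$std(k), 0)
  expect_equal(fns$skewness(k), 0)
  expect_equal(fns$kurtosis(k), 0)
  expect_equal(fns$std(7), 0)                # single sample
  expect_error(nanotrace:::resolve_stats("variance"), "unknown statistic")
})

test_that("statistics are location-equivariant or invariant as appropriate", {
  set.seed(11)
  v <- rnorm(40, 90, 3)
  c0 <- 12.5
  fns <- nanotrace:::resolve_stats(c("mean", "median", "min", "max", "std",
                                     "skewness", "kurtosis", "duration"))
  for (s in c("mean", "median", "min", "max"))
    expect_equal(fns[[s]](v + c0), fns[[s]](v) + c0)
  for (s in c("std", "skewness", "kurtosis", "duration"))
    expect_equal(fns[[s]](v + c0), fns[[s]](v))
})

test_that("stat tables are per read, per position, per statistic", {
  exs <- std_extractions()
  tab <- compute_stats(exs, stats = c("mean", "std", "duration"))
  expect_s3_class(tab, "position_stat_table")
  n_reads <- sum(vapply(exs, function(e) length(e$reads), integer(1)))
  expect_identical(nrow(tab), n_reads * 13L * 3L)
  # vector length per (condition, position, statistic) == surviving reads
  sub <- tab[tab$condition == "modified" & tab$offset == 0L &
             tab$statistic == "mean", ]
  expect_identical(nrow(sub), length(exs$modified$reads))
  expect_false(anyNA(tab$value))
  # per-position mean-of-means tracks the generator's level table
  man <- std_fixture()
  truth <- fixture_true_levels(man, "modified", exs$modified$window$positions)
  mom <- vapply(seq_along(truth), function(i)
    mean(tab$value[tab$condition == "modified" & tab$statistic == "mean" &
                   tab$ref_pos == exs$modified$window$positions[[i]]]),
    numeric(1))
  expect_lt(max(abs(mom - truth)), 1.5)
  # duration in ms converts via the sample rate
  ms <- compute_stats(exs$modified, stats = "duration", duration_unit = "ms")
  smp <- compute_stats(exs$modified, stats = "duration")
  expect_equal(ms$value, smp$value / man$model$sample_rate * 1000)
})

test_that("custom statistic functions get builtin parity", {
  ex <- std_extractions()$control
  tab <- compute_stats(ex, stats = list("mean", my_mean = function(x) mean(x)))
  a <- tab$value[tab$statistic == "mean"]
  b <- tab$value[tab$statistic == "my_mean"]
  expect_identical(a, b)
})

test_that("KDE follows the Scott-bandwidth Gaussian-kernel contract", {
  set.seed(21)
  v <- rnorm(1000)
  k <- signal_kde(v)
  expect_equal(k$bandwidth, sd(v) * 1000^(-1 / 5))
  expect_equal(min(k$grid), min(v) - 3 * k$bandwidth)
  expect_equal(max(k$grid), max(v) + 3 * k$bandwidth)
  at0 <- k$density[[which.min(abs(k$grid))]]
  expect_gt(at0, 0.33); expect_lt(at0, 0.47)   # true N(0,1) density ~0.399
  expect_error(signal_kde(rep(3, 10)), "degenerate")

  # symmetry about 0 for a symmetric sample
  ks <- signal_kde(rep(c(-1, 1), 50), grid_size = 201L)
  expect_lt(max(abs(ks$density - rev(ks$density))), 1e-6)

  # mass conservation and non-negativity across random inputs
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(10:200, 1), sample(-5:5, 1), runif(1, 0.5, 4))
    kk <- signal_kde(x, grid_size = 256L)
    expect_true(all(kk$density >= 0))
    integral <- sum(diff(kk$grid) *
                    (kk$density[-1] + kk$density[-length(kk$density)]) / 2)
    expect_gt(integral, 0.98); expect_lt(integral, 1.02)
  }
})

test_that("histograms conserve counts with right-closed bins", {
  h <- signal_histogram(c(0, 0.5, 1), bins = 2L)
  expect_equal(h$counts, c(2L, 1L))
  expect_equal(h$edges, c(0, 0.5, 1))
  h1 <- signal_histogram(7, bins = 3L)
  expect_identical(sum(h1$counts), 1L)
  expect_identical(sum(h1$counts > 0), 1L)
  set.seed(41)
  v <- runif(10000)
  h2 <- signal_histogram(v, bins = 10L)
  expect_identical(sum(h2$counts), 10000L)
  expect_true(all(abs(h2$counts - 1000) < 4 * sqrt(10000 * 0.1 * 0.9)))
})
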