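# Shared synthetic fixtures, built once per test run and cached.
# The standard fixture: two conditions over one 300 bp reference, +8 pA
# level shift at reference position 150 (0-based) in "modified"; "control"
# additionally carries designated special reads (insertion / mismatch /
# deletion at the center, one secondary alignment, one split read).

fixture_cache <- new.env(parent = emptyenv())

std_fixture <- function() {
  if (is.null(fixture_cache$std)) {
    specials <- data.frame(
      condition = "control",
      kind = c("insertion", "mismatch", "deletion", "secondary", "split"),
      at = c(150L, 150L, 150L, NA, NA))
    fixture_cache$std <- write_fixture_pair(
      conditions = list(
        list(label = "control", n_reads = 20L),
        list(label = "modified", n_reads = 20L,
             mod_positions = 150L, mod_delta = 8)),
      out_dir = file.path(tempdir(), "nanotrace-std-fixture"),
      seed = 101L, special_reads = specials)
  }
  fixture_cache$std
}

std_window <- function(K = 13L, molecule = "DNA") {
  window_spec("synthref", 150L, K = K, molecule = molecule)
}

std_extractions <- function() {
  if (is.null(fixture_cache$ex)) {
    man <- std_fixture()
    fixture_cache$ex <- lapply(man$condition_objects, extract_window,
                               window = std_window())
  }
  fixture_cache$ex
}

# mixed-strand fixture (one condition, half the reads reverse) for
# orientation round-trip checks
strand_fixture <- function(molecule = "DNA") {
  key <- paste0("strand_", molecule)
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- write_fixture_pair(
      conditions = list(list(label = "mix", n_reads = 24L)),
      out_dir = file.path(tempdir(), paste0("nanotrace-strand-", molecule)),
      seed = 77L, reverse_fraction = 0.5, molecule = molecule)
  }
  fixture_cache[[key]]
}

# independent brute-force oracle for move-table segmentation: walk signal
# blocks in order, opening a new base at every 1
oracle_segments <- function(stride, moves, ts, ns) {
  starts <- integer(0); ends <- integer(0)
  for (i in seq_along(moves)) {
    b0 <- ts + (i - 1L) * stride
    if (b0 >= ns) break
    b1 <- min(b0 + stride, ns)
    if (moves[[i]] == 1L) { starts <- c(starts, b0); ends <- c(ends, b1) }
    else ends[[length(ends)]] <- b1
  }
  cbind(start = starts, end = ends)
}

# random valid move table under the given constraints
random_move_table <- function(strides = c(3L, 5L, 6L), max_T = 50L) {
  stride <- sample(strides, 1L)
  T <- sample(2:max_T, 1L)
  moves <- c(1L, sample(0:1, T - 1L, replace = TRUE))
  ts <- sample(0:10, 1L)
  trunc <- sample(0:(stride - 1L), 1L)
  ns <- ts + stride * T - trunc
  list(stride = stride, moves = moves, ts = ts, ns = ns)
}

# manual single-component bivariate gmm_fit (for JS calibration tests)
manual_gmm <- function(mean, sd = c(1, 1)) {
  structure(list(n_components = 1L, weights = 1,
                 means = matrix(mean, 1L, 2L),
                 covariances = array(diag(sd^2), c(2L, 2L, 1L)),
                 assignments = 1L, condition = "manual",
                 data = matrix(mean, 1L, 2L),
                 feature_names = c("f1", "f2"), seed = 0L),
            class = "gmm_fit")
}

# dense-grid quadrature oracle for the JS divergence (base 2) between two
# isotropic bivariate normals
js_quadrature <- function(mu_a, mu_b, lim = 7, step = 0.05) {
  xs <- seq(min(mu_a[1], mu_b[1]) - lim, max(mu_a[1], mu_b[1]) + lim, by = step)
  ys <- seq(min(mu_a[2], mu_b[2]) - lim, max(mu_a[2], mu_b[2]) + lim, by = step)
  pa <- outer(xs, ys, function(x, y) dnorm(x, mu_a[1]) * dnorm(y, mu_a[2]))
  pb <- outer(xs, ys, function(x, y) dnorm(x, mu_b[1]) * dnorm(y, mu_b[2]))
  m <- (pa + pb) / 2
  kl <- function(p) {
    t <- p * log2(p / m)
    t[p == 0] <- 0
    sum(t) * step^2
  }
  0.5 * kl(pa) + 0.5 * kl(pb)
}
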