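## Read-level population analyses: multi-position feature matrices, Gaussian
## mixture clustering (EM via mclust, full covariance), two-sample KS tests
## and Monte-Carlo Jensen-Shannon divergence between fitted mixtures.

#' Build per-read multi-position feature vectors
#'
#' For each surviving read of each extraction, the selected statistics are
#' computed at each offset (relative to the window center) and concatenated
#' in declared order (statistics outer, offsets inner) into one feature
#' vector per read.
#'
#' @param extractions one or more [extract_window()] results.
#' @param stats statistic names / named functions as in [compute_stats()].
#' @param offsets integer offsets relative to the window center; each must
#'   fall inside every extraction's window.
#' @return object of class \code{read_features}: list with \code{x}
#'   (reads x features numeric matrix, columns named \code{stat@offset}),
#'   \code{condition}, \code{read_id}, \code{stats}, \code{offsets}.
#' @export
build_features <- function(extractions, stats = c("median", "std"),
                           offsets = -2:2) {
  if (inherits(extractions, "window_extraction"))
    extractions <- list(extractions)
  stopifnot(all(vapply(extractions, inherits, logical(1), "window_extraction")))
  fns <- resolve_stats(stats)
  offsets <- as.integer(offsets)
  for (ex in extractions) {
    half <- (ex$window$K - 1L) %/% 2L
    bad <- offsets[abs(offsets) > half]
    if (length(bad))
      stop2("offset ", bad[[1]], " lies outside the K=", ex$window$K,
            " window of condition '", ex$condition_label, "'")
    if (!length(ex$reads))
      stop2("condition '", ex$condition_label, "' has no surviving reads")
  }
  rows <- list(); cond <- character(0); ids <- character(0)
  for (ex in extractions) {
    half <- (ex$window$K - 1L) %/% 2L
    idx <- offsets + half + 1L                 # window position index
    for (r in ex$reads) {
      vals <- unlist(lapply(names(fns), function(s)
        vapply(idx, function(i) as.numeric(fns[[s]](r$samples[[i]])),
               numeric(1))))
      rows[[length(rows) + 1L]] <- vals
      cond <- c(cond, ex$condition_label)
      ids <- c(ids, r$read_id)
    }
  }
  x <- do.call(rbind, rows)
  colnames(x) <- as.vector(vapply(names(fns), function(s)
    paste0(s, "@", offsets), character(length(offsets))))
  rownames(x) <- NULL
  structure(list(x = x, condition = cond, read_id = ids,
                 stats = names(fns), offsets = offsets),
            class = "read_features")
}

#' @export
print.read_features <- function(x, ...) {
  cat(sprintf("<read_features: %d reads x %d features (%s x offsets %s); conditions: %s>\n",
              nrow(x$x), ncol(x$x), paste(x$stats, collapse = ","),
              paste(range(x$offsets), collapse = ".."),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Aggregate a feature matrix to one column per statistic
#'
#' Averages each statistic across its offsets, producing the low-dimensional
#' (typically 2-D) per-read feature space used for mixture clustering.
#'
#' @param features a [build_features()] result.
#' @param fn aggregation function (default mean).
#' @return a \code{read_features} with one column per statistic.
#' @export
aggregate_features <- function(features, fn = mean) {
  stopifnot(inherits(features, "read_features"))
  x <- vapply(features$stats, function(s) {
    cols <- paste0(s, "@", features$offsets)
    apply(features$x[, cols, drop = FALSE], 1L, fn)
  }, numeric(nrow(features$x)))
  x <- matrix(x, nrow = nrow(features$x),
              dimnames = list(NULL, features$stats))
  structure(list(x = x, condition = features$condition,
                 read_id = features$read_id, stats = features$stats,
                 offsets = features$offsets),
            class = "read_features")
}

#' Fit a full-covariance Gaussian mixture to a bivariate feature space
#'
#' EM fit (via \pkg{mclust}, model "VVV") on the pooled reads of all
#' conditions; each read is then assigned to its maximum-responsibility
#' component, and the per-condition assignment distribution is tabulated.
#'
#' @param features a [build_features()]/[aggregate_features()] result with
#'   exactly 2 columns, or a plain 2-column numeric matrix.
#' @param n_components number of mixture components.
#' @param seed integer seed recorded with the fit (the EM initialization via
#'   model-based hierarchical clustering is itself deterministic).
#' @return object of class \code{gmm_fit}: n_components, weights, means
#'   (components x 2), covariances (2 x 2 x components), assignments,
#'   condition, assignment_table, loglik, data, feature_names, seed.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_gmm <- function(features, n_components = 2L, seed = 1L) {
  if (inherits(features, "read_features")) {
    x <- features$x; cond <- features$condition
  } else {
    x <- as.matrix(features)
    cond <- rep("all", nrow(x))
  }
  if (ncol(x) != 2L)
    stop2("fit_gmm needs exactly 2 feature columns (got ", ncol(x),
          "); aggregate_features() reduces a wider matrix")
  if (nrow(x) < 5L * n_components)
    stop2("need at least 5 reads per component (", 5L * n_components,
          " total; got ", nrow(x), ")")
  set.seed(stage_seed(seed, "gmm"))
  fit <- tryCatch(
    Mclust(x, G = n_components, modelNames = "VVV", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters))
    stop2("GMM fit failed (singular covariance, e.g. duplicated points); ",
          "jitter the features or reduce n_components")
  means <- t(fit$parameters$mean)
  covs <- fit$parameters$variance$sigma
  if (is.null(covs)) {  # G = 1 degenerate layout
    covs <- array(fit$parameters$variance$Sigma, dim = c(2, 2, 1))
  }
  structure(list(n_components = as.integer(n_components),
                 weights = as.numeric(fit$parameters$pro),
                 means = means, covariances = covs,
                 assignments = as.integer(fit$classification),
                 condition = cond,
                 assignment_table = table(condition = cond,
                                          component = factor(
                                            fit$classification,
                                            levels = seq_len(n_components))),
                 loglik = fit$loglik, data = x,
                 feature_names = colnames(x), seed = as.integer(seed)),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit: %d component(s) on %d reads over (%s)>\n",
              x$n_components, nrow(x$data),
              paste(x$feature_names, collapse = ", ")))
  for (k in seq_len(x$n_components))
    cat(sprintf("  comp %d: weight %.3f, mean (%.3f, %.3f)\n", k,
                x$weights[[k]], x$means[k, 1], x$means[k, 2]))
  print(x$assignment_table)
  invisible(x)
}

## log-density of a 2-D Gaussian mixture at rows of x
gmm_log_density <- function(gmm, x) {
  n <- nrow(x)
  lk <- matrix(NA_real_, n, gmm$n_components)
  for (k in seq_len(gmm$n_components)) {
    mu <- gmm$means[k, ]
    S <- gmm$covariances[, , k]
    ch <- chol(S)
    z <- forwardsolve(t(ch), t(x) - mu)
    lk[, k] <- log(gmm$weights[[k]]) - log(2 * pi) - sum(log(diag(ch))) -
      0.5 * colSums(z^2)
  }
  m <- apply(lk, 1L, max)
  m + log(rowSums(exp(lk - m)))
}

## draw n points from a fitted 2-D mixture
gmm_sample <- function(gmm, n) {
  comp <- sample.int(gmm$n_components, n, replace = TRUE, prob = gmm$weights)
  out <- matrix(NA_real_, n, 2L)
  for (k in seq_len(gmm$n_components)) {
    idx <- which(comp == k)
    if (length(idx))
      out[idx, ] <- MASS::mvrnorm(length(idx), gmm$means[k, ],
                                  gmm$covariances[, , k])
  }
  out
}

#' Pairwise two-sample Kolmogorov-Smirnov tests between conditions
#'
#' For each feature (a statistic/position combination of a
#' \code{position_stat_table}, or a column of a \code{read_features} matrix)
#' the per-read values of the two conditions are compared with the standard
#' two-sample KS test.
#'
#' @param x a [compute_stats()] table or a [build_features()] result.
#' @param conditions character vector of exactly 2 condition labels (default:
#'   the first two present).
#' @return data.frame with columns feature, n_a, n_b, D, p.
#' @export
ks_pairwise <- function(x, conditions = NULL) {
  if (inherits(x, "position_stat_table")) {
    labs <- unique(x$condition)
    conditions <- conditions %||% labs[1:2]
    feats <- unique(paste0(x$statistic, "@", x$offset))
    get <- function(f, cond) {
      parts <- strsplit(f, "@", fixed = TRUE)[[1]]
      x$value[x$statistic == parts[[1]] & x$offset == as.integer(parts[[2]]) &
              x$condition == cond]
    }
  } else if (inherits(x, "read_features")) {
    labs <- unique(x$condition)
    conditions <- conditions %||% labs[1:2]
    feats <- colnames(x$x)
    get <- function(f, cond) x$x[x$condition == cond, f]
  } else stop2("x must be a position_stat_table or read_features")
  if (length(conditions) != 2L || anyNA(conditions) ||
      !all(conditions %in% labs))
    stop2("need exactly 2 condition labels present in the data")
  rows <- lapply(feats, function(f) {
    a <- get(f, conditions[[1]]); b <- get(f, conditions[[2]])
    if (length(a) < 5L || length(b) < 5L)
      stop2("need at least 5 values per side for feature ", f)
    kt <- suppressWarnings(stats::ks.test(a, b))
    data.frame(feature = f, n_a = length(a), n_b = length(b),
               D = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Monte-Carlo Jensen-Shannon divergence between two fitted mixtures
#'
#' Draws \code{mc_samples} points from each model and estimates
#' \deqn{JS = 1/2 E_a[\log_2(p_a/p_m)] + 1/2 E_b[\log_2(p_b/p_m)]}
#' with \eqn{p_m} the equal-weight mixture of the two densities.  Log base 2
#' bounds both divergence and distance (its square root) in [0, 1].
#'
#' @param a,b [fit_gmm()] results over the same 2 features.
#' @param mc_samples Monte-Carlo sample count per model (>= 100).
#' @param seed integer seed.
#' @return object of class \code{js_estimate}: list(divergence, distance,
#'   mc_samples, seed).
#' @export
js_divergence_gmm <- function(a, b, mc_samples = 10000L, seed = 1L) {
  stopifnot(inherits(a, "gmm_fit"), inherits(b, "gmm_fit"))
  if (!is_count(mc_samples) || mc_samples < 100L)
    stop2("mc_samples must be >= 100 for a usable estimate")
  set.seed(stage_seed(seed, "js"))
  xa <- gmm_sample(a, mc_samples)
  xb <- gmm_sample(b, mc_samples)
  term <- function(x, self, other) {
    la <- gmm_log_density(self, x)
    lb <- gmm_log_density(other, x)
    m <- pmax(la, lb)
    lm <- m + log(exp(la - m) + exp(lb - m)) - log(2)  # log mixture density
    mean((la - lm) / log(2))
  }
  div <- 0.5 * term(xa, a, b) + 0.5 * term(xb, b, a)
  div <- max(0, div)
  structure(list(divergence = div, distance = sqrt(div),
                 mc_samples = as.integer(mc_samples),
                 seed = as.integer(seed)),
            class = "js_estimate")
}

#' @export
print.js_estimate <- function(x, ...) {
  cat(sprintf("<js_estimate: divergence %.4f, distance %.4f (base 2, %d MC samples, seed %d)>\n",
              x$divergence, x$distance, x$mc_samples, x$seed))
  invisible(x)
}

#' Export population-comparison results as JSON
#'
#' @param path output path.
#' @param gmm optional [fit_gmm()] (or list of them, e.g. per condition).
#' @param ks optional [ks_pairwise()] table.
#' @param js optional [js_divergence_gmm()] result.
#' @return the written list, invisibly.
#' @export
export_population_json <- function(path, gmm = NULL, ks = NULL, js = NULL) {
  enc_gmm <- function(g) list(
    n_components = g$n_components, weights = g$weights,
    means = g$means, covariances = lapply(seq_len(g$n_components),
                                          function(k) g$covariances[, , k]),
    feature_names = g$feature_names, seed = g$seed,
    assignment_table = as.data.frame(g$assignment_table))
  out <- list()
  if (!is.null(gmm)) {
    out$gmm <- if (inherits(gmm, "gmm_fit")) enc_gmm(gmm) else lapply(gmm, enc_gmm)
  }
  if (!is.null(ks)) out$ks <- ks
  if (!is.null(js)) out$js <- list(divergence = js$divergence,
                                   distance = js$distance,
                                   mc_samples = js$mc_samples, seed = js$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
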