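## UMAP embedding of per-read feature vectors.  The embedding is always fit
## once on the pooled reads of all conditions (labels never influence the
## fit); the numerical work is delegated to umap-learn through a small
## python subprocess with an explicit random_state, so results are
## deterministic for a fixed seed and input.

#' 2-D UMAP embedding of a feature matrix
#'
#' Columns are z-scored over the pooled reads before embedding (mixture
#' fitting, by contrast, is done on unscaled features — covariances absorb
#' scale).  A single model is fit on all rows; output rows align with input
#' rows.
#'
#' @param features a [build_features()] result (or plain numeric matrix).
#' @param n_neighbors UMAP neighborhood size; needs at least
#'   \code{n_neighbors + 1} reads.
#' @param min_dist UMAP minimum embedding distance.
#' @param seed integer seed (passed as \code{random_state}).
#' @param scale z-score columns before embedding.
#' @return object of class \code{umap_embedding}: list(coords [n x 2],
#'   condition, read_id, n_neighbors, min_dist, seed).
#' @export
umap_embed <- function(features, n_neighbors = 15L, min_dist = 0.1,
                       seed = 1L, scale = TRUE) {
  if (inherits(features, "read_features")) {
    x <- features$x; cond <- features$condition; ids <- features$read_id
  } else {
    x <- as.matrix(features)
    cond <- rep("all", nrow(x)); ids <- as.character(seq_len(nrow(x)))
  }
  if (nrow(x) < n_neighbors + 1L)
    stop2("UMAP needs at least n_neighbors + 1 = ", n_neighbors + 1L,
          " reads (got ", nrow(x), ")")
  if (scale) {
    mu <- colMeans(x)
    sd <- apply(x, 2L, stats::sd)
    sd[sd == 0] <- 1
    x <- sweep(sweep(x, 2L, mu), 2L, sd, "/")
  }
  py <- Sys.which("python")
  if (!nzchar(py)) stop2("no 'python' interpreter on PATH (needed for UMAP)")
  script <- system.file("python", "umap_embed.py", package = "nanotrace")
  if (!nzchar(script)) stop2("bundled umap_embed.py not found")
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(x, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  log <- system2(py, c(script, fin, fout, n_neighbors,
                       format(min_dist, digits = 17),
                       stage_seed(seed, "umap")),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(log, "status") %||% 0L
  if (status != 0L || !file.exists(fout))
    stop2("UMAP subprocess failed:\n", paste(log, collapse = "\n"))
  coords <- as.matrix(utils::read.table(fout, sep = ","))
  dimnames(coords) <- list(NULL, c("UMAP1", "UMAP2"))
  if (nrow(coords) != nrow(x)) stop2("UMAP output row count mismatch")
  structure(list(coords = coords, condition = cond, read_id = ids,
                 n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist, seed = as.integer(seed)),
            class = "umap_embedding")
}

#' @export
print.umap_embedding <- function(x, ...) {
  cat(sprintf("<umap_embedding: %d reads, n_neighbors %d, min_dist %g, seed %d>\n",
              nrow(x$coords), x$n_neighbors, x$min_dist, x$seed))
  invisible(x)
}
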