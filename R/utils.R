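## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)

#' Derive a per-stage seed from one global seed
#'
#' One user-facing seed fans out deterministically to the stochastic stages
#' (simulation, UMAP, GMM, Monte-Carlo JS, subsampling) so each stage is
#' individually reproducible.  The derived value is always a valid 32-bit
#' integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
#' @examples
#' stage_seed(1, "umap")
stage_seed <- function(seed, stage) {
  stopifnot(is_count(seed), is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483647L)
}

## reverse complement over the DNA alphabet (U treated as T)
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

## parse a CIGAR string into (op, length) pairs
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*")
    stop2("read has no CIGAR string")
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops  <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) || !length(ops))
    stop2("malformed CIGAR string: ", cigar)
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

default_palette <- function(n) {
  pal <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
           "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")
  rep_len(pal, n)
}
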