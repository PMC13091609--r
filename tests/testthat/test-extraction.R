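# Window extraction: rectangular per-position segments, filters, bookkeeping

test_that("clean reads recover the generator's level table", {
  man <- std_fixture()
  exs <- std_extractions()
  for (label in c("control", "modified")) {
    ex <- exs[[label]]
    truth <- fixture_true_levels(man, label, ex$window$positions)
    sd <- man$model$level_sd
    ok <- 0L; total <- 0L
    for (r in ex$reads) {
      for (i in seq_len(ex$window$K)) {
        v <- r$samples[[i]]
        expect_gte(length(v), 1L)
        expect_identical(length(v), as.integer(r$dwell[[i]]))
        total <- total + 1L
        se <- sd / sqrt(length(v))
        if (abs(mean(v) - truth[[i]]) <= 4 * se) ok <- ok + 1L
      }
    }
    expect_gt(ok / total, 0.95)
  }
})

test_that("dwell equals the generated block count times the stride", {
  man <- std_fixture()
  ex <- std_extractions()$modified
  truth <- man$truth[man$truth$condition == "modified", ]
  for (r in ex$reads[1:5]) {
    rt <- truth[truth$read_id == r$read_id, ]
    want <- rt$dwell_samples[match(ex$window$positions, rt$ref_pos)]
    expect_identical(as.integer(r$dwell), as.integer(want))
  }
})

test_that("indel and mismatch filters exclude exactly the designated reads", {
  man <- std_fixture()
  cond <- man$condition_objects$control
  meta <- man$reads[man$reads$condition == "control", ]
  ins_id <- meta$read_id[meta$kind == "insertion"]
  mis_id <- meta$read_id[meta$kind == "mismatch"]
  del_id <- meta$read_id[meta$kind == "deletion"]
  win <- std_window()
  ids_of <- function(ex) vapply(ex$reads, `[[`, character(1), "read_id")

  base <- extract_window(cond, win)
  # insertion and mismatch reads survive when no filter is set; the
  # deletion read cannot supply a segment at the deleted position
  expect_true(all(c(ins_id, mis_id) %in% ids_of(base)))
  expect_false(del_id %in% ids_of(base))
  expect_identical(base$excluded[["deletion_in_window"]], 1L)

  no_indel <- extract_window(cond, win,
                             extraction_options(exclude_reads_with_indels = TRUE))
  expect_false(ins_id %in% ids_of(no_indel))
  expect_false(del_id %in% ids_of(no_indel))
  expect_true(mis_id %in% ids_of(no_indel))
  expect_identical(no_indel$excluded[["indel_in_window"]], 2L)

  matched <- extract_window(cond, win,
                            extraction_options(matched_query_base = TRUE))
  expect_false(mis_id %in% ids_of(matched))
  expect_true(ins_id %in% ids_of(matched))
  expect_identical(matched$excluded[["mismatch_in_window"]], 1L)

  # conservation and monotonicity across filter settings
  for (ex in list(base, no_indel, matched)) {
    expect_identical(length(ex$reads) + sum(ex$excluded), ex$fetched)
    expect_lte(length(ex$reads), length(base$reads) + 1L)
    expect_true(all(ids_of(ex) %in% c(ids_of(base), del_id)))
  }
  expect_lte(length(no_indel$reads), length(base$reads))
  expect_lte(length(matched$reads), length(base$reads))
})

test_that("reads not spanning the window are reason-coded, not errors", {
  man <- std_fixture()
  cond <- man$condition_objects$modified
  # a window near the reference edge that no simulated read fully covers
  win <- window_spec("synthref", 20L, K = 5L)
  ex <- extract_window(cond, win)
  expect_length(ex$reads, 0L)
  expect_identical(sum(ex$excluded) + length(ex$reads), ex$fetched)
  expect_error(extract_window(cond, window_spec("synthref", 1L, K = 13L)),
               "falls off reference")
})

test_that("concatenated segments reproduce the contiguous signal slice", {
  man <- std_fixture()
  exs <- std_extractions()
  # reads with an insertion inside the window have a genuine gap between
  # window segments, so contiguity only holds for gap-free alignments
  gapfree <- man$reads$read_id[man$reads$kind %in%
                               c("normal", "mismatch", "split")]
  for (ex in exs) {
    checked <- 0L
    for (r in ex$reads) {
      if (!r$read_id %in% gapfree) next
      expect_true(concat_check(ex, r$read_id))
      checked <- checked + 1L
    }
    expect_gte(checked, 15L)
  }
  ins_id <- man$reads$read_id[man$reads$kind == "insertion"]
  if (ins_id %in% vapply(exs$control$reads, `[[`, character(1), "read_id"))
    expect_false(concat_check(exs$control, ins_id))
  # corrupting one segment's samples must break the identity
  ex <- exs$modified
  ex$reads[[1]]$samples[[3]] <- ex$reads[[1]]$samples[[3]] + 1
  expect_false(concat_check(ex, ex$reads[[1]]$read_id))
})

test_that("normalizers see the whole read and must preserve length", {
  man <- std_fixture()
  cond <- man$condition_objects$modified
  win <- std_window()
  zs <- function(x) (x - mean(x)) / sd(x)
  ex <- extract_window(cond, win, extraction_options(normalizer = zs))
  raw <- extract_window(cond, win)
  # z-scored segments are an affine transform of the raw ones, per read
  r1 <- ex$reads[[1]]; r0 <- raw$reads[[1]]
  expect_identical(r1$read_id, r0$read_id)
  v1 <- unlist(r1$samples); v0 <- unlist(r0$samples)
  fitted <- (v0 - mean(v0)) / sd(v0)
  expect_gt(stats::cor(v1, v0), 0.999)
  expect_error(
    extract_window(cond, win,
                   extraction_options(normalizer = function(x) x[-1])),
    "changed the sample count")
})

test_that("TSV export is tidy and complete", {
  ex <- std_extractions()$modified
  path <- tempfile(fileext = ".tsv")
  df <- export_extraction_tsv(ex, path)
  expect_identical(nrow(df), length(ex$reads) * ex$window$K)
  back <- read.delim(path)
  expect_identical(nrow(back), nrow(df))
  expect_named(back, c("condition", "read_id", "ref_pos", "ref_base",
                       "dwell_samples", "mean_pA", "median_pA", "std_pA"))
})
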