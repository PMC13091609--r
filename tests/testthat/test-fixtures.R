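# Synthetic fixture generator: determinism, dwell law, tag/format validity

test_that("simulated reads are deterministic and obey the dwell law", {
  ref <- strrep("ACGTTGCA", 20L)
  s1 <- simulate_read(ref, 30L, 40L, seed = 13L)
  s2 <- simulate_read(ref, 30L, 40L, seed = 13L)
  expect_identical(s1$signal_dac, s2$signal_dac)
  expect_identical(s1$mv, s2$mv)
  expect_identical(s1$ts, s2$ts)

  # degenerate geometric: dwell_p = 0 gives one block per base
  m0 <- pore_model(dwell_p = 0)
  s0 <- simulate_read(ref, 30L, 40L, model = m0, seed = 14L)
  expect_identical(s0$ns, s0$ts + 40L * m0$stride)
  expect_true(all(s0$truth$dwell_blocks == 1L))
  expect_identical(sum(s0$mv[-1]), 40L)

  # move blocks tile [ts, ns)
  expect_identical(s1$ts + s1$mv[[1]] * length(s1$mv[-1]), s1$ns)
})

test_that("modification deltas shift exactly the designated position", {
  ref <- strrep("ACGTTGCA", 20L)
  model <- pore_model()
  s <- simulate_read(ref, 30L, 40L, mod_positions = 50L, mod_delta = 8,
                     model = model, seed = 15L)
  base_truth <- nanotrace:::reference_levels(ref, 30:69, model)
  expect_equal(s$truth$level_pA, base_truth + ifelse(30:69 == 50L, 8, 0))
  # generated samples track the shifted level
  i <- which(s$truth$ref_pos == 50L)
  seg <- parse_move_table(s$mv, s$ts, s$ns)$segments
  v <- s$signal_pA[(seg[i, 1] + 1):seg[i, 2]]
  expect_lt(abs(mean(v) - s$truth$level_pA[[i]]),
            4 * model$level_sd / sqrt(length(v)))
})

test_that("fixture pairs pass standard-reader validation with full tags", {
  man <- std_fixture()
  for (cd in man$conditions) {
    bam <- cd$bam
    expect_true(file.exists(bam) && file.exists(paste0(bam, ".bai")))
    # sorted by coordinate, per the header
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$text
    expect_identical(hdr[["@HD"]][2], "SO:coordinate")
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "pos"),
      tag = c("mv", "ts", "ns", "MD"))
    res <- Rsamtools::scanBam(bam, param = p)[[1]]
    expect_true(all(!is.na(res$pos)))
    expect_true(!is.unsorted(res$pos))
    # every record carries the required tag set
    expect_true(all(!vapply(res$tag$mv, is.null, logical(1))))
    expect_false(anyNA(res$tag$ts))
    expect_false(anyNA(res$tag$ns))
    expect_false(anyNA(res$tag$MD))
    # signals load for every non-split record
    idx <- build_read_index(cd$pod5_dir)
    expect_gt(length(idx), 0L)
  }
  ctrl <- man$conditions[[1]]
  expect_identical(ctrl$label, "control")
  n_records <- length(Rsamtools::scanBam(
    ctrl$bam, param = Rsamtools::ScanBamParam(what = "qname"))[[1]]$qname)
  expect_identical(n_records, 25L)  # 20 normal + 5 designated specials

  # the reference FASTA round-trips through a standard reader
  fa <- Biostrings::readDNAStringSet(man$reference_path)
  expect_identical(names(fa), "synthref")
  expect_identical(as.character(fa[[1]]), man$reference)

  # truth manifest covers every record
  expect_true(all(man$reads$read_id %in% unique(man$truth$read_id)))
  expect_true(file.exists(file.path(dirname(man$reference_path),
                                    "manifest.json")))
})

test_that("designated strand fractions and special reads are realized", {
  man <- strand_fixture("DNA")
  meta <- man$reads
  expect_true(all(table(meta$strand) >= 5L))
  man2 <- std_fixture()
  kinds <- table(man2$reads$kind)
  expect_identical(as.integer(kinds[c("insertion", "mismatch", "deletion",
                                      "secondary", "split")]),
                   rep(1L, 5L))
})

test_that("whole-fixture generation is reproducible given the seed", {
  d1 <- file.path(tempdir(), "repro1"); d2 <- file.path(tempdir(), "repro2")
  m1 <- write_fixture_pair(list(list(label = "c", n_reads = 4L)),
                           out_dir = d1, seed = 99L)
  m2 <- write_fixture_pair(list(list(label = "c", n_reads = 4L)),
                           out_dir = d2, seed = 99L)
  expect_identical(m1$reference, m2$reference)
  expect_identical(m1$truth$level_pA, m2$truth$level_pA)
  expect_identical(m1$truth$dwell_blocks, m2$truth$dwell_blocks)
})
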