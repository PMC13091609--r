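## Ground-truthed synthetic fixtures: a pore model, a per-read signal
## simulator, and a writer producing signal-store directories plus
## sorted+indexed BAMs carrying the full move-table tag set, with a truth
## manifest.  The simulator emulates the input contract, not pore physics:
## per-base current levels are keyed to the reference-forward k-mer at each
## reference position (so forward and reverse simulations of the same locus
## are directly comparable), dwell is geometric in blocks, and noise is
## Gaussian.

#' Synthetic pore model
#'
#' Levels are a deterministic hash of the k-mer into [70, 130] pA — fixed
#' and recorded in manifests, with no claim of biophysical realism.
#'
#' @param kmer_size k-mer context width (odd).
#' @param level_sd Gaussian noise sd around the base level, pA.
#' @param dwell_p geometric per-block continuation probability in (0, 1);
#'   expected dwell is 1 / (1 - dwell_p) blocks.
#' @param stride samples per basecaller block.
#' @param sample_rate sampling rate, Hz.
#' @param calibration_offset,calibration_scale DAC calibration written to
#'   the signal store; \code{pA = (raw + offset) * scale}.
#' @return object of class \code{pore_model}.
#' @export
pore_model <- function(kmer_size = 5L, level_sd = 2.5, dwell_p = 0.55,
                       stride = 6L, sample_rate = 4000,
                       calibration_offset = 10, calibration_scale = 0.25) {
  stopifnot(kmer_size %% 2L == 1L, dwell_p >= 0, dwell_p < 1, stride >= 1L)
  structure(list(kmer_size = as.integer(kmer_size), level_sd = level_sd,
                 dwell_p = dwell_p, stride = as.integer(stride),
                 sample_rate = sample_rate,
                 calibration_offset = calibration_offset,
                 calibration_scale = calibration_scale),
            class = "pore_model")
}

## deterministic k-mer -> level hash into [70, 130] pA
kmer_level <- function(kmers) {
  vapply(kmers, function(km) {
    codes <- c(A = 0, C = 1, G = 2, T = 3, U = 3, N = 0)
    v <- codes[strsplit(km, "", fixed = TRUE)[[1]]]
    idx <- sum(v * 4^(seq_along(v) - 1))
    70 + 60 * ((idx * 2654435761) %% 4096) / 4095
  }, numeric(1), USE.NAMES = FALSE)
}

## expected level at each 0-based reference position (reference-forward
## k-mer context, edges clamped)
reference_levels <- function(reference, positions, model) {
  half <- (model$kmer_size - 1L) %/% 2L
  n <- nchar(reference)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  kmers <- vapply(positions, function(p) {
    idx <- pmin(pmax((p - half):(p + half), 0L), n - 1L)  # edges clamped
    paste(chars[idx + 1L], collapse = "")
  }, character(1))
  kmer_level(kmers)
}

## apply a single edit to a reference span; returns query string, cigar, md
## and per-query-base reference positions (NA for inserted bases)
apply_edit <- function(ref_span, start, edit) {
  L <- nchar(ref_span)
  chars <- strsplit(ref_span, "", fixed = TRUE)[[1]]
  refpos <- start + 0:(L - 1L)
  if (is.null(edit)) {
    return(list(query = ref_span, cigar = paste0(L, "M"), md = as.character(L),
                ref_pos = refpos))
  }
  at <- edit$at - start          # 0-based offset into the span
  if (at < 1L || at > L - 2L)
    stop2("edit position must fall strictly inside the read span")
  if (edit$type == "mismatch") {
    alt <- setdiff(c("A", "C", "G", "T"), chars[[at + 1L]])[[1]]
    q <- chars; q[[at + 1L]] <- alt
    list(query = paste(q, collapse = ""), cigar = paste0(L, "M"),
         md = paste0(at, chars[[at + 1L]], L - at - 1L), ref_pos = refpos)
  } else if (edit$type == "insertion") {
    base <- edit$base %||% "A"
    q <- append(chars, base, after = at + 1L)
    list(query = paste(q, collapse = ""),
         cigar = paste0(at + 1L, "M1I", L - at - 1L, "M"),
         md = as.character(L),
         ref_pos = append(refpos, NA_integer_, after = at + 1L))
  } else if (edit$type == "deletion") {
    q <- chars[-(at + 1L)]
    list(query = paste(q, collapse = ""),
         cigar = paste0(at, "M1D", L - at - 1L, "M"),
         md = paste0(at, "^", chars[[at + 1L]], L - at - 1L),
         ref_pos = refpos[-(at + 1L)])
  } else stop2("unknown edit type: ", edit$type)
}

#' Simulate one read: signal, move table and alignment fields
#'
#' Bases are emitted in signal-time order (reversed relative to the reported
#' 5'->3' sequence for RNA); each base dwells \code{1 + Geometric(dwell_p)}
#' blocks of \code{stride} samples drawn from
#' \code{Normal(level + delta, level_sd)}, where delta applies at modified
#' reference positions.  A small trimmed-prefix (\code{ts}) of junk samples
#' precedes the first block.
#'
#' @param reference reference sequence (character string).
#' @param start 0-based reference start of the read.
#' @param length read span on the reference, bases.
#' @param strand "forward" or "reverse".
#' @param molecule "DNA" or "RNA".
#' @param model a [pore_model()].
#' @param mod_positions 0-based reference positions carrying a level shift.
#' @param mod_delta level shift, pA.
#' @param edit optional \code{list(type = "mismatch"|"insertion"|"deletion",
#'   at = <0-based ref pos>)}.
#' @param levels optional explicit per-reference-position level vector
#'   (indexed 1 + ref_pos) overriding the k-mer model.
#' @param read_id read identifier.
#' @param seed optional integer seed (same seed, same output).
#' @return list with signal (integer DAC), pA truth, calibration, mv tag
#'   (stride + moves), ts, ns, alignment fields (pos, cigar, md, seq,
#'   strand) and a per-query-base \code{truth} data.frame (ref_pos, base,
#'   level_pA, dwell_blocks, dwell_samples).
#' @export
simulate_read <- function(reference, start, length,
                          strand = c("forward", "reverse"),
                          molecule = c("DNA", "RNA"),
                          model = pore_model(), mod_positions = integer(0),
                          mod_delta = 0, edit = NULL, levels = NULL,
                          read_id = "read", seed = NULL) {
  strand <- match.arg(strand); molecule <- match.arg(molecule)
  if (!is.null(seed)) set.seed(seed)
  if (start < 0L || start + length > nchar(reference))
    stop2("read interval [", start, ", ", start + length,
          ") outside the reference (length ", nchar(reference), ")")
  aln <- apply_edit(substr(reference, start + 1L, start + length), start, edit)
  Lq <- nchar(aln$query)
  # expected level per query base (reference-forward context; inserted
  # bases get a fixed neutral level)
  base_level <- rep(100, Lq)
  known <- !is.na(aln$ref_pos)
  base_level[known] <- if (!is.null(levels)) levels[aln$ref_pos[known] + 1L]
                       else reference_levels(reference, aln$ref_pos[known], model)
  base_level[known & aln$ref_pos %in% mod_positions] <-
    base_level[known & aln$ref_pos %in% mod_positions] + mod_delta
  # query index -> emitted (signal-time) order: reverse-strand alignments
  # store the reverse complement, RNA is sequenced 3'->5'
  qidx <- seq_len(Lq)
  midx <- if (strand == "reverse") rev(qidx) else qidx   # molecule 5'->3'
  eidx <- if (molecule == "RNA") rev(midx) else midx     # signal-time order
  dwell_blocks_q <- integer(Lq)
  ts <- sample(0:(2L * model$stride), 1L)
  junk <- as.numeric(stats::rnorm(ts, 100, 20))
  moves <- integer(0)
  sig_pA <- junk
  for (q in eidx) {
    d <- if (model$dwell_p == 0) 1L else
      1L + stats::rgeom(1L, prob = 1 - model$dwell_p)
    dwell_blocks_q[[q]] <- d
    moves <- c(moves, 1L, rep(0L, d - 1L))
    sig_pA <- c(sig_pA, stats::rnorm(d * model$stride, base_level[[q]],
                                     model$level_sd))
  }
  ns <- length(sig_pA)
  dac <- as.integer(round(sig_pA / model$calibration_scale -
                          model$calibration_offset))
  qbases <- strsplit(aln$query, "", fixed = TRUE)[[1]]
  list(read_id = read_id,
       signal_dac = dac, signal_pA = sig_pA,
       calibration_offset = model$calibration_offset,
       calibration_scale = model$calibration_scale,
       sample_rate = model$sample_rate,
       mv = c(model$stride, moves), ts = ts, ns = ns,
       pos = start, cigar = aln$cigar, md = aln$md,
       seq = aln$query, strand = strand, molecule = molecule,
       truth = data.frame(read_id = read_id, query_pos = qidx - 1L,
                          ref_pos = aln$ref_pos, base = qbases,
                          level_pA = base_level,
                          dwell_blocks = dwell_blocks_q,
                          dwell_samples = dwell_blocks_q * model$stride,
                          stringsAsFactors = FALSE))
}

## format one SAM line for a simulated read
sam_record <- function(sim, ref_name, flag = NULL, pi = NULL, sp = NULL,
                       mapq = 60L) {
  flag <- flag %||% if (sim$strand == "reverse") 16L else 0L
  tags <- c(sprintf("mv:B:c,%s", paste(sim$mv, collapse = ",")),
            sprintf("ts:i:%d", sim$ts), sprintf("ns:i:%d", sim$ns),
            sprintf("MD:Z:%s", sim$md))
  if (!is.null(pi)) tags <- c(tags, sprintf("pi:Z:%s", pi))
  if (!is.null(sp)) tags <- c(tags, sprintf("sp:i:%d", sp))
  paste(c(sim$read_id, flag, ref_name, sim$pos + 1L, mapq, sim$cigar, "*",
          0L, 0L, sim$seq, "*", tags), collapse = "\t")
}

#' Write a complete multi-condition fixture: signals + BAMs + truth
#'
#' Generates a random reference (or uses the one given), simulates
#' \code{n_reads} window-covering reads per condition (plus any designated
#' special reads), and writes per condition a signal-store directory and a
#' coordinate-sorted, indexed BAM carrying mv/ts/ns/MD (and pi/sp on split
#' reads), plus a reference FASTA and truth manifest (JSON + TSV).
#'
#' @param conditions list of \code{list(label, n_reads, mod_positions =
#'   <0-based ref positions>, mod_delta = <pA>)}.
#' @param out_dir output directory (created).
#' @param reference optional reference sequence string; random when NULL.
#' @param ref_name reference sequence name.
#' @param ref_length random reference length when generated.
#' @param model a [pore_model()].
#' @param read_length simulated read span, bases.
#' @param window_center 0-based position every read is guaranteed to cover
#'   with at least \code{margin} bases on each side.
#' @param margin guaranteed coverage margin around \code{window_center}.
#' @param molecule "DNA" or "RNA".
#' @param reverse_fraction fraction of reads simulated on the reverse
#'   strand.
#' @param special_reads optional data.frame(condition, kind, at) adding
#'   designated reads: kind in mismatch / insertion / deletion (edit at
#'   0-based ref position \code{at}), secondary (extra secondary alignment)
#'   or split (child record whose signal is a slice of a parent's).
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of it.
#' @return invisibly, the manifest: conditions (as [signal_condition()]
#'   objects), reference info, model parameters, per-read truth table and
#'   file paths.
#' @export
write_fixture_pair <- function(conditions, out_dir, reference = NULL,
                               ref_name = "synthref", ref_length = 300L,
                               model = pore_model(), read_length = 60L,
                               window_center = NULL, margin = 12L,
                               molecule = c("DNA", "RNA"),
                               reverse_fraction = 0, special_reads = NULL,
                               seed = 1L) {
  molecule <- match.arg(molecule)
  set.seed(stage_seed(seed, "simulate"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(reference))
    reference <- paste(sample(c("A", "C", "G", "T"), ref_length,
                              replace = TRUE), collapse = "")
  ref_length <- nchar(reference)
  center <- window_center %||% (ref_length %/% 2L)
  lo_start <- max(0L, center + margin - read_length)
  hi_start <- max(lo_start, min(center - margin, ref_length - read_length))
  ref_path <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::DNAStringSet(reference), ref_name), ref_path)

  truth <- list(); read_meta <- list(); cond_objs <- list()
  for (ci in seq_along(conditions)) {
    cd <- conditions[[ci]]
    label <- cd$label
    modp <- as.integer(cd$mod_positions %||% integer(0))
    delta <- cd$mod_delta %||% 0
    pod5_dir <- file.path(out_dir, label, "signals")
    dir.create(pod5_dir, recursive = TRUE, showWarnings = FALSE)
    sams <- character(0); sigs <- list(); starts <- integer(0)
    specials <- if (!is.null(special_reads))
      special_reads[special_reads$condition == label, , drop = FALSE]
    else NULL
    n_special <- if (is.null(specials)) 0L else nrow(specials)
    n_total <- cd$n_reads + n_special
    for (ri in seq_len(n_total)) {
      spec_kind <- if (ri > cd$n_reads) specials$kind[[ri - cd$n_reads]] else "normal"
      spec_at <- if (ri > cd$n_reads) specials$at[[ri - cd$n_reads]] else NA
      rid <- sprintf("%s-%04d", label, ri)
      start <- if (lo_start < hi_start)
        sample(lo_start:hi_start, 1L) else lo_start
      strand <- if (stats::runif(1) < reverse_fraction) "reverse" else "forward"
      edit <- if (spec_kind %in% c("mismatch", "insertion", "deletion"))
        list(type = spec_kind, at = as.integer(spec_at)) else NULL
      sim <- simulate_read(reference, start, read_length, strand = strand,
                           molecule = molecule, model = model,
                           mod_positions = modp, mod_delta = delta,
                           edit = edit, read_id = rid)
      if (identical(spec_kind, "split")) {
        # embed the read's signal window inside a longer parent signal
        parent_id <- paste0(rid, "-parent")
        pad_l <- 120L; pad_r <- 80L
        parent_pA <- c(stats::rnorm(pad_l, 100, 20), sim$signal_pA,
                       stats::rnorm(pad_r, 100, 20))
        parent_dac <- as.integer(round(parent_pA / model$calibration_scale -
                                       model$calibration_offset))
        parent_dac[(pad_l + 1L):(pad_l + sim$ns)] <- sim$signal_dac
        sigs[[length(sigs) + 1L]] <- read_signal(
          parent_id, parent_dac, model$calibration_offset,
          model$calibration_scale, model$sample_rate)
        sams <- c(sams, sam_record(sim, ref_name, pi = parent_id, sp = pad_l))
      } else {
        sigs[[length(sigs) + 1L]] <- read_signal(
          rid, sim$signal_dac, model$calibration_offset,
          model$calibration_scale, model$sample_rate)
        flag <- if (identical(spec_kind, "secondary"))
          256L + if (sim$strand == "reverse") 16L else 0L else NULL
        sams <- c(sams, sam_record(sim, ref_name, flag = flag))
      }
      starts <- c(starts, sim$pos)
      truth[[length(truth) + 1L]] <- cbind(condition = label,
                                           kind = spec_kind, sim$truth)
      read_meta[[length(read_meta) + 1L]] <- data.frame(
        read_id = rid, condition = label, kind = spec_kind,
        strand = sim$strand, start = sim$pos, cigar = sim$cigar,
        ts = sim$ts, ns = sim$ns, stringsAsFactors = FALSE)
    }
    write_signal_store(sigs, file.path(pod5_dir, "signals.parquet"))
    sam_path <- file.path(out_dir, label, paste0(label, ".sam"))
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_length))
    writeLines(c(header, sams[order(starts)]), sam_path)
    bam_stub <- file.path(out_dir, label, label)
    bam <- Rsamtools::asBam(sam_path, bam_stub, overwrite = TRUE,
                            indexDestination = TRUE)
    unlink(sam_path)
    cond_objs[[label]] <- signal_condition(label, bam, pod5_dir)
  }
  truth <- do.call(rbind, truth)
  read_meta <- do.call(rbind, read_meta)
  utils::write.table(truth, file.path(out_dir, "truth_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    reference_path = ref_path, ref_name = ref_name, ref_length = ref_length,
    reference = reference, center = center, seed = seed,
    molecule = molecule, read_length = read_length,
    model = unclass(model),
    conditions = lapply(conditions, function(cd)
      list(label = cd$label, n_reads = cd$n_reads,
           mod_positions = as.integer(cd$mod_positions %||% integer(0)),
           mod_delta = cd$mod_delta %||% 0,
           bam = file.path(out_dir, cd$label, paste0(cd$label, ".bam")),
           pod5_dir = file.path(out_dir, cd$label, "signals"))),
    reads = read_meta)
  jsonlite::write_json(manifest[setdiff(names(manifest), "reads")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$condition_objects <- cond_objs
  manifest$truth <- truth
  invisible(manifest)
}

#' True expected level at reference positions for a fixture condition
#'
#' Convenience accessor: the k-mer model level plus the condition's
#' modification delta where it applies.
#'
#' @param manifest a [write_fixture_pair()] manifest.
#' @param label condition label.
#' @param positions 0-based reference positions.
#' @return numeric vector of expected pA levels.
#' @export
fixture_true_levels <- function(manifest, label, positions) {
  cd <- Filter(function(x) x$label == label, manifest$conditions)[[1]]
  lv <- reference_levels(manifest$reference, positions,
                         do.call(pore_model, manifest$model))
  lv + ifelse(positions %in% cd$mod_positions, cd$mod_delta, 0)
}
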