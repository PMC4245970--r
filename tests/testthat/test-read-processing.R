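pairs_tbl <- function(r1, channel = NULL, handle = NULL, r2 = NA_character_) {
  tb <- tibble::tibble(id = as.character(seq_along(r1)), r1_seq = r1,
                       r2_seq = r2)
  if (!is.null(channel)) tb$channel <- channel
  if (!is.null(handle)) tb$handle <- handle
  tb
}

test_that("handle demultiplexing follows IUPAC semantics", {
  reads <- pairs_tbl(c("AGACGGG", "TCTGGGG", "ACGTGGG"))
  dm <- demultiplex_by_handle(reads)
  expect_equal(dm$channel, c("plus", "minus", "unassigned"))
  expect_equal(dm$handle, c("AGAC", "TCTG", "ACGT"))
  # handle removed from assigned fragments only
  expect_equal(dm$r1_seq, c("GGG", "GGG", "ACGTGGG"))
})

test_that("demultiplexing is symmetric under swapping the handles", {
  withr::with_seed(5, {
    r1 <- vapply(1:200, function(i) {
      paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    }, "")
  })
  a <- demultiplex_by_handle(pairs_tbl(r1), "RRRY", "YYYR")
  b <- demultiplex_by_handle(pairs_tbl(r1), "YYYR", "RRRY")
  swap <- c(plus = "minus", minus = "plus", unassigned = "unassigned")
  expect_equal(unname(swap[a$channel]), b$channel)
})

test_that("a handle longer than a read is a hard error", {
  expect_error(demultiplex_by_handle(pairs_tbl("AG")), "handle length")
  expect_error(demultiplex_by_handle(pairs_tbl("AGACG"),
                                     "RRRY", "YYY"), "equal length")
})

test_that("adapter trimming removes the longest qualifying suffix", {
  ad <- "AGATCGGAAGAGC"
  frag <- "CCGGAACCTT"
  expect_equal(trim_adapter(paste0(frag, substr(ad, 1, 10)), ad,
                            min_overlap = 4), frag)
  expect_equal(trim_adapter(frag, ad, min_overlap = 4), frag)
  # overlap below threshold is kept
  short <- paste0(frag, substr(ad, 1, 3))
  expect_equal(trim_adapter(short, ad, min_overlap = 4), short)
  # a mismatch in the overlap is tolerated only within the rate
  noisy <- paste0(frag, "AGATCGGAACAGC")
  expect_equal(trim_adapter(noisy, ad, max_mismatch_rate = 0), noisy)
  expect_equal(trim_adapter(noisy, ad, max_mismatch_rate = 0.1), frag)
})

test_that("stop attribution follows the k = p - 1 convention", {
  tg <- target_set("t", "GGAACC")
  lk <- shapeseq_linker()
  reads <- pairs_tbl(
    c(paste0("AACC", lk), paste0("GGAACC", lk), paste0("ACC", lk)),
    channel = "plus", handle = "AGAC"
  )
  aln <- align_fragments(reads, tg, check_r2 = FALSE)
  expect_equal(aln$status, rep("aligned", 3))
  # fragment at positions 3..6 means RT stopped with last base at 3: k = 2
  expect_equal(aln$stop, c(2L, 0L, 3L))
})

test_that("reads matching multiple positions are discarded as ambiguous", {
  tg <- target_set("rep", "ACACAC")
  reads <- pairs_tbl("ACAC", channel = "plus", handle = "AGAC")
  aln <- align_fragments(reads, tg, check_r2 = FALSE)
  expect_equal(aln$status, "ambiguous")
  expect_true(is.na(aln$stop))
})

test_that("adapter read-through beyond the linker still aligns", {
  tg <- target_set("t", "GGAACC")
  lk <- shapeseq_linker()
  ad <- shapeseq_adapter()
  # 2-nt overhang: too short for standalone trimming, handled by the aligner
  reads <- pairs_tbl(paste0("ACC", lk, substr(ad, 1, 2)),
                     channel = "minus", handle = "TCTG")
  aln <- align_fragments(reads, tg, check_r2 = FALSE)
  expect_equal(aln$status, "aligned")
  expect_equal(aln$stop, 3L)
  # an overhang that is not adapter does not align
  reads2 <- pairs_tbl(paste0("ACC", lk, "TT"),
                      channel = "minus", handle = "TCTG")
  expect_equal(align_fragments(reads2, tg, check_r2 = FALSE)$status,
               "unaligned")
})

test_that("empty target set is a hard error", {
  expect_error(align_fragments(pairs_tbl("ACGT", channel = "plus"),
                               target_set(character(0), character(0))),
               "empty target")
})

test_that("count_stops tallies alignments and conserves totals", {
  aln <- tibble::tibble(
    id = as.character(1:3), channel = "plus", status = "aligned",
    target = "t", stop = c(0L, 0L, 2L)
  )
  cs <- count_stops(aln, "t", "plus", L = 3)
  expect_equal(cs$count, c(2L, 0L, 1L, 0L))
  expect_equal(sum(cs$count), 3L)
  empty <- count_stops(aln[0, ], "t", "plus", L = 3)
  expect_equal(empty$count, rep(0L, 4))
})

test_that("pipeline accounting drops nothing silently", {
  tg <- demo_target(L = 40, seed = 3)
  par <- sim_params(tg, n_plus = 1500, n_minus = 1500, error_rate = 0.05,
                    seed = 99)
  sim <- simulate_stop_counts(par)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  suppressWarnings(emit_fastq(sim, f1, f2))
  run <- suppressWarnings(
    process_read_pairs(r1_path = f1, r2_path = f2, targets = tg)
  )
  s <- run$stats
  expect_equal(s$n_pairs, 3000L)
  expect_equal(s$n_unassigned + s$n_plus_assigned + s$n_minus_assigned,
               s$n_pairs)
  expect_equal(s$n_plus_aligned + s$n_minus_aligned + s$n_unaligned +
                 s$n_ambiguous,
               s$n_plus_assigned + s$n_minus_assigned)
  # with 5% substitution error and zero mismatch budget, some reads must fail
  expect_lt(s$n_plus_aligned + s$n_minus_aligned,
            s$n_plus_assigned + s$n_minus_assigned)
  expect_equal(sum(run$counts$plus_count) + sum(run$counts$minus_count),
               s$n_plus_aligned + s$n_minus_aligned)
})

test_that("count tables round-trip through the TSV writer", {
  tg <- demo_target(L = 10, seed = 2)
  sim <- simulate_stop_counts(sim_params(tg, n_plus = 500, n_minus = 500,
                                         seed = 4))
  tab <- dplyr::mutate(sim$counts, target = tg$name, .before = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stop_counts(tab, f)
  expect_equal(as.data.frame(read_stop_counts(f)), as.data.frame(tab))
})
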