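# Read processing: paired-end FASTQ -> per-target RT-stop count tables.
#
# Coordinate convention (load-bearing): a fragment whose 5'-most aligned
# target position is p means RT synthesized positions L..p and terminated with
# its last cDNA base at p; the blocking adduct / drop-off site is one
# nucleotide 5' of that base, so the stop is attributed to index k = p - 1.
# A fragment reaching position 1 is a full-length read-through, k = 0.
# Changing this convention shifts every reactivity spectrum by one position.

#' Default 3' linker and adapter sequences
#'
#' The linker is the universal RT priming site ligated to the RNA 3' end
#' after modification; the adapter is the sequencing adapter observed as
#' read-through when the cDNA insert is shorter than the read length.
#'
#' @return A character scalar.
#' @export
shapeseq_linker <- function() "CACTCGGGCACCAAGGAC"

#' @rdname shapeseq_linker
#' @export
shapeseq_adapter <- function() "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' Read paired-end FASTQ files into a tibble
#'
#' @param r1_path,r2_path Paths to the two mate FASTQ files.
#' @return A tibble with columns `id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  # (suppressed warning: Biostrings drops its unused metadata columns)
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  if (length(r1) != length(r2)) {
    stop("mate files differ in read count: ", length(r1), " vs ", length(r2),
         call. = FALSE)
  }
  clean_id <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  tibble(
    id = clean_id(names(r1)),
    r1_seq = as.character(r1),
    r1_qual = as.character(Biostrings::quality(r1)),
    r2_seq = as.character(r2),
    r2_qual = as.character(Biostrings::quality(r2))
  )
}

#' Assign read pairs to the (+)/(-) channel by their degenerate handle
#'
#' The first `nchar(handle)` bases of R1 are matched against both degenerate
#' handles under IUPAC semantics (R = A/G, Y = C/T). A read matching exactly
#' one handle is assigned to that channel and the handle bases are removed
#' from the fragment; reads matching zero or both handles are `unassigned`.
#' Swapping the two handle arguments swaps the channel labels exactly.
#'
#' @param reads A tibble as returned by [read_fastq_pairs()] (columns `r1_seq`
#'   and optionally `r1_qual`, `r2_seq`, `r2_qual`).
#' @param plus_handle,minus_handle Equal-length IUPAC-degenerate strings
#'   (defaults RRRY / YYYR).
#' @return `reads` with added columns `channel` (`"plus"`, `"minus"` or
#'   `"unassigned"`) and `handle` (the observed concrete handle bases), and
#'   with the handle removed from `r1_seq`/`r1_qual`.
#' @export
demultiplex_by_handle <- function(reads, plus_handle = "RRRY",
                                  minus_handle = "YYYR") {
  stopifnot(is.data.frame(reads), "r1_seq" %in% names(reads))
  if (nchar(plus_handle) != nchar(minus_handle)) {
    stop("handles must have equal length", call. = FALSE)
  }
  nh <- nchar(plus_handle)
  if (nrow(reads) > 0 && any(nchar(reads$r1_seq) < nh)) {
    stop("handle length ", nh, " exceeds the length of ",
         sum(nchar(reads$r1_seq) < nh), " read(s)", call. = FALSE)
  }
  is_plus <- iupac_prefix_match(reads$r1_seq, plus_handle)
  is_minus <- iupac_prefix_match(reads$r1_seq, minus_handle)
  channel <- dplyr::case_when(
    is_plus & !is_minus ~ "plus",
    is_minus & !is_plus ~ "minus",
    .default = "unassigned"
  )
  out <- reads
  out$handle <- substr(reads$r1_seq, 1L, nh)
  out$channel <- channel
  assigned <- channel != "unassigned"
  out$r1_seq[assigned] <- substr(reads$r1_seq[assigned], nh + 1L,
                                 nchar(reads$r1_seq[assigned]))
  if ("r1_qual" %in% names(out)) {
    out$r1_qual[assigned] <- substr(reads$r1_qual[assigned], nh + 1L,
                                    nchar(reads$r1_qual[assigned]))
  }
  out
}

#' Trim sequencing-adapter read-through from the 3' end of reads
#'
#' Finds the longest suffix of each sequence that matches a prefix of the
#' adapter with at least `min_overlap` bases and at most
#' `max_mismatch_rate * overlap` mismatches, and removes it. Sequences with
#' no qualifying match are returned unchanged (a valid outcome, not an
#' error).
#'
#' @param seq Character vector of sequences.
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum overlap length to trim (default 4).
#' @param max_mismatch_rate Maximum allowed mismatch fraction in the overlap
#'   (default 0).
#' @return Character vector of trimmed sequences.
#' @export
trim_adapter <- function(seq, adapter, min_overlap = 4L,
                         max_mismatch_rate = 0) {
  stopifnot(nchar(adapter) >= 1, min_overlap >= 1)
  adapter <- to_dna(toupper(adapter))
  vapply(to_dna(toupper(seq)), function(s) {
    n <- nchar(s)
    max_ov <- min(n, nchar(adapter))
    if (max_ov >= min_overlap) {
      for (ov in seq(max_ov, min_overlap)) {
        suffix <- substr(s, n - ov + 1L, n)
        mm <- sum(charToRaw(suffix) != charToRaw(substr(adapter, 1L, ov)))
        if (mm <= max_mismatch_rate * ov) {
          return(substr(s, 1L, n - ov))
        }
      }
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

# Candidate fragment strings for one target: fragment starting at p runs
# p..L plus the full linker. p = L + 1 (a linker-only fragment carrying zero
# target nucleotides) is deliberately not a candidate: it identifies no
# target, which is why the 3'-terminal stop bin k = L is structurally empty.
target_candidates <- function(target_seq, linker) {
  s <- to_dna(toupper(target_seq))
  L <- nchar(s)
  frags <- paste0(substring(s, seq_len(L), L), to_dna(toupper(linker)))
  tibble(p = seq_len(L), frag = frags, flen = nchar(frags))
}

#' Align demultiplexed fragments to targets and attribute RT stops
#'
#' R1 (handle removed) is matched as a substring of a target beginning at the
#' cDNA 3'-end position; the match may extend through the 3' linker, and any
#' overhang beyond the fragment+linker must match the adapter prefix
#' (read-through). When `check_r2` is `TRUE`, R2 must equal the reverse
#' complement of the same insert (handle + fragment + linker, adapter-padded)
#' within the mismatch budget. A read matching more than one (target,
#' position) is `ambiguous`; ambiguous reads are discarded rather than
#' randomly assigned, so repeats cannot bias hazard estimates.
#'
#' @param reads Demultiplexed tibble from [demultiplex_by_handle()] (rows with
#'   `channel` `"unassigned"` are ignored).
#' @param targets Target tibble from [read_targets()] / [target_set()].
#' @param linker 3' linker sequence (default [shapeseq_linker()]).
#' @param adapter Adapter for read-through matching (default
#'   [shapeseq_adapter()]).
#' @param max_mismatches Per-mate Hamming mismatch budget (default 0, no
#'   indels).
#' @param check_r2 Verify mate consistency (default `TRUE` when `r2_seq` is
#'   present).
#' @return A tibble with one row per input read: `id`, `channel`, `status`
#'   (`aligned`, `unaligned`, `ambiguous`), `target`, `stop` (index `k = p -
#'   1`; 0 = full length; `NA` unless aligned).
#' @export
align_fragments <- function(reads, targets, linker = shapeseq_linker(),
                            adapter = shapeseq_adapter(),
                            max_mismatches = 0L, check_r2 = NULL) {
  if (nrow(targets) == 0) stop("empty target set", call. = FALSE)
  stopifnot(all(c("r1_seq", "channel") %in% names(reads)))
  if (is.null(check_r2)) {
    check_r2 <- "r2_seq" %in% names(reads) && !all(is.na(reads$r2_seq))
  }
  reads <- reads[reads$channel %in% c("plus", "minus"), , drop = FALSE]
  out <- tibble(
    id = if ("id" %in% names(reads)) reads$id else as.character(seq_len(nrow(reads))),
    channel = reads$channel,
    status = rep("unaligned", nrow(reads)),
    target = NA_character_,
    stop = NA_integer_
  )
  if (nrow(reads) == 0) return(out)

  adapter <- to_dna(toupper(adapter))
  cands <- lapply(targets$sequence, target_candidates, linker = linker)
  r1 <- to_dna(toupper(reads$r1_seq))

  uniq <- unique(r1)
  hit_target <- integer(length(uniq))   # 0 = none, -1 = ambiguous
  hit_p <- integer(length(uniq))
  ad_long <- cycle_to_length(adapter, max(nchar(r1), nchar(adapter)))

  for (u in seq_along(uniq)) {
    s <- uniq[[u]]
    ls <- nchar(s)
    nhit <- 0L
    for (ti in seq_along(cands)) {
      cc <- cands[[ti]]
      if (max_mismatches == 0L) {
        long <- cc$flen >= ls & substr(cc$frag, 1L, ls) == s
        short_idx <- which(cc$flen < ls & cc$frag == substring(s, 1L, cc$flen))
        short_ok <- short_idx[vapply(short_idx, function(r) {
          substr(s, cc$flen[r] + 1L, ls) == substr(ad_long, 1L, ls - cc$flen[r])
        }, logical(1))]
        ps <- c(cc$p[long], cc$p[short_ok])
      } else {
        ps <- cc$p[vapply(seq_len(nrow(cc)), function(r) {
          n1 <- min(ls, cc$flen[r])
          mm <- sum(charToRaw(substr(s, 1L, n1)) !=
                      charToRaw(substr(cc$frag[r], 1L, n1)))
          if (ls > n1) {
            mm <- mm + sum(charToRaw(substr(s, n1 + 1L, ls)) !=
                             charToRaw(substr(ad_long, 1L, ls - n1)))
          }
          mm <= max_mismatches
        }, logical(1))]
      }
      if (length(ps) > 0) {
        nhit <- nhit + length(ps)
        if (nhit == 1L) {
          hit_target[u] <- ti
          hit_p[u] <- ps[1]
        }
      }
      if (nhit > 1L) break
    }
    if (nhit > 1L) hit_target[u] <- -1L
  }

  m <- match(r1, uniq)
  ht <- hit_target[m]
  hp <- hit_p[m]
  out$status[ht == -1L] <- "ambiguous"
  ok <- which(ht > 0L)

  if (length(ok) > 0 && check_r2) {
    tseq <- to_dna(toupper(targets$sequence[ht[ok]]))
    L <- nchar(tseq)
    frag <- substring(tseq, hp[ok], L)
    handle <- if ("handle" %in% names(reads)) reads$handle[ok] else ""
    insert <- paste0(to_dna(toupper(handle)), frag, to_dna(toupper(linker)))
    rc <- revcomp_dna(insert)
    lr2 <- nchar(reads$r2_seq[ok])
    expected <- substring(paste0(rc, ad_long), 1L, lr2)
    obs <- to_dna(toupper(reads$r2_seq[ok]))
    if (max_mismatches == 0L) {
      consistent <- obs == expected
    } else {
      consistent <- vapply(seq_along(obs), function(i) {
        n <- min(nchar(obs[i]), nchar(expected[i]))
        sum(charToRaw(substr(obs[i], 1, n)) !=
              charToRaw(substr(expected[i], 1, n))) <= max_mismatches
      }, logical(1))
    }
    ok <- ok[consistent]
  }

  out$status[ok] <- "aligned"
  out$target[ok] <- targets$name[ht[ok]]
  out$stop[ok] <- hp[ok] - 1L
  out
}

#' Tally aligned stops into a per-position count vector
#'
#' @param alignments Tibble from [align_fragments()].
#' @param target Target name to tally.
#' @param channel `"plus"` or `"minus"`.
#' @param L Target length (defines the index range `0..L`; index 0 is the
#'   full-length read-through bin).
#' @return A tibble with columns `target`, `channel`, `index` (`0..L`) and
#'   `count`; `sum(count)` equals the number of aligned rows tallied.
#' @export
count_stops <- function(alignments, target, channel, L) {
  stopifnot(channel %in% c("plus", "minus"))
  keep <- alignments$status == "aligned" &
    alignments$target == target & alignments$channel == channel
  ks <- alignments$stop[keep]
  counts <- tabulate(ks + 1L, nbins = L + 1L)
  tibble(target = target, channel = channel, index = 0:L,
         count = as.integer(counts))
}

#' Combine per-channel stop tallies into the per-target count table
#'
#' @param alignments Tibble from [align_fragments()].
#' @param targets Target tibble.
#' @return A tibble with columns `target`, `index` (0..L per target),
#'   `plus_count`, `minus_count`.
#' @export
stop_count_table <- function(alignments, targets) {
  purrr::map2(targets$name, targets$length, function(nm, L) {
    p <- count_stops(alignments, nm, "plus", L)
    m <- count_stops(alignments, nm, "minus", L)
    tibble(target = nm, index = 0:L,
           plus_count = p$count, minus_count = m$count)
  }) |> bind_rows()
}

#' Run the full read-processing pipeline
#'
#' Demultiplexes by handle, aligns fragments (with adapter read-through and
#' mate-consistency handling) and tallies RT stops per target and channel.
#' Nothing is dropped silently: the `stats` component accounts every input
#' pair as plus/minus-aligned, unaligned, ambiguous or handle-unassigned.
#'
#' @param reads A read-pair tibble ([read_fastq_pairs()]), or set `r1_path` /
#'   `r2_path` to read FASTQ files.
#' @param targets Target tibble.
#' @param r1_path,r2_path Optional FASTQ paths used when `reads` is `NULL`.
#' @param plus_handle,minus_handle Channel handles (defaults RRRY / YYYR).
#' @param linker,adapter See [align_fragments()].
#' @param max_mismatches Per-mate mismatch budget (default 0).
#' @param min_mean_quality Optional minimum mean base quality (Phred) applied
#'   to both mates; `NULL` (default) disables quality filtering.
#' @return An object of class `shapeseq_run`: a list with `counts` (the
#'   per-target count table), `stats` (one-row accounting tibble) and
#'   `alignments`.
#' @export
process_read_pairs <- function(reads = NULL, targets,
                               r1_path = NULL, r2_path = NULL,
                               plus_handle = "RRRY", minus_handle = "YYYR",
                               linker = shapeseq_linker(),
                               adapter = shapeseq_adapter(),
                               max_mismatches = 0L,
                               min_mean_quality = NULL) {
  if (is.null(reads)) {
    if (is.null(r1_path) || is.null(r2_path)) {
      stop("provide either `reads` or both `r1_path` and `r2_path`",
           call. = FALSE)
    }
    reads <- read_fastq_pairs(r1_path, r2_path)
  }
  n_total <- nrow(reads)
  n_lowq <- 0L
  if (!is.null(min_mean_quality) && n_total > 0) {
    mq <- function(q) vapply(q, function(x) mean(utf8ToInt(x) - 33L), 0)
    keep <- mq(reads$r1_qual) >= min_mean_quality &
      mq(reads$r2_qual) >= min_mean_quality
    n_lowq <- sum(!keep)
    reads <- reads[keep, , drop = FALSE]
  }
  dm <- demultiplex_by_handle(reads, plus_handle, minus_handle)
  aln <- align_fragments(dm, targets, linker = linker, adapter = adapter,
                         max_mismatches = max_mismatches)
  counts <- stop_count_table(aln, targets)
  stats <- tibble(
    n_pairs = n_total,
    n_low_quality = n_lowq,
    n_unassigned = sum(dm$channel == "unassigned"),
    n_plus_assigned = sum(dm$channel == "plus"),
    n_minus_assigned = sum(dm$channel == "minus"),
    n_plus_aligned = sum(aln$status == "aligned" & aln$channel == "plus"),
    n_minus_aligned = sum(aln$status == "aligned" & aln$channel == "minus"),
    n_unaligned = sum(aln$status == "unaligned"),
    n_ambiguous = sum(aln$status == "ambiguous")
  )
  structure(list(counts = counts, stats = stats, alignments = aln),
            class = "shapeseq_run")
}

#' @export
print.shapeseq_run <- function(x, ...) {
  s <- x$stats
  cat("<shapeseq_run> ", s$n_pairs, " read pairs: ",
      s$n_plus_aligned, " (+) / ", s$n_minus_aligned, " (-) aligned, ",
      s$n_unaligned, " unaligned, ", s$n_ambiguous, " ambiguous, ",
      s$n_unassigned, " handle-unassigned\n", sep = "")
  invisible(x)
}

#' Write / read a per-target stop-count table (TSV)
#'
#' Columns: `target`, `index` (0 = full-length read-through), `plus_count`,
#' `minus_count`.
#'
#' @param counts Count table from [stop_count_table()].
#' @param path File path.
#' @return `path` (writer, invisibly) or the count tibble (reader).
#' @export
write_stop_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_stop_counts
#' @export
read_stop_counts <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
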