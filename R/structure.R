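#' RNA secondary structure as a canonical base-pair set
#'
#' A secondary structure is a set of base pairs `(i, j)`, `1 <= i < j <=
#' length`, with no nucleotide in more than one pair. Pairs are stored
#' canonically sorted; this is the common currency of the CT and dot-bracket
#' parsers and the sensitivity/PPV scorer.
#'
#' @param length Number of nucleotides.
#' @param pairs A two-column matrix or data frame of paired positions (any
#'   orientation; normalized to `i < j`), or `NULL` for an unpaired structure.
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(length, pairs = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 0)
  if (is.null(pairs) || NROW(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2)
  } else {
    pairs <- as.matrix(pairs)
  }
  dimnames(pairs) <- NULL
  storage.mode(pairs) <- "integer"
  i <- pmin(pairs[, 1], pairs[, 2])
  j <- pmax(pairs[, 1], pairs[, 2])
  if (any(i == j)) stop("a nucleotide cannot pair with itself", call. = FALSE)
  if (any(i < 1L) || any(j > length)) {
    stop("pair index out of range 1..", length, call. = FALSE)
  }
  idx <- c(i, j)
  if (anyDuplicated(idx)) {
    stop("nucleotide(s) ", paste(unique(idx[duplicated(idx)]), collapse = ", "),
         " appear in more than one pair", call. = FALSE)
  }
  ord <- order(i, j)
  structure(
    list(length = length,
         pairs = cbind(i = i[ord], j = j[ord], deparse.level = 0)),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> length", x$length, "with", nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) {
  paste0("rna_structure(", x$length, " nt, ", nrow(x$pairs), " pairs)")
}

#' @rdname rna_structure
#' @param x An `rna_structure`.
#' @param ... Unused.
#' @export
as_tibble.rna_structure <- function(x, ...) {
  tibble(i = as.integer(x$pairs[, 1]), j = as.integer(x$pairs[, 2]))
}

#' Parse a CT (connectivity table) structure file
#'
#' CT dialect: the first token of the header line is the length; each
#' following line has the nucleotide index in column 1 and the pairing partner
#' in column 5 (0 = unpaired). Columns beyond 5 are ignored. Asymmetric
#' pairing records (i says j but j does not say i) are a hard error.
#'
#' @param path Path to a CT file.
#' @return An [rna_structure()].
#' @export
parse_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty CT file: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  len <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(len) || len < 0) {
    stop("CT header does not start with a length: ", lines[1], call. = FALSE)
  }
  if (length(lines) < len + 1) {
    stop("CT file has fewer nucleotide lines (", length(lines) - 1,
         ") than header length ", len, call. = FALSE)
  }
  partner <- integer(len)
  for (r in seq_len(len)) {
    f <- strsplit(trimws(lines[r + 1]), "\\s+")[[1]]
    if (length(f) < 5) stop("CT line ", r + 1, " has fewer than 5 columns",
                            call. = FALSE)
    idx <- as.integer(f[1])
    p <- as.integer(f[5])
    if (is.na(idx) || idx != r) {
      stop("CT line ", r + 1, ": expected nucleotide index ", r, call. = FALSE)
    }
    if (is.na(p) || p < 0 || p > len) {
      stop("CT line ", r + 1, ": partner index ", f[5],
           " out of range 0..", len, call. = FALSE)
    }
    partner[r] <- p
  }
  for (r in seq_len(len)) {
    p <- partner[r]
    if (p != 0 && partner[p] != r) {
      stop("asymmetric pairing in CT: position ", r, " pairs to ", p,
           " but position ", p, " pairs to ", partner[p], call. = FALSE)
    }
  }
  ii <- which(partner > seq_len(len))
  rna_structure(len, cbind(ii, partner[ii]))
}

#' Write a structure to CT format
#'
#' @param structure An [rna_structure()].
#' @param path Output path.
#' @param sequence Optional nucleotide sequence (defaults to `N`s).
#' @param name Header comment.
#' @return `path`, invisibly.
#' @export
write_ct <- function(structure, path, sequence = NULL, name = "structure") {
  len <- structure$length
  if (is.null(sequence)) sequence <- strrep("N", len)
  if (nchar(sequence) != len) {
    stop("sequence length ", nchar(sequence), " does not match structure length ",
         len, call. = FALSE)
  }
  partner <- integer(len)
  if (nrow(structure$pairs) > 0) {
    partner[structure$pairs[, 1]] <- structure$pairs[, 2]
    partner[structure$pairs[, 2]] <- structure$pairs[, 1]
  }
  base <- strsplit(sequence, "")[[1]]
  lines <- c(
    paste(len, name),
    sprintf("%d %s %d %d %d %d",
            seq_len(len), base, seq_len(len) - 1L,
            ifelse(seq_len(len) == len, 0L, seq_len(len) + 1L),
            partner, seq_len(len))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a dot-bracket structure string
#'
#' Nested pairs only: the alphabet is `.`, `(` and `)`. Pseudoknot bracket
#' tiers (`[]`, `{}`, letters) are rejected rather than silently dropped,
#' since dropping pairs would corrupt downstream PPV.
#'
#' @param text A dot-bracket string.
#' @return An [rna_structure()].
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad) > 0) {
    stop("unsupported character '", chars[bad[1]], "' at position ", bad[1],
         " (pseudoknot tiers are not supported)", call. = FALSE)
  }
  stack <- integer(0)
  pairs <- list()
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch == "(") {
      stack <- c(stack, pos)
    } else if (ch == ")") {
      if (length(stack) == 0) {
        stop("unbalanced ')' at position ", pos, call. = FALSE)
      }
      pairs[[length(pairs) + 1]] <- c(stack[length(stack)], pos)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) {
    stop("unbalanced '(' at position ", stack[1], call. = FALSE)
  }
  rna_structure(length(chars), do.call(rbind, pairs))
}
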