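# Internal string / alphabet helpers shared across modules.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T", U = "U",
  R = "AG", Y = "CTU", S = "CG", W = "ATU", K = "GTU", M = "AC",
  B = "CGTU", D = "AGTU", H = "ACTU", V = "ACG", N = "ACGTU"
)

# DNA-alphabet canonical form (U -> T), used for all read/target matching
to_dna <- function(x) chartr("Uu", "Tt", x)

# RNA-alphabet canonical form (T -> U)
to_rna <- function(x) chartr("Tt", "Uu", x)

# Vectorized reverse complement of plain character DNA strings.
revcomp_dna <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# Number of mismatching characters between equal-length strings a and b.
str_mismatch <- function(a, b) {
  stopifnot(length(a) == length(b))
  vapply(seq_along(a), function(i) {
    ra <- charToRaw(a[[i]])
    rb <- charToRaw(b[[i]])
    if (length(ra) != length(rb)) {
      stop("str_mismatch() requires equal-length strings", call. = FALSE)
    }
    sum(ra != rb)
  }, integer(1))
}

# Repeat `x` until it is at least `len` characters, then truncate.
cycle_to_length <- function(x, len) {
  if (nchar(x) == 0L) return(strrep("N", len))
  substr(strrep(x, ceiling(len / nchar(x))), 1L, len)
}

# Regular expression character class for one IUPAC degenerate base
# (DNA-space: U folded onto T).
iupac_class <- function(code) {
  code <- toupper(code)
  if (!code %in% names(IUPAC_CODES)) {
    stop("unknown IUPAC code: ", code, call. = FALSE)
  }
  chars <- unique(to_dna(strsplit(IUPAC_CODES[[code]], "")[[1]]))
  paste0("[", paste(chars, collapse = ""), "]")
}

# TRUE where the first nchar(handle) bases of `seqs` match the degenerate
# `handle` under IUPAC semantics.
iupac_prefix_match <- function(seqs, handle) {
  pat <- paste0(
    "^",
    paste(vapply(strsplit(toupper(handle), "")[[1]], iupac_class, ""),
          collapse = "")
  )
  grepl(pat, to_dna(toupper(seqs)))
}

# Sample one concrete instantiation per row for a degenerate handle.
sample_degenerate <- function(handle, n) {
  letters_by_pos <- lapply(strsplit(toupper(handle), "")[[1]], function(code) {
    unique(to_dna(strsplit(IUPAC_CODES[[code]], "")[[1]]))
  })
  cols <- lapply(letters_by_pos, function(ch) {
    if (length(ch) == 1L) rep(ch, n) else sample(ch, n, replace = TRUE)
  })
  do.call(paste0, cols)
}
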