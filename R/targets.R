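#' Read target RNA sequences from a FASTA file
#'
#' Targets define the coordinate frame for every downstream count: position 1
#' is the RNA 5' end, position `L` the 3'-terminal nucleotide adjacent to the
#' ligated linker. Sequences are uppercased and a canonical RNA-alphabet form
#' (`T` read as `U`) is kept alongside the original, so DNA templates and RNA
#' products are interchangeable inputs.
#'
#' @param path Path to a FASTA file with one record per target.
#' @return A tibble with one row per target and columns `name`, `sequence`
#'   (uppercased original), `seq_rna` (canonical RNA alphabet) and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "GGAACC"), fa)
#' read_targets(fa)
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  target_set(nm, seqs)
}

#' Construct a validated target set
#'
#' @param name Character vector of unique target names.
#' @param sequence Nucleotide sequences over the IUPAC alphabet (T and U
#'   equivalent).
#' @return A tibble as in [read_targets()].
#' @export
target_set <- function(name, sequence) {
  name <- unname(as.character(name))
  sequence <- unname(toupper(sequence))
  if (anyDuplicated(name)) {
    stop("duplicate target name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for target(s): ",
         paste(name[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(sequence)) {
    bad <- regmatches(sequence[i],
                      regexpr(paste0("[^", paste(names(IUPAC_CODES), collapse = ""), "]"),
                              sequence[i]))
    if (length(bad) > 0) {
      off <- regexpr(paste0("[^", paste(names(IUPAC_CODES), collapse = ""), "]"),
                     sequence[i])
      stop("non-nucleotide character '", bad, "' in target '", name[i],
           "' at offset ", as.integer(off), call. = FALSE)
    }
  }
  tibble(
    name = as.character(name),
    sequence = sequence,
    seq_rna = to_rna(sequence),
    length = nchar(sequence)
  )
}
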