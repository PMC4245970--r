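# Generative simulator of the two-channel RT-stop experiment, from model
# parameters down to paired FASTQ files.

#' A deterministic structured theta profile for simulations
#'
#' Emulates the mixture of near-zero (paired/protected) and high (flexible)
#' reactivities seen in real probing spectra: evenly spaced reactive sites on
#' a low background, with the 3'-terminal position fixed at zero (a
#' modification there yields a fragment with no alignable target nucleotide,
#' so it is unobservable by construction).
#'
#' @param L RNA length.
#' @param every Spacing of reactive sites (default 5).
#' @param contrast Ratio of reactive-site to background weight (default 15).
#' @return A numeric theta vector of length `L` summing to 1.
#' @export
structured_theta <- function(L, every = 5L, contrast = 15) {
  stopifnot(L >= 2)
  w <- rep(1, L)
  hot <- seq(3L, L - 1L, by = every)
  w[hot] <- contrast
  w[L] <- 0
  w / sum(w)
}

#' Simulation parameters for a synthetic two-channel experiment
#'
#' Defaults mirror a typical bench setup: RRRY/YYYR channel handles, the
#' standard 18-nt 3' linker, 35-nt reads, half of the (+)-channel molecules
#' carrying one adduct (single-hit regime), and error-free sequencing.
#'
#' @param target One-row target tibble ([target_set()] / [read_targets()]).
#' @param theta Ground-truth modification distribution (default
#'   [structured_theta()] for the target length).
#' @param gamma Natural drop-off hazards in `[0, 1)` (default uniform 0.02).
#' @param p_mod Probability a (+) molecule is modified (default 0.5).
#' @param n_plus,n_minus Molecules per channel.
#' @param read_len Read length in bases (default 35).
#' @param plus_handle,minus_handle Degenerate channel handles.
#' @param linker 3' linker (default [shapeseq_linker()]).
#' @param adapter Adapter appended as read-through filler (default
#'   [shapeseq_adapter()]).
#' @param error_rate Per-base substitution probability in `[0, 0.1]`
#'   (default 0).
#' @param seed Integer seed driving all randomness (default 42).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(target, theta = NULL, gamma = NULL, p_mod = 0.5,
                       n_plus = 10000L, n_minus = 10000L, read_len = 35L,
                       plus_handle = "RRRY", minus_handle = "YYYR",
                       linker = shapeseq_linker(),
                       adapter = shapeseq_adapter(),
                       error_rate = 0, seed = 42L) {
  stopifnot(is.data.frame(target), nrow(target) == 1)
  L <- target$length
  theta <- theta %||% structured_theta(L)
  gamma <- gamma %||% rep(0.02, L)
  model <- dropoff_model(theta, gamma, p_mod)
  stopifnot(n_plus > 0, n_minus > 0)
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must lie in [0, 0.1]", call. = FALSE)
  }
  if (read_len <= nchar(plus_handle)) {
    stop("read_len must exceed the handle length", call. = FALSE)
  }
  structure(
    list(target = target, model = model,
         n_plus = as.integer(n_plus), n_minus = as.integer(n_minus),
         read_len = as.integer(read_len),
         plus_handle = plus_handle, minus_handle = minus_handle,
         linker = linker, adapter = adapter,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Simulate per-channel RT-stop counts
#'
#' Each (-) molecule walks positions `L..1`, stopping at `k` with hazard
#' `gamma_k` given arrival, else reading through to full length (`k = 0`);
#' each (+) molecule first draws whether it is modified (probability
#' `p_mod`) and a site from theta, then stops at natural drop-off or with
#' certainty upon reaching the adduct. Channel counts are drawn in one
#' multinomial step from the implied stop distribution, which is
#' distributionally identical to the per-molecule walk and exactly
#' reproducible under the seed.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `shapeseq_sim`: `counts` (tibble `index`,
#'   `plus_count`, `minus_count`), `truth` (tibble `index`, `theta_true`,
#'   `gamma`), and `params`.
#' @export
simulate_stop_counts <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  pr <- dropoff_stop_probs(params$model)
  plus <- as.integer(rmultinom(1, params$n_plus, pr$plus))
  minus <- as.integer(rmultinom(1, params$n_minus, pr$minus))
  L <- params$model$L
  structure(
    list(
      counts = tibble(index = 0:L, plus_count = plus, minus_count = minus),
      truth = tibble(index = seq_len(L),
                     theta_true = params$model$theta,
                     gamma = params$model$gamma),
      params = params
    ),
    class = "shapeseq_sim"
  )
}

#' @export
print.shapeseq_sim <- function(x, ...) {
  cat("<shapeseq_sim> target '", x$params$target$name, "' (L = ",
      x$params$model$L, "): ", sum(x$counts$plus_count), " (+) / ",
      sum(x$counts$minus_count), " (-) molecules, seed ", x$params$seed,
      "\n", sep = "")
  invisible(x)
}

# Apply iid substitution errors to DNA strings.
apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  alphabet <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < error_rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(alphabet, b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Emit simulated paired FASTQ files
#'
#' For every simulated molecule the cDNA insert is built as `handle +
#' target[k+1..L] + linker` (a stop at `k = L` contributes a linker-only
#' insert). R1 reads the insert from the handle side, R2 is the reverse
#' complement read from the linker side; when the insert is shorter than
#' `read_len` both mates run through into the adapter sequence. Substitution
#' errors are applied at `error_rate`; qualities are uniform. Identical
#' parameters (including the seed) produce byte-identical files.
#'
#' @param sim A `shapeseq_sim` from [simulate_stop_counts()].
#' @param r1_path,r2_path Output FASTQ paths.
#' @param truth_path,params_path Optional paths for a tab-separated truth
#'   sidecar (`index`, `theta_true`, `gamma`) and a parameters echo file.
#' @return Invisibly, a list with the emitted paths and the number of read
#'   pairs written (`n = n_plus + n_minus`).
#' @export
emit_fastq <- function(sim, r1_path, r2_path, truth_path = NULL,
                       params_path = NULL) {
  stopifnot(inherits(sim, "shapeseq_sim"))
  params <- sim$params
  L <- params$model$L
  tseq <- to_dna(toupper(params$target$sequence))
  linker <- to_dna(toupper(params$linker))
  adapter <- to_dna(toupper(params$adapter))
  read_len <- params$read_len

  # derived stream: simulate_stop_counts() consumed the seed itself
  set.seed((params$seed %% 2000000000L) + 1L)

  build_channel <- function(counts, handle, tag) {
    ks <- rep(sim$counts$index, counts)
    n <- length(ks)
    if (n == 0) {
      return(tibble(id = character(0), r1 = character(0), r2 = character(0)))
    }
    handles <- sample_degenerate(handle, n)
    frag <- substring(tseq, ks + 1L, L)
    insert <- paste0(handles, frag, linker)
    pad_len <- read_len # longest possible read-through fill
    ad <- cycle_to_length(adapter, pad_len)
    r1 <- substr(paste0(insert, ad), 1L, read_len)
    r2 <- substr(paste0(revcomp_dna(insert), ad), 1L, read_len)
    r1 <- apply_substitutions(r1, params$error_rate)
    r2 <- apply_substitutions(r2, params$error_rate)
    tibble(id = sprintf("%s_%s_%06d", params$target$name, tag, seq_len(n)),
           r1 = r1, r2 = r2)
  }

  reads <- bind_rows(
    build_channel(sim$counts$plus_count, params$plus_handle, "plus"),
    build_channel(sim$counts$minus_count, params$minus_handle, "minus")
  )

  qual <- strrep("I", read_len)
  write_mate <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::PhredQuality(rep(qual, length(x)))
    qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(x, q))
    Biostrings::writeQualityScaledXStringSet(qs, path)
  }
  write_mate(reads$r1, reads$id, r1_path)
  write_mate(reads$r2, reads$id, r2_path)

  if (!is.null(truth_path)) {
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(params_path)) {
    p <- params
    writeLines(c(
      paste0("target\t", p$target$name),
      paste0("L\t", L),
      paste0("n_plus\t", p$n_plus),
      paste0("n_minus\t", p$n_minus),
      paste0("p_mod\t", p$model$p_mod),
      paste0("read_len\t", p$read_len),
      paste0("plus_handle\t", p$plus_handle),
      paste0("minus_handle\t", p$minus_handle),
      paste0("linker\t", p$linker),
      paste0("adapter\t", p$adapter),
      paste0("error_rate\t", p$error_rate),
      paste0("seed\t", p$seed)
    ), params_path)
  }
  invisible(list(r1 = r1_path, r2 = r2_path, n = nrow(reads)))
}
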