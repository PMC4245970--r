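# Folding constraints and structure scoring.

#' Slope/intercept parameter presets for pseudo-free-energy constraints
#'
#' Two presets are provided: `"shapeseq"` (`m = 1.1`, `b = -0.3`), tuned for
#' length-rescaled rho reactivities, and `"shape"` (`m = 1.8`, `b = -0.6`),
#' the parameters commonly recommended for traditional SHAPE reactivity
#' scales.
#'
#' @param m Slope (kcal/mol).
#' @param b Intercept (kcal/mol).
#' @param preset Optional preset name overriding `m` and `b`.
#' @return A list with elements `m` and `b`.
#' @export
fold_params <- function(m = 1.1, b = -0.3, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("shapeseq", "shape"))
    if (preset == "shapeseq") { m <- 1.1; b <- -0.3 }
    if (preset == "shape") { m <- 1.8; b <- -0.6 }
  }
  stopifnot(is.finite(m), is.finite(b))
  list(m = m, b = b)
}

#' Rescale theta to rho reactivities
#'
#' `rho_i = L' * theta_i`, where `L'` is the number of scored positions, so
#' that the mean rho over the scored range is exactly 1. This puts the
#' probability-scale theta onto the familiar SHAPE reactivity scale consumed
#' by folding engines.
#'
#' @param x A non-degenerate `reactivity_profile`, or a numeric theta vector
#'   summing to 1.
#' @return A numeric rho vector (named by position for a profile input).
#' @export
theta_to_rho <- function(x) {
  if (inherits(x, "reactivity_profile")) {
    if (x$degenerate) {
      stop("degenerate profile: no modification signal, so rho and folding ",
           "constraints cannot be generated", call. = FALSE)
    }
    theta <- x$data$theta[x$data$scored]
    return(setNames(length(theta) * theta, x$scored))
  }
  theta <- as.numeric(x)
  if (any(theta < 0) || abs(sum(theta) - 1) > 1e-8) {
    stop("theta must be a non-negative vector summing to 1", call. = FALSE)
  }
  length(theta) * theta
}

#' Per-position pseudo-free-energy bonus from rho reactivities
#'
#' `dG_i = m * ln(rho_i + 1) + b` (natural logarithm, kcal/mol): an energetic
#' penalty for pairing reactive (flexible) nucleotides, added by SHAPE-aware
#' folding engines during the minimum-free-energy recursion. Monotone
#' increasing in rho for `m > 0`.
#'
#' @param rho Non-negative reactivity vector.
#' @param params A [fold_params()] list.
#' @return Numeric vector of energies (kcal/mol).
#' @export
pseudo_free_energy <- function(rho, params = fold_params()) {
  if (any(rho < 0, na.rm = TRUE)) {
    stop("rho must be non-negative", call. = FALSE)
  }
  params$m * log(rho + 1) + params$b
}

#' Write a SHAPE constraint file
#'
#' Two-column text: 1-based nucleotide index and reactivity, one line per
#' nucleotide of the RNA; positions without data (outside the scored range)
#' carry the conventional no-data sentinel `-999`. The format is the one
#' SHAPE-aware folding engines read via their reactivity-file option.
#'
#' @param x A non-degenerate `reactivity_profile`, or a numeric rho vector
#'   for the scored positions.
#' @param path Output path.
#' @param scored_positions 1-based positions `x` refers to (defaults to the
#'   profile's scored range).
#' @param length Total RNA length (defaults to the profile's `L`).
#' @return `path`, invisibly.
#' @export
write_shape_constraints <- function(x, path, scored_positions = NULL,
                                    length = NULL) {
  if (inherits(x, "reactivity_profile")) {
    rho <- unname(theta_to_rho(x))
    scored_positions <- scored_positions %||% x$scored
    length <- length %||% x$L
  } else {
    rho <- as.numeric(x)
    if (is.null(scored_positions) || is.null(length)) {
      stop("`scored_positions` and `length` are required for a bare rho ",
           "vector", call. = FALSE)
    }
  }
  stopifnot(length(rho) == length(scored_positions), all(is.finite(rho)))
  vals <- rep(-999, length)
  vals[scored_positions] <- rho
  writeLines(sprintf("%d\t%.8g", seq_len(length), vals), path)
  invisible(path)
}

#' @rdname write_shape_constraints
#' @return For the reader: a tibble with columns `index` and `reactivity`
#'   (`NA` where the file carries the -999 sentinel).
#' @export
read_shape_constraints <- function(path) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("index", "reactivity"))
  d$reactivity[d$reactivity <= -998] <- NA_real_
  as_tibble(d)
}

# Maximum bipartite matching between predicted and accepted pairs under the
# slippage adjacency (Kuhn's augmenting-path algorithm; inputs are small).
max_matching_size <- function(adj, n_right) {
  match_right <- rep(0L, n_right)
  try_kuhn <- function(u, seen) {
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        if (match_right[v] == 0L || Recall(match_right[v], seen)) {
          match_right[v] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (u in seq_along(adj)) {
    if (try_kuhn(u, rep(FALSE, n_right))) size <- size + 1L
  }
  size
}

#' Sensitivity and PPV of a predicted structure against an accepted one
#'
#' Sensitivity is the fraction of accepted (e.g. crystallographic) base pairs
#' that are predicted; PPV (positive predictive value) is the fraction of
#' predicted pairs that are correct. With `slippage` on (the default,
#' mirroring the behaviour of common structure scorers), a predicted pair
#' `(i, j)` may be credited by an accepted pair `(i, j)`, `(i±1, j)` or
#' `(i, j±1)`, each accepted pair creditable at most once (a maximum
#' bipartite matching). Numerator and denominator are reported as integers so
#' scores are auditable as fractions.
#'
#' @param predicted,accepted [rna_structure()] objects of the same length.
#' @param slippage Allow one-position slippage credit (default `TRUE`).
#' @return A one-row tibble: `sensitivity`, `sens_num`, `sens_den`, `ppv`,
#'   `ppv_num`, `ppv_den`, `slippage`. An empty accepted (resp. predicted)
#'   structure yields `NA` sensitivity (resp. PPV), not 0 or 1.
#' @export
sensitivity_ppv <- function(predicted, accepted, slippage = TRUE) {
  stopifnot(inherits(predicted, "rna_structure"),
            inherits(accepted, "rna_structure"))
  if (predicted$length != accepted$length) {
    stop("structures have different lengths (", predicted$length, " vs ",
         accepted$length, ")", call. = FALSE)
  }
  P <- predicted$pairs
  A <- accepted$pairs
  np <- nrow(P)
  na_ <- nrow(A)
  if (np == 0L || na_ == 0L) {
    correct <- 0L
  } else if (!slippage) {
    key <- function(m) paste(m[, 1], m[, 2])
    correct <- sum(key(P) %in% key(A))
  } else {
    adj <- lapply(seq_len(np), function(u) {
      which(
        (abs(A[, 1] - P[u, 1]) <= 1L & A[, 2] == P[u, 2]) |
          (A[, 1] == P[u, 1] & abs(A[, 2] - P[u, 2]) <= 1L)
      )
    })
    correct <- max_matching_size(adj, na_)
  }
  tibble(
    sensitivity = if (na_ > 0) correct / na_ else NA_real_,
    sens_num = correct, sens_den = na_,
    ppv = if (np > 0) correct / np else NA_real_,
    ppv_num = correct, ppv_den = np,
    slippage = slippage
  )
}
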