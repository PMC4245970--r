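# Reactivity model: maximum-likelihood correction of RT drop-off.
#
# Generative model ("single-hit" regime). RT processes positions L, L-1, ..,
# 1 in order. In the (-) channel it terminates at position k with natural
# drop-off hazard gamma_k given that it reached k; a molecule surviving all
# positions is a full-length read-through (k = 0). In the (+) channel a
# molecule carries at most one adduct: with probability p_mod it is modified
# at a site s drawn from the distribution theta, and RT stops with certainty
# upon reaching s (natural drop-off still applies at every position before
# that). theta is the quantity of interest: the probability that each
# nucleotide is the modified one, summing to 1 over the RNA.

#' Construct a two-channel RT drop-off model
#'
#' @param theta Modification-position distribution over positions `1..L`
#'   (non-negative, sums to 1).
#' @param gamma Natural drop-off hazards, each in `[0, 1)`, length `L`.
#' @param p_mod Probability that a (+)-channel molecule carries a
#'   modification.
#' @return An object of class `dropoff_model`.
#' @export
dropoff_model <- function(theta, gamma, p_mod) {
  L <- length(theta)
  stopifnot(length(gamma) == L, L >= 1)
  if (any(theta < 0) || abs(sum(theta) - 1) > 1e-8) {
    stop("theta must be a probability distribution over 1..L", call. = FALSE)
  }
  if (any(gamma < 0) || any(gamma >= 1)) {
    stop("gamma hazards must lie in [0, 1)", call. = FALSE)
  }
  if (p_mod < 0 || p_mod > 1) stop("p_mod must lie in [0, 1]", call. = FALSE)
  structure(list(L = L, theta = as.numeric(theta), gamma = as.numeric(gamma),
                 p_mod = as.numeric(p_mod)),
            class = "dropoff_model")
}

# Per-stop-index probabilities (index 0..L) in each channel.
dropoff_stop_probs <- function(model) {
  L <- model$L
  g <- model$gamma
  th <- model$theta
  p <- model$p_mod
  # SG[k] = P(no natural drop-off at any of positions k..L)
  SG <- rev(cumprod(rev(1 - g)))
  SG <- c(SG, 1) # SG[L + 1] = 1
  p_minus <- c(SG[1], g * SG[seq_len(L) + 1L])
  cum_below <- c(0, cumsum(th))[seq_len(L)] # sum_{s < k} theta_s
  p_plus_k <- SG[seq_len(L) + 1L] * (p * th + (1 - p + p * cum_below) * g)
  p_plus <- c((1 - p) * SG[1], p_plus_k)
  list(plus = p_plus, minus = p_minus)
}

#' Log-likelihood of observed stop counts under a drop-off model
#'
#' @param model A [dropoff_model()].
#' @param plus,minus Integer count vectors indexed `0..L` (position 1 of the
#'   vector is the full-length bin `k = 0`).
#' @return The log-likelihood. If any observed count sits at a position with
#'   model probability zero the result is `-Inf`, with the offending
#'   positions reported in the `"impossible"` attribute as a tibble.
#' @export
dropoff_loglik <- function(model, plus, minus) {
  L <- model$L
  if (length(plus) != L + 1 || length(minus) != L + 1) {
    stop("count vectors must have length L + 1 = ", L + 1, call. = FALSE)
  }
  pr <- dropoff_stop_probs(model)
  term <- function(counts, probs) {
    use <- counts > 0
    bad <- use & probs <= 0
    list(ll = sum(counts[use & !bad] * log(probs[use & !bad])),
         bad = which(bad) - 1L)
  }
  tm <- term(minus, pr$minus)
  tp <- term(plus, pr$plus)
  impossible <- bind_rows(
    tibble(channel = "minus", index = tm$bad),
    tibble(channel = "plus", index = tp$bad)
  )
  if (nrow(impossible) > 0) {
    return(structure(-Inf, impossible = impossible))
  }
  tm$ll + tp$ll
}

#' Estimate the modification distribution theta from two-channel stop counts
#'
#' Closed-form maximum-likelihood estimate under the single-hit drop-off
#' model. Per position the (-)-channel hazard `beta_k = Y_k / sum(Y_0..Y_k)`
#' (the fraction of control molecules reaching `k` that stop there) is
#' profiled as the natural drop-off estimate; the (+)-channel hazard
#' `alpha_k` is computed the same way, and the modification hazard is `r_k =
#' (alpha_k - beta_k) / (1 - beta_k)`, clamped below at zero (sampling noise
#' can push `alpha_k` under `beta_k`; the unclamped value is kept in the
#' diagnostics). The MLE of theta then factorizes through the survival
#' product of the modification hazards:
#' `theta_k` is proportional to `r_k * prod(1 - r_j)` over positions `j > k`,
#' normalized to sum to 1 over the scored range. The absolute modification
#' rate `p_mod` is a nuisance parameter: its MLE `1 - prod(1 - r_j)` is
#' reported in the diagnostics but theta itself is the conditional
#' distribution of the modification position.
#'
#' By default the 3'-terminal position `k = L` is excluded from scoring
#' (`exclude_3prime = TRUE`): a stop there corresponds to a fragment with no
#' alignable target nucleotide, so the scored length is `L' = L - 1`.
#'
#' @param counts A count table with columns `index` (`0..L`; 0 = full-length
#'   read-through), `plus_count`, `minus_count` — as produced by
#'   [stop_count_table()], [simulate_stop_counts()] or [read_stop_counts()].
#' @param target Optional one-row target tibble used to annotate nucleotides.
#' @param exclude_3prime Exclude position `L` from the scored range (default
#'   `TRUE`).
#' @return An object of class `reactivity_profile`; see [tidy()] /
#'   [glance()] methods. If every position carries zero modification signal
#'   the profile is degenerate: theta is all zero and `degenerate` is `TRUE`
#'   (not an error).
#' @export
estimate_theta <- function(counts, target = NULL, exclude_3prime = TRUE) {
  stopifnot(is.data.frame(counts),
            all(c("index", "plus_count", "minus_count") %in% names(counts)))
  counts <- arrange(counts, .data$index)
  L <- max(counts$index)
  if (!identical(as.integer(counts$index), 0:L)) {
    stop("`counts$index` must be the complete range 0..L", call. = FALSE)
  }
  X <- as.numeric(counts$plus_count)
  Y <- as.numeric(counts$minus_count)
  if (any(X < 0) || any(Y < 0)) stop("negative counts", call. = FALSE)
  if (sum(X) <= 0 || sum(Y) <= 0) {
    stop("both channels must contain at least one fragment", call. = FALSE)
  }
  n_scored <- L - as.integer(isTRUE(exclude_3prime))
  if (n_scored < 1) stop("no scorable positions (L too small)", call. = FALSE)
  scored <- seq_len(n_scored)

  reach_plus <- cumsum(X)   # molecules reaching position k: stops in 0..k
  reach_minus <- cumsum(Y)
  k <- seq_len(L)
  alpha <- ifelse(reach_plus[k + 1L] > 0, X[k + 1L] / reach_plus[k + 1L], NA)
  beta <- ifelse(reach_minus[k + 1L] > 0, Y[k + 1L] / reach_minus[k + 1L], NA)

  unestimable <- is.na(alpha) | is.na(beta)
  saturated <- !is.na(beta) & beta >= 1
  r_raw <- ifelse(unestimable | saturated, NA,
                  (alpha - beta) / (1 - beta))
  r <- ifelse(is.na(r_raw), 0, pmax(r_raw, 0))
  clamped <- !is.na(r_raw) & r_raw < 0

  # survival product of modification hazards over positions 3' of k
  surv <- rev(cumprod(rev(1 - r)))       # surv[k] = prod_{j >= k} (1 - r_j)
  surv <- c(surv[-1], 1)                 # now prod_{j > k} (1 - r_j)
  theta_raw <- r * surv
  theta_raw[unestimable | saturated] <- 0

  tot <- sum(theta_raw[scored])
  degenerate <- tot <= 0
  theta <- numeric(L)
  if (!degenerate) {
    theta[scored] <- theta_raw[scored] / tot
    stopifnot(abs(sum(theta[scored]) - 1) <= 1e-9)
  }
  rho <- if (degenerate) rep(NA_real_, L) else {
    out <- rep(NA_real_, L)
    out[scored] <- n_scored * theta[scored]
    out
  }

  flag <- rep("", L)
  flag[clamped] <- "clamped"
  flag[saturated] <- "saturated_control"
  flag[unestimable] <- "unestimable"

  nucleotide <- rep(NA_character_, L)
  target_name <- NA_character_
  if (!is.null(target)) {
    stopifnot(is.data.frame(target), nrow(target) == 1)
    if (target$length != L) {
      stop("target length ", target$length, " does not match counts (L = ",
           L, ")", call. = FALSE)
    }
    nucleotide <- strsplit(target$seq_rna, "")[[1]]
    target_name <- target$name
  }

  data <- tibble(
    index = k, nucleotide = nucleotide,
    theta = if (degenerate) rep(0, L) else theta,
    rho = rho, alpha = alpha, beta = beta, r_raw = r_raw, r_clamped = r,
    scored = k %in% scored, flag = flag
  )
  structure(
    list(target = target_name, data = data, L = L, scored = scored,
         degenerate = degenerate,
         p_mod_hat = if (degenerate) 0 else 1 - prod(1 - r),
         n_plus = sum(X), n_minus = sum(Y),
         exclude_3prime = isTRUE(exclude_3prime)),
    class = "reactivity_profile"
  )
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat("<reactivity_profile>",
      if (!is.na(x$target)) paste0("target '", x$target, "',") else "",
      "L =", x$L, "(", length(x$scored), "scored )\n")
  if (x$degenerate) {
    cat("  degenerate: no modification signal above the control channel\n")
  } else {
    cat("  sum(theta) =", sum(x$data$theta[x$data$scored]),
        "; p_mod_hat =", signif(x$p_mod_hat, 4), "\n")
  }
  invisible(x)
}

#' Tidy a reactivity profile into a per-position tibble
#'
#' @param x A `reactivity_profile`.
#' @param ... Unused.
#' @return A tibble with one row per position `1..L`: `index`, `nucleotide`,
#'   `theta`, `rho`, the raw per-channel hazards `alpha` and `beta`, the
#'   unclamped modification hazard `r_raw`, `scored` and `flag`.
#' @export
tidy.reactivity_profile <- function(x, ...) x$data

#' @rdname tidy.reactivity_profile
#' @return For `glance()`: a one-row summary tibble.
#' @export
glance.reactivity_profile <- function(x, ...) {
  tibble(
    target = x$target, L = x$L, n_scored = length(x$scored),
    n_plus = x$n_plus, n_minus = x$n_minus,
    p_mod_hat = x$p_mod_hat, degenerate = x$degenerate
  )
}

#' Plot a reactivity profile
#'
#' @param object A `reactivity_profile`.
#' @param scale Plot `"theta"` (default) or `"rho"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reactivity_profile <- function(object, scale = c("theta", "rho"),
                                        ...) {
  scale <- match.arg(scale)
  d <- filter(object$data, .data$scored)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data[[scale]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "nucleotide position",
      y = if (scale == "theta") expression(theta[i]) else expression(rho[i]),
      title = if (!is.na(object$target)) object$target else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Write / read a per-target reactivity table (TSV)
#'
#' Columns: `index`, `nucleotide`, `theta`, `rho`, `flag`.
#'
#' @param profile A `reactivity_profile`.
#' @param path File path.
#' @export
write_reactivity <- function(profile, path) {
  d <- select(profile$data, "index", "nucleotide", "theta", "rho", "flag")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reactivity
#' @export
read_reactivity <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
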