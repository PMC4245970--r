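# Independent oracles used to pin the implementation to the generative model.
# Everything here is written from the model description directly (enumeration
# over adduct sites, generic numeric optimization, exhaustive matching) and
# shares no code path with the package internals it checks.

# Stop-probability vectors (index 0..L) by direct enumeration over the adduct
# site s: a molecule with adduct at s stops at k > s by natural drop-off, at
# k = s with certainty on arrival, never at k < s.
oracle_stop_probs <- function(theta, gamma, p_mod) {
  L <- length(theta)
  surv <- function(k) { # P(no natural drop-off at positions k..L)
    if (k > L) 1 else prod(1 - gamma[k:L])
  }
  p_stop_given_s <- function(k, s) {
    if (k > s) gamma[k] * surv(k + 1) else if (k == s) surv(s + 1) else 0
  }
  p_minus <- c(surv(1), vapply(1:L, function(k) gamma[k] * surv(k + 1), 0))
  p_plus <- numeric(L + 1)
  p_plus[1] <- (1 - p_mod) * surv(1)
  for (k in 1:L) {
    p_plus[k + 1] <- (1 - p_mod) * gamma[k] * surv(k + 1) +
      sum(vapply(1:L, function(s) {
        p_mod * theta[s] * p_stop_given_s(k, s)
      }, 0))
  }
  list(plus = p_plus, minus = p_minus)
}

oracle_loglik <- function(theta, gamma, p_mod, plus, minus) {
  pr <- oracle_stop_probs(theta, gamma, p_mod)
  term <- function(counts, probs) {
    use <- counts > 0
    if (any(use & probs <= 0)) return(-Inf)
    sum(counts[use] * log(probs[use]))
  }
  term(minus, pr$minus) + term(plus, pr$plus)
}

# Numeric maximum-likelihood estimate of theta with gamma profiled from the
# (-) channel (its hazard MLE) and p_mod free: coarse grid over the theta
# simplex and p_mod, followed by Nelder-Mead refinement of the best grid
# points in (logit p_mod, softmax theta) coordinates.
oracle_mle_theta <- function(plus, minus, grid_step = 6L, n_refine = 6L) {
  L <- length(plus) - 1
  reach_minus <- cumsum(minus)
  gamma_hat <- minus[-1] / reach_minus[-1]
  stopifnot(all(is.finite(gamma_hat)), all(gamma_hat < 1))
  softmax <- function(w) { e <- exp(c(0, w)); e / sum(e) }
  nll <- function(par) {
    p <- stats::plogis(par[1])
    th <- softmax(par[-1])
    -oracle_loglik(th, gamma_hat, p, plus, minus)
  }
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, ncol = 1))
    do.call(rbind, lapply(0:total, function(first) {
      cbind(first, compositions(total - first, parts - 1))
    }))
  }
  thetas <- compositions(grid_step, L) / grid_step
  dimnames(thetas) <- NULL
  ps <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  grid <- expand.grid(row = seq_len(nrow(thetas)), p = ps)
  grid$ll <- vapply(seq_len(nrow(grid)), function(g) {
    oracle_loglik(thetas[grid$row[g], ], gamma_hat, grid$p[g], plus, minus)
  }, 0)
  top <- head(order(-grid$ll), n_refine)
  best <- NULL
  for (g in top) {
    th0 <- pmax(thetas[grid$row[g], ], 1e-3)
    par0 <- c(stats::qlogis(grid$p[g]), log(th0[-1]) - log(th0[1]))
    o <- stats::optim(par0, nll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    o <- stats::optim(o$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  unname(softmax(best$par[-1]))
}

# Exhaustive maximum matching between predicted and accepted pairs for the
# sensitivity/PPV scorer (recursion over predicted pairs; inputs are tiny).
oracle_sens_ppv <- function(pred, acc, slippage) {
  P <- pred$pairs
  A <- acc$pairs
  np <- nrow(P)
  na_ <- nrow(A)
  if (np == 0 || na_ == 0) {
    correct <- 0L
  } else if (!slippage) {
    correct <- sum(paste(P[, 1], P[, 2]) %in% paste(A[, 1], A[, 2]))
  } else {
    adj <- lapply(seq_len(np), function(u) {
      which((abs(A[, 1] - P[u, 1]) <= 1 & A[, 2] == P[u, 2]) |
              (A[, 1] == P[u, 1] & abs(A[, 2] - P[u, 2]) <= 1))
    })
    recurse <- function(u, used) {
      if (u > np) return(0L)
      best <- recurse(u + 1L, used)
      for (v in adj[[u]]) {
        if (!v %in% used) {
          best <- max(best, 1L + recurse(u + 1L, c(used, v)))
        }
      }
      best
    }
    correct <- recurse(1L, integer(0))
  }
  list(
    sensitivity = if (na_ > 0) correct / na_ else NA_real_,
    ppv = if (np > 0) correct / np else NA_real_
  )
}

# Random valid structure: pairs drawn without sharing nucleotides (crossings
# allowed; the scorer does not care about planarity).
random_structure <- function(len, max_pairs = floor(len / 3)) {
  free <- seq_len(len)
  pairs <- list()
  n_pairs <- sample(0:max_pairs, 1)
  while (length(pairs) < n_pairs && length(free) >= 2) {
    ij <- sort(sample(free, 2))
    pairs[[length(pairs) + 1]] <- ij
    free <- setdiff(free, ij)
  }
  rna_structure(len, do.call(rbind, pairs))
}

# Small random count instance drawn from the generative model itself, with
# every position reachable in both channels (so all hazards are estimable).
random_count_instance <- function(L, n_max = 100) {
  for (try in 1:100) {
    theta <- as.numeric(stats::rgamma(L, 1.2)); theta <- theta / sum(theta)
    gamma <- stats::runif(L, 0, 0.15)
    p_mod <- stats::runif(1, 0.3, 0.7)
    n <- sample(50:n_max, 1)
    pr <- oracle_stop_probs(theta, gamma, p_mod)
    plus <- as.integer(stats::rmultinom(1, n, pr$plus))
    minus <- as.integer(stats::rmultinom(1, n, pr$minus))
    if (all(cumsum(plus)[-1] > 0) && all(cumsum(minus)[-1] > 0) &&
        all(minus[-1] < cumsum(minus)[-1])) {
      return(tibble::tibble(index = 0:L, plus_count = plus,
                            minus_count = minus))
    }
  }
  stop("could not draw a well-behaved instance")
}

# Deterministic small demo target used across tests.
demo_target <- function(L = 50, seed = 1) {
  withr::with_seed(seed, {
    target_set("demo",
               paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""))
  })
}
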