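# Minimal 3-state Gaussian-emission hidden Markov model: Baum-Welch with
# scaling for fitting, Viterbi for decoding. Internal to the TAD caller.

hmm_forward_backward <- function(x, init, trans, means, sds) {
  n <- length(x)
  k <- length(means)
  emit <- vapply(seq_len(k), function(s) dnorm(x, means[s], sds[s]), numeric(n))
  emit <- pmax(emit, 1e-300)
  alpha <- matrix(0, n, k)
  scale <- numeric(n)
  alpha[1L, ] <- init * emit[1L, ]
  scale[1L] <- sum(alpha[1L, ])
  alpha[1L, ] <- alpha[1L, ] / scale[1L]
  for (t in 2:n) {
    a <- (alpha[t - 1L, ] %*% trans) * emit[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, n, k)
  beta[n, ] <- 1
  for (t in (n - 1L):1L) {
    beta[t, ] <- (trans %*% (emit[t + 1L, ] * beta[t + 1L, ])) / scale[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(
    alpha = alpha, beta = beta, gamma = gamma, emit = emit,
    scale = scale, loglik = sum(log(scale))
  )
}

# The transition matrix is a fixed persistence prior (sticky diagonal)
# rather than an EM-estimated quantity: state runs along a chromosome are
# long by construction, and freely re-estimated transitions drift toward
# rapid state flipping on noisy directionality profiles.
hmm_fit <- function(x, k = 3L, max_iter = 100L, tol = 1e-6,
                    n_restarts = 10L, seed = 1L, self = 0.95) {
  best <- NULL
  qs <- quantile(x, probs = seq(0.5 / k, 1 - 0.5 / k, length.out = k))
  trans <- matrix((1 - self) / (k - 1), k, k)
  diag(trans) <- self
  for (r in seq_len(n_restarts)) {
    # quantile-anchored means, jittered per restart
    means <- as.numeric(qs)
    if (r > 1L) {
      means <- means + with_seed(seed + r, rnorm(k, 0, sd(x) / 4 + 1e-12))
    }
    sds <- rep(max(sd(x) / 2, 1e-6), k)
    init <- rep(1 / k, k)
    loglik <- -Inf
    for (it in seq_len(max_iter)) {
      fb <- hmm_forward_backward(x, init, trans, means, sds)
      if (fb$loglik - loglik < tol * (abs(loglik) + 1) && it > 1L) {
        loglik <- fb$loglik
        break
      }
      loglik <- fb$loglik
      g <- fb$gamma
      init <- g[1L, ]
      w <- colSums(g)
      means <- colSums(g * x) / pmax(w, 1e-300)
      sds <- sqrt(colSums(g * (outer(x, means, "-")^2)) / pmax(w, 1e-300))
      sds <- pmax(sds, 1e-6)
    }
    if (is.null(best) || loglik > best$loglik) {
      best <- list(
        init = init, trans = trans, means = means, sds = sds, loglik = loglik
      )
    }
  }
  best
}

hmm_viterbi <- function(x, model) {
  n <- length(x)
  k <- length(model$means)
  log_emit <- vapply(
    seq_len(k),
    function(s) dnorm(x, model$means[s], model$sds[s], log = TRUE),
    numeric(n)
  )
  log_trans <- log(pmax(model$trans, 1e-300))
  delta <- matrix(-Inf, n, k)
  psi <- matrix(0L, n, k)
  delta[1L, ] <- log(pmax(model$init, 1e-300)) + log_emit[1L, ]
  for (t in 2:n) {
    cand <- delta[t - 1L, ] + log_trans
    psi[t, ] <- max.col(t(cand), ties.method = "first")
    delta[t, ] <- cand[cbind(psi[t, ], seq_len(k))] + log_emit[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1L):1L) {
    path[t] <- psi[t + 1L, path[t + 1L]]
  }
  path
}
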