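# Exact (O(n^2)) t-SNE, suitable for the few hundred objects a labelled
# enzyme-family visualization involves. Standard recipe: perplexity-
# calibrated Gaussian input affinities, Student-t output kernel, gradient
# descent with momentum and early exaggeration.

# Conditional affinities for one point at a given perplexity via binary
# search over the Gaussian precision beta = 1/(2*sigma^2).
calibrate_row <- function(d2_row, perplexity, tol = 1e-5, max_tries = 50L) {
  target <- log(perplexity)
  beta <- 1
  beta_min <- -Inf
  beta_max <- Inf
  for (i in seq_len(max_tries)) {
    w <- exp(-d2_row * beta)
    sum_w <- sum(w)
    if (sum_w == 0) {
      h <- 0
      p <- w
    } else {
      h <- log(sum_w) + beta * sum(d2_row * w) / sum_w
      p <- w / sum_w
    }
    diff <- h - target
    if (abs(diff) < tol) break
    if (diff > 0) {
      beta_min <- beta
      beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
    } else {
      beta_max <- beta
      beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
    }
  }
  p
}

tsne_exact <- function(x, perplexity = 30, seed = 1L, max_iter = 400L,
                       learning_rate = 200, initial_momentum = 0.5,
                       final_momentum = 0.8, exaggeration = 12,
                       exaggeration_iters = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2

  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- d2[i, -i]
    p[i, -i] <- calibrate_row(row, perplexity)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  p_run <- p * exaggeration
  for (iter in seq_len(max_iter)) {
    if (iter == exaggeration_iters + 1L) p_run <- p
    momentum <- if (iter <= 250L) initial_momentum else final_momentum
    yd2 <- as.matrix(stats::dist(y))^2
    num <- 1 / (1 + yd2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    mult <- (p_run - q) * num
    grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
    inc <- momentum * inc - learning_rate * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}
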