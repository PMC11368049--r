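# Exact (O(n^2)) t-SNE, adequate for the few hundred to few thousand
# molecules of a single dataset's chemical-space map. Standard formulation:
# perplexity-calibrated Gaussian input affinities, Student-t output kernel,
# gradient descent with momentum and early exaggeration. Initialization is
# the scaled leading principal-component plane (the reproducibility-friendly
# choice); identical inputs therefore start, and by symmetry remain,
# coincident. Coordinates are for qualitative trajectory analysis only.

.tsne <- function(X, seed, perplexity = 30, max_iter = 500, eta = NULL) {
  n <- nrow(X)
  if (n < 4) stop_contract("t-SNE needs at least 4 points")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps

  set.seed(as.integer(seed %% 2147483647))  # reserved for stochastic stages
  Y <- stats::prcomp(X, center = TRUE)$x[, 1:2, drop = FALSE]
  s <- stats::sd(Y[, 1])
  Y <- if (s > 0) Y / s * 1e-4 else matrix(0, n, 2)
  G <- matrix(0, n, 2)    # momentum buffer
  gains <- matrix(1, n, 2)
  exaggeration <- 12
  # "auto" learning rate: n / (4 * exaggeration), floored — stable for both
  # small and large n
  if (is.null(eta)) eta <- max(n / (4 * exaggeration), 50)
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 100) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# Binary search per point for the bandwidth matching the target perplexity.
.tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1 / max(mean(di), .Machine$double.eps)
    lo <- -Inf; hi <- Inf
    p <- rep(1 / length(di), length(di))
    for (it in 1:64) {
      pe <- exp(-di * beta)
      sp <- sum(pe)
      if (sp == 0) {
        # too peaked to represent: same direction as entropy below target
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
        next
      }
      p <- pe / sp
      H <- log(sp) + beta * sum(di * pe) / sp
      if (abs(H - target) < 1e-5) break
      if (H > target) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}
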