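# Independent brute-force oracles used to pin down the statistical
# machinery. These deliberately avoid the code paths they check.

# Exact right-tailed rank-sum p-value by exhaustive enumeration of all
# choose(n1+n2, n1) rank assignments.
ranksum_enum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  obs <- sum(rank(c(x, y))[seq_len(n1)])
  assignments <- utils::combn(n, n1)
  stats <- colSums(matrix(seq_len(n)[assignments], nrow = n1))
  mean(stats >= obs)
}

# Exact one-/two-sided signed-rank p-value by enumerating all 2^n sign
# patterns of the absolute differences.
signrank_enum_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.vector(signs %*% r)
  switch(alternative,
         greater = mean(stats >= obs),
         less = mean(stats <= obs),
         two.sided = min(1, 2 * min(mean(stats >= obs), mean(stats <= obs))))
}

# Benjamini-Hochberg step-up by definition: largest k with
# p_(k) <= k/m * alpha is the rejection cutoff.
bh_reject_def <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) / m * alpha)
  reject <- logical(m)
  if (length(k) > 0) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# Holm step-down by definition, with explicit family size.
holm_def <- function(p, family = length(p)) {
  ord <- order(p)
  adj <- numeric(length(p))
  running <- 0
  for (i in seq_along(p)) {
    running <- max(running, min(1, (family - i + 1) * p[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}

# Recursive flood fill (depth-first, 26-connectivity) over a logical 3D
# array; returns a label array.
flood_fill_labels <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  current <- 0L
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k] || labels[i, j, k] != 0L) next
    current <- current + 1L
    stack <- list(c(i, j, k))
    labels[i, j, k] <- current
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(nb))) {
        w <- v + nb[o, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- current
          stack[[length(stack) + 1]] <- w
        }
      }
    }
  }
  labels
}

# Log evidence by a different route: integrate the slope coefficients out
# with the Gaussian convolution identity y | a, s2 ~ N(a*c, s2 (I + Z V0 Z')),
# then integrate the flat-prior intercept a and log(s2) by nested adaptive
# Gauss-Kronrod quadrature.
log_evidence_quadrature <- function(y, X, g = nrow(X), a0 = 0.5,
                                    b0 = 0.5 * stats::var(as.numeric(y))) {
  n <- nrow(X)
  y <- as.numeric(y)
  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  has_int <- any(const)
  if (has_int) {
    cvec <- X[, which(const)[1]]
    Z <- scale(X[, !const, drop = FALSE], scale = FALSE)
  } else {
    cvec <- rep(0, n)
    Z <- X
  }
  V0 <- g * solve(crossprod(Z))
  S <- diag(n) + Z %*% V0 %*% t(Z)
  Si <- solve(S)
  ldS <- as.numeric(determinant(S)$modulus)
  ref <- -n / 2 * log(2 * pi)
  loglik <- function(a, s2) {
    r <- y - a * cvec
    -n / 2 * log(2 * pi * s2) - 0.5 * ldS -
      0.5 * as.numeric(crossprod(r, Si %*% r)) / s2
  }
  log_igprior <- function(l) a0 * log(b0) - lgamma(a0) - a0 * l - b0 / exp(l)
  a_hat <- if (has_int) mean(y) / mean(cvec) else 0
  a_width <- 20 * sd(y) / max(abs(cvec), 1)
  f_outer <- function(ls2) {
    vapply(ls2, function(l) {
      s2 <- exp(l)
      inner <- if (has_int) {
        pracma::quadgk(function(a) {
          vapply(a, function(ai) exp(loglik(ai, s2) - ref), numeric(1))
        }, a_hat - a_width, a_hat + a_width, tol = 1e-12)
      } else {
        exp(loglik(0, s2) - ref)
      }
      inner * exp(log_igprior(l))
    }, numeric(1))
  }
  log(pracma::quadgk(f_outer, -15, 15, tol = 1e-12)) + ref
}

# Exact posterior mean of the h2 frequency under the random-effects model
# with two models and a uniform Dirichlet prior, by dense 1D integration.
rfx_grid_posterior <- function(log_evidence) {
  stopifnot(ncol(log_evidence) == 2)
  r <- seq(1e-6, 1 - 1e-6, length.out = 20001)
  lpost <- rep(0, length(r))
  for (s in seq_len(nrow(log_evidence))) {
    d <- log_evidence[s, ] - max(log_evidence[s, ])
    lpost <- lpost + log((1 - r) * exp(d[1]) + r * exp(d[2]))
  }
  w <- exp(lpost - max(lpost))
  sum(r * w) / sum(w)
}

# Simulate a tidy null beta table: i.i.d. standard-normal betas per
# participant x voxel x condition (already run-averaged).
null_beta_table <- function(n_part, n_vox, rois = NULL,
                            conditions = c("std0", "std1", "std2", "dev4")) {
  tbl <- tidyr::expand_grid(
    participant = seq_len(n_part),
    voxel = seq_len(n_vox),
    condition = conditions
  )
  tbl$beta <- rnorm(nrow(tbl))
  if (!is.null(rois)) {
    tbl$roi <- rois[(tbl$voxel - 1L) %% length(rois) + 1L]
  }
  tbl
}
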