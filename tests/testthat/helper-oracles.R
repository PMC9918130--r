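## Independent oracles used by the tests. These deliberately avoid the
## package's own code paths.

## Exhaustive unit-direction search maximizing |cov(Xw, y)| over the unit
## sphere, for 2 or 3 genes: a dense angular grid followed by a fine grid
## around the coarse argmax. X is samples x genes, y a centred group code.
grid_search_axis1 <- function(X, y) {
  p <- ncol(X)
  score <- function(W) abs(as.vector(W %*% crossprod(X, y)))
  if (p == 2) {
    refine <- function(lo, hi, step) {
      th <- seq(lo, hi, by = step)
      W <- cbind(cos(th), sin(th))
      th[which.max(score(W))]
    }
    best <- refine(0, pi, 1e-3)
    best <- refine(best - 2e-3, best + 2e-3, 1e-6)
    c(cos(best), sin(best))
  } else if (p == 3) {
    refine <- function(th_rng, ph_rng, step) {
      th <- seq(th_rng[1], th_rng[2], by = step)
      ph <- seq(ph_rng[1], ph_rng[2], by = step)
      gr <- expand.grid(th = th, ph = ph)
      W <- cbind(sin(gr$ph) * cos(gr$th), sin(gr$ph) * sin(gr$th),
                 cos(gr$ph))
      gr[which.max(score(W)), ]
    }
    b <- refine(c(0, 2 * pi), c(0, pi), 5e-3)
    b <- refine(c(b$th - 1e-2, b$th + 1e-2), c(b$ph - 1e-2, b$ph + 1e-2),
                1e-5)
    c(sin(b$ph) * cos(b$th), sin(b$ph) * sin(b$th), cos(b$ph))
  } else stop("oracle supports 2 or 3 genes")
}

## Angle in radians between two directions, ignoring sign.
direction_angle <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca))
}

## Gower double-centring PCoA from a distance matrix, by hand.
gower_pcoa <- function(D) {
  A <- -0.5 * as.matrix(D)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen(B, symmetric = TRUE)
  keep <- e$values > 1e-8
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  list(points = pts, eig = e$values)
}

## Upper-tail hypergeometric p by exhaustive enumeration of all possible
## query draws from the universe (feasible for |universe| <= 25).
enum_hyper_p <- function(universe, set, query) {
  k_obs <- length(intersect(set, query))
  n <- length(query)
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2, function(d) length(intersect(d, set)) >= k_obs)
  mean(hits)
}
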