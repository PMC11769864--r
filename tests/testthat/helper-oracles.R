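# Independent oracles and shared fixtures for the test suite.

# Brute-force plane fit: grid search over normal directions (spherical
# coordinates, coarse-to-fine), minimizing the summed squared orthogonal
# residual. Independent of the eigen-decomposition route.
oracle_fit_normal <- function(points) {
  pts <- as.matrix(points)
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2L, ctr)
  resid <- function(n) sum((centered %*% n)^2)
  best <- NULL
  best_val <- Inf
  search <- function(th_seq, ph_seq) {
    for (th in th_seq) {
      for (ph in ph_seq) {
        n <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
        v <- resid(n)
        if (v < best_val) {
          best_val <<- v
          best <<- c(th, ph)
        }
      }
    }
  }
  step <- 2 * pi / 180
  search(seq(0, pi, by = step), seq(0, 2 * pi, by = step))
  for (refine in c(0.2, 0.02, 0.002)) {
    st <- refine * pi / 180
    search(seq(best[1] - 10 * st, best[1] + 10 * st, by = st),
           seq(best[2] - 10 * st, best[2] + 10 * st, by = st))
  }
  th <- best[1]; ph <- best[2]
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

angle_between_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(u * v)))) * 180 / pi  # up-to-sign angle
}

# Kruskal-Wallis H from first principles: mid-ranks computed by sorting,
# H = 12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1), divided by the tie correction
# 1 - sum(t^3 - t)/(N^3 - N).
oracle_kruskal_H <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  ord <- order(values)
  ranks <- numeric(N)
  i <- 1L
  sorted <- values[ord]
  while (i <= N) {
    j <- i
    while (j < N && sorted[j + 1L] == sorted[i]) j <- j + 1L
    ranks[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  gid <- rep(seq_along(groups), lengths(groups))
  rsum <- tapply(ranks, gid, sum)
  H <- 12 / (N * (N + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (N + 1)
  tie_counts <- table(values)
  corr <- 1 - sum(tie_counts^3 - tie_counts) / (N^3 - N)
  if (corr == 0) return(NA_real_)
  H / corr
}

# Mann-Whitney U (number of (x, y) pairs with x > y, plus half-credit ties)
oracle_U <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) assignments
# of the pooled values to group 1 (tie-free pools only: there the exact
# distribution of U is symmetric about n1*n2/2, and the two-sided p is the
# probability of a U at least as far from the center)
oracle_mw_exact_p <- function(x, y) {
  stopifnot(anyDuplicated(c(x, y)) == 0L)
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- oracle_U(x, y)
  center <- n1 * length(y) / 2
  us <- apply(idx, 2L, function(sel) oracle_U(pooled[sel], pooled[-sel]))
  mean(abs(us - center) >= abs(u_obs - center) - 1e-12)
}

random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9L), 3L))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# shared synthetic model, built once per test run (the 0.4 mm default is
# used where recovery accuracy matters; a coarser one where it does not)
the_model <- local({
  cache <- new.env(parent = emptyenv())
  function(coarse = FALSE) {
    key <- if (coarse) "coarse" else "fine"
    if (is.null(cache[[key]])) {
      spec <- if (coarse) {
        synthetic_model_spec(resolution_mm = 1.0)
      } else {
        synthetic_model_spec()
      }
      cache[[key]] <- generate_reference_model(spec)
    }
    cache[[key]]
  }
})
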