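# Independent brute-force oracles, written from the textbook formulas and
# kept free of any package code path they are used to check.

oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1)
  v2 <- sum((y - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# mid-ranks computed by counting, then Pearson from first principles
oracle_midrank <- function(v) {
  vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# product-limit estimator over distinct event times
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (i in seq_along(ts)) {
    n_i <- sum(times >= ts[i])
    d_i <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    out$survival[i] <- s
  }
  out
}

# two-group log-rank chi-square from the O/E/hypergeometric-variance table
oracle_logrank <- function(ta, ea, tb, eb) {
  times <- c(ta, tb); events <- c(ea, eb)
  grp_a <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  ts <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    n <- sum(times >= t); n_a <- sum(times >= t & grp_a)
    d <- sum(times == t & events == 1)
    d_a <- sum(times == t & events == 1 & grp_a)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

oracle_score <- function(mat, genes) {
  z <- matrix(NA_real_, length(genes), ncol(mat))
  for (i in seq_along(genes)) {
    v <- mat[genes[i], ]
    z[i, ] <- (v - mean(v)) / sd(v)
  }
  colMeans(z)
}
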