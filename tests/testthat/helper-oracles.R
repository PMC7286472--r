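# Independent brute-force oracles used across the test files.

# Topological overlap by explicit triple loop.
tom_oracle <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      den <- min(k[i], k[j]) + 1 - a[i, j]
      out[i, j] <- if (den < 1e-10) 0 else (l + a[i, j]) / den
    }
  }
  out
}

# Weighted clustering coefficient by explicit triple loop.
clustcoef_oracle <- function(A) {
  n <- nrow(A)
  a <- A
  diag(a) <- 0
  sapply(seq_len(n), function(i) {
    num <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j != k && j != i && k != i) num <- num + a[i, j] * a[j, k] * a[k, i]
    }
    den <- sum(a[i, -i])^2 - sum(a[i, -i]^2)
    num / den
  })
}

# Naive UPGMA: returns the sorted merge heights.
upgma_heights_oracle <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  dist_fun <- function(a, b) mean(d[a, b])
  while (length(members) > 1L) {
    m <- length(members)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dd <- dist_fun(members[[i]], members[[j]])
      if (dd < best[1L]) best <- c(dd, i, j)
    }
    heights <- c(heights, best[1L])
    members[[best[2L]]] <- c(members[[best[2L]]], members[[best[3L]]])
    members[[best[3L]]] <- NULL
  }
  sort(heights)
}

# Two-group log-rank by explicit accumulation over event times.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  times <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g == 1L)
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}

# Random symmetric adjacency with unit diagonal, values in [0, 1].
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Random expression matrix with rownames/colnames.
random_expr <- function(genes, samples) {
  matrix(stats::rnorm(genes * samples),
         nrow = genes,
         dimnames = list(sprintf("g%03d", seq_len(genes)),
                         sprintf("s%02d", seq_len(samples))))
}
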