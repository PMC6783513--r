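# Independent brute-force oracles used to cross-check the implementation.

# O(V^2) FCS: plain double loop over voxel pairs.
fcsOracle <- function(x, thr) {
  V <- ncol(x)
  out <- numeric(V)
  for (i in seq_len(V)) {
    s <- 0
    for (j in seq_len(V)) {
      if (i == j) next
      r <- cor(x[, i], x[, j])
      if (r > thr) s <- s + r
    }
    out[i] <- s
  }
  out
}

# Kendall's W from the rank-sum formula, with midranks computed by counting.
kccOracle <- function(block) {
  n <- nrow(block); K <- ncol(block)
  ranks <- matrix(0, n, K)
  for (j in seq_len(K)) {
    for (t in seq_len(n)) {
      less <- sum(block[, j] < block[t, j])
      eq <- sum(block[, j] == block[t, j])
      ranks[t, j] <- less + (eq + 1) / 2
    }
  }
  R <- rowSums(ranks)
  S <- sum((R - K * (n + 1) / 2)^2)
  12 * S / (K^2 * (n^3 - n))
}

# Benjamini-Hochberg step-up from the definition.
bhOracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= i / m * q) k <- i
  flags <- logical(m)
  if (k > 0) flags[o[seq_len(k)]] <- TRUE
  flags
}

# Connected components via igraph on the explicit voxel adjacency graph.
igraphComponents <- function(idx, dm, connectivity) {
  co <- arrayInd(idx, dm)
  n <- length(idx)
  edges <- NULL
  for (i in seq_len(n)) {
    d <- abs(co[, 1] - co[i, 1]); e <- abs(co[, 2] - co[i, 2])
    f <- abs(co[, 3] - co[i, 3])
    adj <- switch(as.character(connectivity),
                  "6"  = d + e + f == 1,
                  "18" = pmax(d, e, f) == 1 & d + e + f <= 2,
                  "26" = pmax(d, e, f) == 1)
    j <- which(adj & seq_len(n) > i)
    if (length(j)) edges <- rbind(edges, cbind(i, j))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# Two labelings describe the same partition?
samePartition <- function(a, b) {
  length(a) == length(b) &&
    !is.unsorted(tapply(seq_along(a), a, length)) ==
      !is.unsorted(tapply(seq_along(b), b, length)) &&
    all(tapply(b, a, function(v) length(unique(v))) == 1) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}

# OLS residuals by explicit normal equations.
olsResidOracle <- function(y, D) {
  y - D %*% solve(crossprod(D), crossprod(D, y))
}

key3 <- function(m) paste(m[, 1], m[, 2], m[, 3])

diceCoords <- function(a, b) {
  2 * sum(key3(a) %in% key3(b)) / (nrow(a) + nrow(b))
}
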