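# Independent brute-force oracles used across the suite.

# Exhaustive two-tailed Fisher p for a 2x2 table via direct table
# enumeration with binomial coefficients (no dhyper).
fisherEnumOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pr <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  pObs <- pr[match(a, support)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-7)]))
}

# Triple-loop TOM definition.
bruteTom <- function(a) {
  G <- nrow(a)
  a0 <- a; diag(a0) <- 0
  k <- rowSums(a0)
  t <- matrix(0, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i == j) { t[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(G)) if (u != i && u != j) l <- l + a0[i, u] * a0[u, j]
    t[i, j] <- (l + a0[i, j]) / (min(k[i], k[j]) + 1 - a0[i, j])
  }
  t
}

# Quadratic agglomerative complete-linkage: returns successive merge heights
# and the partition trace, for comparison against hclust.
bruteCompleteLinkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < bestD) { bestD <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestD)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  maxI <- (b + c) / 2
  (a - expected) / (maxI - expected)
}

# 0.001-step grid search for the isoelectric point on the same charge model.
gridSearchPi <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  counts <- table(factor(aa, levels = c(names(noduleTx:::KD_HYDROPATHY))))
  grid <- seq(0, 14, by = 0.001)
  ch <- vapply(grid, function(pH) noduleTx:::netCharge_(counts, pH), numeric(1))
  grid[which.min(abs(ch))]
}

randomPeptide <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), len, replace = TRUE), collapse = "")
}

smallBundle <- function(seed = 1, nGenes = 600, ...) {
  simulateBundle(generatorConfig(nGenes = nGenes, seed = seed, ...))
}
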