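# Independent brute-force oracles, kept deliberately naive (explicit
# loops, no shared code with R/) so they can certify the implementation.

# ---- nearest shrunken centroids, straight off the formulas ----------------

naive_nsc_train <- function(x, labels, delta, uniform_priors = FALSE) {
  classes <- sort(unique(labels))
  n <- ncol(x)
  K <- length(classes)
  G <- nrow(x)
  cent <- matrix(NA_real_, G, K, dimnames = list(rownames(x), classes))
  for (k in classes) {
    for (g in seq_len(G)) cent[g, k] <- mean(x[g, labels == k])
  }
  overall <- numeric(G)
  for (g in seq_len(G)) overall[g] <- mean(x[g, ])
  sj <- numeric(G)
  for (g in seq_len(G)) {
    ss <- 0
    for (k in classes) {
      for (i in which(labels == k)) ss <- ss + (x[g, i] - cent[g, k])^2
    }
    sj[g] <- sqrt(ss / (n - K))
  }
  s0 <- median(sj)
  nk <- sapply(classes, function(k) sum(labels == k))
  mk <- sqrt(1 / nk - 1 / n)
  shr <- cent
  for (k in seq_len(K)) {
    for (g in seq_len(G)) {
      d <- (cent[g, k] - overall[g]) / (mk[k] * (sj[g] + s0))
      dp <- sign(d) * max(abs(d) - delta, 0)
      shr[g, k] <- overall[g] + mk[k] * (sj[g] + s0) * dp
    }
  }
  pk <- if (uniform_priors) rep(1 / K, K) else nk / n
  names(pk) <- classes
  list(classes = classes, overall = overall, centroids = cent,
       shrunken = shr, sj = sj, s0 = s0, priors = pk)
}

naive_nsc_discriminant <- function(fit, xvec) {
  d <- numeric(length(fit$classes))
  names(d) <- fit$classes
  for (k in seq_along(fit$classes)) {
    s <- 0
    for (g in seq_along(xvec)) {
      s <- s + (xvec[g] - fit$shrunken[g, k])^2 / (fit$sj[g] + fit$s0)^2
    }
    d[k] <- s - 2 * log(fit$priors[k])
  }
  d
}

# random small instance with both classes >= 2 samples
random_nsc_instance <- function(genes = 6, samples = 12) {
  g <- sample(2:genes, 1)
  n <- sample(5:samples, 1)
  nA <- sample(2:(n - 2), 1)
  labels <- sample(rep(c("A", "B"), c(nA, n - nA)))
  x <- matrix(rnorm(g * n, sd = runif(1, 0.5, 2)), g, n,
              dimnames = list(paste0("g", seq_len(g)),
                              paste0("s", seq_len(n))))
  list(x = x, labels = labels, delta = runif(1, 0, 1.5))
}

# ---- enumeration oracles --------------------------------------------------

# exact McNemar p by summing binomial coefficients (no pbinom)
enum_mcnemar_p <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  m <- min(b, cc)
  tail <- sum(choose(n, 0:m)) / 2^n
  min(1, 2 * tail)
}

# two-sided Fisher p on a 2x2 table by full hypergeometric enumeration,
# probability-mass criterion (relative tie guard as is conventional)
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n2 <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  d <- dhyper(support, m, n2, k)
  sum(d[d <= dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
}

# ---- naive UPGMA under 1 - centered correlation ---------------------------

# returns the sequence of merged member sets (sorted) and merge heights
naive_upgma <- function(x) {
  n <- nrow(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) D[i, j] <- 1 - cor(x[i, ], x[j, ])
  }
  clusters <- as.list(seq_len(n))
  merges <- list()
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- mean(D[clusters[[i]], clusters[[j]]])
        if (dij < bestd) {
          bestd <- dij
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, bestd)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# member sets in merge order from an hclust object
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    members <- integer()
    for (v in hc$merge[s, ]) {
      members <- c(members, if (v < 0) -v else sets[[v]])
    }
    sets[[s]] <- sort(members)
  }
  sets
}
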