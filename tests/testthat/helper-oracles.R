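# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: draw enumeration instead of distribution
# functions, explicit rank-and-moment arithmetic instead of cor(), and a
# literal agglomeration loop instead of hclust().

# P(X >= k) by enumerating every size-n draw from a population of N with
# the first K elements marked as successes. Feasible for N <= ~12.
hyper_tail_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2L, function(d) sum(d <= K)) >= k)
}

# P(X >= k) as an explicit sum of binomial-coefficient ratios.
hyper_tail_choose <- function(k, n, K, N) {
  j <- seq(k, min(n, K))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Spearman r as average-rank transform followed by hand-rolled Pearson.
spearman_naive <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Agglomerative clustering on a distance matrix by direct simulation of
# the merge loop; returns the n-1 merge heights in merge order.
agglom_heights_naive <- function(d, method = c("complete", "average",
                                               "single")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(length(clusters) - 1L)
  for (step in seq_along(heights)) {
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1L):length(clusters)) {
        pair_d <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dist_ij <- switch(method, complete = max(pair_d),
                          average = mean(pair_d), single = min(pair_d))
        if (dist_ij < best) { best <- dist_ij; bi <- i; bj <- j }
      }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Benjamini-Hochberg by the textbook recipe: p(i) * m / i from the
# largest rank down, with running minima and capping at 1.
bh_naive <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Noise-free time course holding exact model fractions (fractional
# "counts" are legal: the container constrains bounds and monotonicity).
exact_time_course <- function(t50, slope, top = 1,
                              timepoints = seq(5, 80, by = 5)) {
  fr <- logisticFraction(timepoints, t50, slope, top = top)
  new("SeizureTimeCourse",
      data = data.frame(vial_id = "v1", genotype = "g",
                        time_min = timepoints, n_total = 1,
                        n_seized_cum = fr))
}
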