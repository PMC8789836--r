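# Independent oracles and fixture builders used across the suite.

# Brute-force connected components of the <= d proximity graph, written as a
# BFS over the full distance matrix: deliberately a different algorithm from
# the package's sorted-sweep union-find.
oracle_components <- function(coords, d) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  adj <- as.matrix(dist(coords)) <= d
  labels <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (labels[s] > 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- lab
      queue <- c(queue, nb)
    }
  }
  labels
}

# random 3D point cloud at track-like scales
random_instance <- function(n, scale = 1) {
  cbind(runif(n, 0, scale * 5), rnorm(n, 0, scale * 0.1),
        rnorm(n, 0, scale * 0.1))
}

# n well-separated focus centers inside a stack extent
separated_centers <- function(n, extent, margin, min_sep) {
  repeat {
    cen <- cbind(runif(n, margin[1], extent[1] - margin[1]),
                 runif(n, margin[2], extent[2] - margin[2]),
                 runif(n, margin[3], extent[3] - margin[3]))
    if (n < 2L || min(dist(cen)) >= min_sep) return(cen)
  }
}

# straight 1D Poisson track of rate lambda on [0, L] as a coordinate matrix
poisson_segment <- function(lambda, L) {
  n <- rpois(1, lambda * L)
  cbind(runif(n, 0, L), 0, 0)
}
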