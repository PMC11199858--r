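# Shared fixtures and independent oracles for the test suite. Oracles here
# are deliberately naive (double loops, exhaustive enumeration) and never
# share code with the package paths they check.

# random directed weighted connectome; guarantees every node touches a link
random_connectome <- function(n, p = 0.4, seed = 1, coords = FALSE) {
  set.seed(seed)
  repeat {
    W <- matrix(stats::rexp(n * n), n, n) * (matrix(stats::runif(n * n), n, n) < p)
    diag(W) <- 0
    if (sum(W) > 0 && all(rowSums(W) + colSums(W) > 0)) break
  }
  labels <- sprintf("v%02d", seq_len(n))
  dimnames(W) <- list(labels, labels)
  nodes <- data.frame(label = labels, stringsAsFactors = FALSE)
  if (coords) {
    nodes$x <- stats::runif(n, 0, 10)
    nodes$y <- stats::runif(n, 0, 10)
    nodes$z <- stats::runif(n, 0, 10)
  }
  con <- connectome(nodes, W, "LNe")
  if (coords) con <- compute_distances(con)
  con
}

# all set partitions of n elements as membership vectors (restricted growth
# strings); Bell(8) = 4140
all_partitions <- function(n) {
  res <- vector("list", 0)
  rec <- function(z, mx) {
    if (length(z) == n) { res[[length(res) + 1]] <<- z; return() }
    for (v in seq_len(mx + 1)) rec(c(z, v), max(mx, v))
  }
  rec(integer(0), 0L)
  res
}

# participation coefficient straight from the definition, double loop
brute_participation <- function(W, z, direction, weighted) {
  n <- nrow(W)
  if (!weighted) W <- (W > 0) + 0
  sapply(seq_len(n), function(i) {
    links <- if (direction == "out") W[i, ] else W[, i]
    s <- sum(links)
    if (s == 0) return(0)
    1 - sum(sapply(unique(z), function(m) (sum(links[z == m]) / s)^2))
  })
}

# within-module z-score straight from the definition
brute_z <- function(W, z, direction, weighted) {
  n <- nrow(W)
  if (!weighted) W <- (W > 0) + 0
  kappa <- sapply(seq_len(n), function(i) {
    links <- if (direction == "out") W[i, ] else W[, i]
    sum(links[z == z[i]])
  })
  sapply(seq_len(n), function(i) {
    k <- kappa[z == z[i]]
    sig <- sqrt(mean((k - mean(k))^2))
    if (sig == 0) 0 else (kappa[i] - mean(k)) / sig
  })
}

# earliest-arrival search over paths of <= max_order hops with per-hop
# synaptic penalty and per-link weight/length filters: plain enumeration
# over 1- and 2-hop paths
brute_trace_arrivals <- function(W, D, seeds, velocity, delay, min_w, max_len) {
  labels <- rownames(W)
  ok <- W >= min_w & W > 0 & D <= max_len
  arr <- stats::setNames(rep(Inf, length(labels)), labels)
  arr[seeds] <- 0
  for (s in seeds) for (u in labels[ok[s, ]]) {
    t1 <- D[s, u] / velocity
    arr[u] <- min(arr[u], t1)
    for (v in labels[ok[u, ]]) {
      arr[v] <- min(arr[v], t1 + D[u, v] / velocity + delay)
    }
  }
  arr[is.finite(arr)]
}

# small deterministic toy: two weighted 5-cliques joined by one weak link
two_cliques <- function(m = 5, bridge = 0.01) {
  n <- 2 * m
  W <- matrix(0, n, n)
  W[1:m, 1:m] <- 1
  W[(m + 1):n, (m + 1):n] <- 1
  diag(W) <- 0
  W[1, m + 1] <- bridge
  labels <- sprintf("c%02d", 1:n)
  dimnames(W) <- list(labels, labels)
  connectome(data.frame(label = labels), W, "LNe")
}
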