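# Modularity, Louvain comparison partition, and partition-agreement metrics.

#' Newman modularity of a partition
#'
#' Default is the undirected variant on the symmetrised weight matrix
#' `(W + t(W)) / 2` — matching what a stock Louvain implementation with
#' default settings computes on a directed matrix —
#' `Q = sum_m (e_m / m_tot - (a_m / m_tot)^2)` with `e_m` the within-module
#' weight, `a_m` the module strength and `m_tot` the total weight (all
#' counted over the full symmetric matrix). The directed variant is
#' `Q = (1/m_tot) sum_ij [W_ij - s_out_i * s_in_j / m_tot] delta(c_i, c_j)`.
#'
#' @param c a [connectome]
#' @param membership named or ordered module assignment over all nodes of
#'   `c` (a `partition` object is also accepted; its orphans are linkless,
#'   so they contribute nothing to Q however they are grouped)
#' @param variant `"undirected"` (default) or `"directed"`
#' @return modularity Q
#' @export
modularity_q <- function(c, membership, variant = c("undirected", "directed")) {
  variant <- match.arg(variant)
  z <- full_membership(c, membership)
  if (variant == "undirected") {
    S <- (c$W + t(c$W)) / 2
    m_tot <- sum(S)
    e_m <- vapply(unique(z), function(m) sum(S[z == m, z == m]), numeric(1))
    a_m <- vapply(unique(z), function(m) sum(S[z == m, ]), numeric(1))
    sum(e_m / m_tot - (a_m / m_tot)^2)
  } else {
    m_tot <- sum(c$W)
    s_out <- rowSums(c$W); s_in <- colSums(c$W)
    same <- outer(z, z, "==")
    sum((c$W - outer(s_out, s_in) / m_tot)[same]) / m_tot
  }
}

# accept a partition object or a membership vector; return an integer vector
# aligned with c$nodes$label (orphans / missing nodes become fresh singletons)
full_membership <- function(c, membership) {
  if (inherits(membership, "partition")) membership <- membership$assignment
  labels <- c$nodes$label
  if (!is.null(names(membership))) {
    z <- membership[labels]
  } else {
    if (length(membership) != length(labels))
      stop("membership length must match node count")
    z <- membership
  }
  as.integer(factor(z, exclude = NULL))
}

#' Louvain modularity partition
#'
#' Runs the standard two-phase Louvain agglomeration (via igraph) on the
#' symmetrised weighted graph, maximising undirected weighted modularity.
#' Serves as the independent comparison to the map-equation decomposition;
#' the two are conceptually different optimisations that usually agree on
#' strongly modular networks. All nodes are assigned (no orphans). If the
#' result does not decompose the network (a single module), it is flagged
#' `degenerate` — which is what happens when weights carrying the modular
#' signal are binarised away.
#'
#' @param c a [connectome]
#' @param seed RNG seed (Louvain is node-order sensitive)
#' @param binarise if `TRUE`, replace weights by 0/1 before clustering
#' @return a `partition` list with `assignment`, `Q`, `n_modules`,
#'   `degenerate`
#' @export
louvain_partition <- function(c, seed = 1L, binarise = FALSE) {
  if (nrow(c$nodes) < 2) stop("need >= 2 nodes")
  W <- if (binarise) (c$W > 0) + 0 else c$W
  S <- (W + t(W)) / 2
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g)
  z <- igraph::membership(cl)
  assignment <- stats::setNames(as.integer(z), c$nodes$label)
  c2 <- c; c2$W <- W
  Q <- modularity_q(c2, assignment)
  structure(list(assignment = assignment, Q = Q,
                 n_modules = length(unique(z)),
                 degenerate = length(unique(z)) <= 1,
                 orphans = character(0), seed = seed,
                 codelength = NA_real_),
            class = "partition")
}

#' Agreement between two partitions
#'
#' Normalised mutual information and adjusted Rand index between two module
#' assignments over the same node set; orphan nodes (present in only one
#' assignment or flagged as orphans) are excluded before comparison. When
#' either assignment carries zero entropy (a single module) NMI is defined
#' as 1 if the assignments are identical as set partitions and 0 otherwise.
#'
#' @param p1,p2 `partition` objects or named membership vectors
#' @return list with `nmi`, `ari`, `n` (nodes compared)
#' @export
compare_partitions <- function(p1, p2) {
  a <- if (inherits(p1, "partition")) p1$assignment else p1
  b <- if (inherits(p2, "partition")) p2$assignment else p2
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != length(b)) stop("unnamed memberships of different length")
    common <- seq_along(a)
    x <- as.integer(factor(a)); y <- as.integer(factor(b))
  } else {
    common <- intersect(names(a), names(b))
    if (!length(common)) stop("no common nodes between partitions")
    x <- as.integer(factor(a[common])); y <- as.integer(factor(b[common]))
  }
  list(nmi = nmi(x, y), ari = adjusted_rand(x, y), n = length(common))
}

# normalised mutual information, normalised by arithmetic mean of entropies
nmi <- function(x, y) {
  n <- length(x)
  ct <- table(x, y) / n
  px <- rowSums(ct); py <- colSums(ct)
  hx <- -sum(plogp(px)); hy <- -sum(plogp(py))
  if (hx == 0 || hy == 0)
    return(if (identical(unname(as.integer(factor(x))),
                         unname(as.integer(factor(y))))) 1 else 0)
  mi <- sum(ct * log2(ct / outer(px, py)), na.rm = TRUE)
  mi / ((hx + hy) / 2)
}

# adjusted Rand index (Hubert & Arabie)
adjusted_rand <- function(x, y) {
  ct <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(if (sum_ij == max_idx) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}
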