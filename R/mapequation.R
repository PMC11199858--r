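# Two-level map equation over random-walk flow, and its optimiser.
#
# A partition M of the nodes is scored by the expected description length of
# an infinite random walk under a two-level Huffman-style code:
#
#   L(M) = q H(Q) + sum_m p_m^o H(P_m)                       [bits]
#
# where q_m is the exit rate of module m (link flow crossing its boundary
# plus the teleportation share landing outside), q = sum_m q_m, H(Q) the
# entropy of {q_m / q}, and each module codebook holds its nodes' visit
# rates together with the exit rate, normalised by p_m^o = q_m + sum_{i in m}
# p_i. Expanding the entropies gives the form used here,
#
#   L = plogp(q) - 2 sum_m plogp(q_m) - sum_i plogp(p_i)
#       + sum_m plogp(q_m + P_m),       plogp(x) = x log2 x,
#
# whose per-module terms allow O(degree) updates when one node changes
# module. With every node in one module q = 0 and L reduces to the entropy
# of the visit rates.

# x log2 x with plogp(0) = 0; tiny negative inputs (float noise from
# incremental exit-flow updates) are clamped to zero
plogp <- function(x) {
  out <- numeric(length(x))
  i <- which(x > 0)
  out[i] <- x[i] * log2(x[i])
  out
}

# exit rates per module given per-module link-exit flow E, teleport mass T
# and module sizes; teleportation lands uniformly on all n nodes, so the
# share leaving module m is T_m * (n - n_m) / n.
module_exit <- function(E, T_m, n_m, n) pmax(E, 0) + T_m * (n - n_m) / n

#' Two-level map-equation codelength
#'
#' Evaluates the description length (bits per step) of a random walk under
#' the two-level modular code for a given partition, using the flow field's
#' node visit rates and link flows. Teleportation steps are encoded
#' (recorded-teleportation convention).
#'
#' @param flow a `flow_field` from [stationary_flow]
#' @param membership integer (or factor) module assignment, one entry per
#'   node of the flow field, no empty labels required
#' @return codelength in bits
#' @export
map_codelength <- function(flow, membership) {
  p <- flow$node_flow
  n <- length(p)
  if (length(membership) != n) stop("membership length must match node count")
  z <- as.integer(factor(membership))
  if (anyNA(z)) stop("membership has missing entries (empty module labels)")
  t_i <- ifelse(flow$dangling, p, flow$tau * p)
  P_m <- as.vector(rowsum(p, z))
  T_m <- as.vector(rowsum(t_i, z))
  n_m <- tabulate(z)
  A <- rowsum(flow$link_flow, z)                 # K x n: flow from module to node
  Bm <- t(rowsum(t(A), z))                       # K x K: flow module -> module
  E_m <- rowSums(Bm) - diag(Bm)
  q_m <- module_exit(E_m, T_m, n_m, n)
  q <- sum(q_m)
  unname(plogp(q) - 2 * sum(plogp(q_m)) - sum(plogp(p)) +
           sum(plogp(q_m + P_m)))
}

# ---- optimiser ------------------------------------------------------------

# state carried through greedy moves
me_state <- function(flow) {
  p <- flow$node_flow
  n <- length(p)
  F <- flow$link_flow
  t_i <- ifelse(flow$dangling, p, flow$tau * p)
  out_nbr <- apply(F, 1, function(r) which(r > 0), simplify = FALSE)
  in_nbr <- apply(F, 2, function(cl) which(cl > 0), simplify = FALSE)
  list(p = p, t = t_i, n = n, F = F,
       out_nbr = out_nbr, in_nbr = in_nbr,
       const = -sum(plogp(p)))
}

# total codelength from per-module stats
me_L <- function(st, P_m, T_m, n_m, E_m) {
  q_m <- module_exit(E_m, T_m, n_m, st$n)
  q <- sum(q_m)
  plogp(q) - 2 * sum(plogp(q_m)) + sum(plogp(q_m + P_m)) + st$const
}

# one full greedy pass of single-node moves; returns updated state or NULL
# when no move improved the codelength
me_local_pass <- function(st, z, stats, order_idx, eps = 1e-13) {
  improved <- FALSE
  for (i in order_idx) {
    A <- z[i]
    onb <- st$out_nbr[[i]]; inb <- st$in_nbr[[i]]
    cand <- unique(z[c(onb, inb)])
    cand <- setdiff(cand, A)
    if (!length(cand)) next
    fo <- st$F[i, onb]; fi <- st$F[inb, i]
    fo_tot <- sum(fo)
    fo_by <- vapply(cand, function(m) sum(fo[z[onb] == m]), numeric(1))
    fi_by <- vapply(cand, function(m) sum(fi[z[inb] == m]), numeric(1))
    fo_A <- sum(fo[z[onb] == A]); fi_A <- sum(fi[z[inb] == A])
    base_L <- me_L(st, stats$P, stats$T, stats$size, stats$E)
    best <- NULL; best_dL <- -eps
    for (k in seq_along(cand)) {
      B <- cand[k]
      P <- stats$P; T_m <- stats$T; n_m <- stats$size; E <- stats$E
      P[A] <- P[A] - st$p[i]; P[B] <- P[B] + st$p[i]
      T_m[A] <- T_m[A] - st$t[i]; T_m[B] <- T_m[B] + st$t[i]
      n_m[A] <- n_m[A] - 1L; n_m[B] <- n_m[B] + 1L
      E[A] <- E[A] - (fo_tot - fo_A) + fi_A
      E[B] <- E[B] + (fo_tot - fo_by[k]) - fi_by[k]
      dL <- me_L(st, P, T_m, n_m, E) - base_L
      if (dL < best_dL) {
        best_dL <- dL
        best <- list(B = B, P = P, T = T_m, size = n_m, E = E)
      }
    }
    if (!is.null(best)) {
      z[i] <- best$B
      stats$P <- best$P; stats$T <- best$T
      stats$size <- best$size; stats$E <- best$E
      improved <- TRUE
    }
  }
  list(z = z, stats = stats, improved = improved)
}

# per-module stats from scratch for membership z over module ids 1..K
# (rowsum drops empty groups, so dense K-length vectors are rebuilt by id)
me_stats <- function(st, z, K) {
  A <- rowsum(st$F, z)
  grp <- as.integer(rownames(A))
  Bm <- t(rowsum(t(A), z))              # flow module -> module, ids = grp
  E <- numeric(K); E[grp] <- rowSums(Bm) - diag(Bm)
  P <- numeric(K); tmp <- rowsum(st$p, z); P[as.integer(rownames(tmp))] <- tmp
  T_m <- numeric(K); tmp <- rowsum(st$t, z); T_m[as.integer(rownames(tmp))] <- tmp
  list(P = P, T = T_m, size = tabulate(z, nbins = K), E = E)
}

# merge phase: greedily merge module pairs while codelength decreases
me_merge_pass <- function(st, z, stats) {
  improved_any <- FALSE
  repeat {
    active <- which(stats$size > 0)
    if (length(active) < 2) break
    A <- rowsum(st$F, z)
    Bm <- t(rowsum(t(A), z))
    ids <- as.integer(rownames(A))
    base_L <- me_L(st, stats$P, stats$T, stats$size, stats$E)
    best <- NULL; best_dL <- -1e-13
    for (ai in seq_along(ids)) for (bi in seq_along(ids)) {
      if (bi <= ai) next
      a <- ids[ai]; b <- ids[bi]
      if (Bm[ai, bi] == 0 && Bm[bi, ai] == 0) next
      P <- stats$P; T_m <- stats$T; n_m <- stats$size; E <- stats$E
      E[a] <- E[a] + E[b] - Bm[ai, bi] - Bm[bi, ai]
      E[b] <- 0
      P[a] <- P[a] + P[b]; P[b] <- 0
      T_m[a] <- T_m[a] + T_m[b]; T_m[b] <- 0
      n_m[a] <- n_m[a] + n_m[b]; n_m[b] <- 0L
      dL <- me_L(st, P, T_m, n_m, E) - base_L
      if (dL < best_dL) best <- list(a = a, b = b, P = P, T = T_m,
                                     size = n_m, E = E, dL = dL)
    }
    if (is.null(best)) break
    z[z == best$b] <- best$a
    stats$P <- best$P; stats$T <- best$T
    stats$size <- best$size; stats$E <- best$E
    improved_any <- TRUE
  }
  list(z = z, stats = stats, improved = improved_any)
}

#' Map-equation partition by greedy codelength minimisation
#'
#' Decomposes the network into modules by minimising the two-level
#' map-equation codelength: repeated greedy single-node moves (each node
#' tried against its neighbours' modules, in shuffled order) alternate with
#' a module-merge phase until neither improves, and the whole search is
#' restarted `n_trials` times from all-singleton assignments with different
#' node orders; the lowest-codelength partition wins. Areas with no links at
#' all carry no flow and are excluded as orphans before the walk is set up.
#'
#' Module ids in the result are renumbered by descending module flow, so
#' module 1 carries the most random-walk traffic.
#'
#' @param c a [connectome] with >= 2 nodes
#' @param tau teleportation probability (see [stationary_flow])
#' @param n_trials number of restarts (default 100; both this optimiser and
#'   Louvain are node-order sensitive)
#' @param seed RNG seed controlling the shuffles; results are deterministic
#'   given the seed
#' @return a `partition` list: `assignment` (named integer vector over
#'   non-orphan nodes), `module_flow`, `codelength` (bits), `n_modules`,
#'   `orphans` (character vector), `flow` (the `flow_field` used), `tau`,
#'   `seed`
#' @export
optimize_partition <- function(c, tau = 0.15, n_trials = 100, seed = 1L) {
  if (nrow(c$nodes) < 2) stop("need >= 2 nodes")
  orphan <- node_degree(c, "in") + node_degree(c, "out") == 0
  orphans <- c$nodes$label[orphan]
  sub <- subset_connectome(c, c$nodes$label[!orphan])
  flow <- stationary_flow(sub, tau = tau)
  st <- me_state(flow)
  n <- st$n
  set.seed(seed)
  best_z <- NULL; best_L <- Inf
  for (trial in seq_len(n_trials)) {
    z <- seq_len(n)
    stats <- me_stats(st, z, n)
    repeat {
      repeat {
        res <- me_local_pass(st, z, stats, sample.int(n))
        z <- res$z; stats <- res$stats
        if (!res$improved) break
      }
      res <- me_merge_pass(st, z, stats)
      z <- res$z; stats <- res$stats
      if (!res$improved) break
    }
    L <- me_L(st, stats$P, stats$T, stats$size, stats$E)
    if (L < best_L - 1e-12) { best_L <- L; best_z <- z }
  }
  # renumber modules by descending flow
  z <- as.integer(factor(best_z))
  mflow <- as.vector(rowsum(st$p, z))
  ord <- order(-mflow)
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  z <- remap[z]
  mflow <- sort(mflow, decreasing = TRUE)
  assignment <- stats::setNames(z, sub$nodes$label)
  structure(list(assignment = assignment,
                 module_flow = stats::setNames(mflow, seq_along(mflow)),
                 codelength = best_L, n_modules = length(mflow),
                 orphans = orphans, flow = flow, tau = tau, seed = seed),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d modules over %d nodes (%d orphans), codelength %.4f bits\n",
              x$n_modules, length(x$assignment), length(x$orphans),
              x$codelength))
  if (!is.null(x$Q)) cat(sprintf("modularity Q = %.3f\n", x$Q))
  invisible(x)
}

# connectome restricted to a label subset (keeps order of `labels`)
subset_connectome <- function(c, labels) {
  idx <- match(labels, c$nodes$label)
  if (anyNA(idx)) stop("unknown label(s) in subset")
  out <- connectome(c$nodes[idx, , drop = FALSE],
                    c$W[idx, idx, drop = FALSE], c$weight_kind,
                    D = if (is.null(c$D)) NULL else c$D[idx, idx, drop = FALSE])
  out
}

#' Module summary table
#'
#' One row per module, ordered by module flow: id, flow, size, and the key
#' member areas (by node flow, descending).
#'
#' @param partition a `partition` from [optimize_partition]
#' @param n_key how many key members to list
#' @return data.frame `module, flow, n_areas, key_areas`
#' @export
module_summary <- function(partition, n_key = 6) {
  z <- partition$assignment
  p <- partition$flow$node_flow[names(z)]
  rows <- lapply(sort(unique(z)), function(m) {
    members <- names(z)[z == m]
    members <- members[order(-p[members])]
    data.frame(module = m,
               flow = unname(partition$module_flow[as.character(m)]),
               n_areas = length(members),
               key_areas = paste(utils::head(members, n_key), collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(partition$orphans))
    out <- rbind(out, data.frame(module = NA, flow = 0,
                                 n_areas = length(partition$orphans),
                                 key_areas = paste(utils::head(partition$orphans, n_key),
                                                   collapse = ", ")))
  out
}
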