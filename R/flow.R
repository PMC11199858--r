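# Random-walk probability flow.
#
# The walker model is the PageRank-style process: from a node with out-links,
# follow an out-link proportionally to weight with probability 1 - tau, or
# teleport uniformly over all nodes with probability tau; from a dangling
# node (no out-links) teleport with probability 1. The stationary visit rates
# p_i are the node probability flow; link flow is the stationary rate of
# traversing each link, f(s, t) = (1 - tau) * p_s * W[s, t] / s_out(s).

#' Stationary random-walk probability flow
#'
#' @param c a [connectome] with at least one link
#' @param tau teleportation probability, 0 < tau < 1 (default 0.15)
#' @param method `"power"` (power iteration, default) or `"solve"` (direct
#'   linear solve of the stationarity equations); the two agree to ~1e-12
#'   and exist as independent routes for cross-checking
#' @param tol convergence residual for power iteration
#' @param max_iter iteration cap; exceeding it signals pathological input
#' @return a `flow_field` list: `node_flow` (named, sums to 1), `link_flow`
#'   (matrix, zero where no link), `tau`, `n_iter`
#' @export
stationary_flow <- function(c, tau = 0.15, method = c("power", "solve"),
                            tol = 1e-14, max_iter = 10000L) {
  method <- match.arg(method)
  if (n_links(c) == 0) stop("connectome has no links")
  stopifnot(tau > 0, tau < 1)
  W <- c$W
  n <- nrow(W)
  s_out <- rowSums(W)
  dangling <- s_out == 0
  P <- W / ifelse(s_out == 0, 1, s_out)   # row-stochastic on non-dangling rows
  n_iter <- 0L
  if (method == "power") {
    p <- rep(1 / n, n)
    repeat {
      # teleport mass: tau from non-dangling walkers, all of dangling walkers
      tele <- tau * sum(p[!dangling]) + sum(p[dangling])
      p_new <- (1 - tau) * drop(crossprod(P, p * !dangling)) + tele / n
      n_iter <- n_iter + 1L
      if (max(abs(p_new - p)) < tol) { p <- p_new; break }
      p <- p_new
      if (n_iter >= max_iter)
        stop("power iteration failed to converge after ", max_iter, " steps")
    }
  } else {
    # p' M = p' with M[i, j] = (1 - tau) P[i, j] + tele_i / n,
    # tele_i = tau (non-dangling) or 1 (dangling); replace one equation by
    # the normalisation sum(p) = 1.
    tele_i <- ifelse(dangling, 1, tau)
    M <- (1 - tau) * P * (!dangling) + tele_i / n
    A <- t(M) - diag(n)
    A[n, ] <- 1
    b <- c(rep(0, n - 1), 1)
    p <- solve(A, b)
  }
  p <- p / sum(p)
  names(p) <- rownames(W)
  link_flow <- (1 - tau) * (p * !dangling) * P
  structure(list(node_flow = p, link_flow = link_flow, tau = tau,
                 n_iter = n_iter, dangling = dangling),
            class = "flow_field")
}

#' Rank links by probability flow
#'
#' Sorts all links by their stationary traversal rate, descending, ties
#' broken by (source, target) label order, and returns the top fraction or
#' top k.
#'
#' @param flow a `flow_field` from [stationary_flow]
#' @param fraction fraction of links to keep (e.g. 0.15 for the top 15%);
#'   the count kept is `floor(fraction * n_links)`
#' @param k alternatively, an absolute number of links (overrides
#'   `fraction`)
#' @return data.frame `source, target, link_flow, weight_rank` sorted by
#'   flow
#' @export
top_flow_links <- function(flow, fraction = 0.15, k = NULL) {
  F <- flow$link_flow
  idx <- which(F > 0, arr.ind = TRUE)
  df <- data.frame(source = rownames(F)[idx[, 1]],
                   target = colnames(F)[idx[, 2]],
                   link_flow = F[idx], stringsAsFactors = FALSE)
  df <- df[order(-df$link_flow, df$source, df$target), , drop = FALSE]
  m <- nrow(df)
  keep <- if (!is.null(k)) min(k, m) else floor(fraction * m)
  df <- utils::head(df, keep)
  if (nrow(df)) df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
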