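# Hub / connector cartography: participation coefficients, within-module
# z-scores and the R1-R7 role classes, computed separately for in- and
# out-links. Weighted degrees are the default; the unweighted mode exists
# for comparison with binary-matrix studies.

#' Participation coefficient
#'
#' `P_i = 1 - sum_m (s_im / s_i)^2`, where `s_im` is node i's (weighted)
#' degree to module m in the given direction and `s_i` its total. P -> 0
#' for purely within-module linkage, P -> 1 for links spread evenly across
#' many modules. Nodes with no links in the direction get P = 0.
#'
#' @param c a [connectome]
#' @param membership module assignment (named vector or `partition`);
#'   orphans get fresh singleton modules
#' @param direction `"in"` or `"out"`
#' @param weighted use weighted degrees (default `TRUE`)
#' @return named numeric vector of P in \[0, 1\]
#' @export
participation <- function(c, membership, direction = c("in", "out"),
                          weighted = TRUE) {
  direction <- match.arg(direction)
  z <- full_membership(c, membership)
  M <- if (weighted) c$W else (c$W > 0) + 0
  if (direction == "in") M <- t(M)      # rows now index the focal node
  by_mod <- t(rowsum(t(M), z))          # node x module degree
  s <- rowSums(by_mod)
  P <- 1 - rowSums((by_mod / ifelse(s == 0, 1, s))^2)
  P[s == 0] <- 0
  stats::setNames(P, c$nodes$label)
}

#' Within-module degree z-score
#'
#' `kappa_i` is node i's (weighted) degree to members of its own module in
#' the given direction; `z_i = (kappa_i - mu_m) / sigma_m` standardises it
#' against the mean and population standard deviation of `kappa` over i's
#' module. Modules with zero spread (singletons, uniform kappa) give z = 0.
#'
#' @inheritParams participation
#' @return named numeric vector of z-scores
#' @export
within_module_z <- function(c, membership, direction = c("in", "out"),
                            weighted = TRUE) {
  direction <- match.arg(direction)
  z <- full_membership(c, membership)
  M <- if (weighted) c$W else (c$W > 0) + 0
  if (direction == "in") M <- t(M)
  n <- nrow(M)
  kappa <- vapply(seq_len(n), function(i) sum(M[i, z == z[i]]), numeric(1))
  out <- numeric(n)
  for (m in unique(z)) {
    idx <- z == m
    mu <- mean(kappa[idx])
    sig <- sqrt(mean((kappa[idx] - mu)^2))   # population sd
    out[idx] <- if (sig == 0) 0 else (kappa[idx] - mu) / sig
  }
  stats::setNames(out, c$nodes$label)
}

#' Role boundaries of the z-P cartography
#'
#' The classification heuristics of the metabolic-network role cartography:
#' hubs have `z > z_hub`; non-hubs split at P = 0.05 / 0.62 / 0.80 into
#' R1 (ultra-peripheral), R2 (peripheral), R3 (non-hub connector), R4
#' (non-hub kinless); hubs split at P = 0.30 / 0.75 into R5 (provincial
#' hub), R6 (connector hub), R7 (kinless hub). Nodes with
#' `z_marginal < z <= z_hub` are flagged marginal hubs. These cutoffs were
#' tuned on cellular networks and may need revisiting for cortical ones, so
#' they are configuration values.
#'
#' @param z_hub hub cutoff (default 2.5)
#' @param z_marginal marginal-hub cutoff (default 2)
#' @param p_nonhub non-hub P breakpoints (length 3)
#' @param p_hub hub P breakpoints (length 2)
#' @return list of boundaries
#' @export
role_boundaries <- function(z_hub = 2.5, z_marginal = 2,
                            p_nonhub = c(0.05, 0.62, 0.80),
                            p_hub = c(0.30, 0.75)) {
  stopifnot(length(p_nonhub) == 3, length(p_hub) == 2,
            !is.unsorted(p_nonhub), !is.unsorted(p_hub))
  list(z_hub = z_hub, z_marginal = z_marginal,
       p_nonhub = p_nonhub, p_hub = p_hub)
}

#' Classify a node by (P, z)
#'
#' @param P participation coefficient(s) in \[0, 1\]
#' @param z within-module z-score(s)
#' @param boundaries a [role_boundaries] list
#' @return character vector of roles `"R1"`..`"R7"`
#' @export
classify_role <- function(P, z, boundaries = role_boundaries()) {
  if (any(P < 0 | P > 1)) stop("P outside [0, 1]")
  b <- boundaries
  hub <- z > b$z_hub
  nh <- as.integer(cut(P, c(-Inf, b$p_nonhub, Inf)))        # 1..4
  hb <- 4L + as.integer(cut(P, c(-Inf, b$p_hub, Inf)))      # 5..7
  paste0("R", ifelse(hub, hb, nh))
}

#' Full role table for one direction
#'
#' @inheritParams participation
#' @param boundaries a [role_boundaries] list
#' @return data.frame `label, direction, P, z, role, marginal_hub`
#' @export
role_table <- function(c, membership, direction = c("in", "out"),
                       weighted = TRUE, boundaries = role_boundaries()) {
  direction <- match.arg(direction)
  P <- participation(c, membership, direction, weighted)
  zz <- within_module_z(c, membership, direction, weighted)
  data.frame(label = c$nodes$label, direction = direction,
             P = unname(P), z = unname(zz),
             role = classify_role(P, zz, boundaries),
             marginal_hub = zz > boundaries$z_marginal & zz <= boundaries$z_hub,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract ranked hubs and connectors over both directions
#'
#' Hubs are the union of R5/R6/R7 nodes over the in- and out-role tables,
#' ranked by z descending (a node hub in both directions is listed once, at
#' its larger z). Connectors are non-hub R3/R4 nodes ranked by P
#' descending. Marginal hubs (`z_marginal < z <= z_hub`) are listed
#' separately.
#'
#' @param roles_in,roles_out role tables from [role_table]
#' @param top_n truncate each list to this many nodes (default all)
#' @return list of data.frames `hubs`, `connectors`, `marginal_hubs`
#' @export
extract_hubs_and_connectors <- function(roles_in, roles_out, top_n = Inf) {
  both <- rbind(roles_in, roles_out)
  pick_best <- function(df, by) {
    df <- df[order(-df[[by]], df$label), , drop = FALSE]
    df <- df[!duplicated(df$label), , drop = FALSE]
    rownames(df) <- NULL
    utils::head(df, top_n)
  }
  hubs <- pick_best(both[both$role %in% c("R5", "R6", "R7"), ], "z")
  hub_labels <- hubs$label
  conn <- both[both$role %in% c("R3", "R4") & !(both$label %in% hub_labels), ]
  connectors <- pick_best(conn, "P")
  marg <- both[both$marginal_hub & !(both$label %in% hub_labels), ]
  list(hubs = hubs, connectors = connectors,
       marginal_hubs = pick_best(marg, "z"))
}
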