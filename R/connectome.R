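#' Connectome container
#'
#' A `connectome` bundles the directed weight matrix of a mesoscale cortical
#' network with its node metadata. Rows of `W` are source areas, columns are
#' target areas, a convention kept fixed throughout the package. Weights carry
#' a kind tag: `"FLNe"` (fraction of labelled neurons extrinsic; every measured
#' target's in-weights sum to 1) or `"LNe"` (absolute labelled-neuron counts).
#'
#' @param nodes data.frame of node metadata with columns `label` (unique
#'   character), and optionally `region`, `x`, `y`, `z` (centroid, mm) and
#'   `measured` (logical; `TRUE` iff the area was a tracer injection site so
#'   its in-links were measured). Missing `measured` defaults to `TRUE`.
#' @param W non-negative numeric matrix, `length(labels)` square, with
#'   `dimnames` equal to the node labels; `W[s, t]` is the weight of the
#'   directed link s -> t. The diagonal must be zero (no self-links).
#' @param weight_kind `"FLNe"` or `"LNe"`.
#' @param D optional symmetric matrix of pairwise inter-area distances in mm.
#'
#' @return An object of class `connectome`: a list with elements `nodes`, `W`,
#'   `weight_kind` and (optionally) `D`.
#' @export
connectome <- function(nodes, W, weight_kind = c("LNe", "FLNe"), D = NULL) {
  weight_kind <- match.arg(weight_kind)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"label" %in% names(nodes)) stop("nodes must have a 'label' column")
  nodes$label <- as.character(nodes$label)
  if (anyDuplicated(nodes$label)) stop("node labels must be unique")
  if (!"measured" %in% names(nodes)) nodes$measured <- TRUE
  nodes$measured <- as.logical(nodes$measured)
  n <- nrow(nodes)
  W <- as.matrix(W)
  if (nrow(W) != n || ncol(W) != n)
    stop("W must be a square matrix matching the node table")
  if (is.null(dimnames(W))) dimnames(W) <- list(nodes$label, nodes$label)
  if (!identical(rownames(W), nodes$label) ||
      !identical(colnames(W), nodes$label))
    stop("dimnames of W must equal nodes$label, in order")
  if (any(W < 0)) stop("link weights must be non-negative")
  if (any(diag(W) != 0)) stop("self-links (non-zero diagonal) are not allowed")
  obj <- list(nodes = nodes, W = W, weight_kind = weight_kind)
  if (!is.null(D)) {
    D <- as.matrix(D)
    if (!all(dim(D) == n)) stop("D must be n x n")
    if (max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0))
      stop("D must be symmetric with zero diagonal")
    dimnames(D) <- dimnames(W)
    obj$D <- D
  }
  structure(obj, class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d nodes (%d measured), %d links, weights = %s%s\n",
              nrow(x$nodes), sum(x$nodes$measured), sum(x$W > 0),
              x$weight_kind,
              if (is.null(x$D)) "" else ", distances attached"))
  invisible(x)
}

#' Number of directed links
#' @param c a `connectome`
#' @return integer count of non-zero entries of `W`
#' @export
n_links <- function(c) sum(c$W > 0)

#' Labels of measured (injected) areas
#' @param c a `connectome`
#' @export
measured_labels <- function(c) c$nodes$label[c$nodes$measured]

# validate the FLNe column-sum invariant; returns TRUE or a message
check_flne <- function(c, tol = 1e-9) {
  if (c$weight_kind != "FLNe") return(TRUE)
  cs <- colSums(c$W)
  meas <- c$nodes$measured
  bad <- meas & cs > 0 & abs(cs - 1) > tol
  if (any(bad))
    return(sprintf("FLNe columns of measured targets must sum to 1; %d violate (max dev %.3g)",
                   sum(bad), max(abs(cs[bad] - 1))))
  TRUE
}

#' Attach Euclidean inter-area distances
#'
#' Computes the pairwise Euclidean distance matrix between area centroids
#' (in mm) and attaches it as `D`. Centroid coordinates must be present for
#' every node.
#'
#' @param c a `connectome` whose `nodes` carry `x`, `y`, `z` columns
#' @return the connectome with `D` filled in
#' @export
compute_distances <- function(c) {
  need <- c("x", "y", "z")
  if (!all(need %in% names(c$nodes)))
    stop("node table has no x/y/z centroid columns")
  xyz <- as.matrix(c$nodes[, need])
  if (anyNA(xyz) || any(!is.finite(xyz)))
    stop("missing or non-finite coordinate for node(s): ",
         paste(c$nodes$label[!stats::complete.cases(xyz)], collapse = ", "))
  D <- as.matrix(stats::dist(xyz))
  diag(D) <- 0
  dimnames(D) <- dimnames(c$W)
  c$D <- D
  c
}
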