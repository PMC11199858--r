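# Synthetic spatially embedded connectomes with known ground truth.
#
# The generator emulates the statistical structure of a mesoscale tracer
# dataset: ~116 areas in a cortex-sized 3-D box, directed links denser inside
# planted modules than between them, weights decaying exponentially with
# centroid distance and spanning several orders of magnitude under
# multiplicative log-normal noise, and in-link censoring to a measured subset
# of injection sites.

#' Synthetic connectome configuration
#'
#' Defaults emulate the marmoset-scale dataset the pipeline targets: 116
#' areas, 55 injection sites, a 25 x 15 x 10 mm bounding box, weight-distance
#' decay length 4.57 mm, and link probabilities chosen so the censored
#' network carries on the order of 3,500 links.
#'
#' @param n_nodes number of areas
#' @param n_measured number of injection sites (areas whose in-links survive
#'   censoring)
#' @param box 3-vector, spatial extent in mm
#' @param n_modules planted module count K
#' @param p_within,p_between directed-link probabilities inside / between
#'   planted modules (defaults give on the order of 3,500 links after
#'   censoring, ~55% of the observable source-target pairs)
#' @param lambda_decay weight-distance decay length, mm
#' @param log_sigma standard deviation of the natural-log weight noise
#'   (the default, with the decay, spreads censored weights over roughly
#'   five to six orders of magnitude)
#' @param weight_scale weight at zero distance before noise (dimensionless,
#'   a labelled-neuron count scale)
#' @param module_scatter_mm Gaussian scatter of node positions around their
#'   module centre, mm (modules are spatially compact, as cortical modules
#'   are anatomically local)
#' @param seed RNG seed
#' @return a `synth_config` list
#' @export
synth_config <- function(n_nodes = 116, n_measured = 55,
                         box = c(25, 15, 10), n_modules = 8,
                         p_within = 0.95, p_between = 0.5,
                         lambda_decay = 4.57, log_sigma = 1.0,
                         weight_scale = 1000, module_scatter_mm = 2.0,
                         seed = 1L) {
  stopifnot(n_measured > 0, n_measured <= n_nodes,
            p_between >= 0, p_within >= p_between, p_within <= 1,
            lambda_decay > 0, n_modules >= 1, length(box) == 3,
            all(box > 0), log_sigma >= 0, weight_scale > 0)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_measured = as.integer(n_measured),
                 box = as.numeric(box), n_modules = as.integer(n_modules),
                 p_within = p_within, p_between = p_between,
                 lambda_decay = lambda_decay, log_sigma = log_sigma,
                 weight_scale = weight_scale,
                 module_scatter_mm = module_scatter_mm,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# farthest-point ("maximin") selection of K well-separated centres from a
# uniform candidate pool; K = 1 degenerates to one random point
place_module_centres <- function(K, box, pool_size = 200) {
  pool <- matrix(stats::runif(3 * pool_size) * rep(box, each = pool_size),
                 pool_size, 3)
  idx <- sample.int(pool_size, 1)
  while (length(idx) < K) {
    d_min <- apply(pool, 1, function(p)
      min(sqrt(colSums((t(pool[idx, , drop = FALSE]) - p)^2))))
    idx <- c(idx, which.max(d_min))
  }
  pool[idx, , drop = FALSE]
}

#' Generate a synthetic connectome with ground truth
#'
#' Places `n_modules` module centres by farthest-point selection from a
#' uniform candidate pool (so distinct modules do not collapse onto each
#' other inside the small volume), scatters each module's nodes around its
#' centre (Gaussian, `module_scatter_mm`), draws a
#' directed link (s, t) with probability `p_within` when s and t share a
#' planted module and `p_between` otherwise, and assigns the weight
#' `weight_scale * exp(-d(s, t) / lambda_decay) * exp(N(0, log_sigma^2))`.
#' Weights are strictly positive; the result is deterministic given
#' `cfg$seed`. The returned connectome is uncensored (every area's in-links
#' present, all nodes flagged measured); apply [censor] with
#' `ground_truth$measured_set` to emulate the injection-site subsampling.
#'
#' @param cfg a [synth_config]
#' @return list with elements `connectome` (LNe weights, distances attached)
#'   and `ground_truth` (list: `partition` named integer vector,
#'   `lambda_decay`, `measured_set`, `seed`)
#' @export
generate_connectome <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_nodes; K <- cfg$n_modules
  labels <- sprintf("N%03d", seq_len(n))
  membership <- sort(rep_len(seq_len(K), n))
  centres <- place_module_centres(K, cfg$box)
  xyz <- centres[membership, , drop = FALSE] +
    matrix(stats::rnorm(3 * n, sd = cfg$module_scatter_mm), n, 3)
  # keep centroids inside the box (reflect at the walls)
  for (j in 1:3) {
    xyz[, j] <- abs(xyz[, j])
    over <- xyz[, j] > cfg$box[j]
    xyz[over, j] <- 2 * cfg$box[j] - xyz[over, j]
    xyz[, j] <- pmin(pmax(xyz[, j], 0), cfg$box[j])
  }
  D <- as.matrix(stats::dist(xyz)); diag(D) <- 0
  same <- outer(membership, membership, "==")
  p <- ifelse(same, cfg$p_within, cfg$p_between)
  diag(p) <- 0
  link <- matrix(stats::runif(n * n), n, n) < p
  noise <- matrix(exp(stats::rnorm(n * n, sd = cfg$log_sigma)), n, n)
  W <- ifelse(link, cfg$weight_scale * exp(-D / cfg$lambda_decay) * noise, 0)
  dimnames(W) <- list(labels, labels)
  dimnames(D) <- dimnames(W)
  nodes <- data.frame(label = labels,
                      region = sprintf("M%02d", membership),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      measured = TRUE, stringsAsFactors = FALSE)
  measured_set <- sort(sample(labels, cfg$n_measured))
  gt <- list(partition = stats::setNames(membership, labels),
             lambda_decay = cfg$lambda_decay,
             measured_set = measured_set, seed = cfg$seed)
  list(connectome = connectome(nodes, W, "LNe", D = D), ground_truth = gt)
}

#' Censor in-links to the measured subset
#'
#' Zeroes every in-link column of areas outside `measured_set` and updates
#' the measured flags, emulating that tracer data only reports in-links of
#' injection sites. Out-links of unmeasured areas are untouched.
#'
#' @param c a [connectome]
#' @param measured_set character vector of area labels that were injected
#' @return the censored connectome
#' @export
censor <- function(c, measured_set) {
  unknown <- setdiff(measured_set, c$nodes$label)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  drop <- setdiff(c$nodes$label, measured_set)
  c$W[, drop] <- 0
  c$nodes$measured <- c$nodes$label %in% measured_set
  c
}

#' Convert a synthetic LNe connectome to FLNe plus matched injection records
#'
#' Normalises each measured column to fractions and synthesises one
#' injection record per connected measured target whose `LNe` total equals
#' that column's sum, so that [flne_to_lne] on the output reproduces the
#' input exactly. Zero-column targets emit no record.
#'
#' @param c a [connectome] with LNe weights
#' @return list with elements `connectome` (FLNe) and `records` (data.frame
#'   `target, injection_volume, LNi, LNe, LNtot`; volume and LNi are nominal)
#' @export
to_flne <- function(c) {
  if (c$weight_kind != "LNe") stop("input connectome must carry LNe weights")
  cs <- colSums(c$W)
  if (any(cs > 0 & !c$nodes$measured))
    stop("unmeasured areas carry in-links; censor() the connectome first")
  keep <- c$nodes$measured & cs > 0
  records <- data.frame(target = c$nodes$label[keep],
                        injection_volume = 1.0,
                        LNi = 0, LNe = cs[keep], LNtot = cs[keep],
                        stringsAsFactors = FALSE, row.names = NULL)
  list(connectome = lne_to_flne(c), records = records)
}
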