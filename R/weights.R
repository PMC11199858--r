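# FLNe <-> LNe weight conversions.
#
# Retrograde tracing at a target area t labels source neurons across the
# cortex; the count of extrinsic labelled neurons per source, LNe(s, t), is
# the absolute in-link weight. Published matrices usually carry the fraction
# FLNe(s, t) = LNe(s, t) / LNe(t), whose columns sum to 1 for every injected
# target, discarding between-target differences of total in-weight. Given the
# per-experiment totals LNe(t) the absolute weights are recovered by scaling
# each measured column back up: LNe(t) = sum_s LNe(s, t).

combine_totals <- function(values, combine) {
  switch(combine,
         mean = mean(values),
         sum = sum(values),
         max = max(values),
         stop("unknown combine policy: ", combine))
}

#' Rescale fractional weights (FLNe) to absolute counts (LNe)
#'
#' Multiplies every measured target's FLNe column by that target's combined
#' extrinsic labelled-neuron total, recovering the absolute in-link weights.
#' Targets with repeated injections contribute several records; they are
#' pooled by the `combine` policy.
#'
#' @param c a [connectome] with `weight_kind = "FLNe"`
#' @param records injection records (data.frame with columns `target` and
#'   `LNe`), e.g. from [read_injection_records]
#' @param combine pooling rule for repeated injections at one target:
#'   `"mean"` (default; stable against unequal repeat counts), `"sum"` or
#'   `"max"`
#' @return the connectome with `weight_kind = "LNe"`
#' @export
flne_to_lne <- function(c, records, combine = c("mean", "sum", "max")) {
  combine <- match.arg(combine)
  if (c$weight_kind != "FLNe") stop("input connectome must carry FLNe weights")
  msg <- check_flne(c)
  if (!isTRUE(msg)) stop(msg)
  cs <- colSums(c$W)
  need <- c$nodes$label[c$nodes$measured & cs > 0]
  missing <- setdiff(need, records$target)
  if (length(missing))
    stop("measured target(s) with in-links but no injection record: ",
         paste(missing, collapse = ", "))
  for (t in need) {
    tot <- combine_totals(records$LNe[records$target == t], combine)
    if (!is.finite(tot) || tot <= 0)
      stop("non-positive combined LNe total for target ", t)
    c$W[, t] <- c$W[, t] * tot
  }
  c$weight_kind <- "LNe"
  c
}

#' Normalise absolute counts (LNe) to fractional weights (FLNe)
#'
#' Divides every non-zero column by its sum, so that the weighted in-Degree
#' of every connected target becomes 1 (0 if no in-links were measured).
#'
#' @param c a [connectome] with `weight_kind = "LNe"`
#' @return the connectome with `weight_kind = "FLNe"`
#' @export
lne_to_flne <- function(c) {
  if (c$weight_kind != "LNe") stop("input connectome must carry LNe weights")
  cs <- colSums(c$W)
  nz <- cs > 0
  c$W[, nz] <- sweep(c$W[, nz, drop = FALSE], 2, cs[nz], "/")
  c$weight_kind <- "FLNe"
  c
}
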