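# geometric toy: labelled nodes on a line so distances are easy to read
line_connectome <- function(pos, links) {
  n <- length(pos)
  labels <- names(pos)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (l in links) W[l[[1]], l[[2]]] <- as.numeric(l[[3]])
  con <- connectome(data.frame(label = labels, x = pos, y = 0, z = 0,
                               stringsAsFactors = FALSE), W, "LNe")
  compute_distances(con)
}

test_that("arrival = length / velocity, plus synaptic delay per extra hop", {
  con <- line_connectome(c(A = 0, B = 3, C = 7),
                         list(list("A", "B", 2), list("B", "C", 2)))
  tr <- trace_links(con, trace_config("A", min_weight = 0, max_length_mm = Inf))
  expect_equal(tr$events$arrival_ms, c(3, 9))     # 3; 3 + 4 + 2
  expect_equal(tr$events$order, c(1L, 2L))
  expect_equal(tr$node_arrival[["C"]], 9)
  # doubling velocity halves travel times, delay unchanged
  tr2 <- trace_links(con, trace_config("A", velocity_mm_per_ms = 2,
                                       min_weight = 0, max_length_mm = Inf))
  expect_equal(tr2$events$arrival_ms, c(1.5, 5.5))
})

test_that("weight and length filters drop links monotonically", {
  con <- line_connectome(c(A = 0, B = 3, C = 7, D = 20),
                         list(list("A", "B", 2), list("A", "C", 0.5),
                              list("A", "D", 5), list("B", "C", 2)))
  base <- trace_links(con, trace_config("A", min_weight = 0,
                                        max_length_mm = Inf))
  filt <- trace_links(con, trace_config("A", min_weight = 1,
                                        max_length_mm = 5))
  expect_lt(nrow(filt$events), nrow(base$events))
  expect_true(all(filt$events$weight >= 1 & filt$events$length_mm <= 5))
  # A->C (weight 0.5) and A->D (20 mm) filtered; B->C second order kept
  expect_setequal(paste(filt$events$source, filt$events$target),
                  c("A B", "B C"))
  expect_equal(filt$n_filtered, 2L)
  # tightening never adds events
  tighter <- trace_links(con, trace_config("A", min_weight = 3,
                                           max_length_mm = 5))
  expect_lte(nrow(tighter$events), nrow(filt$events))
})

test_that("a node reachable twice keeps its earliest arrival", {
  con <- line_connectome(c(A = 0, B = 2, C = 5),
                         list(list("A", "B", 2), list("A", "C", 2),
                              list("B", "C", 2)))
  tr <- trace_links(con, trace_config("A", min_weight = 0,
                                      max_length_mm = Inf))
  # direct: 5 ms; via B: 2 + 3 + 2 = 7 ms -> keep 5
  expect_equal(tr$node_arrival[["C"]], 5)
  ev <- tr$events
  expect_equal(ev$arrival_ms[ev$source == "A" & ev$target == "C"], 5)
})

test_that("in-traces follow links backwards with original orientation", {
  con <- line_connectome(c(A = 0, B = 3),
                         list(list("A", "B", 2)))
  tr <- trace_links(con, trace_config("B", direction = "in",
                                      min_weight = 0, max_length_mm = Inf))
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$source, "A")
  expect_equal(tr$events$target, "B")
  expect_equal(tr$events$arrival_ms, 3)
})

test_that("arrivals agree with a brute-force bounded-hop search", {
  for (s in 1:20) {
    con <- random_connectome(15, p = 0.3, seed = 400 + s, coords = TRUE)
    seeds <- con$nodes$label[1:2]
    cfg <- trace_config(seeds, min_weight = 0.5, max_length_mm = 9)
    tr <- trace_links(con, cfg)
    ref <- brute_trace_arrivals(con$W, con$D, seeds, velocity = 1, delay = 2,
                                min_w = 0.5, max_len = 9)
    expect_equal(sort(names(tr$node_arrival)), sort(names(ref)))
    expect_equal(tr$node_arrival[names(ref)], ref, tolerance = 1e-12)
  }
})

test_that("local clusters grow with the latency radius", {
  con <- line_connectome(c(A = 0, B = 1, C = 2, D = 12),
                         list(list("A", "B", 2), list("B", "C", 2),
                              list("A", "D", 2)))
  tr <- trace_links(con, trace_config("A", min_weight = 0,
                                      max_length_mm = Inf))
  expect_equal(local_cluster(tr, 0), "A")
  expect_setequal(local_cluster(tr, Inf), c("A", "B", "C", "D"))
  expect_setequal(local_cluster(tr, 5), c("A", "B", "C"))
})

test_that("viz export round-trips edges and colours by module", {
  con <- random_connectome(10, seed = 77, coords = TRUE)
  part <- optimize_partition(con, n_trials = 5, seed = 1)
  prefix <- file.path(withr::local_tempdir(), "viz")
  out <- export_viz(con, part, prefix = prefix)
  expect_true(file.exists(paste0(prefix, "_nodes.csv")))
  edges <- utils::read.csv(paste0(prefix, "_edges.csv"))
  expect_equal(nrow(edges), n_links(con))
  expect_equal(con$W[cbind(edges$source, edges$target)], edges$weight,
               tolerance = 1e-9, ignore_attr = TRUE)
  nodes <- utils::read.csv(paste0(prefix, "_nodes.csv"))
  expect_equal(sort(nodes$label), sort(con$nodes$label))
  expect_true(all(nzchar(nodes$colour)))
  # empty event table still yields the node table
  out2 <- export_viz(con, part, events = trace_links(
    con, trace_config(con$nodes$label[1], min_weight = 1e9))$events,
    prefix = paste0(prefix, "2"))
  expect_equal(nrow(out2$edges), 0)
  expect_equal(nrow(out2$nodes), 10)
})
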