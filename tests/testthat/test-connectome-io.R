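test_that("link lists are read with label union, measured flags and errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# toy", "A\tB\t2.0", "B\tC\t1.0", "A\tC\t0.5"), f)
  con <- read_link_list(f)
  expect_equal(sort(con$nodes$label), c("A", "B", "C"))
  expect_equal(n_links(con), 3)
  expect_equal(con$W["A", "B"], 2.0)
  expect_equal(measured_labels(con), c("B", "C"))  # targets only

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("# nothing here", empty)
  expect_error(read_link_list(empty), "no links parsed")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A B 1", "A A 2"), bad)
  expect_error(read_link_list(bad), "self-link at row.*2")
  writeLines(c("A B 1", "B C -3"), bad)
  expect_error(read_link_list(bad), "negative weight")
  expect_error(read_link_list("no/such/file.txt"), "not found")
})

test_that("duplicate link rows error by default and aggregate on request", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B,1.5", "A,B,2.5", "B,C,1"), f)
  expect_error(read_link_list(f), "duplicate")
  con <- read_link_list(f, duplicates = "sum")
  expect_equal(con$W["A", "B"], 4.0)
})

test_that("delimiter sniffing and headers work across dialects", {
  for (sep in c("\t", ",", " ")) {
    f <- withr::local_tempfile()
    writeLines(c(paste("source", "target", "weight", sep = sep),
                 paste("A", "B", "3", sep = sep)), f)
    con <- read_link_list(f)
    expect_equal(con$W["A", "B"], 3)
  }
})

test_that("adjacency matrices round-trip through write/read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  W <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  con <- connectome(data.frame(label = c("A", "B")), W, "LNe")
  write_adjacency(con, f)
  back <- read_adjacency(f)
  expect_equal(back$W["A", "B"], 3)
  expect_equal(back$W["B", "A"], 1)
  expect_equal(back$W, con$W)

  con2 <- random_connectome(12, seed = 4)
  write_adjacency(con2, f)
  back2 <- read_adjacency(f)
  expect_equal(back2$W[rownames(con2$W), colnames(con2$W)], con2$W,
               tolerance = 1e-12)
})

test_that("rectangular adjacency yields the label union with measured targets", {
  # 20 sources x 8 measured targets, written rectangularly
  con <- random_connectome(20, seed = 9)
  targets <- con$nodes$label[1:8]
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(source = rownames(con$W),
                   con$W[, targets, drop = FALSE], check.names = FALSE)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_adjacency(f)
  expect_equal(nrow(back$nodes), 20)
  expect_setequal(measured_labels(back),
                  targets[colSums(con$W[, targets]) > 0])
  # link multiset restricted to those columns is preserved
  expect_equal(sort(back$W[back$W > 0]),
               sort(con$W[, targets][con$W[, targets] > 0]))
})

test_that("node metadata and injection records round-trip", {
  con <- random_connectome(6, seed = 2, coords = TRUE)
  con$nodes$region <- "R"
  f <- withr::local_tempfile()
  write_node_meta(con, f)
  meta <- read_node_meta(f)
  expect_equal(meta$label, con$nodes$label)
  expect_equal(meta$x, con$nodes$x, tolerance = 1e-6)
  expect_equal(meta$measured, con$nodes$measured)

  rec <- data.frame(target = c("A", "A", "B"), injection_volume = c(1, 2, 1),
                    LNi = c(10, 20, 5), LNe = c(100, 200, 50),
                    LNtot = c(110, 220, 55))
  f2 <- withr::local_tempfile()
  write_injection_records(rec, f2)
  back <- read_injection_records(f2)
  expect_equal(back$LNe, rec$LNe)
  expect_equal(back$target, rec$target)
})

test_that("Euclidean distances match an element-wise recomputation", {
  con <- connectome(data.frame(label = c("a", "b"),
                               x = c(0, 3), y = c(0, 4), z = c(0, 0)),
                    matrix(c(0, 1, 0, 0), 2, 2,
                           dimnames = list(c("a", "b"), c("a", "b"))), "LNe")
  con <- compute_distances(con)
  expect_equal(con$D["a", "b"], 5)
  expect_equal(diag(con$D), c(a = 0, b = 0))

  con2 <- random_connectome(50, seed = 11, coords = TRUE)
  xyz <- as.matrix(con2$nodes[, c("x", "y", "z")])
  Dref <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    Dref[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  expect_equal(unname(con2$D), Dref, tolerance = 1e-12)
})
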