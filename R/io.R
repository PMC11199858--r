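# File formats.
#
# Link list:   delimited text, columns `source target weight [distance_mm]`,
#              optional header, '#' comments ignored, delimiter sniffed among
#              tab / comma / whitespace. Labels are case-sensitive.
# Adjacency:   labelled delimited matrix, row labels (sources) in the first
#              column, column labels (targets) in the header row.
# Node meta:   delimited text `label region x_mm y_mm z_mm measured`.
# Injections:  delimited text `target injection_volume LNi LNe LNtot`.

sniff_delim <- function(lines) {
  probe <- lines[nzchar(lines)][1]
  if (grepl("\t", probe)) "\t" else if (grepl(",", probe)) "," else ""
}

read_delim_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(NULL)
  delim <- sniff_delim(lines)
  utils::read.table(text = lines, sep = delim, header = FALSE,
                    stringsAsFactors = FALSE, strip.white = TRUE,
                    colClasses = "character")
}

has_header <- function(df, numeric_cols) {
  # header iff the designated numeric columns fail to parse on row 1
  suppressWarnings(any(is.na(as.numeric(unlist(df[1, numeric_cols])))))
}

#' Read a directed link list
#'
#' Parses a delimited text file with columns `source target weight`
#' (optionally a fourth `distance_mm` column, ignored here) into a
#' [connectome]. Nodes are the union of all labels; areas appearing as a
#' target are flagged `measured` (their in-links were assayed), mirroring
#' how retrograde-tracer link lists only report in-links of injection sites.
#'
#' @param path path to the link-list file
#' @param node_meta optional path to a node-metadata file
#'   (`label region x y z measured`); labels there are unioned in and
#'   override the target-derived `measured` flags
#' @param weight_kind weight kind tag of the file, `"LNe"` (default) or
#'   `"FLNe"`
#' @param duplicates `"error"` (default: a repeated (source, target) row
#'   aborts) or `"sum"` (aggregate duplicates by summation)
#' @return a [connectome]
#' @export
read_link_list <- function(path, node_meta = NULL,
                           weight_kind = c("LNe", "FLNe"),
                           duplicates = c("error", "sum")) {
  weight_kind <- match.arg(weight_kind)
  duplicates <- match.arg(duplicates)
  df <- read_delim_file(path)
  if (is.null(df)) stop("no links parsed from ", path)
  if (ncol(df) < 3) stop("link list needs >= 3 columns (source target weight)")
  if (has_header(df, 3)) df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) stop("no links parsed from ", path)
  src <- df[[1]]; tgt <- df[[2]]
  w <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(w)) stop("non-numeric weight at row(s): ",
                     paste(which(is.na(w)), collapse = ", "))
  if (any(w < 0)) stop("negative weight at row(s): ",
                       paste(which(w < 0), collapse = ", "))
  if (any(src == tgt)) stop("self-link at row(s): ",
                            paste(which(src == tgt), collapse = ", "))
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    if (duplicates == "error")
      stop("duplicate (source, target) rows at: ",
           paste(which(duplicated(key)), collapse = ", "),
           " (pass duplicates = \"sum\" to aggregate)")
    w <- as.vector(tapply(w, key, sum)[unique(key)])
    src <- sub("\r.*", "", unique(key)); tgt <- sub(".*\r", "", unique(key))
  }
  meta <- if (!is.null(node_meta)) read_node_meta(node_meta) else NULL
  labels <- unique(c(meta$label, src, tgt))
  W <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  W[cbind(src, tgt)] <- w
  nodes <- data.frame(label = labels, measured = labels %in% tgt,
                      stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    idx <- match(labels, meta$label)
    for (col in setdiff(names(meta), "label")) nodes[[col]] <- meta[[col]][idx]
    nodes$measured[is.na(nodes$measured)] <- labels[is.na(nodes$measured)] %in% tgt
  }
  connectome(nodes, W, weight_kind)
}

#' Write a connectome as a link list
#'
#' @param c a [connectome]
#' @param path output path
#' @param sep field separator (default tab)
#' @export
write_link_list <- function(c, path, sep = "\t") {
  idx <- which(c$W > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(source = rownames(c$W)[idx[, 1]],
                   target = colnames(c$W)[idx[, 2]],
                   weight = c$W[idx])
  if (!is.null(c$D)) df$distance_mm <- c$D[idx]
  header <- sprintf("# directed link list (rows: source%starget%sweight%s), weights = %s",
                    sep, sep, if (is.null(c$D)) "" else paste0(sep, "distance_mm"),
                    c$weight_kind)
  writeLines(header, path)
  suppressWarnings(utils::write.table(df, path, sep = sep, quote = FALSE,
                                      row.names = FALSE, col.names = TRUE,
                                      append = TRUE))
  invisible(path)
}

#' Read a labelled adjacency matrix
#'
#' Reads a delimited matrix whose first column holds source labels and whose
#' header row holds target labels. Row and column label sets are unioned into
#' one node set; entries absent in either direction are 0. Targets present as
#' matrix columns are flagged measured iff their column has any weight.
#'
#' @inheritParams read_link_list
#' @param path path to the matrix file
#' @return a [connectome]
#' @export
read_adjacency <- function(path, node_meta = NULL,
                           weight_kind = c("LNe", "FLNe")) {
  weight_kind <- match.arg(weight_kind)
  df <- read_delim_file(path)
  if (is.null(df) || nrow(df) < 1 || ncol(df) < 2)
    stop("no adjacency matrix parsed from ", path)
  col_labels <- as.character(unlist(df[1, -1]))
  row_labels <- as.character(df[[1]][-1])
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels))
    stop("duplicate row or column labels in ", path)
  vals <- suppressWarnings(apply(df[-1, -1, drop = FALSE], c(1, 2), as.numeric))
  if (anyNA(vals)) stop("non-numeric cell(s) in ", path)
  meta <- if (!is.null(node_meta)) read_node_meta(node_meta) else NULL
  labels <- unique(c(meta$label, row_labels, col_labels))
  W <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  W[row_labels, col_labels] <- vals
  measured_cols <- col_labels[colSums(W[, col_labels, drop = FALSE]) > 0]
  nodes <- data.frame(label = labels, measured = labels %in% measured_cols,
                      stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    idx <- match(labels, meta$label)
    for (col in setdiff(names(meta), c("label", "measured")))
      nodes[[col]] <- meta[[col]][idx]
    if ("measured" %in% names(meta)) {
      m <- meta$measured[idx]
      nodes$measured <- ifelse(is.na(m), nodes$measured, m)
    }
  }
  connectome(nodes, W, weight_kind)
}

#' Write a connectome as a labelled adjacency matrix
#' @param c a [connectome]
#' @param path output path
#' @param sep field separator (default tab)
#' @export
write_adjacency <- function(c, path, sep = "\t") {
  df <- data.frame(source = rownames(c$W), c$W, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read node metadata
#'
#' Columns: `label region x y z measured` (header optional; x/y/z in mm,
#' measured as 0/1 or TRUE/FALSE).
#' @param path path to the metadata file
#' @return data.frame with columns label, region, x, y, z, measured
#' @export
read_node_meta <- function(path) {
  df <- read_delim_file(path)
  if (is.null(df)) stop("no node metadata parsed from ", path)
  if (has_header(df, 3:5)) df <- df[-1, , drop = FALSE]
  if (ncol(df) < 6) stop("node metadata needs 6 columns: label region x y z measured")
  out <- data.frame(label = as.character(df[[1]]),
                    region = as.character(df[[2]]),
                    x = as.numeric(df[[3]]), y = as.numeric(df[[4]]),
                    z = as.numeric(df[[5]]),
                    measured = as.logical(as.numeric(df[[6]]) > 0) |
                      toupper(df[[6]]) == "TRUE",
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$label)) stop("duplicate labels in ", path)
  out
}

#' Write node metadata
#' @param c a [connectome]
#' @param path output path
#' @param sep field separator (default tab)
#' @export
write_node_meta <- function(c, path, sep = "\t") {
  nodes <- c$nodes
  for (col in c("region", "x", "y", "z")) if (is.null(nodes[[col]])) nodes[[col]] <- NA
  out <- nodes[, c("label", "region", "x", "y", "z", "measured")]
  out$measured <- as.integer(out$measured)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tracer injection records
#'
#' One row per tracer experiment at a target area: `target injection_volume
#' LNi LNe LNtot` (LNi = labelled neurons intrinsic to the injected volume,
#' LNe = extrinsic, LNtot = total). Repeated targets (repeat experiments) are
#' allowed.
#'
#' @param path path to the records file
#' @return data.frame with columns target, injection_volume, LNi, LNe, LNtot
#' @export
read_injection_records <- function(path) {
  df <- read_delim_file(path)
  if (is.null(df)) stop("no injection records parsed from ", path)
  if (has_header(df, 2:3)) df <- df[-1, , drop = FALSE]
  if (ncol(df) < 5) stop("injection records need 5 columns")
  out <- data.frame(target = as.character(df[[1]]),
                    injection_volume = as.numeric(df[[2]]),
                    LNi = as.numeric(df[[3]]), LNe = as.numeric(df[[4]]),
                    LNtot = as.numeric(df[[5]]), stringsAsFactors = FALSE)
  if (any(out$LNi < 0 | out$LNe < 0 | out$LNtot < 0, na.rm = TRUE))
    stop("labelled-neuron counts must be non-negative")
  ok <- is.na(out$LNtot) | abs(out$LNtot - (out$LNi + out$LNe)) < 1e-6
  if (!all(ok))
    warning(sum(!ok), " record(s) have LNtot != LNi + LNe")
  out
}

#' Write injection records
#' @param records data.frame as returned by [read_injection_records]
#' @param path output path
#' @param sep field separator (default tab)
#' @export
write_injection_records <- function(records, path, sep = "\t") {
  utils::write.table(records, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
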