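#' Ward contiguity graph
#'
#' A `ward_graph` stores the neighbourhood structure over electoral wards:
#' the ordered ward labels, each ward's set of adjacent wards (the
#' neighbourhood sets \eqn{\delta_i}) and the neighbour counts \eqn{\nu_i}.
#' Adjacency is symmetric and self-loops are rejected.
#'
#' @param wards character vector of unique, non-empty ward labels.
#' @param edges two-column matrix or data frame of ward-label pairs; each
#'   undirected edge need only be listed once.
#' @return An object of class `ward_graph` with elements `wards`,
#'   `neighbours` (list of 1-based integer vectors) and `degrees`.
#' @examples
#' g <- ward_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' degrees(g)
#' @export
ward_graph <- function(wards, edges = NULL) {
  wards <- as.character(wards)
  if (length(wards) < 1L) stop("a ward graph needs at least one ward")
  if (anyDuplicated(wards)) stop("duplicated ward labels")
  if (any(!nzchar(wards))) stop("ward labels must be non-empty")
  K <- length(wards)
  nbrs <- rep(list(integer(0)), K)
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    a <- match(as.character(edges[, 1L]), wards)
    b <- match(as.character(edges[, 2L]), wards)
    if (anyNA(a) || anyNA(b)) {
      bad <- unique(c(edges[, 1L][is.na(a)], edges[, 2L][is.na(b)]))
      stop("edge refers to unknown ward(s): ", paste(bad, collapse = ", "))
    }
    if (any(a == b)) stop("self-loop edge for ward ", wards[a[a == b][1L]])
    for (t in seq_along(a)) {
      nbrs[[a[t]]] <- c(nbrs[[a[t]]], b[t])
      nbrs[[b[t]]] <- c(nbrs[[b[t]]], a[t])
    }
    nbrs <- lapply(nbrs, function(v) sort(unique(v)))
  }
  structure(
    list(wards = wards, neighbours = nbrs,
         degrees = vapply(nbrs, length, integer(1))),
    class = "ward_graph")
}

#' @export
print.ward_graph <- function(x, ...) {
  cat("ward_graph with", length(x$wards), "wards and",
      sum(x$degrees) / 2, "edges\n")
  cat("degrees: ", paste(range(x$degrees), collapse = "-"),
      " (mean ", round(mean(x$degrees), 2), ")\n", sep = "")
  invisible(x)
}

#' Number of wards in a graph
#' @param graph a [ward_graph()].
#' @return Integer ward count \eqn{K}.
#' @export
n_wards <- function(graph) length(graph$wards)

#' Ward neighbour counts
#' @param graph a [ward_graph()].
#' @return Named integer vector \eqn{\nu_i}.
#' @export
degrees <- function(graph) stats::setNames(graph$degrees, graph$wards)

#' Connected components of a ward graph
#'
#' Breadth-first labelling of the contiguity graph; isolated wards form
#' their own components. Component membership determines the sum-to-zero
#' constraint groups of the ICAR model and its rank \eqn{K - c}.
#'
#' @param graph a [ward_graph()].
#' @return Integer vector of 1-based component ids, one per ward.
#' @export
graph_components <- function(graph) {
  K <- n_wards(graph)
  comp <- integer(K)
  cur <- 0L
  for (s in seq_len(K)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nxt <- graph$neighbours[[v]]
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      queue <- c(queue, nxt)
    }
  }
  comp
}

#' Graph Laplacian of a ward graph
#' @param graph a [ward_graph()].
#' @return Dense K x K matrix \eqn{L = D - A}.
#' @export
laplacian_matrix <- function(graph) {
  K <- n_wards(graph)
  L <- matrix(0, K, K, dimnames = list(graph$wards, graph$wards))
  for (i in seq_len(K)) L[i, graph$neighbours[[i]]] <- -1
  diag(L) <- graph$degrees
  L
}

#' Edge list of a ward graph
#' @param graph a [ward_graph()].
#' @return Two-column character matrix, each undirected edge once.
#' @export
edge_list <- function(graph) {
  out <- NULL
  for (i in seq_len(n_wards(graph))) {
    js <- graph$neighbours[[i]]
    js <- js[js > i]
    if (length(js))
      out <- rbind(out, cbind(graph$wards[i], graph$wards[js]))
  }
  if (is.null(out)) out <- matrix(character(0), 0, 2)
  colnames(out) <- c("ward_a", "ward_b")
  out
}

#' Induced subgraph on a subset of wards
#' @param graph a [ward_graph()].
#' @param keep character vector of ward labels to retain.
#' @return A [ward_graph()] on the retained wards.
#' @export
subgraph <- function(graph, keep) {
  keep <- as.character(keep)
  if (!all(keep %in% graph$wards)) stop("unknown ward(s) in `keep`")
  el <- edge_list(graph)
  el <- el[el[, 1L] %in% keep & el[, 2L] %in% keep, , drop = FALSE]
  ward_graph(graph$wards[graph$wards %in% keep], el)
}

#' Read a ward adjacency file
#'
#' Two dialects are supported. `"edge_list"`: one `ward_a<TAB>ward_b` pair
#' per line, each undirected edge listed once (either orientation).
#' `"geobugs"`: a ward-count line, then one line per ward holding its
#' neighbour count followed by its 1-based neighbour indices; entries must
#' be symmetric. An optional `# wards: <labels>` comment carries ward
#' labels (written by [write_adjacency()]); otherwise wards are labelled
#' by index.
#'
#' @param path file to read.
#' @param format `"edge_list"` or `"geobugs"`.
#' @param encoding text encoding of the file.
#' @return A [ward_graph()].
#' @export
read_adjacency <- function(path, format = c("edge_list", "geobugs"),
                           encoding = "UTF-8") {
  format <- match.arg(format)
  lines <- readLines(path, encoding = encoding)
  labels <- NULL
  lab_line <- grep("^#\\s*wards:", lines)
  if (length(lab_line))
    labels <- strsplit(trimws(sub("^#\\s*wards:", "", lines[lab_line[1L]])),
                       "\\s+")[[1L]]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (format == "edge_list") {
    if (!length(lines)) {
      if (!is.null(labels)) return(ward_graph(labels))
      stop("empty adjacency file")
    }
    parts <- strsplit(lines, "[\t ]+")
    bad <- which(vapply(parts, length, integer(1)) != 2L)
    if (length(bad)) stop("malformed edge on line ", bad[1L])
    el <- do.call(rbind, parts)
    wards <- if (is.null(labels)) unique(as.vector(t(el))) else labels
    return(ward_graph(wards, el))
  }
  # geobugs dialect
  K <- suppressWarnings(as.integer(lines[1L]))
  if (is.na(K) || K < 1L) stop("geobugs file must start with the ward count")
  if (length(lines) != K + 1L)
    stop("expected ", K, " ward lines, found ", length(lines) - 1L)
  wards <- if (is.null(labels)) as.character(seq_len(K)) else labels
  if (length(wards) != K) stop("ward label count does not match ward count")
  nbrs <- vector("list", K)
  for (i in seq_len(K)) {
    v <- suppressWarnings(as.integer(strsplit(trimws(lines[i + 1L]),
                                              "[\t ]+")[[1L]]))
    if (anyNA(v)) stop("non-integer entry on ward line ", i)
    if (length(v) != v[1L] + 1L)
      stop("ward line ", i, ": neighbour count does not match entries")
    idx <- v[-1L]
    if (any(idx < 1L | idx > K)) stop("ward line ", i, ": index out of range")
    if (any(idx == i)) stop("self-loop for ward ", wards[i])
    nbrs[[i]] <- sort(unique(idx))
  }
  for (i in seq_len(K))
    for (j in nbrs[[i]])
      if (!(i %in% nbrs[[j]]))
        stop("asymmetric adjacency: ", wards[i], " lists ", wards[j],
             " but not vice versa")
  el <- NULL
  for (i in seq_len(K)) {
    js <- nbrs[[i]][nbrs[[i]] > i]
    if (length(js)) el <- rbind(el, cbind(wards[i], wards[js]))
  }
  ward_graph(wards, el)
}

#' Write a ward adjacency file
#'
#' Writes either dialect read by [read_adjacency()]; both include a
#' `# wards:` label comment so a write/read round trip reproduces the
#' graph exactly, labels included.
#'
#' @param graph a [ward_graph()].
#' @param path output file.
#' @param format `"edge_list"` or `"geobugs"`.
#' @export
write_adjacency <- function(graph, path,
                            format = c("edge_list", "geobugs")) {
  format <- match.arg(format)
  header <- paste("# wards:", paste(graph$wards, collapse = " "))
  if (format == "edge_list") {
    el <- edge_list(graph)
    writeLines(c(header, paste(el[, 1L], el[, 2L], sep = "\t")), path)
  } else {
    body <- vapply(seq_len(n_wards(graph)), function(i)
      paste(c(graph$degrees[i], graph$neighbours[[i]]), collapse = " "),
      character(1))
    writeLines(c(header, n_wards(graph), body), path)
  }
  invisible(path)
}
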