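# -- co-occurrence counting and the connectivity network -----------------

#' Pairwise co-occurrence counts from tagged articles
#'
#' Builds the symmetric count table of the analysis: the diagonal holds the
#' number of articles tagged with each concept, the off-diagonal the number
#' tagged with both concepts of the pair. One increment per article per
#' unordered pair.
#'
#' @param tags a `tagged_corpus` from [tag_corpus()], or a bare list of
#'   `tagged_article` objects.
#' @param node_names concept names defining rows/columns (scheme order is
#'   conventional).
#' @param level `"parent"` reads each article's `parent_tags`, `"child"` its
#'   `child_tags`.
#' @return An object of class `cooccurrence_matrix`: an integer matrix with
#'   `dimnames` of `node_names` and attribute `level`.
#' @export
cooccurrence_counts <- function(tags, node_names, level = c("parent", "child")) {
  level <- match.arg(level)
  if (inherits(tags, "tagged_corpus")) tags <- tags$tags
  if (anyDuplicated(node_names)) {
    stop("node_names must be distinct", call. = FALSE)
  }
  m <- length(node_names)
  counts <- matrix(0L, m, m, dimnames = list(node_names, node_names))
  field <- if (level == "parent") "parent_tags" else "child_tags"
  for (t in tags) {
    # tags outside the requested node set are simply not counted
    present <- intersect(t[[field]], node_names)
    idx <- match(present, node_names)
    if (length(idx)) {
      counts[cbind(idx, idx)] <- counts[cbind(idx, idx)] + 1L
      if (length(idx) > 1L) {
        pr <- utils::combn(sort(idx), 2L)
        counts[t(pr)] <- counts[t(pr)] + 1L
        counts[t(pr)[, 2:1, drop = FALSE]] <-
          counts[t(pr)[, 2:1, drop = FALSE]] + 1L
      }
    }
  }
  structure(counts, level = level, class = c("cooccurrence_matrix", "matrix"))
}

#' Validate a co-occurrence matrix
#'
#' @param counts matrix to check: symmetric, non-negative integers, and
#'   every off-diagonal entry bounded by the smaller of the two diagonals.
#' @return `counts`, invisibly; invalid input is fatal.
#' @export
check_cooccurrence <- function(counts) {
  m <- unclass(counts)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("co-occurrence counts must be a square matrix", call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("co-occurrence counts must be non-negative integers", call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m)))) {
    stop("co-occurrence counts must be symmetric", call. = FALSE)
  }
  d <- diag(m)
  cap <- outer(d, d, pmin)
  off <- m; diag(off) <- 0L
  if (any(off > cap)) {
    bad <- which(off > cap, arr.ind = TRUE)[1L, ]
    stop("co-occurrence count N[", rownames(m)[bad[1L]], ", ",
         colnames(m)[bad[2L]], "] exceeds min of the diagonal counts",
         call. = FALSE)
  }
  invisible(counts)
}

#' Build the keyword-normalized connectivity network
#'
#' For each concept pair with at least one joint study, the edge statistic is
#' the connectivity value \eqn{C_{ab} = N_{ab} / (K_a + K_b)}: the number of
#' articles tagged with both concepts divided by the total number of keywords
#' assigned to the two concepts. A node's weighted degree \eqn{W_a} is the
#' sum of the connectivity values of its incident edges. Nodes with zero
#' assigned keywords are excluded (with a warning) before any computation;
#' isolated nodes with keywords are kept.
#'
#' @param counts a [cooccurrence_counts()] matrix.
#' @param scheme the [concept_scheme()] providing keyword counts and
#'   categories.
#' @return An object of class `connectivity_network`: a list with `nodes`
#'   (data frame: `name`, `category`, `keyword_count`, `weighted_degree`),
#'   `edges` (data frame: `from`, `to`, `study_count`, `connectivity`, with
#'   `from < to` lexicographically), `median_connectivity` (`NA` when there
#'   are no edges) and `level`.
#' @export
connectivity_network <- function(counts, scheme) {
  check_cooccurrence(counts)
  level <- attr(counts, "level")
  if (is.null(level)) level <- "parent"
  nm <- rownames(counts)
  K <- keyword_count(scheme, nm)
  if (any(K == 0L)) {
    warning("excluding zero-keyword node(s) from the network: ",
            paste(nm[K == 0L], collapse = ", "), call. = FALSE)
    keep <- nm[K > 0L]
    counts <- counts[keep, keep, drop = FALSE]
    nm <- keep
    K <- K[keep]
  }
  m <- unclass(counts)
  edges <- data.frame(from = character(), to = character(),
                      study_count = integer(), connectivity = numeric(),
                      stringsAsFactors = FALSE)
  if (length(nm) > 1L) {
    pairs <- utils::combn(seq_along(nm), 2L)
    nab <- m[t(pairs)]
    keep <- nab > 0L
    if (any(keep)) {
      i <- pairs[1L, keep]; j <- pairs[2L, keep]
      a <- nm[i]; b <- nm[j]
      swap <- a > b
      from <- ifelse(swap, b, a); to <- ifelse(swap, a, b)
      edges <- data.frame(from = from, to = to,
                          study_count = as.integer(nab[keep]),
                          connectivity = nab[keep] / (K[i] + K[j]),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$from, edges$to, method = "radix"), ]
      row.names(edges) <- NULL
    }
  }
  W <- vapply(nm, function(a) {
    sum(edges$connectivity[edges$from == a | edges$to == a])
  }, 0)
  nodes <- data.frame(name = nm,
                      category = unname(node_category(scheme, nm)),
                      keyword_count = as.integer(unname(K)),
                      weighted_degree = unname(W),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 median_connectivity = if (nrow(edges)) {
                   stats::median(edges$connectivity)
                 } else NA_real_,
                 level = level),
            class = "connectivity_network")
}

#' @export
print.connectivity_network <- function(x, ...) {
  cat(sprintf("<connectivity_network> %d node(s), %d edge(s)",
              nrow(x$nodes), nrow(x$edges)))
  if (!is.na(x$median_connectivity)) {
    cat(sprintf(", median connectivity %.4g", x$median_connectivity))
  }
  cat("\n")
  invisible(x)
}

#' Median of the edge connectivity values
#'
#' The median is taken over realized edges only (pairs with at least one
#' joint study); absent pairs are gaps, not zero-weight edges. Even edge
#' counts use the midpoint convention.
#'
#' @param network a [connectivity_network()].
#' @return numeric scalar.
#' @export
median_connectivity <- function(network) {
  if (!nrow(network$edges)) {
    stop("median undefined: network has no edges", call. = FALSE)
  }
  stats::median(network$edges$connectivity)
}

#' The weak sub-network: edges strictly below the median
#'
#' Retains exactly the edges whose connectivity is strictly below the
#' network's median, plus every node incident to a retained edge; weighted
#' degrees (and the median) are recomputed within the sub-network. With all
#' edges equal the result has no edges.
#'
#' @param network a [connectivity_network()].
#' @return A `connectivity_network`.
#' @export
below_median_subnetwork <- function(network) {
  med <- median_connectivity(network)
  keep <- network$edges$connectivity < med
  edges <- network$edges[keep, , drop = FALSE]
  row.names(edges) <- NULL
  node_keep <- network$nodes$name %in% c(edges$from, edges$to)
  nodes <- network$nodes[node_keep, , drop = FALSE]
  row.names(nodes) <- NULL
  nodes$weighted_degree <- vapply(nodes$name, function(a) {
    sum(edges$connectivity[edges$from == a | edges$to == a])
  }, 0, USE.NAMES = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 median_connectivity = if (nrow(edges)) {
                   stats::median(edges$connectivity)
                 } else NA_real_,
                 level = network$level),
            class = "connectivity_network")
}

#' The k strongest pairwise connections
#'
#' Edges sorted by connectivity descending; ties broken by lexicographic
#' order of the (already sorted) pair names.
#'
#' @param network a [connectivity_network()].
#' @param k number of edges to return; must not exceed the edge count.
#' @return data frame of `k` edge rows in rank order.
#' @export
top_k_pairs <- function(network, k) {
  stopifnot(k >= 1)
  ne <- nrow(network$edges)
  if (ne < k) {
    stop("requested top ", k, " pairs but the network has only ", ne,
         " edge(s)", call. = FALSE)
  }
  e <- network$edges
  ord <- order(-e$connectivity, e$from, e$to, method = "radix")
  out <- e[ord[seq_len(k)], , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Child-level drill-down network
#'
#' Builds the secondary network of child nodes under a set of parents —
#' typically the parents involved in the strongest pairwise connections of
#' the main network. Node set: every child of a parent in `parent_subset`
#' with at least one assigned keyword; counts come from the articles'
#' child tags; connectivity is normalized by child keyword counts.
#'
#' @param tags a `tagged_corpus` (or list of `tagged_article`).
#' @param scheme a [concept_scheme()].
#' @param parent_subset non-empty character vector of parent node names.
#' @return A `connectivity_network` at child level (empty, with a warning,
#'   when no eligible child exists).
#' @export
child_network <- function(tags, scheme, parent_subset) {
  if (!length(parent_subset)) {
    stop("parent_subset must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(parent_subset, parent_nodes(scheme))
  if (length(unknown)) {
    stop("unknown parent node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nd <- scheme$nodes
  kids <- nd$name[nd$level == "child" & nd$parent_name %in% parent_subset]
  if (length(kids)) kids <- kids[keyword_count(scheme, kids) > 0L]
  if (!length(kids)) {
    warning("no child node with assigned keywords under the given parents; ",
            "returning an empty network", call. = FALSE)
    return(structure(list(
      nodes = data.frame(name = character(), category = character(),
                         keyword_count = integer(),
                         weighted_degree = numeric(),
                         stringsAsFactors = FALSE),
      edges = data.frame(from = character(), to = character(),
                         study_count = integer(), connectivity = numeric(),
                         stringsAsFactors = FALSE),
      median_connectivity = NA_real_, level = "child"),
      class = "connectivity_network"))
  }
  counts <- cooccurrence_counts(tags, kids, level = "child")
  connectivity_network(counts, scheme)
}

#' Write co-occurrence and connectivity matrices to CSV
#'
#' The count matrix mirrors the analysis's deposited form: node names on
#' both axes, co-occurrence counts off-diagonal and per-concept article
#' counts on the diagonal. A parallel connectivity-value matrix (zero where
#' no edge, diagonal zero) is written alongside as
#' `<stem>_connectivity.csv`.
#'
#' @param counts a [cooccurrence_counts()] matrix.
#' @param scheme a [concept_scheme()].
#' @param path output CSV path for the count matrix.
#' @return invisible character vector of the two paths written.
#' @export
write_matrix_csv <- function(counts, scheme, path) {
  check_cooccurrence(counts)
  m <- unclass(counts)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  nm <- rownames(m)
  K <- keyword_count(scheme, nm)
  keep <- K > 0L
  conn <- matrix(0, sum(keep), sum(keep),
                 dimnames = list(nm[keep], nm[keep]))
  Kk <- K[keep]
  for (i in seq_len(nrow(conn))) {
    for (j in seq_len(ncol(conn))) {
      if (i != j) {
        conn[i, j] <- m[nm[keep][i], nm[keep][j]] / (Kk[i] + Kk[j])
      }
    }
  }
  path2 <- paste0(tools::file_path_sans_ext(path), "_connectivity.csv")
  utils::write.csv(as.data.frame(conn), path2, row.names = TRUE)
  invisible(c(path, path2))
}

#' Serialize a connectivity network to JSON
#'
#' @param network a [connectivity_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  obj <- list(level = network$level, nodes = network$nodes,
              edges = network$edges,
              median_connectivity = network$median_connectivity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read a connectivity network written by [write_network_json()]
#'
#' @param path JSON path.
#' @return A `connectivity_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        study_count = integer(), connectivity = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 median_connectivity =
                   if (is.null(obj$median_connectivity)) NA_real_
                   else obj$median_connectivity,
                 level = obj$level),
            class = "connectivity_network")
}
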