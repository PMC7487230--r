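# -- hierarchical concept scheme -----------------------------------------

#' Construct a concept scheme
#'
#' A concept scheme is a two-level ontology of research concepts plus a
#' curated keyword-assignment map. Parent nodes belong to open-ended
#' categories (e.g. "Ecology", "Evolution", "General Characteristics");
#' child nodes refine a single parent. Every keyword is assigned to exactly
#' one parent and optionally to one child of that parent. The per-node
#' keyword count is the normalization denominator ingredient of the
#' connectivity statistic: a child's keywords also count toward its parent.
#'
#' @param nodes data frame with columns `name`, `category`, `level`
#'   (`"parent"` or `"child"`) and `parent_name` (`NA` for parents).
#' @param assignments data frame with columns `keyword`, `parent_name` and
#'   `child_name` (`NA` when the keyword maps only to the parent). Keywords
#'   are normalized with [normalize_text()] on construction.
#' @param validate if `TRUE` (default) invariant violations are fatal; set
#'   `FALSE` to build a possibly-invalid scheme for inspection with
#'   [validate_scheme()].
#' @return An object of class `concept_scheme`.
#' @export
concept_scheme <- function(nodes, assignments, validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  need_n <- c("name", "category", "level", "parent_name")
  if (!all(need_n %in% names(nodes))) {
    stop("nodes must have columns: ", paste(need_n, collapse = ", "),
         call. = FALSE)
  }
  need_a <- c("keyword", "parent_name", "child_name")
  if (!all(need_a %in% names(assignments))) {
    stop("assignments must have columns: ", paste(need_a, collapse = ", "),
         call. = FALSE)
  }
  nodes <- nodes[, need_n]
  assignments <- assignments[, need_a]
  assignments$keyword <- vapply(assignments$keyword, normalize_text, "",
                                USE.NAMES = FALSE)
  scheme <- structure(list(nodes = nodes, assignments = assignments),
                      class = "concept_scheme")
  if (validate) {
    v <- validate_scheme(scheme)
    if (length(v)) {
      stop("invalid concept scheme:\n  - ", paste(v, collapse = "\n  - "),
           call. = FALSE)
    }
    zero <- parent_nodes(scheme)
    zero <- c(zero, child_nodes(scheme))
    kc <- keyword_count(scheme, zero)
    if (any(kc == 0L)) {
      warning("concept node(s) with zero assigned keywords (omitted from ",
              "networks): ", paste(zero[kc == 0L], collapse = ", "),
              call. = FALSE)
    }
  }
  scheme
}

#' @export
print.concept_scheme <- function(x, ...) {
  np <- sum(x$nodes$level == "parent")
  nc <- sum(x$nodes$level == "child")
  cat(sprintf(
    "<concept_scheme> %d parent node(s), %d child node(s), %d categories, %d keyword assignment(s)\n",
    np, nc, length(unique(x$nodes$category)), nrow(x$assignments)))
  invisible(x)
}

#' List parent- or child-level node names
#' @param scheme a [concept_scheme()].
#' @return character vector of node names, in scheme order.
#' @export
parent_nodes <- function(scheme) {
  scheme$nodes$name[scheme$nodes$level == "parent"]
}

#' @rdname parent_nodes
#' @export
child_nodes <- function(scheme) {
  scheme$nodes$name[scheme$nodes$level == "child"]
}

#' Keywords assigned to each node
#'
#' For a parent node, counts every assignment naming that parent (including
#' assignments that also name one of its children); for a child node, only
#' assignments naming that child.
#'
#' @param scheme a [concept_scheme()].
#' @param node_names character vector of node names.
#' @return named integer vector of keyword counts.
#' @export
keyword_count <- function(scheme, node_names) {
  lvl <- scheme$nodes$level[match(node_names, scheme$nodes$name)]
  if (anyNA(lvl)) {
    stop("unknown node(s): ", paste(node_names[is.na(lvl)], collapse = ", "),
         call. = FALSE)
  }
  n <- vapply(seq_along(node_names), function(i) {
    if (lvl[i] == "parent") {
      sum(scheme$assignments$parent_name == node_names[i])
    } else {
      sum(!is.na(scheme$assignments$child_name) &
            scheme$assignments$child_name == node_names[i])
    }
  }, 1L)
  stats::setNames(n, node_names)
}

#' Category of each node
#'
#' Child nodes inherit their parent's category.
#' @inheritParams keyword_count
#' @return named character vector.
#' @export
node_category <- function(scheme, node_names) {
  i <- match(node_names, scheme$nodes$name)
  if (anyNA(i)) {
    stop("unknown node(s): ", paste(node_names[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(scheme$nodes$category[i], node_names)
}

#' Validate a concept scheme
#'
#' Checks every structural invariant and returns all violations as data
#' rather than raising: duplicate node names, children pointing at missing
#' or non-parent nodes, parents carrying a parent_name, duplicate keywords,
#' assignments referencing unknown parents or children, and child
#' assignments whose child does not belong to the named parent.
#'
#' @param scheme a `concept_scheme` (possibly built with `validate = FALSE`).
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_scheme <- function(scheme) {
  v <- character()
  nd <- scheme$nodes
  as_ <- scheme$assignments

  dup <- unique(nd$name[duplicated(nd$name)])
  for (d in dup) v <- c(v, paste0("duplicate node name: ", d))
  bad_lvl <- nd$name[!nd$level %in% c("parent", "child")]
  for (b in bad_lvl) v <- c(v, paste0("node with invalid level: ", b))

  parents <- nd$name[nd$level == "parent"]
  is_child <- nd$level == "child"
  miss_par <- is_child & (is.na(nd$parent_name) | !nzchar(nd$parent_name))
  for (b in nd$name[miss_par]) {
    v <- c(v, paste0("child node without parent_name: ", b))
  }
  dangling <- is_child & !miss_par & !(nd$parent_name %in% parents)
  for (i in which(dangling)) {
    v <- c(v, paste0("child node '", nd$name[i],
                     "' references nonexistent parent '", nd$parent_name[i], "'"))
  }
  stray <- nd$level == "parent" & !is.na(nd$parent_name) & nzchar(nd$parent_name)
  for (b in nd$name[stray]) {
    v <- c(v, paste0("parent node with a parent_name: ", b))
  }

  if (nrow(as_)) {
    blank <- !nzchar(as_$keyword)
    if (any(blank)) v <- c(v, "assignment with empty keyword")
    dupk <- unique(as_$keyword[duplicated(as_$keyword) & !blank])
    for (d in dupk) v <- c(v, paste0("keyword assigned more than once: ", d))
    badp <- !(as_$parent_name %in% parents)
    for (i in which(badp)) {
      v <- c(v, paste0("assignment '", as_$keyword[i],
                       "' references unknown parent '", as_$parent_name[i], "'"))
    }
    has_child <- !is.na(as_$child_name) & nzchar(as_$child_name)
    child_par <- nd$parent_name[match(as_$child_name, nd$name)]
    badc <- has_child & is.na(child_par)
    for (i in which(badc)) {
      v <- c(v, paste0("assignment '", as_$keyword[i],
                       "' references unknown child '", as_$child_name[i], "'"))
    }
    mismatch <- has_child & !badc & child_par != as_$parent_name
    for (i in which(mismatch)) {
      v <- c(v, paste0("assignment '", as_$keyword[i], "': child '",
                       as_$child_name[i], "' does not belong to parent '",
                       as_$parent_name[i], "'"))
    }
  }
  v
}

#' Load a concept scheme from CSV files
#'
#' `nodes_file` has columns `category,parent,child` — one row per node, with
#' `child` empty on parent rows. `keyword_map_file` has columns
#' `keyword,parent,child` with `child` optional. Keywords are normalized on
#' load so that the map and the text matcher agree.
#'
#' @param nodes_file CSV of nodes.
#' @param keyword_map_file CSV of keyword assignments.
#' @return A validated [concept_scheme()].
#' @export
load_scheme <- function(nodes_file, keyword_map_file) {
  for (f in c(nodes_file, keyword_map_file)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  nd <- utils::read.csv(nodes_file, colClasses = "character",
                        encoding = "UTF-8")
  km <- utils::read.csv(keyword_map_file, colClasses = "character",
                        encoding = "UTF-8")
  if (!all(c("category", "parent") %in% names(nd))) {
    stop("nodes file must have columns category,parent[,child]", call. = FALSE)
  }
  if (!"child" %in% names(nd)) nd$child <- ""
  if (!all(c("keyword", "parent") %in% names(km))) {
    stop("keyword map file must have columns keyword,parent[,child]",
         call. = FALSE)
  }
  if (!"child" %in% names(km)) km$child <- ""
  is_child <- nzchar(trimws(nd$child))
  nodes <- data.frame(
    name = ifelse(is_child, trimws(nd$child), trimws(nd$parent)),
    category = trimws(nd$category),
    level = ifelse(is_child, "child", "parent"),
    parent_name = ifelse(is_child, trimws(nd$parent), NA_character_),
    stringsAsFactors = FALSE)
  assignments <- data.frame(
    keyword = trimws(km$keyword),
    parent_name = trimws(km$parent),
    child_name = ifelse(nzchar(trimws(km$child)), trimws(km$child),
                        NA_character_),
    stringsAsFactors = FALSE)
  concept_scheme(nodes, assignments)
}

#' Input keywords lacking a scheme assignment
#'
#' Supports the manual curation loop: after pooling a corpus's KeyWords Plus,
#' this reports which ones still need an assignment (or deliberate
#' exclusion). Comparison is over normalized forms; input order is preserved.
#'
#' @param keywords character vector of phrases.
#' @param scheme a [concept_scheme()].
#' @return the sub-vector of `keywords` with no assignment.
#' @export
unassigned_keywords <- function(keywords, scheme) {
  if (!length(keywords)) return(character())
  norm <- vapply(keywords, normalize_text, "", USE.NAMES = FALSE)
  keywords[!(norm %in% scheme$assignments$keyword)]
}

#' The packaged plant-rarity concept scheme (nodes only)
#'
#' The 14-parent, 3-category node hierarchy used in the plant species rarity
#' literature mapping: Ecology and Evolution parents each carry child nodes,
#' General Characteristics parents do not. The curated keyword-assignment map
#' is a separate research artifact and is not bundled; pair these nodes with
#' your own map via [concept_scheme()] or [load_scheme()].
#'
#' @return data frame of nodes in the shape [concept_scheme()] expects.
#' @export
rarity_nodes <- function() {
  f <- system.file("extdata", "rarity_nodes.csv", package = "cowordnet",
                   mustWork = TRUE)
  nd <- utils::read.csv(f, colClasses = "character", encoding = "UTF-8")
  is_child <- nzchar(nd$child)
  data.frame(
    name = ifelse(is_child, nd$child, nd$parent),
    category = nd$category,
    level = ifelse(is_child, "child", "parent"),
    parent_name = ifelse(is_child, nd$parent, NA_character_),
    stringsAsFactors = FALSE)
}
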