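# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately written without calling the package's matching or
# counting code paths, so oracle agreement is a real check.

# run code under a seed without disturbing the session RNG state
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# oracle normalization: same documented rules, independent implementation
oracle_normalize <- function(x) {
  x <- tolower(x)
  for (h in c("-", "‐", "‑", "–", "—")) {
    x <- gsub(h, " ", x, fixed = TRUE)
  }
  trimws(gsub("[[:space:]]+", " ", x))
}

# brute-force phrase matcher: enumerate every start position
oracle_match <- function(keyword, document, mode) {
  L <- nchar(keyword)
  n <- nchar(document)
  if (L > n) return(FALSE)
  starts <- seq_len(n - L + 1L)
  hits <- starts[substring(document, starts, starts + L - 1L) == keyword]
  if (!length(hits)) return(FALSE)
  if (mode == "substring") return(TRUE)
  ok_start <- hits == 1L | substring(document, hits - 1L, hits - 1L) == " "
  if (mode == "word_start") return(any(ok_start))
  ends <- hits + L - 1L
  ok_end <- ends == n | substring(document, ends + 1L, ends + 1L) == " "
  any(ok_start & ok_end)
}

# brute-force tagger over a corpus: one doc per record, scan every keyword
oracle_tag_corpus <- function(corp, scheme, mode) {
  lapply(seq_len(nrow(corp)), function(i) {
    doc <- oracle_normalize(paste(
      corp$title[i], corp$abstract[i],
      paste(corp$author_keywords[[i]], collapse = " "),
      paste(corp$keywords_plus[[i]], collapse = " ")))
    as_ <- scheme$assignments
    hit <- vapply(as_$keyword, oracle_match, NA, document = doc, mode = mode,
                  USE.NAMES = FALSE)
    parents <- sort(unique(as_$parent_name[hit]), method = "radix")
    children <- as_$child_name[hit]
    children <- sort(unique(children[!is.na(children)]), method = "radix")
    list(parent_tags = parents, child_tags = children)
  })
}

# double-loop co-occurrence counter over explicit tag sets
oracle_cooccurrence <- function(tag_sets, node_names) {
  m <- length(node_names)
  counts <- matrix(0L, m, m, dimnames = list(node_names, node_names))
  for (tags in tag_sets) {
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (node_names[i] %in% tags && node_names[j] %in% tags) {
          counts[i, j] <- counts[i, j] + 1L
        }
      }
    }
  }
  counts
}

# hand-built two-category scheme used across tests
tiny_scheme <- function() {
  nodes <- data.frame(
    name = c("Microevolution", "Macroevolution", "Physiology",
             "Gene Flow", "Genetic Drift", "Hybridization"),
    category = c("Evolution", "Evolution", "General Characteristics",
                 "Evolution", "Evolution", "Evolution"),
    level = c("parent", "parent", "parent", "child", "child", "child"),
    parent_name = c(NA, NA, NA, "Microevolution", "Microevolution",
                    "Macroevolution"),
    stringsAsFactors = FALSE)
  assignments <- data.frame(
    keyword = c("gene flow", "genetic drift", "drift load", "hybrid zones",
                "photosynthesis", "selection"),
    parent_name = c("Microevolution", "Microevolution", "Microevolution",
                    "Macroevolution", "Physiology", "Microevolution"),
    child_name = c("Gene Flow", "Genetic Drift", "Genetic Drift",
                   "Hybridization", NA, NA),
    stringsAsFactors = FALSE)
  concept_scheme(nodes, assignments)
}

# random corpus of free-text records (no planted structure)
random_corpus <- function(n, seed = 1) {
  local_seed(seed, {
    vocab <- c("gene", "flow", "drift", "hybrid", "zones", "selection",
               "photosynthesis", "rarity", "plant", "species", "load",
               "genetic", "population", "climate")
    corpus(
      record_id = sprintf("R%03d", seq_len(n)),
      title = vapply(seq_len(n), function(i) {
        paste(sample(vocab, sample(3:6, 1), replace = TRUE), collapse = " ")
      }, ""),
      abstract = vapply(seq_len(n), function(i) {
        paste(sample(vocab, sample(10:25, 1), replace = TRUE), collapse = " ")
      }, ""),
      author_keywords = lapply(seq_len(n), function(i) {
        sample(vocab, sample(0:3, 1))
      }),
      keywords_plus = lapply(seq_len(n), function(i) {
        sample(vocab, sample(0:3, 1))
      }))
  })
}

# a small connectivity_network built directly from explicit parts (bypasses
# counting) for layout/scaling/export tests
manual_network <- function(nodes, edges, level = "parent") {
  W <- vapply(nodes$name, function(a) {
    sum(edges$connectivity[edges$from == a | edges$to == a])
  }, 0, USE.NAMES = FALSE)
  nodes$weighted_degree <- W
  structure(list(nodes = nodes, edges = edges,
                 median_connectivity = if (nrow(edges)) {
                   stats::median(edges$connectivity)
                 } else NA_real_,
                 level = level),
            class = "connectivity_network")
}

# write a WoS-style tab-delimited export file; returns the path
write_wos_fixture <- function(rows, header = c("PT", "TI", "AB", "DE", "ID",
                                               "PY", "UT"),
                              dir = withr::local_tempdir(.local_envir =
                                                           parent.frame())) {
  path <- file.path(dir, "wos_export.txt")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  path
}
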