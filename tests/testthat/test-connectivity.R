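# explicit tag lists make counting cases easy to state
as_tags <- function(sets) {
  lapply(seq_along(sets), function(i) {
    structure(list(record_id = as.character(i), parent_tags = sets[[i]],
                   child_tags = character(),
                   matches = data.frame(keyword = character(),
                                        parent_name = character(),
                                        child_name = character())),
              class = "tagged_article")
  })
}

# scheme with K_a keywords per parent, arbitrary keyword strings
scheme_with_counts <- function(K) {
  nm <- names(K)
  asg <- do.call(rbind, lapply(nm, function(a) {
    data.frame(keyword = sprintf("kw %s %d", tolower(a), seq_len(K[[a]])),
               parent_name = a, child_name = NA_character_)
  }))
  concept_scheme(
    data.frame(name = nm, category = "S", level = "parent",
               parent_name = NA_character_),
    asg)
}

test_that("cooccurrence counting: single-article enumeration", {
  counts <- cooccurrence_counts(as_tags(list(c("A", "B", "C"))),
                                c("A", "B", "C"))
  expect_equal(unclass(counts),
               matrix(1L, 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C"))),
               ignore_attr = TRUE)
  # disjoint articles never co-occur
  counts2 <- cooccurrence_counts(as_tags(list("A", "B")), c("A", "B"))
  expect_equal(counts2[["A", "B"]], 0L)
  expect_equal(diag(unclass(counts2)), c(A = 1L, B = 1L))
})

test_that("cooccurrence counting equals the double-loop oracle", {
  local_seed(31, {
    nodes <- LETTERS[1:6]
    sets <- lapply(1:300, function(i) sample(nodes, sample(0:4, 1)))
    got <- cooccurrence_counts(as_tags(sets), nodes)
    expect_equal(unclass(got), oracle_cooccurrence(sets, nodes),
                 ignore_attr = TRUE)
  })
})

test_that("invalid count matrices are rejected", {
  bad <- matrix(c(2L, 5L, 5L, 3L), 2, 2, dimnames = list(c("A", "B"),
                                                         c("A", "B")))
  expect_error(check_cooccurrence(bad), "exceeds")
  asym <- matrix(c(2L, 1L, 0L, 3L), 2, 2, dimnames = list(c("A", "B"),
                                                          c("A", "B")))
  expect_error(check_cooccurrence(asym), "symmetric")
  expect_error(check_cooccurrence(matrix(-1L, 1, 1)), "non-negative")
})

test_that("connectivity arithmetic and weighted degree", {
  scheme <- scheme_with_counts(c(A = 10L, B = 5L))
  counts <- cooccurrence_counts(
    as_tags(c(rep(list(c("A", "B")), 3), list("A"))), c("A", "B"))
  net <- connectivity_network(counts, scheme)
  expect_equal(net$edges$connectivity, 3 / (10 + 5))  # 0.2
  expect_equal(net$nodes$weighted_degree, c(0.2, 0.2))

  # no joint studies -> no edge, but isolated nodes kept
  counts0 <- cooccurrence_counts(as_tags(list("A", "B")), c("A", "B"))
  net0 <- connectivity_network(counts0, scheme)
  expect_equal(nrow(net0$edges), 0L)
  expect_equal(nrow(net0$nodes), 2L)
  expect_true(is.na(net0$median_connectivity))
  expect_error(median_connectivity(net0), "median undefined")
})

test_that("handshake identity and per-node incident-sum oracle", {
  local_seed(41, {
    for (rep in 1:20) {
      nodes <- LETTERS[1:6]
      K <- stats::setNames(sample(3:20, 6, replace = TRUE), nodes)
      scheme <- scheme_with_counts(K)
      sets <- lapply(1:60, function(i) sample(nodes, sample(0:4, 1)))
      net <- connectivity_network(cooccurrence_counts(as_tags(sets), nodes),
                                  scheme)
      expect_lt(abs(sum(net$nodes$weighted_degree) -
                      2 * sum(net$edges$connectivity)), 1e-12)
      # independent incident-sum per node
      for (a in nodes) {
        inc <- net$edges$connectivity[net$edges$from == a | net$edges$to == a]
        expect_equal(
          net$nodes$weighted_degree[net$nodes$name == a], sum(inc))
      }
    }
  })
})

test_that("doubling every keyword count exactly halves C and W", {
  local_seed(43, {
    nodes <- LETTERS[1:5]
    K <- stats::setNames(sample(2:10, 5, replace = TRUE), nodes)
    sets <- lapply(1:80, function(i) sample(nodes, sample(0:3, 1)))
    counts <- cooccurrence_counts(as_tags(sets), nodes)
    net1 <- connectivity_network(counts, scheme_with_counts(K))
    net2 <- connectivity_network(counts, scheme_with_counts(2L * K))
    expect_identical(net2$edges$connectivity, net1$edges$connectivity / 2)
    expect_identical(net2$nodes$weighted_degree,
                     net1$nodes$weighted_degree / 2)
  })
})

test_that("zero-keyword nodes are excluded with a warning", {
  scheme <- scheme_with_counts(c(A = 4L, B = 2L))
  scheme$nodes <- rbind(scheme$nodes,
                        data.frame(name = "C", category = "S",
                                   level = "parent",
                                   parent_name = NA_character_))
  counts <- cooccurrence_counts(as_tags(list(c("A", "B", "C"))),
                                c("A", "B", "C"))
  expect_warning(net <- connectivity_network(counts, scheme),
                 "zero-keyword")
  expect_setequal(net$nodes$name, c("A", "B"))
})

test_that("median convention over edge values", {
  e3 <- manual_network(
    data.frame(name = LETTERS[1:4], category = "S", keyword_count = 1L),
    data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
               study_count = 1L, connectivity = c(0.1, 0.2, 0.4)))
  expect_equal(median_connectivity(e3), 0.2)
  e2 <- manual_network(
    data.frame(name = LETTERS[1:3], category = "S", keyword_count = 1L),
    data.frame(from = c("A", "B"), to = c("B", "C"), study_count = 1L,
               connectivity = c(0.1, 0.2)))
  expect_equal(median_connectivity(e2), 0.15)
})

test_that("below-median sub-network keeps strictly-below edges only", {
  net <- manual_network(
    data.frame(name = LETTERS[1:4], category = "S", keyword_count = 1L),
    data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
               study_count = 1L, connectivity = c(0.1, 0.2, 0.4)))
  weak <- below_median_subnetwork(net)
  expect_equal(nrow(weak$edges), 1L)
  expect_equal(weak$edges$connectivity, 0.1)
  expect_setequal(weak$nodes$name, c("A", "B"))

  # all edges equal -> empty sub-network
  flat <- manual_network(
    data.frame(name = LETTERS[1:3], category = "S", keyword_count = 1L),
    data.frame(from = c("A", "B"), to = c("B", "C"), study_count = 1L,
               connectivity = c(0.3, 0.3)))
  expect_equal(nrow(below_median_subnetwork(flat)$edges), 0L)
})

test_that("median split partitions edges: below vs not-below", {
  local_seed(47, {
    for (rep in 1:25) {
      nodes <- LETTERS[1:6]
      K <- stats::setNames(sample(2:12, 6, replace = TRUE), nodes)
      sets <- lapply(1:50, function(i) sample(nodes, sample(0:4, 1)))
      net <- connectivity_network(
        cooccurrence_counts(as_tags(sets), nodes), scheme_with_counts(K))
      if (!nrow(net$edges)) next
      med <- median_connectivity(net)
      weak <- below_median_subnetwork(net)
      key <- function(e) paste(e$from, e$to)
      in_weak <- key(net$edges) %in% key(weak$edges)
      expect_identical(in_weak, net$edges$connectivity < med)
    }
  })
})

test_that("top_k_pairs sorts by connectivity with lexicographic ties", {
  net <- manual_network(
    data.frame(name = LETTERS[1:4], category = "S", keyword_count = 1L),
    data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
               study_count = 1L, connectivity = c(0.5, 0.3, 0.1)))
  top2 <- top_k_pairs(net, 2)
  expect_equal(top2$connectivity, c(0.5, 0.3))
  tied <- manual_network(
    data.frame(name = LETTERS[1:3], category = "S", keyword_count = 1L),
    data.frame(from = c("A", "A"), to = c("C", "B"), study_count = 1L,
               connectivity = c(0.5, 0.5)))
  expect_equal(top_k_pairs(tied, 1)[, c("from", "to")],
               data.frame(from = "A", to = "B"))
  expect_error(top_k_pairs(net, 4), "only 3")

  # full-sort oracle on random instances
  local_seed(53, {
    for (rep in 1:10) {
      nodes <- LETTERS[1:7]
      K <- stats::setNames(sample(2:12, 7, replace = TRUE), nodes)
      sets <- lapply(1:60, function(i) sample(nodes, sample(0:4, 1)))
      net <- connectivity_network(
        cooccurrence_counts(as_tags(sets), nodes), scheme_with_counts(K))
      if (nrow(net$edges) < 5L) next
      got <- top_k_pairs(net, 5)
      e <- net$edges
      ord <- order(-e$connectivity, e$from, e$to, method = "radix")
      expect_equal(got, e[ord[1:5], ], ignore_attr = TRUE)
    }
  })
})

test_that("child drill-down network matches brute force on child tags", {
  cfg <- synthetic_config(
    n_articles = 120,
    concepts = data.frame(name = c("P1", "P2", "P3"), category = "S",
                          keywords_per_concept = 6L,
                          n_children = c(3L, 2L, 0L)),
    seed = 61)
  sg <- generate_scheme(cfg)
  gen <- generate_corpus(sg, cfg)
  tg <- tag_corpus(gen$corpus, sg$scheme)

  net <- child_network(tg, sg$scheme, c("P1", "P2"))
  kids <- sg$scheme$nodes$name[sg$scheme$nodes$level == "child" &
                                 sg$scheme$nodes$parent_name %in% c("P1", "P2")]
  expect_setequal(net$nodes$name, kids)
  child_sets <- lapply(tg$tags, function(t) t$child_tags)
  expect_equal(
    unclass(cooccurrence_counts(tg, kids, level = "child")),
    oracle_cooccurrence(child_sets, kids), ignore_attr = TRUE)
  # connectivity normalized by child keyword counts
  K <- keyword_count(sg$scheme, kids)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    expect_equal(e$connectivity,
                 e$study_count / (K[[e$from]] + K[[e$to]]))
  }

  # childless parents contribute nothing
  expect_warning(empty <- child_network(tg, sg$scheme, "P3"), "no child")
  expect_equal(nrow(empty$nodes), 0L)
  expect_error(child_network(tg, sg$scheme, character()), "non-empty")
  expect_error(child_network(tg, sg$scheme, "Nope"), "unknown parent")
})

test_that("matrix CSV export mirrors counts and connectivity", {
  scheme <- scheme_with_counts(c(A = 10L, B = 5L))
  counts <- cooccurrence_counts(
    as_tags(c(rep(list(c("A", "B")), 3), list("A"))), c("A", "B"))
  dir <- withr::local_tempdir()
  paths <- write_matrix_csv(counts, scheme, file.path(dir, "m.csv"))
  m <- as.matrix(utils::read.csv(file.path(dir, "m.csv"), row.names = 1))
  expect_equal(m, unclass(counts), ignore_attr = TRUE)
  conn <- as.matrix(utils::read.csv(file.path(dir, "m_connectivity.csv"),
                                    row.names = 1))
  expect_equal(conn["A", "B"], 0.2)
  expect_equal(diag(conn), c(A = 0, B = 0))
})

test_that("network JSON round-trips", {
  scheme <- scheme_with_counts(c(A = 4L, B = 3L, C = 2L))
  sets <- c(rep(list(c("A", "B")), 2), list(c("B", "C")), list("A"))
  net <- connectivity_network(
    cooccurrence_counts(as_tags(sets), c("A", "B", "C")), scheme)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$median_connectivity, net$median_connectivity)
  expect_equal(back$level, net$level)
})
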