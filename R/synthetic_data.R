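# -- synthetic corpora with planted concept co-occurrence ----------------

# run code under a local RNG seed, restoring global .Random.seed afterwards
with_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic corpus generator
#'
#' Describes the statistical world the generator emulates: a set of latent
#' research concepts with marginal prevalences and pairwise dependence, a
#' curated keyword vocabulary planted into article text, and distractor
#' prose. Concept co-membership follows a pairwise log-linear model: the
#' unnormalized probability of a membership vector `z` is
#' `prod(p^z (1-p)^(1-z)) * prod(boost[a,b]^(z_a z_b))`, so `boost = 1`
#' everywhere gives independence, large boosts plant strong connections and
#' `boost = 0` plants a hard gap (the pair never co-occurs).
#'
#' @param n_articles number of articles to generate.
#' @param concepts data frame with columns `name`, `category`,
#'   `keywords_per_concept` and optionally `n_children` (default 0). Defaults
#'   to 8 one-category concepts with 4 keywords each.
#' @param base_prevalence marginal inclusion weight per concept, in (0,1);
#'   recycled. Default 0.25 (under independence a background pair then
#'   co-occurs in about 6% of articles, the order of magnitude of a mid-rank
#'   concept pair in a curated corpus).
#' @param pair_boost symmetric non-negative multiplier matrix (1 =
#'   independence); default all 1.
#' @param keyword_emission_prob probability `q` in (0,1] that each keyword of
#'   a held concept is planted into the article; `q = 1` makes detection
#'   certain.
#' @param distractor_vocab_size number of distractor tokens; never overlaps
#'   the concept keyword vocabulary.
#' @param title_length,abstract_length integer ranges `c(min, max)` of
#'   distractor tokens in title and abstract.
#' @param seed default RNG seed used when the generator functions are not
#'   given one explicitly.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_articles = 500,
                             concepts = NULL,
                             base_prevalence = 0.25,
                             pair_boost = NULL,
                             keyword_emission_prob = 1,
                             distractor_vocab_size = 300,
                             title_length = c(4, 8),
                             abstract_length = c(30, 60),
                             seed = 20200803) {
  if (is.null(concepts)) {
    concepts <- data.frame(name = sprintf("Concept %02d", 1:8),
                           category = "Synthetic",
                           keywords_per_concept = 4L,
                           stringsAsFactors = FALSE)
  }
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  if (!"n_children" %in% names(concepts)) concepts$n_children <- 0L
  m <- nrow(concepts)
  problems <- character()
  if (!is.numeric(n_articles) || n_articles < 1) {
    problems <- c(problems, "n_articles must be a positive integer")
  }
  if (m < 2) problems <- c(problems, "need at least 2 concepts")
  if (anyDuplicated(concepts$name)) {
    problems <- c(problems, "concept names must be distinct")
  }
  if (any(concepts$keywords_per_concept < 1)) {
    problems <- c(problems, "keywords_per_concept must be >= 1")
  }
  p <- rep_len(base_prevalence, m)
  if (any(p <= 0 | p >= 1)) {
    problems <- c(problems, "base_prevalence must lie in (0,1)")
  }
  if (is.null(pair_boost)) pair_boost <- matrix(1, m, m)
  pair_boost <- as.matrix(pair_boost)
  if (!all(dim(pair_boost) == m)) {
    problems <- c(problems, "pair_boost must be an m x m matrix")
  } else {
    if (any(pair_boost < 0)) {
      problems <- c(problems, "pair_boost entries must be >= 0")
    }
    if (!isTRUE(all.equal(pair_boost, t(pair_boost)))) {
      problems <- c(problems, "pair_boost must be symmetric")
    }
  }
  q <- keyword_emission_prob
  if (q <= 0 || q > 1) {
    problems <- c(problems, "keyword_emission_prob must lie in (0,1]")
  }
  if (distractor_vocab_size < 10) {
    problems <- c(problems, "distractor_vocab_size must be >= 10")
  }
  if (length(problems)) {
    stop("invalid synthetic_config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(n_articles = as.integer(n_articles), concepts = concepts,
                 base_prevalence = p, pair_boost = pair_boost,
                 keyword_emission_prob = q,
                 distractor_vocab_size = as.integer(distractor_vocab_size),
                 title_length = as.integer(title_length),
                 abstract_length = as.integer(abstract_length),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# fixed-length pseudoword tokens, globally unique => a keyword phrase can
# only appear in text where it was planted (no accidental cross-matches)
make_tokens <- function(n, len = 7L) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need * 2L), function(i) {
      paste(sample(letters, len, replace = TRUE), collapse = "")
    }, "")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Generate a synthetic concept scheme
#'
#' Each concept receives `keywords_per_concept` distinct keyword phrases of
#' 2-3 pseudoword tokens; tokens are globally unique across all keywords, so
#' no phrase can arise by accident from unrelated plantings. When a concept
#' declares `n_children`, its keywords are spread over the children
#' round-robin (every keyword then carries both a parent and a child
#' assignment). Deterministic given the seed.
#'
#' @param config a [synthetic_config()].
#' @param rng_seed RNG seed; defaults to `config$seed`.
#' @return list with `scheme` (a validated [concept_scheme()]) and
#'   `distractors` (the distractor token vocabulary, disjoint from all
#'   keyword tokens).
#' @export
generate_scheme <- function(config, rng_seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng(rng_seed, {
    cc <- config$concepts
    m <- nrow(cc)
    toks_per_kw <- lapply(seq_len(m), function(i) {
      sample(2:3, cc$keywords_per_concept[i], replace = TRUE)
    })
    total_tokens <- sum(unlist(toks_per_kw)) + config$distractor_vocab_size
    pool <- make_tokens(total_tokens)
    distractors <- pool[seq_len(config$distractor_vocab_size)]
    pool <- pool[-seq_len(config$distractor_vocab_size)]
    nodes <- data.frame(name = cc$name, category = cc$category,
                        level = "parent", parent_name = NA_character_,
                        stringsAsFactors = FALSE)
    assignments <- NULL
    used <- 0L
    for (i in seq_len(m)) {
      kws <- vapply(toks_per_kw[[i]], function(nt) {
        kw <- paste(pool[used + seq_len(nt)], collapse = " ")
        used <<- used + nt
        kw
      }, "")
      child <- rep(NA_character_, length(kws))
      if (cc$n_children[i] > 0L) {
        kids <- sprintf("%s / child %d", cc$name[i], seq_len(cc$n_children[i]))
        nodes <- rbind(nodes, data.frame(
          name = kids, category = cc$category[i], level = "child",
          parent_name = cc$name[i], stringsAsFactors = FALSE))
        child <- kids[(seq_along(kws) - 1L) %% cc$n_children[i] + 1L]
      }
      assignments <- rbind(assignments, data.frame(
        keyword = kws, parent_name = cc$name[i], child_name = child,
        stringsAsFactors = FALSE))
    }
    list(scheme = concept_scheme(nodes, assignments),
         distractors = distractors)
  })
}

# exact joint over membership vectors for m <= 12 concepts:
# 2^m x m matrix of states plus the normalized probability of each
exact_joint <- function(config) {
  m <- nrow(config$concepts)
  if (m > 12L) stop("exact joint enumeration limited to 12 concepts",
                    call. = FALSE)
  states <- as.matrix(expand.grid(rep(list(0:1), m)))
  colnames(states) <- config$concepts$name
  p <- config$base_prevalence
  logw <- states %*% log(p) + (1 - states) %*% log(1 - p)
  boost <- config$pair_boost
  pairmult <- apply(states, 1L, function(z) {
    on <- which(z == 1)
    if (length(on) < 2L) return(1)
    prs <- utils::combn(on, 2L)
    prod(boost[t(prs)])
  })
  w <- exp(as.vector(logw)) * pairmult
  tot <- sum(w)
  if (tot <= 0) stop("infeasible joint: all membership states have weight 0",
                     call. = FALSE)
  list(states = states, prob = w / tot)
}

# P(a and b) matrix (diagonal = marginals) from the exact joint
joint_prob_matrix <- function(config) {
  ej <- exact_joint(config)
  t(ej$states) %*% (ej$states * ej$prob)
}

#' Calibrate one pair's boost to hit a target joint prevalence
#'
#' Solves (by root finding on the exact joint) for the `pair_boost[a, b]`
#' multiplier making `P(a and b)` equal `target_joint`, holding everything
#' else in the config fixed.
#'
#' @param config a [synthetic_config()] with at most 12 concepts.
#' @param a,b concept names or indices.
#' @param target_joint desired `P(a and b)`, in (0,1).
#' @return a new `synthetic_config` with the calibrated boost.
#' @export
calibrate_pair_boost <- function(config, a, b, target_joint) {
  stopifnot(inherits(config, "synthetic_config"),
            target_joint > 0, target_joint < 1)
  nm <- config$concepts$name
  ia <- if (is.character(a)) match(a, nm) else as.integer(a)
  ib <- if (is.character(b)) match(b, nm) else as.integer(b)
  stopifnot(!is.na(ia), !is.na(ib), ia != ib)
  f <- function(log_boost) {
    cfg <- config
    cfg$pair_boost[ia, ib] <- cfg$pair_boost[ib, ia] <- exp(log_boost)
    joint_prob_matrix(cfg)[ia, ib] - target_joint
  }
  root <- stats::uniroot(f, lower = log(1e-8), upper = log(1e8),
                         tol = 1e-10)$root
  config$pair_boost[ia, ib] <- config$pair_boost[ib, ia] <- exp(root)
  config
}

# Gibbs sampler over the pairwise model, used beyond the enumeration limit
gibbs_membership <- function(config, n, sweeps = 60L) {
  m <- nrow(config$concepts)
  p <- config$base_prevalence
  boost <- config$pair_boost
  out <- matrix(0L, n, m, dimnames = list(NULL, config$concepts$name))
  for (r in seq_len(n)) {
    z <- integer(m)  # all-off is always feasible
    for (s in seq_len(sweeps)) {
      for (j in seq_len(m)) {
        on <- which(z == 1L); on <- on[on != j]
        w1 <- p[j] * prod(boost[j, on])
        w0 <- 1 - p[j]
        z[j] <- if (stats::runif(1) < w1 / (w0 + w1)) 1L else 0L
      }
    }
    out[r, ] <- z
  }
  out
}

#' Generate a synthetic corpus with ground truth
#'
#' Samples each article's concept memberships from the pairwise-dependent
#' joint (exact enumeration up to 12 concepts, Gibbs sampling beyond), then
#' plants each keyword of each held concept independently with probability
#' `q` into a uniformly chosen field (title, abstract, author keywords or
#' KeyWords Plus), padding title and abstract with distractor tokens.
#'
#' @param scheme_gen result of [generate_scheme()] (scheme + distractors).
#' @param config the same [synthetic_config()].
#' @param rng_seed RNG seed; defaults to `config$seed + 1`.
#' @return list with `corpus` (a [corpus]), `truth` (class
#'   `synthetic_truth`: `membership` list of per-article concept sets,
#'   `joint_prob` matrix, `expected_counts` = `n_articles * joint_prob`
#'   valid at `q = 1`, `expected_connectivity` matrix).
#' @export
generate_corpus <- function(scheme_gen, config, rng_seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  scheme <- scheme_gen$scheme
  distract <- scheme_gen$distractors
  m <- nrow(config$concepts)
  n <- config$n_articles
  q <- config$keyword_emission_prob
  with_rng(rng_seed, {
    member <- if (m <= 12L) {
      ej <- exact_joint(config)
      rows <- sample.int(nrow(ej$states), n, replace = TRUE, prob = ej$prob)
      ej$states[rows, , drop = FALSE]
    } else {
      gibbs_membership(config, n)
    }
    as_ <- scheme$assignments
    rint <- function(rng) sample(rng[1L]:rng[2L], 1L)
    title <- character(n); abstract <- character(n)
    de <- vector("list", n); id <- vector("list", n)
    for (r in seq_len(n)) {
      held <- config$concepts$name[member[r, ] == 1L]
      kws <- as_$keyword[as_$parent_name %in% held]
      kws <- kws[stats::runif(length(kws)) <= q]
      field <- if (length(kws)) sample(4L, length(kws), replace = TRUE)
               else integer()
      ttl <- sample(distract, rint(config$title_length), replace = TRUE)
      abs_ <- sample(distract, rint(config$abstract_length), replace = TRUE)
      for (k in seq_along(kws)) {
        switch(field[k],
          ttl <- append(ttl, kws[k], after = sample(0:length(ttl), 1L)),
          abs_ <- append(abs_, kws[k], after = sample(0:length(abs_), 1L)),
          de[[r]] <- c(de[[r]], kws[k]),
          id[[r]] <- c(id[[r]], kws[k]))
      }
      # a couple of distractor keyword entries so DE/ID are not pure signal
      de[[r]] <- c(de[[r]], sample(distract, 2L))
      id[[r]] <- c(id[[r]], sample(distract, 2L))
      title[r] <- paste(ttl, collapse = " ")
      abstract[r] <- paste(abs_, collapse = " ")
    }
    corp <- corpus(record_id = sprintf("SYN:%06d", seq_len(n)),
                   title = title, abstract = abstract,
                   author_keywords = de, keywords_plus = id,
                   year = rep(2020L, n),
                   source_label = "synthetic corpus")
    jp <- if (m <= 12L) joint_prob_matrix(config) else NULL
    truth <- structure(list(
      membership = lapply(seq_len(n), function(r) {
        config$concepts$name[member[r, ] == 1L]
      }),
      joint_prob = jp,
      expected_counts = if (!is.null(jp)) n * jp else NULL,
      expected_connectivity = if (!is.null(jp)) {
        expected_connectivity(config, scheme)
      } else NULL),
      class = "synthetic_truth")
    list(corpus = corp, truth = truth)
  })
}

#' Expected connectivity matrix under a synthetic configuration
#'
#' `E[C_ab] = n * P(a and b) * d(q) / (K_a + K_b)` where the detection
#' factor `d(q) = (1 - (1-q)^K_a)(1 - (1-q)^K_b)` is the probability that at
#' least one keyword of each concept was planted; exact at `q = 1` (`d = 1`),
#' an independence approximation otherwise.
#'
#' @param config a [synthetic_config()] with at most 12 concepts.
#' @param scheme the matching generated [concept_scheme()].
#' @return symmetric matrix of expected connectivity values, zero diagonal.
#' @export
expected_connectivity <- function(config, scheme) {
  jp <- joint_prob_matrix(config)
  nm <- config$concepts$name
  K <- keyword_count(scheme, nm)
  q <- config$keyword_emission_prob
  d <- 1 - (1 - q)^K
  ec <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i != j) {
        ec[i, j] <- config$n_articles * jp[i, j] * d[i] * d[j] / (K[i] + K[j])
      }
    }
  }
  ec
}
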