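---
title: "Mapping a research literature as a concept co-occurrence network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a research literature as a concept co-occurrence network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowordnet)
```

## The method

Co-word analysis infers the intellectual structure of a research field from
the co-occurrence of concepts across documents. `cowordnet` implements a
specific, hierarchical variant of it:

1. **Corpus.** A curated set of bibliographic records, each with four
   searchable text fields: title, abstract, author keywords, and KeyWords
   Plus (index terms Web of Science derives from cited-reference titles).
   Curation — which records belong in the corpus — is a human judgment and
   is *input* to this package, not computed by it.
2. **Concept scheme.** A two-level ontology: broad *parent* concepts grouped
   into open-ended categories (e.g. Ecology / Evolution / General
   Characteristics), refined by *child* concepts. A curated map assigns each
   keyword to exactly one parent and optionally one child of that parent.
   The assignment itself is again expert judgment, supplied as data.
3. **Tagging.** An article is tagged with every concept one of whose
   keywords occurs in the normalized concatenation of its four text fields.
   Tagging is binary per concept: ten matching keywords count the same as
   one. A child tag always implies its parent tag.
4. **Counting.** The symmetric co-occurrence table \(N\) holds per-concept
   article counts on the diagonal and per-pair joint counts off it.
5. **Connectivity.** The edge statistic between concepts \(a\) and \(b\) is
   \[ C_{ab} = \frac{N_{ab}}{K_a + K_b}, \]
   the number of joint studies normalized by the total number of keywords
   assigned to the two concepts, so that a concept represented by many
   keywords is not credited merely for being easy to hit. A node's weighted
   degree \(W_a = \sum_{b} C_{ab}\) summarizes its overall research focus.
6. **Thresholding.** The median of all edge connectivity values splits the
   network: the top-\(k\) (conventionally five) strongest pairs seed a
   child-level drill-down network; edges *strictly below* the median form
   the "weak" network of under-studied combinations. Concept pairs with
   \(N_{ab} = 0\) are *gaps*: absent edges, deliberately not zero-weight
   edges, and therefore excluded from the median.
7. **Export.** Deterministic circular layout (nodes sorted by category,
   then alphabetically) and GEXF/GraphML output for viewers such as Gephi.

## Matching semantics

Text and keywords are normalized identically: lowercase, hyphens and
en/em-dashes folded to spaces, whitespace collapsed. The matcher then runs
a *substring search with a word-start boundary* by default: the keyword
must begin at a word boundary but may end mid-word, so `"life history"`
matches "life history traits" (the behaviour that lets a curator drop
redundant longer keywords) while `"rarity"` cannot fire inside an unrelated
longer word. Two alternative modes are exposed through `tag_options()`:
plain `substring`, and `word` (boundaries at both ends). The original
extraction scripts in this literature predate such options being
documented, so all three readings are reproducible; all three are held to
the same brute-force oracle in the test suite.

## Worked example on synthetic data

```{r example}
cfg <- synthetic_config(n_articles = 300, seed = 42)
cfg <- calibrate_pair_boost(cfg, "Concept 01", "Concept 02", 0.30)
sg  <- generate_scheme(cfg)
gen <- generate_corpus(sg, cfg)

tagged <- tag_corpus(gen$corpus, sg$scheme)
counts <- cooccurrence_counts(tagged, parent_nodes(sg$scheme))
net    <- connectivity_network(counts, sg$scheme)
net
top_k_pairs(net, 3)
weak <- below_median_subnetwork(net)
weak

layout  <- circular_layout(net, "Synthetic")
visuals <- scale_visuals(net)
path <- file.path(tempdir(), "network.gexf")
write_graph_file(net, layout, visuals, path, "gexf")
```

## The synthetic world

The generator emulates the statistical structure the analysis measures,
not the surface of real articles. Its stated world:

- **Concept co-membership** follows a pairwise log-linear model: the
  unnormalized probability of a membership vector \(z\) is
  \(\prod_a p_a^{z_a}(1-p_a)^{1-z_a} \prod_{a<b} \beta_{ab}^{z_a z_b}\).
  \(\beta = 1\) everywhere is independence; a large \(\beta_{ab}\) plants a
  strong connection; \(\beta_{ab} = 0\) plants a hard gap (the pair never
  co-occurs). This is the minimal model able to plant both of the features
  the method is supposed to detect. The joint is enumerated exactly up to
  12 concepts and Gibbs-sampled beyond.
- **Defaults.** 8 concepts with 4 keywords each, marginal prevalence 0.25,
  500 articles, emission probability \(q = 1\). The corpus the method was
  developed on had ~800 articles over 14 parent concepts and ~35 keywords
  per concept; the default synthetic world is deliberately smaller (tests
  must run in seconds) but keeps the per-article tag multiplicity (~2
  concepts/article) in the same regime. Absolute connectivity values are
  therefore larger than in a real corpus — \(C\) scales as
  articles/keywords — which is immaterial to every check, since the
  statistic's contracts (ratio arithmetic, ordering, median split) are
  scale-free.
- **Keyword planting.** Each keyword of each held concept is planted with
  probability \(q\) into one uniformly chosen field; pseudoword tokens are
  fixed-length and globally unique across keywords and distractors, so a
  phrase can only occur where it was planted. With \(q = 1\) detection is
  certain and the full pipeline must recover ground truth *exactly* — a
  property the acceptance suite asserts. With \(q < 1\) the expected
  connectivity uses the independence approximation
  \(d(q) = (1-(1-q)^{K_a})(1-(1-q)^{K_b})\), exact at \(q = 1\).
- **What a green test does not establish.** The generator does not emulate
  natural-language abstracts, keyword ambiguity, curation error, or the
  derivation of KeyWords Plus from cited titles. Green tests establish
  that the pipeline computes the intended statistic on text whose ground
  truth is known — not that any particular real-world tagging is
  semantically correct.

## Numerical and design choices

- **Denominator.** "Total keywords relevant to the two concepts" is
  implemented as \(K_a + K_b\). At parent level this equals the size of the
  union, because every keyword has exactly one parent. At child level a
  keyword has at most one child, so the same identity holds within the
  scheme's rules; the sum convention is applied uniformly.
- **Median over realized edges.** Zero-count pairs are absent edges
  ("gaps"), not weak edges; including them would drag the median toward
  zero and empty the weak network. A pair equal to the median belongs to
  neither the strong nor the below-median set.
- **Strict inequality** for the weak network ("below the median"), so an
  all-equal network yields an empty weak network rather than all of it.
- **Ties in top-\(k\)** are broken by lexicographic order of the sorted
  pair names — deterministic and explainable, with no hidden dependence on
  edge insertion order.
- **Zero-keyword nodes** (a concept the curators defined but no keyword
  was assigned to) are excluded before computing anything, with a warning;
  they cannot participate in \(C\) (the denominator ingredient is 0) and
  matching the published treatment they are omitted from networks rather
  than drawn isolated.
- **Layout** starts at 90° (top of the circle) and proceeds
  counter-clockwise; the angular origin and direction are not part of any
  published contract and are configurable.
- **Label/edge sizing** is affine min–max scaling into a target range —
  "proportional to" is honoured as order preservation, with the degenerate
  all-equal case mapped to the range midpoint.
- **Export determinism.** Graph files are emitted with fixed element
  order and fixed `%.15g` number formatting, so identical inputs give
  byte-identical files and re-parsing reproduces every numeric attribute
  far below the 1e-9 contract. (A coarser 6-digit format would break the
  1e-9 round-trip guarantee; determinism and round-trip fidelity were
  judged the binding contracts.)

## Limitations

- Keyword→concept assignment is curation, not computation; the package
  validates maps but will not build them.
- No statistical significance is attached to connectivity values; the
  method is descriptive.
- Tagging has no stemming, lemmatization or synonym expansion — by design,
  since the curated keyword list is expected to carry that burden.
- The Gibbs regime (>12 concepts) provides membership ground truth but no
  closed-form expectation matrices.
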