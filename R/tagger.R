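# -- text normalization and concept tagging ------------------------------

#' Tagging options
#'
#' Controls the matching semantics of the concept tagger. Defaults reproduce
#' the documented behaviour: case-insensitive, hyphens folded to spaces, and
#' phrase matches required to start (but not end) at a word boundary, so
#' "life history" hits "life history traits" while "rarity" cannot match
#' inside "temporarity".
#'
#' @param case_fold lowercase text before matching.
#' @param hyphen_fold fold hyphens, en/em-dashes and the Unicode hyphen to
#'   spaces before matching.
#' @param boundary_mode one of `"word_start"` (default; the match must begin
#'   at a word boundary but may end mid-word), `"substring"` (plain substring
#'   search) or `"word"` (both ends at word boundaries).
#' @return A list of class `tag_options`.
#' @export
tag_options <- function(case_fold = TRUE, hyphen_fold = TRUE,
                        boundary_mode = c("word_start", "substring", "word")) {
  boundary_mode <- match.arg(boundary_mode)
  structure(list(case_fold = isTRUE(case_fold),
                 hyphen_fold = isTRUE(hyphen_fold),
                 boundary_mode = boundary_mode),
            class = "tag_options")
}

#' Normalize free text for matching
#'
#' Lowercases (if `case_fold`), replaces ASCII hyphens, Unicode hyphen
#' (U+2010), en-dash and em-dash with spaces (if `hyphen_fold`), collapses
#' whitespace runs to single spaces and strips leading/trailing space.
#' Idempotent.
#'
#' @param text character scalar.
#' @param options a [tag_options()].
#' @return normalized character scalar.
#' @export
normalize_text <- function(text, options = tag_options()) {
  if (is.na(text)) return("")
  x <- as.character(text)
  if (options$case_fold) x <- tolower(x)
  if (options$hyphen_fold) x <- gsub("[-‐‑–—]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Test whether a keyword phrase occurs in a document
#'
#' Both arguments must already be normalized (see [normalize_text()]). In
#' `word_start` mode the occurrence must begin at the start of the document
#' or after a space; it may end mid-word. `word` mode additionally requires
#' the occurrence to end at a word boundary; `substring` imposes neither.
#'
#' @param keyword normalized phrase; must be non-empty.
#' @param document normalized text.
#' @param options a [tag_options()].
#' @return logical scalar.
#' @export
match_keyword <- function(keyword, document, options = tag_options()) {
  if (!nzchar(keyword)) stop("empty keyword is unmatchable", call. = FALSE)
  if (!nzchar(document)) return(FALSE)
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", keyword)
  pattern <- switch(options$boundary_mode,
    substring = esc,
    word_start = paste0("(^| )", esc),
    word = paste0("(^| )", esc, "( |$)"))
  grepl(pattern, document, perl = TRUE)
}

# One searchable document per record: the four fields concatenated and
# normalized; a hit in any field suffices.
searchable_document <- function(record_row, options = tag_options()) {
  normalize_text(paste(record_row$title, record_row$abstract,
                       paste(record_row$author_keywords[[1L]], collapse = " "),
                       paste(record_row$keywords_plus[[1L]], collapse = " ")),
                 options)
}

#' Tag one article with the concepts its text mentions
#'
#' Searches the normalized concatenation of title, abstract, author keywords
#' and KeyWords Plus for every assigned keyword of the scheme. Each matching
#' assignment contributes its parent node (and its child node, if any) to the
#' tag sets; tagging is binary per concept regardless of how many of its
#' keywords match. Child tags always imply their parent tag.
#'
#' @param record a single-row [corpus] slice (or a corpus; then row `1`).
#' @param scheme a [concept_scheme()].
#' @param options a [tag_options()].
#' @return A list of class `tagged_article` with elements `record_id`,
#'   `parent_tags`, `child_tags` and `matches` (data frame of keyword /
#'   parent / child evidence rows).
#' @export
tag_article <- function(record, scheme, options = tag_options()) {
  doc <- searchable_document(record[1L, ], options)
  as_ <- scheme$assignments
  hit <- if (nrow(as_)) {
    vapply(as_$keyword, match_keyword, NA, document = doc, options = options,
           USE.NAMES = FALSE)
  } else logical()
  matches <- as_[hit, , drop = FALSE]
  row.names(matches) <- NULL
  child <- matches$child_name[!is.na(matches$child_name)]
  structure(list(record_id = record$record_id[1L],
                 parent_tags = sort(unique(matches$parent_name), method = "radix"),
                 child_tags = sort(unique(child), method = "radix"),
                 matches = matches),
            class = "tagged_article")
}

#' Tag every article in a corpus
#'
#' @param corpus a [corpus].
#' @param scheme a [concept_scheme()].
#' @param options a [tag_options()].
#' @return A list of class `tagged_corpus`: `tags` (one `tagged_article` per
#'   record, input order preserved), `summary` (data frame of per-concept
#'   article counts at both levels) and `n_untagged`.
#' @export
tag_corpus <- function(corpus, scheme, options = tag_options()) {
  stopifnot(inherits(corpus, "corpus"))
  tags <- lapply(seq_len(nrow(corpus)),
                 function(i) tag_article(corpus[i, ], scheme, options))
  all_nodes <- c(parent_nodes(scheme), child_nodes(scheme))
  lvl <- c(rep("parent", length(parent_nodes(scheme))),
           rep("child", length(child_nodes(scheme))))
  counts <- vapply(seq_along(all_nodes), function(i) {
    nm <- all_nodes[i]
    if (lvl[i] == "parent") {
      sum(vapply(tags, function(t) nm %in% t$parent_tags, NA))
    } else {
      sum(vapply(tags, function(t) nm %in% t$child_tags, NA))
    }
  }, 1L)
  structure(list(
    tags = tags,
    summary = data.frame(node = all_nodes, level = lvl, n_articles = counts,
                         stringsAsFactors = FALSE),
    n_untagged = sum(vapply(tags, function(t) length(t$parent_tags) == 0L, NA))),
    class = "tagged_corpus")
}

#' @export
print.tagged_corpus <- function(x, ...) {
  cat(sprintf("<tagged_corpus> %d article(s), %d untagged\n",
              length(x$tags), x$n_untagged))
  top <- x$summary[x$summary$level == "parent", ]
  top <- top[order(-top$n_articles), ]
  print(utils::head(top, 5L), row.names = FALSE)
  invisible(x)
}

#' Write article tags to TSV
#'
#' Columns `record_id`, `parent_tags`, `child_tags` (both `"|"`-joined) and
#' `evidence` (semicolon-joined `keyword->parent[/child]` pairs).
#'
#' @param tagged a `tagged_corpus` from [tag_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tagged, path) {
  stopifnot(inherits(tagged, "tagged_corpus"))
  rows <- lapply(tagged$tags, function(t) {
    ev <- if (nrow(t$matches)) {
      paste0(t$matches$keyword, "->", t$matches$parent_name,
             ifelse(is.na(t$matches$child_name), "",
                    paste0("/", t$matches$child_name)),
             collapse = ";")
    } else ""
    data.frame(record_id = t$record_id,
               parent_tags = paste(t$parent_tags, collapse = "|"),
               child_tags = paste(t$child_tags, collapse = "|"),
               evidence = ev, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- data.frame(record_id = character(), parent_tags = character(),
                     child_tags = character(), evidence = character())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read article tags written by [write_tags()]
#'
#' @param path TSV path.
#' @return A `tagged_corpus` (summary restricted to tags present; evidence
#'   restored from the `evidence` column).
#' @export
read_tags <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  split_bar <- function(x) {
    if (!nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1L]]
  }
  tags <- lapply(seq_len(nrow(df)), function(i) {
    ev <- df$evidence[i]
    matches <- if (nzchar(ev)) {
      parts <- strsplit(strsplit(ev, ";", fixed = TRUE)[[1L]], "->", fixed = TRUE)
      tgt <- vapply(parts, `[[`, "", 2L)
      pc <- strsplit(tgt, "/", fixed = TRUE)
      data.frame(keyword = vapply(parts, `[[`, "", 1L),
                 parent_name = vapply(pc, `[[`, "", 1L),
                 child_name = vapply(pc, function(x)
                   if (length(x) > 1L) x[[2L]] else NA_character_, ""),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(keyword = character(), parent_name = character(),
                 child_name = character(), stringsAsFactors = FALSE)
    }
    structure(list(record_id = df$record_id[i],
                   parent_tags = split_bar(df$parent_tags[i]),
                   child_tags = split_bar(df$child_tags[i]),
                   matches = matches),
              class = "tagged_article")
  })
  structure(list(tags = tags, summary = NULL,
                 n_untagged = sum(!nzchar(df$parent_tags))),
            class = "tagged_corpus")
}
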