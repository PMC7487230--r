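# -- corpus construction -------------------------------------------------

#' Construct a bibliographic corpus
#'
#' A `corpus` holds an ordered collection of bibliographic records, each with
#' the four searchable text fields used in co-word analysis: title, abstract,
#' author-supplied keywords and KeyWords Plus (the index terms Web of Science
#' derives from cited-reference titles).
#'
#' @param record_id character vector of unique, non-empty record identifiers
#'   (e.g. WoS "UT" accession numbers).
#' @param title character vector of article titles (non-empty).
#' @param abstract character vector of abstracts; `""` for records without one.
#' @param author_keywords list of character vectors (the "DE" field).
#' @param keywords_plus list of character vectors (the "ID" field).
#' @param year optional integer vector of publication years (`NA` allowed).
#' @param source_label free-text provenance note.
#'
#' @return An object of class `corpus`: a data frame with one row per record
#'   and list columns for the keyword fields.
#' @export
corpus <- function(record_id = character(), title = character(),
                   abstract = character(), author_keywords = list(),
                   keywords_plus = list(), year = NULL,
                   source_label = "") {
  n <- length(record_id)
  stopifnot(length(title) == n)
  if (length(abstract) == 0L && n > 0L) abstract <- rep("", n)
  if (length(author_keywords) == 0L && n > 0L) {
    author_keywords <- rep(list(character()), n)
  }
  if (length(keywords_plus) == 0L && n > 0L) {
    keywords_plus <- rep(list(character()), n)
  }
  if (is.null(year)) year <- rep(NA_integer_, n)
  stopifnot(length(abstract) == n, length(author_keywords) == n,
            length(keywords_plus) == n, length(year) == n)

  record_id <- as.character(record_id)
  if (anyNA(record_id) || any(!nzchar(trimws(record_id)))) {
    stop("corpus: record_id entries must be non-empty", call. = FALSE)
  }
  dup <- record_id[duplicated(record_id)]
  if (length(dup)) {
    stop("corpus: duplicate record_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(trimws(title)))) {
    stop("corpus: empty titles are not allowed", call. = FALSE)
  }
  drop_blank <- function(x) {
    x <- trimws(as.character(x))
    x[nzchar(x)]
  }
  out <- data.frame(record_id = record_id, title = as.character(title),
                    abstract = as.character(abstract),
                    year = as.integer(year),
                    stringsAsFactors = FALSE)
  out$author_keywords <- lapply(author_keywords, drop_blank)
  out$keywords_plus <- lapply(keywords_plus, drop_blank)
  out <- out[, c("record_id", "title", "abstract",
                 "author_keywords", "keywords_plus", "year")]
  attr(out, "source_label") <- source_label
  class(out) <- c("corpus", "data.frame")
  out
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d record(s)", nrow(x)))
  src <- attr(x, "source_label")
  if (!is.null(src) && nzchar(src)) cat(" from ", src, sep = "")
  cat("\n")
  if (nrow(x)) {
    show <- utils::head(x$title, 3L)
    cat(paste0("  - ", substr(show, 1L, 70L), collapse = "\n"), "\n")
  }
  invisible(x)
}

# -- Web of Science export reader ----------------------------------------

# Split a ";"-separated multi-value WoS cell, trimming and dropping blanks.
split_wos_cell <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(character())
  parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
  parts[nzchar(parts)]
}

#' Read a Web of Science tab-delimited export
#'
#' Parses the headered tab-delimited dialect of WoS "marked list" exports.
#' The header row carries two-letter field tags; `TI` (title) and `UT`
#' (accession id) are required, `AB` (abstract), `DE` (author keywords),
#' `ID` (KeyWords Plus) and `PY` (year) are used when present, and any other
#' columns are ignored. `DE`/`ID` cells are split on `";"` and trimmed.
#' A UTF-8 byte-order mark is tolerated.
#'
#' @param path path to the export file.
#' @param dialect export dialect; only `"tab_headered"` is supported (the
#'   legacy `FN/VR/.../ER` plain-text dialect is not).
#' @return A [corpus].
#' @export
read_wos_export <- function(path, dialect = "tab_headered") {
  dialect <- match.arg(dialect, "tab_headered")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty export file: ", path, call. = FALSE)
  lines[1L] <- sub("^﻿", "", lines[1L])

  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  header <- trimws(header)
  for (tag in c("TI", "UT")) {
    if (!tag %in% header) {
      stop("WoS export format error: required column '", tag, "' is missing",
           call. = FALSE)
    }
  }
  idx <- function(tag) match(tag, header)
  has <- function(tag) !is.na(idx(tag))
  for (tag in c("AB", "DE", "ID")) {
    if (!has(tag)) {
      warning("WoS export lacks '", tag, "' column; field treated as empty",
              call. = FALSE)
    }
  }

  body <- lines[-1L]
  body <- body[nzchar(body)]
  n <- length(body)
  ncol_expect <- length(header)
  cells <- strsplit(body, "\t", fixed = TRUE)
  # trailing empty cells are dropped by strsplit; pad them back
  cells <- lapply(cells, function(x) {
    if (length(x) < ncol_expect) x <- c(x, rep("", ncol_expect - length(x)))
    x
  })
  bad <- which(vapply(cells, length, 1L) != ncol_expect)
  if (length(bad)) {
    stop("WoS export row ", bad[1L] + 1L, " has ",
         length(cells[[bad[1L]]]), " columns, expected ", ncol_expect,
         call. = FALSE)
  }
  get_col <- function(tag) {
    if (!has(tag)) return(rep("", n))
    vapply(cells, `[[`, "", idx(tag))
  }
  ut <- trimws(get_col("UT"))
  ti <- trimws(get_col("TI"))
  keep_bad <- !nzchar(ut) | !nzchar(ti)
  if (any(keep_bad)) {
    stop("WoS export rows rejected (empty UT or TI): row(s) ",
         paste(which(keep_bad) + 1L, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ut)) {
    stop("WoS export contains duplicate UT: ",
         paste(unique(ut[duplicated(ut)]), collapse = ", "), call. = FALSE)
  }
  py <- suppressWarnings(as.integer(get_col("PY")))
  corpus(record_id = ut, title = ti, abstract = get_col("AB"),
         author_keywords = lapply(get_col("DE"), split_wos_cell),
         keywords_plus = lapply(get_col("ID"), split_wos_cell),
         year = py, source_label = path)
}

# -- canonical TSV -------------------------------------------------------

CANONICAL_COLUMNS <- c("record_id", "title", "abstract",
                       "author_keywords", "keywords_plus", "year")

#' Write a corpus to the canonical TSV format
#'
#' Columns `record_id`, `title`, `abstract`, `author_keywords`,
#' `keywords_plus`, `year`; keyword lists are `"|"`-joined. The format
#' round-trips: `read_corpus(write_corpus(x))` reproduces `x` field for field.
#'
#' @param corpus a [corpus].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "corpus"))
  join <- function(lst) vapply(lst, paste, "", collapse = "|")
  df <- data.frame(record_id = corpus$record_id, title = corpus$title,
                   abstract = corpus$abstract,
                   author_keywords = join(corpus$author_keywords),
                   keywords_plus = join(corpus$keywords_plus),
                   year = ifelse(is.na(corpus$year), "", corpus$year),
                   stringsAsFactors = FALSE)
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "")
  invisible(path)
}

#' Read a canonical corpus TSV
#'
#' @param path path written by [write_corpus()].
#' @return A [corpus].
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(CANONICAL_COLUMNS, names(df))
  if (length(missing)) {
    stop("canonical TSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unjoin <- function(x) {
    lapply(x, function(cell) {
      if (!nzchar(cell)) character() else strsplit(cell, "|", fixed = TRUE)[[1L]]
    })
  }
  corpus(record_id = df$record_id, title = df$title, abstract = df$abstract,
         author_keywords = unjoin(df$author_keywords),
         keywords_plus = unjoin(df$keywords_plus),
         year = suppressWarnings(as.integer(df$year)),
         source_label = path)
}

#' Collect the distinct KeyWords Plus of a corpus
#'
#' Pools the `keywords_plus` field across all records, normalizes each phrase
#' with [normalize_text()] and deduplicates case-insensitively; this is the
#' raw material handed to curators for concept assignment. Output is sorted
#' lexicographically (C collation) over the normalized forms.
#'
#' @param corpus a [corpus].
#' @return character vector of distinct normalized phrases, sorted.
#' @export
collect_keywords_plus <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  all_kw <- unlist(corpus$keywords_plus, use.names = FALSE)
  if (!length(all_kw)) return(character())
  norm <- vapply(all_kw, normalize_text, "", USE.NAMES = FALSE)
  norm <- norm[nzchar(norm)]
  sort(unique(norm), method = "radix")
}
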