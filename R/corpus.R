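#' Segment a free-text field into symptom tokens
#'
#' Splits `text` at every occurrence of any character in `punctuation`,
#' trims surrounding whitespace from each fragment and drops empty
#' fragments.  Order of appearance is preserved and duplicates are retained:
#' deduplication happens at vocabulary level, not here.  No synonym
#' normalisation or sub-token segmentation is performed; tokens are compared
#' downstream by exact string equality.
#'
#' @param text Character scalar (raw field text; may be empty).
#' @param punctuation Character vector of single separator characters.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' segment_field("A,B;C")
#' segment_field("")           # character(0)
#' segment_field("A,,  ,B")    # empty fragments dropped
segment_field <- function(text, punctuation = default_punctuation()) {
  stopifnot(is.character(text), length(text) == 1L, length(punctuation) >= 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  rx <- paste0("[", paste0("\\Q", punctuation, "\\E", collapse = ""), "]")
  parts <- strsplit(text, rx, perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

new_emr_corpus <- function(df) {
  stopifnot(is.data.frame(df))
  class(df) <- c("emr_corpus", "data.frame")
  df
}

#' Construct an EMR corpus
#'
#' A corpus is a data frame with one row per patient visit: a `record_id`
#' column, one character column per diagnostic field (see [field_types()]),
#' and a `syndrome` label column (`NA` or `""` for unlabelled prediction
#' records).  Field texts must not contain tab or newline characters, which
#' are reserved as file delimiters.
#'
#' @param record_id Character vector of unique record identifiers, or `NULL`
#'   to number records sequentially.
#' @param fields Named list of character vectors, names in [field_types()];
#'   missing fields are filled with `""`.
#' @param syndrome Character vector of labels (`NA` allowed).
#' @return An `emr_corpus` data frame.
#' @export
emr_corpus <- function(record_id = NULL, fields = list(), syndrome = NA_character_) {
  bad <- setdiff(names(fields), field_types())
  if (length(bad)) stop("unknown field type(s): ", paste(bad, collapse = ", "))
  n <- max(1L, lengths(fields), length(syndrome),
           if (is.null(record_id)) 0L else length(record_id))
  if (length(fields)) n <- max(vapply(fields, length, 1L), length(syndrome))
  if (!is.null(record_id)) n <- max(n, length(record_id))
  if (is.null(record_id)) record_id <- sprintf("R%05d", seq_len(n))
  df <- data.frame(record_id = as.character(record_id), stringsAsFactors = FALSE)
  for (ft in field_types()) {
    v <- if (ft %in% names(fields)) as.character(fields[[ft]]) else rep("", n)
    v[is.na(v)] <- ""
    df[[ft]] <- rep_len(v, n)
  }
  df$syndrome <- rep_len(as.character(syndrome), n)
  validate_corpus(new_emr_corpus(df))
}

validate_corpus <- function(corpus, require_labels = FALSE) {
  stopifnot(inherits(corpus, "emr_corpus") || is.data.frame(corpus))
  need <- c("record_id", field_types(), "syndrome")
  miss <- setdiff(need, names(corpus))
  if (length(miss)) stop("corpus missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(corpus$record_id))
    stop("duplicate record_id: ",
         paste(unique(corpus$record_id[duplicated(corpus$record_id)]), collapse = ", "))
  for (col in c(field_types(), "syndrome")) {
    v <- corpus[[col]]
    if (any(grepl("[\t\n\r]", v[!is.na(v)])))
      stop("field '", col, "' contains a tab or newline character")
  }
  if (require_labels) {
    lab <- corpus$syndrome
    bad <- is.na(lab) | !nzchar(trimws(lab))
    if (any(bad))
      stop("record(s) without syndrome label: ",
           paste(corpus$record_id[bad], collapse = ", "))
  }
  invisible(new_emr_corpus(as.data.frame(corpus)))
}

#' Read and write EMR corpora
#'
#' Two on-disk dialects are supported: `"tsv"` (UTF-8 delimited text, one
#' record per line, columns `record_id`, the seven field texts, `syndrome`)
#' and `"json"` (an array of one object per record).  `write_corpus()`
#' followed by `read_corpus()` is the identity for both dialects.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"json"`.
#' @param strict_training If `TRUE`, every record must carry a non-empty
#'   syndrome label (the training-corpus invariant).
#' @return `read_corpus()`: an `emr_corpus`; `write_corpus()`: `path`,
#'   invisibly.
#' @export
read_corpus <- function(path, dialect = c("tsv", "json"), strict_training = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines)) stop("empty corpus file: ", path)
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    need <- c("record_id", field_types(), "syndrome")
    if (!identical(header, need))
      stop("bad corpus header in ", path, " (line 1)")
    rows <- lapply(seq_along(lines)[-1], function(i) {
      cells <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      # a trailing empty syndrome column is dropped by strsplit; restore it
      if (length(cells) == length(need) - 1L) cells <- c(cells, "")
      if (length(cells) != length(need))
        stop("malformed corpus row at line ", i, " of ", path,
             " (", length(cells), " columns, expected ", length(need), ")")
      cells
    })
    m <- if (length(rows)) do.call(rbind, rows) else
      matrix(character(0), 0, length(need))
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- need
  } else {
    objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    need <- c("record_id", field_types(), "syndrome")
    df <- as.data.frame(
      setNames(lapply(need, function(col)
        vapply(objs, function(o) {
          v <- o[[col]]
          if (is.null(v)) "" else as.character(v)
        }, "")), need),
      stringsAsFactors = FALSE)
    if (!nrow(df) && length(objs) == 0L)
      df <- df[0, , drop = FALSE]
  }
  df$syndrome[df$syndrome == ""] <- NA_character_
  if (!nrow(df)) return(new_emr_corpus(df))
  if (all(!nzchar(df$record_id)))
    df$record_id <- sprintf("R%05d", seq_len(nrow(df)))
  validate_corpus(df, require_labels = strict_training)
}

#' @param corpus An `emr_corpus` (or conforming data frame).
#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  corpus <- validate_corpus(corpus)
  cols <- c("record_id", field_types(), "syndrome")
  df <- as.data.frame(corpus)[, cols, drop = FALSE]
  df$syndrome[is.na(df$syndrome)] <- ""
  if (dialect == "tsv") {
    lines <- c(paste(cols, collapse = "\t"),
               if (nrow(df)) apply(df, 1L, paste, collapse = "\t"))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         na = "string")
  }
  invisible(path)
}
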