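#' Typed knowledge graph of symptoms and syndromes
#'
#' A `dsds_kg` holds three tables:
#' \describe{
#'   \item{entities}{`id` (integer), `name`, `etype` (one of
#'     [entity_types()]). Entity identity is the pair (name, etype): the same
#'     string observed in two field types yields two distinct entities.}
#'   \item{relations}{`id`, `name`, `kind` (`"method_performance"` or
#'     `"symptom_syndrome"`), `field_type`, `diagnostic` (logical; `FALSE`
#'     for nursing-precaution relations, which are excluded at prediction
#'     time).  For each of the seven non-syndrome field types `t` there are
#'     exactly two relations: `performance of {t}` and `{t}-syndrome`.}
#'   \item{triples}{`h`, `l`, `t` integer id columns; deduplicated.}
#' }
#'
#' For every record, field type `t` and segmented token `s` of that field,
#' [build_kg()] emits two triples: `(method node of t, performance of t, s)`
#' and `(s, t-syndrome, syndrome entity)`.  The method node is a single
#' shared entity per field type, so the graph stays connected across
#' records.  Triples are deduplicated across records (set semantics).
#'
#' @param records An `emr_corpus`; every record must have a syndrome label.
#' @param include_nursing Keep nursing-precaution triples in the graph
#'   (default `TRUE`; they enrich the graph but are flagged non-diagnostic).
#' @param punctuation Separator set passed to [segment_field()].
#' @return A `dsds_kg` object.
#' @export
build_kg <- function(records, include_nursing = TRUE,
                     punctuation = default_punctuation()) {
  records <- validate_corpus(records, require_labels = TRUE)
  if (!nrow(records)) stop("empty corpus: cannot build a knowledge graph")
  fts <- field_types()
  if (!include_nursing) fts <- diagnostic_field_types()

  relations <- data.frame(
    id = seq_len(2L * length(fts)),
    name = c(paste0("performance of ", fts), paste0(fts, "-syndrome")),
    kind = rep(c("method_performance", "symptom_syndrome"), each = length(fts)),
    field_type = rep(fts, 2L),
    diagnostic = rep(fts != "nursing_precautions", 2L),
    stringsAsFactors = FALSE
  )

  # entity key "etype\rname"; \r is forbidden inside values
  ent_key <- function(etype, name) paste(etype, name, sep = "\r")
  keys <- character(0)
  h <- integer(0); l <- integer(0); t <- integer(0)

  # collect (etype, name) pairs first, then assign ids
  method_keys <- ent_key("method", fts)   # method nodes, one per field type
  tok_by_ft <- lapply(fts, function(ft) {
    lapply(records[[ft]], segment_field, punctuation = punctuation)
  })
  names(tok_by_ft) <- fts
  syn <- records$syndrome

  all_keys <- c(method_keys, ent_key("syndrome", unique(syn)))
  for (ft in fts) {
    toks <- unique(unlist(tok_by_ft[[ft]], use.names = FALSE))
    if (length(toks))   # paste() would recycle character(0) to ""
      all_keys <- c(all_keys, ent_key(ft, toks))
  }
  all_keys <- unique(all_keys)
  id_of <- seq_along(all_keys)
  names(id_of) <- all_keys

  perf_rel <- setNames(relations$id[relations$kind == "method_performance"],
                       relations$field_type[relations$kind == "method_performance"])
  ss_rel <- setNames(relations$id[relations$kind == "symptom_syndrome"],
                     relations$field_type[relations$kind == "symptom_syndrome"])

  for (ft in fts) {
    mnode <- id_of[[ent_key("method", ft)]]
    per_rec <- tok_by_ft[[ft]]
    for (i in seq_along(per_rec)) {
      toks <- per_rec[[i]]
      if (!length(toks)) next
      sids <- unname(id_of[ent_key(ft, toks)])
      syid <- id_of[[ent_key("syndrome", syn[[i]])]]
      h <- c(h, rep(mnode, length(sids)), sids)
      l <- c(l, rep(perf_rel[[ft]], length(sids)), rep(ss_rel[[ft]], length(sids)))
      t <- c(t, sids, rep(syid, length(sids)))
    }
  }
  tr <- unique(data.frame(h = h, l = l, t = t))
  rownames(tr) <- NULL

  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  entities <- data.frame(
    id = unname(id_of),
    name = vapply(parts, function(p) paste(p[-1], collapse = "\r"), ""),
    etype = vapply(parts, `[[`, "", 1L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  # method nodes carry the field name; give them their own etype "method"
  structure(list(entities = entities, relations = relations, triples = tr),
            class = "dsds_kg")
}

#' @export
print.dsds_kg <- function(x, ...) {
  cat("<dsds_kg> ", nrow(x$entities), " entities, ",
      nrow(x$relations), " relations, ", nrow(x$triples), " triples\n",
      sep = "")
  invisible(x)
}

# id lookup helpers ---------------------------------------------------------

kg_entity_id <- function(kg, name, etype) {
  hit <- kg$entities$id[kg$entities$name == name & kg$entities$etype == etype]
  if (length(hit) != 1L) return(NA_integer_)
  hit
}

kg_syndrome_ids <- function(kg) kg$entities$id[kg$entities$etype == "syndrome"]

kg_triple_keys <- function(kg) {
  paste(kg$triples$h, kg$triples$l, kg$triples$t, sep = "_")
}

#' Repetition percentage of an entity category
#'
#' The corpus redundancy statistic: `100 * (1 - dedup / participle)`, the
#' share of post-segmentation token occurrences that are repeats of an
#' already-seen token, rounded half-up to one decimal.
#'
#' @param participle_count Total token occurrences after segmentation.
#' @param dedup_count Unique token strings.
#' @return Percentage in `[0, 100]`, one decimal.
#' @export
#' @examples
#' repetition_percentage(371760, 34144)  # 90.8
repetition_percentage <- function(participle_count, dedup_count) {
  stopifnot(length(participle_count) == length(dedup_count))
  if (any(participle_count <= 0))
    stop("participle_count must be positive")
  if (any(dedup_count <= 0) || any(dedup_count > participle_count))
    stop("dedup_count must satisfy 0 < dedup <= participle")
  x <- 100 * (1 - dedup_count / participle_count)
  floor(x * 10 + 0.5) / 10   # round half-up, one decimal
}

#' Entity statistics of a corpus
#'
#' Per entity category: `original` (raw non-empty field instances),
#' `participle` (token occurrences after segmentation), `dedup` (unique
#' token strings) and the repetition percentage.  Syndrome labels are not
#' segmented; their repetition is computed from label occurrences versus
#' unique labels.  The `average_percent` is the arithmetic mean of the eight
#' per-category percentages; totals sum the count columns.
#'
#' @param records An `emr_corpus`.
#' @param punctuation Separator set for [segment_field()].
#' @return A list with `table` (data frame, one row per entity type),
#'   `total_original`, `total_participle`, `total_dedup`, `average_percent`.
#' @export
entity_statistics <- function(records, punctuation = default_punctuation()) {
  records <- validate_corpus(records)
  rows <- lapply(field_types(), function(ft) {
    txt <- records[[ft]]
    toks <- unlist(lapply(txt, segment_field, punctuation = punctuation),
                   use.names = FALSE)
    data.frame(etype = ft,
               original = sum(!is.na(txt) & nzchar(trimws(txt))),
               participle = length(toks),
               dedup = length(unique(toks)),
               stringsAsFactors = FALSE)
  })
  lab <- records$syndrome
  lab <- lab[!is.na(lab) & nzchar(trimws(lab))]
  rows <- c(rows, list(data.frame(etype = "syndrome",
                                  original = length(lab),
                                  participle = NA_integer_,
                                  dedup = length(unique(lab)))))
  tab <- do.call(rbind, rows)
  tab$percent <- NA_real_
  for (i in seq_len(nrow(tab))) {
    denom <- if (is.na(tab$participle[i])) tab$original[i] else tab$participle[i]
    if (!is.na(denom) && denom > 0 && tab$dedup[i] > 0)
      tab$percent[i] <- repetition_percentage(denom, tab$dedup[i])
    else if (!is.na(denom) && denom == tab$dedup[i])
      tab$percent[i] <- 0
  }
  list(table = tab,
       total_original = sum(tab$original, na.rm = TRUE),
       # labels are not segmented, so each label occurrence is its own token
       total_participle = sum(ifelse(is.na(tab$participle), tab$original,
                                     tab$participle)),
       total_dedup = sum(tab$dedup, na.rm = TRUE),
       average_percent = average_repetition(tab$percent))
}

#' Average of per-category repetition percentages
#'
#' Arithmetic mean of the per-entity-type percentages, rounded half-up to
#' one decimal.  This is the corpus-level "overall repetition" figure.
#'
#' @param percents Numeric vector of per-type percentages (NAs dropped).
#' @return Scalar percentage, one decimal.
#' @export
#' @examples
#' average_repetition(c(90.8, 91.5, 97.5, 91.5, 88.4, 96.7, 87.3, 85.8))
average_repetition <- function(percents) {
  p <- percents[!is.na(percents)]
  if (!length(p)) stop("no percentages to average")
  floor(mean(p) * 10 + 0.5) / 10
}

# triple file I/O -----------------------------------------------------------

#' Export and import a knowledge graph as portable TSV files
#'
#' Writes `triples.tsv` (head/relation/tail names), `entities.tsv`
#' (id, name, etype) and `relations.tsv` (id, name, kind, field_type,
#' diagnostic) into `dir`.  `import_kg()` reads them back;
#' `import_kg(export_kg(kg))` reproduces `kg` exactly.
#'
#' @param kg A `dsds_kg`.
#' @param dir Output directory (created if missing).
#' @return `export_kg()`: `dir`, invisibly.  `import_kg()`: a `dsds_kg`.
#' @export
export_kg <- function(kg, dir) {
  stopifnot(inherits(kg, "dsds_kg"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  wt(kg$entities, "entities.tsv")
  wt(kg$relations, "relations.tsv")
  ename <- kg$entities$name; rname <- kg$relations$name
  wt(data.frame(head = ename[kg$triples$h],
                relation = rname[kg$triples$l],
                tail = ename[kg$triples$t]), "triples.tsv")
  invisible(dir)
}

#' @rdname export_kg
#' @export
import_kg <- function(dir) {
  rd <- function(f, what) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing ", what, " file: ", p)
    utils::read.table(p, sep = "\t", header = TRUE, quote = "",
                      colClasses = "character", fileEncoding = "UTF-8")
  }
  ent <- rd("entities.tsv", "entity vocabulary")
  rel <- rd("relations.tsv", "relation vocabulary")
  tri <- rd("triples.tsv", "triple")
  ent$id <- as.integer(ent$id)
  rel$id <- as.integer(rel$id)
  rel$diagnostic <- as.logical(rel$diagnostic)
  # names alone do not identify an entity (vocabularies are type-scoped);
  # a triple file stores names, so heads/tails are disambiguated below by
  # the relation's field type.
  eid <- setNames(ent$id, paste(ent$etype, ent$name, sep = "\r"))
  rid <- setNames(rel$id, rel$name)
  lr <- rid[tri$relation]
  if (anyNA(lr))
    stop("import: unknown relation name: ",
         paste(unique(tri$relation[is.na(lr)]), collapse = ", "))
  # disambiguate heads/tails by the relation's field type
  ft <- rel$field_type[match(unname(lr), rel$id)]
  kind <- rel$kind[match(unname(lr), rel$id)]
  htype <- ifelse(kind == "method_performance", "method", ft)
  ttype <- ifelse(kind == "method_performance", ft, "syndrome")
  hkey <- paste(htype, tri$head, sep = "\r")
  tkey <- paste(ttype, tri$tail, sep = "\r")
  hh <- unname(eid[hkey]); tt <- unname(eid[tkey])
  if (anyNA(hh) || anyNA(tt))
    stop("import: undeclared entity: ",
         paste(unique(c(tri$head[is.na(hh)], tri$tail[is.na(tt)])), collapse = ", "))
  tr <- data.frame(h = hh, l = unname(lr), t = tt)
  if (nrow(tr) == 0L) tr <- data.frame(h = integer(0), l = integer(0), t = integer(0))
  rownames(ent) <- rownames(rel) <- rownames(tr) <- NULL
  structure(list(entities = ent, relations = rel, triples = tr),
            class = "dsds_kg")
}
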