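#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: where the corpus comes from
#' (a file, or the synthetic generator when `corpus_path` is `NULL`), the
#' segmentation punctuation, the embedding training configuration, the
#' aggregation parameters and the split.  One `seed` is propagated to every
#' stochastic component.
#'
#' @param corpus_path Path to a corpus file, or `NULL` to generate one.
#' @param dialect Corpus file dialect, `"tsv"` or `"json"`.
#' @param synth A [synth_config()] used when `corpus_path` is `NULL`.
#' @param train A [train_config()].
#' @param punctuation Separator set.
#' @param k Shortlist size for scoring-and-voting.
#' @param top_n N values reported.
#' @param train_frac Training fraction.
#' @param seed Master seed.
#' @param out_dir Run directory to create.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus_path = NULL, dialect = "tsv",
                            synth = synth_config(), train = train_config(),
                            punctuation = default_punctuation(), k = 10L,
                            top_n = c(1L, 3L, 5L), train_frac = 0.8,
                            seed = 1L, out_dir = tempfile("dsds_run_")) {
  if (!is.null(corpus_path) && !file.exists(corpus_path))
    stop("corpus path does not exist: ", corpus_path)
  structure(list(corpus_path = corpus_path, dialect = dialect, synth = synth,
                 train = train, punctuation = punctuation, k = as.integer(k),
                 top_n = as.integer(top_n), train_frac = train_frac,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_log <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(line, con)
  message(line)
}

#' Run the full pipeline
#'
#' Executes build -> train -> predict -> evaluate and writes a
#' self-describing run directory: the knowledge-graph TSVs (`kg/`), the
#' embedding checkpoint (`checkpoint/`), per-record recommendations
#' (`recommendations.tsv`), the metrics report (`metrics.json`) and a run
#' log recording the configuration and seed.  Any stage failure aborts with
#' the stage name; artifacts written before the failure are retained.
#'
#' @param config A [pipeline_config()].
#' @return The run directory path, invisibly; the `metrics_report` is
#'   attached as attribute `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  stage <- function(name, expr) {
    pipeline_log(logf, "stage ", name, " ...")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    pipeline_log(logf, "stage ", name, " done in ",
                 sprintf("%.1fs", proc.time()[["elapsed"]] - t0))
    out
  }

  corpus <- stage("corpus", {
    if (is.null(config$corpus_path)) {
      cfg <- config$synth; cfg$seed <- config$seed
      gen <- generate_corpus(do.call(synth_config, unclass(cfg)),
                             config$punctuation)
      write_corpus(gen$records, file.path(config$out_dir, "corpus.tsv"))
      gen$records
    } else {
      read_corpus(config$corpus_path, config$dialect, strict_training = TRUE)
    }
  })
  pipeline_log(logf, "corpus: ", nrow(corpus), " records, sha: ",
               corpus_digest(corpus))

  report <- stage("evaluate", {
    tc <- config$train; tc$seed <- config$seed
    evaluate_split(corpus, train_frac = config$train_frac,
                   seed = config$seed, config = tc, k = config$k,
                   top_n = config$top_n, punctuation = config$punctuation)
  })

  stage("artifacts", {
    split <- attr(report, "split")
    train <- new_emr_corpus(
      as.data.frame(corpus)[corpus$record_id %in% split$train, , drop = FALSE])
    kg <- build_kg(train, punctuation = config$punctuation)
    export_kg(kg, file.path(config$out_dir, "kg"))
    tc <- config$train; tc$seed <- config$seed
    emb <- train_model(kg, tc)
    save_checkpoint(emb, file.path(config$out_dir, "checkpoint"))
    recs <- attr(report, "recommendations")
    lines <- c("record_id\trank\tsyndrome")
    for (rid in names(recs)) {
      r <- recs[[rid]]
      if (length(r))
        lines <- c(lines, paste(rid, seq_along(r), r, sep = "\t"))
    }
    writeLines(lines, file.path(config$out_dir, "recommendations.tsv"),
               useBytes = TRUE)
    jsonlite::write_json(
      list(seed = config$seed, k = config$k, train_frac = config$train_frac,
           top_n = as.list(stats::setNames(as.numeric(report$top_n),
                                           names(report$top_n))),
           weighted_precision = report$weighted_precision,
           weighted_recall = report$weighted_recall,
           weighted_f1 = report$weighted_f1,
           accuracy = report$accuracy),
      file.path(config$out_dir, "metrics.json"), auto_unbox = TRUE,
      digits = NA)
    NULL
  })
  out <- config$out_dir
  attr(out, "report") <- report
  invisible(out)
}

# dependency-free provenance hash of a corpus (djb2 over the TSV lines)
corpus_digest <- function(corpus) {
  cols <- c("record_id", field_types(), "syndrome")
  df <- as.data.frame(corpus)[, cols, drop = FALSE]
  df$syndrome[is.na(df$syndrome)] <- ""
  txt <- paste(apply(df, 1L, paste, collapse = "\t"), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
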