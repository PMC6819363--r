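#' Read a TREC-style qrels file
#'
#' Parses relevance judgments in the four-column qrels dialect used by the
#' CLEF technology-assisted-review shared tasks: each non-blank line holds
#' `topic iteration document relevance`, whitespace-separated. The iteration
#' column is ignored; a document is relevant iff its relevance integer is
#' positive. Topics with no relevant documents are retained.
#'
#' @param path Path to the qrels file.
#' @return Named list: topic id -> named logical vector (document id ->
#'   relevant).
#' @export
read_qrels <- function(path) {
  if (!file.exists(path)) stop("qrels file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  topics <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    fields <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(fields) < 4L) {
      stop("qrels parse error at line ", i, ": expected >= 4 fields, got ",
           length(fields))
    }
    rel <- suppressWarnings(as.integer(fields[[4]]))
    if (is.na(rel)) {
      stop("qrels parse error at line ", i, ": non-integer relevance '",
           fields[[4]], "'")
    }
    topic <- fields[[1]]; doc <- fields[[3]]
    if (is.null(topics[[topic]])) topics[[topic]] <- logical(0)
    topics[[topic]][[doc]] <- rel > 0L
  }
  topics
}

#' Write qrels judgments
#'
#' Inverse of [read_qrels()]; the iteration column is written as 0 and
#' relevance as 1/0.
#'
#' @param qrels Named list as returned by [read_qrels()].
#' @param path Output path.
#' @export
write_qrels <- function(qrels, path) {
  lines <- unlist(lapply(names(qrels), function(topic) {
    docs <- qrels[[topic]]
    sprintf("%s 0 %s %d", topic, names(docs), as.integer(docs))
  }), use.names = FALSE)
  writeLines(if (is.null(lines)) character(0) else lines, path)
}

#' Read a flat 2x2-table export
#'
#' Reads a delimited table with header columns `review_id, ma_id, study_id,
#' tp, fp, fn, tn` (one row per study per meta-analysis, the flat-file shape
#' of per-review groupings of diagnostic 2x2 tables) and assembles one
#' [ma_group()] per `(review_id, ma_id)` pair.
#'
#' @param path Path to the CSV file.
#' @return List of `dta_ma_group` objects.
#' @export
read_2x2_table <- function(path) {
  if (!file.exists(path)) stop("2x2 table file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("review_id", "ma_id", "study_id", "tp", "fp", "fn", "tn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("2x2 table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("tp", "fp", "fn", "tn")) {
    v <- df[[col]]
    if (any(is.na(v)) || any(v < 0)) {
      stop("2x2 table: column '", col, "' contains negative or missing counts")
    }
  }
  key <- paste(df$ma_id, df$study_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop("2x2 table: duplicate (ma_id, study_id): ",
         paste(unique(paste0(dup$ma_id, "/", dup$study_id)), collapse = ", "))
  }
  grp_key <- paste(df$review_id, df$ma_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(grp_key, levels = unique(grp_key))),
    function(idx) {
      rows <- df[idx, , drop = FALSE]
      studies <- lapply(seq_len(nrow(rows)), function(j) {
        two_by_two(rows$tp[j], rows$fp[j], rows$fn[j], rows$tn[j], rows$study_id[j])
      })
      ma_group(rows$ma_id[[1]], studies, review_id = rows$review_id[[1]])
    })
  unname(out)
}

#' Write a 2x2-table export
#'
#' @param groups List of `dta_ma_group` objects.
#' @param path Output CSV path.
#' @export
write_2x2_table <- function(groups, path) {
  rows <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(g$studies, function(s) {
      data.frame(review_id = g$review_id, ma_id = g$ma_id,
                 study_id = s$study_ref, tp = s$tp, fp = s$fp,
                 fn = s$fn, tn = s$tn, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(rows)) {
    rows <- data.frame(review_id = character(0), ma_id = character(0),
                       study_id = character(0), tp = integer(0), fp = integer(0),
                       fn = integer(0), tn = integer(0))
  }
  write.csv(rows, path, row.names = FALSE)
}

#' Read a candidate-pool CSV
#'
#' Columns `ref_id, title, abstract` and optionally `source_id` and
#' `is_relevant` (0/1 or logical; when absent, labels can be supplied from
#' qrels via `relevance`).
#'
#' @param path Path to the pool CSV.
#' @param relevance Optional named logical vector (ref_id -> relevant)
#'   overriding / supplying the labels, e.g. one topic from [read_qrels()].
#'   References absent from the vector are labeled not relevant.
#' @return List of `dta_reference` objects.
#' @export
read_pool_csv <- function(path, relevance = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("ref_id", "title", "abstract")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pool CSV missing column(s): ", paste(miss, collapse = ", "))
  has_src <- "source_id" %in% names(df)
  rel <- if (!is.null(relevance)) {
    unname(relevance[df$ref_id]) %in% TRUE
  } else if ("is_relevant" %in% names(df)) {
    df$is_relevant %in% c("1", "TRUE", "true")
  } else rep(FALSE, nrow(df))
  lapply(seq_len(nrow(df)), function(i) {
    reference(df$ref_id[i], df$title[i],
              if (is.na(df$abstract[i])) "" else df$abstract[i],
              is_relevant = rel[i],
              source_id = if (has_src) df$source_id[i] else NA_character_)
  })
}

#' Write a candidate-pool CSV
#'
#' @param pool List of `dta_reference` objects.
#' @param path Output CSV path.
#' @param labels Write the `is_relevant` column (default `TRUE`).
#' @export
write_pool_csv <- function(pool, path, labels = TRUE) {
  df <- data.frame(
    ref_id = vapply(pool, `[[`, character(1), "ref_id"),
    title = vapply(pool, `[[`, character(1), "title"),
    abstract = vapply(pool, `[[`, character(1), "abstract"),
    source_id = vapply(pool, `[[`, character(1), "source_id"),
    stringsAsFactors = FALSE
  )
  if (labels) df$is_relevant <- as.integer(vapply(pool, `[[`, logical(1), "is_relevant"))
  write.csv(df, path, row.names = FALSE)
}

#' Write a screening trace CSV
#'
#' One row per screening position: `position, ref_id, is_relevant`.
#'
#' @param trace A `dta_trace`.
#' @param path Output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(position = seq_len(trace$n_total), ref_id = trace$order,
                   is_relevant = as.integer(trace$relevant))
  write.csv(df, path, row.names = FALSE)
}

#' @rdname write_trace_csv
#' @param method_tag Tag recorded on the reconstructed trace.
#' @export
read_trace_csv <- function(path, method_tag = "ranked") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(df$position), , drop = FALSE]
  screening_trace(as.character(df$ref_id), df$is_relevant == 1,
                  method_tag = method_tag)
}

#' Write a simulation report
#'
#' The CSV layout mirrors a per-criterion summary table: one row per
#' (order method, criterion) with trigger counts, mean effort (absolute and
#' as a fraction of the pool), mean recall at trigger, and mean losses of the
#' point estimates and their 95% CI bounds against the final estimates.
#'
#' @param report A `dta_simulation_report` from [run_simulation()].
#' @param path Output path.
#' @param format `"csv"` (the aggregate table) or `"json"` (aggregates plus
#'   all raw events).
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "dta_simulation_report"))
  if (format == "csv") {
    write.csv(report$aggregates, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(review_id = report$review_id, aggregates = report$aggregates,
           events = report$events, meta = report$meta),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
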