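# Pentamer fold-pattern database: maps each five-residue sequence fragment
# to the ranked PFSC fold patterns observed for it in a structure corpus,
# with a background marginal used as statistical backoff for unseen
# pentamers.

#' Size of the pentamer sequence space
#'
#' @param n_letters alphabet size (20 standard amino acids).
#' @param k fragment length (5).
#' @return `n_letters ^ k` (3,200,000 for the defaults).
#' @examples
#' enumerate_pentamer_space()  # 3200000
#' @export
enumerate_pentamer_space <- function(n_letters = 20L, k = 5L) {
  stopifnot(n_letters >= 1, k >= 1)
  as.numeric(n_letters)^as.numeric(k)
}

# rank a code-count table: count descending, ties lexicographic by code
rank_patterns <- function(df) {
  df <- df[order(-df$count, df$code), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the pentamer fold-pattern database from a structure corpus
#'
#' Every chain of every corpus file is encoded to its PFSC string; window
#' `i` contributes the pair (pentamer = residues `i..i+4`, code = symbol
#' `i`) unless the code is `$` or the pentamer contains `X`. Counts are
#' aggregated over the whole corpus and each pentamer's patterns ranked by
#' count (ties broken lexicographically). The marginal distribution of
#' codes over all contributing windows is kept as the backoff background.
#'
#' @param corpus character vector of structure file paths.
#' @param alphabet a [pfsc_alphabet()].
#' @param model_index model used for multi-model files.
#' @return Object of class `pentamer_db` with elements `records` (named
#'   list: pentamer -> data.frame(code, count)), `background` (ranked
#'   data.frame(code, count)), `corpus_manifest`.
#' @export
build_db <- function(corpus, alphabet = default_alphabet(), model_index = 1L) {
  stopifnot(length(corpus) >= 1)
  pent <- character(0); code <- character(0)
  manifest <- character(0)
  n_read <- 0L
  for (f in sort(corpus)) {
    traces <- tryCatch(read_structure(f, model_index),
                       error = function(e) {
                         message("skipping unreadable file ", f, ": ",
                                 conditionMessage(e))
                         NULL
                       })
    if (is.null(traces)) next
    n_read <- n_read + 1L
    for (tr in traces) {
      if (length(tr) < 5) next
      manifest <- c(manifest, tr$source_id)
      s <- strsplit(as.character(encode_chain(tr, alphabet)), "")[[1]]
      aa <- tr$residues$aa1
      for (i in seq_along(s)) {
        p <- paste(aa[i:(i + 4)], collapse = "")
        if (s[i] == "$" || grepl("X", p, fixed = TRUE)) next
        pent <- c(pent, p); code <- c(code, s[i])
      }
    }
  }
  if (n_read == 0L) stop("no readable corpus files")
  records <- list()
  if (length(pent)) {
    tab <- table(pent, code)
    for (p in rownames(tab)) {
      cnt <- setNames(as.integer(tab[p, ]), colnames(tab))
      cnt <- cnt[cnt > 0]
      records[[p]] <- rank_patterns(
        data.frame(code = names(cnt), count = as.integer(cnt),
                   stringsAsFactors = FALSE))
    }
    bg <- table(code)
    background <- rank_patterns(
      data.frame(code = names(bg), count = as.integer(bg),
                 stringsAsFactors = FALSE))
  } else {
    background <- data.frame(code = character(0), count = integer(0))
  }
  structure(list(records = records[order(names(records))],
                 background = background,
                 corpus_manifest = sort(manifest)),
            class = "pentamer_db")
}

#' @export
print.pentamer_db <- function(x, ...) {
  cat(sprintf("Pentamer fold-pattern database: %d observed pentamers from %d chain(s), %d windows\n",
              length(x$records), length(x$corpus_manifest),
              sum(x$background$count)))
  invisible(x)
}

#' Query a pentamer's fold patterns
#'
#' Returns the observed record when the pentamer was seen in the corpus.
#' Unseen pentamers fall back to a synthetic record holding the corpus-wide
#' background ranking truncated to `k_backoff` patterns; such records carry
#' `synthetic = TRUE` so downstream reports can mark them.
#'
#' @param db a [build_db()] result.
#' @param pentamer five-letter sequence over the 20-letter alphabet.
#' @param k_backoff maximum number of background patterns returned for
#'   unseen pentamers.
#' @return List with `pentamer`, `patterns` (data.frame(code, count)),
#'   `synthetic`.
#' @export
query_pentamer <- function(db, pentamer, k_backoff = 5L) {
  stopifnot(inherits(db, "pentamer_db"))
  if (!is.character(pentamer) || length(pentamer) != 1L || nchar(pentamer) != 5L)
    stop("pentamer must be a single 5-letter string")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]{5}$", pentamer))
    stop("pentamer must use the 20-letter amino-acid alphabet: ", pentamer)
  rec <- db$records[[pentamer]]
  if (!is.null(rec))
    return(list(pentamer = pentamer, patterns = rec, synthetic = FALSE))
  if (nrow(db$background) == 0)
    stop("empty database: no background available for backoff")
  list(pentamer = pentamer,
       patterns = head(db$background, k_backoff),
       synthetic = TRUE)
}

#' Save a pentamer database
#'
#' XML schema: `<db><meta>...</meta><rec p="AAAAA"><pat c="A" n="16"/></rec>
#' ...</db>`; the JSON format mirrors it. Both round-trip losslessly.
#'
#' @param db a `pentamer_db`.
#' @param path output file.
#' @param format `"xml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
save_db <- function(db, path, format = c("xml", "json")) {
  stopifnot(inherits(db, "pentamer_db"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(meta = list(manifest = db$corpus_manifest,
                            background = list(code = db$background$code,
                                              count = db$background$count)),
                records = lapply(db$records, function(r)
                  list(code = r$code, count = r$count)))
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  } else {
    doc <- xml2::xml_new_root("db")
    meta <- xml2::xml_add_child(doc, "meta")
    for (m in db$corpus_manifest)
      xml2::xml_add_child(meta, "src", id = m)
    bgn <- xml2::xml_add_child(meta, "background")
    for (i in seq_len(nrow(db$background)))
      xml2::xml_add_child(bgn, "pat", c = db$background$code[i],
                          n = as.character(db$background$count[i]))
    for (p in names(db$records)) {
      rec <- xml2::xml_add_child(doc, "rec", p = p)
      r <- db$records[[p]]
      for (i in seq_len(nrow(r)))
        xml2::xml_add_child(rec, "pat", c = r$code[i],
                            n = as.character(r$count[i]))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Load a pentamer database saved by [save_db()]
#'
#' The format (XML or JSON) is detected from the file content.
#'
#' @param path file written by [save_db()].
#' @return A `pentamer_db`.
#' @export
load_db <- function(path) {
  if (!file.exists(path)) stop("cannot read database file: ", path)
  first <- substr(trimws(readLines(path, n = 1L, warn = FALSE)[1]), 1, 1)
  if (identical(first, "{")) {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e) stop("malformed JSON database: ", path))
    if (is.null(obj$records) || is.null(obj$meta))
      stop("malformed database file: ", path)
    records <- lapply(obj$records, function(r)
      rank_patterns(data.frame(code = unlist(r$code),
                               count = as.integer(unlist(r$count)),
                               stringsAsFactors = FALSE)))
    bg <- obj$meta$background
    background <- data.frame(code = unlist(bg$code),
                             count = as.integer(unlist(bg$count)),
                             stringsAsFactors = FALSE)
    manifest <- as.character(unlist(obj$meta$manifest))
  } else {
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) stop("malformed XML database: ", path))
    if (xml2::xml_name(doc) != "db") stop("malformed database file: ", path)
    manifest <- xml2::xml_attr(xml2::xml_find_all(doc, "./meta/src"), "id")
    bgn <- xml2::xml_find_all(doc, "./meta/background/pat")
    background <- data.frame(code = xml2::xml_attr(bgn, "c"),
                             count = as.integer(xml2::xml_attr(bgn, "n")),
                             stringsAsFactors = FALSE)
    recs <- xml2::xml_find_all(doc, "./rec")
    records <- lapply(recs, function(rec) {
      pats <- xml2::xml_find_all(rec, "./pat")
      rank_patterns(data.frame(code = xml2::xml_attr(pats, "c"),
                               count = as.integer(xml2::xml_attr(pats, "n")),
                               stringsAsFactors = FALSE))
    })
    names(records) <- xml2::xml_attr(recs, "p")
  }
  if (length(records)) records <- records[order(names(records))]
  structure(list(records = records,
                 background = rank_patterns(background),
                 corpus_manifest = sort(manifest)),
            class = "pentamer_db")
}
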