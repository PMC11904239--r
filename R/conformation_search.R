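# Conformation-homology search and Ca-model assembly: a PFSC-indexed
# structure library is screened for fragments whose encoding matches a
# query conformation string above the PFSA acceptance threshold, and the
# accepted fragments are spliced into whole-chain Ca-trace models.

#' Build a PFSC-indexed structure library
#'
#' Encodes every chain of every corpus file and builds a k-gram index over
#' the encodings (default k = 8) for seeded candidate lookup. Entries are
#' sorted by source identifier, so rebuilding from the same files in any
#' order yields an identical library.
#'
#' @param corpus character vector of structure file paths (non-empty).
#' @param alphabet a [pfsc_alphabet()].
#' @param k k-gram length of the index.
#' @param model_index model used for multi-model files.
#' @return Object of class `structure_library` with `entries` (each:
#'   `source_id`, `string`, `trace`) and `index` (k-gram -> data.frame of
#'   entry/offset postings).
#' @export
index_library <- function(corpus, alphabet = default_alphabet(), k = 8L,
                          model_index = 1L) {
  if (length(corpus) < 1) stop("corpus must be non-empty")
  entries <- list()
  for (f in sort(corpus)) {
    for (tr in read_structure(f, model_index)) {
      if (length(tr) < 5) next
      entries[[length(entries) + 1L]] <-
        list(source_id = tr$source_id,
             string = as.character(encode_chain(tr, alphabet)),
             trace = tr)
    }
  }
  if (length(entries) == 0) stop("no encodable chains in corpus")
  ord <- order(vapply(entries, function(e) e$source_id, character(1)))
  entries <- entries[ord]
  index <- new.env(parent = emptyenv())
  for (e in seq_along(entries)) {
    s <- entries[[e]]$string
    n <- nchar(s)
    if (n < k) next
    for (off in seq_len(n - k + 1L)) {
      g <- substr(s, off, off + k - 1L)
      index[[g]] <- rbind(index[[g]], c(entry = e, offset = off))
    }
  }
  structure(list(entries = entries, index = index, k = as.integer(k)),
            class = "structure_library")
}

#' @export
print.structure_library <- function(x, ...) {
  cat(sprintf("Structure library: %d chain(s), %d-gram index with %d keys\n",
              length(x$entries), x$k, length(ls(x$index))))
  invisible(x)
}

#' Split a conformation string into overlapping residue fragments
#'
#' Whole chains rarely find a single conformational homolog above the
#' acceptance threshold, so queries are divided into fragments of about
#' 40-50 residues which are searched independently and spliced back.
#' Spans step by `target_len - overlap`; the final span is right-aligned
#' to cover the tail, so the union of spans is the full residue range and
#' adjacent spans share at least `overlap` residues.
#'
#' @param s a [pfsc_string()] (or character): the query conformation.
#' @param target_len fragment length in residues (default 45).
#' @param overlap minimum overlap between adjacent fragments (>= 4).
#' @return data.frame of residue spans (`start`, `end`, 1-based inclusive,
#'   over the `nchar(s) + 4` residues the string covers).
#' @export
split_into_fragments <- function(s, target_len = 45L, overlap = 4L) {
  n_res <- nchar(as_pfsc_chars(s)) + 4L
  if (overlap < 4) stop("overlap must be at least 4 residues (one window)")
  if (target_len <= overlap) stop("target_len must exceed overlap")
  if (n_res <= target_len)
    return(data.frame(start = 1L, end = n_res))
  step <- target_len - overlap
  starts <- seq(1L, n_res - target_len, by = step)
  spans <- data.frame(start = as.integer(starts),
                      end = as.integer(starts + target_len - 1L))
  if (tail(spans$end, 1) < n_res)
    spans <- rbind(spans, data.frame(start = n_res - target_len + 1L,
                                     end = n_res))
  spans
}

# residue span -> window (string) span covering the same residues
span_to_windows <- function(span) c(span[["start"]], span[["end"]] - 4L)

#' Search the library for conformation-homologous fragments
#'
#' Scores the query substring over `span` against source windows of the
#' same length and keeps hits whose PFSA score is strictly larger than
#' `threshold`, ranked by score then source then offset. `method
#' "exhaustive"` (default) scans every same-length window of every entry;
#' `"seeded"` restricts scoring to windows sharing at least one k-gram
#' with the query, which is faster on large libraries but can miss hits
#' whose similarity is purely class-level.
#'
#' @param lib an [index_library()] result.
#' @param s query [pfsc_string()] (or character).
#' @param span residue span (`c(start, end)` or a one-row data.frame from
#'   [split_into_fragments()]); `NULL` means the whole string.
#' @param model a [similarity_model()].
#' @param threshold acceptance threshold in (0, 1]; default 0.70.
#' @param method `"exhaustive"` or `"seeded"`.
#' @return data.frame of hits: `source_id`, `source_start` (residue),
#'   `score`, `query_start`, `query_end`, `entry`.
#' @export
search_fragments <- function(lib, s, span = NULL, model = default_model(),
                             threshold = 0.70,
                             method = c("exhaustive", "seeded")) {
  stopifnot(inherits(lib, "structure_library"))
  method <- match.arg(method)
  if (threshold <= 0) stop("threshold must be in (0, 1]")
  sc <- as_pfsc_chars(s)
  if (is.null(span)) span <- c(start = 1L, end = nchar(sc) + 4L)
  if (is.data.frame(span)) span <- unlist(span[1, c("start", "end")])
  span <- setNames(as.integer(span[1:2]), c("start", "end"))
  wspan <- span_to_windows(span)
  q <- substr(sc, wspan[1], wspan[2])
  qlen <- nchar(q)
  hits <- list()
  for (e in seq_along(lib$entries)) {
    entry <- lib$entries[[e]]
    n <- nchar(entry$string)
    if (n < qlen) next
    offsets <- seq_len(n - qlen + 1L)
    if (method == "seeded") {
      k <- lib$k
      cand <- integer(0)
      if (qlen >= k) {
        for (qo in seq_len(qlen - k + 1L)) {
          g <- substr(q, qo, qo + k - 1L)
          post <- lib$index[[g]]
          if (!is.null(post)) {
            mine <- post[post[, "entry"] == e, , drop = FALSE]
            cand <- c(cand, mine[, "offset"] - qo + 1L)
          }
        }
      }
      offsets <- sort(unique(cand[cand >= 1 & cand <= n - qlen + 1L]))
      if (length(offsets) == 0) next
    }
    for (off in offsets) {
      sub <- substr(entry$string, off, off + qlen - 1L)
      sco <- pfsa_score(q, sub, model)$score
      if (sco > threshold)
        hits[[length(hits) + 1L]] <-
          data.frame(source_id = entry$source_id, source_start = off,
                     score = sco, query_start = span[[1]],
                     query_end = span[[2]], entry = e,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(source_id = character(0), source_start = integer(0),
                      score = numeric(0), query_start = integer(0),
                      query_end = integer(0), entry = integer(0)))
  out <- do.call(rbind, hits)
  out <- out[order(-out$score, out$source_id, out$source_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# cut the Ca fragment (residues) backing a hit out of its library entry
hit_fragment <- function(lib, hit) {
  entry <- lib$entries[[hit$entry]]
  len <- hit$query_end - hit$query_start + 1L
  idx <- seq(hit$source_start, hit$source_start + len - 1L)
  res <- entry$trace$residues[idx, , drop = FALSE]
  res$seq_index <- seq_len(nrow(res))
  ca_trace(res, chain_id = entry$trace$chain_id,
           source_id = sprintf("%s[%d-%d]", entry$source_id, idx[1],
                               idx[length(idx)]))
}

#' Splice per-span fragments into one Cα-trace model
#'
#' Fragments are chained left to right; each incoming fragment is rigidly
#' superposed onto the growing model over the residues the two spans
#' share (least squares on the overlap Cα, at least 3 residues), then its
#' non-overlapping residues are appended. The least-squares residual of
#' every junction is recorded.
#'
#' @param fragments list of [ca_trace()], one per span, in span order.
#' @param spans data.frame from [split_into_fragments()] (same order).
#' @param sequence optional query sequence; when given, residue identities
#'   of the output are taken from it rather than from the source fragments.
#' @return A [ca_trace()] covering the full residue range, with attribute
#'   `junction_rmsd` (numeric, one value per junction).
#' @export
assemble_model <- function(fragments, spans, sequence = NULL) {
  stopifnot(length(fragments) == nrow(spans), length(fragments) >= 1)
  n_res <- spans$end[nrow(spans)]
  coords <- matrix(NA_real_, n_res, 3)
  sp1 <- c(spans$start[1], spans$end[1])
  coords[sp1[1]:sp1[2], ] <- trace_xyz(fragments[[1]])
  aa <- rep("A", n_res)
  aa[sp1[1]:sp1[2]] <- fragments[[1]]$residues$aa1
  junction_rmsd <- numeric(0)
  if (length(fragments) > 1) for (f in 2:length(fragments)) {
    span <- c(spans$start[f], spans$end[f])
    frag <- trace_xyz(fragments[[f]])
    done <- max(spans$end[seq_len(f - 1)])
    ov <- seq(span[1], min(span[2], done))
    if (length(ov) < 3)
      stop("overlap of ", length(ov),
           " residue(s) at junction ", f - 1, " is too small to superpose")
    moved <- superpose_onto(coords, frag,
                            fix_idx = ov, mob_idx = ov - span[1] + 1L)
    junction_rmsd <- c(junction_rmsd,
                       rmsd_xyz(moved[ov - span[1] + 1L, , drop = FALSE],
                                coords[ov, , drop = FALSE]))
    new_idx <- seq(done + 1L, span[2])
    coords[new_idx, ] <- moved[new_idx - span[1] + 1L, , drop = FALSE]
    aa[new_idx] <- fragments[[f]]$residues$aa1[new_idx - span[1] + 1L]
  }
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    stopifnot(nchar(sequence) == n_res)
    aa <- strsplit(sequence, "")[[1]]
  }
  res <- data.frame(seq_index = seq_len(n_res),
                    resname = unname(ifelse(aa %in% names(AA1TO3),
                                            AA1TO3[aa], "UNK")),
                    aa1 = aa, x = coords[, 1], y = coords[, 2],
                    z = coords[, 3], has_ca = TRUE, stringsAsFactors = FALSE)
  out <- ca_trace(res, chain_id = "A", source_id = "assembled")
  attr(out, "junction_rmsd") <- junction_rmsd
  out
}

#' Build a Cα-trace ensemble from conformation strings
#'
#' For each conformation string: split into overlapping fragments, search
#' the library for each fragment's best conformational homolog (relaxing
#' the acceptance threshold stepwise when a span has no hit), and splice
#' the winning fragments into one model. Members whose spans find no hit
#' even at the relaxation floor fail with a recorded reason.
#'
#' @param lib an [index_library()] result.
#' @param conformations a [generate_variants()] result, or a named list of
#'   [pfsc_string()].
#' @param model a [similarity_model()].
#' @param target_len,overlap fragmentation parameters
#'   (see [split_into_fragments()]).
#' @param threshold starting PFSA acceptance threshold (default 0.70).
#' @param relax_step,relax_floor threshold relaxation ladder applied when a
#'   span has no hit (default 0.70 -> 0.60 -> 0.50).
#' @param sequence optional query sequence stamped onto the models.
#' @return Object of class `ca_ensemble`: list with `models` (named list of
#'   [ca_trace()]), `provenance` (data.frame: member, span, source, score,
#'   junction RMSD) and `failures` (named character of reasons).
#' @export
build_ensemble <- function(lib, conformations, model = default_model(),
                           target_len = 45L, overlap = 4L, threshold = 0.70,
                           relax_step = 0.10, relax_floor = 0.50,
                           sequence = NULL) {
  if (inherits(conformations, "conformation_set"))
    conformations <- conformation_strings(conformations)
  stopifnot(length(conformations) >= 1)
  models <- list()
  failures <- character(0)
  prov <- list()
  for (nm in names(conformations)) {
    s <- conformations[[nm]]
    spans <- split_into_fragments(s, target_len, overlap)
    frags <- vector("list", nrow(spans))
    hit_rows <- vector("list", nrow(spans))
    failed <- NULL
    for (f in seq_len(nrow(spans))) {
      thr <- threshold
      hits <- search_fragments(lib, s, spans[f, ], model, thr)
      while (nrow(hits) == 0 && thr - relax_step >= relax_floor - 1e-9) {
        thr <- thr - relax_step
        hits <- search_fragments(lib, s, spans[f, ], model, thr)
      }
      if (nrow(hits) == 0) {
        failed <- sprintf("span %d-%d: no hit above %.2f",
                          spans$start[f], spans$end[f], relax_floor)
        break
      }
      hit_rows[[f]] <- cbind(member = nm, hits[1, , drop = FALSE],
                             threshold_used = thr)
      frags[[f]] <- hit_fragment(lib, hits[1, ])
    }
    if (!is.null(failed)) {
      failures[nm] <- failed
      next
    }
    tr <- assemble_model(frags, spans, sequence)
    tr$source_id <- nm
    models[[nm]] <- tr
    jr <- attr(tr, "junction_rmsd")
    pv <- do.call(rbind, hit_rows)
    pv$junction_rmsd <- c(NA_real_, jr)[seq_len(nrow(pv))]
    prov[[nm]] <- pv
  }
  if (length(models) == 0)
    stop("every ensemble member failed:\n  ",
         paste(names(failures), failures, sep = ": ", collapse = "\n  "))
  structure(list(models = models,
                 provenance = do.call(rbind, c(prov, list(make.row.names = FALSE))),
                 failures = failures),
            class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat(sprintf("Ca ensemble: %d model(s), %d failed member(s)\n",
              length(x$models), length(x$failures)))
  invisible(x)
}

#' Validate an ensemble against a given conformation
#'
#' An adequate ensemble should contain at least one member whose
#' conformation aligns with the given structure's conformation at PFSA
#' score 1.00.
#'
#' @param strings list of ensemble member [pfsc_string()] (or characters).
#' @param given the reference conformation string.
#' @param model a [similarity_model()].
#' @return List with `max_score` and `argmax` (name or index of the best
#'   member).
#' @export
validate_ensemble <- function(strings, given, model = default_model()) {
  stopifnot(length(strings) >= 1)
  scores <- vapply(strings, function(s) pfsa_score(s, given, model)$score,
                   numeric(1))
  best <- which.max(scores)
  nm <- names(strings)[best]
  list(max_score = scores[[best]],
       argmax = if (!is.null(nm) && nzchar(nm)) nm else best)
}
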