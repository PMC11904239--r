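# PFSC encoder: Ca trace -> folding shape string over the 27-symbol alphabet.

#' Construct a PFSC string object
#'
#' @param codes character scalar over the PFSC alphabet.
#' @param source_id provenance label.
#' @param offset 1-based residue ordinal of the first window's first residue.
#' @return Object of class `pfsc_string`.
#' @export
pfsc_string <- function(codes, source_id = "", offset = 1L) {
  stopifnot(is.character(codes), length(codes) == 1L, nchar(codes) >= 1)
  structure(list(codes = codes, source_id = source_id,
                 offset = as.integer(offset)),
            class = "pfsc_string")
}

#' @export
print.pfsc_string <- function(x, ...) {
  cat(sprintf("PFSC string [%s] (%d windows, offset %d)\n%s\n",
              x$source_id, nchar(x$codes), x$offset, x$codes))
  invisible(x)
}

#' @exportS3Method base::nchar
nchar.pfsc_string <- function(x, ...) nchar(x$codes)

#' @export
as.character.pfsc_string <- function(x, ...) x$codes

# accept either a pfsc_string or a bare character scalar
as_pfsc_chars <- function(s) {
  if (inherits(s, "pfsc_string")) s$codes
  else if (is.character(s) && length(s) == 1L) s
  else stop("expected a pfsc_string or a single character string")
}

#' Geometry descriptors of one five-residue window
#'
#' Window `i` covers residues `i..i+4`. The descriptors are the Cα
#' pseudo-torsion over residues `i..i+3` (`tau1`), the pseudo-torsion over
#' `i+1..i+4` (`tau2`), both IUPAC-signed in degrees, and the bend angle
#' `theta` at Cα(i+2) over Cα(i), Cα(i+2), Cα(i+4) in \[0, 180\]. Collinear
#' point sets yield torsion 0 by convention. A window containing a missing
#' Cα or an internal chain break is undefined and returns `NA` descriptors
#' with `defined = FALSE`.
#'
#' @param trace a [ca_trace()].
#' @param i window start ordinal (`1 <= i <= length - 4`).
#' @return List with `tau1`, `tau2`, `theta`, `defined`.
#' @export
compute_window_descriptors <- function(trace, i) {
  stopifnot(inherits(trace, "ca_trace"))
  n <- length(trace)
  if (i < 1 || i > n - 4) stop("window start out of range: ", i)
  if (!all(trace$residues$has_ca[i:(i + 4)]) || any(trace$breaks[i:(i + 3)]))
    return(list(tau1 = NA_real_, tau2 = NA_real_, theta = NA_real_,
                defined = FALSE))
  xyz <- trace_xyz(trace)
  list(tau1 = torsion_angle(xyz[i, ], xyz[i + 1, ], xyz[i + 2, ], xyz[i + 3, ]),
       tau2 = torsion_angle(xyz[i + 1, ], xyz[i + 2, ], xyz[i + 3, ], xyz[i + 4, ]),
       theta = bend_angle(xyz[i, ], xyz[i + 2, ], xyz[i + 4, ]),
       defined = TRUE)
}

#' Encode a Cα trace as a PFSC string
#'
#' Slides a five-residue window along the chain, one residue per step, and
#' quantizes each window's descriptor triple into one of the 27 folding
#' shape codes; undefined windows (missing Cα, internal chain break) emit
#' `$`. A chain of N residues yields a string of N - 4 symbols.
#'
#' @param trace a [ca_trace()] of length >= 5.
#' @param alphabet a [pfsc_alphabet()].
#' @return A [pfsc_string()].
#' @examples
#' tr <- make_ideal_backbone(list(c("helix", 20)))
#' as.character(encode_chain(tr))  # "AAAAAAAAAAAAAAAA"
#' @export
encode_chain <- function(trace, alphabet = default_alphabet()) {
  stopifnot(inherits(trace, "ca_trace"), inherits(alphabet, "pfsc_alphabet"))
  n <- length(trace)
  if (n < 5) stop("chain must have at least 5 residues to encode")
  out <- character(n - 4)
  for (i in seq_len(n - 4)) {
    d <- compute_window_descriptors(trace, i)
    out[i] <- if (!d$defined) "$"
      else cell_code(quantize_window(d$tau1, d$tau2, d$theta, alphabet), alphabet)
  }
  pfsc_string(paste(out, collapse = ""), source_id = trace$source_id)
}

#' Write PFSC records to a `.pfsc` file
#'
#' Plain-text format: one `>name` header line followed by the string, per
#' record (FASTA-like).
#'
#' @param strings a [pfsc_string()] or list of them (names taken from
#'   `source_id` when the list is unnamed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pfsc <- function(strings, path) {
  if (inherits(strings, "pfsc_string")) strings <- list(strings)
  nms <- names(strings)
  if (is.null(nms))
    nms <- vapply(strings, function(s) if (nzchar(s$source_id)) s$source_id else "pfsc",
                  character(1))
  lines <- unlist(Map(function(nm, s) c(paste0(">", nm), as_pfsc_chars(s)),
                      nms, strings), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read PFSC records from a `.pfsc` file
#' @param path input file written by [write_pfsc()].
#' @return Named list of [pfsc_string()].
#' @export
read_pfsc <- function(path) {
  if (!file.exists(path)) stop("cannot read pfsc file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("malformed pfsc file (no headers): ", path)
  out <- list()
  for (k in seq_along(hdr)) {
    from <- hdr[k] + 1
    to <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    nm <- sub("^>", "", lines[hdr[k]])
    out[[nm]] <- pfsc_string(paste(lines[from:to], collapse = ""), source_id = nm)
  }
  out
}
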