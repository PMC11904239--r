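# Structure and sequence I/O: PDB reading via bio3d, Ca-trace extraction
# with altloc resolution and chain-break detection, Ca-model writing, FASTA.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))

#' Construct a Cα trace
#'
#' A `ca_trace` holds the ordered Cα records of one chain: residue ordinals
#' (1-based by position in the chain), residue names, one-letter codes
#' (`X` for non-standard), coordinates in Angstrom and a completeness flag.
#' Chain breaks are inferred between consecutive residues whose Cα-Cα
#' distance falls outside \[2.0, 4.5\] Angstrom.
#'
#' @param residues data.frame with columns `seq_index`, `resname`, `aa1`,
#'   `x`, `y`, `z`, `has_ca`. Coordinates may be `NA` where `has_ca` is
#'   `FALSE`.
#' @param chain_id chain identifier.
#' @param source_id free-text provenance label (file + chain).
#' @return Object of class `ca_trace`; element `breaks` is a logical vector
#'   of length `n - 1` flagging a break between residues `i` and `i + 1`.
#' @export
ca_trace <- function(residues, chain_id = "A", source_id = chain_id) {
  need <- c("seq_index", "resname", "aa1", "x", "y", "z", "has_ca")
  stopifnot(is.data.frame(residues), all(need %in% names(residues)))
  n <- nrow(residues)
  if (n < 1) stop("a ca_trace needs at least one residue")
  if (any(diff(residues$seq_index) <= 0))
    stop("seq_index must be strictly increasing within a chain")
  if (any(residues$has_ca & (is.na(residues$x) | is.na(residues$y) | is.na(residues$z))))
    stop("has_ca is TRUE but coordinates are absent")
  residues$has_ca <- residues$has_ca & !is.na(residues$x)
  breaks <- logical(max(n - 1, 0))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (residues$has_ca[i] && residues$has_ca[i + 1]) {
        d <- sqrt(sum((unlist(residues[i, c("x", "y", "z")]) -
                       unlist(residues[i + 1, c("x", "y", "z")]))^2))
        breaks[i] <- d < 2.0 || d > 4.5
      }
    }
  }
  structure(list(chain_id = chain_id, source_id = source_id,
                 residues = residues, breaks = breaks),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  n <- nrow(x$residues)
  cat(sprintf("Ca trace %s (chain %s): %d residues, %d with Ca, %d chain break(s)\n",
              x$source_id, x$chain_id, n, sum(x$residues$has_ca), sum(x$breaks)))
  invisible(x)
}

#' @export
length.ca_trace <- function(x) nrow(x$residues)

# n x 3 coordinate matrix (NA rows where Ca absent)
trace_xyz <- function(trace) {
  as.matrix(trace$residues[, c("x", "y", "z")])
}

# one-letter sequence of a trace
trace_sequence <- function(trace) paste(trace$residues$aa1, collapse = "")

#' Read a structure file into per-chain Cα traces
#'
#' Parses PDB ATOM records (via [bio3d::read.pdb()]), selects the requested
#' model of multi-model (e.g. NMR) files, resolves alternate locations by
#' highest occupancy then lexicographic altloc identifier, maps non-standard
#' residues to `X`, and returns one [ca_trace()] per chain. Residues are
#' renumbered 1-based by ordinal position; author numbering is kept in the
#' `auth_resno` column as metadata.
#'
#' @param path PDB file.
#' @param model_index 1-based model to extract from multi-model files.
#' @return List of `ca_trace`, one per chain, in file order.
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not a readable PDB file: ", path, " (", conditionMessage(e), ")"))
  atoms <- pdb$atom
  if (is.null(atoms) || nrow(atoms) == 0) stop("no ATOM records in ", path)
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1 || model_index > n_models)
    stop("model ", model_index, " not present (file has ", n_models, " model(s))")
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else as.vector(pdb$xyz)

  ca <- atoms$elety == "CA" & atoms$type %in% c("ATOM", "HETATM")
  ca <- ca & !atoms$resid %in% c("HOH", "WAT")
  idx <- which(ca)
  if (length(idx) == 0) stop("no Ca atoms in ", path)
  df <- data.frame(row = idx,
                   chain = atoms$chain[idx],
                   resno = atoms$resno[idx],
                   insert = ifelse(is.na(atoms$insert[idx]), "", atoms$insert[idx]),
                   resid = atoms$resid[idx],
                   alt = ifelse(is.na(atoms$alt[idx]), "", atoms$alt[idx]),
                   occ = ifelse(is.na(atoms$o[idx]), 1, atoms$o[idx]),
                   stringsAsFactors = FALSE)
  df$chain[is.na(df$chain)] <- "A"
  # altloc resolution: highest occupancy, then lexicographic altloc id
  keykey <- paste(df$chain, df$resno, df$insert)
  df <- df[order(keykey, -df$occ, df$alt), ]
  df <- df[!duplicated(paste(df$chain, df$resno, df$insert)), ]
  df <- df[order(df$row), ]

  out <- list()
  for (ch in unique(df$chain)) {
    sub <- df[df$chain == ch, , drop = FALSE]
    xi <- 3 * (sub$row - 1) + 1
    res <- data.frame(seq_index = seq_len(nrow(sub)),
                      resname = sub$resid,
                      aa1 = unname(ifelse(sub$resid %in% names(AA3TO1),
                                          AA3TO1[sub$resid], "X")),
                      x = xyz[xi], y = xyz[xi + 1], z = xyz[xi + 2],
                      has_ca = !is.na(xyz[xi]),
                      auth_resno = sub$resno,
                      stringsAsFactors = FALSE)
    out[[ch]] <- ca_trace(res, chain_id = ch,
                          source_id = paste0(basename(path), ":", ch))
  }
  out
}

#' Write a Cα trace as a PDB model
#'
#' Emits standard ATOM records, one CA atom per residue, 1-based numbering,
#' occupancy 1.00, element C, followed by TER and END.
#'
#' @param trace a [ca_trace()] whose residues all have Cα.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ca_model <- function(trace, path) {
  stopifnot(inherits(trace, "ca_trace"))
  res <- trace$residues
  if (nrow(res) == 0 || !all(res$has_ca))
    stop("all residues must have a Ca coordinate to write a model")
  lines <- ca_atom_lines(res, trace$chain_id)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# format ATOM records for one chain (serial offset for multi-model files)
ca_atom_lines <- function(res, chain_id, serial_from = 1L) {
  resname <- ifelse(res$aa1 %in% names(AA1TO3), AA1TO3[res$aa1], "UNK")
  keep <- !is.na(res$resname) & nchar(res$resname) == 3
  resname[keep] <- res$resname[keep]
  sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          seq_len(nrow(res)) + serial_from - 1L, resname,
          substr(chain_id, 1, 1), res$seq_index, res$x, res$y, res$z, 1, 0)
}

#' Write an ensemble of Cα traces as a multi-model PDB file
#'
#' @param traces list of [ca_trace()] (one MODEL record each).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traces, path) {
  stopifnot(length(traces) >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(traces)) {
    tr <- traces[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(ca_atom_lines(tr$residues, tr$chain_id), con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named list of upper-case sequence strings (characters outside the
#'   20-letter amino-acid alphabet mapped to `X`), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA: ", path))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[!ch %in% unname(AA3TO1)] <- "X"
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  as.list(seqs)
}
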