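# Synthetic backbone fixtures: ideal helix/strand/coil Ca traces built from
# canonical backbone torsions, and miniature on-disk structure corpora.

CANONICAL_TORSIONS <- list(
  helix  = c(phi = -57,  psi = -47),
  strand = c(phi = -139, psi = 135)
)

# seeded draw from broadly allowed (phi, psi) space for coil residues
draw_coil_torsions <- function(n) {
  region <- sample.int(3L, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  phi <- numeric(n); psi <- numeric(n)
  beta <- region == 1L; alpha <- region == 2L; left <- region == 3L
  phi[beta] <- runif(sum(beta), -160, -60);  psi[beta] <- runif(sum(beta), 90, 175)
  phi[alpha] <- runif(sum(alpha), -100, -45); psi[alpha] <- runif(sum(alpha), -60, -25)
  phi[left] <- runif(sum(left), 45, 65);      psi[left] <- runif(sum(left), 25, 60)
  cbind(phi = phi, psi = psi)
}

#' Specification of a synthetic backbone
#'
#' @param segments list of `c(kind, length)` pairs (or a 2-column data.frame)
#'   with `kind` in `helix`, `strand`, `coil` and integer residue lengths.
#' @param sequence one-letter sequence of the total length, or `NULL` to
#'   draw a seeded random sequence over the 20 standard amino acids.
#' @param noise_deg standard deviation (degrees) of Gaussian jitter added to
#'   every backbone torsion; `0` gives the ideal geometry.
#' @param seed integer seed controlling the sequence, coil torsions and
#'   jitter; fixed seed gives identical coordinates.
#' @return Object of class `backbone_spec`.
#' @export
backbone_spec <- function(segments, sequence = NULL, noise_deg = 0, seed = 1L) {
  if (is.data.frame(segments))
    segments <- lapply(seq_len(nrow(segments)),
                       function(i) c(segments[[1]][i], segments[[2]][i]))
  kinds <- vapply(segments, function(s) as.character(s[[1]]), character(1))
  lens <- vapply(segments, function(s) as.integer(s[[2]]), integer(1))
  if (!all(kinds %in% c("helix", "strand", "coil")))
    stop("segment kinds must be helix, strand or coil")
  if (any(lens < 1)) stop("segment lengths must be positive")
  if (sum(lens) < 5) stop("total length must be at least 5 for encodable output")
  if (noise_deg < 0) stop("noise_deg must be non-negative")
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != sum(lens))
      stop("sequence length must equal total segment length")
  }
  structure(list(kinds = kinds, lens = lens, sequence = sequence,
                 noise_deg = noise_deg, seed = as.integer(seed)),
            class = "backbone_spec")
}

#' Build an ideal (or jittered) synthetic Cα trace
#'
#' Segments use canonical textbook torsions (helix phi = -57, psi = -47;
#' strand phi = -139, psi = +135; coil drawn from allowed torsion regions),
#' realized through ideal backbone internal coordinates so that consecutive
#' Cα sit about 3.8 Angstrom apart. Deterministic for a fixed seed.
#'
#' @param spec a [backbone_spec()], or a list of segments accepted by it.
#' @param ... passed to [backbone_spec()] when `spec` is a segment list.
#' @return A [ca_trace()] of the total segment length.
#' @examples
#' tr <- make_ideal_backbone(list(c("helix", 20)))
#' length(tr)  # 20
#' @export
make_ideal_backbone <- function(spec, ...) {
  if (!inherits(spec, "backbone_spec")) spec <- backbone_spec(spec, ...)
  n <- sum(spec$lens)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  phi <- numeric(0); psi <- numeric(0)
  for (k in seq_along(spec$kinds)) {
    kind <- spec$kinds[k]; len <- spec$lens[k]
    if (kind == "coil") {
      tp <- draw_coil_torsions(len)
      phi <- c(phi, tp[, "phi"]); psi <- c(psi, tp[, "psi"])
    } else {
      phi <- c(phi, rep(CANONICAL_TORSIONS[[kind]]["phi"], len))
      psi <- c(psi, rep(CANONICAL_TORSIONS[[kind]]["psi"], len))
    }
  }
  if (spec$noise_deg > 0) {
    phi <- phi + rnorm(n, 0, spec$noise_deg)
    psi <- psi + rnorm(n, 0, spec$noise_deg)
  }
  seq1 <- spec$sequence
  if (is.null(seq1))
    seq1 <- paste(sample(unname(AA3TO1), n, replace = TRUE), collapse = "")
  ca <- build_ca_from_torsions(phi, psi)
  aa1 <- strsplit(seq1, "")[[1]]
  res <- data.frame(seq_index = seq_len(n),
                    resname = unname(ifelse(aa1 %in% names(AA1TO3),
                                            AA1TO3[aa1], "UNK")),
                    aa1 = aa1,
                    x = ca[, 1], y = ca[, 2], z = ca[, 3],
                    has_ca = TRUE, stringsAsFactors = FALSE)
  ca_trace(res, chain_id = "A",
           source_id = paste0("fixture-", paste(spec$kinds, spec$lens,
                                                sep = "", collapse = "-")))
}

# save/restore .Random.seed so fixture generation does not disturb the
# caller's RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# seeded random composite spec used by the fixture library; sequences are
# drawn from a reduced 6-letter alphabet so that pentamers recur across
# chains in different geometric contexts (the corpus is meant to exercise
# multi-variant fold columns, which a 20-letter random corpus of this size
# would almost never produce)
FIXTURE_SEQ_ALPHABET <- c("A", "E", "G", "K", "L", "V")

random_backbone_spec <- function(seed) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  n_seg <- sample(2:5, 1)
  kinds <- sample(c("helix", "strand", "coil"), n_seg, replace = TRUE)
  lens <- sample(6:24, n_seg, replace = TRUE)
  total <- sum(lens)
  if (total < 30) lens[1] <- lens[1] + (30 - total)
  if (sum(lens) > 120) lens <- pmax(6L, floor(lens * 120 / sum(lens)))
  seq1 <- paste(sample(FIXTURE_SEQ_ALPHABET, sum(lens), replace = TRUE),
                collapse = "")
  backbone_spec(Map(c, kinds, lens), sequence = seq1, noise_deg = 2,
                seed = seed + 1000L)
}

#' Write a miniature synthetic structure corpus
#'
#' Generates `n_chains` mixed-segment chains (total lengths 30-120), writes
#' each as a Cα-only PDB file plus a tab-separated manifest. Deterministic
#' for a fixed seed.
#'
#' @param n_chains number of chains to generate (>= 1).
#' @param seed integer seed.
#' @param out_dir output directory (created if absent).
#' @return Character vector of the PDB file paths (the manifest is written
#'   alongside as `manifest.tsv`).
#' @export
make_fixture_library <- function(n_chains, seed = 1L, out_dir) {
  if (n_chains < 1) stop("n_chains must be at least 1")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(n_chains)
  man <- data.frame(file = character(n_chains), n_residues = integer(n_chains),
                    segments = character(n_chains), stringsAsFactors = FALSE)
  for (i in seq_len(n_chains)) {
    spec <- random_backbone_spec(seed * 10000L + i)
    tr <- make_ideal_backbone(spec)
    f <- file.path(out_dir, sprintf("fixture_%03d.pdb", i))
    write_ca_model(tr, f)
    paths[i] <- f
    man$file[i] <- basename(f)
    man$n_residues[i] <- length(tr)
    man$segments[i] <- paste(spec$kinds, spec$lens, sep = ":", collapse = ",")
  }
  write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
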