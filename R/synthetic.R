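# Synthetic fixture generator.
#
# Desk-scale stand-ins for the real inputs: small multi-chain complexes
# with known anchor-atom contact maps, per-chain a3m alignments, and (via
# the mock backend) network outputs consistent with a chosen ground truth.
# Chains are ideal alpha-helices on parallel axes: geometry is simple,
# fully deterministic given the seed, and produces a realistic band of
# inter-chain contacts (tens of pairs per interface at the 8 A cutoff,
# the order observed at real dimer interfaces) between adjacent chains.

#' Generate a toy multi-chain complex with a known contact map
#'
#' Chain k is an ideal alpha-helix (2.3 A radius, 1.5 A rise, 100 degrees
#' per residue) along the z axis, with its axis placed at
#' x = (k-1) * `spacing`. Anchors (C-beta) point radially outward;
#' glycines use the C-alpha anchor. Sequences are random with roughly 8%
#' glycine. Adjacent chains form an interface; the true contact set is
#' whatever an exhaustive anchor-distance scan reports.
#'
#' @param lengths Integer vector of chain lengths (default `c(60, 55)`).
#' @param spacing Axis-to-axis distance in Angstrom (default 9.5, close
#'   helix packing).
#' @param seed Integer seed (sequences and helix phases).
#' @param chain_ids Chain identifiers (default `LETTERS`).
#' @return A [new_complex()] object.
#' @export
toy_complex <- function(lengths = c(60L, 55L), spacing = 9.5, seed = 1L,
                        chain_ids = LETTERS[seq_along(lengths)]) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 3L))
  withr::with_seed(as.integer(seed), {
    chains <- lapply(seq_along(lengths), function(k) {
      L <- lengths[k]
      aa <- sample(AA_LETTERS[AA_LETTERS != "X"], L, replace = TRUE,
                   prob = ifelse(AA_LETTERS[AA_LETTERS != "X"] == "G",
                                 0.08, 0.92 / 19))
      phase <- stats::runif(1L, 0, 2 * pi)
      i <- seq_len(L)
      theta <- phase + i * 100 * pi / 180
      axis_x <- (k - 1) * spacing
      ca <- cbind(axis_x + 2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
      radial <- cbind(cos(theta), sin(theta), 0)
      cb <- ca + 1.53 * radial
      new_chain_record(chain_ids[k], paste(aa, collapse = ""),
                       residue_numbers = i, ca = ca, cb = cb)
    })
    new_complex(chains)
  })
}

#' Fabricate an a3m alignment for a query sequence
#'
#' Rows are point-mutated copies of the query with occasional '-' deletions
#' and lowercase insertions, following the a3m convention.
#'
#' @param query Query sequence (row 1 of the output).
#' @param n_rows Total rows including the query (default 5).
#' @param mutation_rate Per-position substitution probability (default 0.1).
#' @param deletion_rate Per-position '-' probability (default 0.05).
#' @param insertion_rate Per-position lowercase-insertion probability
#'   (default 0.03).
#' @param seed Integer seed.
#' @return Character vector of a3m lines (headers + rows).
#' @export
toy_a3m <- function(query, n_rows = 5L, mutation_rate = 0.1,
                    deletion_rate = 0.05, insertion_rate = 0.03, seed = 1L) {
  assert_aa_string(query)
  aa20 <- AA_LETTERS[AA_LETTERS != "X"]
  withr::with_seed(as.integer(seed), {
    lines <- c(">query", query)
    for (r in seq_len(max(0L, n_rows - 1L))) {
      ch <- seq_chars(query)
      mut <- stats::runif(length(ch)) < mutation_rate
      ch[mut] <- sample(aa20, sum(mut), replace = TRUE)
      del <- stats::runif(length(ch)) < deletion_rate
      ch[del] <- "-"
      ins <- stats::runif(length(ch)) < insertion_rate
      ch[ins] <- paste0(tolower(sample(aa20, sum(ins), replace = TRUE)),
                        ch[ins])
      lines <- c(lines, sprintf(">seq%03d", r), paste(ch, collapse = ""))
    }
    lines
  })
}

#' Write a complete synthetic input set to a directory
#'
#' Produces `target.fasta` (one record per chain), `truth.pdb` (the ground
#' truth), `template.pdb` (the truth, optionally rigid-body perturbed), and
#' one `chain_<k>.a3m` per chain under `msas/`. All files are plain text.
#'
#' @param dir Output directory (created if needed).
#' @param lengths Chain lengths (default `c(60, 55)`).
#' @param seed Integer seed.
#' @param rotrans Optional `c(max_angle, max_shift)` applied to the
#'   template (e.g. `c(30, 5)`); NULL leaves the template unperturbed.
#' @param msa_rows Rows per fabricated chain MSA (default 5).
#' @return Invisibly, a list of the generated paths and the truth complex.
#' @export
write_fixture_set <- function(dir, lengths = c(60L, 55L), seed = 1L,
                              rotrans = NULL, msa_rows = 5L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "msas"), showWarnings = FALSE)
  truth <- toy_complex(lengths = lengths, seed = seed)
  seqs <- vapply(truth$chains, `[[`, character(1), "sequence")
  fasta <- file.path(dir, "target.fasta")
  writeLines(as.vector(rbind(paste0(">chain_", seq_along(seqs)), seqs)),
             fasta)
  truth_path <- file.path(dir, "truth.pdb")
  write_structure(truth, truth_path, "pdb")
  template <- truth
  if (!is.null(rotrans))
    template <- perturb_template(truth, max_angle = rotrans[1],
                                 max_shift = rotrans[2], seed = seed + 1L)
  template_path <- file.path(dir, "template.pdb")
  write_structure(template, template_path, "pdb")
  msa_paths <- character(0)
  for (k in seq_along(seqs)) {
    p <- file.path(dir, "msas", sprintf("chain_%d.a3m", k))
    writeLines(toy_a3m(seqs[k], n_rows = msa_rows, seed = seed + 10L + k), p)
    msa_paths <- c(msa_paths, p)
  }
  invisible(list(fasta = fasta, truth = truth_path, template = template_path,
                 msas = msa_paths, truth_complex = truth))
}
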