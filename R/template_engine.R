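# Template engine: greedy assignment of targets to template chains, merging
# of all target chains into the gap-spaced pseudo-chain, projection of
# template coordinates onto merged positions (keeping inter-chain geometry
# — the unmasking), and rigid-body template perturbation for benchmarking.

#' Greedy assignment of target sequences to template chains
#'
#' Every (target, template chain) pair is scored by [sequence_identity()];
#' pairs are then accepted greedily in descending identity order, skipping
#' pairs whose target or chain is already used. Ties are broken by lower
#' target index, then lexicographic chain ID.
#'
#' @param targets Character vector of target sequences (FASTA order).
#' @param template A [new_complex()] template.
#' @return An object of class `gs_assignment`: data.frame `pairs`
#'   (`target_index`, `template_chain_id`, `identity`) plus
#'   `unmatched_targets` and `unmatched_template_chains`.
#' @export
assign_chains <- function(targets, template) {
  stopifnot(inherits(template, "gs_complex"))
  if (!length(targets)) stop("no target sequences", call. = FALSE)
  ids <- chain_ids(template)
  idm <- matrix(0, length(targets), length(ids),
                dimnames = list(NULL, ids))
  for (t in seq_along(targets))
    for (c in seq_along(ids))
      idm[t, c] <- sequence_identity(targets[t],
                                     template$chains[[c]]$sequence)
  greedy_assign(idm, template_chain_ids = ids)
}

#' Greedy assignment from a precomputed identity matrix
#'
#' The greedy rule of [assign_chains()], exposed separately so it can be
#' verified against an independent oracle on enumerable matrices.
#'
#' @param identity_matrix Numeric matrix, targets in rows, template chains
#'   in columns; values in \[0, 1\].
#' @param template_chain_ids Column (chain) identifiers.
#' @return A `gs_assignment` object.
#' @export
greedy_assign <- function(identity_matrix,
                          template_chain_ids = colnames(identity_matrix)) {
  m <- as.matrix(identity_matrix)
  if (any(m < 0 | m > 1)) stop("identities must be in [0, 1]", call. = FALSE)
  nt <- nrow(m); nc <- ncol(m)
  ids <- as.character(template_chain_ids)
  # order all pairs: identity desc, target index asc, chain ID lexicographic
  grid <- expand.grid(t = seq_len(nt), c = seq_len(nc))
  ord <- order(-m[cbind(grid$t, grid$c)], grid$t, ids[grid$c])
  grid <- grid[ord, ]
  used_t <- logical(nt); used_c <- logical(nc)
  rows <- list()
  for (k in seq_len(nrow(grid))) {
    t <- grid$t[k]; c <- grid$c[k]
    if (used_t[t] || used_c[c]) next
    used_t[t] <- TRUE; used_c[c] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      target_index = t, template_chain_id = ids[c],
      identity = m[t, c], stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_index = integer(0), template_chain_id = character(0),
               identity = numeric(0))
  pairs <- pairs[order(pairs$target_index), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_targets = which(!used_t),
                 unmatched_template_chains = ids[!used_c]),
            class = "gs_assignment")
}

#' Merge target chains into a single gap-spaced pseudo-chain
#'
#' The merged sequence is the plain concatenation of the chains (no physical
#' gap residues); chain boundaries are encoded purely as jumps of
#' `gap_size + 1` in the per-position residue index, which is what makes a
#' monomer-trained network treat the chains as one protein with breaks.
#'
#' @param targets Character vector of target chain sequences.
#' @param gap_size Residue-index gap inserted between consecutive chains
#'   (default 200).
#' @return An object of class `gs_merged` with fields `sequence`,
#'   `residue_index`, `chain_of_position`, `chain_lengths`, `gap_size`.
#' @export
merge_chains <- function(targets, gap_size = 200L) {
  if (!length(targets)) stop("no target sequences", call. = FALSE)
  gap_size <- as.integer(gap_size)
  if (gap_size < 1L) stop("gap_size must be >= 1", call. = FALSE)
  for (s in targets) assert_aa_string(s)
  lens <- nchar(targets)
  residue_index <- integer(0)
  chain_of_position <- integer(0)
  start <- 1L
  for (k in seq_along(targets)) {
    residue_index <- c(residue_index, seq.int(start, start + lens[k] - 1L))
    chain_of_position <- c(chain_of_position, rep.int(k, lens[k]))
    start <- start + lens[k] + gap_size
  }
  structure(list(sequence = paste(targets, collapse = ""),
                 residue_index = residue_index,
                 chain_of_position = chain_of_position,
                 chain_lengths = as.integer(lens),
                 gap_size = gap_size),
            class = "gs_merged")
}

merged_length <- function(merged) sum(merged$chain_lengths)
merged_chain_positions <- function(merged, k)
  which(merged$chain_of_position == k)

#' Project template coordinates onto merged positions
#'
#' For each assigned target chain, the target/template global alignment maps
#' template residue anchor coordinates onto merged positions. Coordinates
#' from different template chains keep their original relative geometry, so
#' inter-chain contacts present in the template are carried into the
#' features (the unmasking). Unassigned target chains get an all-false mask.
#'
#' @param merged A [merge_chains()] result built from the same targets.
#' @param assignment A [assign_chains()] result.
#' @param template The template [new_complex()].
#' @return An object of class `gs_template_features`: `ca`, `cb` (L x 3,
#'   NA where absent), `mask` (logical L), `template_sequence` (per-position
#'   one-letter code or `"-"`).
#' @export
build_template_features <- function(merged, assignment, template) {
  stopifnot(inherits(merged, "gs_merged"),
            inherits(assignment, "gs_assignment"),
            inherits(template, "gs_complex"))
  L <- merged_length(merged)
  ca <- matrix(NA_real_, L, 3L)
  cb <- matrix(NA_real_, L, 3L)
  mask <- logical(L)
  tseq <- rep("-", L)
  targets <- split_sequence(merged)
  for (r in seq_len(nrow(assignment$pairs))) {
    t_idx <- assignment$pairs$target_index[r]
    cid <- assignment$pairs$template_chain_id[r]
    if (!cid %in% chain_ids(template))
      stop("assignment references unknown template chain ", cid,
           call. = FALSE)
    tch <- template$chains[[cid]]
    aln <- align_global(targets[t_idx], tch$sequence)
    pos <- merged_chain_positions(merged, t_idx)
    for (p in seq_len(nrow(aln$pairs))) {
      it <- aln$pairs[p, 1L]   # position in target chain
      jt <- aln$pairs[p, 2L]   # residue in template chain
      mp <- pos[it]
      ca[mp, ] <- tch$ca[jt, ]
      cb[mp, ] <- tch$cb[jt, ]
      mask[mp] <- TRUE
      tseq[mp] <- substr(tch$sequence, jt, jt)
    }
  }
  structure(list(ca = ca, cb = cb, mask = mask, template_sequence = tseq),
            class = "gs_template_features")
}

# Per-chain sequences of a merged target.
split_sequence <- function(merged) {
  ends <- cumsum(merged$chain_lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  vapply(seq_along(ends),
         function(k) substr(merged$sequence, starts[k], ends[k]),
         character(1))
}

#' Rigid-body template perturbation
#'
#' Emulates a low-accuracy template (e.g. chains rigid-body fitted into a
#' cryo-EM map): each chain is independently rotated about its own centre
#' by an angle drawn uniformly from \[0, `max_angle`\] degrees about an axis
#' uniform on the sphere, then translated along a direction uniform on the
#' sphere by a magnitude uniform in \[0, `max_shift`\] Angstrom.
#' Intra-chain geometry is preserved exactly; the draw is deterministic
#' given `seed`. The sampled transforms are attached as attribute
#' `"transforms"`.
#'
#' @param template A [new_complex()] object.
#' @param max_angle Maximum rotation angle in degrees (default 30).
#' @param max_shift Maximum translation in Angstrom (default 5).
#' @param seed Integer seed.
#' @return The perturbed complex.
#' @export
perturb_template <- function(template, max_angle = 30, max_shift = 5,
                             seed = 1L) {
  stopifnot(inherits(template, "gs_complex"))
  if (max_angle < 0 || max_shift < 0)
    stop("max_angle and max_shift must be non-negative", call. = FALSE)
  transforms <- list()
  chains <- withr::with_seed(as.integer(seed), {
    lapply(template$chains, function(ch) {
      axis <- runif_unit_vector()
      angle <- stats::runif(1L, 0, max_angle)
      dir <- runif_unit_vector()
      mag <- stats::runif(1L, 0, max_shift)
      R <- rotation_matrix(axis, angle)
      shift <- dir * mag
      rot <- function(xyz) sweep(tcrossprod(sweep(xyz, 2L, ch$com), R),
                                 2L, ch$com + shift, "+")
      transforms[[ch$chain_id]] <<- list(axis = axis, angle_deg = angle,
                                         shift = shift, shift_mag = mag)
      new_chain_record(ch$chain_id, ch$sequence, ch$residue_numbers,
                       ca = rot(ch$ca), cb = rot(ch$cb))
    })
  })
  out <- new_complex(chains, source_format = template$source_format)
  attr(out, "transforms") <- transforms
  attr(out, "perturbation") <- list(max_angle = max_angle,
                                    max_shift = max_shift,
                                    seed = as.integer(seed),
                                    angle_sampling = "axis uniform on sphere, angle ~ U(0, max)",
                                    shift_sampling = "direction uniform on sphere, magnitude ~ U(0, max)")
  out
}

#' @export
print.gs_assignment <- function(x, ...) {
  cat("<gs_assignment>\n")
  if (nrow(x$pairs)) print(x$pairs) else cat("  (no pairs)\n")
  if (length(x$unmatched_targets))
    cat("  unmatched targets:", paste(x$unmatched_targets, collapse = ","),
        "\n")
  if (length(x$unmatched_template_chains))
    cat("  unmatched template chains:",
        paste(x$unmatched_template_chains, collapse = ","), "\n")
  invisible(x)
}
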