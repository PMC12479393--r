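# Distogram -> contact extraction and contact-set scoring.
#
# Contact definition: two residues are in contact when their anchor atoms
# (C-beta; C-alpha for glycine) are closer than 8 Angstrom. Predicted
# contacts are inter-chain pairs whose distogram mass below the cutoff
# exceeds a probability threshold (0.8 by default). The 8 A rule is a
# proximity criterion, not evidence of a physical interaction.

#' Per-pair contact probability from a distogram
#'
#' Integrates each pair's bin masses below `cutoff`: bins entirely below
#' the cutoff count fully and the straddling bin contributes the linear
#' fraction of its width below the cutoff (`mode = "linear"`), or nothing
#' (`mode = "floor"`). Bin edges are taken from the distogram, never
#' assumed.
#'
#' @param distogram A [new_distogram()] object.
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @param mode Straddling-bin rule: `"linear"` (default) or `"floor"`.
#' @return A symmetric L x L matrix of probabilities in \[0, 1\].
#' @export
contact_probability <- function(distogram, cutoff = 8,
                                mode = c("linear", "floor")) {
  stopifnot(inherits(distogram, "gs_distogram"))
  mode <- match.arg(mode)
  edges <- distogram$bin_edges
  nb <- length(edges) + 1L
  w <- numeric(nb)
  if (cutoff < edges[1]) {
    warning("cutoff below the first interior bin edge; only the open ",
            "lower bin contributes")
    w[1] <- 1
  } else {
    w[1] <- 1
    if (nb > 2L) {
      lo <- edges[-length(edges)]
      hi <- edges[-1]
      wi <- ifelse(hi <= cutoff, 1,
                   ifelse(lo >= cutoff, 0, (cutoff - lo) / (hi - lo)))
      if (mode == "floor") wi[wi > 0 & wi < 1] <- 0
      w[2:(nb - 1L)] <- wi
    }
    if (cutoff > edges[length(edges)]) {
      warning("cutoff above the last interior bin edge; the open upper ",
              "bin is not integrated")
    }
    w[nb] <- 0
  }
  L <- dim(distogram$probs)[1]
  flat <- matrix(distogram$probs, L * L, nb)
  matrix(pmin(pmax(flat %*% w, 0), 1), L, L)
}

new_contact_set <- function(df) {
  cols <- c("chain_a", "res_a", "aa_a", "chain_b", "res_b", "aa_b", "prob")
  if (!nrow(df)) {
    df <- data.frame(chain_a = character(0), res_a = integer(0),
                     aa_a = character(0), chain_b = character(0),
                     res_b = integer(0), aa_b = character(0),
                     prob = numeric(0), stringsAsFactors = FALSE)
  }
  df <- df[, cols]
  # canonical unordered-pair orientation + ordering
  flip <- df$chain_a > df$chain_b |
    (df$chain_a == df$chain_b & df$res_a > df$res_b)
  if (any(flip)) {
    tmp <- df[flip, c("chain_a", "res_a", "aa_a")]
    df[flip, c("chain_a", "res_a", "aa_a")] <-
      df[flip, c("chain_b", "res_b", "aa_b")]
    df[flip, c("chain_b", "res_b", "aa_b")] <- tmp
  }
  if (any(df$chain_a == df$chain_b))
    stop("contact sets are inter-chain only", call. = FALSE)
  key <- contact_keys(df)
  if (anyDuplicated(key)) stop("duplicate contact pairs", call. = FALSE)
  df <- df[order(df$chain_a, df$chain_b, df$res_a, df$res_b), ]
  rownames(df) <- NULL
  structure(df, class = c("gs_contacts", "data.frame"),
            scope = "inter_chain_only")
}

contact_keys <- function(cs)
  paste(cs$chain_a, cs$res_a, cs$chain_b, cs$res_b, sep = "|")

#' Inter-chain contacts predicted from a distogram
#'
#' Thresholds the integrated contact probability, keeps only pairs whose
#' merged positions belong to different chains, and translates positions
#' back to per-chain 1-based residue numbering.
#'
#' @param result A `gs_prediction` from [predict_models()].
#' @param merged The [merge_chains()] result the prediction was made for.
#' @param chain_ids Output chain identifiers (default `LETTERS`).
#' @param threshold Minimum probability, exclusive (default 0.8).
#' @param cutoff Contact distance cutoff in Angstrom (default 8).
#' @param mode Straddling-bin rule, see [contact_probability()].
#' @return A `gs_contacts` data.frame.
#' @export
predicted_contacts <- function(result, merged,
                               chain_ids = LETTERS[seq_along(merged$chain_lengths)],
                               threshold = 0.8, cutoff = 8,
                               mode = c("linear", "floor")) {
  stopifnot(inherits(result, "gs_prediction"), inherits(merged, "gs_merged"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  cp <- contact_probability(result$distogram, cutoff, match.arg(mode))
  L <- merged_length(merged)
  stopifnot(nrow(cp) == L)
  co <- merged$chain_of_position
  aa <- seq_chars(merged$sequence)
  starts <- cumsum(c(1L, merged$chain_lengths))[seq_along(merged$chain_lengths)]
  pos_res <- seq_len(L) - starts[co] + 1L
  idx <- which(upper.tri(cp) & outer(co, co, "!=") & cp > threshold,
               arr.ind = TRUE)
  df <- data.frame(
    chain_a = chain_ids[co[idx[, 1]]],
    res_a = pos_res[idx[, 1]],
    aa_a = aa[idx[, 1]],
    chain_b = chain_ids[co[idx[, 2]]],
    res_b = pos_res[idx[, 2]],
    aa_b = aa[idx[, 2]],
    prob = cp[idx],
    stringsAsFactors = FALSE)
  new_contact_set(df)
}

#' Reference contacts from a complex's coordinates
#'
#' Exhaustive inter-chain anchor-atom scan; a pair is a contact when its
#' distance is strictly below `cutoff`.
#'
#' @param complex A [new_complex()] object.
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @param renumber Use 1-based positions instead of author numbering
#'   (default TRUE, matching [predicted_contacts()] output).
#' @return A `gs_contacts` data.frame (prob = NA).
#' @export
reference_contacts <- function(complex, cutoff = 8, renumber = TRUE) {
  stopifnot(inherits(complex, "gs_complex"))
  chains <- complex$chains
  if (length(chains) < 2L) {
    warning("single-chain complex has no inter-chain contacts")
    return(new_contact_set(data.frame()))
  }
  out <- list()
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (i >= j) next
    a <- chains[[i]]; b <- chains[[j]]
    d <- cross_dist(a$cb, b$cb)
    hit <- which(d < cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    ra <- if (renumber) hit[, 1] else a$residue_numbers[hit[, 1]]
    rb <- if (renumber) hit[, 2] else b$residue_numbers[hit[, 2]]
    out[[length(out) + 1L]] <- data.frame(
      chain_a = a$chain_id, res_a = as.integer(ra),
      aa_a = seq_chars(a$sequence)[hit[, 1]],
      chain_b = b$chain_id, res_b = as.integer(rb),
      aa_b = seq_chars(b$sequence)[hit[, 2]],
      prob = NA_real_, stringsAsFactors = FALSE)
  }
  new_contact_set(if (length(out)) do.call(rbind, out) else data.frame())
}

#' Score predicted contacts against reference and template contacts
#'
#' precision = |predicted intersect reference| / |predicted|;
#' recall = |predicted intersect reference| / |reference|;
#' template_satisfaction = |predicted intersect template| / |predicted|.
#' Empty denominators yield NA with `defined = FALSE` flags (recall of an
#' empty prediction against a non-empty reference is 0, not NA).
#'
#' @param predicted,reference Contact sets with the same chain naming.
#' @param template Optional template contact set.
#' @return An object of class `gs_metrics`.
#' @export
score_contacts <- function(predicted, reference, template = NULL) {
  stopifnot(inherits(predicted, "gs_contacts"),
            inherits(reference, "gs_contacts"))
  check_chain_naming(predicted, reference)
  if (!is.null(template)) check_chain_naming(predicted, template)
  kp <- contact_keys(predicted)
  kr <- contact_keys(reference)
  tp <- length(intersect(kp, kr))
  precision <- if (length(kp)) tp / length(kp) else NA_real_
  recall <- if (length(kr)) tp / length(kr) else NA_real_
  sat <- if (is.null(template)) NA_real_
  else if (length(kp)) length(intersect(kp, contact_keys(template))) /
    length(kp) else NA_real_
  structure(list(precision = precision, recall = recall,
                 template_satisfaction = sat,
                 n_predicted = length(kp), n_reference = length(kr),
                 n_true_positive = tp,
                 defined = c(precision = length(kp) > 0L,
                             recall = length(kr) > 0L,
                             template_satisfaction = !is.null(template) &&
                               length(kp) > 0L)),
            class = "gs_metrics")
}

check_chain_naming <- function(a, b) {
  ca <- unique(c(a$chain_a, a$chain_b))
  cb <- unique(c(b$chain_a, b$chain_b))
  if (length(ca) && length(cb) && !length(intersect(ca, cb)))
    stop("contact sets use disjoint chain names: ",
         paste(ca, collapse = ","), " vs ", paste(cb, collapse = ","),
         call. = FALSE)
  invisible(TRUE)
}

#' Contact-count plausibility classifier
#'
#' A prediction is classified as plausible when it has at least
#' `min_contacts` predicted inter-chain contacts (default 3, the operating
#' point at which benchmarked predictions are correct in over 85% of cases).
#'
#' @param predicted A `gs_contacts` set.
#' @param min_contacts Minimum contact count (default 3).
#' @return TRUE/FALSE.
#' @export
classify_plausible <- function(predicted, min_contacts = 3L) {
  stopifnot(inherits(predicted, "gs_contacts"))
  if (min_contacts < 1L) stop("min_contacts must be >= 1", call. = FALSE)
  nrow(predicted) >= min_contacts
}

#' Per-interface contact counts
#'
#' @param contacts A `gs_contacts` set.
#' @return data.frame with `chain_a`, `chain_b`, `n_contacts`.
#' @export
interface_counts <- function(contacts) {
  stopifnot(inherits(contacts, "gs_contacts"))
  if (!nrow(contacts))
    return(data.frame(chain_a = character(0), chain_b = character(0),
                      n_contacts = integer(0)))
  agg <- stats::aggregate(list(n_contacts = rep(1L, nrow(contacts))),
                          by = list(chain_a = contacts$chain_a,
                                    chain_b = contacts$chain_b), FUN = sum)
  agg[order(agg$chain_a, agg$chain_b), , drop = FALSE]
}

#' Write a contact set as TSV
#'
#' Columns: chain_a, resnum_a, aa_a, chain_b, resnum_b, aa_b, probability.
#'
#' @param contacts A `gs_contacts` set.
#' @param path Output path.
#' @export
write_contacts <- function(contacts, path) {
  stopifnot(inherits(contacts, "gs_contacts"))
  df <- as.data.frame(contacts)
  names(df) <- c("chain_a", "resnum_a", "aa_a", "chain_b", "resnum_b",
                 "aa_b", "probability")
  utils::write.table(format(df, digits = 6, scientific = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
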