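# Splitting merged predictions back into multi-chain models and ranking.

#' Split a merged prediction into a multi-chain complex
#'
#' Positions are partitioned by the merged target's chain-of-position map
#' (never inferred from coordinate gaps), each chain is renumbered 1..L,
#' and coordinates are carried through unchanged.
#'
#' @param result A `gs_prediction` (anything with `coords$ca`/`coords$cb`
#'   matrices over merged positions).
#' @param merged The [merge_chains()] result.
#' @param chain_ids One ID per chain, FASTA input order.
#' @return A [new_complex()] object.
#' @export
split_merged <- function(result, merged,
                         chain_ids = LETTERS[seq_along(merged$chain_lengths)]) {
  stopifnot(inherits(merged, "gs_merged"))
  if (length(chain_ids) != length(merged$chain_lengths))
    stop("need one chain ID per merged chain", call. = FALSE)
  ca <- result$coords$ca
  cb <- result$coords$cb
  L <- merged_length(merged)
  if (is.null(ca) || nrow(ca) != L || nrow(cb) != L)
    stop("prediction coordinates do not cover every merged position",
         call. = FALSE)
  seqs <- split_sequence(merged)
  chains <- lapply(seq_along(seqs), function(k) {
    pos <- merged_chain_positions(merged, k)
    new_chain_record(chain_ids[k], seqs[k],
                     residue_numbers = seq_along(pos),
                     ca = ca[pos, , drop = FALSE],
                     cb = cb[pos, , drop = FALSE])
  })
  new_complex(chains, source_format = "constructed")
}

#' Rank predictions by pTM
#'
#' Sorted by pTM descending; ties broken by lower model ID. The top-ranked
#' model is flagged for relaxation (performed only when a real backend
#' provides it; the mock never does).
#'
#' @param results Non-empty list of `gs_prediction` objects.
#' @param merged The [merge_chains()] result.
#' @param chain_ids One ID per chain.
#' @return List of `gs_ranked` objects (`complex`, `ptm`, `model_id`,
#'   `rank`, `relaxed`, `relax_requested`).
#' @export
rank_models <- function(results, merged,
                        chain_ids = LETTERS[seq_along(merged$chain_lengths)]) {
  if (!length(results)) stop("no prediction results to rank", call. = FALSE)
  ptm <- vapply(results, `[[`, numeric(1), "ptm")
  mid <- vapply(results, `[[`, integer(1), "model_id")
  ord <- order(-ptm, mid)
  lapply(seq_along(ord), function(r) {
    res <- results[[ord[r]]]
    structure(list(complex = split_merged(res, merged, chain_ids),
                   ptm = res$ptm, model_id = res$model_id, rank = r,
                   relaxed = isTRUE(res$relaxed),
                   relax_requested = r == 1L),
              class = "gs_ranked")
  })
}
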