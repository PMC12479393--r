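# Prediction backend contract.
#
# A backend turns a PredictionRequest (merged pseudo-chain + merged MSA +
# unmasked template features) into one PredictionResult per requested
# network model. The network itself is out of scope: the mock backend
# fabricates coordinates and a distogram from a known ground-truth complex
# (optionally degraded with Gaussian noise), which makes every downstream
# computation verifiable without GPUs or weights. An adapter to a real
# AlphaFold2 installation satisfies the same contract but is not part of
# the test surface.

#' Build a prediction request
#'
#' @param merged A [merge_chains()] result.
#' @param msa A [merge_msas()] result.
#' @param template_features A [build_template_features()] result.
#' @param model_ids Network models to run; subset of 1..5. Defaults to
#'   `c(1, 3)`, the two models that accept input templates.
#' @param seed Integer seed forwarded to the backend.
#' @return An object of class `gs_request`.
#' @export
prediction_request <- function(merged, msa, template_features,
                               model_ids = c(1L, 3L), seed = 1L) {
  stopifnot(inherits(merged, "gs_merged"))
  model_ids <- as.integer(model_ids)
  if (!length(model_ids) || any(model_ids < 1L | model_ids > 5L))
    stop("model_ids must be a non-empty subset of 1..5", call. = FALSE)
  structure(list(merged = merged, msa = msa,
                 template_features = template_features,
                 model_ids = model_ids, seed = as.integer(seed)),
            class = "gs_request")
}

#' Construct a distogram
#'
#' @param probs L x L x nbins array; `probs[i, j, ]` is a probability
#'   vector over distance bins for the merged position pair (i, j).
#' @param bin_edges Increasing interior bin edges in Angstrom; bin 1 is
#'   open below the first edge, the last bin open above the last edge, so
#'   `nbins == length(bin_edges) + 1`.
#' @return An object of class `gs_distogram`.
#' @export
new_distogram <- function(probs, bin_edges) {
  bin_edges <- as.numeric(bin_edges)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  d <- dim(probs)
  if (length(d) != 3L || d[1] != d[2] || d[3] != length(bin_edges) + 1L)
    stop("probs must be L x L x (length(bin_edges) + 1)", call. = FALSE)
  structure(list(probs = probs, bin_edges = bin_edges),
            class = "gs_distogram")
}

#' Validate distogram invariants
#'
#' Asserts non-negativity, per-pair normalisation (1e-6) and symmetry.
#' Applied at the backend boundary to every result, not trusted.
#'
#' @param dg A [new_distogram()] object.
#' @export
validate_distogram <- function(dg) {
  stopifnot(inherits(dg, "gs_distogram"))
  if (any(dg$probs < -1e-12))
    stop("distogram has negative probabilities", call. = FALSE)
  sums <- rowSums(dg$probs, dims = 2L)
  if (any(abs(sums - 1) > 1e-6))
    stop("distogram probabilities do not sum to 1", call. = FALSE)
  tp <- aperm(dg$probs, c(2L, 1L, 3L))
  if (max(abs(dg$probs - tp)) > 1e-9)
    stop("distogram is not symmetric", call. = FALSE)
  invisible(dg)
}

#' Deterministic mock backend built from a ground-truth complex
#'
#' The backend's coordinates are the truth coordinates mapped through the
#' merge layout, plus optional Gaussian noise of scale `noise_scale`; its
#' distogram concentrates mass around the (noisy) anchor-atom distances
#' with spread `noise_scale` (a delta in the containing bin when the scale
#' is 0). Reported pTM equals `ptm_value` for every model. The distogram
#' grid uses quarter-Angstrom bins from 2 to 22 A; the 8 A contact cutoff
#' falls exactly on a bin edge, so with zero noise every true contact
#' integrates to probability exactly 1.
#'
#' @param truth A [new_complex()] whose chains match the merged target's
#'   chains in order, length and sequence.
#' @param noise_scale Gaussian noise s.d. in Angstrom (0 = exact).
#' @param ptm_value pTM reported for every model, in \[0, 1\].
#' @return A backend handle of class `gs_backend`.
#' @export
mock_backend_from_truth <- function(truth, noise_scale = 0, ptm_value = 0.9) {
  stopifnot(inherits(truth, "gs_complex"))
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  if (ptm_value < 0 || ptm_value > 1)
    stop("ptm_value must be in [0, 1]", call. = FALSE)
  structure(list(name = "mock", truth = truth,
                 noise_scale = noise_scale, ptm_value = ptm_value,
                 bin_edges = seq(2, 22, by = 0.25)),
            class = "gs_backend")
}

#' Run a backend on a prediction request
#'
#' Returns one result per requested model; deterministic given the request
#' seed for the mock backend. Distogram invariants are asserted on every
#' result at this boundary.
#'
#' @param request A [prediction_request()].
#' @param backend A backend handle, e.g. [mock_backend_from_truth()].
#' @return A list of `gs_prediction` objects (`coords$ca`, `coords$cb`,
#'   `distogram`, `ptm`, `model_id`, `relaxed`).
#' @export
predict_models <- function(request, backend) {
  stopifnot(inherits(request, "gs_request"))
  if (!inherits(backend, "gs_backend"))
    stop("backend unavailable: pass a backend handle such as ",
         "mock_backend_from_truth(); the real AlphaFold2 adapter requires ",
         "an external installation", call. = FALSE)
  results <- withr::with_seed(request$seed, {
    lapply(request$model_ids, function(mid) mock_predict_one(request,
                                                             backend, mid))
  })
  for (r in results) validate_distogram(r$distogram)
  results
}

mock_predict_one <- function(request, backend, model_id) {
  merged <- request$merged
  truth <- backend$truth
  targets <- split_sequence(merged)
  if (length(truth$chains) != length(targets))
    stop("mock backend truth chain count does not match the merged target",
         call. = FALSE)
  tseqs <- vapply(truth$chains, `[[`, character(1), "sequence")
  if (!all(tseqs == targets))
    stop("mock backend truth chain sequences do not match the merged target",
         call. = FALSE)
  ca <- do.call(rbind, lapply(truth$chains, `[[`, "ca"))
  cb <- do.call(rbind, lapply(truth$chains, `[[`, "cb"))
  L <- merged_length(merged)
  s <- backend$noise_scale
  if (s > 0) {
    ca <- ca + matrix(stats::rnorm(3L * L, sd = s), L, 3L)
    cb <- cb + matrix(stats::rnorm(3L * L, sd = s), L, 3L)
    gly <- seq_chars(merged$sequence) == "G"
    cb[gly, ] <- ca[gly, ]
  }
  d <- cross_dist(cb, cb)
  edges <- backend$bin_edges
  nb <- length(edges) + 1L
  probs <- array(0, dim = c(L, L, nb))
  if (s > 0) {
    bounds <- c(-Inf, edges, Inf)
    prev <- matrix(0, L, L)
    for (k in seq_len(nb)) {
      cur <- if (is.infinite(bounds[k + 1L])) matrix(1, L, L) else
        stats::pnorm(bounds[k + 1L], mean = d, sd = s)
      probs[, , k] <- cur - prev
      prev <- cur
    }
  } else {
    bin <- findInterval(d, edges) + 1L
    idx <- cbind(as.vector(row(d)), as.vector(col(d)), as.vector(bin))
    probs[idx] <- 1
  }
  structure(list(coords = list(ca = ca, cb = cb),
                 distogram = new_distogram(probs, edges),
                 ptm = backend$ptm_value, model_id = as.integer(model_id),
                 relaxed = FALSE),
            class = "gs_prediction")
}
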