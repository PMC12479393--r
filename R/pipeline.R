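# Single-command pipeline: MSA acquisition -> chain assignment -> merging
# -> MSA merging -> prediction -> split/rank -> contact analysis, with a
# machine-readable run manifest for reproducibility.

#' Build a pipeline run configuration
#'
#' Defaults are the method's stated parameter set: gap size 200, contact
#' probability threshold 0.8, contact cutoff 8 A, network models 1 and 3,
#' plausibility classifier at 3 contacts.
#'
#' @param fasta_path FASTA with one record per target chain.
#' @param template_path PDB/mmCIF multimeric template.
#' @param output_dir Output directory (created if needed).
#' @param msa_dir Optional directory of per-chain a3m files, named
#'   `<sanitized FASTA header>.a3m` or `chain_<k>.a3m`; chains without a
#'   file fall back to a single-sequence MSA.
#' @param gap_size Residue-index gap between chains (default 200).
#' @param contact_threshold Contact probability threshold (default 0.8).
#' @param contact_cutoff Contact distance cutoff in Angstrom (default 8).
#' @param min_contacts Plausibility classifier operating point (default 3).
#' @param rotrans Optional `c(max_angle, max_shift)` rigid-body template
#'   perturbation (the benchmarking protocol uses `c(30, 5)`).
#' @param backend `"mock"` (the only backend bundled; a real AlphaFold2
#'   adapter satisfies the same contract but needs an external
#'   installation).
#' @param mock_truth_path Structure the mock backend treats as ground
#'   truth; defaults to `template_path`.
#' @param mock_noise Mock backend noise scale in Angstrom (default 0).
#' @param mock_ptm pTM reported by the mock (default 0.9).
#' @param model_ids Network models to run (default `c(1, 3)`).
#' @param seed Integer seed for every stochastic step.
#' @param min_chain_length Template chains shorter than this are dropped.
#' @return An object of class `gs_config`.
#' @export
run_config <- function(fasta_path, template_path, output_dir,
                       msa_dir = NULL, gap_size = 200L,
                       contact_threshold = 0.8, contact_cutoff = 8,
                       min_contacts = 3L, rotrans = NULL,
                       backend = "mock", mock_truth_path = NULL,
                       mock_noise = 0, mock_ptm = 0.9,
                       model_ids = c(1L, 3L), seed = 1L,
                       min_chain_length = 5L) {
  backend <- match.arg(backend, c("mock", "alphafold2"))
  if (contact_threshold <= 0 || contact_threshold > 1)
    stop("contact_threshold must be in (0, 1]", call. = FALSE)
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0", call. = FALSE)
  if (!is.null(rotrans) && length(rotrans) != 2L)
    stop("rotrans must be c(max_angle, max_shift)", call. = FALSE)
  structure(list(fasta_path = fasta_path, template_path = template_path,
                 output_dir = output_dir, msa_dir = msa_dir,
                 gap_size = as.integer(gap_size),
                 contact_threshold = contact_threshold,
                 contact_cutoff = contact_cutoff,
                 min_contacts = as.integer(min_contacts),
                 rotrans = if (!is.null(rotrans)) as.numeric(rotrans),
                 backend = backend,
                 mock_truth_path = mock_truth_path %||% template_path,
                 mock_noise = mock_noise, mock_ptm = mock_ptm,
                 model_ids = as.integer(model_ids),
                 seed = as.integer(seed),
                 min_chain_length = as.integer(min_chain_length)),
            class = "gs_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full prediction pipeline
#'
#' Executes, in order: per-chain MSA acquisition, template chain
#' assignment, chain merging, MSA merging, backend prediction, model
#' splitting/ranking, and contact analysis. Writes ranked models (PDB and
#' mmCIF), a contact TSV and JSON summary, an assignment report, the
#' merged MSA, a per-pair contact probability table, and a run manifest
#' that suffices to re-run the pipeline. Two runs with the same config and
#' seed produce byte-identical outputs.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a run summary list (`manifest`, `ranked`, `contacts`,
#'   `metrics`, `plausible`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "gs_config"))
  if (config$backend != "mock")
    stop("[stage backend] the alphafold2 backend requires an external ",
         "AlphaFold2 installation and is not bundled; use backend = 'mock' ",
         "or provide an adapter via predict_models()", call. = FALSE)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "models"), showWarnings = FALSE)

  targets_df <- stage("read_targets", read_fasta(config$fasta_path))
  targets <- targets_df$sequence
  n_chains <- length(targets)
  cids <- LETTERS[seq_len(n_chains)]

  template <- stage("read_template",
                    read_structure(config$template_path,
                                   config$min_chain_length))
  perturbation <- NULL
  if (!is.null(config$rotrans)) {
    template <- stage("perturb_template",
                      perturb_template(template,
                                       max_angle = config$rotrans[1],
                                       max_shift = config$rotrans[2],
                                       seed = config$seed))
    perturbation <- attr(template, "perturbation")
    write_structure(template, file.path(out, "template_perturbed.pdb"),
                    "pdb")
  }

  msas <- stage("msa_acquisition", acquire_msas(targets, targets_df$header,
                                                config$msa_dir))
  assignment <- stage("assign_chains", assign_chains(targets, template))
  if (length(assignment$unmatched_template_chains))
    warning("unmatched template chains dropped: ",
            paste(assignment$unmatched_template_chains, collapse = ","))
  merged <- stage("merge_chains", merge_chains(targets, config$gap_size))
  features <- stage("template_features",
                    build_template_features(merged, assignment, template))
  merged_msa <- stage("merge_msas", merge_msas(msas, merged))
  write_a3m(merged_msa, file.path(out, "merged_msa.a3m"))

  truth <- stage("mock_truth",
                 read_structure(config$mock_truth_path,
                                config$min_chain_length))
  backend <- stage("backend",
                   mock_backend_from_truth(truth,
                                           noise_scale = config$mock_noise,
                                           ptm_value = config$mock_ptm))
  request <- prediction_request(merged, merged_msa, features,
                                model_ids = config$model_ids,
                                seed = config$seed)
  results <- stage("predict", predict_models(request, backend))
  ranked <- stage("rank_models", rank_models(results, merged, cids))

  model_files <- list()
  for (rm in ranked) {
    base <- sprintf("ranked_%d_model_%d", rm$rank, rm$model_id)
    pdb <- file.path(out, "models", paste0(base, ".pdb"))
    cif <- file.path(out, "models", paste0(base, ".cif"))
    write_structure(rm$complex, pdb, "pdb")
    write_structure(rm$complex, cif, "mmcif")
    model_files[[base]] <- list(model_id = rm$model_id, ptm = rm$ptm,
                                rank = rm$rank, relaxed = rm$relaxed,
                                pdb = pdb, cif = cif)
  }

  ord <- order(-vapply(results, `[[`, numeric(1), "ptm"),
               vapply(results, `[[`, integer(1), "model_id"))
  top <- results[[ord[1]]]
  contacts <- stage("contact_analysis",
                    predicted_contacts(top, merged, cids,
                                       threshold = config$contact_threshold,
                                       cutoff = config$contact_cutoff))
  write_contacts(contacts, file.path(out, "contacts.tsv"))
  write_probability_table(top, merged, cids, config$contact_cutoff,
                          file.path(out, "contact_probs.tsv"))

  template_contacts <- stage("template_contacts",
                             template_contact_set(template, assignment,
                                                  targets, cids,
                                                  config$contact_cutoff))
  metrics <- score_contacts(contacts, template_contacts,
                            template = template_contacts)
  plausible <- classify_plausible(contacts, config$min_contacts)

  summary_json <- list(
    n_predicted_contacts = nrow(contacts),
    interfaces = interface_counts(contacts),
    plausible = plausible,
    min_contacts = config$min_contacts,
    template_satisfaction = metrics$template_satisfaction,
    top_model = list(model_id = top$model_id, ptm = top$ptm))
  jsonlite::write_json(summary_json, file.path(out, "contacts.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  assignment_json <- list(
    pairs = assignment$pairs,
    unmatched_targets = assignment$unmatched_targets,
    unmatched_template_chains = assignment$unmatched_template_chains)
  jsonlite::write_json(assignment_json, file.path(out, "assignment.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ranking_json <- lapply(model_files, function(m)
    m[c("model_id", "ptm", "rank", "relaxed", "pdb", "cif")])
  jsonlite::write_json(ranking_json, file.path(out, "ranking.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest <- list(
    tool = "gapstitch",
    version = as.character(utils::packageVersion("gapstitch")),
    config = unclass(config),
    perturbation = perturbation,
    n_chains = n_chains, chain_ids = cids,
    chain_lengths = merged$chain_lengths,
    models = names(model_files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(manifest = manifest, ranked = ranked, contacts = contacts,
                 metrics = metrics, plausible = plausible,
                 assignment = assignment,
                 paths = list(output_dir = out,
                              manifest = file.path(out, "manifest.json"),
                              contacts = file.path(out, "contacts.tsv"))))
}

# Per-chain MSAs: user a3m when present (homomer chains share one parse),
# single-sequence fallback otherwise.
acquire_msas <- function(targets, headers, msa_dir) {
  cache <- new.env(parent = emptyenv())
  lapply(seq_along(targets), function(k) {
    key <- targets[k]
    if (!is.null(cache[[key]])) return(cache[[key]])
    msa <- NULL
    if (!is.null(msa_dir)) {
      sane <- gsub("[^A-Za-z0-9_.-]", "_", headers[k])
      for (cand in file.path(msa_dir, c(paste0(sane, ".a3m"),
                                        sprintf("chain_%d.a3m", k)))) {
        if (file.exists(cand)) { msa <- parse_a3m(cand); break }
      }
      if (!is.null(msa) && msa$query != targets[k])
        stop("a3m query does not match target chain ", k, call. = FALSE)
    }
    if (is.null(msa)) msa <- single_sequence_msa(targets[k])
    cache[[key]] <- msa
    msa
  })
}

# Inter-chain contacts of the template, expressed in target chain naming
# and 1-based target numbering via the assignment + alignment mapping.
template_contact_set <- function(template, assignment, targets, chain_ids,
                                 cutoff) {
  merged <- merge_chains(targets, gap_size = 200L)
  features <- build_template_features(merged, assignment, template)
  ok <- features$mask
  if (sum(ok) < 2L) return(new_contact_set(data.frame()))
  co <- merged$chain_of_position
  starts <- cumsum(c(1L, merged$chain_lengths))[seq_along(merged$chain_lengths)]
  pos_res <- seq_len(merged_length(merged)) - starts[co] + 1L
  aa <- seq_chars(merged$sequence)
  idx <- which(ok)
  d <- cross_dist(features$cb[idx, , drop = FALSE],
                  features$cb[idx, , drop = FALSE])
  hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  if (nrow(hit)) {
    i <- idx[hit[, 1]]; j <- idx[hit[, 2]]
    keep <- co[i] != co[j]
    i <- i[keep]; j <- j[keep]
  } else i <- j <- integer(0)
  new_contact_set(data.frame(
    chain_a = chain_ids[co[i]], res_a = pos_res[i], aa_a = aa[i],
    chain_b = chain_ids[co[j]], res_b = pos_res[j], aa_b = aa[j],
    prob = NA_real_, stringsAsFactors = FALSE))
}

# All inter-chain pair probabilities above a reporting floor, for offline
# re-thresholding by the `contacts` CLI subcommand.
write_probability_table <- function(result, merged, chain_ids, cutoff,
                                    path, floor = 0.01) {
  cp <- contact_probability(result$distogram, cutoff)
  co <- merged$chain_of_position
  starts <- cumsum(c(1L, merged$chain_lengths))[seq_along(merged$chain_lengths)]
  pos_res <- seq_len(merged_length(merged)) - starts[co] + 1L
  aa <- seq_chars(merged$sequence)
  idx <- which(upper.tri(cp) & outer(co, co, "!=") & cp >= floor,
               arr.ind = TRUE)
  df <- data.frame(chain_a = chain_ids[co[idx[, 1]]],
                   resnum_a = pos_res[idx[, 1]], aa_a = aa[idx[, 1]],
                   chain_b = chain_ids[co[idx[, 2]]],
                   resnum_b = pos_res[idx[, 2]], aa_b = aa[idx[, 2]],
                   probability = cp[idx], stringsAsFactors = FALSE)
  df <- df[order(df$chain_a, df$chain_b, df$resnum_a, df$resnum_b), ]
  utils::write.table(format(df, digits = 6, scientific = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
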