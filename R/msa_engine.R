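# a3m parsing and block-diagonal (unpaired) MSA merging.
#
# a3m convention: uppercase/'-' characters are alignment columns of the
# query; lowercase characters are insertions relative to the query and are
# stripped into per-column deletion counts. No sequence pairing is performed
# when merging: each row of a per-chain MSA covers only its own chain's
# column block in the merged alignment, everything else is gap-padded.

#' Parse an a3m alignment
#'
#' @param path Path to an a3m (or aligned FASTA) file; the first record is
#'   the query.
#' @param max_rows Optional cap on the number of rows kept (file order,
#'   query always kept). Default unlimited.
#' @return An object of class `gs_msa`: `query`, `rows` (character vector,
#'   row 1 == query), `names`, `deletions` (rows x columns matrix of
#'   insertion counts preceding each column), `source`.
#' @export
parse_a3m <- function(path, max_rows = Inf) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty a3m file: ", path, call. = FALSE)
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stop("a3m file must start with a '>' header: ", path,
                    call. = FALSE)
  rec_id <- cumsum(hdr)
  names <- sub("^>", "", lines[hdr])
  raw <- unname(vapply(split(lines[!hdr], rec_id[!hdr]),
                       paste, character(1), collapse = ""))
  msa_from_rows(raw, names, source = "user_a3m", max_rows = max_rows,
                path = path)
}

msa_from_rows <- function(raw, names, source, max_rows = Inf, path = "") {
  if (length(raw) > max_rows) {
    raw <- raw[seq_len(max_rows)]
    names <- names[seq_len(max_rows)]
  }
  stripped <- gsub("[a-z.]", "", raw)
  ncol <- nchar(stripped[1])
  bad <- which(nchar(stripped) != ncol)
  if (length(bad))
    stop(sprintf("a3m row %d has %d columns after insertion stripping, expected %d%s",
                 bad[1], nchar(stripped[bad[1]]), ncol,
                 if (nzchar(path)) paste0(" (", path, ")") else ""),
         call. = FALSE)
  deletions <- t(vapply(raw, count_insertions, numeric(ncol), ncol = ncol,
                        USE.NAMES = FALSE))
  if (ncol == 1L) deletions <- matrix(deletions, ncol = 1L)
  query <- stripped[1]
  if (grepl("-", query, fixed = TRUE))
    stop("a3m query row must not contain gaps", call. = FALSE)
  assert_aa_string(query, "a3m query")
  structure(list(query = query, rows = unname(stripped), names = names,
                 deletions = deletions, source = source),
            class = "gs_msa")
}

# Number of lowercase insertions immediately preceding each query column.
count_insertions <- function(row, ncol) {
  ch <- seq_chars(row)
  ch <- ch[ch != "."]   # '.' is a non-informative insertion placeholder
  out <- numeric(ncol)
  col <- 0L
  run <- 0L
  for (c in ch) {
    if (c >= "a" && c <= "z") {
      run <- run + 1L
    } else {
      col <- col + 1L
      out[col] <- run
      run <- 0L
    }
  }
  out
}

#' Single-sequence MSA for a chain with no alignment
#'
#' @param query The chain sequence.
#' @return A `gs_msa` with the query as its only row.
#' @export
single_sequence_msa <- function(query) {
  assert_aa_string(query)
  msa_from_rows(query, names = "query", source = "user_a3m")
}

#' Merge per-chain MSAs over the merged pseudo-chain (no pairing)
#'
#' Rows are laid out block-diagonally: each non-query row of chain k is
#' padded with `-` over every other chain's columns, so no merged row ever
#' combines sequences from two chains. Per-column residue counts within a
#' block are unchanged by merging.
#'
#' @param chain_msas List of [parse_a3m()] objects, one per target chain in
#'   merged order.
#' @param merged The [merge_chains()] result for the same chains.
#' @return An object of class `gs_merged_msa`: `query`, `rows`,
#'   `row_origin` (0 for the query row, else source chain ordinal), `names`.
#' @export
merge_msas <- function(chain_msas, merged) {
  stopifnot(inherits(merged, "gs_merged"))
  targets <- split_sequence(merged)
  if (length(chain_msas) != length(targets))
    stop("need exactly one MSA per merged chain", call. = FALSE)
  for (k in seq_along(targets)) {
    if (!inherits(chain_msas[[k]], "gs_msa"))
      stop("chain_msas must be gs_msa objects", call. = FALSE)
    if (chain_msas[[k]]$query != targets[k])
      stop("MSA query for chain ", k, " does not match the merged target",
           call. = FALSE)
  }
  lens <- merged$chain_lengths
  pad <- vapply(lens, function(L) paste(rep("-", L), collapse = ""),
                character(1))
  rows <- merged$sequence
  names <- "query"
  origin <- 0L
  for (k in seq_along(chain_msas)) {
    msa <- chain_msas[[k]]
    if (length(msa$rows) < 2L) next
    blocks <- pad
    for (r in 2:length(msa$rows)) {
      blocks[k] <- msa$rows[r]
      rows <- c(rows, paste(blocks, collapse = ""))
      names <- c(names, msa$names[r])
      origin <- c(origin, k)
    }
  }
  structure(list(query = merged$sequence, rows = rows, row_origin = origin,
                 names = names),
            class = "gs_merged_msa")
}

#' Write an alignment as a3m/aligned FASTA
#'
#' Insertions are not re-inserted; rows are written over query columns only.
#'
#' @param msa A `gs_msa` or `gs_merged_msa`.
#' @param path Output path.
#' @export
write_a3m <- function(msa, path) {
  stopifnot(inherits(msa, "gs_msa") || inherits(msa, "gs_merged_msa"))
  nm <- msa$names %||% paste0("row", seq_along(msa$rows))
  writeLines(as.vector(rbind(paste0(">", nm), msa$rows)), path)
  invisible(path)
}
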