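# Structure and sequence I/O.
#
# A gs_complex is an ordered list of gs_chain records, one per polymer chain.
# Each chain keeps exactly the geometric primitives downstream modules
# consume: per-residue anchor atoms (C-beta, with C-alpha standing in for
# glycine and for residues whose C-beta is missing) and C-alpha positions,
# plus author residue numbers and a one-letter sequence.
#
# No pre-installed R package parses PDB/mmCIF, so a minimal reader/writer
# pair lives here: first model only, first alternate location only, protein
# residues only (waters, ions and ligands are excluded).

#' Construct a chain record
#'
#' @param chain_id Single-character (or short) chain identifier.
#' @param sequence One-letter amino-acid string (X allowed).
#' @param residue_numbers Integer vector of author residue numbers,
#'   strictly increasing, one per residue.
#' @param ca Numeric matrix (L x 3) of C-alpha coordinates in Angstrom.
#' @param cb Numeric matrix (L x 3) of anchor coordinates: C-beta, or
#'   C-alpha for glycine. Defaults to `ca` where missing.
#' @param com Optional centre (3-vector); defaults to the centroid of the
#'   retained anchor atoms.
#' @return An object of class `gs_chain`.
#' @export
new_chain_record <- function(chain_id, sequence, residue_numbers, ca,
                             cb = NULL, com = NULL) {
  assert_aa_string(sequence, sprintf("chain %s sequence", chain_id))
  L <- nchar(sequence)
  ca <- matrix(as.numeric(ca), ncol = 3L)
  if (is.null(cb)) cb <- ca
  cb <- matrix(as.numeric(cb), ncol = 3L)
  if (nrow(ca) != L || nrow(cb) != L || length(residue_numbers) != L)
    stop("chain ", chain_id, ": sequence, residue_numbers and coordinates ",
         "must have equal length", call. = FALSE)
  residue_numbers <- as.integer(residue_numbers)
  if (L > 1L && any(diff(residue_numbers) <= 0L))
    stop("chain ", chain_id, ": residue numbers must be strictly increasing",
         call. = FALSE)
  # glycine anchor is C-alpha by definition
  gly <- seq_chars(sequence) == "G"
  cb[gly, ] <- ca[gly, ]
  if (is.null(com)) com <- colMeans(rbind(ca, cb))
  structure(
    list(chain_id = as.character(chain_id), sequence = sequence,
         residue_numbers = residue_numbers, ca = ca, cb = cb,
         com = as.numeric(com)),
    class = "gs_chain")
}

#' Construct a multi-chain complex
#'
#' @param chains List of [new_chain_record()] objects with unique chain IDs.
#' @param source_format One of `"pdb"`, `"mmcif"`, `"constructed"`.
#' @return An object of class `gs_complex`.
#' @export
new_complex <- function(chains, source_format = "constructed") {
  if (!length(chains)) stop("a complex needs at least one chain", call. = FALSE)
  stopifnot(all(vapply(chains, inherits, logical(1), "gs_chain")))
  ids <- vapply(chains, `[[`, character(1), "chain_id")
  if (anyDuplicated(ids))
    stop("chain IDs must be unique within a complex", call. = FALSE)
  source_format <- match.arg(source_format, c("pdb", "mmcif", "constructed"))
  names(chains) <- ids
  structure(list(chains = chains, source_format = source_format),
            class = "gs_complex")
}

#' @export
print.gs_complex <- function(x, ...) {
  cat(sprintf("<gs_complex: %d chain(s) [%s], lengths %s>\n",
              length(x$chains),
              paste(names(x$chains), collapse = ","),
              paste(vapply(x$chains, function(ch) nchar(ch$sequence),
                           integer(1)), collapse = ",")))
  invisible(x)
}

chain_ids <- function(complex) names(complex$chains)
chain_lengths <- function(complex)
  vapply(complex$chains, function(ch) nchar(ch$sequence), integer(1))

# ---------------------------------------------------------------------------
# Reading

#' Read a PDB or mmCIF structure into a complex
#'
#' Uses the first model of multi-model files and the first alternate
#' location. Non-protein components (waters, ions, ligands) are excluded.
#' The anchor atom is C-beta, falling back to C-alpha for glycine and (with
#' a warning) for any residue lacking a C-beta; residues missing both are
#' dropped with a warning.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file; the format
#'   is sniffed from content when the extension is ambiguous.
#' @param min_chain_length Chains shorter than this are discarded.
#' @return A [new_complex()] object.
#' @export
read_structure <- function(path, min_chain_length = 5L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  fmt <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
             any(grepl("^_atom_site\\.", lines))) "mmcif" else "pdb"
  atoms <- if (fmt == "mmcif") parse_mmcif_atoms(lines) else
    parse_pdb_atoms(lines)
  if (is.null(atoms) || nrow(atoms) == 0L)
    stop("could not parse any atom records from ", path, call. = FALSE)
  complex_from_atoms(atoms, fmt, min_chain_length, path)
}

# Fixed-column PDB ATOM/HETATM parser; stops at the first ENDMDL.
parse_pdb_atoms <- function(lines) {
  end <- which(startsWith(lines, "ENDMDL"))
  if (length(end)) lines <- lines[seq_len(end[1] - 1L)]
  rec <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (!length(rec)) return(NULL)
  fld <- function(from, to) trimws(substr(rec, from, to))
  data.frame(
    group = substr(rec, 1, 6),
    atom = fld(13, 16),
    altloc = substr(rec, 17, 17),
    resname = fld(18, 20),
    chain = fld(22, 22),
    resseq = suppressWarnings(as.integer(fld(23, 26))),
    icode = substr(rec, 27, 27),
    x = as.numeric(fld(31, 38)),
    y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)),
    stringsAsFactors = FALSE)
}

# Minimal mmCIF atom_site loop parser. Handles whitespace-separated rows and
# single/double-quoted tokens (enough for atom names like "C1'").
parse_mmcif_atoms <- function(lines) {
  lines <- sub("\r$", "", lines)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) return(NULL)
  # contiguous header block starting at the first _atom_site line
  i <- hdr_idx[1]
  fields <- character(0)
  while (i <= length(lines) && grepl("^_atom_site\\.", lines[i])) {
    fields <- c(fields, sub("^_atom_site\\.(\\S+).*$", "\\1", lines[i]))
    i <- i + 1L
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_") || startsWith(ln, "data_")) break
    rows[[length(rows) + 1L]] <- cif_tokens(ln)
    i <- i + 1L
  }
  if (!length(rows)) return(NULL)
  nf <- length(fields)
  ok <- vapply(rows, function(r) length(r) == nf, logical(1))
  rows <- rows[ok]
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  get <- function(...) {
    for (nm in c(...)) if (nm %in% fields) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  df <- data.frame(
    group = get("group_PDB"),
    atom = get("auth_atom_id", "label_atom_id"),
    altloc = get("label_alt_id"),
    resname = get("auth_comp_id", "label_comp_id"),
    chain = get("auth_asym_id", "label_asym_id"),
    resseq = suppressWarnings(as.integer(get("auth_seq_id", "label_seq_id"))),
    icode = get("pdbx_PDB_ins_code"),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    model = get("pdbx_PDB_model_num"),
    stringsAsFactors = FALSE)
  df$altloc[df$altloc %in% c(".", "?", NA)] <- " "
  df$icode[df$icode %in% c(".", "?", NA)] <- " "
  if (!all(is.na(df$model))) df <- df[df$model == df$model[1], ]
  df$model <- NULL
  df
}

cif_tokens <- function(line) {
  out <- character(0)
  rest <- line
  while (nzchar(rest)) {
    rest <- sub("^\\s+", "", rest)
    if (!nzchar(rest)) break
    first <- substr(rest, 1, 1)
    if (first %in% c("'", '"')) {
      m <- regexpr(paste0(first, "[^", first, "]*", first), rest)
      tok <- substr(rest, 2, attr(m, "match.length") - 1L)
      rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
    } else {
      m <- regexpr("^\\S+", rest)
      tok <- substr(rest, 1, attr(m, "match.length"))
      rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
    }
    out <- c(out, tok)
  }
  out
}

# Assemble per-chain records from a flat atom table.
complex_from_atoms <- function(atoms, fmt, min_chain_length, path) {
  atoms <- atoms[!is.na(atoms$resseq) & !is.na(atoms$x), ]
  # first altloc wins
  atoms <- atoms[atoms$altloc %in% c(" ", "", "A", ".", "1"), ]
  known <- atoms$resname %in% names(AA3_TO_1)
  # ATOM records with unknown residue names are kept as X; HETATM unknowns
  # (waters, ions, ligands) are dropped.
  keep <- known | trimws(atoms$group) == "ATOM"
  atoms <- atoms[keep, ]
  if (!nrow(atoms)) stop("no protein atoms in ", path, call. = FALSE)
  if (any(atoms$icode != " " & atoms$icode != "")) {
    warning("residues with insertion codes were skipped")
    atoms <- atoms[atoms$icode %in% c(" ", ""), ]
  }
  chains <- list()
  for (cid in unique(atoms$chain)) {
    ca_at <- atoms[atoms$chain == cid & atoms$atom == "CA", ]
    cb_at <- atoms[atoms$chain == cid & atoms$atom == "CB", ]
    if (!nrow(ca_at) && !nrow(cb_at)) next
    # residue list from union of anchor-bearing residues, file order by resseq
    res <- sort(unique(c(ca_at$resseq, cb_at$resseq)))
    ca_at <- ca_at[!duplicated(ca_at$resseq), ]
    cb_at <- cb_at[!duplicated(cb_at$resseq), ]
    ca_m <- matrix(NA_real_, length(res), 3L)
    cb_m <- matrix(NA_real_, length(res), 3L)
    ca_m[match(ca_at$resseq, res), ] <- as.matrix(ca_at[, c("x", "y", "z")])
    cb_m[match(cb_at$resseq, res), ] <- as.matrix(cb_at[, c("x", "y", "z")])
    rn <- atoms$resname[atoms$chain == cid]
    rn <- rn[match(res, atoms$resseq[atoms$chain == cid])]
    aa <- unname(AA3_TO_1[rn])
    aa[is.na(aa)] <- "X"
    # drop residues missing both anchors; fall back to CA where CB missing
    have_ca <- !is.na(ca_m[, 1])
    have_cb <- !is.na(cb_m[, 1])
    drop <- !have_ca & !have_cb
    if (any(drop))
      warning(sprintf("chain %s: dropped %d residue(s) missing both CA and CB",
                      cid, sum(drop)))
    no_cb <- have_ca & !have_cb & aa != "G"
    if (any(no_cb))
      warning(sprintf("chain %s: %d residue(s) lack CB; using CA anchor",
                      cid, sum(no_cb)))
    cb_m[!have_cb, ] <- ca_m[!have_cb, ]
    ca_m[!have_ca, ] <- cb_m[!have_ca, ]
    keep_r <- !drop
    if (sum(keep_r) < min_chain_length) next
    chains[[length(chains) + 1L]] <- new_chain_record(
      chain_id = cid,
      sequence = paste(aa[keep_r], collapse = ""),
      residue_numbers = res[keep_r],
      ca = ca_m[keep_r, , drop = FALSE],
      cb = cb_m[keep_r, , drop = FALSE])
  }
  if (!length(chains))
    stop("no polymer chain of length >= ", min_chain_length, " in ", path,
         call. = FALSE)
  new_complex(chains, source_format = fmt)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read target sequences from a FASTA file
#'
#' Order is preserved and duplicate sequences are kept as distinct entries
#' (homomers). Wrapped lines and Windows line endings are handled.
#'
#' @param path FASTA file with one record per target chain.
#' @return A data.frame with columns `header` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # Biostrings silently drops invalid sequence codes, so character
  # validation happens on the raw text first.
  raw <- sub("\r$", "", readLines(path, warn = FALSE))
  body <- toupper(gsub("[[:space:]]", "", raw[!startsWith(raw, ">")]))
  bad <- setdiff(unique(unlist(strsplit(body, ""))), AA_LETTERS)
  if (length(bad))
    stop("FASTA contains non-amino-acid characters: ",
         paste(bad, collapse = ""), call. = FALSE)
  set <- tryCatch(suppressWarnings(Biostrings::readAAStringSet(path)),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e),
                                           ")", call. = FALSE))
  if (!length(set)) stop("FASTA file has no records: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  for (s in seqs) assert_aa_string(s, "FASTA record")
  data.frame(header = names(set), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Writing

#' Write a complex to PDB or mmCIF
#'
#' Emits the retained anchor atoms (CA always; CB for non-glycine residues).
#' A read-back with [read_structure()] reproduces chain IDs, sequences,
#' residue numbers and coordinates to 1e-3 Angstrom.
#'
#' @param complex A [new_complex()] object.
#' @param path Output path.
#' @param format `"pdb"` or `"mmcif"`.
#' @export
write_structure <- function(complex, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  stopifnot(inherits(complex, "gs_complex"))
  if (!length(complex$chains)) stop("refusing to write an empty complex",
                                    call. = FALSE)
  lines <- if (format == "pdb") format_pdb(complex) else format_mmcif(complex)
  ok <- tryCatch({ suppressWarnings(writeLines(lines, path)); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

format_pdb <- function(complex) {
  out <- character(0)
  serial <- 0L
  for (ch in complex$chains) {
    aa <- seq_chars(ch$sequence)
    for (i in seq_along(aa)) {
      res3 <- AA1_TO_3[[if (aa[i] %in% names(AA1_TO_3)) aa[i] else "X"]]
      emit <- function(name, xyz, element) {
        serial <<- serial + 1L
        sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                serial, paste0(" ", name), " ", res3, ch$chain_id,
                ch$residue_numbers[i], " ", xyz[1], xyz[2], xyz[3],
                1, 0, element)
      }
      out <- c(out, emit("CA", ch$ca[i, ], "C"))
      if (aa[i] != "G") out <- c(out, emit("CB", ch$cb[i, ], "C"))
    }
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %3s %1s%4d", serial,
                          AA1_TO_3[[if (aa[length(aa)] %in% names(AA1_TO_3))
                            aa[length(aa)] else "X"]],
                          ch$chain_id,
                          ch$residue_numbers[length(aa)]))
  }
  c(out, "END")
}

format_mmcif <- function(complex) {
  hdr <- c("data_gapstitch", "#", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "label_atom_id",
                                   "label_alt_id", "label_comp_id",
                                   "label_asym_id", "auth_asym_id",
                                   "auth_seq_id", "pdbx_PDB_ins_code",
                                   "Cartn_x", "Cartn_y", "Cartn_z",
                                   "occupancy", "B_iso_or_equiv",
                                   "type_symbol", "pdbx_PDB_model_num")))
  rows <- character(0)
  serial <- 0L
  for (ch in complex$chains) {
    aa <- seq_chars(ch$sequence)
    for (i in seq_along(aa)) {
      res3 <- AA1_TO_3[[if (aa[i] %in% names(AA1_TO_3)) aa[i] else "X"]]
      emit <- function(name, xyz) {
        serial <<- serial + 1L
        sprintf("ATOM %d %s . %s %s %s %d ? %.3f %.3f %.3f 1.00 0.00 C 1",
                serial, name, res3, ch$chain_id, ch$chain_id,
                ch$residue_numbers[i], xyz[1], xyz[2], xyz[3])
      }
      rows <- c(rows, emit("CA", ch$ca[i, ]))
      if (aa[i] != "G") rows <- c(rows, emit("CB", ch$cb[i, ]))
    }
  }
  c(hdr, rows, "#")
}
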