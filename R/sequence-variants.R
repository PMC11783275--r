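# 20 standard residues; X tolerated inside sequences but never as a
# substitution endpoint (no thermodynamic meaning for an unknown residue).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_SEQ_ALPHABET <- c(AA_ALPHABET, "X")

#' Construct a protein sequence record
#'
#' Validates a full-length amino-acid sequence against the 20-letter
#' alphabet (plus `X` for unknown residues) and attaches an identifier,
#' typically a UniProt accession or user label.
#'
#' @param id Single non-empty string naming the protein.
#' @param residues Single string of one-letter residue codes, length >= 1.
#' @return An object of class `protein_sequence` with fields `id`,
#'   `residues` and `length`.
#' @examples
#' protein_sequence("P00698", "MATG")
#' @export
protein_sequence <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string", call. = FALSE)
  if (!is.character(residues) || length(residues) != 1L)
    stop("'residues' must be a single string", call. = FALSE)
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  if (length(chars) < 1L)
    stop("sequence must contain at least one residue", call. = FALSE)
  bad <- setdiff(unique(chars), AA_SEQ_ALPHABET)
  if (length(bad))
    stop("invalid residue character(s) in '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(id = id, residues = residues, length = length(chars)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  head <- if (x$length > 40L) paste0(substr(x$residues, 1L, 40L), "...")
          else x$residues
  cat(sprintf("Protein sequence '%s' (%d aa): %s\n", x$id, x$length, head))
  invisible(x)
}

as_protein_sequence <- function(x, id = "seq") {
  if (inherits(x, "protein_sequence")) return(x)
  protein_sequence(id, x)
}

#' Parse a variant string into a validated substitution set
#'
#' A variant is one substitution token `"XnY"` (wild-type residue, 1-based
#' position, variant residue) or several tokens joined by commas for a
#' multi-point variation, e.g. `"C57Y,A23G"`. Substitutions are normalised
#' to increasing position.
#'
#' @param text Single variant string.
#' @return A `variant_spec`: data frame with columns `wt`, `pos`, `vt`,
#'   sorted by position.
#' @examples
#' parse_variant("A23G")
#' parse_variant("C57Y,A23G")
#' @export
parse_variant <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("variant must be a single non-empty string", call. = FALSE)
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  if (any(!nzchar(tokens)))
    stop("empty substitution token in '", text, "'", call. = FALSE)
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
  bad <- tokens[vapply(m, length, 1L) != 4L]
  if (length(bad))
    stop("malformed substitution token(s): ", paste(bad, collapse = ", "),
         " (expected form 'XnY')", call. = FALSE)
  wt  <- toupper(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  vt  <- toupper(vapply(m, `[`, "", 4L))
  variant_spec(wt, pos, vt)
}

#' Build a substitution set from its components
#'
#' @param wt,vt Character vectors of wild-type / variant residue letters.
#' @param pos Integer vector of 1-based positions.
#' @return A `variant_spec` data frame sorted by position.
#' @export
variant_spec <- function(wt, pos, vt) {
  wt <- unname(as.character(wt)); vt <- unname(as.character(vt))
  pos <- unname(as.integer(pos))
  if (length(wt) != length(pos) || length(vt) != length(pos) ||
      length(pos) < 1L)
    stop("wt, pos, vt must be non-empty and of equal length", call. = FALSE)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("positions must be positive integers", call. = FALSE)
  bad <- setdiff(unique(c(wt, vt)), AA_ALPHABET)
  if (length(bad))
    stop("substitution endpoints must be standard residues; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(wt == vt))
    stop("null substitution (wild-type equals variant residue) at position ",
         paste(pos[wt == vt], collapse = ", "), call. = FALSE)
  if (anyDuplicated(pos))
    stop("duplicate substitution position: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "), call. = FALSE)
  o <- order(pos)
  structure(data.frame(wt = wt[o], pos = pos[o], vt = vt[o],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("variant_spec", "data.frame"))
}

#' Render a substitution set back to its canonical string
#'
#' Inverse of [parse_variant()]: `parse_variant(format_variant(s))` is
#' identical to `s` for any valid spec.
#'
#' @param spec A `variant_spec`.
#' @return Single string, tokens comma-joined in position order.
#' @export
format_variant <- function(spec) {
  stopifnot(inherits(spec, "variant_spec"))
  paste0(spec$wt, spec$pos, spec$vt, collapse = ",")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat("Variant:", format_variant(x), "\n")
  invisible(x)
}

#' Apply substitutions to a wild-type sequence
#'
#' All positions refer to wild-type coordinates; substitutions never shift
#' coordinates, so multi-point specs are applied in one pass. The residue
#' found at each position must match the spec's wild-type letter, otherwise
#' the coordinates (or the sequence) are wrong and an error is raised.
#'
#' @param seq A `protein_sequence` (or plain residue string).
#' @param spec A `variant_spec` or variant string.
#' @return The variant `protein_sequence`; same id, same length.
#' @examples
#' apply_variants(protein_sequence("p", "MATG"), parse_variant("A2G"))
#' @export
apply_variants <- function(seq, spec) {
  seq <- as_protein_sequence(seq)
  if (is.character(spec)) spec <- parse_variant(spec)
  stopifnot(inherits(spec, "variant_spec"))
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  if (any(spec$pos > seq$length))
    stop("substitution position ", max(spec$pos), " exceeds sequence length ",
         seq$length, " for '", seq$id, "'", call. = FALSE)
  found <- chars[spec$pos]
  bad <- which(found != spec$wt)
  if (length(bad))
    stop("wild-type mismatch for '", seq$id, "' at position ",
         paste(spec$pos[bad], collapse = ", "), ": sequence has ",
         paste(found[bad], collapse = ", "), ", variant expects ",
         paste(spec$wt[bad], collapse = ", "), call. = FALSE)
  chars[spec$pos] <- spec$vt
  protein_sequence(seq$id, paste(chars, collapse = ""))
}

#' Reverse a variation
#'
#' Builds the thermodynamic reverse of a variation: the variant sequence
#' becomes the new wild type and every substitution is inverted
#' (`A23G` becomes `G23A`). Under reversibility the true ddG of the
#' reversed variation is the negation of the direct one.
#'
#' @inheritParams apply_variants
#' @return List with `seq` (variant sequence) and `spec` (inverted spec);
#'   applying `spec` to `seq` restores the original sequence.
#' @examples
#' reverse_variant(protein_sequence("p", "MATG"), parse_variant("A2G"))
#' @export
reverse_variant <- function(seq, spec) {
  seq <- as_protein_sequence(seq)
  if (is.character(spec)) spec <- parse_variant(spec)
  vseq <- apply_variants(seq, spec)
  rspec <- variant_spec(spec$vt, spec$pos, spec$wt)
  list(seq = vseq, spec = rspec)
}

#' Read protein sequences from a FASTA file
#'
#' The identifier is the header token before the first whitespace.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named list of `protein_sequence` objects.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, call. = FALSE)
  out <- lapply(seq_along(aas),
                function(i) protein_sequence(ids[i], as.character(aas[[i]])))
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs List of `protein_sequence` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  aas <- Biostrings::AAStringSet(vapply(seqs, function(s) s$residues, ""))
  names(aas) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Read a variant table
#'
#' Tab-separated table with columns `protein_id`, `variant` and optionally
#' `ddg` (experimental ddG in kcal/mol; negative = destabilizing) and
#' `direction` (`direct`/`reverse`).
#'
#' @param path TSV file.
#' @return Data frame with parsed columns; every `variant` string is
#'   validated through [parse_variant()].
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_id", "variant")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_variant(df$variant[i]), error = function(e)
      stop("row ", i, " of ", path, ": ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(df$ddg)) df$ddg <- as.numeric(df$ddg)
  df
}

#' Write a variant table
#'
#' @param df Data frame with at least `protein_id` and `variant` columns.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
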