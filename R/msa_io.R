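# Alignment input/output and integer/one-hot encoding.
#
# All model code indexes residues against a single fixed 21-symbol alphabet:
# the 20 canonical amino acids in alphabetical one-letter order, then the gap
# character '-'. The gap is an ordinary 21st category everywhere (model,
# statistics, Hamming distances).

GAP_CHAR <- "-"

#' The fixed 21-symbol residue alphabet
#'
#' Returns the ordered symbol set used by every encoded alignment and model
#' tensor in this package: `"ACDEFGHIKLMNPQRSTVWY-"` (20 canonical amino
#' acids, gap last). Integer codes are 1-based positions in this vector, so
#' the gap always encodes as 21.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' msa_alphabet()
msa_alphabet <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY-", "")[[1]]
}

# Symbols silently tolerated in input but carrying no frequency information of
# their own: ambiguity/rare codes and the '.' gap dialect all map to the gap.
NONCANONICAL <- c("B", "Z", "X", "J", "U", "O", ".")

#' Encode aligned sequences as an integer matrix
#'
#' Turns equal-length residue strings into an `encoded_msa`: an N x L integer
#' matrix with entries in 1..21 indexing [msa_alphabet()]. Lowercase letters
#' are uppercased first; the ambiguity codes B, Z, X, J, U, O and the '.' gap
#' variant are mapped to the gap symbol with a warning giving the total count.
#' Any other character is an error.
#'
#' @param seqs Character vector of aligned sequences, all the same length.
#' @param ids Optional record identifiers; empty or missing ids are replaced
#'   by `seq_<i>` (0-based, in input order).
#' @return An object of class `encoded_msa`: list with `ids` (character N),
#'   `codes` (N x L integer matrix), `n_sequences`, `length`, `alphabet`.
#' @export
encode_msa <- function(seqs, ids = NULL) {
  if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
  lens <- nchar(seqs)
  if (any(lens != lens[1L])) {
    bad <- which(lens != lens[1L])[1L]
    nm <- if (!is.null(ids)) ids[bad] else as.character(bad)
    stop(sprintf(
      "record '%s' has length %d but the alignment width is %d; input must be a fixed-width alignment",
      nm, lens[bad], lens[1L]
    ))
  }
  if (lens[1L] < 1L) stop("alignment width must be at least 1")
  if (is.null(ids)) ids <- character(length(seqs))
  blank <- is.na(ids) | !nzchar(ids)
  ids[blank] <- sprintf("seq_%d", which(blank) - 1L)

  alpha <- msa_alphabet()
  chars <- matrix(
    unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE
  )
  noncanon <- chars %in% NONCANONICAL
  if (any(noncanon)) {
    warning(sprintf(
      "%d non-canonical residue(s) (B/Z/X/J/U/O/'.') mapped to the gap symbol",
      sum(noncanon)
    ))
    chars[noncanon] <- GAP_CHAR
  }
  codes <- match(chars, alpha)
  if (anyNA(codes)) {
    stop(sprintf(
      "unrecognized character(s) in alignment: %s",
      paste(unique(chars[is.na(codes)]), collapse = " ")
    ))
  }
  dim(codes) <- dim(chars)
  structure(
    list(
      ids = ids, codes = codes,
      n_sequences = nrow(codes), length = ncol(codes),
      alphabet = alpha
    ),
    class = "encoded_msa"
  )
}

#' @export
print.encoded_msa <- function(x, ...) {
  cat(sprintf(
    "encoded_msa: %d sequences x %d positions (alphabet of %d symbols, gap '-')\n",
    x$n_sequences, x$length, length(x$alphabet)
  ))
  invisible(x)
}

#' Decode an encoded alignment back to residue strings
#'
#' @param msa An `encoded_msa`.
#' @return Character vector of sequences, named by record id.
#' @export
decode_msa <- function(msa) {
  stopifnot(inherits(msa, "encoded_msa"))
  out <- apply(msa$codes, 1L, function(row) paste(msa$alphabet[row], collapse = ""))
  names(out) <- msa$ids
  out
}

#' Read an aligned FASTA file
#'
#' Reads a fixed-width amino-acid alignment (gap '-') and encodes it against
#' the package alphabet. Records of unequal length are an error naming the
#' offending record; an empty file is an error.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `encoded_msa` with ids in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path))
  encode_msa(as.character(set), ids = names(set))
}

#' Write an encoded alignment as FASTA
#'
#' One record per sequence, gap written as '-', lines wrapped at 80 columns.
#'
#' @param msa An `encoded_msa`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "encoded_msa"))
  seqs <- decode_msa(msa)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- msa$ids
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' One-hot encode an alignment
#'
#' Expands the integer codes into the binary indicator tensor sigma with
#' `sigma[n, a, l] = 1` iff sequence n carries symbol a at position l.
#'
#' @param msa An `encoded_msa`.
#' @return Numeric array of dimension N x 21 x L summing to 1 over the symbol
#'   axis at every (n, l).
#' @export
one_hot <- function(msa) {
  stopifnot(inherits(msa, "encoded_msa"))
  n <- msa$n_sequences
  l <- msa$length
  a <- length(msa$alphabet)
  out <- array(0, dim = c(n, a, l))
  idx <- cbind(
    rep.int(seq_len(n), l),
    as.vector(msa$codes),
    rep(seq_len(l), each = n)
  )
  out[idx] <- 1
  out
}

# Internal: build an encoded_msa from a bare codes matrix (ids synthesized).
msa_from_codes <- function(codes, ids = NULL, id_prefix = "seq") {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  a <- length(msa_alphabet())
  stopifnot(nrow(codes) >= 1L, ncol(codes) >= 1L,
            all(codes >= 1L), all(codes <= a))
  if (is.null(ids)) ids <- sprintf("%s_%d", id_prefix, seq_len(nrow(codes)) - 1L)
  structure(
    list(
      ids = ids, codes = codes,
      n_sequences = nrow(codes), length = ncol(codes),
      alphabet = msa_alphabet()
    ),
    class = "encoded_msa"
  )
}
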