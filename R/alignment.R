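#' Construct an alignment object
#'
#' An alignment is stored as an S x p character matrix (one cell per residue)
#' with unique taxon names as row names and a declared alphabet.  Characters
#' are uppercase; `U` is mapped to `T` for nucleotide data and `?` to the gap
#' character `-` (both denote missing data here).
#'
#' @param seqs named character vector of aligned sequences (equal length), or
#'   an S x p character matrix with taxon row names.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @return An object of class `esl_alignment`: a character matrix with
#'   attribute `alphabet`.
#' @examples
#' aln <- esl_alignment(c(t1 = "ACGT", t2 = "ACGA"), "nucleotide")
#' n_taxa(aln); n_positions(aln)
#' @export
esl_alignment <- function(seqs, alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- .match_alphabet(alphabet)
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    nms <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nms
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("all sequences must carry non-empty taxon names", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment-length error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (ncol(m) < 1L) stop("alignment-length error: zero positions", call. = FALSE)
  if (is.null(rownames(m)) || any(!nzchar(rownames(m))))
    stop("taxon identifier error: missing or empty taxon names", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("taxon identifier error: duplicate taxon name(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  m[] <- toupper(m)
  m[m == "?"] <- .esl_gap
  m[m == "."] <- .esl_gap
  if (alphabet == "nucleotide") m[m == "U"] <- "T"
  bad <- !(m %in% .allowed_chars(alphabet))
  if (any(bad)) {
    stop("alphabet error: character(s) outside the ", alphabet,
         " alphabet/ambiguity/gap set: ",
         paste(unique(m[bad]), collapse = ", "), call. = FALSE)
  }
  structure(m, alphabet = alphabet, class = "esl_alignment")
}

#' @rdname esl_alignment
#' @param x an `esl_alignment`.
#' @export
n_taxa <- function(x) nrow(x)

#' @rdname esl_alignment
#' @export
n_positions <- function(x) ncol(x)

#' @export
print.esl_alignment <- function(x, ...) {
  cat(sprintf("<esl_alignment> %d taxa x %d positions (%s)\n",
              nrow(x), ncol(x), attr(x, "alphabet")))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA (default) or relaxed sequential PHYLIP, uppercases, maps `U`
#' to `T` for nucleotide data and `?` to `-`, and validates every character
#' against the declared alphabet plus IUPAC ambiguity codes and the gap.
#'
#' @param path path to the alignment file.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @return An [esl_alignment()].
#' @export
read_alignment <- function(path, alphabet = c("nucleotide", "amino_acid"),
                           format = c("fasta", "phylip")) {
  alphabet <- .match_alphabet(alphabet)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))  # first token of the header
  } else {
    pd <- phangorn::read.phyDat(path,
                                format = "sequential",
                                type = if (alphabet == "nucleotide") "DNA" else "AA")
    m <- as.character(pd)
    seqs <- apply(m, 1L, paste, collapse = "")
  }
  esl_alignment(seqs, alphabet)
}

#' Write an alignment to FASTA
#'
#' @param aln an [esl_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "esl_alignment"))
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(aln)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Extract one alignment column's characters
#' @noRd
.aln_column <- function(aln, i) unclass(aln)[, i]
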