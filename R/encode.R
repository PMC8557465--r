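#' One-hot encode an alignment
#'
#' Each alignment position contributes one binary bit-column per distinct
#' residue state observed unambiguously at that position (at most 4 for
#' nucleotides, 20 for amino acids, +1 if the gap is encoded as a state).
#' Bit-columns are ordered by position ascending, then by state in fixed
#' alphabet order (gap last), so the encoding is deterministic.
#'
#' Ambiguity codes are handled by policy: `"missing"` (default) sets no bits;
#' `"constituent_bits"` sets the bit of every constituent base whose
#' bit-column exists at that position (e.g. `R` sets the `A` and `G` bits).
#' Bit-columns are never centered or standardized: sparsity scores are
#' interpreted on the raw 0/1 coding.
#'
#' @param aln an [esl_alignment()].
#' @param gap_as_state encode `-` as its own state with its own bit-column
#'   (default FALSE: gaps set no bits).
#' @param ambiguity_policy `"missing"` or `"constituent_bits"`.
#' @return An object of class `esl_onehot`: list with the S x c binary
#'   matrix `X` (taxa as row names), the bit-column map `map` (data frame
#'   with 1-based `position` and `state` per bit-column), and encoding
#'   metadata.
#' @examples
#' aln <- esl_alignment(c(a = "AAC", b = "ACC", c = "GCC"), "nucleotide")
#' enc <- one_hot_encode(aln)
#' enc$map
#' @export
one_hot_encode <- function(aln, gap_as_state = FALSE,
                           ambiguity_policy = c("missing", "constituent_bits")) {
  stopifnot(inherits(aln, "esl_alignment"))
  ambiguity_policy <- match.arg(ambiguity_policy)
  M <- unclass(aln)
  S <- nrow(M); p <- ncol(M)
  if (S == 0L || p == 0L) stop("empty-input error: empty alignment", call. = FALSE)
  alphabet <- attr(aln, "alphabet")
  alpha <- .esl_alphabets[[alphabet]]
  states <- alpha$states
  if (gap_as_state) states <- c(states, .esl_gap)
  nst <- length(states)

  # observation (unambiguous) and activation (bits actually set) per state
  obs <- lapply(states, function(s) M == s)
  names(obs) <- states
  act <- obs
  if (ambiguity_policy == "constituent_bits") {
    for (s in alpha$states) {
      codes <- names(alpha$ambiguity)[
        vapply(alpha$ambiguity, function(cc) s %in% cc, logical(1L))]
      if (length(codes) > 0L) {
        hit <- matrix(M %in% codes, S, p)
        act[[s]] <- obs[[s]] | hit
      }
    }
  }

  # a bit-column exists iff the state is observed unambiguously at the position
  pres <- vapply(obs, function(B) colSums(B) > 0L, logical(p))  # p x nst
  if (p == 1L) pres <- matrix(pres, nrow = 1L)
  w <- which(t(pres))                        # position-major, state-minor order
  state_idx <- (w - 1L) %% nst + 1L
  pos_idx <- (w - 1L) %/% nst + 1L

  A <- do.call(cbind, act)                   # S x (p * nst), state-major blocks
  X <- A[, (state_idx - 1L) * p + pos_idx, drop = FALSE]
  storage.mode(X) <- "integer"
  rownames(X) <- rownames(M)
  map <- data.frame(position = pos_idx, state = states[state_idx],
                    stringsAsFactors = FALSE)
  structure(list(X = X, map = map, alphabet = alphabet,
                 gap_as_state = gap_as_state,
                 ambiguity_policy = ambiguity_policy,
                 p = p, n_removed_monomorphic = 0L),
            class = "esl_onehot")
}

#' @export
print.esl_onehot <- function(x, ...) {
  cat(sprintf(
    "<esl_onehot> %d taxa x %d bit-columns (%d positions, %d monomorphic bit-columns removed)\n",
    nrow(x$X), ncol(x$X), x$p, x$n_removed_monomorphic))
  invisible(x)
}

#' Remove monomorphic (constant) bit-columns
#'
#' Bit-columns that are all 0 or all 1 carry no information about any
#' response and are dropped; the bit-column map is updated and the removal
#' count recorded.  May return a zero-column matrix (the solver rejects it).
#'
#' @param enc an `esl_onehot`.
#' @return The filtered `esl_onehot`.
#' @export
filter_monomorphic <- function(enc) {
  stopifnot(inherits(enc, "esl_onehot"))
  S <- nrow(enc$X)
  cs <- colSums(enc$X)
  keep <- cs > 0L & cs < S
  enc$n_removed_monomorphic <- enc$n_removed_monomorphic + sum(!keep)
  enc$X <- enc$X[, keep, drop = FALSE]
  enc$map <- enc$map[keep, , drop = FALSE]
  rownames(enc$map) <- NULL
  enc
}

#' Assign every retained bit-column to its group
#'
#' Maps groups of alignment positions onto slices of bit-column indices.
#' Groups whose positions were all filtered out yield empty slices (inert
#' groups).  Encoded positions not covered by any group are an error unless
#' `drop_uncovered = TRUE`, in which case their bit-columns are removed.
#'
#' @param enc an `esl_onehot`.
#' @param groups an [group_map()] object.
#' @param drop_uncovered drop bit-columns at positions outside all groups.
#' @return The `esl_onehot` with a `group` column added to `map` and a named
#'   list `group_bits` of bit-column index vectors (one per group, in group
#'   order).
#' @export
map_groups_to_bits <- function(enc, groups, drop_uncovered = FALSE) {
  stopifnot(inherits(enc, "esl_onehot"), inherits(groups, "esl_groups"))
  if (groups$p != enc$p)
    stop("range error: group map is for p = ", groups$p,
         " but encoding has p = ", enc$p, call. = FALSE)
  pos2grp <- rep(NA_character_, enc$p)
  for (g in names(groups$groups)) pos2grp[groups$groups[[g]]] <- g
  grp <- pos2grp[enc$map$position]
  if (anyNA(grp)) {
    if (!drop_uncovered)
      stop("range error: ", sum(is.na(grp)),
           " bit-column(s) at positions outside all groups", call. = FALSE)
    keep <- !is.na(grp)
    enc$X <- enc$X[, keep, drop = FALSE]
    enc$map <- enc$map[keep, , drop = FALSE]
    rownames(enc$map) <- NULL
    grp <- grp[keep]
  }
  enc$map$group <- grp
  gb <- lapply(names(groups$groups), function(g) which(grp == g))
  names(gb) <- names(groups$groups)
  enc$group_bits <- gb
  enc$group_weights <- groups$weights
  enc
}

#' Decode an (unfiltered) one-hot encoding back to an alignment
#'
#' Inverse of [one_hot_encode()] for unambiguous data: each row position with
#' exactly one set bit recovers its state; rows with no set bit at a position
#' decode to the gap.
#'
#' @param enc an `esl_onehot` (before monomorphic filtering).
#' @return An [esl_alignment()].
#' @export
decode_onehot <- function(enc) {
  stopifnot(inherits(enc, "esl_onehot"))
  S <- nrow(enc$X)
  M <- matrix(.esl_gap, S, enc$p)
  rownames(M) <- rownames(enc$X)
  for (k in seq_len(ncol(enc$X))) {
    on <- enc$X[, k] == 1L
    M[on, enc$map$position[k]] <- enc$map$state[k]
  }
  esl_alignment(M, enc$alphabet)
}

#' Write the bit-column map (and optionally the matrix) as TSV for audit
#'
#' One row per bit-column: bit index, 1-based position, state, group (if
#' assigned).
#'
#' @param enc an `esl_onehot`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_encoding <- function(enc, path) {
  tab <- cbind(bit = seq_len(nrow(enc$map)), enc$map)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
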