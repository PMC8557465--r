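#' Simulate an alignment with planted clade-diagnostic signal
#'
#' Generates S sequences over p positions partitioned into G contiguous
#' genes.  A designated clade of `clade_size` taxa carries signal at
#' `n_diag_per_gene` positions in each of `n_diag_genes` randomly chosen
#' genes: at a diagnostic position, clade members draw the clade state with
#' probability `fidelity` (otherwise the background state) and non-members
#' draw it with probability `leakage`.  All other positions are i.i.d. over
#' the alphabet (uniform by default).  Everything is seed-deterministic.
#'
#' Signal is injected site-wise rather than simulated along a tree: the
#' method under study works on the concordance between site patterns and a
#' bipartition, so direct injection gives exact ground truth.
#'
#' @param S number of sequences.
#' @param p number of positions.
#' @param G number of genes (contiguous blocks of near-equal length).
#' @param n_diag_genes number of genes carrying diagnostic positions
#'   (0 for pure noise).
#' @param n_diag_per_gene diagnostic positions per diagnostic gene.
#' @param clade_size taxa in the focal clade, in `[2, S-2]`.
#' @param fidelity probability a clade member carries the clade state.
#' @param leakage probability a non-member carries it; `0 <= leakage <
#'   fidelity <= 1`.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param composition optional probability vector over the core alphabet for
#'   background draws (default uniform).
#' @param seed integer seed.
#' @return An object of class `esl_simulation`: `aln` ([esl_alignment()]),
#'   `classes` (data frame taxon/label with +1 for clade members),
#'   `groups` ([group_map()]), and `truth` (clade members, diagnostic
#'   positions with clade/background states, diagnostic genes, fidelity,
#'   leakage, seed).
#' @examples
#' sim <- simulate_alignment(S = 20, p = 60, G = 3, n_diag_genes = 1,
#'                           n_diag_per_gene = 4, clade_size = 6, seed = 7)
#' sim$truth$diag_genes
#' @export
simulate_alignment <- function(S = 100L, p = 2000L, G = 20L,
                               n_diag_genes = 2L, n_diag_per_gene = 10L,
                               clade_size = 20L, fidelity = 0.95,
                               leakage = 0.05,
                               alphabet = c("nucleotide", "amino_acid"),
                               composition = NULL, seed = 1L) {
  alphabet <- .match_alphabet(alphabet)
  stopifnot(S >= 4L, p >= 1L, G >= 1L, G <= p,
            n_diag_genes >= 0L, n_diag_genes <= G,
            leakage >= 0, leakage < fidelity, fidelity <= 1)
  if (clade_size < 2L || clade_size > S - 2L)
    stop("clade_size must lie in [2, S-2]", call. = FALSE)
  if (n_diag_genes * n_diag_per_gene > p)
    stop("capacity error: more diagnostic positions than alignment positions",
         call. = FALSE)
  states <- .esl_alphabets[[alphabet]]$states
  if (is.null(composition)) composition <- rep(1 / length(states),
                                               length(states))
  stopifnot(length(composition) == length(states), all(composition >= 0))
  composition <- composition / sum(composition)

  # contiguous near-equal gene blocks
  sizes <- rep(p %/% G, G)
  if (p %% G > 0L) sizes[seq_len(p %% G)] <- sizes[seq_len(p %% G)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  gnames <- sprintf("gene%02d", seq_len(G))
  glist <- stats::setNames(mapply(seq, starts, ends, SIMPLIFY = FALSE), gnames)
  if (n_diag_genes > 0L && n_diag_per_gene > min(sizes))
    stop("capacity error: n_diag_per_gene exceeds the shortest gene",
         call. = FALSE)

  rng <- .seeded_rng(seed)
  taxa <- sprintf("t%03d", seq_len(S))
  members <- sort(rng$sample(taxa, size = clade_size, replace = FALSE))
  is_member <- taxa %in% members

  # background: i.i.d. draws over the core alphabet
  draw_states <- function(n) states[
    findInterval(rng$runif(n), cumsum(composition), left.open = TRUE) + 1L]
  M <- matrix(draw_states(S * p), S, p)
  rownames(M) <- taxa

  diag_genes <- character(0)
  diag_tab <- data.frame(position = integer(0), gene = character(0),
                         clade_state = character(0),
                         background_state = character(0),
                         stringsAsFactors = FALSE)
  if (n_diag_genes > 0L) {
    diag_genes <- sort(rng$sample(gnames, size = n_diag_genes,
                                  replace = FALSE))
    for (g in diag_genes) {
      posns <- sort(rng$sample(glist[[g]], size = n_diag_per_gene,
                               replace = FALSE))
      for (i in posns) {
        pair <- rng$sample(states, size = 2L, replace = FALSE)
        clade_state <- pair[1L]; background_state <- pair[2L]
        carry <- ifelse(is_member,
                        rng$runif(S) < fidelity,
                        rng$runif(S) < leakage)
        M[, i] <- ifelse(carry, clade_state, background_state)
        diag_tab <- rbind(diag_tab, data.frame(
          position = i, gene = g, clade_state = clade_state,
          background_state = background_state, stringsAsFactors = FALSE))
      }
    }
  }
  aln <- esl_alignment(M, alphabet)
  structure(list(
    aln = aln,
    classes = data.frame(taxon = taxa,
                         label = ifelse(is_member, "+1", "-1"),
                         stringsAsFactors = FALSE),
    groups = group_map(glist, p),
    truth = structure(list(clade = members, diag_positions = diag_tab,
                           diag_genes = diag_genes, fidelity = fidelity,
                           leakage = leakage, seed = as.integer(seed)),
                      class = "esl_truth")),
    class = "esl_simulation")
}

#' @export
print.esl_simulation <- function(x, ...) {
  cat(sprintf(
    "<esl_simulation> %d taxa x %d positions, %d genes | clade of %d | %d diagnostic gene(s)\n",
    nrow(x$aln), ncol(x$aln), length(x$groups$groups),
    length(x$truth$clade), length(x$truth$diag_genes)))
  invisible(x)
}

#' Write a simulation to disk
#'
#' FASTA alignment, RAxML-style partition file, taxon-class TSV and a truth
#' JSON, under `<prefix>.fasta/.partitions/.classes.tsv/.truth.json`.
#'
#' @param sim an `esl_simulation`.
#' @param prefix output path prefix.
#' @return Files written, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "esl_simulation"))
  fa <- paste0(prefix, ".fasta")
  write_alignment(sim$aln, fa)
  pf <- paste0(prefix, ".partitions")
  dtype <- if (attr(sim$aln, "alphabet") == "nucleotide") "DNA" else "WAG"
  lines <- vapply(names(sim$groups$groups), function(g) {
    ix <- sim$groups$groups[[g]]
    sprintf("%s, %s = %d-%d", dtype, g, min(ix), max(ix))
  }, character(1L))
  writeLines(lines, pf)
  cl <- paste0(prefix, ".classes.tsv")
  utils::write.table(sim$classes, cl, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tj <- paste0(prefix, ".truth.json")
  jsonlite::write_json(unclass(sim$truth), tj, auto_unbox = TRUE, digits = NA)
  invisible(c(fa, pf, cl, tj))
}
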