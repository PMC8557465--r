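# Shared fixture builders: everything is generated in code at test time.

# tiny hand-written nucleotide alignment
tiny_aln <- function() {
  esl_alignment(c(A = "ACGTACGTAC",
                  B = "ACGTACGAAC",
                  C = "TGGTACGTTC",
                  D = "TGGAACGTTC"), "nucleotide")
}

# write a FASTA string to a temp file, return the path
write_tmp_fasta <- function(records, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

# small planted-signal dataset used across solver/score/workflow tests:
# 30 taxa x 120 positions, 6 genes, one diagnostic gene
small_planted <- function(seed = 42, n_diag_genes = 1) {
  simulate_alignment(S = 30, p = 120, G = 6, n_diag_genes = n_diag_genes,
                     n_diag_per_gene = 6, clade_size = 8,
                     fidelity = 1, leakage = 0, seed = seed)
}

# encoded + balanced-response bundle for a simulation
prep_sim <- function(sim) {
  resp <- balance_response(build_response(rownames(sim$aln), sim$truth$clade))
  enc <- map_groups_to_bits(filter_monomorphic(one_hot_encode(sim$aln)),
                            sim$groups)
  list(enc = enc, resp = resp, lmax = lambda_max(enc, resp))
}

# default analysis lambdas: 1% / 2% of lambda_max (the package's standard
# operating point for these problem sizes)
default_opts <- function(lmax, ...) {
  fit_options(lambda1 = 0.01 * lmax, lambda2 = 0.02 * lmax, ...)
}

# brute-force AUC: Mann-Whitney pair counting with ties at 1/2
pair_auc <- function(scores, y) {
  pos <- scores[y > 0]; neg <- scores[y < 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
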