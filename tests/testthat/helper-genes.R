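# fixture builders used across test files

toy_gene <- function(y, n, gene_id = "g1") {
  ase_counts(gene_id, as.matrix(y), as.matrix(n))
}

# a balanced J x K gene with constant totals
flat_gene <- function(J = 2, K = 2, n = 20, y = NULL, gene_id = "g1") {
  nm <- matrix(n, J, K)
  if (is.null(y)) y <- matrix(round(n / 2), J, K)
  ase_counts(gene_id, y, nm)
}

# draw one random gene from the logistic mixed model
random_gene <- function(J, K, nmax = 50, beta = 0, s2s = 0, s2r = 0,
                        gene_id = "g1", nmin = 5) {
  n <- matrix(sample(nmin:nmax, J * K, replace = TRUE), J, K)
  S <- rnorm(J, 0, sqrt(s2s))
  R <- rnorm(K, 0, sqrt(s2r))
  p <- plogis(beta + outer(S, R, `+`))
  y <- matrix(rbinom(J * K, n, p), J, K)
  ase_counts(gene_id, y, n)
}

# swap maternal and paternal roles
swap_alleles <- function(gene) {
  ase_counts(gene$gene_id, gene$n - gene$y, gene$n, gene$snp_ids,
             gene$rep_ids, gene$observed)
}

# small genome as a dataset (list of random genes, all observed)
random_dataset <- function(G, J = 3, K = 4, nmax = 80,
                           beta = function() 0, s2s = function() 0,
                           s2r = function() 0) {
  genes <- lapply(seq_len(G), function(i)
    random_gene(J, K, nmax, beta(), s2s(), s2r(),
                gene_id = sprintf("g%04d", i)))
  ase_dataset(genes)
}

write_long_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
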