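# Shared fixture builders. Everything is generated in code; seeds are fixed
# by the caller so fixtures are reproducible.

unit_pair <- function() homeolog_pair("geneA", "geneB", 1, 1)

# a pair with unequal lengths for offset-sensitive checks
uneven_pair <- function() homeolog_pair("geneA", "geneB", 1.0, 2.5)

# random small fixture: unequal lengths and depths, counts guaranteed
# testable (resampled until both homeologs have at least one read)
rand_fixture <- function(seed, n = NULL, r = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:6, 1)
  if (is.null(r)) r <- runif(1, 2, 50)
  la <- runif(1, 0.3, 3); lb <- runif(1, 0.3, 3)
  d <- runif(n, 0.5, 4)
  lam <- runif(1, 5, 200); omega <- exp(runif(1, -1.5, 1.5))
  repeat {
    a <- rnbinom(n, size = r, mu = lam * la * d)
    b <- rnbinom(n, size = r, mu = omega * lam * lb * d)
    if (sum(a) >= 1 && sum(b) >= 1) break
  }
  list(pair = homeolog_pair("gA", "gB", la, lb),
       counts = count_set(a, b, depths = d),
       r = r, lam = lam, omega = omega, n = n)
}

# write a count table TSV for io/cli tests; counts: matrix with rownames
write_count_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
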