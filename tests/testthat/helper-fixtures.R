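# tiny raw count fixture: 4 endogenous, 2 housekeeping, 2 positive, 2 negative
tiny_raw <- function(n_samples = 3, seed = 42) {
  set.seed(seed)
  ids <- paste0("G", 1:4)
  m <- matrix(c(rpois(4 * n_samples, 200), rpois(2 * n_samples, 500),
                rpois(2 * n_samples, 1000), rpois(2 * n_samples, 2)),
              nrow = 10, byrow = TRUE)
  rownames(m) <- c(ids, "HK1", "HK2", "POS1", "POS2", "NEG1", "NEG2")
  colnames(m) <- paste0("S", seq_len(n_samples))
  raw_count_matrix(m, c(rep("endogenous", 4), rep("housekeeping", 2),
                        rep("positive", 2), rep("negative", 2)))
}

# small well-separated training matrix for NSC / centroid tests
toy_training <- function(n_per_class = 6, n_genes = 20, sep = 3, seed = 1) {
  set.seed(seed)
  st <- tnbc_subtypes()
  labels <- rep(st, each = n_per_class)
  block <- split(seq_len(n_genes), rep(st, length.out = n_genes))
  x <- matrix(rnorm(n_genes * length(labels), 8, 1), n_genes, length(labels))
  for (k in st) x[block[[k]], labels == k] <- x[block[[k]], labels == k] + sep
  rownames(x) <- sprintf("G%02d", seq_len(n_genes))
  colnames(x) <- sprintf("T%02d", seq_along(labels))
  list(x = x, labels = labels, block = block)
}

# centroids with orthogonal rank profiles, one block up per subtype
toy_centroids <- function(n_genes = 20) {
  st <- tnbc_subtypes()
  block <- split(seq_len(n_genes), rep(st, length.out = n_genes))
  ctr <- matrix(0.3, 4, n_genes,
                dimnames = list(st, sprintf("G%02d", seq_len(n_genes))))
  for (k in st) ctr[k, block[[k]]] <- seq(0.7, 0.95, length.out = length(block[[k]]))
  signature_centroids(ctr)
}
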