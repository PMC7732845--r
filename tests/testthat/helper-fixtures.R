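# Small shared fixtures for unit tests.

toyQuant <- function(n_prot = 6, n_ctrl = 3, n_case = 3, seed = 11,
                     condition = "syn", effect = NULL) {
  set.seed(seed)
  n <- n_ctrl + n_case
  m <- matrix(2^rnorm(n_prot * n, 10, 1), n_prot, n,
              dimnames = list(sprintf("P%02d", seq_len(n_prot)),
                              c(sprintf("c%d", seq_len(n_ctrl)),
                                sprintf("k%d", seq_len(n_case)))))
  if (!is.null(effect))
    m[seq_along(effect), n_ctrl + seq_len(n_case)] <-
      m[seq_along(effect), n_ctrl + seq_len(n_case)] * 2^effect
  QuantMatrix(m, c(rep("control", n_ctrl), rep("case", n_case)), condition)
}

# A small weighted graph with named vertices and confidence attribute.
toyGraph <- function(edges, confidence) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  igraph::E(g)$confidence <- confidence
  g
}

# Minimal DE table builder.
toyDE <- function(protein, log2FC, q, p = q / 2) {
  data.frame(protein = protein, log2FC = log2FC, t = sign(log2FC) * 3,
             p = p, q = q, direction = ifelse(log2FC >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}
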