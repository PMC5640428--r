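# Independent brute-force oracles used to cross-check the package
# implementations.  These deliberately avoid the code paths they verify.

# two-component Poisson mixture posterior, direct (non-log) evaluation
oracle_posterior <- function(x, lambda_bg, factor, prior = 0.5) {
  num <- prior * dpois(x, factor * lambda_bg)
  den <- num + (1 - prior) * dpois(x, lambda_bg)
  num / den
}

# adjacency matrix from an edge data frame over an explicit node set
oracle_adjacency <- function(edges, nodes) {
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$node_a[[i]])
    b <- as.character(edges$node_b[[i]])
    if (a != b) {
      A[a, b] <- 1L
      A[b, a] <- 1L
    }
  }
  A
}

# Watts-Strogatz local clustering by explicit triangle enumeration
oracle_local_clustering <- function(edges, nodes, node) {
  A <- oracle_adjacency(edges, nodes)
  nb <- nodes[A[node, ] == 1L]
  k <- length(nb)
  if (k < 2) return(0)
  tri <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (A[nb[[i]], nb[[j]]] == 1L) tri <- tri + 1L
    }
  }
  2 * tri / (k * (k - 1))
}

oracle_mean_degree <- function(edges, nodes) {
  mean(rowSums(oracle_adjacency(edges, nodes)))
}

# random simple undirected graph on n nodes as an edge tibble
random_edges <- function(n, p = 0.3) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  tibble::tibble(node_a = pairs[keep, 1], node_b = pairs[keep, 2])
}

# minimal single-purification observation builder
toy_observation <- function(prey_id, spectral_count, unique_peptides,
                            channel = "BAIT", antibody = "C_TERM",
                            age = "P50", replicate = 1L,
                            gene_symbol = prey_id) {
  tibble::tibble(
    prey_id = prey_id, gene_symbol = gene_symbol,
    purification_id = sprintf("%s_%s_R%d_%s", antibody, age, replicate,
                              channel),
    antibody = antibody, age = age, replicate = as.integer(replicate),
    channel = channel, spectral_count = as.integer(spectral_count),
    unique_peptides = as.integer(unique_peptides),
    protein_length = NA_integer_
  )
}

# profile-row builder for filter/tier unit tests
toy_profile <- function(prey_id, fold_ratio = 2, unique_peptides_max = 2,
                        replicate_presence = 1, n_conditions = 1,
                        maxp = 0.5, gene_symbol = prey_id,
                        psm_bait = 10, psm_control = 5) {
  tibble::tibble(
    prey_id = prey_id, gene_symbol = gene_symbol,
    psm_bait = psm_bait, psm_control = psm_control,
    fold_ratio = fold_ratio, unique_peptides_max = unique_peptides_max,
    replicate_presence = replicate_presence, n_conditions = n_conditions,
    maxp = maxp
  )
}
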