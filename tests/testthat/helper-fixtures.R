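# shared helpers: tiny graph builders and independent textbook oracles

# network from "A-B" style edge strings
net_from <- function(..., nodes = NULL, name = "test") {
  edges <- do.call(rbind, strsplit(c(...), "-", fixed = TRUE))
  interaction_network(edges, nodes = nodes, name = name)
}

path_abc <- function() net_from("A-B", "B-C")

# textbook Pearson correlation, written out from the definition
pearson_formula <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# textbook Spearman: Pearson on average ranks
spearman_formula <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) {
      sum(v < vi) + (1 + sum(v == vi)) / 2
    }, numeric(1))
  }
  pearson_formula(avg_rank(x), avg_rank(y))
}

# a small pool of seeded random graphs reused by the property tests
random_graph_pool <- function(n_graphs = 25L, n_min = 5L, n_max = 10L,
                              probs = c(0.2, 0.5), base_seed = 100L) {
  lapply(seq_len(n_graphs), function(g) {
    set.seed(base_seed + g)
    n <- sample(n_min:n_max, 1L)
    p <- sample(probs, 1L)
    random_disease_network(n, p, labels = c("X", "Y"),
                           dp_per_label = c(1L, 1L),
                           seed = base_seed + g)
  })
}
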