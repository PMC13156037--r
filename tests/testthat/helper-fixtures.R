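# Shared fixtures, built in code at test time.

# Three-level toy ontology over 8 genes with exactly computable ICs:
# root (8 genes) -> A (g1..g4), B (g5..g8); A -> A1 (g1..g2); B -> B1 (g5..g6).
toy_ontology <- function(namespace = "BP") {
  parents <- list(root = NULL, A = "root", B = "root", A1 = "A", B1 = "B")
  ann <- list(
    g1 = "A1", g2 = "A1", g3 = "A", g4 = "A",
    g5 = "B1", g6 = "B1", g7 = "B", g8 = "B"
  )
  build_ontology(parents, ann, namespace = namespace)
}

# Ten-gene chain GRN with mixed-sign weights (fixed, PD by diagonal dominance).
chain_grn <- function(panel = sprintf("g%02d", 1:10)) {
  w <- c(-0.35, 0.30, -0.25, 0.40, -0.30, 0.20, -0.45, 0.35, -0.20)
  data.frame(gene_a = panel[-length(panel)], gene_b = panel[-1], weight = w,
             stringsAsFactors = FALSE)
}

# Independent exact two-tailed sign-test p by binomial enumeration.
sign_test_oracle <- function(n_pos, n) {
  k <- min(n_pos, n - n_pos)
  tail <- sum(vapply(0:k, function(i) choose(n, i), numeric(1))) / 2^n
  min(1, 2 * tail)
}

# Brute-force local clustering coefficients via triangle enumeration.
local_cc_oracle <- function(nodes, edges) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    adj[edges$gene_a[r], edges$gene_b[r]] <- TRUE
    adj[edges$gene_b[r], edges$gene_a[r]] <- TRUE
  }
  vapply(nodes, function(v) {
    nb <- nodes[adj[v, ]]
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) if (adj[nb[i], nb[j]]) tri <- tri + 1
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# Floyd-Warshall mean shortest path over connected ordered pairs.
avg_path_oracle <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    d[edges$gene_a[r], edges$gene_b[r]] <- 1
    d[edges$gene_b[r], edges$gene_a[r]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# Independent truth-table oracle for the five rescue categories, written
# straight from the category definitions.
rescue_oracle <- function(mb, mp, db, dp, alpha = 0.06) {
  if (mp >= alpha) return(NA_character_)
  if (dp >= alpha) return("rescued")
  if (sign(db) != sign(mb)) return("over_corrected")
  if (abs(db) < abs(mb)) return("partial_rescue")
  if (dp <= mp && abs(db) > abs(mb)) return("exacerbated")
  "unchanged"
}

# Classic (weight 0) GSEA running-sum oracle by explicit step walk.
gsea_walk_oracle <- function(ordered_hits) {
  n <- length(ordered_hits)
  nh <- sum(ordered_hits)
  walk <- cumsum(ifelse(ordered_hits, 1 / nh, -1 / (n - nh)))
  walk[which.max(abs(walk))]
}
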