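#' Build a consensus co-expression network over resampled runs
#'
#' Stand-in for sparse-factor network reconstruction: over `n_runs` bootstrap
#' resamples of the pooled samples, genes are connected when the absolute
#' Pearson correlation of their expression meets `corr_min`; the consensus
#' keeps edges reappearing in at least a `dup_min` fraction of runs, carrying
#' each edge's duplication count. The builder is pluggable: any function
#' `f(expr_resampled)` returning a 2-column character matrix of edges can be
#' supplied.
#'
#' @param expr Samples x genes expression matrix (column names are gene ids)
#'   pooled across the KO subset and controls.
#' @param n_runs Number of resampled runs (default 40).
#' @param corr_min Absolute-correlation threshold for an edge (default 0.8).
#' @param dup_min Minimum duplication fraction to retain a consensus edge
#'   (default 0.5).
#' @param builder Optional custom per-run edge builder (see Details).
#' @param seed Integer seed governing the resampling.
#' @return A `gene_network`: list with `nodes`, `edges` (data frame `gene_a`,
#'   `gene_b`, `duplication_count`), `n_runs`, `unscorable` flag and builder
#'   metadata. Returned empty (and flagged) when no edge survives.
#' @export
build_consensus_network <- function(expr, n_runs = 40L, corr_min = 0.8,
                                    dup_min = 0.5, builder = NULL,
                                    seed = 1L) {
  n_runs <- .check_count(n_runs, "n_runs")
  if (nrow(expr) < 10) {
    warning("fewer than 10 pooled samples; consensus edges will be unstable",
            call. = FALSE)
  }
  genes <- colnames(expr)
  if (is.null(builder)) {
    builder <- function(x) {
      cm <- suppressWarnings(stats::cor(x))
      cm[is.na(cm)] <- 0
      hit <- which(abs(cm) >= corr_min & upper.tri(cm), arr.ind = TRUE)
      cbind(genes[hit[, 1]], genes[hit[, 2]])
    }
  }
  tally <- new.env(parent = emptyenv())
  .with_seed(seed, {
    for (run in seq_len(n_runs)) {
      idx <- sample.int(nrow(expr), replace = TRUE)
      ed <- builder(expr[idx, , drop = FALSE])
      if (is.null(ed) || nrow(ed) == 0) next
      keys <- ifelse(ed[, 1] < ed[, 2],
                     paste(ed[, 1], ed[, 2], sep = "\r"),
                     paste(ed[, 2], ed[, 1], sep = "\r"))
      for (k in unique(keys)) {
        tally[[k]] <- (if (is.null(tally[[k]])) 0L else tally[[k]]) + 1L
      }
    }
  })
  keys <- ls(tally)
  counts <- vapply(keys, function(k) tally[[k]], integer(1))
  keep <- counts / n_runs >= dup_min
  if (!any(keep)) {
    return(structure(list(nodes = character(0),
                          edges = data.frame(gene_a = character(0),
                                             gene_b = character(0),
                                             duplication_count = integer(0)),
                          n_runs = n_runs, unscorable = TRUE,
                          meta = list(method = "corr_bootstrap",
                                      corr_min = corr_min, dup_min = dup_min,
                                      seed = seed)),
                     class = "gene_network"))
  }
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  edges <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                      gene_b = vapply(parts, `[`, "", 2),
                      duplication_count = unname(counts[keep]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges, n_runs = n_runs, unscorable = FALSE,
                 meta = list(method = "corr_bootstrap", corr_min = corr_min,
                             dup_min = dup_min, seed = seed)),
            class = "gene_network")
}

#' Construct a gene network from an explicit edge list
#'
#' @param edges Data frame with `gene_a`, `gene_b` and optionally
#'   `duplication_count` (default 1 per edge).
#' @param n_runs Total number of reconstruction runs backing the duplication
#'   counts (default: max duplication count).
#' @param nodes Optional node set (defaults to genes touched by edges).
#' @return A `gene_network`.
#' @export
gene_network <- function(edges, n_runs = NULL, nodes = NULL) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  if (any(edges$gene_a == edges$gene_b)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (is.null(edges$duplication_count)) edges$duplication_count <- 1L
  if (is.null(n_runs)) n_runs <- max(edges$duplication_count, 1L)
  if (any(edges$duplication_count < 1) ||
      any(edges$duplication_count > n_runs)) {
    stop("duplication_count must lie in [1, n_runs]", call. = FALSE)
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  if (anyDuplicated(paste(a, b))) stop("duplicate edges", call. = FALSE)
  edges <- data.frame(gene_a = a, gene_b = b,
                      duplication_count = edges$duplication_count,
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(a, b)))
  structure(list(nodes = nodes, edges = edges, n_runs = n_runs,
                 unscorable = nrow(edges) == 0, meta = list(method = "manual")),
            class = "gene_network")
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Mean local clustering coefficient
#'
#' Average over all nodes of the local clustering coefficient; nodes of
#' degree < 2 contribute 0.
#'
#' @param net A `gene_network`.
#' @return Value in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  if (length(net$nodes) < 1) stop("network has no node", call. = FALSE)
  if (nrow(net$edges) == 0) return(0)
  g <- .as_igraph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(cc)
}

#' Average shortest-path length
#'
#' Mean shortest-path length over all connected ordered node pairs;
#' disconnected pairs are excluded and their count attached as attribute
#' `"n_excluded_pairs"`.
#'
#' @param net A `gene_network` with >= 2 nodes.
#' @return Mean path length (>= 1), or `NA` when no pair is connected.
#' @export
avg_path_length <- function(net) {
  if (length(net$nodes) < 2) stop("need >= 2 nodes", call. = FALSE)
  g <- .as_igraph(net)
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  conn <- off[is.finite(off)]
  res <- if (length(conn)) mean(conn) else NA_real_
  attr(res, "n_excluded_pairs") <- sum(!is.finite(off))
  res
}

#' Composite network-convergence score
#'
#' The network-level convergence score sums four components:
#' connectivity (mean clustering coefficient Cp), compactness relative to
#' the scored collection (`max_lp - Lp`, where `max_lp` is the largest
#' average path length across the collection), functional coherence (mean
#' over unordered node pairs of the summed MF + BP + CC semantic
#' similarities), and reproducibility (minimum edge duplication count over
#' retained edges divided by the number of runs).
#'
#' @param net A `gene_network`.
#' @param collection_max_lp Maximum average path length across the scored
#'   collection; values below this network's Lp are clipped to Lp (with a
#'   warning), making the path term 0. Defaults to this network's Lp.
#' @param semsim_scores Optional function `(gene_a, gene_b) -> numeric` or a
#'   symmetric named matrix giving the per-pair MF+BP+CC similarity sum;
#'   `NULL` scores the semantic term 0.
#' @return A `network_score` list: `cp`, `lp`, `max_lp`, `path_term`,
#'   `semsim_mean`, `dup_ratio`, `total` (the exact component sum), or `NA`
#'   total with a reason for an unscorable empty network.
#' @export
network_convergence_score <- function(net, collection_max_lp = NULL,
                                      semsim_scores = NULL) {
  if (isTRUE(net$unscorable) || nrow(net$edges) == 0) {
    return(structure(list(cp = NA_real_, lp = NA_real_, max_lp = NA_real_,
                          path_term = NA_real_, semsim_mean = NA_real_,
                          dup_ratio = NA_real_, total = NA_real_,
                          reason = "empty network"),
                     class = "network_score"))
  }
  cp <- clustering_coefficient(net)
  lp <- as.numeric(avg_path_length(net))
  if (is.null(collection_max_lp)) collection_max_lp <- lp
  if (!is.na(lp) && collection_max_lp < lp) {
    warning("collection_max_lp below this network's Lp; clipped", call. = FALSE)
    collection_max_lp <- lp
  }
  path_term <- collection_max_lp - lp
  semsim_mean <- 0
  if (!is.null(semsim_scores)) {
    pairs <- utils::combn(net$nodes, 2, simplify = FALSE)
    vals <- vapply(pairs, function(pr) {
      if (is.function(semsim_scores)) {
        semsim_scores(pr[1], pr[2])
      } else {
        semsim_scores[pr[1], pr[2]]
      }
    }, numeric(1))
    semsim_mean <- mean(vals, na.rm = TRUE)
  }
  dup_ratio <- min(net$edges$duplication_count) / net$n_runs
  structure(list(cp = cp, lp = lp, max_lp = collection_max_lp,
                 path_term = path_term, semsim_mean = semsim_mean,
                 dup_ratio = dup_ratio,
                 total = cp + path_term + semsim_mean + dup_ratio),
            class = "network_score")
}
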