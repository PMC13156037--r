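#' Build an ontology object from parent links and annotations
#'
#' Stores a rooted DAG of terms, gene annotations closed under the true-path
#' rule (every annotation propagated to all ancestors), and per-term
#' information content
#' \deqn{IC(t) = -\log(n_{annotated}(t) / n_{total}),}
#' natural log, so the root (annotating every gene) has IC 0.
#'
#' @param parents Named list: term -> character vector of parent terms
#'   (the root has no parents / `NULL`). Must be acyclic with a single root.
#' @param annotations Named list: gene -> character vector of directly
#'   annotated terms (propagation to ancestors is applied here).
#' @param namespace Namespace label (`"BP"`, `"CC"`, `"MF"` or synthetic).
#' @return An `ontology` object: list with `terms`, `parents`, `ancestors`
#'   (term -> ancestors including self), `root`, `annotations`
#'   (ancestor-closed, every gene annotated to the root),
#'   `direct_annotations` (as given, used for gene-level similarity),
#'   `gene_count`
#'   (term -> annotated genes), `ic`, `n_genes`, `namespace`.
#' @export
build_ontology <- function(parents, annotations, namespace = "BP") {
  terms <- names(parents)
  if (is.null(terms)) stop("`parents` must be a named list", call. = FALSE)
  roots <- terms[vapply(parents, function(p) length(p) == 0, logical(1))]
  if (length(roots) != 1) {
    stop("ontology must have exactly one root", call. = FALSE)
  }
  for (p in unlist(parents)) {
    if (!p %in% terms) stop("unknown parent term: ", p, call. = FALSE)
  }
  # Ancestor closure; cycle detection via bounded walk.
  anc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    seen <- character(0)
    frontier <- t
    steps <- 0L
    while (length(frontier)) {
      steps <- steps + 1L
      if (steps > length(terms) + 1L) {
        stop("ontology contains a cycle involving term ", t, call. = FALSE)
      }
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parents[frontier])), seen)
    }
    anc[[t]] <- seen
  }
  genes <- names(annotations)
  direct <- lapply(annotations, function(ts) unique(intersect(ts, terms)))
  closed <- lapply(direct, function(ts) unique(c(unlist(anc[ts]), roots)))
  gene_count <- stats::setNames(integer(length(terms)), terms)
  for (ts in closed) gene_count[ts] <- gene_count[ts] + 1L
  n_genes <- length(genes)
  ic <- ifelse(gene_count > 0, -log(gene_count / n_genes), NA_real_)
  names(ic) <- terms
  structure(list(terms = terms, parents = parents, ancestors = anc,
                 root = roots, annotations = closed,
                 direct_annotations = direct,
                 gene_count = gene_count, ic = ic, n_genes = n_genes,
                 namespace = namespace),
            class = "ontology")
}

#' Information content of ontology terms
#'
#' @param ontology An `ontology` from [build_ontology()].
#' @return Named numeric vector of per-term IC (natural log); terms
#'   annotating no gene are `NA` and excluded from similarity comparisons.
#' @export
information_content <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  ontology$ic
}

#' Semantic similarity between two ontology terms
#'
#' Lin similarity: `2 * IC(MICA) / (IC(t1) + IC(t2))`, where MICA is the
#' maximum-IC common ancestor. Resnik similarity (`IC(MICA)` normalized by
#' the corpus maximum IC) is available as an alternative. Self-similarity is
#' 1 for terms of positive IC; when both ICs are 0 the similarity is 1 for
#' identical terms and 0 otherwise.
#'
#' @param ontology An `ontology`.
#' @param t1,t2 Term ids.
#' @param method `"lin"` (default) or `"resnik"`.
#' @return Similarity in `[0, 1]`, symmetric in its arguments.
#' @export
term_similarity <- function(ontology, t1, t2, method = c("lin", "resnik")) {
  method <- match.arg(method)
  ic <- ontology$ic
  if (is.na(ic[[t1]]) || is.na(ic[[t2]])) {
    stop("both terms must have defined IC", call. = FALSE)
  }
  common <- intersect(ontology$ancestors[[t1]], ontology$ancestors[[t2]])
  common <- common[!is.na(ic[common])]
  mica_ic <- if (length(common)) max(ic[common]) else 0
  if (method == "lin") {
    denom <- ic[[t1]] + ic[[t2]]
    if (denom == 0) return(if (identical(t1, t2)) 1 else 0)
    2 * mica_ic / denom
  } else {
    max_ic <- max(ic, na.rm = TRUE)
    if (max_ic == 0) return(if (identical(t1, t2)) 1 else 0)
    mica_ic / max_ic
  }
}

# Best-match-average similarity between two genes' term sets.
.gene_bma <- function(ontology, terms_a, terms_b, method = "lin") {
  terms_a <- terms_a[!is.na(ontology$ic[terms_a])]
  terms_b <- terms_b[!is.na(ontology$ic[terms_b])]
  if (!length(terms_a) || !length(terms_b)) return(NA_real_)
  m <- outer(terms_a, terms_b,
             Vectorize(function(x, y) term_similarity(ontology, x, y, method)))
  m <- matrix(m, nrow = length(terms_a))
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

#' Semantic similarity between gene sets
#'
#' Gene-to-gene similarity is the best-match average (BMA) over the pairwise
#' term-similarity matrix of the two genes' directly annotated terms (the
#' ancestor-closed sets would trivially share the root and inflate every
#' similarity). For two distinct
#' gene sets the result averages over all cross pairs; for a single KO set
#' (identical arguments) it averages over all unordered pairs of distinct
#' genes (a singleton set scores its self-similarity). Genes without any
#' annotation in the namespace are dropped with a warning.
#'
#' @param genes_a,genes_b Character vectors of gene ids.
#' @param ontology An `ontology`.
#' @param method Term-similarity method passed to [term_similarity()].
#' @return Similarity in `[0, 1]`, or `NA` when no annotated pair remains.
#' @export
geneset_similarity <- function(genes_a, genes_b, ontology, method = "lin") {
  stopifnot(inherits(ontology, "ontology"))
  keep <- function(gs) {
    ann <- gs %in% names(ontology$annotations)
    if (any(!ann)) {
      warning("dropping unannotated gene(s): ",
              paste(gs[!ann], collapse = ", "), call. = FALSE)
    }
    gs[ann]
  }
  genes_a <- unique(keep(genes_a)); genes_b <- unique(keep(genes_b))
  if (!length(genes_a) || !length(genes_b)) return(NA_real_)
  same_set <- setequal(genes_a, genes_b)
  ann <- ontology$direct_annotations
  if (same_set && length(genes_a) == 1) {
    return(.gene_bma(ontology, ann[[genes_a]], ann[[genes_a]], method))
  }
  vals <- c()
  if (same_set) {
    gs <- sort(unique(genes_a))
    for (i in seq_along(gs)) {
      for (j in seq_along(gs)) {
        if (j <= i) next
        vals <- c(vals, .gene_bma(ontology, ann[[gs[i]]], ann[[gs[j]]],
                                  method))
      }
    }
  } else {
    for (a in genes_a) {
      for (b in genes_b) {
        vals <- c(vals, .gene_bma(ontology, ann[[a]], ann[[b]], method))
      }
    }
  }
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Brain co-expression similarity of a KO gene set
#'
#' Mean pairwise Pearson correlation between the KO genes' expression
#' vectors in a reference brain expression matrix.
#'
#' @param ko_genes Character vector of KO gene ids (>= 2 must be present in
#'   the reference).
#' @param reference_expr Genes x samples expression matrix (rownames are
#'   gene ids).
#' @return Mean pairwise correlation in `[-1, 1]`; `NA` when fewer than 2 KO
#'   genes are present.
#' @export
brain_coexpression_score <- function(ko_genes, reference_expr) {
  present <- ko_genes %in% rownames(reference_expr)
  if (any(!present)) {
    warning("KO gene(s) absent from reference: ",
            paste(ko_genes[!present], collapse = ", "), call. = FALSE)
  }
  ko_genes <- ko_genes[present]
  if (length(ko_genes) < 2) return(NA_real_)
  cm <- stats::cor(t(reference_expr[ko_genes, , drop = FALSE]))
  mean(cm[upper.tri(cm)])
}

#' Assemble the similarity feature vector for a KO set
#'
#' Predictor features for convergence-strength modeling: semantic similarity
#' of the KO genes in each of three ontology namespaces (BP/CC/MF),
#' their brain co-expression correlation, the set size and the cell type.
#'
#' @param ko_set Character vector of KO gene ids.
#' @param ontologies Named list of `ontology` objects; names used as the
#'   namespace keys (typically `bp`, `cc`, `mf`).
#' @param reference_expr Reference expression matrix for
#'   [brain_coexpression_score()].
#' @param cell_type Cell-type label carried through to the feature row.
#' @return One-row data frame with columns `bp_score`, `cc_score`,
#'   `mf_score`, `brain_expr_corr`, `n_kos`, `cell_type` (missing namespaces
#'   yield `NA`).
#' @export
ko_similarity_features <- function(ko_set, ontologies, reference_expr,
                                   cell_type) {
  get_ns <- function(key) {
    ont <- ontologies[[key]]
    if (is.null(ont)) return(NA_real_)
    suppressWarnings(geneset_similarity(ko_set, ko_set, ont))
  }
  data.frame(
    bp_score = get_ns("bp"),
    cc_score = get_ns("cc"),
    mf_score = get_ns("mf"),
    brain_expr_corr = suppressWarnings(
      brain_coexpression_score(ko_set, reference_expr)),
    n_kos = length(ko_set),
    cell_type = cell_type,
    stringsAsFactors = FALSE
  )
}
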