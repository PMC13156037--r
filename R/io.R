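# Plain-TSV readers/writers for the pipeline's exchange formats.

#' Write / read DEG summary tables
#'
#' TSV with columns `ko_id`, `cell_type`, `gene_id`, `log2fc`, `se`,
#' `pvalue`, `n`; multiple tables are concatenated and split back on
#' (`ko_id`, `cell_type`).
#'
#' @param tables Named list of DEG data frames.
#' @param path File path.
#' @return `read_deg_tables()` returns a named list of DEG tables.
#' @export
write_deg_tables <- function(tables, path) {
  all <- do.call(rbind, tables)
  utils::write.table(all, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_tables
#' @export
read_deg_tables <- function(path) {
  all <- utils::read.delim(path, stringsAsFactors = FALSE)
  key <- paste(all$ko_id, all$cell_type, sep = ".")
  split(all, factor(key, levels = unique(key)))
}

#' Write / read GRN edge lists
#'
#' TSV with columns `context`, `gene_a`, `gene_b`, `weight`; read back as
#' the named per-context list [assemble_lnctp()] consumes.
#'
#' @param grn Named list of edge data frames.
#' @param path File path.
#' @return `read_grn()` returns the named list form.
#' @export
write_grn <- function(grn, path) {
  rows <- lapply(names(grn), function(ctx) {
    ed <- grn[[ctx]]
    if (is.null(ed) || nrow(ed) == 0) return(NULL)
    data.frame(context = ctx, gene_a = ed$gene_a, gene_b = ed$gene_b,
               weight = if (is.null(ed$weight)) -0.25 else ed$weight,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_grn
#' @export
read_grn <- function(path) {
  all <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(all, factor(all$context, levels = unique(all$context))),
         function(d) d[, c("gene_a", "gene_b", "weight")])
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional per-set description column (defaults to the
#'   set names).
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(gene_sets)
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1))
}
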