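#' Gene model constructor
#'
#' Exon structure of one gene. Coordinates are 0-based, half-open base pairs;
#' introns are derived as the gaps between consecutive exons.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of exon intervals; they must
#'   be disjoint and are sorted internally.
#' @return An object of class `"gene_model"` with derived `introns`.
#' @examples
#' gene_model("g1", "chrX", "+", rbind(c(0, 100), c(200, 300)))
#' @export
gene_model <- function(gene_id, chromosome = "chrU", strand = "+", exons) {
  exons <- matrix(as.numeric(exons), ncol = 2)
  if (any(exons[, 2] <= exons[, 1]))
    stop("exon end must exceed exon start (0-based half-open)")
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("exons overlap in gene ", gene_id)
  introns <- if (nrow(exons) > 1)
    cbind(exons[-nrow(exons), 2], exons[-1, 1]) else
    matrix(numeric(0), ncol = 2)
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 exons = exons, introns = introns,
                 span = c(exons[1, 1], exons[nrow(exons), 2])),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "on", x$chromosome, x$strand,
      "with", nrow(x$exons), "exon(s),", nrow(x$introns), "intron(s)\n")
  invisible(x)
}

#' Count introns fully contained in an interval
#'
#' @param model A [gene_model()].
#' @param interval Numeric `c(start, end)`, 0-based half-open.
#' @return Integer count of introns with both ends inside the interval.
#' @export
introns_in_interval <- function(model, interval) {
  if (interval[2] < interval[1])
    stop("inverted interval: end precedes start")
  if (nrow(model$introns) == 0) return(0L)
  sum(model$introns[, 1] >= interval[1] & model$introns[, 2] <= interval[2])
}

#' Paralog hit record
#'
#' @param child_id,parent_id Gene identifiers.
#' @param child_start,child_end,parent_start,parent_end Aligned intervals on
#'   the child and parent (0-based half-open bp).
#' @param e_value Alignment e-value (> 0).
#' @return A one-row data.frame.
#' @export
paralog_hit <- function(child_id, parent_id, child_start, child_end,
                        parent_start, parent_end, e_value) {
  if (e_value <= 0) stop("e_value must be > 0")
  if (child_end <= child_start || parent_end <= parent_start)
    stop("aligned intervals must be non-empty")
  data.frame(child_id = child_id, parent_id = parent_id,
             child_start = child_start, child_end = child_end,
             parent_start = parent_start, parent_end = parent_end,
             e_value = e_value)
}

#' Classify the origin mechanism of a young gene
#'
#' A gene with no paralog hit at `e_value <= evalue_cutoff` and no annotated
#' paralog is de novo. Otherwise the best hit (lowest e-value; ties broken by
#' longer aligned span on the child, then lexical parent id) is examined: the
#' gene is a retrogene when the parent carries at least one intron fully
#' inside its aligned interval while the child has none inside its own;
#' every other configuration is a DNA-level duplicate. A gene whose only
#' paralog evidence is an annotation (no alignment to test the intron rule)
#' is conservatively a DNA-level duplicate.
#'
#' @param child A [gene_model()].
#' @param hits data.frame of [paralog_hit()] rows for this child (may be
#'   pre-filtered; filtering at `evalue_cutoff` is applied internally too).
#' @param parents Named list of [gene_model()]s covering every parent id.
#' @param has_annotated_paralog Logical flag from an external annotation.
#' @param evalue_cutoff Maximum e-value for a hit to count (default 1e-6).
#' @return One of `"dna_duplicate"`, `"retrogene"`, `"de_novo"`.
#' @export
classify_origin <- function(child, hits = NULL, parents = list(),
                            has_annotated_paralog = FALSE,
                            evalue_cutoff = 1e-6) {
  if (!is.null(hits) && nrow(hits) > 0)
    hits <- hits[hits$e_value <= evalue_cutoff, , drop = FALSE]
  if (is.null(hits) || nrow(hits) == 0)
    return(if (has_annotated_paralog) "dna_duplicate" else "de_novo")
  span <- hits$child_end - hits$child_start
  ord <- order(hits$e_value, -span, hits$parent_id)
  best <- hits[ord[1], ]
  parent <- parents[[best$parent_id]]
  if (is.null(parent))
    stop("best hit references unknown parent gene '", best$parent_id, "'")
  parent_introns <- introns_in_interval(parent,
                                        c(best$parent_start, best$parent_end))
  child_introns <- introns_in_interval(child,
                                       c(best$child_start, best$child_end))
  if (parent_introns >= 1 && child_introns == 0) "retrogene" else "dna_duplicate"
}

#' Classify many genes at once
#'
#' @param children Named list of [gene_model()]s (the young genes).
#' @param hits_table data.frame with [paralog_hit()] columns, pooled over all
#'   children.
#' @param parents Named list of [gene_model()]s for candidate parents.
#' @param annotated Character vector of child ids with an annotated paralog.
#' @param evalue_cutoff Passed to [classify_origin()].
#' @return data.frame with `gene_id` and `mechanism`.
#' @export
classify_origins <- function(children, hits_table = NULL, parents = list(),
                             annotated = character(0), evalue_cutoff = 1e-6) {
  mech <- vapply(names(children), function(id) {
    h <- if (!is.null(hits_table))
      hits_table[hits_table$child_id == id, , drop = FALSE] else NULL
    classify_origin(children[[id]], h, parents,
                    has_annotated_paralog = id %in% annotated,
                    evalue_cutoff = evalue_cutoff)
  }, character(1))
  data.frame(gene_id = names(children), mechanism = unname(mech))
}

#' Read gene models from an exon-table TSV
#'
#' Expects columns `gene_id`, `chromosome`, `strand`, `exon_start`,
#' `exon_end` (one row per exon, 0-based half-open).
#'
#' @param path TSV path.
#' @return Named list of [gene_model()]s.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(df)))
    stop("schema error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  out <- lapply(split(df, df$gene_id), function(g)
    gene_model(g$gene_id[1], g$chromosome[1], g$strand[1],
               cbind(g$exon_start, g$exon_end)))
  out[unique(df$gene_id)]
}

#' Write gene models to an exon-table TSV
#' @param models Named list of [gene_model()]s.
#' @param path Output TSV path.
#' @export
write_gene_models <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m)
    data.frame(gene_id = m$gene_id, chromosome = m$chromosome,
               strand = m$strand, exon_start = m$exons[, 1],
               exon_end = m$exons[, 2])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
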