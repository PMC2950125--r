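#' Genome partition constructor
#'
#' Per-gene chromosomal class (X vs autosome), optional X stratum and
#' position. Strata ids (1-5, PAR1, PAR2, or `undefined`) are only allowed
#' on X-linked genes.
#'
#' @param gene_id Character vector of gene ids.
#' @param class Character vector, `"X"` or `"autosome"`.
#' @param stratum Optional stratum id per gene (`NA` off the X).
#' @param position Optional position (bp).
#' @return A validated data.frame of class `"genome_partition"`.
#' @export
genome_partition <- function(gene_id, class, stratum = NA, position = NA) {
  if (anyDuplicated(gene_id)) stop("duplicate gene id in partition")
  if (!all(class %in% c("X", "autosome")))
    stop("class must be 'X' or 'autosome'")
  df <- data.frame(gene_id = as.character(gene_id), class = class,
                   stratum = as.character(stratum), position = position,
                   stringsAsFactors = FALSE)
  ok <- is.na(df$stratum) |
    df$stratum %in% c("1", "2", "3", "4", "5", "PAR1", "PAR2", "undefined")
  if (!all(ok)) stop("unknown stratum id: ", df$stratum[!ok][1])
  if (any(!is.na(df$stratum) & df$class != "X"))
    stop("stratum ids are only defined for X-linked genes")
  class(df) <- c("genome_partition", class(df))
  df
}

merge_partition <- function(assignments, partition) {
  miss <- setdiff(assignments$gene_id, partition$gene_id)
  if (length(miss))
    stop("genes assigned but missing from the partition: ",
         paste(utils::head(miss, 3), collapse = ", "))
  merge(assignments, as.data.frame(partition), by = "gene_id")
}

#' Per-branch X-linked share of gene gains
#'
#' For every branch, the proportion of genes originating there that are
#' X-linked, with the branch midpoint age attached. Branches with zero gains
#' get an undefined (NA) share rather than 0.
#'
#' @param assignments Assignment data.frame from [assign_genome()].
#' @param partition A [genome_partition()] covering every assigned gene.
#' @param ladder The [branch_ladder()] used for dating.
#' @return data.frame: `branch`, `midpoint`, `n`, `n_x`, `x_share`.
#' @export
branch_proportions <- function(assignments, partition, ladder) {
  d <- merge_partition(assignments, partition)
  B <- ladder$n_branches - 1L
  br <- factor(d$branch, levels = 0:B)
  n <- as.integer(table(br))
  n_x <- as.integer(table(br[d$class == "X"]))
  data.frame(branch = 0:B, midpoint = ladder$branches$midpoint,
             n = n, n_x = n_x,
             x_share = ifelse(n > 0, n_x / n, NA_real_))
}

#' Male-biased proportion by branch and chromosome class
#'
#' Proportion of male-biased genes among assayed genes, per branch,
#' separately for the X chromosome and autosomes, with an (unweighted)
#' least-squares regression of the proportion on branch midpoint age per
#' class. Branch/class points covered by fewer than `min_covered` assayed
#' genes are omitted.
#'
#' @param bias_calls data.frame from [call_sex_bias()].
#' @param assignments Assignment data.frame from [assign_genome()].
#' @param partition A [genome_partition()].
#' @param ladder The [branch_ladder()].
#' @param min_covered Minimum assayed genes per point (default 5).
#' @return List: `points` (branch, midpoint, class, n_assayed, n_male,
#'   prop_male) and `fits` (class, intercept, slope).
#' @export
bias_by_age <- function(bias_calls, assignments, partition, ladder,
                        min_covered = 5) {
  d <- merge_partition(assignments, partition)
  d <- merge(d, bias_calls[c("gene_id", "call")], by = "gene_id")
  d <- d[d$call != "not_assayed", , drop = FALSE]
  mids <- branch_midpoints(ladder)
  agg <- do.call(rbind, lapply(split(d, list(d$branch, d$class), drop = TRUE),
    function(g) data.frame(branch = g$branch[1],
                           midpoint = unname(mids[as.character(g$branch[1])]),
                           class = g$class[1],
                           n_assayed = nrow(g),
                           n_male = sum(g$call == "male"))))
  agg <- agg[agg$n_assayed >= min_covered, , drop = FALSE]
  agg$prop_male <- agg$n_male / agg$n_assayed
  agg <- agg[order(agg$class, agg$branch), ]
  rownames(agg) <- NULL
  fits <- do.call(rbind, lapply(split(agg, agg$class), function(g) {
    if (nrow(g) < 2)
      return(data.frame(class = g$class[1], intercept = NA_real_,
                        slope = NA_real_))
    co <- stats::coef(stats::lm(prop_male ~ midpoint, data = g))
    data.frame(class = g$class[1], intercept = unname(co[1]),
               slope = unname(co[2]))
  }))
  rownames(fits) <- NULL
  list(points = agg, fits = fits)
}

#' Sex-bias contingency table for a gene subset
#'
#' Builds the 2 x 3 table (X/autosome by male/female/unbiased, not-assayed
#' genes excluded) for a subset of genes — e.g. all genes originating in one
#' branch — and tests it with the chi-square test of independence.
#'
#' @param gene_ids Character vector defining the subset.
#' @param partition A [genome_partition()].
#' @param bias_calls data.frame from [call_sex_bias()].
#' @return List with `table` (a [contingency_table()]) and `test`
#'   (a [test_result()]).
#' @export
bias_contingency <- function(gene_ids, partition, bias_calls) {
  if (length(gene_ids) == 0) stop("empty gene subset")
  d <- merge(data.frame(gene_id = gene_ids),
             as.data.frame(partition), by = "gene_id")
  d <- merge(d, bias_calls[c("gene_id", "call")], by = "gene_id")
  d <- d[d$call %in% c("male", "female", "unbiased"), , drop = FALSE]
  if (nrow(d) == 0) stop("no assayed genes left in the subset")
  tab <- table(factor(d$class, levels = c("X", "autosome")),
               factor(d$call, levels = c("male", "female", "unbiased")))
  ct <- contingency_table(unclass(as.matrix(tab)),
                          row_labels = c("X", "autosome"),
                          col_labels = c("male", "female", "unbiased"))
  list(table = ct, test = chi_square_independence(ct))
}

#' Expression presence across spermatogenesis stages
#'
#' For each stage (cell type) and age class, the proportion of genes called
#' present — `present / (present + absent)`, ambiguous excluded — on the X
#' and on autosomes, with a chi-square test of the X-vs-autosome 2 x 2
#' present/absent table. Stages with no informative gene in a class are
#' flagged undefined.
#'
#' @param presence Long data.frame: `gene_id`, `stage`, `call` (consensus
#'   calls, `present`/`absent`/`ambiguous`).
#' @param young Logical vector or data.frame(gene_id, young) flagging young
#'   genes; bare vectors must be named by gene id.
#' @param partition A [genome_partition()].
#' @return data.frame with one row per stage x age class: counts,
#'   proportions, chi-square p and an `undefined` flag.
#' @export
stage_presence_table <- function(presence, young, partition) {
  if (is.data.frame(young)) {
    yv <- stats::setNames(young$young, young$gene_id)
  } else yv <- young
  d <- merge(presence, as.data.frame(partition), by = "gene_id")
  d$age_class <- ifelse(yv[d$gene_id], "young", "old")
  d <- d[d$call %in% c("present", "absent"), , drop = FALSE]
  empty <- data.frame(stage = character(0), age_class = character(0),
                      x_present = integer(0), x_absent = integer(0),
                      x_prop = numeric(0), auto_present = integer(0),
                      auto_absent = integer(0), auto_prop = numeric(0),
                      p_value = numeric(0), undefined = logical(0))
  if (nrow(d) == 0) return(empty)
  out <- do.call(rbind, lapply(split(d, list(d$stage, d$age_class),
                                     drop = TRUE), function(g) {
    xs <- g[g$class == "X", ]; as_ <- g[g$class == "autosome", ]
    xp <- sum(xs$call == "present"); xa <- sum(xs$call == "absent")
    ap <- sum(as_$call == "present"); aa <- sum(as_$call == "absent")
    undef_x <- (xp + xa) == 0; undef_a <- (ap + aa) == 0
    p <- NA_real_
    if (!undef_x && !undef_a && (xp + ap) > 0 && (xa + aa) > 0) {
      tt <- contingency_table(rbind(X = c(xp, xa), autosome = c(ap, aa)),
                              col_labels = c("present", "absent"))
      p <- chi_square_independence(tt)$p_value
    }
    data.frame(stage = g$stage[1], age_class = g$age_class[1],
               x_present = xp, x_absent = xa,
               x_prop = if (undef_x) NA_real_ else xp / (xp + xa),
               auto_present = ap, auto_absent = aa,
               auto_prop = if (undef_a) NA_real_ else ap / (ap + aa),
               p_value = p, undefined = undef_x || undef_a)
  }))
  rownames(out) <- NULL
  out
}

#' Signed-log enrichment heatmap of X vs autosome expression
#'
#' For each branch x tissue cell, a Fisher exact test of whether the X
#' chromosome and autosomes have the same proportion of genes expressed in
#' that tissue. The cell score is -log10(p), given a positive sign when the
#' X-linked expressed proportion exceeds the autosomal one and a negative
#' sign otherwise, and clamped symmetrically at `±clamp`. Tissues are
#' ordered by average-linkage hierarchical clustering on the Euclidean
#' distance between score columns.
#'
#' @param presence Long data.frame: `gene_id`, `tissue`, `call`.
#' @param assignments Assignment data.frame from [assign_genome()].
#' @param partition A [genome_partition()].
#' @param clamp Symmetric score bound (default 8).
#' @return List: `scores` (branch x tissue matrix), `tissue_order`,
#'   `clustering` (an `hclust`, or NULL with < 3 tissues).
#' @export
enrichment_heatmap <- function(presence, assignments, partition, clamp = 8) {
  d <- merge(presence, merge_partition(assignments, partition),
             by = "gene_id")
  d <- d[d$call %in% c("present", "absent"), , drop = FALSE]
  branches <- sort(unique(assignments$branch))
  tissues <- sort(unique(presence$tissue))
  scores <- matrix(NA_real_, length(branches), length(tissues),
                   dimnames = list(branches, tissues))
  for (b in branches) for (ts in tissues) {
    g <- d[d$branch == b & d$tissue == ts, ]
    xp <- sum(g$class == "X" & g$call == "present")
    xa <- sum(g$class == "X" & g$call == "absent")
    ap <- sum(g$class == "autosome" & g$call == "present")
    aa <- sum(g$class == "autosome" & g$call == "absent")
    if (xp + xa == 0 || ap + aa == 0) next  # cell stays flagged NA
    p <- fisher_exact(rbind(c(xp, xa), c(ap, aa)))$p_value
    sgn <- sign(xp / (xp + xa) - ap / (ap + aa))
    scores[as.character(b), ts] <- max(-clamp, min(clamp, sgn * -log10(p)))
  }
  clustering <- NULL
  ord <- tissues
  if (length(tissues) >= 3) {
    dd <- stats::dist(t(scores))
    if (!any(is.na(dd))) {
      clustering <- stats::hclust(dd, method = "average")
      ord <- tissues[clustering$order]
    }
  }
  list(scores = scores, tissue_order = ord, clustering = clustering)
}

#' Association between evolutionary strata and gene age on the X
#'
#' Cross-tabulates X-linked genes by stratum age (old strata 1-3 vs young
#' strata 4-5; PAR and undefined excluded) against gene age (old vs young)
#' and applies a one-sided Fisher exact test for the association of old
#' strata with old genes.
#'
#' @param assignments Assignment data.frame from [assign_genome()].
#' @param partition A [genome_partition()] with stratum ids on X genes.
#' @param young Named logical vector (or data.frame gene_id/young).
#' @return List with `table` and `test`.
#' @export
strata_age_association <- function(assignments, partition, young) {
  if (is.data.frame(young)) young <- stats::setNames(young$young, young$gene_id)
  d <- merge_partition(assignments, partition)
  d <- d[d$class == "X" & d$stratum %in% c("1", "2", "3", "4", "5"), ,
         drop = FALSE]
  if (nrow(d) == 0) stop("no X-linked genes with a defined stratum")
  d$strata_class <- ifelse(d$stratum %in% c("1", "2", "3"),
                           "old_strata", "young_strata")
  d$age_class <- ifelse(young[d$gene_id], "young_gene", "old_gene")
  if (length(unique(d$strata_class)) < 2)
    stop("empty stratum class: need genes in both old and young strata")
  if (length(unique(d$age_class)) < 2)
    stop("empty age class: need both old and young genes")
  tab <- table(factor(d$strata_class, c("old_strata", "young_strata")),
               factor(d$age_class, c("old_gene", "young_gene")))
  ct <- contingency_table(unclass(as.matrix(tab)),
                          row_labels = c("old_strata", "young_strata"),
                          col_labels = c("old_gene", "young_gene"))
  list(table = ct, test = fisher_exact(ct, sided = "one_greater"))
}

#' Read a strata/PAR region map from BED
#'
#' BED columns chrom, start, end, name where name is the stratum id.
#' @param path BED file path.
#' @return data.frame chrom/start/end/stratum.
#' @export
read_region_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("schema error in ", path, ": BED needs 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "stratum")
  df
}

#' Look up the stratum of X positions in a region map
#' @param positions Numeric positions (bp) on the X.
#' @param map data.frame from [read_region_map()].
#' @return Character stratum ids (`"undefined"` outside any region).
#' @export
stratum_of <- function(positions, map) {
  vapply(positions, function(p) {
    hit <- which(map$start <= p & p < map$end)
    if (length(hit)) as.character(map$stratum[hit[1]]) else "undefined"
  }, character(1))
}
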