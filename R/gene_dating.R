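#' Species-ladder constructor
#'
#' A branch ladder is an ordered sequence of speciation splits along the
#' focal lineage. Branch `i` (i = 0..B) is the interval between split `i`
#' (where the outgroup clade `outgroups[[i + 1]]` diverged) and split `i + 1`;
#' branch `B` is the focal-species-specific terminal interval. A gene
#' originating in branch `b` is carried by every outgroup joining at splits
#' `>= b` and absent from deeper outgroups. Branch ages are megayears before
#' present, stored as negative numbers; the midpoint of the oldest branch
#' (branch 0) is fixed at `-root_age` by convention.
#'
#' @param outgroups List of character vectors, one per split in root-to-tip
#'   order: `outgroups[[i]]` is the clade joining at the split that closes
#'   branch `i - 1` (R is 1-based; list element i corresponds to branch
#'   index i - 1).
#' @param split_ages Positive ages (myr before present) of the splits,
#'   strictly decreasing, same length as `outgroups`.
#' @param focal Name of the focal species (not part of the evidence).
#' @param root_age Display age assigned to the midpoint of branch 0
#'   (default 500 myr).
#' @return An object of class `"branch_ladder"`.
#' @examples
#' branch_ladder(list("fish", "chicken", "mouse"), c(450, 310, 90), "human")
#' @export
branch_ladder <- function(outgroups, split_ages, focal = "focal",
                          root_age = 500) {
  if (!is.list(outgroups)) outgroups <- as.list(outgroups)
  B <- length(outgroups)
  if (B < 1L) stop("a ladder needs at least one outgroup split")
  if (length(split_ages) != B)
    stop("split_ages must have one age per outgroup split")
  if (any(split_ages <= 0)) stop("split ages are myr before present (> 0)")
  if (any(diff(split_ages) >= 0))
    stop("split ages must strictly decrease toward the present")
  species <- unlist(outgroups)
  if (anyDuplicated(species))
    stop("species may appear in only one outgroup set")
  bounds <- c(-root_age, -split_ages, 0)   # branch i spans bounds[i+1]..bounds[i+2]
  mid <- (bounds[-length(bounds)] + bounds[-1]) / 2
  mid[1] <- -root_age
  branches <- data.frame(
    branch = 0:B,
    age_start = bounds[-length(bounds)],
    age_end = bounds[-1],
    midpoint = mid
  )
  structure(list(branches = branches, outgroups = outgroups,
                 species = species,
                 split_of = stats::setNames(rep(0:(B - 1L),
                                                lengths(outgroups)), species),
                 focal = focal, n_branches = B + 1L),
            class = "branch_ladder")
}

#' @export
print.branch_ladder <- function(x, ...) {
  cat("branch ladder for", x$focal, "with", x$n_branches, "branches\n")
  og <- c(vapply(x$outgroups, paste, "", collapse = ","), "(terminal)")
  print(cbind(x$branches, outgroup = og), row.names = FALSE)
  invisible(x)
}

#' Branch midpoint ages
#' @param ladder A [branch_ladder()].
#' @return Named numeric vector of midpoint ages (myr, negative) indexed by
#'   branch.
#' @export
branch_midpoints <- function(ladder) {
  stats::setNames(ladder$branches$midpoint, ladder$branches$branch)
}

#' Build a ladder from a Newick tree
#'
#' Reads a rooted binary tree and converts it into a [branch_ladder()] by
#' walking from the root to the focal tip; the sister clade at each split
#' becomes that split's outgroup set. Non-ladder input (a polytomy on the
#' focal path, or a focal tip missing from the tree) is rejected.
#'
#' @param tree An `ape::phylo` object, a file path, or a Newick string.
#' @param focal Focal species tip label.
#' @param split_ages Optional split ages (myr before present, root to tip).
#'   When omitted they are derived from the (ultrametric) branch lengths.
#' @param root_age Passed to [branch_ladder()].
#' @return A [branch_ladder()].
#' @export
ladder_from_newick <- function(tree, focal, split_ages = NULL,
                               root_age = 500) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick")
  if (!focal %in% tree$tip.label)
    stop("focal species '", focal, "' is not a tip of the tree")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  # spine: path from root to the focal tip
  spine <- integer(0)
  node <- which(tree$tip.label == focal)
  while (node != root) {
    node <- parent_of[node]
    spine <- c(node, spine)
  }
  outgroups <- list()
  for (i in seq_along(spine)) {
    node <- spine[i]
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) != 2L)
      stop("non-ladder topology: node with ", length(kids),
           " children on the focal path")
    next_on <- if (i < length(spine)) spine[i + 1] else which(tree$tip.label == focal)
    sister <- setdiff(kids, next_on)
    if (length(sister) != 1L)
      stop("non-ladder topology: focal path broken at an internal node")
    tips <- if (sister <= ntip) tree$tip.label[sister]
            else ape::extract.clade(tree, sister)$tip.label
    outgroups[[i]] <- tips
  }
  if (is.null(split_ages)) {
    depth <- ape::node.depth.edgelength(tree)
    total <- depth[which(tree$tip.label == focal)]
    split_ages <- total - depth[spine]
    if (any(split_ages <= 0))
      stop("cannot derive split ages from branch lengths; pass split_ages")
  }
  branch_ladder(outgroups, split_ages, focal = focal, root_age = root_age)
}

#' Built-in human species ladder
#'
#' Thirteen branches (0..12) along the human lineage with twelve outgroup
#' splits at standard divergence times; branch 12 is human-specific
#' (midpoint -3 myr) and branch 0 is fixed at -500 myr.
#' @return A [branch_ladder()].
#' @export
human_ladder <- function() {
  branch_ladder(
    outgroups = list("zebrafish", "frog", "chicken", "platypus", "opossum",
                     "elephant", "dog", "mouse", "bushbaby", "marmoset",
                     "macaque", "chimp"),
    split_ages = c(450, 370, 310, 220, 180, 140, 105, 90, 60, 40, 25, 6),
    focal = "human")
}

#' Built-in mouse species ladder
#'
#' Twelve branches (0..11) along the mouse lineage; branch 11 is
#' mouse-specific (the mouse-rat split is placed at 37 myr).
#' @return A [branch_ladder()].
#' @export
mouse_ladder <- function() {
  branch_ladder(
    outgroups = list("zebrafish", "frog", "chicken", "platypus", "opossum",
                     "elephant", "dog", "human", "squirrel", "guinea_pig",
                     "rat"),
    split_ages = c(450, 370, 310, 220, 180, 140, 105, 90, 75, 60, 37),
    focal = "mouse")
}

CALL_LEVELS <- c("present", "absent", "missing")

# Collapse per-species calls to one call per split: a clade is present if any
# member is present, absent if any member is absent (and none present),
# missing otherwise.
split_calls <- function(call_matrix, ladder) {
  B <- ladder$n_branches - 1L
  out <- matrix(0L, nrow = nrow(call_matrix), ncol = B)
  for (i in seq_len(B)) {
    spp <- ladder$outgroups[[i]]
    sub <- call_matrix[, spp, drop = FALSE]
    pres <- rowSums(sub == "present") > 0
    abs_ <- !pres & rowSums(sub == "absent") > 0
    out[, i] <- ifelse(pres, 1L, ifelse(abs_, -1L, 0L))
  }
  out
}

# Vectorised single-origin parsimony over a genes x splits matrix coded
# 1 = present, -1 = absent, 0 = missing. For each candidate origin branch b,
# the gain costs one event and every absent call at a split >= b costs one
# loss; origins younger than any present call are infeasible (single origin).
# Minimum cost wins; ties resolve to the older branch.
parsimony_assign <- function(S) {
  n <- nrow(S); B <- ncol(S)
  abs_mat <- S == -1L
  pres_mat <- S == 1L
  # losses[, b+1] = number of absent splits with index >= b (b = 0..B)
  ge <- outer(seq_len(B), seq_len(B + 1L), `>=`) * 1
  losses <- abs_mat %*% ge
  # infeasible origins: b such that a present call exists at a split < b
  lt <- outer(seq_len(B), seq_len(B + 1L), `<`) * 1
  cost <- losses
  cost[(pres_mat %*% lt) > 0] <- Inf
  branch <- max.col(-cost, ties.method = "first") - 1L
  first_present <- apply(pres_mat, 1L, function(z) {
    w <- which(z); if (length(w)) w[1] - 1L else NA_integer_
  })
  max_absent <- apply(abs_mat, 1L, function(z) {
    w <- which(z); if (length(w)) w[length(w)] - 1L else NA_integer_
  })
  conflict <- !is.na(first_present) & !is.na(max_absent) &
    max_absent > first_present
  upper <- ifelse(is.na(first_present), B, first_present)  # exclusive bound
  gap <- vapply(seq_len(n), function(g) {
    lo <- branch[g]; hi <- upper[g] - 1L
    hi >= lo && any(S[g, (lo + 1L):(hi + 1L)] == 0L)
  }, logical(1))
  data.frame(branch = branch, conflict_resolved = conflict,
             gap_inferred = gap)
}

check_calls <- function(call_matrix, ladder) {
  if (!setequal(colnames(call_matrix), ladder$species))
    stop("schema error: evidence species do not match the ladder (",
         paste(setdiff(colnames(call_matrix), ladder$species), collapse = ","),
         if (length(setdiff(ladder$species, colnames(call_matrix)))) " missing: ",
         paste(setdiff(ladder$species, colnames(call_matrix)), collapse = ","),
         ")")
  bad <- !(call_matrix %in% CALL_LEVELS)
  if (any(bad))
    stop("schema error: invalid call value(s): ",
         paste(unique(call_matrix[bad]), collapse = ", "))
  call_matrix[, ladder$species, drop = FALSE]
}

#' Assign one gene to its origination branch
#'
#' Single-origin parsimony: the gene gain is placed on the oldest branch
#' that explains the evidence with the fewest loss events. A present call in
#' an outgroup makes all younger origins impossible; each absent call
#' crownward of a candidate origin costs one loss; missing calls are
#' uninformative and ties resolve toward the older branch (so assembly gaps
#' can only age an assignment, never rejuvenate it). All-absent evidence
#' dates the gene to the youngest, species-specific branch.
#'
#' @param calls Named character vector over every ladder species, values in
#'   `present`, `absent`, `missing`.
#' @param ladder A [branch_ladder()].
#' @return A one-row data.frame: `branch`, `conflict_resolved` (a loss was
#'   inferred crownward of a present call), `gap_inferred` (the assignment
#'   leaned on missing calls).
#' @examples
#' lad <- human_ladder()
#' ev <- setNames(rep("absent", 12), lad$species)
#' ev["chimp"] <- "present"
#' assign_branch(ev, lad)   # branch 11: origin before the human-chimp split
#' @export
assign_branch <- function(calls, ladder) {
  m <- matrix(calls, nrow = 1, dimnames = list(NULL, names(calls)))
  m <- check_calls(m, ladder)
  if (all(m == "missing"))
    stop("unassignable: all ortholog calls are missing")
  S <- split_calls(m, ladder)
  parsimony_assign(S)
}

#' Date a whole genome
#'
#' Applies [assign_branch()] to every row of an ortholog-evidence matrix and
#' tabulates per-branch gain counts.
#'
#' @param evidence Character matrix (genes x species, rownames = gene ids) or
#'   data.frame with a `gene_id` column plus one column per species.
#' @param ladder A [branch_ladder()].
#' @return List with `assignments` (data.frame: gene_id, branch,
#'   conflict_resolved, gap_inferred) and `gains` (named integer vector over
#'   branches 0..B, zero-gain branches included).
#' @export
assign_genome <- function(evidence, ladder) {
  if (is.data.frame(evidence)) {
    if (!"gene_id" %in% names(evidence))
      stop("schema error: evidence data.frame needs a gene_id column")
    ids <- as.character(evidence$gene_id)
    m <- as.matrix(evidence[setdiff(names(evidence), "gene_id")])
  } else {
    m <- as.matrix(evidence)
    ids <- rownames(m)
    if (is.null(ids)) {
      if (nrow(m) > 0) stop("evidence matrix needs gene ids as rownames")
      ids <- character(0)
    }
  }
  if (anyDuplicated(ids)) stop("duplicate gene id: ",
                               ids[duplicated(ids)][1])
  B <- ladder$n_branches - 1L
  gains <- stats::setNames(integer(B + 1L), 0:B)
  if (length(ids) == 0L)
    return(list(assignments = data.frame(gene_id = character(0),
                                         branch = integer(0),
                                         conflict_resolved = logical(0),
                                         gap_inferred = logical(0)),
                gains = gains))
  m <- check_calls(m, ladder)
  if (any(all_missing <- rowSums(m != "missing") == 0))
    stop("unassignable: all calls missing for gene ",
         ids[which(all_missing)[1]])
  res <- parsimony_assign(split_calls(m, ladder))
  res <- cbind(gene_id = ids, res)
  tab <- table(factor(res$branch, levels = 0:B))
  gains[] <- as.integer(tab)
  list(assignments = res, gains = gains)
}

#' Flag young genes
#'
#' A gene is young when its origination branch is at least `cutoff_branch`
#' (e.g. primate-specific genes on the human ladder: branches 8-12).
#'
#' @param assignments Assignment data.frame from [assign_genome()] (or a bare
#'   integer vector of branches).
#' @param cutoff_branch Integer branch index in 0..B.
#' @return Logical vector, `TRUE` for young genes.
#' @export
flag_young <- function(assignments, cutoff_branch) {
  branch <- if (is.data.frame(assignments)) assignments$branch else assignments
  if (cutoff_branch < 0) stop("cutoff_branch must be >= 0")
  branch >= cutoff_branch
}

#' Read ortholog evidence from long-format TSV
#'
#' Expects columns `gene_id`, `species`, `call` with calls in
#' `present`/`absent`/`missing`; malformed rows are reported with their line
#' number.
#'
#' @param path TSV file path.
#' @return Character matrix genes x species.
#' @export
read_ortholog_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "call")
  if (!all(need %in% names(df)))
    stop("schema error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  bad <- which(!(df$call %in% CALL_LEVELS))
  if (length(bad))
    stop("schema error in ", path, " line ", bad[1] + 1L,
         ": invalid call '", df$call[bad[1]], "'")
  genes <- unique(df$gene_id); spp <- unique(df$species)
  m <- matrix("missing", length(genes), length(spp),
              dimnames = list(genes, spp))
  m[cbind(match(df$gene_id, genes), match(df$species, spp))] <- df$call
  m
}

#' Write ortholog evidence as long-format TSV
#' @param evidence Character matrix genes x species.
#' @param path Output TSV path.
#' @export
write_ortholog_evidence <- function(evidence, path) {
  df <- data.frame(gene_id = rep(rownames(evidence), ncol(evidence)),
                   species = rep(colnames(evidence), each = nrow(evidence)),
                   call = as.vector(evidence))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
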