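toy_assignments <- function(branches, ids = NULL) {
  if (is.null(ids)) ids <- paste0("g", seq_along(branches))
  data.frame(gene_id = ids, branch = branches,
             conflict_resolved = FALSE, gap_inferred = FALSE)
}

test_that("genome partition validates classes and strata placement", {
  expect_error(genome_partition("g1", "Y"), "'X' or 'autosome'")
  expect_error(genome_partition(c("g1", "g1"), c("X", "X")), "duplicate")
  expect_error(genome_partition("g1", "autosome", stratum = "2"),
               "only defined for X-linked")
  p <- genome_partition(c("g1", "g2"), c("X", "autosome"),
                        stratum = c("PAR1", NA))
  expect_s3_class(p, "genome_partition")
})

test_that("per-branch X shares: trivial compositions and count identities", {
  lad <- toy_ladder(4)
  asg <- toy_assignments(c(0, 0, 2, 2, 2, 4))
  part_auto <- genome_partition(asg$gene_id, rep("autosome", 6))
  bp <- branch_proportions(asg, part_auto, lad)
  expect_equal(bp$x_share[bp$n > 0], rep(0, 3))
  expect_true(all(is.na(bp$x_share[bp$n == 0])))  # undefined, not zero

  part_onex <- genome_partition(asg$gene_id,
                                c("autosome", "autosome", "X", "autosome",
                                  "autosome", "X"))
  bp2 <- branch_proportions(asg, part_onex, lad)
  expect_equal(bp2$x_share[bp2$branch == 4], 1)
  expect_equal(bp2$n_x + (bp2$n - bp2$n_x), bp2$n)
  expect_equal(sum(bp2$n), nrow(asg))
  expect_equal(bp2$midpoint, lad$branches$midpoint)

  expect_error(branch_proportions(asg, part_auto[-1, ], lad),
               "missing from the partition")
})

test_that("the synthetic two-peak X-gain curve is recovered within binomial
           bounds", {
  cfg <- sim_config(seed = 202, genes_per_branch = rep(770, 13))  # ~10k genes
  g <- simulate_genome(cfg)
  ev <- simulate_ortholog_evidence(g$truth, cfg$ladder, 0, seed = 203)
  asg <- assign_genome(ev, cfg$ladder)$assignments
  bp <- branch_proportions(asg, g$partition, cfg$ladder)
  peaks <- bp$x_share[bp$branch %in% c(5, 12)]
  expect_true(all(peaks > 0.06 & peaks < 0.16))
  baseline <- bp$x_share[bp$branch %in% c(0, 1, 2, 3, 4)]
  expect_true(all(baseline < 0.04))
})

test_that("bias-by-age drops thin branches and fits flat curves as zero", {
  lad <- toy_ladder(4)
  ids <- paste0("g", 1:24)
  asg <- toy_assignments(rep(c(0, 2, 4), each = 8), ids)
  part <- genome_partition(ids, rep(c("X", "autosome"), 12))
  # 4 assayed X genes in branch 4: the X point for that branch is omitted
  calls <- data.frame(gene_id = ids, call = "unbiased")
  calls$call[ids %in% c("g23")] <- "not_assayed"
  res <- bias_by_age(calls, asg, part, lad, min_covered = 4)
  expect_false(any(res$points$branch == 4 & res$points$class == "X"))
  expect_true(any(res$points$branch == 4 & res$points$class == "autosome"))

  # all unbiased: flat zero proportions, zero slopes
  expect_true(all(res$points$prop_male == 0))
  expect_equal(res$fits$slope, c(0, 0), tolerance = 1e-12)
})

test_that("branch-restricted contingency reproduces a direct chi-square on
           its own table", {
  counts <- rbind(X = c(28, 35, 27), autosome = c(187, 137, 409))
  ids <- paste0("g", seq_len(sum(counts)))
  class <- rep(rep(c("X", "autosome"), 3), counts[cbind(rep(1:2, 3),
                                                        rep(1:3, each = 2))])
  # build gene lists matching the counts exactly
  class <- c(rep("X", 28), rep("autosome", 187),
             rep("X", 35), rep("autosome", 137),
             rep("X", 27), rep("autosome", 409))
  bias <- rep(c("male", "female", "unbiased"), c(215, 172, 436))
  part <- genome_partition(ids, class)
  calls <- data.frame(gene_id = ids, call = bias)
  res <- bias_contingency(ids, part, calls)
  expect_equal(unclass(res$table)[, ], counts, ignore_attr = TRUE)
  expect_equal(res$test$p_value,
               chi_square_independence(counts)$p_value)
  expect_error(bias_contingency(character(0), part, calls), "empty")
})

test_that("proportional rows give p = 1", {
  ids <- paste0("g", 1:60)
  part <- genome_partition(ids, rep(c("X", "autosome"), each = 30))
  calls <- data.frame(gene_id = ids,
                      call = rep(rep(c("male", "female", "unbiased"), each = 10), 2))
  res <- bias_contingency(ids, part, calls)
  expect_equal(res$test$p_value, 1)
  expect_equal(res$test$statistic, 0)
})

test_that("stage presence table reproduces proportions and flags undefined
           cells", {
  ids <- paste0("g", 1:489)
  part <- genome_partition(ids, rep("X", 489))
  pres <- data.frame(gene_id = ids, stage = "spermatogonia",
                     call = rep(c("present", "absent", "ambiguous"),
                                c(319, 141, 29)))
  young <- setNames(rep(FALSE, 489), ids)
  out <- stage_presence_table(pres, young, part)
  expect_equal(round(100 * out$x_prop), 69)
  expect_true(out$undefined)  # no informative autosomal gene in this toy set

  pres$call <- "ambiguous"
  out2 <- stage_presence_table(pres, young, part)
  expect_equal(nrow(out2), 0)  # nothing informative at all
})

test_that("the MSCI round trip reproduces the published direction: young X
           genes excel post-meiotically, old X genes are silenced in
           meiosis", {
  cfg <- sim_config(seed = 60, genes_per_branch = rep(300, 13))
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g, cfg, seed = 61)
  pres <- do.call(rbind, lapply(names(ex$stages$mouse), function(s) {
    calls <- consensus_presence(ex$stages$mouse[[s]])
    data.frame(gene_id = names(calls), stage = s, call = unname(calls))
  }))
  young <- setNames(g$truth$young, g$truth$gene_id)
  tab <- stage_presence_table(pres, young, g$partition)
  spermatid <- tab[tab$stage == "round_spermatid", ]
  gap <- spermatid$x_prop[spermatid$age_class == "young"] -
    spermatid$auto_prop[spermatid$age_class == "young"]
  expect_gt(gap, 0.2)
  meiotic <- tab[tab$stage == "pachytene_spermatocyte", ]
  expect_lt(meiotic$x_prop[meiotic$age_class == "old"],
            meiotic$auto_prop[meiotic$age_class == "old"])
})

test_that("enrichment scores are signed -log10 p, clamped, and flip with the
           partition", {
  ids <- paste0("g", 1:400)
  asg <- toy_assignments(rep(0, 400), ids)
  part <- genome_partition(ids, rep(c("X", "autosome"), each = 200))
  # X-leaning tissue and an extreme autosome-leaning tissue
  pres <- rbind(
    data.frame(gene_id = ids, tissue = "brain",
               call = c(rep(c("present", "absent"), c(150, 50)),
                        rep(c("present", "absent"), c(100, 100)))),
    data.frame(gene_id = ids, tissue = "liver",
               call = c(rep("absent", 200), rep("present", 200))))
  hm <- enrichment_heatmap(pres, asg, part)
  direct <- fisher_exact(rbind(c(150, 50), c(100, 100)))$p_value
  expect_equal(hm$scores["0", "brain"], -log10(direct))
  expect_gt(hm$scores["0", "brain"], 0)
  expect_equal(hm$scores["0", "liver"], -8)  # clamped from far below

  flipped <- genome_partition(ids, rep(c("autosome", "X"), each = 200))
  hm2 <- enrichment_heatmap(pres, asg, flipped)
  expect_equal(hm2$scores["0", "brain"], -hm$scores["0", "brain"])
  expect_equal(hm2$scores["0", "liver"], 8)
})

test_that("tissue clustering orders somatic tissues from the generator run", {
  cfg <- sim_config(seed = 71, genes_per_branch = rep(120, 13))
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g, cfg, seed = 72)
  ev <- simulate_ortholog_evidence(g$truth, cfg$ladder, 0, seed = 73)
  asg <- assign_genome(ev, cfg$ladder)$assignments
  hm <- enrichment_heatmap(ex$somatic, asg, g$partition)
  expect_equal(sort(hm$tissue_order), sort(unique(ex$somatic$tissue)))
  expect_true(all(abs(hm$scores) <= 8, na.rm = TRUE))
})

test_that("strata-age association: perfect association attains the
           enumeration minimum and the null is calibrated", {
  ids <- paste0("g", 1:40)
  asg <- toy_assignments(rep(c(0, 4), each = 20), ids)
  part <- genome_partition(ids, rep("X", 40),
                           stratum = rep(c("1", "2", "4", "5"), each = 10))
  young <- setNames(rep(c(FALSE, TRUE), each = 20), ids)
  res <- strata_age_association(asg, part, young)
  expect_equal(res$test$p_value,
               fisher_oracle(rbind(c(20, 0), c(0, 20)), "one_greater"))

  set.seed(74)
  null_ps <- replicate(120, {
    part_r <- genome_partition(ids, rep("X", 40),
                               stratum = sample(rep(c("1", "4"), 20)))
    strata_age_association(asg, part_r, young)$test$p_value
  })
  expect_gt(mean(null_ps > 0.05), 0.8)   # roughly uniform null
  expect_gt(mean(null_ps < 0.7), 0.2)

  part_one <- genome_partition(ids, rep("X", 40), stratum = "1")
  expect_error(strata_age_association(asg, part_one, young),
               "empty stratum class")
})

test_that("strata lookups resolve positions against a BED region map", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chrX\t0\t1000\t1", "chrX\t1000\t3000\tPAR1"), f)
  map <- read_region_map(f)
  expect_equal(stratum_of(c(10, 1500, 9999), map), c("1", "PAR1", "undefined"))
})
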