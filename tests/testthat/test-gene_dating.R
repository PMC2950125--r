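test_that("ladder construction enforces ordering and conventions", {
  lad <- human_ladder()
  expect_equal(lad$n_branches, 13L)
  mids <- branch_midpoints(lad)
  expect_equal(unname(mids["0"]), -500)   # oldest branch pinned by convention
  expect_equal(unname(mids["12"]), -3)    # human-specific branch
  expect_true(all(diff(lad$branches$age_start[-1]) > 0))
  expect_error(branch_ladder(list("a", "b"), c(100, 100), "f"),
               "strictly decrease")
  expect_error(branch_ladder(list("a", "a"), c(100, 50), "f"),
               "only one outgroup set")
})

test_that("single-gene parsimony assignments match the canonical cases", {
  lad <- human_ladder()
  all_present <- make_calls(lad, rep("present", 12))
  expect_equal(assign_branch(all_present, lad)$branch, 0L)

  all_absent <- make_calls(lad, rep("absent", 12))
  expect_equal(assign_branch(all_absent, lad)$branch, 12L)

  chimp_only <- make_calls(lad, rep("absent", 12))
  chimp_only["chimp"] <- "present"
  res <- assign_branch(chimp_only, lad)
  expect_equal(res$branch, 11L)  # origin precedes the human-chimp split
  expect_false(res$gap_inferred)

  # presence in a deep outgroup wins over crownward absences (losses)
  deep <- make_calls(lad, rep("absent", 12))
  deep[c("chicken")] <- "present"
  deep["opossum"] <- "missing"
  res <- assign_branch(deep, lad)
  expect_equal(res$branch, 2L)   # the chicken split
  expect_true(res$conflict_resolved)

  expect_error(assign_branch(make_calls(lad, rep("missing", 12)), lad),
               "unassignable")
  bad <- make_calls(lad, rep("absent", 12)); names(bad)[1] <- "unicorn"
  expect_error(assign_branch(bad, lad), "schema error")
})

test_that("assignments equal the brute-force parsimony oracle on all
           3^S patterns", {
  for (S in c(5, 7)) {
    lad <- toy_ladder(S)
    grid <- as.matrix(expand.grid(rep(list(c("present", "absent", "missing")),
                                      S), stringsAsFactors = FALSE))
    colnames(grid) <- lad$species
    informative <- rowSums(grid != "missing") > 0
    grid <- grid[informative, , drop = FALSE]
    rownames(grid) <- paste0("p", seq_len(nrow(grid)))
    got <- assign_genome(grid, lad)$assignments$branch
    want <- apply(grid, 1, parsimony_oracle)
    expect_equal(got, unname(want))
  }
})

test_that("assignment is monotone under added ancestral presence and under
           censoring", {
  lad <- toy_ladder(6)
  set.seed(12)
  for (i in 1:80) {
    pattern <- sample(c("present", "absent", "missing"), 6, replace = TRUE)
    if (all(pattern == "missing")) next
    b0 <- assign_branch(make_calls(lad, pattern), lad)$branch

    # a new present call deeper than every existing one
    deepest <- which(pattern == "present")
    anc <- if (length(deepest)) min(deepest) - 1L else
      max(which(pattern != "missing")) - 1L
    if (anc >= 1) {
      p2 <- pattern; p2[anc] <- "present"
      expect_lte(assign_branch(make_calls(lad, p2), lad)$branch, b0)
    }

    # censoring an absent call can only age the assignment, whatever the
    # pattern (dropping a present call may rejuvenate only when that call
    # was contradicted by crownward absences, i.e. it had forced losses)
    ab <- which(pattern == "absent")
    if (length(ab)) {
      j <- if (length(ab) == 1) ab else sample(ab, 1)
      p3 <- pattern; p3[j] <- "missing"
      if (!all(p3 == "missing"))
        expect_lte(assign_branch(make_calls(lad, p3), lad)$branch, b0)
    }
  }

  # on loss-free (staircase-compatible) evidence, censoring ANY call never
  # rejuvenates: this is what protects dating against assembly gaps
  set.seed(13)
  for (i in 1:60) {
    b_true <- sample(0:6, 1)
    pattern <- c(rep("absent", b_true), rep("present", 6 - b_true))
    keep <- pattern
    j <- sample(6, 1)
    keep[j] <- "missing"
    if (all(keep == "missing")) next
    b0 <- assign_branch(make_calls(lad, pattern), lad)$branch
    expect_lte(assign_branch(make_calls(lad, keep), lad)$branch, b0)
  }
})

test_that("genome-wide dating round-trips the generator and errs old, never
           young, under dropout", {
  cfg <- sim_config(seed = 303, genes_per_branch = rep(385, 13))  # 5005 genes
  g <- simulate_genome(cfg)

  clean <- simulate_ortholog_evidence(g$truth, cfg$ladder, dropout = 0,
                                      seed = 304)
  res <- assign_genome(clean, cfg$ladder)
  expect_equal(res$assignments$branch, g$truth$branch)
  expect_equal(sum(res$gains), nrow(g$truth))

  noisy <- simulate_ortholog_evidence(g$truth, cfg$ladder, dropout = 0.1,
                                      seed = 305)
  res <- assign_genome(noisy, cfg$ladder)
  exact <- res$assignments$branch == g$truth$branch
  expect_gte(mean(exact), 0.9)
  expect_true(all(res$assignments$branch[!exact] <
                    g$truth$branch[!exact]))  # only toward older branches
  expect_true(all(res$assignments$gap_inferred[!exact]))
})

test_that("assign_genome validates inputs and handles the empty matrix", {
  lad <- toy_ladder(3)
  empty <- matrix(character(0), 0, 3, dimnames = list(NULL, lad$species))
  res <- assign_genome(empty, lad)
  expect_equal(unname(res$gains), rep(0L, 4))

  dup <- matrix("present", 2, 3,
                dimnames = list(c("g1", "g1"), lad$species))
  expect_error(assign_genome(dup, lad), "duplicate gene id")
})

test_that("young flags follow the branch cutoff", {
  asg <- data.frame(gene_id = c("a", "b", "c"), branch = c(8L, 7L, 0L))
  expect_equal(flag_young(asg, 8), c(TRUE, FALSE, FALSE))
  expect_true(all(flag_young(asg, 0)))
})

test_that("ladders survive a Newick + age-table round trip", {
  lad <- mouse_ladder()
  nwk <- tempfile(fileext = ".nwk"); ages <- tempfile(fileext = ".tsv")
  write_ladder(lad, nwk, ages)
  back <- read_ladder(nwk, ages, "mouse")
  expect_equal(back$outgroups, lad$outgroups)
  expect_equal(back$branches$midpoint, lad$branches$midpoint)
  expect_equal(unname(back$split_of[lad$species]),
               unname(lad$split_of[lad$species]))

  expect_error(ladder_from_newick("(a,b,c);", "a"), "non-ladder")
  expect_error(ladder_from_newick("((a:1,b:1):1,c:2);", "zzz"), "not a tip")
})

test_that("long-format evidence TSV round-trips and flags bad rows", {
  lad <- toy_ladder(3)
  m <- matrix(sample(c("present", "absent", "missing"), 12, replace = TRUE),
              4, 3, dimnames = list(paste0("g", 1:4), lad$species))
  f <- tempfile(fileext = ".tsv")
  write_ortholog_evidence(m, f)
  back <- read_ortholog_evidence(f)
  expect_equal(back[rownames(m), colnames(m)], m)

  bad <- data.frame(gene_id = "g1", species = "sp1", call = "perhaps")
  f2 <- tempfile(fileext = ".tsv")
  write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ortholog_evidence(f2), "line 2")
})
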