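#' Write a ladder as Newick plus a branch-age table
#'
#' The Newick tree is ultrametric (clade tips reach the present); the
#' companion TSV carries branch age intervals and midpoints.
#'
#' @param ladder A [branch_ladder()].
#' @param newick_path,ages_path Output paths.
#' @export
write_ladder <- function(ladder, newick_path, ages_path) {
  B <- ladder$n_branches - 1L
  ages <- -ladder$branches$age_start[-1]   # split ages, oldest first
  clade_str <- function(spp, s) {
    if (length(spp) == 1) paste0(spp, ":", s)
    else paste0("(", paste0(spp, ":", s, collapse = ","), "):0")
  }
  cur <- paste0(ladder$focal, ":", ages[B])
  for (i in B:1) {
    s <- ages[i]
    inner <- paste0("(", clade_str(ladder$outgroups[[i]], s), ",", cur, ")")
    cur <- if (i > 1) paste0(inner, ":", ages[i - 1] - s) else inner
  }
  writeLines(paste0(cur, ";"), newick_path)
  utils::write.table(ladder$branches, ages_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a ladder written by [write_ladder()]
#' @param newick_path,ages_path Input paths.
#' @param focal Focal species tip label.
#' @return A [branch_ladder()].
#' @export
read_ladder <- function(newick_path, ages_path, focal) {
  br <- utils::read.delim(ages_path)
  ladder_from_newick(newick_path, focal,
                     split_ages = -br$age_start[-1],
                     root_age = -br$midpoint[1])
}

write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df)), rownames_as),
                as.data.frame(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path, id_col = "gene_id") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[setdiff(names(df), id_col)])
  rownames(m) <- df[[id_col]]
  m
}

#' Default pipeline configuration
#'
#' @param seed Top-level seed, the single source of randomness.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       simulate = list(dropout = 0.1, n_replicates = 4L, noise_sd = 0.25),
       dating = list(young_cutoff = 8L),
       expression = list(fdr = 0.05),
       compose = list(min_covered = 5L, clamp = 8, focus_branch = 5L),
       decay = list(min_covered = 5L))
}

pipeline_config <- function(config) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing input file: ", config)
    config <- yaml::read_yaml(config)
  }
  modifyList(base, config)
}

manifest_write <- function(out_dir, cfg, stages, files) {
  files <- files[file.exists(file.path(out_dir, files))]
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  cfg_file <- tempfile(); yaml::write_yaml(cfg, cfg_file)
  man <- list(config_hash = unname(tools::md5sum(cfg_file)),
              seed = cfg$seed, stages = I(stages), files = digests,
              version = as.character(utils::packageVersion("geneage")))
  unlink(cfg_file)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

stage_presence_long <- function(flags_by_stage) {
  do.call(rbind, lapply(names(flags_by_stage), function(s) {
    calls <- consensus_presence(flags_by_stage[[s]])
    data.frame(gene_id = names(calls), stage = s, call = unname(calls))
  }))
}

#' Run a pipeline stage
#'
#' Orchestrates the full analysis over a shared output directory. Stages read
#' the files earlier stages wrote, never mutate their inputs, and record a
#' manifest (config hash, seed, stage list, output digests, package version).
#' Re-running with the same config and inputs reproduces identical digests.
#'
#' Subcommands: `simulate` (synthetic study -> evidence/expression/truth
#' TSVs, Newick ladder), `date` (parsimony assignments + gain histogram),
#' `classify-origin`, `call-expression` (sex-bias and stage presence calls),
#' `compose` (branch proportions, bias-by-age, contingency, stage table,
#' enrichment heatmap, strata association), `diverge` (RA divergence and
#' group tests), `fit-decay`, and `report` (everything in order).
#'
#' @param command Subcommand name.
#' @param config A YAML file path, a config list, or NULL for defaults.
#' @param out_dir Output/working directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(command, config = NULL, out_dir = "geneage_run",
                         seed = NULL) {
  commands <- c("simulate", "date", "classify-origin", "call-expression",
                "compose", "diverge", "fit-decay", "report")
  if (!command %in% commands)
    stop("unknown subcommand '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  cfg <- pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  stages_run <- character(0)
  outputs <- character(0)
  do_stage <- function(name, fn) {
    fn()
    stages_run <<- c(stages_run, name)
  }

  sim_stage <- function() {
    sc <- do.call(sim_config, c(list(seed = cfg$seed),
                                cfg$simulate[names(cfg$simulate) %in%
                                             names(formals(sim_config))]))
    study <- simulate_study(sc)
    write_ladder(sc$ladder, p("ladder.nwk"), p("branches.tsv"))
    write_ortholog_evidence(study$evidence, p("evidence.tsv"))
    write_tsv(study$genome$truth, p("truth.tsv"))
    write_tsv(as.data.frame(study$genome$partition), p("partition.tsv"))
    write_gene_models(study$genome$models, p("exons.tsv"))
    write_tsv(study$genome$hits, p("hits.tsv"))
    write_tsv(study$expression$gonads$testis, p("gonads_testis.tsv"), "gene_id")
    write_tsv(study$expression$gonads$ovary, p("gonads_ovary.tsv"), "gene_id")
    write_tsv(study$expression$gonads$samples, p("samples.tsv"))
    for (sp in names(study$expression$stages))
      write_tsv(stage_presence_long(study$expression$stages[[sp]]),
                p(paste0("stage_presence_", sp, ".tsv")))
    for (sp in names(study$expression$profiles))
      write_tsv(study$expression$profiles[[sp]],
                p(paste0("profiles_", sp, ".tsv")), "gene_id")
    write_tsv(study$expression$somatic, p("somatic_presence.tsv"))
    outputs <<- c(outputs, "ladder.nwk", "branches.tsv", "evidence.tsv",
                  "truth.tsv", "partition.tsv", "exons.tsv", "hits.tsv",
                  "gonads_testis.tsv", "gonads_ovary.tsv", "samples.tsv",
                  "stage_presence_mouse.tsv", "stage_presence_rat.tsv",
                  "profiles_mouse.tsv", "profiles_rat.tsv",
                  "somatic_presence.tsv")
  }

  load_ladder <- function() {
    sc <- do.call(sim_config, list(seed = cfg$seed))
    read_ladder(p("ladder.nwk"), p("branches.tsv"), sc$ladder$focal)
  }

  date_stage <- function() {
    for (f in c("evidence.tsv", "ladder.nwk", "branches.tsv"))
      if (!file.exists(p(f))) stop("missing input file: ", p(f))
    lad <- load_ladder()
    ev <- read_ortholog_evidence(p("evidence.tsv"))
    res <- assign_genome(ev, lad)
    res$assignments$young <- flag_young(res$assignments,
                                        cfg$dating$young_cutoff)
    write_tsv(res$assignments, p("assignments.tsv"))
    write_tsv(data.frame(branch = as.integer(names(res$gains)),
                         gains = as.integer(res$gains)), p("gains.tsv"))
    outputs <<- c(outputs, "assignments.tsv", "gains.tsv")
  }

  classify_stage <- function() {
    for (f in c("exons.tsv", "hits.tsv", "assignments.tsv"))
      if (!file.exists(p(f))) stop("missing input file: ", p(f))
    models <- read_gene_models(p("exons.tsv"))
    hits <- utils::read.delim(p("hits.tsv"))
    asg <- utils::read.delim(p("assignments.tsv"))
    young_ids <- asg$gene_id[asg$young]
    mech <- classify_origins(models[young_ids], hits, models)
    write_tsv(mech, p("mechanisms.tsv"))
    outputs <<- c(outputs, "mechanisms.tsv")
  }

  express_stage <- function() {
    for (f in c("gonads_testis.tsv", "gonads_ovary.tsv"))
      if (!file.exists(p(f))) stop("missing input file: ", p(f))
    testis <- read_matrix_tsv(p("gonads_testis.tsv"))
    ovary <- read_matrix_tsv(p("gonads_ovary.tsv"))
    bias <- call_sex_bias(testis, ovary, fdr = cfg$expression$fdr)
    write_tsv(bias, p("bias.tsv"))
    outputs <<- c(outputs, "bias.tsv")
  }

  compose_stage <- function() {
    for (f in c("assignments.tsv", "partition.tsv", "bias.tsv",
                "stage_presence_mouse.tsv", "somatic_presence.tsv"))
      if (!file.exists(p(f))) stop("missing input file: ", p(f))
    lad <- load_ladder()
    asg <- utils::read.delim(p("assignments.tsv"))
    part <- utils::read.delim(p("partition.tsv"))
    part <- genome_partition(part$gene_id, part$class, part$stratum,
                             part$position)
    bias <- utils::read.delim(p("bias.tsv"))
    write_tsv(branch_proportions(asg, part, lad),
              p("branch_proportions.tsv"))
    bba <- bias_by_age(bias, asg, part, lad,
                       min_covered = cfg$compose$min_covered)
    write_tsv(bba$points, p("bias_by_age.tsv"))
    write_tsv(bba$fits, p("bias_by_age_fits.tsv"))
    focus <- asg$gene_id[asg$branch == cfg$compose$focus_branch]
    bc <- bias_contingency(focus, part, bias)
    write_tsv(data.frame(class = rownames(bc$table),
                         as.data.frame.matrix(unclass(bc$table)),
                         p_value = bc$test$p_value),
              p("bias_contingency.tsv"))
    stage_pres <- utils::read.delim(p("stage_presence_mouse.tsv"))
    young <- stats::setNames(asg$young, asg$gene_id)
    write_tsv(stage_presence_table(stage_pres, young, part),
              p("stage_presence_table.tsv"))
    som <- utils::read.delim(p("somatic_presence.tsv"))
    hm <- enrichment_heatmap(som, asg, part, clamp = cfg$compose$clamp)
    write_tsv(hm$scores, p("enrichment_heatmap.tsv"), "branch")
    sa <- strata_age_association(asg, part, young)
    write_tsv(data.frame(strata = rownames(sa$table),
                         as.data.frame.matrix(unclass(sa$table)),
                         p_one_sided = sa$test$p_value),
              p("strata_association.tsv"))
    outputs <<- c(outputs, "branch_proportions.tsv", "bias_by_age.tsv",
                  "bias_by_age_fits.tsv", "bias_contingency.tsv",
                  "stage_presence_table.tsv", "enrichment_heatmap.tsv",
                  "strata_association.tsv")
  }

  diverge_stage <- function() {
    for (f in c("profiles_mouse.tsv", "profiles_rat.tsv", "assignments.tsv",
                "partition.tsv"))
      if (!file.exists(p(f))) stop("missing input file: ", p(f))
    a <- read_matrix_tsv(p("profiles_mouse.tsv"))
    b <- read_matrix_tsv(p("profiles_rat.tsv"))
    ra_a <- ra_matrix(a); ra_b <- ra_matrix(b)
    D <- rowSums((ra_a - ra_b)^2)
    asg <- utils::read.delim(p("assignments.tsv"))
    part <- utils::read.delim(p("partition.tsv"))
    d <- merge(data.frame(gene_id = rownames(a), D = D),
               merge(asg, part, by = "gene_id"), by = "gene_id")
    d$group <- paste(ifelse(d$young, "young", "old"), d$class, sep = "_")
    write_tsv(d[c("gene_id", "D", "group")], p("divergence.tsv"))
    write_tsv(group_divergence_compare(d$D, d$group), p("divergence_tests.tsv"))
    outputs <<- c(outputs, "divergence.tsv", "divergence_tests.tsv")
  }

  decay_stage <- function() {
    if (!file.exists(p("bias_by_age.tsv")))
      stop("missing input file: ", p("bias_by_age.tsv"))
    pts <- utils::read.delim(p("bias_by_age.tsv"))
    xs <- pts[pts$class == "X", ]
    fit <- fit_decay(xs$midpoint, xs$prop_male, xs$n_assayed)
    jsonlite::write_json(
      list(parameters = as.list(coef(fit)), objective = fit$objective,
           converged = fit$converged, n_points = nrow(xs)),
      p("decay_fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, "decay_fit.json")
  }

  switch(command,
    "simulate" = do_stage("simulate", sim_stage),
    "date" = do_stage("date", date_stage),
    "classify-origin" = do_stage("classify-origin", classify_stage),
    "call-expression" = do_stage("call-expression", express_stage),
    "compose" = do_stage("compose", compose_stage),
    "diverge" = do_stage("diverge", diverge_stage),
    "fit-decay" = do_stage("fit-decay", decay_stage),
    "report" = {
      do_stage("simulate", sim_stage)
      do_stage("date", date_stage)
      do_stage("classify-origin", classify_stage)
      do_stage("call-expression", express_stage)
      do_stage("compose", compose_stage)
      do_stage("diverge", diverge_stage)
      do_stage("fit-decay", decay_stage)
    })
  manifest_write(out_dir, cfg, stages_run, unique(outputs))
}
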