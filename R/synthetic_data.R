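# Run code under a seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

SPERM_STAGES <- c("type_a_spermatogonia", "type_b_spermatogonia",
                  "pachytene_spermatocyte", "round_spermatid", "whole_testis")
SOMATIC_TISSUES <- c("brain", "heart", "kidney", "liver", "lung", "muscle",
                     "spleen", "thymus")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study conditions on the human ladder: a two-peak X-linked gene-gain curve
#' (3% baseline; the post-marsupial burst on branches 5-7 and the recent
#' burst on branches 11-12 at 8-14%), male-bias fractions following the
#' decay model per chromosome class, progressive feminization of old X
#' genes, MSCI-style silencing of old X genes from meiosis on, a
#' post-meiotic expression excess of young X genes, log-normal intensity
#' noise, and assembly-gap dropout of ortholog calls.
#'
#' @param seed Mandatory integer seed.
#' @param ladder A [branch_ladder()] (default [human_ladder()]).
#' @param genes_per_branch Integer gains per branch (length = number of
#'   branches).
#' @param x_share_baseline Baseline X-linked share of gains (default 0.03).
#' @param x_share_peaks Named vector of per-branch X shares overriding the
#'   baseline at the burst branches.
#' @param male_bias_x,male_bias_auto Decay parameters `c(N, r, d)` governing
#'   the probability that a gene born at age t is male-biased, per class.
#' @param female_bias List: `x_old`, `x_young`, `auto`, `rate` — female-bias
#'   probability is `x_old - (x_old - x_young) * exp(rate * t)` on the X and
#'   flat `auto` on autosomes.
#' @param msci_prob Probability that an otherwise-expressed old X gene is
#'   silenced in meiotic cells (half effect post-meiosis; default 0.37).
#' @param young_x_postmeiotic Expressed proportion of young X genes in round
#'   spermatid (default 0.70).
#' @param young_cutoff First young branch (default 8).
#' @param n_replicates Gonad replicates per tissue (default 4).
#' @param noise_sd Log2-scale intensity noise (default 0.25).
#' @param effect_log2fc Planted log2 fold change of sex-biased genes
#'   (default 2).
#' @param dropout Probability an ortholog call is lost to an assembly gap
#'   (default 0.1).
#' @param flip_noise Per-replicate detection flag flip probability
#'   (default 0.02).
#' @param mechanism_mix Origin-mechanism probabilities for young genes.
#' @param divergence_sd,divergence_boost Between-species log-profile noise sd
#'   and its multiplier for young X genes.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       ladder = human_ladder(),
                       genes_per_branch = NULL,
                       x_share_baseline = 0.03,
                       x_share_peaks = c(`5` = 0.12, `6` = 0.10, `7` = 0.08,
                                         `11` = 0.08, `12` = 0.12),
                       male_bias_x = c(N = 0.74, r = 0.08, d = 0.42),
                       male_bias_auto = c(N = 0.30, r = 0.05, d = 0.90),
                       female_bias = list(x_old = 0.38, x_young = 0.10,
                                          auto = 0.17, rate = 0.08),
                       msci_prob = 0.37,
                       young_x_postmeiotic = 0.70,
                       young_cutoff = 8L,
                       n_replicates = 4L,
                       noise_sd = 0.25,
                       effect_log2fc = 2,
                       dropout = 0.1,
                       flip_noise = 0.02,
                       mechanism_mix = c(dna_duplicate = 0.80,
                                         retrogene = 0.12, de_novo = 0.08),
                       divergence_sd = 0.3,
                       divergence_boost = 3) {
  if (missing(seed)) stop("seed is mandatory")
  nb <- ladder$n_branches
  if (is.null(genes_per_branch)) {
    base <- c(2800, 170, 170, 280, 220, 380, 130, 130, 200, 110, 80, 80, 110)
    genes_per_branch <- if (nb == 13L) base else
      round(rep(sum(base) / nb, nb))
  }
  if (length(genes_per_branch) != nb)
    stop("genes_per_branch must have one count per branch")
  if (any(genes_per_branch < 0)) stop("gene counts must be >= 0")
  if (sum(genes_per_branch) == 0) stop("zero total genes")
  x_share <- rep(x_share_baseline, nb)
  if (length(x_share_peaks)) {
    idx <- as.integer(names(x_share_peaks))
    keep <- idx >= 0 & idx < nb
    x_share[idx[keep] + 1L] <- x_share_peaks[keep]
  }
  probs <- c(x_share, dropout, flip_noise, msci_prob, young_x_postmeiotic,
             mechanism_mix, unlist(female_bias[c("x_old", "x_young", "auto")]))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (dropout >= 1) stop("dropout must be < 1")
  structure(list(seed = as.integer(seed), ladder = ladder,
                 genes_per_branch = genes_per_branch, x_share = x_share,
                 male_bias_x = male_bias_x, male_bias_auto = male_bias_auto,
                 female_bias = female_bias, msci_prob = msci_prob,
                 young_x_postmeiotic = young_x_postmeiotic,
                 young_cutoff = as.integer(young_cutoff),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, effect_log2fc = effect_log2fc,
                 dropout = dropout, flip_noise = flip_noise,
                 mechanism_mix = mechanism_mix,
                 divergence_sd = divergence_sd,
                 divergence_boost = divergence_boost),
            class = "sim_config")
}

stratum_probs <- function(branch, young_cutoff) {
  # old genes sit mostly in old strata 1-3; young genes favour strata 4-5
  if (branch <= 4)
    c(`1` = .32, `2` = .30, `3` = .28, `4` = .03, `5` = .03,
      PAR1 = .01, PAR2 = .01, undefined = .02)
  else if (branch < young_cutoff)
    c(`1` = .24, `2` = .24, `3` = .30, `4` = .09, `5` = .09,
      PAR1 = .01, PAR2 = .01, undefined = .02)
  else
    c(`1` = .14, `2` = .14, `3` = .22, `4` = .22, `5` = .22,
      PAR1 = .01, PAR2 = .01, undefined = .04)
}

stage_presence_probs <- function(class, young, cfg) {
  old_auto <- c(.64, .67, .57, .57, .65)
  young_auto <- c(.18, .22, .23, .27, .29)
  if (class == "autosome") {
    if (young) young_auto else old_auto
  } else if (!young) {
    # MSCI silences old X genes in meiosis, half effect post-meiosis
    p <- c(.69, .70, old_auto[3] * (1 - cfg$msci_prob),
           old_auto[4] * (1 - cfg$msci_prob / 2), .57)
    p
  } else {
    c(.33, .37, .29, cfg$young_x_postmeiotic, .71)
  }
}

#' Simulate a genome with known truth
#'
#' Draws per-gene branch of origin (fixed per-branch counts), chromosome
#' class (two-peak X-share curve), X stratum, origin mechanism, sex-bias
#' label (decay-model probabilities) and spermatogenesis-stage expression
#' pattern, plus gene models and a consistent paralog-hit table so the
#' origin classifier can be round-tripped. Deterministic under the
#' configured seed.
#'
#' @param config A [sim_config()].
#' @return List: `truth` (data.frame), `stage_truth` (genes x stages logical
#'   matrix), `models` (list of [gene_model()]), `parents`, `hits`
#'   (paralog-hit data.frame), `partition` ([genome_partition()]),
#'   `ladder`, `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lad <- config$ladder
    nb <- lad$n_branches
    mids <- lad$branches$midpoint
    branch <- rep(0:(nb - 1L), config$genes_per_branch)
    n <- length(branch)
    gene_id <- sprintf("g%05d", seq_len(n))
    is_x <- stats::runif(n) < config$x_share[branch + 1L]
    class <- ifelse(is_x, "X", "autosome")
    young <- branch >= config$young_cutoff

    stratum <- rep(NA_character_, n)
    for (i in which(is_x)) {
      pr <- stratum_probs(branch[i], config$young_cutoff)
      stratum[i] <- sample(names(pr), 1L, prob = pr)
    }
    position <- round(stats::runif(n, 1, 1.5e8))

    mechanism <- rep(NA_character_, n)
    mechanism[young] <- sample(names(config$mechanism_mix), sum(young),
                               replace = TRUE, prob = config$mechanism_mix)

    pm_x <- decay_curve(mids[branch + 1L], config$male_bias_x["N"],
                        config$male_bias_x["r"], config$male_bias_x["d"])
    pm_a <- decay_curve(mids[branch + 1L], config$male_bias_auto["N"],
                        config$male_bias_auto["r"], config$male_bias_auto["d"])
    pm <- ifelse(is_x, pm_x, pm_a)
    fb <- config$female_bias
    pf <- ifelse(is_x,
                 fb$x_old - (fb$x_old - fb$x_young) *
                   exp(fb$rate * mids[branch + 1L]),
                 fb$auto)
    pf <- pmin(pf, 1 - pm)  # keep the categorical proper
    u <- stats::runif(n)
    bias <- ifelse(u < pm, "male", ifelse(u < pm + pf, "female", "unbiased"))

    stage_truth <- matrix(FALSE, n, length(SPERM_STAGES),
                          dimnames = list(gene_id, SPERM_STAGES))
    for (cls in c("X", "autosome")) for (yg in c(TRUE, FALSE)) {
      idx <- which(class == cls & young == yg)
      if (!length(idx)) next
      pr <- stage_presence_probs(cls, yg, config)
      for (s in seq_along(SPERM_STAGES))
        stage_truth[idx, s] <- stats::runif(length(idx)) < pr[s]
    }

    # gene models: retrogenes are intronless, everything else multi-exon
    make_exons <- function(intronless) {
      if (intronless) {
        st <- round(stats::runif(1, 0, 1e6))
        matrix(c(st, st + round(stats::runif(1, 300, 3000))), 1)
      } else {
        k <- sample(2:8, 1)
        st <- round(stats::runif(1, 0, 1e6))
        lens <- round(stats::runif(k, 80, 400))
        gaps <- round(stats::runif(k - 1, 200, 2000))
        starts <- st + cumsum(c(0, lens[-k] + gaps))
        cbind(starts, starts + lens)
      }
    }
    models <- vector("list", n); names(models) <- gene_id
    for (i in seq_len(n))
      models[[i]] <- gene_model(gene_id[i],
                                if (is_x[i]) "chrX" else "chr1",
                                sample(c("+", "-"), 1),
                                make_exons(identical(mechanism[i], "retrogene")))

    # parents drawn from old multi-exon genes; hits span both full gene bodies
    old_ids <- gene_id[!young]
    hits <- NULL
    if (length(old_ids)) {
      kids <- which(young & mechanism != "de_novo")
      if (length(kids)) {
        parent <- sample(old_ids, length(kids), replace = TRUE)
        hits <- do.call(rbind, lapply(seq_along(kids), function(j) {
          ch <- models[[kids[j]]]; pa <- models[[parent[j]]]
          paralog_hit(ch$gene_id, pa$gene_id,
                      ch$span[1], ch$span[2], pa$span[1], pa$span[2],
                      e_value = 10^stats::runif(1, -30, -8))
        }))
      }
    }
    if (is.null(hits))
      hits <- data.frame(child_id = character(0), parent_id = character(0),
                         child_start = numeric(0), child_end = numeric(0),
                         parent_start = numeric(0), parent_end = numeric(0),
                         e_value = numeric(0))

    truth <- data.frame(gene_id = gene_id, branch = branch, class = class,
                        stratum = stratum, position = position,
                        mechanism = mechanism, bias = bias, young = young,
                        stringsAsFactors = FALSE)
    partition <- genome_partition(gene_id, class, stratum, position)
    list(truth = truth, stage_truth = stage_truth, models = models,
         parents = models[old_ids], hits = hits, partition = partition,
         ladder = lad, config = config)
  })
}

#' Simulate ortholog presence/absence evidence
#'
#' Each outgroup that split after a gene's true origination branch carries
#' the gene (present); deeper outgroups lack it (absent); every call is then
#' independently lost to an assembly gap (missing) with probability
#' `dropout`. With zero dropout the staircase patterns date back exactly to
#' the true branches.
#'
#' @param truth Truth data.frame from [simulate_genome()].
#' @param ladder The [branch_ladder()].
#' @param dropout Missingness probability in \[0, 1).
#' @param seed Optional seed (otherwise the ambient RNG stream is used).
#' @return Character matrix genes x species.
#' @export
simulate_ortholog_evidence <- function(truth, ladder, dropout = 0.1,
                                       seed = NULL) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  run <- function() {
    split_idx <- ladder$split_of[ladder$species]
    m <- outer(truth$branch, split_idx,
               function(b, s) ifelse(s >= b, "present", "absent"))
    dimnames(m) <- list(truth$gene_id, ladder$species)
    if (dropout > 0) {
      drop <- matrix(stats::runif(length(m)) < dropout, nrow(m))
      m[drop] <- "missing"
    }
    m
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate expression data for every downstream stage
#'
#' Builds (i) gonad intensity matrices with planted male/female effects,
#' (ii) per-stage spermatogenesis detection flags for two species (the
#' second species shares the truth pattern), (iii) two-species cell-type
#' intensity profiles with extra divergence planted in young X genes, and
#' (iv) somatic-tissue presence calls with broader expression for old genes
#' and a transcriptional bonus for X genes of the post-marsupial burst.
#' Intensities are log-normal around class means with replicate noise.
#'
#' @param truth Truth data.frame from [simulate_genome()] (pass the full
#'   genome list to reuse its `stage_truth`).
#' @param config A [sim_config()].
#' @param stage_truth Genes x stages logical matrix (taken from `truth` when
#'   a full [simulate_genome()] result is passed).
#' @param seed Optional seed.
#' @return List: `gonads` (testis/ovary matrices + sample sheet), `stages`
#'   (per species: per-stage replicate detection-flag matrices),
#'   `profiles` (per species: genes x cell-type mean intensities),
#'   `somatic` (long presence data.frame).
#' @export
simulate_expression <- function(truth, config, stage_truth = NULL,
                                seed = NULL) {
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$truth)) {
    stage_truth <- truth$stage_truth
    truth <- truth$truth
  }
  if (is.null(stage_truth)) stop("stage_truth is required")
  run <- function() {
    n <- nrow(truth)
    ids <- truth$gene_id
    nrep <- config$n_replicates
    base <- stats::rnorm(n, mean = 7, sd = 1)

    lt <- base + ifelse(truth$bias == "male", config$effect_log2fc, 0)
    lo <- base + ifelse(truth$bias == "female", config$effect_log2fc, 0)
    noise <- function() matrix(stats::rnorm(n * nrep, 0, config$noise_sd), n)
    testis <- 2^(lt + noise()); ovary <- 2^(lo + noise())
    dimnames(testis) <- list(ids, paste0("testis_", seq_len(nrep)))
    dimnames(ovary) <- list(ids, paste0("ovary_", seq_len(nrep)))
    samples <- data.frame(
      sample = c(colnames(testis), colnames(ovary)),
      tissue = rep(c("testis", "ovary"), each = nrep),
      replicate_group = rep(c("testis", "ovary"), each = nrep))

    stage_flags <- function() {
      out <- list()
      for (s in colnames(stage_truth)) {
        f <- matrix(rep(stage_truth[, s], 2), n, 2,
                    dimnames = list(ids, paste0(s, "_rep", 1:2)))
        flip <- matrix(stats::runif(n * 2) < config$flip_noise, n)
        f[flip] <- !f[flip]
        out[[s]] <- ifelse(f, "present", "absent")
      }
      out
    }
    stages <- list(mouse = stage_flags(), rat = stage_flags())

    cells <- setdiff(SPERM_STAGES, "whole_testis")
    prof_a <- matrix(stats::rgamma(n * length(cells), shape = 2), n,
                     dimnames = list(ids, cells))
    boost <- ifelse(truth$young & truth$class == "X",
                    config$divergence_boost, 1)
    pert <- matrix(stats::rnorm(n * length(cells), 0, config$divergence_sd),
                   n) * boost
    prof_b <- prof_a * exp(pert)
    profiles <- list(mouse = prof_a, rat = prof_b)

    breadth <- ifelse(truth$young, 0.25, 0.70) +
      ifelse(truth$class == "X" & truth$branch >= 5 & truth$branch <= 7,
             0.15, 0)
    somatic <- do.call(rbind, lapply(SOMATIC_TISSUES, function(ts) {
      expressed <- stats::runif(n) < breadth
      data.frame(gene_id = ids, tissue = ts,
                 call = ifelse(expressed, "present", "absent"))
    }))
    list(gonads = list(testis = testis, ovary = ovary, samples = samples),
         stages = stages, profiles = profiles, somatic = somatic)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' One-call synthetic study
#'
#' Seeds once from the config and produces genome, ortholog evidence and
#' expression data in a single reproducible bundle.
#'
#' @param config A [sim_config()].
#' @return List: `genome`, `evidence`, `expression`.
#' @export
simulate_study <- function(config) {
  genome <- simulate_genome(config)
  evidence <- simulate_ortholog_evidence(genome$truth, config$ladder,
                                         dropout = config$dropout,
                                         seed = config$seed + 1L)
  expression <- simulate_expression(genome, config, seed = config$seed + 2L)
  list(genome = genome, evidence = evidence, expression = expression)
}
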