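## End-to-end orchestration: simulate -> classify -> pnps -> aa
## substitutions -> properties -> synteny -> report, with a run manifest.

#' Demo run configuration
#'
#' A small, fully simulated end-to-end configuration (runs in well under
#' a minute). The `thresholds` block mirrors the analysis defaults:
#' outgroup E-value 0.001 with 2 species, duplication support 0.5, MAF
#' 0, MUM length 20 and cluster gap 100.
#'
#' @param seed integer seed.
#' @return a config list accepted by [runPipeline()].
#' @export
demoConfig <- function(seed = 1L) {
  list(seed = as.integer(seed),
       reference = "Scer",
       pooling = "yeast",
       sim = list(nGenes = 60L, codonsPerGene = 150L, nSnps = 2000L,
                  nIntronSnps = 5000L, intronLength = 20000L,
                  purifyingFactor = 0.5, divergence = 0.05,
                  genomeLength = 4000L, nInsertions = 2L,
                  insertionLength = 300L),
       thresholds = list(e_value = 0.001, min_outgroup_species = 2L,
                         maf_min = 0, support_min = 0.5,
                         max_gap = 100L, min_len = 20L))
}

.readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes every stage on data drawn by the generators under the
#' config's seed and writes `classification.tsv`, `events.tsv`,
#' `branch_rates.tsv`, `pnps.tsv`, `aasub_pairs.tsv`,
#' `aasub_classes.tsv`, `props.tsv`, `blocks.tsv` and a `manifest.yaml`
#' (package version, config, derived seeds) into `outDir`. Reruns with
#' the same config are byte-identical.
#'
#' @param config a config list (see [demoConfig()]) or a YAML file path.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = demoConfig(), outDir = tempfile("run")) {
  config <- .readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  simArgs <- c(list(seed = config$seed), config$sim)
  cfg <- do.call(simConfig, simArgs)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## gene histories -> classification -> branch rates
  hist <- stage("simulate", simulateGeneHistories(cfg))
  classed <- stage("classify", classifyGenes(
    hist$orthogroups, hist$duplications, hist$tree,
    wgdGenes = hist$wgdGenes, outgroupHits = hist$hits,
    supportMin = th$support_min, eMax = th$e_value,
    minOutgroupSpecies = th$min_outgroup_species))
  rates <- stage("branch_rates", branchRates(classed, hist$tree))

  ## SNP panel -> normalized PN/PS (intron-estimated matrix)
  panel <- stage("simulate_snps", simulateCdsSnps(cfg))
  mat <- stage("mutation_matrix", buildMutationMatrix(panel$snps))
  pnps <- stage("pnps", normalizedPnPs(panel$genes, panel$snps, mat,
                                       group = "all",
                                       mafMin = th$maf_min))

  ## protein family -> observed vs expected amino-acid changes
  fam <- stage("simulate_family", simulateProteinFamily(cfg, nSpecies = 2L))
  pairs <- stage("aasub_pairs", extractPairCounts(fam$alignments$ref,
                                                  fam$alignments$derived))
  freqs <- codonFrequencies(fam$ancestralCds)
  oe <- stage("aasub_expected",
              log2OE(expectedChangeTable(freqs, fam$matrix, pairs)))

  ## sequence properties of the simulated proteomes
  prof <- stage("props", {
    prot <- translateCds(panel$genes$cds, allowStops = TRUE)
    prot <- gsub("*", "", prot, fixed = TRUE)
    keep <- nchar(prot) > 0
    proteinProfiles(setNames(prot[keep], panel$genes$gene_id[keep]),
                    rep("simulated", sum(keep)))
  })

  ## genome pair -> MUM synteny blocks
  gp <- stage("simulate_genomes", simulateGenomePair(cfg))
  mums <- stage("mums", findMums(gp$a, gp$b, minLen = th$min_len))
  blocks <- stage("blocks", clusterMums(mums, maxGap = th$max_gap))

  w <- function(x, f) write.table(x, file.path(outDir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  w(classed$classification, "classification.tsv")
  ev <- rbind(
    if (nrow(classed$denovoEvents))
      data.frame(mechanism = "de_novo", classed$denovoEvents)
    else NULL,
    if (nrow(classed$dupEvents))
      data.frame(mechanism = "duplication",
                 classed$dupEvents[c("og_id", "branch")])
    else NULL)
  if (is.null(ev)) ev <- data.frame(mechanism = character(),
                                    og_id = character(), branch = character())
  w(ev, "events.tsv")
  w(rates, "branch_rates.tsv")
  w(pnps, "pnps.tsv")
  w(oe$pairs, "aasub_pairs.tsv")
  w(oe$classes, "aasub_classes.tsv")
  w(prof, "props.tsv")
  w(blocks, "blocks.tsv")
  manifest <- list(
    package = "geneBirthDynamics",
    version = as.character(utils::packageVersion("geneBirthDynamics")),
    config = config,
    derived_seeds = list(histories = .childSeed(config$seed, 1L),
                         snps = .childSeed(config$seed, 2L),
                         family = .childSeed(config$seed, 3L),
                         genomes = .childSeed(config$seed, 4L)))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(list(histories = hist, classed = classed, rates = rates,
                 pnps = pnps, oe = oe, profiles = prof, blocks = blocks,
                 outDir = outDir))
}

#' Summarize pipeline outputs into figure-level tables
#'
#' Reads whatever stage outputs are present in a run directory and
#' writes `report_events.tsv` (events and normalized rates per branch),
#' `report_pnps.tsv` and `report_aasub.tsv`. Missing stages are skipped;
#' empty stage outputs yield empty tables with headers.
#'
#' @param outDir a [runPipeline()] output directory.
#' @return invisibly, the list of report tables.
#' @export
makeReport <- function(outDir) {
  rd <- function(f) {
    p <- file.path(outDir, f)
    if (!file.exists(p)) return(NULL)
    read.delim(p)
  }
  out <- list()
  rates <- rd("branch_rates.tsv")
  if (!is.null(rates)) {
    out$events <- rates[, c("branch", "n_denovo_events", "n_dup_events",
                            "normalized_denovo", "normalized_dup")]
    write.table(out$events, file.path(outDir, "report_events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pnps <- rd("pnps.tsv")
  if (!is.null(pnps)) {
    out$pnps <- pnps
    write.table(out$pnps, file.path(outDir, "report_pnps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cls <- rd("aasub_classes.tsv")
  if (!is.null(cls)) {
    out$aasub <- cls
    write.table(out$aasub, file.path(outDir, "report_aasub.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
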