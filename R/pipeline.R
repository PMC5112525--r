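# End-to-end orchestration: simulate -> similarity -> ancestry -> trace ->
# annotate -> de-filter -> scan-motifs -> intersect, with a JSON manifest.

.writeTsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s=%s", k, paste(params[[k]], collapse = ",")), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

.cfgGet <- function(config, path, default = NULL) {
  node <- config
  for (k in path) {
    if (is.null(node[[k]])) return(default)
    node <- node[[k]]
  }
  node
}

#' Default pipeline configuration (fully synthetic run)
#'
#' A small end-to-end configuration: simulates a three-founder backcross
#' pedigree on a random reference genome with gene models, then runs every
#' downstream stage on the simulated data.
#'
#' @param outdir output directory.
#' @param seed integer seed driving every stage.
#' @param chromLengthBp chromosome length for the simulated genome
#'   (default 1 Mb; keep small for smoke runs).
#' @param nGenes genes to place on the simulated genome.
#' @return A nested configuration list accepted by [runPipeline()].
#' @export
defaultPipelineConfig <- function(outdir, seed = 1L, chromLengthBp = 1e6,
                                  nGenes = 30) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = list(n_chrom = 2L, chrom_length_bp = chromLengthBp,
                    chrom_morgans = 1, snp_density = 1e-3,
                    polymorphism_rate = 0.5, missing_rate = 0,
                    n_genes = nGenes),
    roles = list(
      offspring = "offspring", recurrent = "recurrent",
      donors = c("donor", "grandparentA", "grandparentB"),
      ancestors = c("grandparentA", "grandparentB", "recurrent"),
      panel = c("grandparentA", "grandparentB", "recurrent", "donor",
                "offspring")),
    ancestry = list(window_bp = 1e5, step_bp = 1e4, min_snps = 10,
                    tie_margin = 0.05, fallback_threshold = 0.5,
                    min_windows = 50),
    trace = list(promoter_bp = 2000),
    annotation = list(promoter_bp = 2000, splice_bp = 2),
    expression = list(fc_threshold = 2, p_threshold = 0.05,
                      pseudocount = 0.1, deg_fraction = 0.2),
    motif = list(promoter_length = 3000, threshold_fraction = 0.8))
}

.validatePipelineConfig <- function(config) {
  for (role in c("offspring", "recurrent"))
    if (is.null(.cfgGet(config, c("roles", role))))
      stop("config error: roles$", role, " is required")
  if (is.null(.cfgGet(config, c("roles", "donors"))))
    stop("config error: roles$donors is required")
  if (is.null(config$outdir)) stop("config error: outdir is required")
  if (is.null(config$seed)) stop("config error: seed is required")
  roles <- config$roles
  if (roles$offspring == roles$recurrent)
    stop("config error: offspring and recurrent must differ")
  if (is.null(config$simulate) && is.null(.cfgGet(config, c("paths", "vcf"))))
    stop("config error: either a simulate block or paths$vcf is required")
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order, writing each stage's outputs
#' before the next starts, and ends with a JSON run manifest recording the
#' package version, full configuration and per-stage outputs. A stage
#' failure aborts with the failing stage named; outputs already written are
#' retained.
#'
#' @param config nested list (see [defaultPipelineConfig()]) or path to a
#'   YAML file with the same structure.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the key in-memory results (`sim`,
#'   `similarity`, `blocks`, `contributions`, `traced`, `annotations`,
#'   `degs`, `network`, `manifest`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validatePipelineConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  roles <- config$roles
  outputs <- list()
  say <- function(...) if (!quiet) message("[pedtrace] ", ...)
  stage <- function(name, fun) {
    say("stage: ", name)
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  # ---- inputs: simulate or load -------------------------------------------
  stage("simulate", function() {
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      spec <- defaultPedigreeSpec(
        seed = seed, nChrom = sc$n_chrom,
        chromLengthBp = sc$chrom_length_bp,
        chromMorgans = sc$chrom_morgans, snpDensity = sc$snp_density,
        polymorphismRate = sc$polymorphism_rate,
        missingRate = if (is.null(sc$missing_rate)) 0 else sc$missing_rate)
      genome <- simulateGenome(
        setNames(rep(as.integer(sc$chrom_length_bp), sc$n_chrom),
                 spec@genome$chrom), seed = seed)
      models <- simulateGeneModels(genome, nGenes = sc$n_genes, seed = seed)
      sim <- runPedigree(spec, genome = genome)
      res$sim <<- sim; res$genome <<- genome; res$models <<- models
      res$gm <<- sim@genotypes
      outputs$vcf <<- file.path(outdir, "genotypes.vcf")
      writeVcfGenotypes(sim@genotypes, outputs$vcf)
      outputs$gff3 <<- file.path(outdir, "genes.gff3")
      writeGeneModelsGff3(models, outputs$gff3)
      outputs$fasta <<- file.path(outdir, "genome.fa")
      writeXStringSet(genome, outputs$fasta)
      outputs$truth_bed <<- character()
      for (ln in names(sim@mosaics)) {
        p <- file.path(outdir, sprintf("truth_%s.bed", ln))
        writeTruthBed(sim@mosaics[[ln]], p)
        outputs$truth_bed <<- c(outputs$truth_bed, p)
      }
    } else {
      p <- config$paths
      res$gm <<- readVcfGenotypes(p$vcf)
      res$models <<- if (!is.null(p$gff3)) readGeneModels(p$gff3)
      res$genome <<- if (!is.null(p$fasta)) readDNAStringSet(p$fasta)
      res$sim <<- NULL
    }
  })

  # ---- similarity ----------------------------------------------------------
  stage("similarity", function() {
    sm <- pairwiseSimilarity(res$gm, minSites = 10)
    res$similarity <<- sm
    outputs$similarity <<- file.path(outdir, "similarity.tsv")
    writeSimilarityTsv(sm, outputs$similarity,
                       params = list(het_policy = sm@hetPolicy))
  })

  # ---- ancestry ------------------------------------------------------------
  stage("ancestry", function() {
    ac <- config$ancestry
    panel <- if (!is.null(roles$panel)) roles$panel else sampleIds(res$gm)
    gmPanel <- subsetSamples(res$gm, panel)
    sl <- seqlengths(variantSites(res$gm))
    windows <- makeWindows(sl, windowBp = ac$window_bp, stepBp = ac$step_bp)
    prof <- windowDiversity(gmPanel, windows, roles$offspring,
                            roles$ancestors, minSnps = ac$min_snps)
    thr <- ancestryThresholds(
      prof, minWindows = ac$min_windows, fallback = ac$fallback_threshold)
    blocks <- callBlocks(prof, thr, tieMargin = ac$tie_margin)
    contrib <- contributionFractions(
      blocks, setNames(as.numeric(sl), names(sl)))
    res$profile <<- prof; res$blocks <<- blocks
    res$contributions <<- contrib
    outputs$blocks_bed <<- file.path(outdir, "blocks.bed")
    writeBlocksBed(blocks, outputs$blocks_bed)
    outputs$contributions <<- file.path(outdir, "contributions.tsv")
    .writeTsv(data.frame(ancestor = names(contrib$fractions),
                         fraction = unname(contrib$fractions)),
              outputs$contributions,
              params = list(assigned_bp = contrib$assigned_bp,
                            unassigned_bp = contrib$unassigned_bp,
                            window_bp = ac$window_bp, step_bp = ac$step_bp))
    outputs$contributions_json <<- file.path(outdir, "contributions.json")
    write_json(list(fractions = as.list(contrib$fractions),
                    assigned_bp = contrib$assigned_bp,
                    unassigned_bp = contrib$unassigned_bp),
               outputs$contributions_json, auto_unbox = TRUE, digits = NA)
  })

  # ---- trace ---------------------------------------------------------------
  stage("trace", function() {
    traced <- traceSpecificAlleles(res$gm, roles$offspring,
                                   roles$recurrent, roles$donors)
    res$traced <<- traced
    outputs$traced_snps <<- file.path(outdir, "traced_snps.tsv")
    writeTraceTsv(traced, outputs$traced_snps,
                  params = list(offspring = roles$offspring,
                                recurrent = roles$recurrent,
                                donors = roles$donors))
    if (!is.null(res$models)) {
      asg <- assignToGenes(traced, res$models,
                           promoterBp = .cfgGet(config,
                             c("trace", "promoter_bp"), 2000))
      res$tracedGenes <<- asg$genes
      outputs$traced_genes <<- file.path(outdir, "traced_genes.tsv")
      .writeTsv(asg$genes, outputs$traced_genes)
    }
  })

  # ---- annotate ------------------------------------------------------------
  if (!is.null(res$models) && !is.null(res$genome)) stage("annotate", function() {
    an <- config$annotation
    ann <- annotateSnps(variantSites(res$gm), res$models, res$genome,
                        promoterBp = an$promoter_bp,
                        spliceBp = an$splice_bp)
    res$annotations <<- ann
    outputs$annotations <<- file.path(outdir, "snp_annotations.tsv")
    .writeTsv(ann, outputs$annotations)
    s <- annotationSummary(ann)
    outputs$annotation_summary <<- file.path(outdir,
                                             "annotation_summary.json")
    write_json(list(feature_counts = as.list(s$feature_counts),
                    feature_percent = as.list(s$feature_percent),
                    effect_counts = as.list(s$effect_counts),
                    nonsyn_syn_ratio = s$nonsyn_syn_ratio),
               outputs$annotation_summary, auto_unbox = TRUE, digits = NA)
  })

  # ---- de-filter -----------------------------------------------------------
  if (!is.null(res$models)) stage("de-filter", function() {
    ec <- config$expression
    expr <- simulateExpression(mcols(geneRanges(res$models))$gene_id,
                               degFraction = ec$deg_fraction, seed = seed)
    sets <- lapply(expr$contrasts$label, function(lb)
      degsForContrast(expr, lb, fcThreshold = ec$fc_threshold,
                      pThreshold = ec$p_threshold,
                      pseudocount = ec$pseudocount))
    degs <- do.call(unionDegs, sets)
    res$expr <<- expr; res$degs <<- degs
    outputs$degs <<- file.path(outdir, "degs.tsv")
    .writeTsv(data.frame(
      gene_id = c(degs$up, degs$down),
      direction = c(rep("up", length(degs$up)),
                    rep("down", length(degs$down)))),
      outputs$degs,
      params = list(fc_threshold = ec$fc_threshold,
                    p_threshold = ec$p_threshold))
  })

  # ---- scan-motifs ---------------------------------------------------------
  if (!is.null(res$models) && !is.null(res$genome) && !is.null(res$degs))
    stage("scan-motifs", function() {
      mc <- config$motif
      degGenes <- unique(c(res$degs$up, res$degs$down))
      if (!length(degGenes)) degGenes <- mcols(geneRanges(res$models))$gene_id
      proms <- extractPromoters(res$models, res$genome, degGenes,
                                length = mc$promoter_length)
      pwmPath <- .cfgGet(config, c("paths", "pwms"), toyPwmFile())
      pwms <- readJasparPfm(pwmPath)
      net <- buildNetwork(proms, pwms,
                          thresholdFraction = mc$threshold_fraction)
      res$network <<- net
      outputs$network_sif <<- file.path(outdir, "network.sif.tsv")
      outputs$network_hits <<- file.path(outdir, "network_hits.tsv")
      writeNetworkTsv(net, outputs$network_sif, outputs$network_hits)
    })

  # ---- intersect -----------------------------------------------------------
  if (!is.null(res$degs) && !is.null(res$tracedGenes))
    stage("intersect", function() {
      ov <- intersectWithTracedGenes(res$degs, res$tracedGenes)
      res$tracedDegs <<- ov
      outputs$traced_deg_overlap <<- file.path(outdir,
                                               "traced_deg_overlap.tsv")
      .writeTsv(ov, outputs$traced_deg_overlap)
    })

  # ---- manifest ------------------------------------------------------------
  manifest <- list(
    package = "pedtrace",
    version = as.character(utils::packageVersion("pedtrace")),
    seed = seed,
    config = config,
    outputs = outputs)
  manifestPath <- file.path(outdir, "manifest.json")
  write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
             null = "null")
  res$manifest <- manifest
  say("done: ", length(outputs), " output families in ", outdir)
  invisible(res)
}
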