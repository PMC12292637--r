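## End-to-end orchestration: fixtures -> VQ-GAN -> latents -> clustering
## sweep -> validity-index consensus -> conditional diffusion -> sampling ->
## evaluation. Every stage writes its artifacts under the run directory,
## tagged with a hash of the configuration, and is skipped on resume when a
## matching artifact exists.

#' Desk-scale pipeline configuration
#'
#' A configuration that completes the full pipeline on one CPU in minutes:
#' 32-px tiles, 8 x 8 latent grids, T = 50 diffusion steps, reduced epochs.
#' Override any field via `...`.
#'
#' @param ... named overrides of the defaults.
#' @return a list of class `"PipelineConfig"`.
#' @export
deskConfig <- function(...) {
  cfg <- list(
    scale = "desk",
    nClasses = 3L, nPerClass = 16L, nPerClassTest = 4L, tileSize = 32L,
    latentDim = 8L, codebookSize = 32L, baseChannels = 12L, nDown = 2L,
    beta = 0.2, lambdaPerc = 1.0, lambdaAdv = 0.5,
    vqEpochs = 16L, vqBatch = 8L, vqLr = 1e-3, advWarmupSteps = 1e9,
    kRange = 2:4, clusterIters = 300L, muSat = 1.0, featureMode = "mean-pool",
    ## linear-schedule endpoints scaled by 1000/T so the terminal
    ## signal-to-noise ratio matches the T = 1000 chain (alphaBar_T ~ 0)
    timesteps = 50L, betaStart = 0.002, betaEnd = 0.4,
    ldmEpochs = c(60L, 15L, 15L), ldmLrs = c(1.0, 1e-3, 1.0),
    ldmBatch = 8L, ldmChannels = 24L,
    ldmNDown = 1L, nPerClusterSample = 8L,
    seed = 1L, outDir = tempfile("cldm_run_")
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

#' Study-scale pipeline configuration
#'
#' Mirrors the study's hyperparameter tables: 128-px tiles, 32 x 32 x 16
#' latents, codebook of 128, VQ-GAN trained 20 epochs with Adam at 1e-4
#' (batch 16), diffusion with T = 1000 linear steps, U-Net bottleneck 8 x 8,
#' three phases (Adadelta 0.003 x 600, Adam 1e-4 x 130, Adadelta
#' 0.003 x 70), cluster sweep k = 10..16. Not intended for CPU test runs.
#'
#' @param ... named overrides.
#' @return a `"PipelineConfig"`.
#' @export
paperConfig <- function(...) {
  deskConfig(
    scale = "paper", tileSize = 128L, latentDim = 16L, codebookSize = 128L,
    baseChannels = 32L, nDown = 2L, vqEpochs = 20L, vqBatch = 16L,
    vqLr = 1e-4, kRange = 10:16, timesteps = 1000L, betaStart = 1e-4,
    betaEnd = 0.02, ldmEpochs = c(600L, 130L, 70L),
    ldmLrs = c(0.003, 1e-4, 0.003), ldmBatch = 16L, ldmChannels = 64L,
    ldmNDown = 2L, ...
  )
}

configHash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg[sort(names(cfg))])),
             collapse = "\n")
  ## small stable text hash (djb2) -- avoids a digest dependency
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

stageArtifact <- function(cfg, stage) {
  file.path(cfg$outDir, sprintf("stage_%s_%s.rds", stage, configHash(cfg)))
}

runStage <- function(cfg, stage, fn, resume = TRUE, verbose = FALSE) {
  path <- stageArtifact(cfg, stage)
  if (resume && file.exists(path)) {
    if (verbose) message("stage ", stage, ": reusing ", basename(path))
    return(readRDS(path))
  }
  if (verbose) message("stage ", stage, ": running")
  out <- fn()
  saveRDS(out, path)
  out
}

#' Run the full cluster-conditioned latent diffusion pipeline
#'
#' Executes, in order: fixture generation, VQ-GAN training, latent/feature
#' extraction, a clustering sweep over `kRange` with the five validity
#' indices per k, consensus selection of k, three-phase conditional
#' diffusion training for the consensus assignment, per-cluster sampling,
#' and image-quality evaluation of the samples against their conditioning
#' sources. All randomness flows from `config$seed`. Artifacts (validity
#' and similarity CSVs, manifest JSON, stage RDS files) are written under
#' `config$outDir`; rerunning with the same config resumes from existing
#' stage artifacts.
#'
#' @param config a [deskConfig()] / [paperConfig()] list.
#' @param resume reuse stage artifacts with a matching config hash.
#' @param verbose print stage progress.
#' @return the run manifest (list), invisibly also written as
#'   `manifest.json`.
#' @export
runPipeline <- function(config = deskConfig(), resume = TRUE,
                        verbose = FALSE) {
  cfg <- config
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(configHash = configHash(cfg), seed = cfg$seed,
                   scale = cfg$scale, stages = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  ## 1. fixtures
  fix <- runStage(cfg, "fixtures", function() {
    train <- generateTileSet(cfg$nClasses, cfg$nPerClass, cfg$tileSize,
                             seed = cfg$seed, split = "train")
    test <- generateTileSet(cfg$nClasses, cfg$nPerClassTest, cfg$tileSize,
                            seed = cfg$seed + 1L, split = "test")
    list(train = train, test = test)
  }, resume, verbose)
  manifest$stages$fixtures <- basename(stageArtifact(cfg, "fixtures"))

  ## 2. VQ-GAN
  vqr <- runStage(cfg, "vqgan", function() {
    model0 <- vqganModel(size = cfg$tileSize, latentDim = cfg$latentDim,
                         codebookSize = cfg$codebookSize,
                         baseChannels = cfg$baseChannels, nDown = cfg$nDown,
                         beta = cfg$beta, lambdaPerc = cfg$lambdaPerc,
                         lambdaAdv = cfg$lambdaAdv, seed = cfg$seed)
    mseUntrained <- reconstructionMse(model0, fix$test)
    tr <- trainVqgan(fix$train, model = model0, epochs = cfg$vqEpochs,
                     batchSize = cfg$vqBatch, lr = cfg$vqLr,
                     advWarmupSteps = cfg$advWarmupSteps, seed = cfg$seed)
    list(model = tr$model, losses = tr$losses,
         mseUntrained = mseUntrained,
         mseTrained = reconstructionMse(tr$model, fix$test))
  }, resume, verbose)
  utils::write.csv(vqr$losses, file.path(cfg$outDir, "vqgan_losses.csv"),
                   row.names = FALSE)
  manifest$stages$vqgan <- basename(stageArtifact(cfg, "vqgan"))
  manifest$reconstruction <- list(mseTrained = vqr$mseTrained,
                                  mseUntrained = vqr$mseUntrained)

  ## 3. latents + features (+ augmented features for SAT)
  lat <- runStage(cfg, "latents", function() {
    vq <- vqr$model
    qs <- lapply(tiles(fix$train), function(tl)
      quantizeLatent(encodeTile(vq, tl), vq$codebook))
    feats <- t(vapply(qs, latentFeatures, mode = cfg$featureMode,
                      numeric(featureLength(cfg))))
    augSeeds <- withr::with_seed(cfg$seed + 2L,
      sample.int(.Machine$integer.max - 1L, length(qs)))
    aug <- t(vapply(seq_along(qs), function(i) {
      at <- augmentTile(tiles(fix$train)[[i]], augSeeds[i])
      latentFeatures(quantizeLatent(encodeTile(vq, at), vq$codebook),
                     cfg$featureMode)
    }, numeric(featureLength(cfg))))
    list(latents = lapply(qs, latentEmbedded), features = feats,
         augmented = aug)
  }, resume, verbose)
  manifest$stages$latents <- basename(stageArtifact(cfg, "latents"))

  ## 4. clustering sweep + validity indices
  sweep <- runStage(cfg, "cluster_sweep", function() {
    runs <- lapply(cfg$kRange, function(k) {
      trainClustering(lat$features, k, augmented = lat$augmented,
                      muSat = cfg$muSat, iters = cfg$clusterIters,
                      seed = cfg$seed + k)
    })
    names(runs) <- as.character(cfg$kRange)
    idx <- do.call(rbind, lapply(seq_along(runs), function(i) {
      labs <- runs[[i]]$labels
      if (length(unique(labs)) < 2L) {
        ## degenerate head (all mass on one cluster): worst-possible row
        return(data.frame(k = cfg$kRange[i], ch = -Inf, c_index = Inf,
                          dunn = -Inf, hartigan = -Inf, mcclain_rao = Inf))
      }
      r <- validityIndexReport(lat$features, labs)
      r$k <- cfg$kRange[i]   # report the requested k even if a cluster died
      r
    }))
    list(runs = runs, indices = idx, consensus = consensusSelectK(idx))
  }, resume, verbose)
  utils::write.csv(sweep$indices, file.path(cfg$outDir, "validity_indices.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(consensus_k = sweep$consensus$k, winners = as.list(sweep$consensus$winners)),
    file.path(cfg$outDir, "consensus_k.json"), auto_unbox = TRUE)
  manifest$stages$cluster_sweep <- basename(stageArtifact(cfg, "cluster_sweep"))
  manifest$consensusK <- sweep$consensus$k

  ## 5. conditional diffusion for the consensus assignment
  kSel <- sweep$consensus$k
  selRun <- sweep$runs[[as.character(kSel)]]
  ldm <- runStage(cfg, "diffusion", function() {
    trainLDM(lat$latents, selRun$labels, K = kSel,
             phases = ldmPhases(cfg$ldmEpochs, cfg$ldmLrs),
             schedule = linearSchedule(cfg$timesteps, cfg$betaStart,
                                       cfg$betaEnd),
             batchSize = cfg$ldmBatch, channels = cfg$ldmChannels,
             nDown = cfg$ldmNDown, head = selRun$head,
             features = lat$features, augmented = lat$augmented,
             muSat = cfg$muSat, seed = cfg$seed)
  }, resume, verbose)
  utils::write.csv(ldm$losses, file.path(cfg$outDir, "ldm_losses.csv"),
                   row.names = FALSE)
  manifest$stages$diffusion <- basename(stageArtifact(cfg, "diffusion"))

  ## 6. sampling + evaluation + fidelity
  evalr <- runStage(cfg, "evaluation", function() {
    vq <- vqr$model
    clusters <- sort(unique(ldm$conditions))
    gen <- NULL
    intended <- integer(0)
    for (cl in clusters) {
      g <- sampleTiles(ldm, vq, cfg$nPerClusterSample, cl,
                       seed = cfg$seed + 100L + cl)
      gen <- if (is.null(gen)) g else
        TileSet(c(tiles(gen), tiles(g)),
                ids = c(tileIds(gen), tileIds(g)),
                labels = c(tileLabels(gen), tileLabels(g)), split = "test")
      intended <- c(intended, rep(cl, cfg$nPerClusterSample))
    }
    ## by-source references: for each generated tile, a training tile whose
    ## assignment matches the conditioning cluster
    refIdx <- unlist(lapply(clusters, function(cl) {
      src <- which(ldm$conditions == cl)
      rep_len(src, cfg$nPerClusterSample)
    }))
    refs <- fix$train[refIdx]
    sim <- evaluateGeneration(gen, refs, extractor = vq$extractor, k = kSel)
    fid <- conditionalFidelity(gen, intended, vq, selRun$head,
                               cfg$featureMode)
    list(generated = gen, similarity = sim, fidelity = fid)
  }, resume, verbose)
  utils::write.csv(evalr$similarity,
                   file.path(cfg$outDir, "similarity_report.csv"),
                   row.names = FALSE)
  utils::write.csv(evalr$fidelity$table,
                   file.path(cfg$outDir, "fidelity.csv"), row.names = FALSE)
  manifest$stages$evaluation <- basename(stageArtifact(cfg, "evaluation"))
  manifest$similarity <- as.list(evalr$similarity)
  manifest$fidelityOverall <- evalr$fidelity$overall
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

featureLength <- function(cfg) {
  if (cfg$featureMode == "mean-pool") cfg$latentDim
  else (cfg$tileSize %/% (2L^cfg$nDown))^2L * cfg$latentDim
}

## Held-out mean reconstruction MSE through encode-quantize-decode.
reconstructionMse <- function(model, dataset) {
  mean(vapply(tiles(dataset), function(tl) {
    q <- quantizeLatent(encodeTile(model, tl), model$codebook)
    mean((decodeLatent(model, q) - tl)^2)
  }, numeric(1)))
}

#' Summarize a pipeline run
#'
#' Renders a plain-text summary of a run directory (consensus k, validity
#' and similarity tables, per-cluster fidelity) and writes PNG image grids
#' of reconstructions and generated samples when the corresponding stage
#' artifacts exist; stages without artifacts are reported as not run.
#'
#' @param outDir the `outDir` of a [runPipeline()] run.
#' @return character vector of summary lines, invisibly; also printed.
#' @export
reportPipeline <- function(outDir) {
  lines <- c(sprintf("Pipeline run at %s", outDir))
  manFile <- file.path(outDir, "manifest.json")
  if (file.exists(manFile)) {
    man <- jsonlite::read_json(manFile)
    lines <- c(lines, sprintf("config hash %s, seed %s", man$configHash,
                              man$seed))
    if (!is.null(man$consensusK))
      lines <- c(lines, sprintf("consensus cluster count: %s", man$consensusK))
    if (!is.null(man$reconstruction))
      lines <- c(lines, sprintf(
        "held-out reconstruction MSE: %.4f (untrained %.4f)",
        man$reconstruction$mseTrained, man$reconstruction$mseUntrained))
    if (!is.null(man$fidelityOverall))
      lines <- c(lines, sprintf("conditional fidelity (overall): %.3f",
                                man$fidelityOverall))
  } else lines <- c(lines, "manifest: not found")
  for (f in c("validity_indices.csv", "similarity_report.csv",
              "fidelity.csv")) {
    p <- file.path(outDir, f)
    if (file.exists(p)) {
      lines <- c(lines, paste0("-- ", f),
                 utils::capture.output(print(utils::read.csv(p))))
    } else lines <- c(lines, paste0("-- ", f, ": not run"))
  }
  ## image grids from stage artifacts, when present
  rds <- list.files(outDir, pattern = "^stage_evaluation_.*rds$",
                    full.names = TRUE)
  if (length(rds)) {
    ev <- readRDS(rds[1])
    writeTileGrid(ev$generated, file.path(outDir, "samples_grid.png"))
    lines <- c(lines, "wrote samples_grid.png")
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' Write a PNG grid of tiles
#'
#' @param dataset a [TileSet-class].
#' @param path output PNG path.
#' @param nCol number of grid columns.
#' @export
writeTileGrid <- function(dataset, path, nCol = 8L) {
  tl <- tiles(dataset)
  s <- tileSize(dataset)
  n <- length(tl)
  nCol <- min(nCol, n)
  nRow <- ceiling(n / nCol)
  grid <- array(1, c(nRow * s, nCol * s, 3))
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% nCol
    cc <- (i - 1L) %% nCol
    grid[r * s + seq_len(s), cc * s + seq_len(s), ] <- tl[[i]]
  }
  png::writePNG(grid, path)
  invisible(path)
}
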