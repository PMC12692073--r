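## End-to-end orchestration: one-call reproduction of the published assay
## correlation table and the full synthetic pipeline with all seven block
## combinations.

.TABLE3_PRINTED <- matrix(
  c(1,      0.8592, 0.5348, 0.8097,
    0.8592, 1,      0.6771, 0.8532,
    0.5348, 0.6771, 1,      0.8389,
    0.8097, 0.8532, 0.8389, 1),
  4, 4, dimnames = list(c("tpc", "tfc", "frap", "abts"),
                        c("tpc", "tfc", "frap", "abts")))

#' Reproduce the published assay correlation table
#'
#' Computes the class-mean Pearson correlation matrix over the four
#' spectrophotometric variables (TPC, TFC, FRAP, ABTS) from the built-in
#' class means, and reports it alongside the published values with
#' absolute deviations. The published column ordering is kept: note that
#' the printed "antiradical activity" column matches the FRAP class means
#' numerically and "antioxidant activity" matches ABTS, the opposite of
#' the assays' usual naming; the correlations here are keyed to the
#' numeric identity.
#'
#' @return list: \code{computed} (4 x 4 class-mean Pearson matrix),
#'   \code{printed} (published values), \code{deviation} (absolute
#'   differences).
#' @examples
#' tab <- reproduceTable3()
#' tab$computed["tpc", "tfc"]  # 0.8590
#' @export
reproduceTable3 <- function() {
  sp <- citrusClassSpecs()
  sub <- sp[sp$block == "spectro", ]
  m <- matrix(sub$mean, nrow = 6, byrow = TRUE,
              dimnames = list(unique(as.character(sub$class)),
                              sub$feature[sub$class == sub$class[1L]]))
  m <- m[, c("tpc", "tfc", "frap", "abts")]
  computed <- pearsonMatrix(m, mode = "class_mean",
                            classes = rownames(m))
  attr(computed, "mode") <- NULL
  list(computed = computed, printed = .TABLE3_PRINTED,
       deviation = abs(computed - .TABLE3_PRINTED))
}

.BLOCK_COMBOS <- list(
  ftir = "ftir", spectro = "spectro", physico = "physico",
  `ftir+spectro` = c("ftir", "spectro"),
  `ftir+physico` = c("ftir", "physico"),
  `spectro+physico` = c("spectro", "physico"),
  `ftir+spectro+physico` = c("ftir", "spectro", "physico"))

#' Cross-validated accuracy for every block combination
#'
#' Fits LDA with stratified k-fold cross-validation on each of the seven
#' block combinations (three single blocks, three two-block fusions, the
#' full multi-block fusion) of a replicate MultiBlock.
#'
#' @param mb a \linkS4class{MultiBlock} with blocks ftir, spectro,
#'   physico.
#' @param folds CV folds (default 5).
#' @param seed fold-shuffle seed.
#' @param scaleMode passed to \code{\link{cvAccuracy}}.
#' @return named list of \code{peelCV} results, one per combination.
#' @export
fusionAccuracies <- function(mb, folds = 5L, seed = 1L,
                             scaleMode = "global") {
  lapply(.BLOCK_COMBOS, function(ids) {
    fused <- concatenateBlocks(mb, ids)
    cvAccuracy(measurements(fused), classLabels(fused), folds = folds,
               seed = seed, scaleMode = scaleMode)
  })
}

#' Run the full synthetic pipeline and write its report bundle
#'
#' Simulates replicate blocks from the built-in class specifications,
#' profiles synthetic peel-texture images per class, runs the per-feature
#' class comparisons, evaluates all seven LDA block combinations by
#' stratified cross-validation, and builds the thresholded correlation
#' network over the fused feature space. All outputs are written under
#' \code{outDir} (CSV / JSON / GraphML); the run is deterministic per
#' seed.
#'
#' @param outDir output directory, created if needed.
#' @param seed master seed.
#' @param nPerClass replicates per class (default 10).
#' @param folds CV folds.
#' @param edgeThreshold,boldThreshold network |r| thresholds.
#' @param alpha significance level for the letter displays.
#' @param scaleMode CV scaling mode.
#' @param nImagesPerClass synthetic texture images per class (default 2).
#' @return invisibly, the summary list (also written as summary.json).
#' @export
runPipeline <- function(outDir, seed = 42L, nPerClass = 10L, folds = 5L,
                        edgeThreshold = 0.60, boldThreshold = 0.80,
                        alpha = 0.05, scaleMode = "global",
                        nImagesPerClass = 2L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(stage, ...)
    message(sprintf("[peelfusion:%s] %s", stage, sprintf(...)))

  log_("simulate", "seed %d, %d replicates/class", seed, nPerClass)
  mb <- simulateReplicateBlocks(nPerClass = nPerClass, seed = seed)
  writeBlockCSV(mb, outDir)

  log_("texture", "%d image(s) per class", nImagesPerClass)
  regimes <- citrusImageRegimes()
  specs <- peelImageSpecs()
  texRows <- list()
  for (cl in names(regimes)) {
    for (i in seq_len(nImagesPerClass)) {
      argl <- specs[[regimes[[cl]]]]
      img <- do.call(simulateTextureImage,
                     c(argl, list(seed = .subSeed(seed, 9L,
                       match(cl, names(regimes)) * 10L + i))))
      prof <- textureProfile(img)
      texRows[[paste(cl, i)]] <- data.frame(
        class = cl, image = i, t(prof$mean), stringsAsFactors = FALSE)
    }
  }
  texTab <- do.call(rbind, texRows)
  rownames(texTab) <- NULL
  write.csv(texTab, file.path(outDir, "texture_features.csv"),
            row.names = FALSE)

  log_("stats", "class comparison tables, alpha = %.2f", alpha)
  for (id in blockIds(mb)) {
    tab <- classComparisonTable(getBlock(mb, id), alpha = alpha)
    write.csv(tab, file.path(outDir, sprintf("stats_%s.csv", id)),
              row.names = FALSE)
  }

  log_("fusion", "CV over %d block combinations", length(.BLOCK_COMBOS))
  cvs <- fusionAccuracies(mb, folds = folds, seed = seed,
                          scaleMode = scaleMode)

  log_("network", "|r| >= %.2f, bold >= %.2f", edgeThreshold, boldThreshold)
  fused <- concatenateBlocks(mb)
  C <- pearsonMatrix(fused)
  write.csv(C, file.path(outDir, "fused_correlation.csv"))
  net <- buildNetwork(C, edgeThreshold, boldThreshold)
  writeNetwork(net, graphml = file.path(outDir, "network.graphml"),
               edgeCsv = file.path(outDir, "network_edges.csv"))
  lay <- springLayout(net, seed = seed)
  write.csv(lay, file.path(outDir, "network_layout.csv"), row.names = FALSE)

  topPairs <- list()
  for (combo in list(c("ftir", "spectro"), c("ftir", "physico"),
                     c("spectro", "physico"))) {
    tp <- crossBlockTopPairs(getBlock(mb, combo[1L]),
                             getBlock(mb, combo[2L]), k = 5L)
    tp$blocks <- paste(combo, collapse = "+")
    topPairs[[paste(combo, collapse = "+")]] <- tp
  }
  write.csv(do.call(rbind, topPairs), file.path(outDir, "top_pairs.csv"),
            row.names = FALSE)

  summary_ <- list(
    seed = seed, n_per_class = nPerClass, folds = folds,
    scale_mode = scaleMode,
    cv_accuracy = lapply(cvs, function(cv)
      list(mean = cv$mean, sd = cv$sd, folds = cv$foldAccuracy)),
    network = list(nodes = nrow(net$nodes), edges = nrow(net$edges),
                   bold_edges = sum(net$edges$bold),
                   edge_threshold = edgeThreshold,
                   bold_threshold = boldThreshold))
  jsonlite::write_json(summary_, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary_)
}
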