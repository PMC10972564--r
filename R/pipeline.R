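## End-to-end orchestration: simulate -> uptake -> dAUC -> classify ->
## NMR -> report, with YAML config and seeded reproducibility.

#' Default run configuration
#'
#' @return Named list of pipeline parameters: seed, noise levels,
#'   replicate count, segment definitions, classification thresholds,
#'   reference ids, and output directory.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    noise_sd = 0,
    volume_noise_sd = 0,
    n_replicates = 2L,
    segments = list(DFG_161_168 = c(161L, 168L),
                    P1_191_198 = c(191L, 198L)),
    thresholds = c(t_low = 0.4, t_high = 0.6),
    reference_ids = c("VTX11e", "GDC0994"),
    pR_2P = 0.8,
    pR_0P = 0,
    output_dir = ".")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' \code{\link{defaultRunConfig}}.
#'
#' @param path path to a YAML config file.
#' @return Validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(base, cfg)
  if (!is.null(cfg$thresholds)) out$thresholds <- unlist(cfg$thresholds)
  if (!is.null(cfg$segments))
    out$segments <- lapply(cfg$segments, as.integer)
  validateRunConfig(out)
}

#' Validate a run configuration
#'
#' Checks types, threshold ordering, and that every segment matches a
#' peptide in the default peptide set, before any computation is done.
#'
#' @param config config list.
#' @return The config, invisibly unchanged, or an error.
#' @export
validateRunConfig <- function(config) {
  stopifnot(is.numeric(config$seed), length(config$seed) == 1L,
            config$noise_sd >= 0, config$volume_noise_sd >= 0,
            config$n_replicates >= 1L)
  th <- config$thresholds
  if (!all(c("t_low", "t_high") %in% names(th)) || th["t_low"] > th["t_high"])
    stop("thresholds must supply t_low <= t_high")
  peps <- defaultPeptides()
  starts <- vapply(peps, function(p) p@start, integer(1))
  for (sg in names(config$segments)) {
    if (!config$segments[[sg]][1] %in% starts)
      stop("unknown segment id (no matching peptide): ", sg)
  }
  invisible(config)
}

#' Run the full conformation-selection pipeline
#'
#' Stages: (1) simulate the HDX panel dataset and write the uptake
#' table; (2) compute per-segment dAUC, rank, and classify the panel;
#' (3) simulate apo and bound methyl peak tables, estimate R:L
#' populations from the slow-exchange reporters, build the
#' chemical-shift-perturbation matrix, and categorise the probes;
#' (4) write all CSVs and a provenance block (seed + parameter hash).
#' The run is deterministic given (config, seed).
#'
#' @param config config list from \code{\link{readRunConfig}} /
#'   \code{\link{defaultRunConfig}}, or a path to a YAML file.
#' @param quiet suppress progress messages (written to stderr).
#' @return Invisibly, a list with elements uptake, dauc,
#'   classification, populations, csp, categories, provenance, files.
#' @export
runPipeline <- function(config = defaultRunConfig(), quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  validateRunConfig(config)
  log <- function(...) if (!quiet) message("[ConfSel] ", ...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$output_dir, f)

  panel <- defaultInhibitorPanel()
  model2P <- ConformerModel(config$pR_2P)
  model0P <- ConformerModel(config$pR_0P)

  log("simulating HDX panel (noise sd ", config$noise_sd, " Da)")
  uptake <- simulatePanel(panel, model2P = model2P, model0P = model0P,
                          nReplicates = config$n_replicates,
                          noiseSd = config$noise_sd, seed = config$seed)
  writeUptakeTable(uptake, outfile("uptake_table.csv"))

  log("computing dAUC and classification")
  dauc <- daucTable(uptake, config$segments)
  for (sg in names(config$segments)) dauc <- rankInhibitors(dauc, sg)
  cls <- classifyPanel(dauc, names(config$segments),
                       tLow = config$thresholds[["t_low"]],
                       tHigh = config$thresholds[["t_high"]],
                       referenceIds = config$reference_ids)
  utils::write.csv(dauc, outfile("dauc.csv"), row.names = FALSE)
  utils::write.csv(cls, outfile("classification.csv"), row.names = FALSE)

  log("simulating HMQC peak tables and estimating populations")
  probes <- defaultMethylProbes()
  apoTab <- simulateHmqcPeakPairs(probes, model2P,
                                  noiseSd = config$volume_noise_sd,
                                  seed = config$seed)
  boundTabs <- lapply(panel, function(inh)
    simulateHmqcPeakPairs(probes, model2P, inh,
                          noiseSd = config$volume_noise_sd,
                          seed = config$seed + match(inh@inhibitorId,
                                                     names(panel))))
  names(boundTabs) <- names(panel)
  pops <- estimatePopulations(peakPairs(apoTab))
  pops <- pops[!is.na(pops$p_R), , drop = FALSE]
  utils::write.csv(pops, outfile("populations.csv"), row.names = FALSE)

  csp <- cspMatrix(apoTab, boundTabs)
  cats <- categorizeProbes(
    csp,
    classLabels = panelClasses(panel),
    leftSideLabels = vapply(panel, function(x) x@leftSideGroup,
                            character(1)))
  cspOut <- data.frame(probe_id = rownames(csp), csp, check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.csv(cspOut, outfile("csp_matrix.csv"), row.names = FALSE,
                   na = "BROADENED")
  utils::write.csv(
    data.frame(probe_id = names(cats), category = unname(cats),
               stringsAsFactors = FALSE),
    outfile("probe_categories.csv"), row.names = FALSE)

  prov <- list(seed = config$seed, parameter_hash = configHash(config),
               package_version = as.character(
                 utils::packageVersion("ConfSel")))
  writeLines(yaml::as.yaml(prov), outfile("provenance.yml"))
  log("done; outputs in ", normalizePath(config$output_dir))

  invisible(list(uptake = uptake, dauc = dauc, classification = cls,
                 populations = pops, csp = csp, categories = cats,
                 provenance = prov,
                 files = outfile(c("uptake_table.csv", "dauc.csv",
                                   "classification.csv", "populations.csv",
                                   "csp_matrix.csv", "probe_categories.csv",
                                   "provenance.yml"))))
}

#' Hash of the run parameters
#'
#' MD5 of the canonical YAML serialisation of the config; changes iff
#' any parameter changes.
#'
#' @param config config list.
#' @return Character MD5 digest.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
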