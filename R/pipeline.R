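## snake_case (file interface) -> simulationConfig() argument mapping
.simFieldMap <- c(n_cases = "nCases", n_controls = "nControls",
                  cells_per_specimen = "cellsPerSpecimen",
                  truncation_prob = "truncationProb",
                  abnormality_priors = "abnormalityPriors",
                  planted_effects = "plantedEffects",
                  effect_strata = "effectStrata",
                  gleason_coupling = "gleasonCoupling",
                  risk_group_probs = "riskGroupProbs",
                  case_risk_group_probs = "caseRiskGroupProbs",
                  seed = "seed")

simConfigFromList <- function(lst) {
    unknown <- setdiff(names(lst), names(.simFieldMap))
    if (length(unknown))
        stop("unknown simulation field(s): ",
             paste(unknown, collapse = ", "))
    args <- lst
    names(args) <- .simFieldMap[names(lst)]
    for (f in c("plantedEffects", "gleasonCoupling", "riskGroupProbs",
                "caseRiskGroupProbs"))
        if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
    if (!is.null(args$abnormalityPriors))
        args$abnormalityPriors <- as.data.frame(args$abnormalityPriors)
    do.call(simulationConfig, args)
}

#' Read a run configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON. Top-level fields: either `simulation`
#' (a block mirroring [simulationConfig()] fields in snake_case) or the
#' input paths `cells`, `clinical`, `probes`; plus optional
#' `candidates`, `alpha`, `k_min`, `k_max`, `grid_step`, `auc_method`,
#' `apply_screen`, `output_dir`, `seed`.
#'
#' @param path Configuration file path.
#' @return A named list suitable for [runPipeline()].
#' @export
readRunConfig <- function(path) {
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else
        jsonlite::fromJSON(path, simplifyVector = TRUE)
}

.logStage <- function(...) message("[FISHpanel] ", ...)

#' Run the full panel-discovery pipeline
#'
#' Executes simulate (optional) -> parameter-matrix construction ->
#' correlation screen (excluded probes removed from the candidate
#' list) -> combination enumeration and ranking -> association models
#' (FISH-only, FISH + NCCN, clinical-only, risk-stratified), writing
#' all tab-separated outputs plus a JSON run manifest to the output
#' directory. Identical configuration and seed reproduce identical
#' outputs.
#'
#' @param config A named list: either a `simulation` block (see
#'   [readRunConfig()]) or `cells`/`clinical`/`probes` file paths;
#'   `output_dir` (required); optional `candidates`, `alpha` (0.05),
#'   `k_min` (3), `k_max` (6), `grid_step` (1), `auc_method`
#'   (`"logistic"`), `apply_screen` (`TRUE`), `seed` (overrides the
#'   simulation seed).
#' @return Invisibly, a list with the `cohort`, `screen`, `ranking`,
#'   `models`, `stratified` results and the `manifest`.
#' @export
runPipeline <- function(config) {
    t0 <- proc.time()[["elapsed"]]
    timings <- list()
    tick <- function(stage, since) {
        timings[[stage]] <<- round(proc.time()[["elapsed"]] - since, 3)
    }
    if (is.null(config$output_dir))
        stop("pipeline stage 'setup': config$output_dir is required")
    hasSim <- !is.null(config$simulation)
    hasPaths <- !is.null(config$cells)
    if (hasSim == hasPaths)
        stop("pipeline stage 'setup': supply exactly one of a ",
             "'simulation' block or input paths ('cells', 'clinical', ",
             "'probes')")
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

    t <- proc.time()[["elapsed"]]
    if (hasSim) {
        simArgs <- config$simulation
        if (!is.null(config$seed)) simArgs$seed <- config$seed
        simCfg <- simConfigFromList(simArgs)
        .logStage("simulate: ", simCfg@nCases, " cases / ",
                  simCfg@nControls, " controls (seed ", simCfg@seed, ")")
        sim <- simulateCohort(simCfg)
        writeCohortTables(sim, config$output_dir)
        cells <- sim$cells; clinical <- sim$clinical; panel <- sim$panel
    } else {
        .logStage("read: ", config$cells)
        cells <- readCellTable(config$cells)
        clinical <- readClinicalTable(config$clinical)
        panel <- if (!is.null(config$probes)) readProbeTable(config$probes)
                 else defaultProbePanel()
    }
    tick("input", t)

    t <- proc.time()[["elapsed"]]
    .logStage("enumerate: building parameter matrix")
    cohort <- tryCatch(
        buildParameterMatrix(cells, clinical, panel),
        error = function(e)
            stop("pipeline stage 'parameter_matrix': ",
                 conditionMessage(e), call. = FALSE))
    writeParameterTable(cohort, file.path(config$output_dir,
                                          "parameters.tsv"))
    tick("parameter_matrix", t)

    t <- proc.time()[["elapsed"]]
    alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
    .logStage("screen: Pearson correlation vs clinical (alpha ", alpha,
              ")")
    screen <- screenParameters(cohort, alpha = alpha)
    writeScreenTable(screen, file.path(config$output_dir, "screen.tsv"))
    candidates <- if (is.null(config$candidates)) candidateParameters()
                  else config$candidates
    applyScreen <- !identical(config$apply_screen, FALSE)
    if (applyScreen && length(excludedProbes(screen))) {
        rd <- as.data.frame(rowData(cohort))
        drop <- rd$parameter[rd$probe_id %in% excludedProbes(screen)]
        removed <- intersect(candidates, drop)
        if (length(removed))
            .logStage("screen: excluding ",
                      paste(removed, collapse = ", "))
        candidates <- setdiff(candidates, drop)
    }
    tick("screen", t)

    t <- proc.time()[["elapsed"]]
    kMin <- if (is.null(config$k_min)) 3 else config$k_min
    kMax <- if (is.null(config$k_max)) 6 else config$k_max
    if (length(candidates) < kMin)
        stop("pipeline stage 'selection': only ", length(candidates),
             " candidate parameter(s) remain after screening; need ",
             kMin)
    .logStage("select: ranking combinations of ", kMin, "-", kMax,
              " of ", length(candidates), " parameters")
    ranking <- enumerateAndRank(
        cohort, candidates = candidates, kMin = kMin, kMax = kMax,
        gridStep = if (is.null(config$grid_step)) 1 else config$grid_step,
        aucMethod = if (is.null(config$auc_method)) "logistic"
                    else config$auc_method)
    writeCombinationTables(ranking, config$output_dir)
    tick("selection", t)

    t <- proc.time()[["elapsed"]]
    .logStage("fit: association models for per-size leaders")
    models <- modelTable(ranking, cohort)
    write.table(models, file.path(config$output_dir, "models.tsv"),
                sep = "\t", quote = FALSE, na = "", row.names = FALSE)
    stratified <- stratifiedModelTable(ranking, cohort)
    write.table(stratified,
                file.path(config$output_dir, "models_stratified.tsv"),
                sep = "\t", quote = FALSE, na = "", row.names = FALSE)
    clin <- clinicalData(cohort)
    clinOnly <- tryCatch(
        clinicalOnlyModel(clin$risk_group, clin$age, clin$outcome),
        error = function(e) NULL)
    tick("models", t)

    cfgFile <- tempfile(fileext = ".json")
    jsonlite::write_json(config, cfgFile, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    manifest <- list(
        package = "FISHpanel",
        version = as.character(packageVersion("FISHpanel")),
        config = config,
        config_md5 = unname(tools::md5sum(cfgFile)),
        seed = if (hasSim) simCfg@seed else NULL,
        n_specimens = ncol(cohort),
        qc_exclusions = qcExclusions(cohort),
        excluded_probes = excludedProbes(screen),
        candidates_used = candidates,
        n_combinations = nrow(ranking$table),
        stage_seconds = timings,
        total_seconds = round(proc.time()[["elapsed"]] - t0, 3))
    unlink(cfgFile)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    .logStage("done: outputs in ", config$output_dir)
    invisible(list(cohort = cohort, screen = screen, ranking = ranking,
                   models = models, stratified = stratified,
                   clinical_only = clinOnly, manifest = manifest))
}
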