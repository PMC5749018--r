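## Lesion vocabulary behind each measurable parameter statistic. "Loss"
## priors drive the hemizygous-deletion lesion; the measured Loss percent
## additionally contains homozygous cells and truncation background.
.statLesion <- c(Gain = "gain", Loss = "hemizygous",
                 Homozygous = "homozygous", Split = "split",
                 `2Edel` = "2edel")

.riskGroups <- c("VeryLow", "Low", "Intermediate", "High")

splitParameterName <- function(parameter) {
    stat <- sub("^.* ", "", parameter)
    probe <- sub(" [^ ]+$", "", parameter)
    data.frame(parameter = parameter, probe_label = probe, statistic = stat,
               stringsAsFactors = FALSE)
}

#' Simulation configuration for synthetic FISH cohorts
#'
#' An S4 class holding every knob of the synthetic case-control cohort
#' generator. Construct with [simulationConfig()], which supplies
#' defaults mirroring the developmental active-surveillance study design:
#' 58 cases and 49 controls, 100 enumerated nuclei per specimen per probe
#' mix, and a per-signal truncation probability of 0.08 that reproduces
#' mean observed centromere copy numbers near 1.84.
#'
#' @slot nCases,nControls Number of case / control specimens.
#' @slot cellsPerSpecimen Enumerated nuclei per specimen per probe mix.
#' @slot truncationProb Probability that a true hybridisation signal is
#'   unobserved in the tissue section (independent per signal).
#' @slot abnormalityPriors `data.frame` with columns `parameter`,
#'   `shape1`, `shape2`: the Beta prior on the specimen-level
#'   abnormal-cell fraction for each lesion-bearing parameter, in
#'   controls.
#' @slot plantedEffects Named numeric: multiplicative case enrichment of
#'   the Beta-prior mean for the named parameters.
#' @slot effectStrata NCCN risk groups in which the planted case
#'   enrichment applies (default: all).
#' @slot gleasonCoupling Named numeric: strength `g` of a Gleason-score
#'   link, scaling a parameter's prior mean by `1 + g * max(0, gleason - 6)`
#'   in cases and controls alike.
#' @slot riskGroupProbs,caseRiskGroupProbs Distribution over the four
#'   NCCN risk groups for controls and cases respectively (cases default
#'   to the control distribution, emulating the matched design).
#' @slot seed Integer RNG seed.
#' @export
setClass("SimulationConfig", representation(
    nCases = "integer",
    nControls = "integer",
    cellsPerSpecimen = "integer",
    truncationProb = "numeric",
    abnormalityPriors = "data.frame",
    plantedEffects = "numeric",
    effectStrata = "character",
    gleasonCoupling = "numeric",
    riskGroupProbs = "numeric",
    caseRiskGroupProbs = "numeric",
    seed = "integer"
))

configError <- function(field, msg) {
    stop("invalid simulation configuration: field '", field, "' ", msg,
         call. = FALSE)
}

setValidity("SimulationConfig", function(object) {
    msg <- tryCatch({ checkConfig(object); NULL },
                    error = function(e) conditionMessage(e))
    if (is.null(msg)) TRUE else msg
})

defaultAbnormalityPriors <- function() {
    pars <- c("PTEN Loss", "PTEN Homozygous",
              "NKX3.1 Loss", "NKX3.1 Homozygous",
              "CDKN1B Loss", "CDKN1B Homozygous",
              "MYC Gain", "FGFR1 Gain", "NMYC Gain",
              "ERG Split", "ERG 2Edel", "ETV1 Split")
    ## mean 0.03, concentration 50: a low background abnormal fraction
    data.frame(parameter = pars, shape1 = 1.5, shape2 = 48.5,
               stringsAsFactors = FALSE)
}

checkConfig <- function(x) {
    if (length(x@nCases) != 1L || is.na(x@nCases) || x@nCases < 0L)
        configError("n_cases", "must be a single non-negative count")
    if (length(x@nControls) != 1L || is.na(x@nControls) || x@nControls < 0L)
        configError("n_controls", "must be a single non-negative count")
    if (x@nCases + x@nControls < 1L)
        configError("n_cases/n_controls", "must total at least 1 specimen")
    if (length(x@cellsPerSpecimen) != 1L || is.na(x@cellsPerSpecimen) ||
        x@cellsPerSpecimen < 1L)
        configError("cells_per_specimen", "must be a positive count")
    if (length(x@truncationProb) != 1L || is.na(x@truncationProb) ||
        x@truncationProb < 0 || x@truncationProb > 1)
        configError("truncation_prob", "must be a probability in [0, 1]")
    ap <- x@abnormalityPriors
    if (!all(c("parameter", "shape1", "shape2") %in% names(ap)))
        configError("abnormality_priors",
                    "needs columns parameter, shape1, shape2")
    if (any(!is.finite(ap$shape1)) || any(!is.finite(ap$shape2)) ||
        any(ap$shape1 <= 0) || any(ap$shape2 <= 0))
        configError("abnormality_priors",
                    "Beta shapes must be finite and positive")
    stats <- splitParameterName(ap$parameter)$statistic
    if (!all(stats %in% names(.statLesion)))
        configError("abnormality_priors",
                    "has parameters with unknown statistic")
    if (length(x@plantedEffects)) {
        if (is.null(names(x@plantedEffects)) ||
            any(!nzchar(names(x@plantedEffects))))
            configError("planted_effects", "must be a named vector")
        unknown <- setdiff(names(x@plantedEffects), ap$parameter)
        if (length(unknown))
            configError("planted_effects",
                        paste0("names not in abnormality_priors: ",
                               paste(unknown, collapse = ", ")))
        if (any(!is.finite(x@plantedEffects)) || any(x@plantedEffects <= 0))
            configError("planted_effects",
                        "multipliers must be finite and positive")
    }
    if (length(x@gleasonCoupling)) {
        unknown <- setdiff(names(x@gleasonCoupling), ap$parameter)
        if (length(unknown))
            configError("gleason_coupling",
                        paste0("names not in abnormality_priors: ",
                               paste(unknown, collapse = ", ")))
        if (any(!is.finite(x@gleasonCoupling)) || any(x@gleasonCoupling < 0))
            configError("gleason_coupling",
                        "strengths must be finite and non-negative")
    }
    for (field in c("risk_group_probs", "case_risk_group_probs")) {
        p <- if (field == "risk_group_probs") x@riskGroupProbs
             else x@caseRiskGroupProbs
        if (!identical(sort(names(p)), sort(.riskGroups)))
            configError(field, paste0("must be named over ",
                                      paste(.riskGroups, collapse = ", ")))
        if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
            configError(field, "must be a proper probability distribution")
    }
    if (!all(x@effectStrata %in% .riskGroups))
        configError("effect_strata", "contains unknown risk groups")
    if (length(x@seed) != 1L || is.na(x@seed))
        configError("seed", "must be a single integer")
    invisible(x)
}

#' Construct a simulation configuration
#'
#' @param nCases,nControls Cohort size (defaults 58 / 49).
#' @param cellsPerSpecimen Enumerated nuclei per specimen per mix
#'   (default 100).
#' @param truncationProb Per-signal FFPE truncation probability
#'   (default 0.08, reproducing mean CEP copy numbers of about 1.84).
#' @param abnormalityPriors Control-arm Beta priors; see
#'   [`SimulationConfig`].
#' @param plantedEffects Named case-enrichment multipliers. Default:
#'   1.6-fold enrichment of all seven candidate parameters, sized so
#'   that each marker shifts by roughly half a within-group standard
#'   deviation and a three-marker panel lands in the moderate
#'   discrimination regime typical of FISH progression panels rather
#'   than near-perfect separation.
#' @param effectStrata Risk groups in which planted effects apply.
#' @param gleasonCoupling Named Gleason-link strengths. Default couples
#'   NKX3.1 Loss to Gleason score (strength 1.5), emulating the
#'   confounded marker the correlation screen must catch.
#' @param riskGroupProbs,caseRiskGroupProbs NCCN risk-group frequencies
#'   (default approximates 54 Low/Very Low, 29 Intermediate and 24 High
#'   of 107 specimens).
#' @param seed Integer RNG seed.
#' @return A validated [`SimulationConfig`] object.
#' @examples
#' cfg <- simulationConfig(nCases = 4, nControls = 4, seed = 1)
#' @export
simulationConfig <- function(nCases = 58L, nControls = 49L,
                             cellsPerSpecimen = 100L,
                             truncationProb = 0.08,
                             abnormalityPriors = defaultAbnormalityPriors(),
                             plantedEffects =
                                 setNames(rep(1.6, 7), candidateParameters()),
                             effectStrata = .riskGroups,
                             gleasonCoupling = c("NKX3.1 Loss" = 1.5),
                             riskGroupProbs = c(VeryLow = 0.10, Low = 0.40,
                                                Intermediate = 0.27,
                                                High = 0.23),
                             caseRiskGroupProbs = riskGroupProbs,
                             seed = 1L) {
    cfg <- new("SimulationConfig",
               nCases = as.integer(nCases),
               nControls = as.integer(nControls),
               cellsPerSpecimen = as.integer(cellsPerSpecimen),
               truncationProb = as.numeric(truncationProb),
               abnormalityPriors = abnormalityPriors,
               plantedEffects = if (length(plantedEffects))
                   plantedEffects else setNames(numeric(0), character(0)),
               effectStrata = effectStrata,
               gleasonCoupling = if (length(gleasonCoupling))
                   gleasonCoupling else setNames(numeric(0), character(0)),
               riskGroupProbs = riskGroupProbs[.riskGroups],
               caseRiskGroupProbs = caseRiskGroupProbs[.riskGroups],
               seed = as.integer(seed))
    names(cfg@riskGroupProbs) <- .riskGroups
    names(cfg@caseRiskGroupProbs) <- .riskGroups
    checkConfig(cfg)
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nCases, "cases /", object@nControls,
        "controls,", object@cellsPerSpecimen, "cells/specimen/mix\n")
    cat("  truncation_prob:", object@truncationProb,
        " seed:", object@seed, "\n")
    if (length(object@plantedEffects)) {
        cat("  planted effects:",
            paste0(names(object@plantedEffects), " x",
                   object@plantedEffects, collapse = ", "), "\n")
        if (!identical(sort(object@effectStrata), sort(.riskGroups)))
            cat("  effect strata:",
                paste(object@effectStrata, collapse = ", "), "\n")
    }
    invisible(NULL)
})
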