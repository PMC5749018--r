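#' FishCohort: specimens by FISH parameters with clinical annotation
#'
#' The central container of the pipeline, extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are FISH
#' parameters (e.g. `"MYC Gain"`, `"PTEN Homozygous"`), columns are
#' specimens, and the single `"parameters"` assay holds percent-of-cells
#' values in `[0, 100]` (or unitless values for `Ratio` parameters).
#' `colData` carries the clinical record (outcome, age, PSA, Gleason
#' score, tumour stage, NCCN risk group); `metadata` carries the probe
#' panel, per-specimen enumerated-cell counts and QC exclusions.
#'
#' Use [buildParameterMatrix()] to construct one from per-cell
#' enumeration records, and the accessors [parameterMatrix()],
#' [clinicalData()], [probePanel()], [outcomeLabels()] and
#' [qcExclusions()] instead of touching slots.
#'
#' @aliases FishCohort
#' @export
setClass("FishCohort", contains = "SummarizedExperiment")

setValidity("FishCohort", function(object) {
    msgs <- character(0)
    if (!"parameters" %in% SummarizedExperiment::assayNames(object))
        msgs <- c(msgs, "assay 'parameters' is required")
    rd <- rowData(object)
    if (!all(c("parameter", "probe_id", "statistic") %in% names(rd)))
        msgs <- c(msgs,
                  "rowData needs columns parameter, probe_id, statistic")
    cd <- colData(object)
    if (!"outcome" %in% names(cd)) {
        msgs <- c(msgs, "colData needs an 'outcome' column")
    } else if (!all(cd$outcome %in% c("case", "control"))) {
        msgs <- c(msgs, "outcome must be 'case' or 'control'")
    }
    if (!length(msgs) && ncol(object)) {
        m <- assay(object, "parameters")
        pct <- rd$statistic != "Ratio"
        v <- m[pct, , drop = FALSE]
        if (any(!is.na(v) & (v < 0 | v > 100)))
            msgs <- c(msgs, "percent parameters must lie in [0, 100]")
        r <- m[!pct, , drop = FALSE]
        if (any(!is.na(r) & r < 0))
            msgs <- c(msgs, "Ratio parameters must be non-negative")
    }
    if (length(msgs)) msgs else TRUE
})

newFishCohort <- function(parameters, clinical, panel,
                          nCellsEnumerated = NULL, qcExclusions = list()) {
    stopifnot(is.matrix(parameters))
    info <- splitParameterName(rownames(parameters))
    labels <- probeLabel(panel$probe_id)
    probe_id <- panel$probe_id[match(info$probe_label, labels)]
    rd <- DataFrame(parameter = info$parameter, probe_id = probe_id,
                    statistic = info$statistic)
    clinical <- clinical[match(colnames(parameters), clinical$specimen_id), ,
                         drop = FALSE]
    cd <- DataFrame(clinical, row.names = clinical$specimen_id)
    se <- SummarizedExperiment(assays = list(parameters = parameters),
                               rowData = rd, colData = cd)
    metadata(se)$probePanel <- panel
    metadata(se)$nCellsEnumerated <- nCellsEnumerated
    metadata(se)$qcExclusions <- qcExclusions
    methods::new("FishCohort", se)
}

#' Accessors for FishCohort objects
#'
#' @param x A [`FishCohort`].
#' @return `parameterMatrix()`: the numeric parameters-by-specimens
#'   matrix; `clinicalData()`: the clinical records as a `data.frame`;
#'   `probePanel()`: the probe definition table; `outcomeLabels()`: a
#'   factor with levels `control`, `case`; `qcExclusions()`: a
#'   `data.frame` of specimens excluded at enumeration QC with reasons
#'   (zero rows when none).
#' @name FishCohort-accessors
NULL

#' @rdname FishCohort-accessors
#' @export
setGeneric("parameterMatrix", function(x) standardGeneric("parameterMatrix"))

#' @rdname FishCohort-accessors
#' @export
setMethod("parameterMatrix", "FishCohort",
          function(x) assay(x, "parameters"))

#' @rdname FishCohort-accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname FishCohort-accessors
#' @export
setMethod("clinicalData", "FishCohort",
          function(x) as.data.frame(colData(x)))

#' @rdname FishCohort-accessors
#' @export
setGeneric("probePanel", function(x) standardGeneric("probePanel"))

#' @rdname FishCohort-accessors
#' @export
setMethod("probePanel", "FishCohort",
          function(x) metadata(x)$probePanel)

#' @rdname FishCohort-accessors
#' @export
setGeneric("outcomeLabels", function(x) standardGeneric("outcomeLabels"))

#' @rdname FishCohort-accessors
#' @export
setMethod("outcomeLabels", "FishCohort", function(x)
    factor(colData(x)$outcome, levels = c("control", "case")))

#' @rdname FishCohort-accessors
#' @export
setGeneric("qcExclusions", function(x) standardGeneric("qcExclusions"))

#' @rdname FishCohort-accessors
#' @export
setMethod("qcExclusions", "FishCohort", function(x) {
    qc <- metadata(x)$qcExclusions
    if (is.null(qc) || !length(qc))
        data.frame(specimen_id = character(0), reason = character(0),
                   stringsAsFactors = FALSE)
    else qc
})

setMethod("show", "FishCohort", function(object) {
    lab <- outcomeLabels(object)
    cat("FishCohort:", nrow(object), "FISH parameters x", ncol(object),
        "specimens (", sum(lab == "case"), "cases /",
        sum(lab == "control"), "controls )\n")
    prm <- rownames(object)
    cat("  parameters:",
        paste(utils::head(prm, 4), collapse = ", "),
        if (length(prm) > 4) paste0("... (", length(prm), " total)") else "",
        "\n")
    qc <- qcExclusions(object)
    if (nrow(qc))
        cat("  QC-excluded specimens:", nrow(qc), "\n")
    invisible(NULL)
})
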