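## Extract per-cell signal counts for a locus/centromere probe from
## either a numeric vector or a data.frame of cell records.
.signalCounts <- function(cells) {
    if (is.data.frame(cells)) {
        if (!"n_signals" %in% names(cells))
            stop("cell records lack an n_signals column")
        if (nrow(cells) && all(is.na(cells$n_signals)))
            stop("signal-count parameters are undefined for ",
                 "break-apart probes")
        cells <- cells$n_signals
    }
    cells <- as.numeric(cells)
    if (!length(cells)) stop("no enumerated cells")
    if (anyNA(cells) || any(cells < 0))
        stop("signal counts must be non-negative and non-missing")
    cells
}

.baCounts <- function(cells, green) {
    if (is.data.frame(cells)) {
        if (!all(c("n_single_red", "n_single_green") %in% names(cells)))
            stop("cell records lack break-apart signal columns")
        if (nrow(cells) && all(is.na(cells$n_single_red)))
            stop("break-apart parameters are undefined for ",
                 "locus/centromere probes")
        green <- cells$n_single_green
        cells <- cells$n_single_red
    }
    if (!length(cells)) stop("no enumerated cells")
    if (length(green) != length(cells))
        stop("red and green count vectors differ in length")
    if (anyNA(cells) || anyNA(green) || any(cells < 0) || any(green < 0))
        stop("signal counts must be non-negative and non-missing")
    list(red = as.numeric(cells), green = as.numeric(green))
}

#' Specimen-level FISH parameters from per-cell signal counts
#'
#' The six parameters summarising a specimen's enumeration for one
#' probe:
#' \describe{
#'   \item{`pctGain()`}{percent of cells with more than 2 signals;}
#'   \item{`pctLoss()`}{percent of cells with fewer than 2 signals
#'     (homozygous cells included, so `pctLoss >= pctHomozygous`);}
#'   \item{`pctHomozygous()`}{percent of cells with 0 signals;}
#'   \item{`signalRatio()`}{mean probe signals per cell divided by mean
#'     signals of the same-chromosome centromeric control probe;}
#'   \item{`pctSplit()`}{break-apart probes: percent of cells with at
#'     least one isolated red \emph{and} one isolated green signal
#'     (signal separation is resolved at enumeration time);}
#'   \item{`pct2Edel()`}{ERG break-apart pattern: percent of cells with
#'     two or more isolated red signals and fewer isolated green than
#'     red signals (red gain with green loss). Split and 2Edel are
#'     disjoint cell classes.}
#' }
#'
#' @param cells Per-cell signal counts for one specimen and probe:
#'   a numeric vector of `n_signals` (or a cell-record `data.frame`)
#'   for the count-based parameters; a numeric vector of isolated red
#'   counts (or a cell-record `data.frame`) for the break-apart
#'   parameters.
#' @param green Isolated green counts, when `cells` is a vector.
#' @param controlCells Signal counts of the centromeric control probe,
#'   same specimen and mix.
#' @return Percent of cells in `[0, 100]`, or a non-negative ratio.
#' @examples
#' pctGain(c(3, 2, 2, 4, 1))        # 40
#' pctLoss(c(1, 0, 2, 2))           # 50
#' pctHomozygous(c(0, 0, 2, 2))     # 50
#' signalRatio(c(3, 3, 2), c(2, 2, 2))
#' pctSplit(red = c(1, 0), green = c(1, 0))   # 50
#' pct2Edel(red = c(3, 1), green = c(0, 1))   # 50
#' @name fish-parameters
NULL

#' @rdname fish-parameters
#' @export
pctGain <- function(cells) {
    x <- .signalCounts(cells)
    100 * mean(x > 2)
}

#' @rdname fish-parameters
#' @export
pctLoss <- function(cells) {
    x <- .signalCounts(cells)
    100 * mean(x < 2)
}

#' @rdname fish-parameters
#' @export
pctHomozygous <- function(cells) {
    x <- .signalCounts(cells)
    100 * mean(x == 0)
}

#' @rdname fish-parameters
#' @export
signalRatio <- function(cells, controlCells) {
    x <- .signalCounts(cells)
    ctrl <- .signalCounts(controlCells)
    if (mean(ctrl) == 0)
        stop("undefined ratio: control probe mean signal count is zero")
    mean(x) / mean(ctrl)
}

#' @rdname fish-parameters
#' @export
pctSplit <- function(cells, green = NULL) {
    ba <- .baCounts(cells, green)
    100 * mean(ba$red >= 1 & ba$green >= 1)
}

#' @rdname fish-parameters
#' @export
pct2Edel <- function(cells, green = NULL) {
    ba <- .baCounts(cells, green)
    100 * mean(ba$red >= 2 & ba$green < ba$red)
}

#' Build the specimen-by-parameter FISH matrix
#'
#' Applies the six parameter operations to every applicable
#' (probe, statistic) pair of the panel, per specimen, producing a
#' [`FishCohort`]. Specimens with no enumerated cells for a required
#' probe fail hybridisation QC: they are excluded from the matrix and
#' listed (with reasons) in `qcExclusions()` of the result.
#'
#' @param cells Per-nucleus enumeration records
#'   (see [readCellTable()]).
#' @param clinical Specimen-level clinical records
#'   (see [readClinicalTable()]).
#' @param panel Probe panel `data.frame`.
#' @return A [`FishCohort`]; parameters in the deterministic
#'   [panelParameters()] order, specimens in clinical-record order.
#' @examples
#' sim <- simulateCohort(simulationConfig(nCases = 3, nControls = 3,
#'                                        cellsPerSpecimen = 25, seed = 2))
#' cohort <- buildParameterMatrix(sim$cells, sim$clinical, sim$panel)
#' parameterMatrix(cohort)[, 1:3]
#' @export
buildParameterMatrix <- function(cells, clinical,
                                 panel = defaultProbePanel()) {
    validateProbePanel(panel)
    specimens <- clinical$specimen_id
    if (anyDuplicated(specimens))
        stop("duplicated specimen_id in clinical records")
    params <- panelParameters(panel)

    ## per-specimen cell-count bookkeeping and QC
    bySpecProbe <- split(seq_len(nrow(cells)),
                         list(factor(cells$specimen_id,
                                     levels = specimens),
                              factor(cells$probe_id,
                                     levels = panel$probe_id)),
                         drop = FALSE)
    counts <- vapply(bySpecProbe, length, integer(1))
    countMat <- matrix(counts, nrow = length(specimens),
                       dimnames = list(specimens, panel$probe_id))
    orphan <- setdiff(unique(cells$specimen_id), specimens)
    if (length(orphan))
        stop("cell records for specimens absent from the clinical ",
             "table: ", paste(orphan, collapse = ", "))
    failed <- rowSums(countMat == 0) > 0
    qc <- data.frame(specimen_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
    if (any(failed)) {
        qc <- do.call(rbind, lapply(specimens[failed], function(s) {
            miss <- colnames(countMat)[countMat[s, ] == 0]
            data.frame(specimen_id = s,
                       reason = paste0("no enumerated cells for probe(s) ",
                                       paste(miss, collapse = ", ")),
                       stringsAsFactors = FALSE)
        }))
        warning(sum(failed), " specimen(s) failed enumeration QC and ",
                "were excluded: ",
                paste(specimens[failed], collapse = ", "))
    }
    keep <- specimens[!failed]
    if (!length(keep))
        stop("no specimen passed enumeration QC")

    mat <- matrix(NA_real_, nrow = nrow(params), ncol = length(keep),
                  dimnames = list(params$parameter, keep))
    for (i in seq_len(nrow(panel))) {
        pr <- panel[i, ]
        sub <- cells[cells$probe_id == pr$probe_id &
                         cells$specimen_id %in% keep, , drop = FALSE]
        fac <- factor(sub$specimen_id, levels = keep)
        stats <- params$statistic[params$probe_id == pr$probe_id]
        if (pr$probe_class == "break_apart") {
            red <- split(sub$n_single_red, fac)
            grn <- split(sub$n_single_green, fac)
            for (st in stats) {
                fun <- if (st == "Split") pctSplit else pct2Edel
                val <- mapply(function(r, g) fun(r, g), red, grn)
                mat[paste(probeLabel(pr$probe_id), st), ] <- val
            }
        } else {
            sig <- split(sub$n_signals, fac)
            for (st in setdiff(stats, "Ratio")) {
                fun <- switch(st, Gain = pctGain, Loss = pctLoss,
                              Homozygous = pctHomozygous)
                mat[paste(probeLabel(pr$probe_id), st), ] <-
                    vapply(sig, fun, numeric(1))
            }
            if ("Ratio" %in% stats) {
                ctrl <- cells[cells$probe_id == pr$control_probe_id &
                                  cells$specimen_id %in% keep, ,
                              drop = FALSE]
                ctrlSig <- split(ctrl$n_signals,
                                 factor(ctrl$specimen_id, levels = keep))
                mat[paste(probeLabel(pr$probe_id), "Ratio"), ] <-
                    mapply(function(a, b) signalRatio(a, b), sig, ctrlSig)
            }
        }
    }
    clinKeep <- clinical[match(keep, clinical$specimen_id), , drop = FALSE]
    newFishCohort(mat, clinKeep, panel,
                  nCellsEnumerated = countMat[keep, , drop = FALSE],
                  qcExclusions = qc)
}

#' Write / read the wide parameter matrix
#'
#' `parameters.tsv` holds one row per specimen: `specimen_id`, then one
#' column per FISH parameter (spaces in parameter names preserved).
#'
#' @param cohort A [`FishCohort`].
#' @param path File path.
#' @return `writeParameterTable()` returns `path` invisibly;
#'   `readParameterTable()` returns a specimens-by-parameters numeric
#'   matrix with specimen ids as rownames.
#' @export
writeParameterTable <- function(cohort, path) {
    m <- t(parameterMatrix(cohort))
    df <- data.frame(specimen_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, na = "",
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeParameterTable
#' @export
readParameterTable <- function(path) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE, na.strings = c("NA", ""))
    if (!"specimen_id" %in% names(df))
        stop("parameter table lacks a specimen_id column")
    m <- as.matrix(df[setdiff(names(df), "specimen_id")])
    rownames(m) <- df$specimen_id
    storage.mode(m) <- "double"
    m
}
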