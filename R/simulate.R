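## True signal configuration for one lesion class.
## locus / centromere probes: a single n_signals count.
## break-apart probes: (fusion, isolated red, isolated green) counts.
.lesionsFor <- function(probe_class) {
    if (probe_class == "break_apart") c("normal", "split", "2edel")
    else c("normal", "gain", "hemizygous", "homozygous")
}

#' Simulate the observed FISH signals of a single nucleus
#'
#' Draws the true signal configuration implied by a lesion class, then
#' drops each true signal independently with probability
#' `truncationProb`, emulating nuclear truncation in thin FFPE sections.
#' True configurations: normal locus/centromere = 2 signals; gain =
#' uniform on 3-6 signals; hemizygous loss = 1; homozygous deletion = 0;
#' break-apart normal = 2 fused signals; split = 1 fused + 1 isolated
#' red + 1 isolated green; 2Edel = 1 fused + 2-4 isolated red + 0
#' isolated green.
#'
#' @param probeClass `"locus"`, `"centromere_control"` or
#'   `"break_apart"`.
#' @param lesion One of `"normal"`, `"gain"`, `"hemizygous"`,
#'   `"homozygous"` (locus/centromere) or `"normal"`, `"split"`,
#'   `"2edel"` (break-apart).
#' @param truncationProb Per-signal loss probability in `[0, 1]`.
#' @return A one-row `data.frame` with columns `n_signals`, `n_fusion`,
#'   `n_single_red`, `n_single_green` (`NA` for the fields not used by
#'   the probe class). Uses the current RNG state.
#' @examples
#' set.seed(1)
#' simulateCell("locus", "gain", truncationProb = 0)
#' simulateCell("break_apart", "split", truncationProb = 0)
#' @export
simulateCell <- function(probeClass, lesion, truncationProb) {
    if (!probeClass %in% c("locus", "centromere_control", "break_apart"))
        stop("unknown probe class: ", probeClass)
    if (!lesion %in% .lesionsFor(probeClass))
        stop("lesion '", lesion, "' is incompatible with probe class '",
             probeClass, "'")
    if (!is.finite(truncationProb) || truncationProb < 0 ||
        truncationProb > 1)
        stop("truncationProb must be a probability in [0, 1]")
    keep <- 1 - truncationProb
    if (probeClass == "break_apart") {
        true <- switch(lesion,
                       normal = c(2L, 0L, 0L),
                       split = c(1L, 1L, 1L),
                       `2edel` = c(1L, sample(2:4, 1L), 0L))
        obs <- rbinom(3L, true, keep)
        data.frame(n_signals = NA_integer_, n_fusion = obs[1],
                   n_single_red = obs[2], n_single_green = obs[3])
    } else {
        true <- switch(lesion,
                       normal = 2L,
                       gain = sample(3:6, 1L),
                       hemizygous = 1L,
                       homozygous = 0L)
        data.frame(n_signals = rbinom(1L, true, keep),
                   n_fusion = NA_integer_, n_single_red = NA_integer_,
                   n_single_green = NA_integer_)
    }
}

## Specimen-level Beta means for one prior row, over all specimens.
.specimenMeans <- function(prior, clinical, config) {
    m0 <- prior$shape1 / (prior$shape1 + prior$shape2)
    m <- rep(m0, nrow(clinical))
    pe <- config@plantedEffects
    if (prior$parameter %in% names(pe)) {
        hit <- clinical$outcome == "case" &
            clinical$risk_group %in% config@effectStrata
        m[hit] <- m[hit] * pe[[prior$parameter]]
    }
    gc <- config@gleasonCoupling
    if (prior$parameter %in% names(gc))
        m <- m * (1 + gc[[prior$parameter]] *
                      pmax(0, clinical$gleason - 6))
    pmin(pmax(m, 1e-5), 0.45)
}

## Draw per-cell lesion classes for one probe across all specimens.
## Returns an integer matrix cells x specimens of indices into
## c("normal", lesion names).
.drawLesionMatrix <- function(fractions, nCells) {
    nSpec <- nrow(fractions)
    nLes <- ncol(fractions)
    tot <- rowSums(fractions)
    over <- tot > 0.95
    if (any(over))  # keep the mixture proper under extreme priors
        fractions[over, ] <- fractions[over, ] * (0.95 / tot[over])
    cum <- t(apply(cbind(0, fractions), 1, cumsum))  # nSpec x (nLes+1)
    u <- matrix(runif(nCells * nSpec), nrow = nCells)
    les <- matrix(1L, nrow = nCells, ncol = nSpec)
    for (l in seq_len(nLes)) {
        lo <- matrix(rep(cum[, l], each = nCells), nrow = nCells)
        hi <- matrix(rep(cum[, l + 1L], each = nCells), nrow = nCells)
        les[u >= lo & u < hi] <- l + 1L
    }
    les
}

.simulateClinical <- function(config) {
    n <- config@nCases + config@nControls
    outcome <- c(rep("case", config@nCases),
                 rep("control", config@nControls))
    specimen_id <- sprintf("S%03d", seq_len(n))
    target <- character(n)
    isCase <- outcome == "case"
    if (any(isCase))
        target[isCase] <- sample(.riskGroups, sum(isCase), replace = TRUE,
                                 prob = config@caseRiskGroupProbs)
    if (any(!isCase))
        target[!isCase] <- sample(.riskGroups, sum(!isCase), replace = TRUE,
                                  prob = config@riskGroupProbs)
    age <- pmin(pmax(round(rnorm(n, 66, 6)), 45), 85)
    stage <- character(n); psa <- numeric(n); gleason <- integer(n)
    veryLow <- logical(n)
    for (i in seq_len(n)) {
        u <- runif(1)
        switch(target[i],
               VeryLow = {
                   stage[i] <- "T1c"; gleason[i] <- 6L
                   psa[i] <- runif(1, 2, 9); veryLow[i] <- TRUE
               },
               Low = {
                   stage[i] <- sample(c("T1c", "T2a"), 1)
                   gleason[i] <- sample(c(5L, 6L), 1, prob = c(0.2, 0.8))
                   psa[i] <- runif(1, 3, 9.9)
               },
               Intermediate = {
                   if (u < 0.6) {
                       stage[i] <- sample(c("T1c", "T2a"), 1)
                       gleason[i] <- 7L; psa[i] <- runif(1, 3, 9.9)
                   } else if (u < 0.85) {
                       stage[i] <- sample(c("T1c", "T2a"), 1)
                       gleason[i] <- 6L; psa[i] <- runif(1, 10, 20)
                   } else {
                       stage[i] <- sample(c("T2b", "T2c"), 1)
                       gleason[i] <- 6L; psa[i] <- runif(1, 3, 9.9)
                   }
               },
               High = {
                   if (u < 0.5) {
                       stage[i] <- sample(c("T1c", "T2a"), 1)
                       gleason[i] <- 8L; psa[i] <- runif(1, 4, 10)
                   } else {
                       stage[i] <- sample(c("T1c", "T2a"), 1)
                       gleason[i] <- 6L; psa[i] <- runif(1, 20.5, 35)
                   }
               })
    }
    psa <- round(psa, 1)
    risk <- assignNccnRisk(stage, psa, gleason, veryLow)
    data.frame(specimen_id = specimen_id, outcome = outcome, age = age,
               psa = psa, gleason = gleason, stage = stage,
               risk_group = risk, stringsAsFactors = FALSE)
}

#' Generate a synthetic FISH case-control cohort
#'
#' Generates clinical records and per-nucleus FISH signal enumerations
#' for a matched case-control active-surveillance cohort. Specimen-level
#' abnormal-cell fractions are drawn from Beta priors (case-enriched for
#' planted parameters), per-cell lesions are i.i.d. given the fraction,
#' and every true signal is dropped independently with the configured
#' truncation probability. Identical configuration (including seed)
#' reproduces identical output.
#'
#' @param config A [`SimulationConfig`] from [simulationConfig()].
#' @param panel A probe panel `data.frame`
#'   (default [defaultProbePanel()]).
#' @return A list of class `"CohortSim"` with elements
#'   \describe{
#'     \item{clinical}{specimen-level clinical records,}
#'     \item{cells}{per-nucleus enumeration records (one row per
#'       nucleus per probe),}
#'     \item{truth}{planted lesion cell counts per specimen and
#'       parameter (ground truth for testing),}
#'     \item{config, panel}{the inputs.}
#'   }
#' @examples
#' sim <- simulateCohort(simulationConfig(nCases = 2, nControls = 2,
#'                                        cellsPerSpecimen = 20, seed = 7))
#' head(sim$cells)
#' @export
simulateCohort <- function(config, panel = defaultProbePanel()) {
    checkConfig(config)
    validateProbePanel(panel)
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(config@seed)
    clinical <- .simulateClinical(config)
    n <- nrow(clinical)
    nCells <- config@cellsPerSpecimen
    keep <- 1 - config@truncationProb
    priors <- config@abnormalityPriors
    priorInfo <- splitParameterName(priors$parameter)
    labels <- probeLabel(panel$probe_id)

    cellBlocks <- vector("list", nrow(panel))
    truthBlocks <- list()
    for (pi in seq_len(nrow(panel))) {
        pr <- panel[pi, ]
        isBA <- pr$probe_class == "break_apart"
        rows <- which(priorInfo$probe_label == labels[pi])
        lesionNames <- .statLesion[priorInfo$statistic[rows]]
        fractions <- matrix(0, nrow = n, ncol = length(rows))
        for (k in seq_along(rows)) {
            prior <- priors[rows[k], ]
            m <- .specimenMeans(prior, clinical, config)
            conc <- prior$shape1 + prior$shape2
            fractions[, k] <- rbeta(n, m * conc, (1 - m) * conc)
        }
        les <- .drawLesionMatrix(fractions, nCells)  # cells x specimens
        lesVec <- as.vector(les)                     # cell-major, specimen blocks
        total <- n * nCells
        if (isBA) {
            fus <- rep(2L, total); red <- rep(0L, total)
            grn <- rep(0L, total)
            for (k in seq_along(rows)) {
                idx <- lesVec == k + 1L
                if (lesionNames[k] == "split") {
                    fus[idx] <- 1L; red[idx] <- 1L; grn[idx] <- 1L
                } else if (lesionNames[k] == "2edel") {
                    fus[idx] <- 1L
                    red[idx] <- sample(2:4, sum(idx), replace = TRUE)
                    grn[idx] <- 0L
                }
            }
            block <- data.frame(
                specimen_id = rep(clinical$specimen_id, each = nCells),
                mix_id = pr$mix_id,
                cell_index = rep(seq_len(nCells), times = n),
                probe_id = pr$probe_id,
                n_signals = NA_integer_,
                n_fusion = rbinom(total, fus, keep),
                n_single_red = rbinom(total, red, keep),
                n_single_green = rbinom(total, grn, keep),
                stringsAsFactors = FALSE)
        } else {
            true <- rep(2L, total)
            for (k in seq_along(rows)) {
                idx <- lesVec == k + 1L
                true[idx] <- switch(lesionNames[k],
                                    gain = sample(3:6, sum(idx),
                                                  replace = TRUE),
                                    hemizygous = 1L,
                                    homozygous = 0L)
            }
            block <- data.frame(
                specimen_id = rep(clinical$specimen_id, each = nCells),
                mix_id = pr$mix_id,
                cell_index = rep(seq_len(nCells), times = n),
                probe_id = pr$probe_id,
                n_signals = rbinom(total, true, keep),
                n_fusion = NA_integer_,
                n_single_red = NA_integer_,
                n_single_green = NA_integer_,
                stringsAsFactors = FALSE)
        }
        cellBlocks[[pi]] <- block
        if (length(rows)) {
            counts <- matrix(0L, nrow = n, ncol = length(rows))
            for (k in seq_along(rows))
                counts[, k] <- colSums(les == k + 1L)
            tb <- data.frame(
                specimen_id = rep(clinical$specimen_id, length(rows)),
                parameter = rep(priors$parameter[rows], each = n),
                n_cells = as.vector(counts), stringsAsFactors = FALSE)
            ## measured "Loss" includes homozygous cells; fold them into
            ## the Loss truth so fixtures at truncation 0 match exactly
            homo <- which(priorInfo$statistic[rows] == "Homozygous")
            loss <- which(priorInfo$statistic[rows] == "Loss")
            if (length(homo) && length(loss)) {
                add <- counts[, homo[1]]
                sel <- tb$parameter == priors$parameter[rows[loss[1]]]
                tb$n_cells[sel] <- tb$n_cells[sel] + add
            }
            truthBlocks[[length(truthBlocks) + 1L]] <- tb
        }
    }
    structure(list(clinical = clinical,
                   cells = do.call(rbind, cellBlocks),
                   truth = do.call(rbind, truthBlocks),
                   config = config, panel = panel),
              class = "CohortSim")
}

#' @export
print.CohortSim <- function(x, ...) {
    cat("CohortSim:", nrow(x$clinical), "specimens,",
        nrow(x$cells), "cell records\n")
    invisible(x)
}

#' Write / read cohort tables
#'
#' Serialises a simulated cohort to the pipeline's tab-separated
#' interchange files: `cells.tsv` (per-nucleus enumeration records),
#' `clinical.tsv` (specimen-level clinical records) and `probes.tsv`
#' (probe panel). All files are UTF-8, tab-separated, with a header row;
#' unused signal-count fields are left empty.
#'
#' @param sim A `"CohortSim"` from [simulateCohort()], or any list with
#'   `cells`, `clinical` and `panel` elements.
#' @param dir Output directory (created if missing).
#' @param path A single TSV file path.
#' @return `writeCohortTables()` returns the file paths invisibly;
#'   the readers return validated `data.frame`s.
#' @export
writeCohortTables <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("cells.tsv", "clinical.tsv", "probes.tsv"))
    write.table(sim$cells, paths[1], sep = "\t", quote = FALSE, na = "",
                row.names = FALSE)
    write.table(sim$clinical, paths[2], sep = "\t", quote = FALSE,
                na = "", row.names = FALSE)
    writeProbeTable(sim$panel, paths[3])
    invisible(paths)
}

#' @rdname writeCohortTables
#' @export
readCellTable <- function(path) {
    cells <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
    required <- c("specimen_id", "mix_id", "cell_index", "probe_id",
                  "n_signals", "n_fusion", "n_single_red",
                  "n_single_green")
    missing <- setdiff(required, names(cells))
    if (length(missing))
        stop("cell table is missing columns: ",
             paste(missing, collapse = ", "))
    cells
}

#' @rdname writeCohortTables
#' @export
readClinicalTable <- function(path) {
    clin <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
    required <- c("specimen_id", "outcome", "age", "psa", "gleason",
                  "stage", "risk_group")
    missing <- setdiff(required, names(clin))
    if (length(missing))
        stop("clinical table is missing columns: ",
             paste(missing, collapse = ", "))
    if (!all(clin$outcome %in% c("case", "control")))
        stop("outcome must be 'case' or 'control'")
    clin
}
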