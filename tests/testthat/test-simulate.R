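test_that("simulateCell reproduces the stated signal configurations", {
    set.seed(1)
    ## homozygous deletion: nothing to truncate
    for (p in c(0, 0.3, 1)) {
        cell <- simulateCell("locus", "homozygous", p)
        expect_identical(cell$n_signals, 0L)
    }
    ## split with no truncation: 1 fused + 1 red + 1 green
    cell <- simulateCell("break_apart", "split", 0)
    expect_equal(unlist(cell[c("n_fusion", "n_single_red",
                               "n_single_green")], use.names = FALSE),
                 c(1L, 1L, 1L))
    ## normal diploid, no truncation
    expect_equal(simulateCell("locus", "normal", 0)$n_signals, 2L)
    expect_equal(simulateCell("break_apart", "normal", 0)$n_fusion, 2L)
    ## gain in 3..6; 2Edel red multiplicity in 2..4 with no green
    g <- replicate(50, simulateCell("locus", "gain", 0)$n_signals)
    expect_true(all(g >= 3 & g <= 6))
    e <- replicate(30, {
        cl <- simulateCell("break_apart", "2edel", 0)
        c(cl$n_fusion, cl$n_single_red, cl$n_single_green)
    })
    expect_true(all(e[1, ] == 1 & e[2, ] >= 2 & e[2, ] <= 4 & e[3, ] == 0))
    ## incompatible lesion/probe combinations are errors
    expect_error(simulateCell("locus", "split", 0), "incompatible")
    expect_error(simulateCell("break_apart", "gain", 0), "incompatible")
    expect_error(simulateCell("locus", "normal", 1.5), "probability")
})

test_that("truncation thins observed centromere counts to 2(1-p)", {
    set.seed(42)
    obs <- replicate(10000,
                     simulateCell("centromere_control", "normal",
                                  0.08)$n_signals)
    expect_equal(mean(obs), 1.84, tolerance = 0.02 / 1.84)
})

test_that("assignNccnRisk applies the threshold rules", {
    expect_identical(assignNccnRisk("T1c", 5, 6), "Low")
    expect_identical(assignNccnRisk("T2a", 8, 7), "Intermediate")
    expect_identical(assignNccnRisk("T2a", 25, 6), "High")
    expect_identical(assignNccnRisk("T1c", 5, 6, veryLow = TRUE),
                     "VeryLow")
    expect_identical(assignNccnRisk("T2b", 5, 6), "Intermediate")
    expect_identical(assignNccnRisk("T1c", 15, 6), "Intermediate")
    expect_identical(assignNccnRisk("T1c", 5, 9), "High")
    ## very-low flag is ignored unless the T1c/Gleason/PSA gate holds
    expect_identical(assignNccnRisk("T2a", 5, 6, veryLow = TRUE), "Low")
    expect_error(assignNccnRisk("T3", 5, 6), "stage")
    expect_error(assignNccnRisk("T1c", -1, 6), "psa")
    expect_error(assignNccnRisk("T1c", 5, 11), "gleason")
})

test_that("invalid configurations raise errors naming the field", {
    expect_error(simulationConfig(nCases = -1), "n_cases")
    expect_error(simulationConfig(truncationProb = 1.2),
                 "truncation_prob")
    expect_error(simulationConfig(cellsPerSpecimen = 0),
                 "cells_per_specimen")
    bad <- data.frame(parameter = "MYC Gain", shape1 = -1, shape2 = 2)
    expect_error(simulationConfig(abnormalityPriors = bad),
                 "abnormality_priors")
    expect_error(simulationConfig(plantedEffects = c("No Such" = 2)),
                 "planted_effects")
    expect_error(
        simulationConfig(riskGroupProbs = c(VeryLow = 0.5, Low = 0.5,
                                            Intermediate = 0.5,
                                            High = 0.5)),
        "risk_group_probs")
})

test_that("degenerate cohort sizes and zero truncation behave exactly", {
    cfg <- simulationConfig(nCases = 0, nControls = 1,
                            plantedEffects = numeric(0), seed = 5)
    sim <- simulateCohort(cfg)
    expect_identical(nrow(sim$clinical), 1L)
    expect_true(all(sim$clinical$outcome == "control"))
    counts <- table(sim$cells$probe_id)
    expect_true(all(counts == cfg@cellsPerSpecimen))

    cfg0 <- simulationConfig(nCases = 2, nControls = 2,
                             truncationProb = 0, cellsPerSpecimen = 30,
                             seed = 6)
    sim0 <- simulateCohort(cfg0)
    cep <- sim0$cells[sim0$cells$probe_id %in% c("CEP8", "CEP10"), ]
    expect_true(all(cep$n_signals == 2L))
})

test_that("identical seed and config reproduce byte-identical tables", {
    cfg <- simulationConfig(nCases = 3, nControls = 3,
                            cellsPerSpecimen = 25, seed = 7)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeCohortTables(simulateCohort(cfg), d1)
    writeCohortTables(simulateCohort(cfg), d2)
    for (f in c("cells.tsv", "clinical.tsv", "probes.tsv"))
        expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                         readBin(file.path(d2, f), "raw", 1e7))
    ## a different seed changes the cell draws
    other <- simulateCohort(simulationConfig(nCases = 3, nControls = 3,
                                             cellsPerSpecimen = 25,
                                             seed = 8))
    expect_false(identical(other$cells,
                           simulateCohort(cfg)$cells))
})

test_that("generated risk groups are consistent with the NCCN rule", {
    sim <- simulateCohort(simulationConfig(nCases = 30, nControls = 30,
                                           cellsPerSpecimen = 5,
                                           seed = 9))
    cl <- sim$clinical
    recomputed <- assignNccnRisk(cl$stage, cl$psa, cl$gleason,
                                 veryLow = cl$risk_group == "VeryLow")
    expect_identical(recomputed, cl$risk_group)
})

test_that("planted case enrichment raises case means across seeds", {
    diffs <- vapply(1:20, function(s) {
        cfg <- simulationConfig(
            nCases = 12, nControls = 12, cellsPerSpecimen = 40,
            plantedEffects = c("MYC Gain" = 3), seed = 100 + s)
        sim <- simulateCohort(cfg)
        co <- buildParameterMatrix(sim$cells, sim$clinical, sim$panel)
        v <- parameterMatrix(co)["MYC Gain", ]
        isCase <- outcomeLabels(co) == "case"
        mean(v[isCase]) - mean(v[!isCase])
    }, numeric(1))
    expect_gt(mean(diffs), 0)
    expect_gte(sum(diffs > 0), 16)
})
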