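test_that("monoisotopic adduct arithmetic reproduces known masses", {
    expect_equal(adductMz("C10H16N2O2", "[M+H]+"), 197.1285, tolerance = 1e-4)
    expect_equal(adductMz("C11H12N2O3", "[M+H]+"), 221.0921, tolerance = 1e-4)
    expect_equal(adductMz("H", "[M+H]+"), 1.00782503207 + 1.00727646,
                 tolerance = 1e-8)
    expect_equal(monoisotopicMass("H"), 1.00782503207)
    expect_error(monoisotopicMass("C2Xx3"), "unknown element")
    # additivity over concatenated formulas
    expect_equal(monoisotopicMass("C6H12O6"),
                 monoisotopicMass("C3H6O3") + monoisotopicMass("C3H6O3"),
                 tolerance = 1e-10)
    expect_equal(monoisotopicMass("C11H12N2O3"),
                 monoisotopicMass("C11H12") + monoisotopicMass("N2O3"),
                 tolerance = 1e-10)
})

test_that("published m/z values match theory where rounding agrees", {
    t1 <- loadTable1()
    lib <- loadCompoundLibrary()
    agree <- c(pos1147 = "C10H16N2O2",
               pos568 = "C11H12N2O3",       # 5-hydroxy-L-tryptophan
               pos726 = "C7H11NO3",         # N-acetylproline
               pos441 = "C6H7N5O",          # N-methylguanine
               pos537 = "C9H9NO4",          # dopaquinone
               pos102 = "C11H16N2O2",       # pilocarpine
               pos588 = "C14H19NO4",
               pos887 = "C24H27N3O4",
               pos928 = "C23H30N2O5",
               neg279 = "C13H16N2O4")       # phenylacetyl-L-glutamine
    for (fid in names(agree)) {
        row <- t1[t1$feature_id == fid, ]
        adduct <- if (row$ion_mode == "positive") "[M+H]+" else "[M-H]-"
        expect_equal(round(adductMz(agree[[fid]], adduct), 2), row$mz,
                     info = fid)
    }
    expect_true(all(c("C11H12N2O3", "C7H11NO3") %in% lib$formula))
})

test_that("ppm matching is inclusive at the boundary and ranked by error", {
    lib <- data.frame(compound_id = c("a", "b"),
                      name = c("exact", "off"),
                      formula = c("C11H12N2O3", "C11H12N2O3"),
                      monoisotopic_mass = c(220.08480768, 220.08480768 * (1 + 4e-6)))
    theo <- 220.08480768 + 1.00727646
    hits <- libraryMatch(theo, "positive", lib, ppm_tolerance = 10)
    expect_identical(hits$compound_id, c("a", "b"))
    expect_equal(hits$ppm[1], 0, tolerance = 1e-9)
    # exactly 10 ppm off still matches; 15 ppm does not
    hits10 <- libraryMatch(theo * (1 + 10e-6), "positive",
                           lib[1, ], ppm_tolerance = 10)
    expect_identical(nrow(hits10), 1L)
    hits15 <- libraryMatch(theo * (1 + 15e-6), "positive",
                           lib[1, ], ppm_tolerance = 10)
    expect_identical(nrow(hits15), 0L)
    expect_error(libraryMatch(100, "positive", lib[0, ]), "empty")
})

test_that("MSI bookkeeping follows the highest-evidence rule and the fixture accounting", {
    expect_identical(assignMsiLevel(inhouse_spectral = TRUE,
                                    public_spectral = TRUE), "1")
    expect_identical(assignMsiLevel(), "unknown")
    expect_identical(assignMsiLevel(formula_only = TRUE), "formula_only")

    t1 <- loadTable1()
    lev <- assignMsiLevel(t1$inhouse_spectral, t1$public_spectral,
                          t1$in_silico_structure, t1$class_only,
                          t1$formula_only)
    counts <- table(factor(lev, levels = c("1", "2", "3", "4",
                                           "formula_only", "unknown")))
    expect_identical(as.integer(counts), c(4L, 32L, 12L, 8L, 3L, 10L))
    # the four in-house-confirmed features named in the source methods
    expect_setequal(t1$feature_id[t1$inhouse_spectral],
                    c("pos568", "pos726", "neg301", "neg461"))
})

test_that("class enrichment matches the hypergeometric oracle and direction rule", {
    # spec'd worked example: 6/10 selected in class A, 9/90 in the remainder
    sel <- c(rep("A", 6), rep("B", 4))
    bg <- c(sel, rep("A", 9), rep("B", 81))
    res1 <- classEnrichment(sel, bg, alpha = 0.005, alternative = "greater")
    a <- res1[res1$class == "A", ]
    expect_equal(a$fisher_p, 0.000623503310565, tolerance = 1e-9)
    expect_true(a$enriched)

    # identical proportions: not enriched, p in the ~1 region
    sel2 <- c(rep("A", 2), rep("B", 8))
    bg2 <- c(sel2, rep("A", 18), rep("B", 72))
    res2 <- classEnrichment(sel2, bg2, alpha = 0.005)
    expect_false(any(res2$enriched))
    expect_gt(res2$fisher_p[res2$class == "A"], 0.5)

    # strong depletion is never flagged, however small its p
    sel3 <- rep("B", 20)
    bg3 <- c(sel3, rep("A", 60), rep("B", 20))
    res3 <- classEnrichment(sel3, bg3, alpha = 0.005)
    aa <- res3[res3$class == "A", ]
    expect_lt(aa$fisher_p, 1e-6)
    expect_lt(aa$difference, 0)
    expect_false(aa$enriched)
    expect_error(classEnrichment(character(0), bg3), "empty")
})

test_that("two-sided fisher p equals exhaustive enumeration on small tables", {
    set.seed(14)
    for (i in 1:200) {
        tab <- as.vector(stats::rmultinom(1, sample(4:28, 1), rep(0.25, 4)))
        p_pkg <- stats::fisher.test(matrix(tab, 2))$p.value
        p_enum <- enumFisherP(tab[1], tab[2], tab[3], tab[4])
        expect_equal(p_pkg, p_enum, tolerance = 1e-12)
    }
})

test_that("planted enriched classes are recovered from the synthetic cohort", {
    # class counts only clear the conservative alpha at the full design scale
    # (69 selected of 1841), so this runs the full-size generator
    found <- 0L; planted_total <- 0L
    for (s in 1:3) {
        cfg <- cohortConfig(class_odds_ratio = 20, rng_seed = s)
        sim <- generateCohort(cfg)
        cls <- generateSpectralClasses(sim$truth, cfg)
        enr_true <- attr(cls, "enriched_classes")
        sel <- cls$class_path[cls$feature_id %in% sim$truth$age_features$feature_id]
        res <- classEnrichment(sel, cls$class_path, alpha = 0.005,
                               alternative = "greater")
        found <- found + sum(enr_true %in% res$class[res$enriched])
        planted_total <- planted_total + length(enr_true)
        # no class is simultaneously enriched and depleted
        expect_false(any(res$enriched & res$difference < 0))
    }
    expect_gte(found / planted_total, 0.8)
})

test_that("ontology pruning normalises case and drops removal-list branches", {
    paths <- data.frame(
        compound_id = c("c1", "c1", "c1", "c2", "c2"),
        path = c("Biological location/Blood",
                 "biological location/blood",
                 "Disposition/Source/Endogenous",
                 "Pathways/Tryptophan metabolism",
                 "Process/Biological process"))
    out <- pruneOntology(paths)
    expect_identical(out$path[out$compound_id == "c1"],
                     "Biological location/Blood")
    expect_identical(nrow(out[out$compound_id == "c1", ]), 1L)
    expect_false(any(startsWith(out$path, "Disposition")))
    expect_false(any(startsWith(out$path, "Process")))
    expect_identical(out$path[out$compound_id == "c2"],
                     "Pathways/Tryptophan metabolism")
    expect_error(pruneOntology(data.frame(compound_id = "c", path = "a//b")),
                 "malformed")
    # untouched path is retained unchanged
    keep <- pruneOntology(data.frame(compound_id = "c", path = "Pathways/Urea cycle"))
    expect_identical(keep$path, "Pathways/Urea cycle")
})

test_that("treemap counts distinct compounds and stays monotone down the hierarchy", {
    paths <- data.frame(
        compound_id = c("f1", "f2", "f2", "f3"),
        path = c("A/B", "A/B", "A", "A"))
    agg <- aggregateTreemap(paths)
    expect_identical(agg$count[agg$term == "A"], 3L)
    expect_identical(agg$count[agg$term == "A/B"], 2L)
    # parent counts never below child counts on generated fixtures
    tab <- pruneOntology(generateOntologyFixture(paste0("x", 1:15), seed = 2))
    agg2 <- aggregateTreemap(tab)
    for (i in seq_len(nrow(agg2))) {
        parent <- sub("/[^/]+$", "", agg2$term[i])
        if (parent != agg2$term[i]) {
            expect_gte(agg2$count[agg2$term == parent], agg2$count[i])
        }
    }
    expect_identical(nrow(aggregateTreemap(tab[0, ])), 0L)
})

test_that("annotateFeatures joins library hits with regression directions", {
    lib <- loadCompoundLibrary()
    feats <- data.frame(feature_id = c("pos568", "posX"),
                        ion_mode = "positive",
                        mz = c(adductMz("C11H12N2O3", "[M+H]+"), 999.9))
    reg <- data.frame(feature_id = c("pos568", "posX"),
                      slope = c(0.5, -0.1), p_value = c(0.01, 0.6),
                      direction = c("increasing", "decreasing"))
    ann <- annotateFeatures(feats, lib, reg)
    expect_match(ann$putative_name[1], "tryptophan", ignore.case = TRUE)
    expect_identical(ann$msi_level[2], "unknown")
    expect_identical(ann$direction, c("increasing", "decreasing"))
})
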