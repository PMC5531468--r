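test_that("predictor consensus requires four simultaneous damaging verdicts", {
    expect_true(predictorConsensus("damaging", "deleterious",
                                   "probably_damaging", "disease_causing"))
    expect_true(predictorConsensus("damaging", "deleterious",
                                   "possibly_damaging", "disease_causing"))
    expect_false(predictorConsensus("tolerated", "deleterious",
                                    "probably_damaging", "disease_causing"))
    expect_false(predictorConsensus("damaging", "deleterious", "absent",
                                    "disease_causing"))
    expect_false(predictorConsensus(NA, "deleterious", "probably_damaging",
                                    "disease_causing"))
})

test_that("evidence codes reproduce the curated annotation bundles", {
    fx <- referenceFixtures()
    v <- variants(fx$cohort)
    codes <- evidenceCodeString(evidenceCodes(v))
    pick <- function(protein) unique(codes[v$protein %in% protein])
    expect_equal(pick("V310I"), "PP2, MT, PC, PP, CV, HG")
    expect_equal(pick("G2337R"), "GS, SI, PR, PP2, MT, PC, PP")
    expect_equal(pick("L140_A146dup"), "REF")
    # an all-neutral bundle yields no code
    neutral <- engine_row("missense")
    expect_equal(evidenceCodeString(evidenceCodes(neutral)), "")
})

test_that("rule branches fire as specified on canonical cases", {
    map <- ttnDefaultRegionMap()
    # nonsense + MutationTaster disease causing -> radical rule
    r <- classifyVariant(engine_row("nonsense",
                                    mutation_taster = "disease_causing"),
                         map)
    expect_true(r$potentially_pathogenic)
    expect_equal(r$branch, "radical_mt")
    # in-frame dup, MutationTaster not decisive, published support -> override
    r <- classifyVariant(engine_row("inframe_indel",
                                    published_support = TRUE), map)
    expect_true(r$potentially_pathogenic)
    expect_equal(r$branch, "database_override")
    # TTN missense with full damaging consensus stays negative
    r <- classifyVariant(engine_row("missense", gene = "TTN",
                                    transcript = "NM_003319",
                                    sift = "damaging",
                                    provean = "deleterious",
                                    polyphen2 = "probably_damaging",
                                    mutation_taster = "disease_causing"),
                         map)
    expect_false(r$potentially_pathogenic)
    expect_equal(r$branch, "ttn_missense_exempt")
    # consensus-true missense demoted by a ClinVar VUS without HGMD/literature
    r <- classifyVariant(engine_row("missense", sift = "damaging",
                                    provean = "deleterious",
                                    polyphen2 = "probably_damaging",
                                    mutation_taster = "disease_causing",
                                    clinvar_class = "vus"), map)
    expect_false(r$potentially_pathogenic)
    expect_equal(r$branch, "demoted_clinvar")
    # ... but HGMD support overrides the demotion (precedence flagged)
    r <- classifyVariant(engine_row("missense", sift = "damaging",
                                    provean = "deleterious",
                                    polyphen2 = "probably_damaging",
                                    mutation_taster = "disease_causing",
                                    clinvar_class = "vus",
                                    hgmd_same_pheno = TRUE), map)
    expect_true(r$potentially_pathogenic)
    expect_equal(r$branch, "missense_consensus")
    expect_true(r$precedence_decisive)
})

test_that("a TTN truncating variant without a region map is an error", {
    v <- engine_row("frameshift_indel", gene = "TTN",
                    transcript = "NM_003319", protein_pos = 16477L)
    expect_error(classifyVariant(v, ttn_map = NULL), "region map")
})

test_that("the engine agrees with the truth-table oracle on all atom combinations", {
    map <- ttnDefaultRegionMap()
    bools <- c(FALSE, TRUE)
    clinvar_states <- c("absent", "path_same", "path_other", "vus")
    rows <- list(); oracle <- list(); k <- 0L
    for (consequence in c("missense", "nonsense", "stoploss",
                          "canonical_splice", "frameshift_indel",
                          "inframe_indel"))
        for (gene in c("MYH7", "TTN"))
            for (sift_d in bools) for (pr_d in bools)
                for (pp2_d in bools) for (mt_d in bools)
                    for (cv in clinvar_states)
                        for (hgmd in bools) for (ref in bools) {
                            pos_set <- if (gene == "TTN" &&
                                           consequence != "missense" &&
                                           consequence != "inframe_indel")
                                c(16477L, 24944L) else 100L
                            for (pos in pos_set) {
                                k <- k + 1L
                                rows[[k]] <- atoms_to_row(
                                    consequence, gene, sift_d, pr_d,
                                    pp2_d, mt_d, cv, hgmd, ref, pos)
                                oracle[[k]] <- oracle_classify(
                                    consequence, gene, sift_d, pr_d,
                                    pp2_d, mt_d, cv, hgmd, ref,
                                    ttn_rule_pass = (pos == 16477L))
                            }
                        }
    calls <- classifyVariant(do.call(rbind, rows), map)
    expect_equal(calls$potentially_pathogenic,
                 vapply(oracle, `[[`, logical(1), "pathogenic"))
    expect_equal(calls$branch,
                 vapply(oracle, `[[`, character(1), "branch"))
    # exactly one branch fires and positives come only from positive branches
    expect_true(all(calls$branch %in% c(
        "missense_consensus", "radical_mt", "ttn_truncating_a_band",
        "database_override", "demoted_clinvar", "ttn_missense_exempt",
        "not_pathogenic")))
    expect_true(all(calls$branch[calls$potentially_pathogenic] %in%
                    c("missense_consensus", "radical_mt",
                      "ttn_truncating_a_band", "database_override")))
})

test_that("demotion dominates predictors when no HGMD/literature rescue exists", {
    map <- ttnDefaultRegionMap()
    for (cls in c("benign", "likely_benign", "vus")) {
        r <- classifyVariant(engine_row("missense", sift = "damaging",
                                        provean = "deleterious",
                                        polyphen2 = "probably_damaging",
                                        mutation_taster = "disease_causing",
                                        clinvar_class = cls), map)
        expect_false(r$potentially_pathogenic)
        expect_equal(r$branch, "demoted_clinvar")
    }
})

test_that("no TTN missense is ever positive for any predictor profile", {
    map <- ttnDefaultRegionMap()
    set.seed(42)
    for (i in 1:50) {
        r <- classifyVariant(engine_row(
            "missense", gene = "TTN", transcript = "NM_003319",
            protein_pos = sample(26926L, 1),
            sift = sample(c("damaging", "tolerated", "absent"), 1),
            provean = sample(c("deleterious", "neutral", "absent"), 1),
            polyphen2 = sample(c("probably_damaging", "possibly_damaging",
                                 "benign", "absent"), 1),
            mutation_taster = sample(c("disease_causing", "polymorphism",
                                       "absent"), 1)), map)
        expect_false(r$potentially_pathogenic)
    }
})

test_that("classification is deterministic for identical inputs", {
    fx <- referenceFixtures()
    rare <- filterCohort(fx$cohort)$rare
    c1 <- classifyCohort(rare)
    c2 <- classifyCohort(rare)
    expect_identical(c1$calls, c2$calls)
})
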