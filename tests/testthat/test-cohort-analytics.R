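ref_distinct_rare <- function(fx) {
    # one row per distinct variant (the curated splice variant is carried
    # by two patients)
    f <- filterCohort(fx$cohort)
    v <- variants(f$rare)
    subsetVariants(f$rare, !duplicated(paste(v$gene, v$chrom, v$pos, v$cdna)))
}

test_that("per-patient burden covers zero-carriers and recovers planted counts", {
    fx <- referenceFixtures()
    f <- filterCohort(fx$cohort)
    cl <- classifyCohort(f$rare)
    b <- burdenSummary(f$rare, cl$calls)
    expect_equal(nrow(b$per_patient), 38L)
    expect_equal(sum(b$per_patient$n_pathogenic == 2), 3L)
    expect_equal(sum(b$per_patient$n_pathogenic == 0), 12L)
    expect_equal(sort(b$per_patient$patient_id[b$per_patient$n_pathogenic == 2]),
                 c("1173HCM", "1776HCM", "76DCM"))
    expect_equal(sum(b$per_patient$n_rare), 29L)
    # single-patient cohort: mean equals the count, degenerate range
    one <- subsetVariants(fx$cohort, variants(fx$cohort)$patient_id == "76DCM")
    r1 <- roster(one)[roster(one)$patient_id == "76DCM", ]
    solo <- cardioCohort(variants(one), r1)
    b1 <- burdenSummary(solo)
    expect_equal(b1$mean, 2)
    expect_equal(b1$range, c(2L, 2L))
    # planted per-patient counts recovered exactly on a simulated cohort
    sim <- simulateCohort(simulationConfig(), seed = 7)
    fs <- filterCohort(sim$cohort)
    bs <- burdenSummary(fs$rare)
    planted <- table(factor(sim$truth$patient_id[sim$truth$planted_rare],
                            roster(sim$cohort)$patient_id))
    expect_equal(bs$per_patient$n_rare, as.integer(planted))
    # a variant carried by an unrostered patient is rejected up front
    ghost <- variants(f$rare)
    ghost$patient_id[1] <- "GHOST"
    expect_error(methods::new("CardioCohort", variants = ghost,
                              roster = roster(f$rare)[0, ]),
                 "absent from roster")
})

test_that("gene tallies count distinct curated variants per gene", {
    fx <- referenceFixtures()
    tal <- geneTally(ref_distinct_rare(fx))
    expect_equal(tal$total[tal$gene == "MYBPC3"], 4L)
    expect_equal(tal$total[tal$gene == "OBSCN"], 4L)
    expect_equal(sum(tal$total), 28L)
    # phenotype and type breakdowns sum to the totals
    expect_equal(rowSums(tal[c("DCM", "HCM", "ARVC")]), tal$total,
                 ignore_attr = TRUE)
    expect_equal(tal$missense[tal$gene == "OBSCN"], 3L)
    # empty set gives an empty frame
    empty <- subsetVariants(fx$cohort, logical(0))
    expect_equal(nrow(geneTally(empty)), 0L)
})

test_that("the curated variant types tally 15/5/4/2/2", {
    fx <- referenceFixtures()
    v <- variants(ref_distinct_rare(fx))
    tab <- table(v$consequence)
    expect_equal(as.integer(tab[c("missense", "nonsense", "frameshift_indel",
                                  "inframe_indel", "canonical_splice")]),
                 c(15L, 5L, 4L, 2L, 2L))
})

test_that("overlap partition is disjoint, covering, and matches brute force", {
    fx <- referenceFixtures()
    rare <- filterCohort(fx$cohort)$rare
    ov <- phenotypeOverlap(rare)
    expect_named(ov, c("DCM", "HCM", "ARVC", "DCM+HCM", "DCM+ARVC",
                       "HCM+ARVC", "DCM+HCM+ARVC"))
    all_genes <- unlist(ov, use.names = FALSE)
    expect_false(any(duplicated(all_genes)))
    expect_setequal(all_genes, unique(variants(rare)$gene))
    # MYH7 appears in DCM and HCM carriers of the curated set
    expect_true("MYH7" %in% ov[["DCM+HCM"]])
    # a gene observed in a single DCM patient lands in the DCM-only region
    expect_true("TTN" %in% ov[["DCM"]])
    # fuzzed cohorts against a brute-force subset computation
    set.seed(99)
    for (rep in 1:15) {
        n <- sample(5:40, 1)
        ros <- data.frame(patient_id = paste0("P", 1:6),
                          phenotype = rep(c("DCM", "HCM", "ARVC"), 2),
                          sex = "unknown")
        v <- do.call(rbind, replicate(n, engine_row(
            "missense", gene = sample(LETTERS[1:8], 1),
            patient_id = sample(ros$patient_id, 1)), simplify = FALSE))
        v$phenotype <- ros$phenotype[match(v$patient_id, ros$patient_id)]
        cc <- methods::new("CardioCohort", variants = v, roster = ros)
        ovf <- phenotypeOverlap(cc)
        expect_false(any(duplicated(unlist(ovf))))
        expect_setequal(unlist(ovf, use.names = FALSE), unique(v$gene))
        for (g in unique(v$gene)) {
            phs <- sort(unique(v$phenotype[v$gene == g]))
            lab <- paste(intersect(c("DCM", "HCM", "ARVC"), phs),
                         collapse = "+")
            expect_true(g %in% ovf[[lab]])
        }
    }
})

test_that("tallies and partitions are invariant under row permutation", {
    fx <- referenceFixtures()
    rare <- filterCohort(fx$cohort)$rare
    set.seed(1)
    perm <- subsetVariants(rare, sample(nVariants(rare)))
    expect_equal(geneTally(rare), geneTally(perm))
    expect_equal(phenotypeOverlap(rare), phenotypeOverlap(perm))
    b1 <- burdenSummary(rare); b2 <- burdenSummary(perm)
    expect_equal(b1$per_patient, b2$per_patient)
})

test_that("novel pairs are declared strictly against the catalog", {
    fx <- referenceFixtures()
    f <- filterCohort(fx$cohort)
    cl <- classifyCohort(f$rare)
    nv <- novelAssociations(f$rare, cl$calls, fx$catalog)
    pairs <- paste(nv$novel_pairs$gene, nv$novel_pairs$phenotype)
    # channelopathy-only genes are novel in any cardiomyopathy
    expect_true("AKAP9 DCM" %in% pairs)
    expect_true("AKAP9 HCM" %in% pairs)
    expect_true("DLG1 HCM" %in% pairs)
    # phenotype-shifted observations of known genes
    expect_true("OBSCN ARVC" %in% pairs)
    expect_true("DMD ARVC" %in% pairs)
    # established associations are not novel
    expect_false("MYBPC3 HCM" %in% pairs)
    expect_false("OBSCN DCM" %in% pairs)
    expect_false("TTN DCM" %in% pairs)
    # the pathogenic-restricted view is a subset of the all-rare view
    expect_true(all(paste(nv$pathogenic_pairs$gene,
                          nv$pathogenic_pairs$phenotype) %in% pairs))
    expect_setequal(paste(nv$pathogenic_pairs$gene,
                          nv$pathogenic_pairs$phenotype),
                    c("AKAP9 DCM", "AKAP9 HCM", "DLG1 HCM",
                      "OBSCN ARVC", "DMD ARVC"))
    # planted novelty recovered exactly on a simulated cohort
    sim <- simulateCohort(simulationConfig(), seed = 13)
    fs <- filterCohort(sim$cohort)
    cs <- classifyCohort(fs$rare)
    nvs <- novelAssociations(fs$rare, cs$calls, sim$catalog)
    rt <- sim$truth[sim$truth$planted_rare, ]
    expect_equal(unname(nvs$per_patient_novel),
                 unname(vapply(roster(sim$cohort)$patient_id, function(p)
                     any(rt$planted_novel[rt$patient_id == p]),
                     logical(1))))
    # off-panel genes warn
    v <- variants(f$rare)
    v$gene[1] <- "NOTAPANELGENE"
    cc <- methods::new("CardioCohort", variants = v, roster = roster(f$rare))
    expect_warning(novelAssociations(cc, NULL, fx$catalog), "absent from the panel")
})

test_that("the report bundle mirrors the curated evidence strings and survives JSON", {
    fx <- referenceFixtures()
    f <- filterCohort(fx$cohort)
    cl <- classifyCohort(f$rare)
    b <- burdenSummary(f$rare, cl$calls)
    rep <- renderReports(f$rare, cl, b, geneTally(f$rare),
                         phenotypeOverlap(f$rare),
                         novelAssociations(f$rare, cl$calls, fx$catalog))
    # evidence strings in the rendered table match the curated codes row-wise
    t1 <- fx$table1
    m <- match(paste(t1$gene, t1$cdna),
               paste(rep$pathogenic_table$gene,
                     rep$pathogenic_table$nucleotide))
    expect_false(anyNA(m))
    expect_equal(rep$pathogenic_table$evidence[m], t1$codes)
    expect_equal(rep$summary$burden_range, c(0L, 2L))
    # JSON round trip preserves the summary scalars
    path <- tempfile(fileext = ".json")
    writeReports(rep, path)
    back <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(back$summary$n_potentially_pathogenic,
                 rep$summary$n_potentially_pathogenic)
    expect_equal(back$summary$n_patients, 38L)
    # empty cohort yields an empty-but-valid bundle
    empty <- subsetVariants(fx$cohort, logical(0))
    clE <- classifyCohort(empty)
    repE <- renderReports(empty, clE, burdenSummary(empty), geneTally(empty),
                          phenotypeOverlap(empty))
    expect_equal(repE$summary$n_rare_variants, 0L)
    expect_silent(writeReports(repE, tempfile(fileext = ".json")))
})
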