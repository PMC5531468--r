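test_that("variant tables round-trip through the TSV dialect", {
    fx <- referenceFixtures()
    v <- variants(fx$cohort)
    path <- tempfile(fileext = ".tsv")
    writeVariantTable(v, path)
    expect_match(readLines(path, n = 1), "^# cardioTriage")
    back <- readVariantTable(path)
    for (col in c("patient_id", "gene", "cdna", "protein", "depth",
                  "clinvar_class", "hgmd_same_pheno", "maf_gnomad"))
        expect_equal(back[[col]], v[[col]], ignore_attr = TRUE)
})

test_that("decimal-comma frequencies are normalised with a warning", {
    fx <- referenceFixtures()
    path <- tempfile(fileext = ".tsv")
    writeVariantTable(variants(fx$cohort), path)
    lines <- readLines(path)
    lines <- sub("0\\.0006", "0,0006", lines)
    writeLines(lines, path)
    expect_warning(v <- readVariantTable(path), "decimal comma")
    expect_true(any(v$maf_gnomad %in% 6e-4))
})

test_that("malformed tables fail with informative errors", {
    fx <- referenceFixtures()
    path <- tempfile(fileext = ".tsv")
    writeVariantTable(variants(fx$cohort), path)
    # truncated row
    lines <- readLines(path)
    lines[5] <- sub("\t[^\t]*$", "", lines[5])
    trunc <- tempfile(fileext = ".tsv")
    writeLines(lines, trunc)
    expect_error(readVariantTable(trunc), "line")
    # unknown column
    lines <- readLines(path)
    lines[2] <- paste0(lines[2], "\tmystery")
    lines[-(1:2)] <- paste0(lines[-(1:2)], "\tx")
    unk <- tempfile(fileext = ".tsv")
    writeLines(lines, unk)
    expect_error(readVariantTable(unk), "mystery")
    # missing required column
    miss <- tempfile(fileext = ".tsv")
    utils::write.table(data.frame(patient_id = "P1", gene = "MYH7"),
                       miss, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readVariantTable(miss), "lacks column")
    # unknown predictor verdict names the line
    lines <- readLines(path)
    lines[3] <- sub("\tdamaging\t", "\tSUPERBAD\t", lines[3])
    badv <- tempfile(fileext = ".tsv")
    writeLines(lines, badv)
    expect_error(readVariantTable(badv), "SUPERBAD")
})

test_that("policy YAML loads with percent and decimal-comma normalisation", {
    path <- tempfile(fileext = ".yaml")
    writeLines(c("thresholds:",
                 "  DCM: '0,4%'", "  HCM: '0.2%'", "  ARVC: 0.0005",
                 "min_depth: 10",
                 "aggregation: max_across_sources"), path)
    pol <- readPolicy(path)
    expect_equal(methods::slot(pol, "thresholds"),
                 c(DCM = 0.004, HCM = 0.002, ARVC = 5e-04))
    expect_equal(methods::slot(pol, "minDepth"), 10L)
})

test_that("catalog TSV parses multi-tag genes", {
    cat <- defaultPanelCatalog()
    expect_length(catalogGenes(cat), 115L)
    expect_true(isKnownAssociation(cat, "TTN", "DCM"))
    expect_true(isKnownAssociation(cat, "RYR2", "channelopathy"))
    expect_false(isKnownAssociation(cat, "AKAP9", "DCM"))
})

test_that("outputs are byte-stable across repeated writes", {
    fx <- referenceFixtures()
    f <- filterCohort(fx$cohort)
    cl <- classifyCohort(f$rare)
    p1 <- tempfile(); p2 <- tempfile()
    writeCalls(cl$calls, p1)
    writeCalls(cl$calls, p2)
    expect_identical(readLines(p1), readLines(p2))
    b <- burdenSummary(f$rare, cl$calls)
    rep <- renderReports(f$rare, cl, b, geneTally(f$rare),
                         phenotypeOverlap(f$rare))
    j1 <- tempfile(); j2 <- tempfile()
    writeReports(rep, j1)
    writeReports(rep, j2)
    expect_identical(readLines(j1), readLines(j2))
})

test_that("VCF ingestion splits multi-allelic records and maps INFO keys", {
    vcf_path <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
        "##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description=\"Tx\">",
        "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"cDNA\">",
        "##INFO=<ID=PROTEIN,Number=1,Type=String,Description=\"Protein\">",
        "##INFO=<ID=DEPTH,Number=1,Type=Integer,Description=\"Depth\">",
        "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT\">",
        "##INFO=<ID=PROVEAN,Number=1,Type=String,Description=\"PROVEAN\">",
        "##INFO=<ID=POLYPHEN2,Number=1,Type=String,Description=\"PP2\">",
        "##INFO=<ID=MUTATION_TASTER,Number=1,Type=String,Description=\"MT\">",
        "##INFO=<ID=MAF_GNOMAD,Number=1,Type=Float,Description=\"MAF\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "PT1", sep = "\t"),
        paste("1", "1000", "rs1", "A", "G", ".", "PASS",
              "GENE=MYH7;TRANSCRIPT=NM_000257;CDNA=c.100A>G;PROTEIN=K34E;DEPTH=55;SIFT=damaging;PROVEAN=deleterious;POLYPHEN2=probably_damaging;MUTATION_TASTER=disease_causing;MAF_GNOMAD=0.0001",
              "GT", "0/1", sep = "\t"),
        paste("1", "2000", ".", "C", "T,G", ".", "PASS",
              "GENE=TNNT2;DEPTH=40", "GT", "0/1", sep = "\t"),
        paste("2", "500", ".", "G", "A", ".", "PASS",
              "GENE=TTN;TRANSCRIPT=NM_003319;PROTEIN=R100X;DEPTH=30",
              "GT", "0/1", sep = "\t")),
        vcf_path)
    v <- readVCF(vcf_path)
    expect_equal(nrow(v), 4L)                 # multi-allelic split in two
    expect_equal(v$alt[2:3], c("T", "G"))
    expect_equal(v$gene, c("MYH7", "TNNT2", "TNNT2", "TTN"))
    expect_equal(v$patient_id, rep("PT1", 4))
    expect_equal(v$depth, c(55L, 40L, 40L, 30L))
    # unmapped predictor keys come back absent and later fail consensus
    expect_equal(v$sift, c("damaging", "absent", "absent", "absent"))
    expect_false(any(predictorConsensus(v$sift, v$provean, v$polyphen2,
                                        v$mutation_taster)[2:4]))
    # downstream model accepts the converted rows
    ros <- data.frame(patient_id = "PT1", phenotype = "DCM", sex = "M")
    cohort <- cardioCohort(v, ros)
    expect_equal(variants(cohort)$consequence[1], "missense")
})
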