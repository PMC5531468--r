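## Synthetic cohorts with recorded ground truth, plus the curated reference
## cohort (38 probands, 29 observations of 28 expert-classified variants)
## reconstructed in code from published annotations.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

X_GENES <- c("DMD", "LAMP2", "EMD", "GLA", "TAZ", "FHL1")

## template variant row with every annotation in its neutral/absent state
blank_variant <- function(n = 1L) {
    data.frame(patient_id = rep(NA_character_, n), gene = NA_character_,
               transcript = NA_character_, chrom = NA_character_,
               pos = NA_integer_, ref = NA_character_, alt = NA_character_,
               cdna = NA_character_, protein = NA_character_,
               depth = NA_integer_, dbsnp = NA_character_,
               maf_gnomad = NA_real_, maf_1000g = NA_real_,
               maf_esp = NA_real_,
               sift = "absent", provean = "absent", polyphen2 = "absent",
               mutation_taster = "absent",
               phylop = NA_real_, phastcons = NA_real_,
               grantham = NA_real_,
               clinvar_class = "absent", clinvar_same_pheno = FALSE,
               hgmd_same_pheno = FALSE, published_support = FALSE,
               genotype = "0/1", stringsAsFactors = FALSE)
}

#' The panel catalog distributed with the package
#'
#' Loads the bundled 115-gene pan-cardiomyopathy panel catalog
#' (\code{inst/extdata/panel_catalog.tsv}): for each gene the cardiomyopathy
#' phenotypes (DCM/HCM/ARVC) and/or channelopathy association it is an
#' established disease gene for. The tag set is a best-effort curation of
#' the literature-reported associations a diagnostic panel encodes.
#'
#' @return An [AssociationCatalog-class] over 115 genes.
#' @examples
#' defaultPanelCatalog()
#' @export
defaultPanelCatalog <- function() {
    readCatalog(system.file("extdata", "panel_catalog.tsv",
                            package = "cardioTriage", mustWork = TRUE))
}

## ---------------------------------------------------------------------------
## Reference fixtures: the curated 38-proband cohort
## ---------------------------------------------------------------------------

reference_roster <- function() {
    dcm <- c("76DCM", "99DCM", "310DCM", "365DCM", "682DCM", "737DCM",
             "968DCM", "1060DCM", "1329DCM", "1584DCM", "1669DCM",
             "1717DCM", "1718DCM", "1801DCM", "1816DCM", "1838DCM")
    hcm <- c("1173HCM", "1657HCM", "1661HCM", "1674HCM", "1685HCM",
             "1699HCM", "1721HCM", "1739HCM", "1740HCM", "1741HCM",
             "1776HCM", "1798HCM", "1832HCM", "1833HCM")
    arvc <- c("1662ARVC", "1665ARVC", "1666ARVC", "1708ARVC", "1751ARVC",
              "1812ARVC", "1825ARVC", "1830ARVC")
    ## sexes are synthetic assignments consistent with the cohort-level
    ## male/female counts (DCM 14M/2F, HCM 7M/7F, ARVC 5M/3F); individual
    ## sexes are not published. The DMD carrier 1751ARVC is male so the
    ## X-linked variant types as hemizygous.
    sex <- c(DCM = list(ifelse(dcm %in% c("310DCM", "365DCM"), "F", "M")),
             HCM = list(ifelse(hcm %in% c("1657HCM", "1674HCM", "1699HCM",
                                          "1739HCM", "1740HCM", "1798HCM",
                                          "1832HCM"), "F", "M")),
             ARVC = list(ifelse(arvc %in% c("1665ARVC", "1708ARVC",
                                            "1830ARVC"), "F", "M")))
    data.frame(patient_id = c(dcm, hcm, arvc),
               phenotype = rep(c("DCM", "HCM", "ARVC"),
                               c(length(dcm), length(hcm), length(arvc))),
               sex = unlist(sex, use.names = FALSE),
               stringsAsFactors = FALSE)
}

## 28 curated potentially pathogenic variants: annotation bundles are
## reconstructed from the published supporting-evidence codes (a code
## present means the underlying annotation is in its flagged state, a code
## absent the converse); read depths are not published per variant and are
## set to a constant 50, which is above the inclusion threshold and never
## decisive.
reference_table1 <- function() {
    txt <- "gene|chrom|pos|transcript|cdna|protein|dbsnp|maf|phenotype|codes|patients
ACTC1|chr15|35084392|NM_005159|c.707C>T|S236F|.|.|HCM|GS,SI,PR,PP2,MT,PC,PP|1741HCM
AKAP9|chr7|91726576|NM_005751|c.10303C>T|R3435X|.|.|DCM|MT|76DCM
AKAP9|chr7|91737871|NM_005751|c.11610C>G|Y3870X|rs757753258|4.06e-6|HCM|MT|1833HCM
DLG1|chr3|196812473|NM_004087|c.1915G>A|G639R|rs369412843|8.12e-6|HCM|GS,SI,PR,PP2,MT,PC,PP|1776HCM
DMD|chrX|32456458|NM_004009|c.3959G>A|R1320H|rs768990357|2.24e-5|ARVC|SI,PR,PP2,MT,PC,PP|1751ARVC
DSP|chr6|7569522|NM_004415|c.1524dupG|V508fs|.|.|DCM|MT|76DCM
DSP|chr6|7580243|NM_004415|c.3820G>C|A1274P|.|.|DCM|SI,PR,PP2,MT,PP|1060DCM
LAMP2|chrX|119576454|NM_013995|c.928G>A|V310I|rs104894858|.|HCM|PP2,MT,PC,PP,CV,HG|1740HCM
LMNA|chr1|156100468|NM_170708|c.667_687dup|L140_A146dup|.|.|DCM|REF|737DCM
LMNA|chr1|156106964|NM_170708|c.1549C>T|Q517X|.|.|DCM|MT,PC,PP,HG|1816DCM
MYBPC3|chr11|47371475|NM_000256|c.506-2A>C|.|rs397516057|.|HCM|MT,PC,PP,CV|1657HCM;1661HCM
MYBPC3|chr11|47369407|NM_000256|c.821+1G>A|.|rs397516073|2.98e-5|HCM|MT,PC,PP,CV,HG|1699HCM
MYBPC3|chr11|47367758|NM_000256|c.1090G>A|A364T|.|.|HCM|SI,PR,PP2,MT,PC,PP|1776HCM
MYBPC3|chr11|47360197|NM_000256|c.2182G>T|E728X|rs397515954|.|HCM|MT,PC,PP,CV|1173HCM
MYH7|chr14|23895233|NM_000257|c.2102G>A|G701D|.|.|HCM|SI,PR,PP2,MT,PC,PP|1832HCM
MYH7|chr14|23886383|NM_000257|c.4498C>T|R1500W|rs45544633|.|DCM|SI,PR,PP2,MT,CV,HG|1801DCM
MYH7|chr14|23884353|NM_000257|c.5410G>A|A1804T|rs730880818|4.06e-6|DCM|SI,PR,PP2,MT,PC,PP,CV|1329DCM
NEXN|chr1|78401657|NM_144573|c.1398_1400delAAT|I467del|.|.|HCM|MT,PC|1674HCM
OBSCN|chr1|228400286|NM_052843|c.802G>T|E268X|.|.|HCM|MT,PP|1173HCM
OBSCN|chr1|228525823|NM_001098623|c.16979C>T|A5660V|rs191098985|6e-4|DCM|GS,SI,PR,PP2,MT,PC,PP|1718DCM
OBSCN|chr1|228527758|NM_001098623|c.17371G>C|A5791P|rs200362121|4e-4|ARVC|SI,PR,PP2,MT,PC,PP|1662ARVC
OBSCN|chr1|228557681|NM_001098623|c.20006G>A|R6669H|rs373638525|9.4e-5|DCM|SI,PR,PP2,MT,PP|682DCM
PKP2|chr12|33030842|NM_004572|c.962_972delTCGGCCAGGCG|V321GfsX11|.|.|ARVC|MT|1825ARVC
PKP2|chr12|32974392|NM_004572|c.2043delT|I681fs|.|.|ARVC|MT|1666ARVC
RAF1|chr3|12626632|NM_002880|c.1657A>C|N553H|rs745876012|4.06e-6|HCM|SI,PR,PP2,MT,PC,PP|1721HCM
RYR2|chr1|237802395|NM_001035|c.7009G>C|G2337R|.|.|ARVC|GS,SI,PR,PP2,MT,PC,PP|1812ARVC
TNNT2|chr1|201334425|NM_001276345|c.305G>A|R102Q|rs121964856|.|HCM|SI,PR,PP2,MT,PC,PP,CV,HG|1739HCM
TTN|chr2|179434235|NM_003319|c.49429delG|V16477fs|.|.|DCM|MT,PC,PP|99DCM"
    tab <- utils::read.delim(text = txt, sep = "|", stringsAsFactors = FALSE,
                             na.strings = ".")
    tab$maf <- as.numeric(tab$maf)
    tab
}

## expand a code string into the annotation bundle it implies
codes_to_annotations <- function(row, codes) {
    has <- function(code) code %in% codes
    is_missense <- !is.na(row$protein[1]) &&
        parseProteinChange(row$protein[1])$kind == "missense"
    if (is_missense) {
        row$sift <- if (has("SI")) "damaging" else "tolerated"
        row$provean <- if (has("PR")) "deleterious" else "neutral"
        row$polyphen2 <- if (has("PP2")) "probably_damaging" else "benign"
        row$grantham <- if (has("GS")) 120 else 40
    }
    row$mutation_taster <- if (has("MT")) "disease_causing" else "absent"
    row$phastcons <- if (has("PC")) 1 else 0.62
    row$phylop <- if (has("PP")) 2.5 else 0.4
    if (has("CV")) {
        row$clinvar_class <- "pathogenic"
        row$clinvar_same_pheno <- TRUE
    }
    row$hgmd_same_pheno <- has("HG")
    row$published_support <- has("REF")
    row
}

#' Curated reference cohort and expected classifications
#'
#' Reconstructs, entirely in code, the package's worked example: a cohort
#' of 38 unrelated cardiomyopathy probands (16 DCM, 14 HCM, 8 ARVC) whose
#' 28 expert-classified potentially pathogenic variants (29 carrier
#' observations; one splice variant is carried by two patients) are encoded
#' from their published annotations. The per-variant annotation bundle
#' (predictor verdicts, conservation scores, ClinVar/HGMD/literature
#' support) is derived from the published supporting-evidence codes; read
#' depths, not published per variant, are a constant 50. The accompanying
#' expectation table gives, per distinct variant, the evidence-code display
#' string and the rule branch the engine is expected to reproduce.
#'
#' @return A list with elements \code{cohort} (a [CardioCohort-class] of 29
#'   observations over 38 patients), \code{table1} (data.frame of the 28
#'   distinct variants with columns including \code{codes} -- the expected
#'   evidence string -- and \code{expected_branch}), and \code{catalog}
#'   (the bundled [AssociationCatalog-class]).
#' @examples
#' fx <- referenceFixtures()
#' nVariants(fx$cohort)
#' @export
referenceFixtures <- function() {
    tab <- reference_table1()
    ros <- reference_roster()
    rows <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
        carriers <- strsplit(tab$patients[i], ";", fixed = TRUE)[[1]]
        codes <- strsplit(tab$codes[i], ",", fixed = TRUE)[[1]]
        vr <- blank_variant(length(carriers))
        vr$patient_id <- carriers
        vr$gene <- tab$gene[i]
        vr$transcript <- tab$transcript[i]
        vr$chrom <- tab$chrom[i]
        vr$pos <- tab$pos[i]
        sub <- regmatches(tab$cdna[i],
                          regexec("([ACGT])>([ACGT])$", tab$cdna[i]))[[1]]
        if (length(sub)) {
            vr$ref <- sub[2]
            vr$alt <- sub[3]
        }
        vr$cdna <- tab$cdna[i]
        vr$protein <- tab$protein[i]
        vr$depth <- 50L
        vr$dbsnp <- tab$dbsnp[i]
        vr$maf_gnomad <- tab$maf[i]
        male <- vr$patient_id %in% ros$patient_id[ros$sex == "M"]
        vr$genotype <- ifelse(tab$chrom[i] == "chrX" & male, "1", "0/1")
        vr <- codes_to_annotations(vr, codes)
        rows[[i]] <- vr
    }
    variants <- do.call(rbind, rows)
    tab$expected_branch <- vapply(seq_len(nrow(tab)), function(i) {
        codes <- strsplit(tab$codes[i], ",", fixed = TRUE)[[1]]
        kind <- parseProteinChange(tab$protein[i])$kind
        if (tab$gene[i] == "TTN") "ttn_truncating_a_band"
        else if (kind == "missense" &&
                 all(c("SI", "PR", "PP2", "MT") %in% codes))
            "missense_consensus"
        else if (kind != "missense" && "MT" %in% codes) "radical_mt"
        else "database_override"
    }, character(1))
    tab$codes <- vapply(strsplit(tab$codes, ",", fixed = TRUE),
                        paste, character(1), collapse = ", ")
    list(cohort = cardioCohort(variants, ros),
         table1 = tab,
         catalog = defaultPanelCatalog())
}

## ---------------------------------------------------------------------------
## Simulator
## ---------------------------------------------------------------------------

#' Configuration for the cohort simulator
#'
#' Defaults emulate the reference study design: 16 DCM, 14 HCM and 8 ARVC
#' patients screened on a 115-gene panel, with on average 85/89/92
#' candidate variants per DCM/HCM/ARVC patient collapsing to on average
#' 4.5/3.6/2.4 rare variants. Rare variants are assigned a rule branch with
#' the stated probabilities and their annotations are constructed to
#' satisfy exactly that branch; non-rare candidates are constructed to fail
#' exactly one inclusion criterion (chosen with \code{failCriterionProbs}).
#'
#' @param nPatients Named integer vector of patients per phenotype.
#' @param candidateMean Named numeric: mean candidate variants per patient.
#' @param rareMean Named numeric: mean rare variants per patient.
#' @param branchRates Named probabilities over rule branches for rare
#'   variants (must sum to 1). \code{not_pathogenic} covers benign missense
#'   and radical variants.
#' @param failCriterionProbs Probabilities that a non-rare candidate fails
#'   the \code{maf}, \code{depth} or \code{consequence} criterion.
#' @param predictorNoise Probability of corrupting each predictor verdict
#'   after the ground truth is recorded (0 = noiseless).
#' @param novelFromAbsent Fraction of rare variants absent from every
#'   population database (frequency unknown everywhere).
#' @param geneSkew Exponent of the rank-weight decay used when sampling
#'   genes, producing the few-genes-dominate tallies seen in panels.
#' @param policy The [MAFPolicy-class] the planted frequencies respect.
#' @return A list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(nPatients = c(DCM = 16L, HCM = 14L, ARVC = 8L),
                             candidateMean = c(DCM = 85, HCM = 89, ARVC = 92),
                             rareMean = c(DCM = 4.5, HCM = 3.6, ARVC = 2.4),
                             branchRates = c(missense_consensus = 0.10,
                                             radical_mt = 0.08,
                                             database_override = 0.015,
                                             ttn_truncating_a_band = 0.007,
                                             demoted_clinvar = 0.02,
                                             ttn_missense_exempt = 0.28,
                                             not_pathogenic = 0.498),
                             failCriterionProbs = c(maf = 0.90,
                                                    depth = 0.05,
                                                    consequence = 0.05),
                             predictorNoise = 0,
                             novelFromAbsent = 0.23,
                             geneSkew = 1.2,
                             policy = mafPolicy()) {
    cfg <- list(nPatients = nPatients, candidateMean = candidateMean,
                rareMean = rareMean, branchRates = branchRates,
                failCriterionProbs = failCriterionProbs,
                predictorNoise = predictorNoise,
                novelFromAbsent = novelFromAbsent,
                geneSkew = geneSkew, policy = policy)
    validateSimulationConfig(cfg)
    structure(cfg, class = "simulationConfig")
}

validateSimulationConfig <- function(cfg) {
    stopifnot(setequal(names(cfg$nPatients), PHENOTYPES),
              all(cfg$nPatients >= 0),
              all(cfg$candidateMean > 0), all(cfg$rareMean >= 0),
              cfg$predictorNoise >= 0, cfg$predictorNoise <= 1,
              cfg$novelFromAbsent >= 0, cfg$novelFromAbsent <= 1)
    if (any(cfg$rareMean > cfg$candidateMean))
        stop("infeasible config: rareMean exceeds candidateMean")
    if (any(cfg$branchRates < 0) ||
        abs(sum(cfg$branchRates) - 1) > 1e-8)
        stop("branchRates must be non-negative and sum to 1")
    if (!all(names(cfg$branchRates) %in%
             c(POSITIVE_BRANCHES, "demoted_clinvar",
               "ttn_missense_exempt", "not_pathogenic")))
        stop("unknown branch name in branchRates")
    if (sum(cfg$branchRates) == 0 && any(cfg$rareMean > 0))
        stop("infeasible config: rare variants requested but no branch rates")
    invisible(TRUE)
}

## deterministic chromosome for a panel gene
gene_chrom <- function(gene, panel_genes) {
    ifelse(gene %in% X_GENES, "chrX",
           paste0("chr", 1L + (match(gene, panel_genes) %% 22L)))
}

sim_missense_token <- function(pos) {
    aa <- sample(AA1, 2L)
    paste0(aa[1], pos, aa[2])
}

#' Simulate an annotated cohort with recorded ground truth
#'
#' Generates a roster, an annotated-variant table, and a truth table
#' recording -- at generation time, never recomputed -- each variant's
#' planted filter fate (rare, or the single failed criterion) and, for rare
#' variants, the planted rule branch, pathogenicity label and gene-
#' phenotype novelty against the bundled panel catalog. Annotations are
#' constructed so that a noiseless run of [filterCohort()] and
#' [classifyCohort()] reproduces the truth exactly: planted-rare
#' frequencies sit below the phenotype threshold with a 20\% margin and
#' planted-common frequencies above it, and each branch's annotation bundle
#' satisfies exactly that rule.
#'
#' @param config A [simulationConfig()].
#' @param seed Integer seed; mandatory, the generator is fully
#'   deterministic given it.
#' @return A list: \code{cohort} (a [CardioCohort-class]), \code{catalog}
#'   (the bundled panel catalog), \code{truth} (data.frame with
#'   \code{variant_uid}, \code{patient_id}, \code{gene},
#'   \code{planted_rare}, \code{failed_criterion}, \code{planted_branch},
#'   \code{planted_pathogenic}, \code{planted_novel}) and \code{seed}.
#' @examples
#' sim <- simulateCohort(simulationConfig(), seed = 17)
#' table(sim$truth$planted_branch)
#' @export
simulateCohort <- function(config = simulationConfig(), seed) {
    if (missing(seed) || is.na(seed))
        stop("a seed is mandatory for reproducibility")
    validateSimulationConfig(config)
    set.seed(as.integer(seed))
    catalog <- defaultPanelCatalog()
    panel_genes <- catalogGenes(catalog)
    nonttn <- setdiff(panel_genes, "TTN")
    w <- 1 / seq_along(nonttn)^config$geneSkew
    ## a handful of large genes dominate panel tallies; put the heaviest
    ## weights on the genes that dominate real panels
    heavy <- c("OBSCN", "RYR2", "SYNE1", "ANK2", "AKAP9", "DMD")
    ord <- c(heavy[heavy %in% nonttn],
             sample(setdiff(nonttn, heavy)))
    gene_weights <- stats::setNames(w, ord)

    roster <- do.call(rbind, lapply(PHENOTYPES, function(ph) {
        n <- config$nPatients[[ph]]
        if (n == 0) return(NULL)
        data.frame(patient_id = sprintf("S%02d%s", seq_len(n), ph),
                   phenotype = ph,
                   sex = sample(c("M", "F"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
    }))

    thr <- config$policy@thresholds
    min_depth <- config$policy@minDepth
    branches <- names(config$branchRates)

    all_rows <- list()
    truth_rows <- list()
    uid <- 0L
    for (p in seq_len(nrow(roster))) {
        ph <- roster$phenotype[p]
        pid <- roster$patient_id[p]
        sex <- roster$sex[p]
        n_rare <- stats::rpois(1L, config$rareMean[[ph]])
        n_common <- max(stats::rpois(1L, config$candidateMean[[ph]]) - n_rare,
                        0L)
        n <- n_rare + n_common
        if (n == 0L) next
        rows <- blank_variant(n)
        rows$patient_id <- pid
        is_rare <- c(rep(TRUE, n_rare), rep(FALSE, n_common))
        branch <- rep(NA_character_, n)
        failed <- rep(NA_character_, n)
        if (n_rare > 0)
            branch[seq_len(n_rare)] <- sample(branches, n_rare,
                                              replace = TRUE,
                                              prob = config$branchRates)
        if (n_common > 0)
            failed[n_rare + seq_len(n_common)] <-
                sample(names(config$failCriterionProbs), n_common,
                       replace = TRUE, prob = config$failCriterionProbs)

        for (i in seq_len(n)) {
            uid <- uid + 1L
            rows$pos[i] <- sample.int(2e8L, 1L)
            rows$depth[i] <- sample(seq(min_depth, 300L), 1L)
            rows$ref[i] <- sample(c("A", "C", "G", "T"), 1L)
            rows$alt[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                          rows$ref[i]), 1L)
            if (is_rare[i]) {
                br <- branch[i]
                if (br %in% c("ttn_missense_exempt",
                              "ttn_truncating_a_band")) {
                    rows$gene[i] <- "TTN"
                    rows$transcript[i] <- "NM_003319"
                } else {
                    rows$gene[i] <- sample(names(gene_weights), 1L,
                                           prob = gene_weights)
                    rows$transcript[i] <- paste0("NM_",
                                                 formatC(match(rows$gene[i],
                                                               panel_genes),
                                                         width = 6,
                                                         flag = "0"))
                }
                ## frequency below threshold with a 20% margin, or absent
                ## from every database
                if (stats::runif(1) < config$novelFromAbsent) {
                    rows$maf_gnomad[i] <- NA_real_
                } else {
                    rows$maf_gnomad[i] <- stats::runif(1, 0, 0.8 * thr[[ph]])
                    rows$dbsnp[i] <- sprintf("rs%08d", uid)
                }
                rows[i, ] <- plant_branch(rows[i, ], br, ph)
            } else {
                rows$gene[i] <- sample(names(gene_weights), 1L,
                                       prob = gene_weights)
                rows$transcript[i] <- paste0("NM_",
                                             formatC(match(rows$gene[i],
                                                           panel_genes),
                                                     width = 6, flag = "0"))
                pos_aa <- sample.int(900L, 1L)
                rows$protein[i] <- sim_missense_token(pos_aa)
                rows$cdna[i] <- sprintf("c.%d%s>%s", 3L * pos_aa,
                                        rows$ref[i], rows$alt[i])
                rows$dbsnp[i] <- sprintf("rs%08d", uid)
                rows$maf_gnomad[i] <- stats::runif(1, 0, 0.8 * thr[[ph]])
                if (failed[i] == "maf") {
                    rows$maf_gnomad[i] <- stats::runif(1, 1.2 * thr[[ph]],
                                                       min(1, 5 * thr[[ph]]))
                } else if (failed[i] == "depth") {
                    rows$depth[i] <- sample(seq_len(min_depth - 1L), 1L)
                } else {
                    ## synonymous substitution: consequence class 'other'
                    aa <- sample(AA1, 1L)
                    rows$protein[i] <- paste0(aa, pos_aa, aa)
                }
            }
            rows$chrom[i] <- gene_chrom(rows$gene[i], panel_genes)
            if (rows$chrom[i] == "chrX" && sex == "M")
                rows$genotype[i] <- "1"
            truth_rows[[uid]] <- data.frame(
                variant_uid = uid, patient_id = pid, phenotype = ph,
                gene = rows$gene[i], planted_rare = is_rare[i],
                failed_criterion = failed[i], planted_branch = branch[i],
                planted_pathogenic = !is.na(branch[i]) &&
                    branch[i] %in% POSITIVE_BRANCHES,
                planted_novel = is_rare[i] &&
                    !isKnownAssociation(catalog, rows$gene[i], ph),
                stringsAsFactors = FALSE)
        }
        rows$variant_uid <- (uid - n + 1L):uid
        all_rows[[p]] <- rows
    }
    variants <- do.call(rbind, all_rows)
    truth <- do.call(rbind, truth_rows)

    if (config$predictorNoise > 0)
        variants <- corrupt_predictors(variants, config$predictorNoise)

    list(cohort = cardioCohort(variants, roster), catalog = catalog,
         truth = truth, config = config, seed = as.integer(seed))
}

## construct the annotation bundle satisfying exactly one rule branch
plant_branch <- function(row, branch, phenotype) {
    damaging <- function(row) {
        row$sift <- "damaging"; row$provean <- "deleterious"
        row$polyphen2 <- sample(c("probably_damaging",
                                  "possibly_damaging"), 1L)
        row$mutation_taster <- "disease_causing"
        row$grantham <- sample(c(60, 120), 1L)
        row$phastcons <- sample(c(1, 0.7), 1L)
        row$phylop <- sample(c(2.2, 0.5), 1L)
        row
    }
    benign <- function(row) {
        row$sift <- "tolerated"
        row$provean <- sample(c("deleterious", "neutral"), 1L)
        row$polyphen2 <- sample(c("benign", "possibly_damaging"), 1L)
        row$mutation_taster <- sample(c("polymorphism", "disease_causing"),
                                      1L)
        row$grantham <- 40; row$phastcons <- 0.5; row$phylop <- 0.2
        row
    }
    radical_token <- function(row, pos_aa) {
        kind <- sample(c("nonsense", "frameshift", "inframe_del",
                         "canonical_splice"), 1L)
        if (kind == "nonsense") {
            row$protein <- paste0(sample(AA1, 1L), pos_aa, "X")
            row$cdna <- sprintf("c.%dC>T", 3L * pos_aa)
        } else if (kind == "frameshift") {
            row$protein <- paste0(sample(AA1, 1L), pos_aa, "fs")
            row$cdna <- sprintf("c.%ddelG", 3L * pos_aa)
        } else if (kind == "inframe_del") {
            row$protein <- paste0(sample(AA1, 1L), pos_aa, "del")
            row$cdna <- sprintf("c.%d_%ddelAAA", 3L * pos_aa, 3L * pos_aa + 2L)
        } else {
            row$protein <- NA_character_
            row$cdna <- sprintf("c.%d-2A>G", 3L * pos_aa)
        }
        row
    }
    pos_aa <- sample.int(900L, 1L)
    if (branch == "missense_consensus") {
        row$protein <- sim_missense_token(pos_aa)
        row$cdna <- sprintf("c.%dA>G", 3L * pos_aa)
        row <- damaging(row)
    } else if (branch == "ttn_missense_exempt") {
        pos_aa <- sample(801:13600, 1L)
        row$protein <- sim_missense_token(pos_aa)
        row$cdna <- sprintf("c.%dA>G", 3L * pos_aa)
        row <- damaging(row)  # exempt regardless of verdicts
    } else if (branch == "ttn_truncating_a_band") {
        pos_aa <- sample(13601:24750, 1L)
        row$protein <- paste0(sample(AA1, 1L), pos_aa, "fs")
        row$cdna <- sprintf("c.%ddelG", 3L * pos_aa)
        row$mutation_taster <- "disease_causing"
    } else if (branch == "radical_mt") {
        row <- radical_token(row, pos_aa)
        row$mutation_taster <- "disease_causing"
    } else if (branch == "database_override") {
        if (stats::runif(1) < 0.5) {
            row$protein <- sim_missense_token(pos_aa)
            row$cdna <- sprintf("c.%dA>G", 3L * pos_aa)
            row <- benign(row)
            row$sift <- "tolerated"   # consensus must fail
        } else {
            row <- radical_token(row, pos_aa)
            row$mutation_taster <- "polymorphism"
        }
        if (stats::runif(1) < 0.5) row$hgmd_same_pheno <- TRUE
        else row$published_support <- TRUE
    } else if (branch == "demoted_clinvar") {
        row$protein <- sim_missense_token(pos_aa)
        row$cdna <- sprintf("c.%dA>G", 3L * pos_aa)
        row <- damaging(row)
        row$clinvar_class <- sample(c("vus", "likely_benign", "benign"), 1L)
    } else {  # not_pathogenic
        if (stats::runif(1) < 0.8) {
            row$protein <- sim_missense_token(pos_aa)
            row$cdna <- sprintf("c.%dA>G", 3L * pos_aa)
            row <- benign(row)
        } else {
            row <- radical_token(row, pos_aa)
            row$mutation_taster <- "polymorphism"
        }
    }
    row
}

corrupt_predictors <- function(variants, p) {
    flip <- function(x, levels) {
        hit <- stats::runif(length(x)) < p & x != "absent"
        x[hit] <- vapply(x[hit], function(cur)
            sample(setdiff(levels, cur), 1L), character(1))
        x
    }
    variants$sift <- flip(variants$sift, c("damaging", "tolerated"))
    variants$provean <- flip(variants$provean, c("deleterious", "neutral"))
    variants$polyphen2 <- flip(variants$polyphen2,
                               c("probably_damaging", "possibly_damaging",
                                 "benign"))
    variants$mutation_taster <- flip(variants$mutation_taster,
                                     c("disease_causing", "polymorphism"))
    variants
}
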