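## Single entry point wiring the stages: (simulate) -> filter -> classify
## -> report. The exported function is the programmatic interface; a thin
## Rscript wrapper lives in inst/scripts/triage.R.

#' Run the full triage pipeline
#'
#' Stages, in order: load (or simulate) the annotated cohort, apply the
#' rarity filter, classify the rare set, and assemble the report bundle.
#' Each stage logs its input and output counts; the counts reconcile
#' across stages. Re-running with unchanged inputs overwrites the output
#' files with identical bytes.
#'
#' @param variants Path to an annotated-variant TSV, or a data.frame, or
#'   \code{NULL} to simulate a cohort.
#' @param roster Path to a roster TSV or a data.frame (ignored when
#'   simulating).
#' @param catalog Path to a panel catalog TSV or an
#'   [AssociationCatalog-class]; defaults to the bundled panel.
#' @param policy A [MAFPolicy-class] or path to a policy YAML.
#' @param ttnMap A [TTNRegionMap-class] or path to a region-map YAML;
#'   defaults to the bundled map.
#' @param simulate A [simulationConfig()] used when \code{variants} is
#'   \code{NULL}.
#' @param seed Seed for simulation.
#' @param outDir Output directory; created if needed. \code{NULL} writes
#'   no files.
#' @param stopAfter Run only up to this stage: \code{"filter"},
#'   \code{"classify"} or \code{"report"} (default).
#' @param quiet Suppress stage logging.
#' @return A list with the artifacts computed so far: \code{cohort},
#'   \code{filtered}, \code{classification}, \code{report} (and
#'   \code{truth} when simulated), invisibly.
#' @examples
#' fx <- referenceFixtures()
#' res <- runPipeline(variants(fx$cohort), roster(fx$cohort))
#' res$classification$summary$n_positive
#' @export
runPipeline <- function(variants = NULL, roster = NULL,
                        catalog = defaultPanelCatalog(),
                        policy = mafPolicy(),
                        ttnMap = ttnDefaultRegionMap(),
                        simulate = simulationConfig(), seed = 1L,
                        outDir = NULL,
                        stopAfter = c("report", "classify", "filter"),
                        quiet = FALSE) {
    stopAfter <- match.arg(stopAfter)
    say <- function(...) if (!quiet) message(sprintf(...))
    if (is.character(policy)) policy <- readPolicy(policy)
    if (is.character(ttnMap)) ttnMap <- readTTNRegionMap(ttnMap)
    if (is.character(catalog)) catalog <- readCatalog(catalog)

    truth <- NULL
    if (is.null(variants)) {
        sim <- simulateCohort(simulate, seed = seed)
        cohort <- sim$cohort
        truth <- sim$truth
        say("[simulate] %d patients, %d candidate variants",
            nPatients(cohort), nVariants(cohort))
    } else {
        if (is.character(variants)) variants <- readVariantTable(variants)
        if (is.character(roster)) roster <- readRoster(roster)
        cohort <- cardioCohort(variants, roster)
        say("[load] %d patients, %d candidate variants",
            nPatients(cohort), nVariants(cohort))
    }
    if (!is.null(outDir))
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    filtered <- filterCohort(cohort, policy)
    say("[filter] %d in -> %d rare variants retained",
        filtered$report$n_input, filtered$report$n_retained)
    if (!is.null(outDir))
        writeVariantTable(variants(filtered$rare),
                          file.path(outDir, "rare.tsv"))
    out <- list(cohort = cohort, filtered = filtered, truth = truth)
    if (stopAfter == "filter") return(invisible(out))

    classification <- classifyCohort(filtered$rare, ttnMap)
    say("[classify] %d rare -> %d potentially pathogenic",
        classification$summary$n, classification$summary$n_positive)
    if (!is.null(outDir))
        writeCalls(classification$calls, file.path(outDir, "calls.tsv"))
    out$classification <- classification
    if (stopAfter == "classify") return(invisible(out))

    burden <- burdenSummary(filtered$rare, classification$calls)
    tally <- geneTally(filtered$rare)
    overlap <- phenotypeOverlap(filtered$rare)
    novelty <- novelAssociations(filtered$rare, classification$calls,
                                 catalog)
    report <- renderReports(filtered$rare, classification, burden, tally,
                            overlap, novelty)
    say("[report] %d novel gene-phenotype pairs in %d patients",
        nrow(novelty$novel_pairs), sum(novelty$per_patient_novel))
    if (!is.null(outDir))
        writeReports(report, file.path(outDir, "report.json"))
    out$report <- report
    invisible(out)
}
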