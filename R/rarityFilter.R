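## Phenotype-specific rarity filter: protein-altering consequence, read
## support, and per-phenotype MAF thresholds.

## Aggregate the maf_* columns of a variant table into one frequency per
## row. Absence from every database counts as frequency 0 (a variant never
## observed in any population resource is maximally rare).
aggregateMAF <- function(variants) {
    maf_cols <- grep("^maf_", names(variants), value = TRUE)
    if (!length(maf_cols))
        return(rep(0, nrow(variants)))
    m <- as.matrix(as.data.frame(lapply(variants[maf_cols], as.numeric)))
    agg <- apply(m, 1L, function(x) {
        if (all(is.na(x))) 0 else max(x, na.rm = TRUE)
    })
    as.numeric(agg)
}

#' Per-variant inclusion decision
#'
#' Tests one or more annotated variants against the three inclusion
#' criteria that define the rare-variant set: a protein-altering consequence
#' (missense, nonsense, stop-loss, canonical splice, frameshift or in-frame
#' indel), read support of at least \code{minDepth} reads, and an aggregated
#' minor allele frequency at or below the threshold of the carrier's
#' phenotype. A variant absent from every population database counts as
#' frequency zero and passes the frequency criterion.
#'
#' @param variants Annotated-variant data.frame carrying the derived columns
#'   added by [cardioCohort()] (in particular \code{consequence} and
#'   \code{phenotype}).
#' @param policy A [MAFPolicy-class].
#' @return A data.frame with columns \code{retained} (logical) and the
#'   per-criterion failure flags \code{failed_consequence},
#'   \code{failed_depth}, \code{failed_maf}; \code{retained} is \code{TRUE}
#'   exactly when no criterion failed. The aggregated frequency is returned
#'   in \code{maf_aggregate}.
#' @examples
#' fx <- referenceFixtures()
#' head(passesInclusion(variants(fx$cohort), mafPolicy()))
#' @export
passesInclusion <- function(variants, policy = mafPolicy()) {
    stopifnot(is(policy, "MAFPolicy"))
    if (any(is.na(variants$phenotype)))
        stop("carrier phenotype unknown for some variants; ",
             "the MAF threshold is undefined without it")
    thr <- policy@thresholds[variants$phenotype]
    maf <- aggregateMAF(variants)
    failed_consequence <- !variants$consequence %in% PROTEIN_ALTERING
    failed_depth <- is.na(variants$depth) | variants$depth < policy@minDepth
    failed_maf <- maf > thr
    data.frame(retained = !(failed_consequence | failed_depth | failed_maf),
               failed_consequence = failed_consequence,
               failed_depth = failed_depth,
               failed_maf = failed_maf,
               maf_aggregate = maf)
}

#' Apply the rarity filter to a cohort
#'
#' Evaluates [passesInclusion()] on every variant observation and splits the
#' cohort into the retained rare-variant set (the input to pathogenicity
#' classification) and a filter report.
#'
#' @param cohort A [CardioCohort-class].
#' @param policy A [MAFPolicy-class].
#' @return A list with elements \code{rare} (a \code{CardioCohort} holding
#'   the retained rows over the unchanged roster), \code{decisions} (the
#'   [passesInclusion()] table for all input rows), and \code{report}: input
#'   and retained totals, per-criterion failure counts, and a per-patient
#'   input/retained table covering every rostered patient.
#' @examples
#' fx <- referenceFixtures()
#' filtered <- filterCohort(fx$cohort, mafPolicy())
#' filtered$report$n_retained
#' @export
filterCohort <- function(cohort, policy = mafPolicy()) {
    stopifnot(is(cohort, "CardioCohort"))
    v <- variants(cohort)
    if (!nrow(v)) {
        warning("empty cohort: nothing to filter")
        empty <- data.frame(retained = logical(), failed_consequence = logical(),
                            failed_depth = logical(), failed_maf = logical(),
                            maf_aggregate = numeric())
        per_patient <- data.frame(patient_id = roster(cohort)$patient_id,
                                  n_input = 0L, n_retained = 0L)
        return(list(rare = cohort, decisions = empty,
                    report = list(n_input = 0L, n_retained = 0L,
                                  n_failed_consequence = 0L,
                                  n_failed_depth = 0L, n_failed_maf = 0L,
                                  per_patient = per_patient)))
    }
    dec <- passesInclusion(v, policy)
    rare <- subsetVariants(cohort, dec$retained)
    ids <- roster(cohort)$patient_id
    per_patient <- data.frame(
        patient_id = ids,
        n_input = as.integer(table(factor(v$patient_id, ids))),
        n_retained = as.integer(table(factor(v$patient_id[dec$retained], ids))))
    report <- list(n_input = nrow(v),
                   n_retained = sum(dec$retained),
                   n_failed_consequence = sum(dec$failed_consequence),
                   n_failed_depth = sum(dec$failed_depth),
                   n_failed_maf = sum(dec$failed_maf),
                   per_patient = per_patient)
    list(rare = rare, decisions = dec, report = report)
}
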