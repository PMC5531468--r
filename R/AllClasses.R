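#' @import methods
NULL

PHENOTYPES <- c("DCM", "HCM", "ARVC")
SEXES <- c("M", "F", "unknown")

CONSEQUENCE_CLASSES <- c("missense", "nonsense", "stoploss",
                         "canonical_splice", "frameshift_indel",
                         "inframe_indel", "other")

## consequence classes that alter the protein and enter the rarity filter
PROTEIN_ALTERING <- setdiff(CONSEQUENCE_CLASSES, "other")

## "radical" variants: everything non-missense that alters the protein
RADICAL_CLASSES <- c("nonsense", "stoploss", "canonical_splice",
                     "frameshift_indel", "inframe_indel")

## truncating classes relevant to the TTN isoform rule
TRUNCATING_CLASSES <- c("nonsense", "stoploss", "canonical_splice",
                        "frameshift_indel")

RULE_BRANCHES <- c("missense_consensus", "radical_mt",
                   "ttn_truncating_a_band", "database_override",
                   "demoted_clinvar", "ttn_missense_exempt",
                   "not_pathogenic")

POSITIVE_BRANCHES <- c("missense_consensus", "radical_mt",
                       "ttn_truncating_a_band", "database_override")

EVIDENCE_CODE_ORDER <- c("GS", "SI", "PR", "PP2", "MT", "PC", "PP",
                         "CV", "HG", "REF")

CLINVAR_CLASSES <- c("pathogenic", "likely_pathogenic", "vus",
                     "likely_benign", "benign", "absent")
CLINVAR_DEMOTING <- c("vus", "likely_benign", "benign")

ASSOCIATION_TAGS <- c("DCM", "HCM", "ARVC", "channelopathy")

## columns every annotated-variant table must provide
VARIANT_COLUMNS <- c("patient_id", "gene", "transcript", "chrom", "pos",
                     "ref", "alt", "cdna", "protein", "depth", "dbsnp",
                     "sift", "provean", "polyphen2", "mutation_taster",
                     "phylop", "phastcons", "grantham",
                     "clinvar_class", "clinvar_same_pheno",
                     "hgmd_same_pheno", "published_support", "genotype")

## ---------------------------------------------------------------------------
## MAFPolicy
## ---------------------------------------------------------------------------

#' Phenotype-specific rarity policy
#'
#' Thresholds on the minor allele frequency (MAF), one per cardiomyopathy
#' phenotype, together with the minimum read support a call must have and the
#' rule used to aggregate frequencies across population databases. The
#' defaults are MAF \eqn{\le} 0.4\% for DCM, \eqn{\le} 0.2\% for HCM and
#' \eqn{\le} 0.05\% for ARVC carriers, with at least 10 supporting reads.
#'
#' @slot thresholds Named numeric vector of MAF thresholds (fractions on the
#'   0--1 scale) with names \code{DCM}, \code{HCM}, \code{ARVC}.
#' @slot minDepth Minimum number of reads supporting a variant call.
#' @slot aggregation How per-database frequencies are combined before the
#'   threshold test. \code{"max_across_sources"} compares the largest
#'   frequency observed in any database (a variant is rare only if it is rare
#'   in every database); \code{"any_source_exceeds"} rejects a variant as soon
#'   as any single database exceeds the threshold. The two formulations test
#'   the same condition and are both accepted.
#'
#' @seealso [mafPolicy()], [filterCohort()]
#' @export
setClass("MAFPolicy",
         representation(thresholds = "numeric",
                        minDepth = "integer",
                        aggregation = "character"))

setValidity("MAFPolicy", function(object) {
    msg <- character()
    if (!setequal(names(object@thresholds), PHENOTYPES))
        msg <- c(msg, "thresholds must be named DCM, HCM, ARVC")
    if (any(!is.finite(object@thresholds)) || any(object@thresholds <= 0))
        msg <- c(msg, "thresholds must be strictly positive fractions")
    if (any(object@thresholds > 1))
        msg <- c(msg, "thresholds are fractions on the 0-1 scale")
    if (length(object@minDepth) != 1L || is.na(object@minDepth) ||
        object@minDepth < 1L)
        msg <- c(msg, "minDepth must be a single integer >= 1")
    if (!object@aggregation %in% c("max_across_sources", "any_source_exceeds"))
        msg <- c(msg, "unknown aggregation rule")
    if (length(msg)) msg else TRUE
})

#' Construct a rarity policy
#'
#' @param thresholds Named numeric vector of per-phenotype MAF thresholds
#'   (fractions). Defaults to 0.004 (DCM), 0.002 (HCM), 0.0005 (ARVC).
#' @param minDepth Minimum read support (default 10).
#' @param aggregation Frequency aggregation rule, see [MAFPolicy-class].
#' @return A [MAFPolicy-class] object.
#' @examples
#' mafPolicy()
#' mafPolicy(thresholds = c(DCM = 0.01, HCM = 0.01, ARVC = 0.01))
#' @export
mafPolicy <- function(thresholds = c(DCM = 0.004, HCM = 0.002, ARVC = 5e-04),
                      minDepth = 10L,
                      aggregation = c("max_across_sources",
                                      "any_source_exceeds")) {
    aggregation <- match.arg(aggregation)
    new("MAFPolicy", thresholds = thresholds[PHENOTYPES],
        minDepth = as.integer(minDepth), aggregation = aggregation)
}

## ---------------------------------------------------------------------------
## AssociationCatalog
## ---------------------------------------------------------------------------

#' Catalog of known gene-phenotype associations
#'
#' The prior knowledge encoded in a gene panel: which genes are established
#' disease genes for which cardiomyopathy phenotype (or for channelopathies).
#' Novel gene-phenotype associations are declared against this catalog: an
#' observed (gene, carrier phenotype) pair is novel when the catalog carries
#' no entry tagging that gene with that phenotype. A gene tagged only as a
#' channelopathy gene therefore yields a novel pair in any cardiomyopathy.
#'
#' @slot entries A data.frame with columns \code{gene} and \code{tag}
#'   (one of \code{DCM}, \code{HCM}, \code{ARVC}, \code{channelopathy}).
#' @seealso [associationCatalog()], [novelAssociations()]
#' @export
setClass("AssociationCatalog",
         representation(entries = "data.frame"))

setValidity("AssociationCatalog", function(object) {
    e <- object@entries
    msg <- character()
    if (!all(c("gene", "tag") %in% names(e)))
        msg <- c(msg, "entries needs columns gene, tag")
    else {
        if (any(!e$tag %in% ASSOCIATION_TAGS))
            msg <- c(msg, sprintf("unknown association tag(s): %s",
                                  paste(setdiff(e$tag, ASSOCIATION_TAGS),
                                        collapse = ", ")))
        if (anyDuplicated(e[c("gene", "tag")]))
            msg <- c(msg, "duplicated (gene, tag) entries")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an association catalog
#'
#' @param entries A data.frame with columns \code{gene} and \code{tag}, one
#'   row per known association. A gene may carry several tags.
#' @return An [AssociationCatalog-class] object.
#' @examples
#' associationCatalog(data.frame(gene = c("MYH7", "MYH7", "PKP2"),
#'                               tag = c("HCM", "DCM", "ARVC")))
#' @export
associationCatalog <- function(entries) {
    entries <- as.data.frame(entries, stringsAsFactors = FALSE)
    entries <- unique(entries[c("gene", "tag")])
    rownames(entries) <- NULL
    new("AssociationCatalog", entries = entries)
}

#' @describeIn AssociationCatalog-class genes present in the catalog.
#' @param x An \code{AssociationCatalog}.
#' @export
catalogGenes <- function(x) sort(unique(x@entries$gene))

#' @describeIn AssociationCatalog-class catalog entries as a data.frame.
#' @export
catalogEntries <- function(x) x@entries

#' Test whether gene-phenotype pairs are known to the catalog
#'
#' @param catalog An [AssociationCatalog-class].
#' @param gene,phenotype Character vectors, recycled to a common length.
#' @return Logical vector: \code{TRUE} where the catalog tags \code{gene}
#'   with \code{phenotype}.
#' @export
isKnownAssociation <- function(catalog, gene, phenotype) {
    key <- paste(catalog@entries$gene, catalog@entries$tag)
    paste(gene, phenotype) %in% key
}

## ---------------------------------------------------------------------------
## CardioCohort
## ---------------------------------------------------------------------------

#' A phenotype-labelled cohort of annotated variants
#'
#' Container pairing an annotated-variant table (one row per patient x
#' variant observation) with a patient roster (one row per patient, carrying
#' the phenotype label and sex). On construction the variant table is
#' augmented with derived columns: the parsed protein-change kind and
#' position, the intronic splice offset of the cDNA change, the consequence
#' class and the zygosity call.
#'
#' @slot variants data.frame of annotated variants; see [readVariantTable()]
#'   for the column dictionary.
#' @slot roster data.frame with columns \code{patient_id}, \code{phenotype}
#'   (\code{DCM}/\code{HCM}/\code{ARVC}) and \code{sex}
#'   (\code{M}/\code{F}/\code{unknown}).
#' @seealso [cardioCohort()], [filterCohort()], [classifyCohort()]
#' @export
setClass("CardioCohort",
         representation(variants = "data.frame",
                        roster = "data.frame"))

setValidity("CardioCohort", function(object) {
    msg <- character()
    r <- object@roster
    v <- object@variants
    if (!all(c("patient_id", "phenotype", "sex") %in% names(r)))
        return("roster needs columns patient_id, phenotype, sex")
    if (anyDuplicated(r$patient_id))
        msg <- c(msg, "duplicated patient_id in roster")
    if (any(!r$phenotype %in% PHENOTYPES))
        msg <- c(msg, "roster phenotypes must be DCM, HCM or ARVC")
    if (any(!r$sex %in% SEXES))
        msg <- c(msg, "roster sex must be M, F or unknown")
    if (nrow(v)) {
        missing_cols <- setdiff(VARIANT_COLUMNS, names(v))
        if (length(missing_cols))
            msg <- c(msg, sprintf("variant table lacks column(s): %s",
                                  paste(missing_cols, collapse = ", ")))
        else if (any(!v$patient_id %in% r$patient_id))
            msg <- c(msg, "variant table carries patient_id absent from roster")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a cohort from a variant table and a roster
#'
#' @param variants data.frame of annotated variants (see
#'   [readVariantTable()] for columns). Frequency columns are any columns
#'   named \code{maf_<source>}.
#' @param roster data.frame with \code{patient_id}, \code{phenotype},
#'   \code{sex}; every variant row must reference a rostered patient.
#' @return A [CardioCohort-class] whose variant table carries the derived
#'   columns \code{protein_kind}, \code{protein_pos}, \code{splice_offset},
#'   \code{consequence}, \code{phenotype} and \code{zygosity}.
#' @examples
#' fx <- referenceFixtures()
#' cardioCohort(variants(fx$cohort), roster(fx$cohort))
#' @export
cardioCohort <- function(variants, roster) {
    variants <- as.data.frame(variants, stringsAsFactors = FALSE)
    roster <- as.data.frame(roster, stringsAsFactors = FALSE)
    rownames(variants) <- NULL
    rownames(roster) <- NULL
    if (nrow(variants))
        variants <- annotateVariants(variants, roster)
    new("CardioCohort", variants = variants, roster = roster)
}

#' @describeIn CardioCohort-class the annotated-variant table.
#' @param x A \code{CardioCohort}.
#' @export
variants <- function(x) x@variants

#' @describeIn CardioCohort-class the patient roster.
#' @export
roster <- function(x) x@roster

#' @describeIn CardioCohort-class number of rostered patients.
#' @export
nPatients <- function(x) nrow(x@roster)

#' @describeIn CardioCohort-class number of variant observations.
#' @export
nVariants <- function(x) nrow(x@variants)

#' Subset a cohort to selected variant rows, keeping the full roster
#'
#' @param x A [CardioCohort-class].
#' @param keep Logical or integer index into the variant table.
#' @return A \code{CardioCohort} with the selected variant rows; the roster
#'   is untouched so zero-carrier patients stay in burden denominators.
#' @export
subsetVariants <- function(x, keep) {
    v <- x@variants[keep, , drop = FALSE]
    rownames(v) <- NULL
    new("CardioCohort", variants = v, roster = x@roster)
}

setMethod("show", "CardioCohort", function(object) {
    tab <- table(factor(object@roster$phenotype, PHENOTYPES))
    cat("CardioCohort with", nrow(object@roster), "patients (",
        paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
        ") and", nrow(object@variants), "variant observations\n")
    if (nrow(object@variants)) {
        g <- sort(table(object@variants$gene), decreasing = TRUE)
        cat("  top genes:",
            paste(sprintf("%s(%d)", names(head(g, 5)),
                          as.integer(head(g, 5))), collapse = " "), "\n")
    }
})

setMethod("show", "MAFPolicy", function(object) {
    cat("MAFPolicy: MAF <=",
        paste(sprintf("%s %g", names(object@thresholds), object@thresholds),
              collapse = ", "),
        "| depth >=", object@minDepth,
        "| aggregation:", object@aggregation, "\n")
})

setMethod("show", "AssociationCatalog", function(object) {
    cat("AssociationCatalog:", length(unique(object@entries$gene)),
        "genes,", nrow(object@entries), "gene-phenotype tags\n")
})
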