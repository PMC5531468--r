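## Cohort-level summaries over the rare-variant set and the pathogenicity
## calls: burden, gene tallies, phenotype-overlap partition and novel
## gene-phenotype association detection.

OVERLAP_REGIONS <- c("DCM", "HCM", "ARVC", "DCM+HCM", "DCM+ARVC",
                     "HCM+ARVC", "DCM+HCM+ARVC")

#' Per-patient rare-variant burden
#'
#' Counts rare variants per patient over the full roster (patients without
#' any retained variant contribute zeros to the denominators), the cohort
#' mean and range, per-phenotype means, and -- when classification calls
#' are supplied -- the per-patient count of potentially pathogenic variants.
#'
#' @param rare A [CardioCohort-class] holding the rare-variant set.
#' @param calls Optional calls table from [classifyCohort()].
#' @return A list: \code{per_patient} (data.frame with \code{patient_id},
#'   \code{phenotype}, \code{n_rare}, \code{n_pathogenic}), \code{mean},
#'   \code{range} (length-2 integer), \code{per_phenotype_mean} (named
#'   numeric over DCM/HCM/ARVC).
#' @examples
#' fx <- referenceFixtures()
#' res <- classifyCohort(filterCohort(fx$cohort)$rare)
#' b <- burdenSummary(filterCohort(fx$cohort)$rare, res$calls)
#' sum(b$per_patient$n_pathogenic == 2)
#' @export
burdenSummary <- function(rare, calls = NULL) {
    stopifnot(is(rare, "CardioCohort"))
    r <- roster(rare)
    v <- variants(rare)
    if (nrow(v) && any(!v$patient_id %in% r$patient_id))
        stop("variant table carries patients absent from the roster")
    ids <- r$patient_id
    n_rare <- as.integer(table(factor(v$patient_id, ids)))
    n_path <- rep(0L, length(ids))
    if (!is.null(calls) && nrow(calls)) {
        pos <- calls[calls$potentially_pathogenic, , drop = FALSE]
        if (any(!pos$patient_id %in% ids))
            stop("calls carry patients absent from the roster")
        n_path <- as.integer(table(factor(pos$patient_id, ids)))
    }
    per_patient <- data.frame(patient_id = ids, phenotype = r$phenotype,
                              n_rare = n_rare, n_pathogenic = n_path)
    per_pheno <- vapply(PHENOTYPES, function(ph)
        mean(n_rare[r$phenotype == ph]), numeric(1))
    list(per_patient = per_patient,
         mean = mean(n_rare),
         range = c(min(n_rare), max(n_rare)),
         per_phenotype_mean = per_pheno)
}

#' Per-gene tallies of rare variants
#'
#' @param rare A [CardioCohort-class] holding the rare-variant set.
#' @return A data.frame sorted by descending total (ties by gene symbol)
#'   with one row per gene: \code{gene}, \code{total}, one column per
#'   phenotype and one per consequence class. Totals sum to the size of
#'   the rare set. Empty input gives a zero-row frame.
#' @examples
#' fx <- referenceFixtures()
#' head(geneTally(filterCohort(fx$cohort)$rare))
#' @export
geneTally <- function(rare) {
    stopifnot(is(rare, "CardioCohort"))
    v <- variants(rare)
    if (!nrow(v)) {
        cols <- c("gene", "total", PHENOTYPES, CONSEQUENCE_CLASSES)
        out <- as.data.frame(setNames(rep(list(integer(0)), length(cols)),
                                      cols))
        out$gene <- character(0)
        return(out)
    }
    genes <- sort(unique(v$gene))
    gf <- factor(v$gene, genes)
    out <- data.frame(gene = genes,
                      total = as.integer(table(gf)))
    for (ph in PHENOTYPES)
        out[[ph]] <- as.integer(table(gf[v$phenotype == ph]))
    for (cc in CONSEQUENCE_CLASSES)
        out[[cc]] <- as.integer(table(gf[v$consequence == cc]))
    out <- out[order(-out$total, out$gene), ]
    rownames(out) <- NULL
    out
}

#' Phenotype-overlap partition of genes
#'
#' Partitions the genes carrying at least one rare variant into the seven
#' non-empty phenotype subsets (the regions of a three-set Venn diagram):
#' genes observed in a single phenotype, in each pair, and in all three.
#' The regions are pairwise disjoint and jointly cover every gene in the
#' rare set.
#'
#' @param rare A [CardioCohort-class] holding the rare-variant set.
#' @return A named list of sorted gene vectors, with names \code{"DCM"},
#'   \code{"HCM"}, \code{"ARVC"}, \code{"DCM+HCM"}, \code{"DCM+ARVC"},
#'   \code{"HCM+ARVC"}, \code{"DCM+HCM+ARVC"}.
#' @examples
#' fx <- referenceFixtures()
#' lengths(phenotypeOverlap(filterCohort(fx$cohort)$rare))
#' @export
phenotypeOverlap <- function(rare) {
    stopifnot(is(rare, "CardioCohort"))
    v <- variants(rare)
    regions <- setNames(vector("list", length(OVERLAP_REGIONS)),
                        OVERLAP_REGIONS)
    regions[] <- list(character(0))
    if (!nrow(v))
        return(regions)
    by_gene <- split(v$phenotype, v$gene)
    for (g in names(by_gene)) {
        phs <- PHENOTYPES[PHENOTYPES %in% unique(by_gene[[g]])]
        lab <- paste(phs, collapse = "+")
        regions[[lab]] <- c(regions[[lab]], g)
    }
    lapply(regions, sort)
}

#' Detect novel gene-phenotype associations
#'
#' A (gene, carrier phenotype) pair is novel when the association catalog
#' carries no entry tagging that gene with that cardiomyopathy phenotype;
#' genes tagged only as channelopathy genes are therefore novel in any
#' cardiomyopathy. Novelty is computed over all rare variants and reported
#' separately restricted to potentially pathogenic calls.
#'
#' @param rare A [CardioCohort-class] holding the rare-variant set.
#' @param calls Optional calls table from [classifyCohort()]; required for
#'   the pathogenic-restricted view.
#' @param catalog An [AssociationCatalog-class].
#' @param offPanelNovel Whether genes entirely absent from the catalog
#'   count as novel pairs (default \code{TRUE}, with a warning when any
#'   such gene is seen).
#' @return A list: \code{novel_pairs} (data.frame \code{gene},
#'   \code{phenotype}, \code{n_variants}, \code{n_pathogenic}),
#'   \code{pathogenic_pairs} (the subset with \code{n_pathogenic > 0}),
#'   \code{per_patient_novel} (named logical: carries at least one variant
#'   in a novel pair) and \code{per_gene_novel_counts}.
#' @examples
#' fx <- referenceFixtures()
#' res <- classifyCohort(filterCohort(fx$cohort)$rare)
#' novelAssociations(filterCohort(fx$cohort)$rare, res$calls, fx$catalog)$pathogenic_pairs
#' @export
novelAssociations <- function(rare, calls = NULL, catalog,
                              offPanelNovel = TRUE) {
    stopifnot(is(rare, "CardioCohort"), is(catalog, "AssociationCatalog"))
    v <- variants(rare)
    r <- roster(rare)
    empty_pairs <- data.frame(gene = character(), phenotype = character(),
                              n_variants = integer(),
                              n_pathogenic = integer())
    if (!nrow(v))
        return(list(novel_pairs = empty_pairs,
                    pathogenic_pairs = empty_pairs,
                    per_patient_novel = setNames(rep(FALSE, nrow(r)),
                                                 r$patient_id),
                    per_gene_novel_counts = integer(0)))
    off_panel <- setdiff(unique(v$gene), catalogGenes(catalog))
    if (length(off_panel))
        warning("gene(s) absent from the panel catalog: ",
                paste(off_panel, collapse = ", "))
    novel_row <- !isKnownAssociation(catalog, v$gene, v$phenotype)
    if (!offPanelNovel)
        novel_row <- novel_row & !(v$gene %in% off_panel)

    path_row <- if (!is.null(calls)) {
        key <- paste(v$patient_id, v$gene, v$chrom, v$pos, v$alt)
        pos <- calls[calls$potentially_pathogenic, , drop = FALSE]
        key %in% paste(pos$patient_id, pos$gene, pos$chrom, pos$pos, pos$alt)
    } else rep(FALSE, nrow(v))

    nv <- v[novel_row, , drop = FALSE]
    if (nrow(nv)) {
        pair <- paste(nv$gene, nv$phenotype, sep = "\t")
        upair <- sort(unique(pair))
        parts <- strsplit(upair, "\t", fixed = TRUE)
        novel_pairs <- data.frame(
            gene = vapply(parts, `[`, character(1), 1L),
            phenotype = vapply(parts, `[`, character(1), 2L),
            n_variants = as.integer(table(factor(pair, upair))),
            n_pathogenic = as.integer(table(factor(
                pair[path_row[novel_row]], upair))))
    } else novel_pairs <- empty_pairs

    per_patient_novel <- setNames(
        r$patient_id %in% nv$patient_id, r$patient_id)
    per_gene <- if (nrow(nv)) {
        tab <- table(nv$gene)
        stats::setNames(as.integer(tab), names(tab))
    } else integer(0)
    list(novel_pairs = novel_pairs,
         pathogenic_pairs = novel_pairs[novel_pairs$n_pathogenic > 0, ,
                                        drop = FALSE],
         per_patient_novel = per_patient_novel,
         per_gene_novel_counts = per_gene)
}

#' Assemble the report bundle
#'
#' Collects filtering, classification, burden, tally, overlap and novelty
#' results into one machine-readable structure plus a human-readable table
#' of the potentially pathogenic calls (gene, position, transcript,
#' nucleotide and protein change, dbSNP id, MAF, phenotype and the
#' supporting-evidence string).
#'
#' @param rare A [CardioCohort-class] (rare set).
#' @param classification Result of [classifyCohort()].
#' @param burden Result of [burdenSummary()].
#' @param tally Result of [geneTally()].
#' @param overlap Result of [phenotypeOverlap()].
#' @param novelty Result of [novelAssociations()] (optional).
#' @return A list of class \code{triageReport} with elements
#'   \code{summary}, \code{pathogenic_table}, \code{per_patient},
#'   \code{gene_tally}, \code{overlap} and \code{novelty}. Means are
#'   rounded to one decimal in \code{summary}.
#' @export
renderReports <- function(rare, classification, burden, tally, overlap,
                          novelty = NULL) {
    calls <- classification$calls
    pos <- if (length(calls) && nrow(calls))
        calls[calls$potentially_pathogenic, , drop = FALSE]
    else calls
    maf_cols <- grep("^maf_", names(pos), value = TRUE)
    pathogenic_table <- if (nrow(pos)) data.frame(
        gene = pos$gene,
        position = paste0(pos$chrom, ":", pos$pos),
        transcript = pos$transcript,
        nucleotide = pos$cdna,
        protein = ifelse(is.na(pos$protein), "-", pos$protein),
        dbsnp = ifelse(is.na(pos$dbsnp), "-", pos$dbsnp),
        maf = if (length(maf_cols)) {
            agg <- aggregateMAF(pos)
            ifelse(agg > 0, formatC(agg, format = "g"), "-")
        } else "-",
        phenotype = pos$phenotype,
        evidence = pos$evidence_codes,
        branch = pos$branch) else NULL
    summary <- list(
        n_patients = nrow(burden$per_patient),
        n_rare_variants = nVariants(rare),
        n_potentially_pathogenic = classification$summary$n_positive,
        positive_by_type = as.list(classification$summary$positive_by_type),
        by_branch = as.list(classification$summary$by_branch),
        burden_mean = round(burden$mean, 1),
        burden_range = burden$range,
        burden_mean_by_phenotype = as.list(round(burden$per_phenotype_mean, 1)),
        overlap_region_sizes = lapply(overlap, length))
    if (!is.null(novelty)) {
        summary$n_novel_pairs <- nrow(novelty$novel_pairs)
        summary$n_patients_with_novel_pair <- sum(novelty$per_patient_novel)
    }
    structure(list(summary = summary,
                   pathogenic_table = pathogenic_table,
                   per_patient = burden$per_patient,
                   gene_tally = tally,
                   overlap = overlap,
                   novelty = novelty),
              class = "triageReport")
}

#' @export
print.triageReport <- function(x, ...) {
    s <- x$summary
    cat("Rare-variant triage report\n")
    cat(sprintf("  %d patients, %d rare variants, %d potentially pathogenic\n",
                s$n_patients, s$n_rare_variants,
                s$n_potentially_pathogenic))
    cat(sprintf("  burden: mean %.1f per patient (range %d-%d)\n",
                s$burden_mean, s$burden_range[1], s$burden_range[2]))
    invisible(x)
}
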