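## The rule engine assigning the "potentially pathogenic" label to rare
## variants: predictor consensus for missense, a MutationTaster-only rule
## for radical variants, TTN special rules, ClinVar/HGMD/literature
## overrides and ClinVar demotions. Every call records the single rule
## branch that fired and the full evidence-code set.

#' Four-predictor consensus for missense variants
#'
#' \code{TRUE} only when all four in-silico predictors simultaneously place
#' the variant in their damaging category: SIFT \emph{damaging}, PROVEAN
#' \emph{deleterious}, PolyPhen-2 \emph{possibly} or \emph{probably
#' damaging}, and MutationTaster \emph{disease causing}. A missing
#' (\code{absent} or \code{NA}) verdict breaks the consensus.
#'
#' @param sift,provean,polyphen2,mutation_taster Character vectors of
#'   predictor verdicts, recycled to a common length.
#' @return Logical vector.
#' @examples
#' predictorConsensus("damaging", "deleterious", "probably_damaging",
#'                    "disease_causing")                        # TRUE
#' predictorConsensus("tolerated", "deleterious", "probably_damaging",
#'                    "disease_causing")                        # FALSE
#' @export
predictorConsensus <- function(sift, provean, polyphen2, mutation_taster) {
    n <- max(length(sift), length(provean), length(polyphen2),
             length(mutation_taster))
    eq <- function(x, lv) rep_len(as.character(x), n) %in% lv
    eq(sift, "damaging") &
        eq(provean, "deleterious") &
        eq(polyphen2, c("probably_damaging", "possibly_damaging")) &
        eq(mutation_taster, "disease_causing")
}

#' Evidence codes for a variant table
#'
#' Computes the per-variant supporting-evidence codes, identically for
#' positive and negative calls:
#' \describe{
#'   \item{GS}{Grantham score > 100 (missense only)}
#'   \item{SI}{SIFT damaging}
#'   \item{PR}{PROVEAN deleterious}
#'   \item{PP2}{PolyPhen-2 probably or possibly damaging}
#'   \item{MT}{MutationTaster disease causing}
#'   \item{PC}{PhastCons score equal to 1}
#'   \item{PP}{PhyloP score > 1}
#'   \item{CV}{ClinVar pathogenic / likely pathogenic for the same cardiac
#'     phenotype}
#'   \item{HG}{HGMD entry for the same cardiac phenotype}
#'   \item{REF}{published data supporting pathogenicity}
#' }
#'
#' @param variants Annotated-variant data.frame (derived columns present).
#' @return A logical matrix with one row per variant and one column per
#'   code, in the canonical display order.
#' @seealso [evidenceCodeString()]
#' @export
evidenceCodes <- function(variants) {
    v <- variants
    num <- function(x) suppressWarnings(as.numeric(x))
    m <- cbind(
        GS = v$consequence == "missense" & !is.na(num(v$grantham)) &
            num(v$grantham) > 100,
        SI = v$sift %in% "damaging",
        PR = v$provean %in% "deleterious",
        PP2 = v$polyphen2 %in% c("probably_damaging", "possibly_damaging"),
        MT = v$mutation_taster %in% "disease_causing",
        PC = !is.na(num(v$phastcons)) & num(v$phastcons) == 1,
        PP = !is.na(num(v$phylop)) & num(v$phylop) > 1,
        CV = v$clinvar_class %in% c("pathogenic", "likely_pathogenic") &
            v$clinvar_same_pheno %in% TRUE,
        HG = v$hgmd_same_pheno %in% TRUE,
        REF = v$published_support %in% TRUE)
    m[, EVIDENCE_CODE_ORDER, drop = FALSE]
}

#' Render evidence codes as a display string
#'
#' @param codes Logical matrix from [evidenceCodes()].
#' @return Character vector of comma-joined codes (e.g.
#'   \code{"SI, PR, PP2, MT, PC, PP"}); empty string when no code applies.
#' @export
evidenceCodeString <- function(codes) {
    apply(codes, 1L, function(x)
        paste(EVIDENCE_CODE_ORDER[x], collapse = ", "))
}

## The rule tree for one variant, given its (already computed) evidence
## codes. Returns branch + flags; see classifyVariant() for the contract.
classify_one <- function(consequence, gene, protein_pos, transcript,
                         mutation_taster, clinvar_class, codes, ttn_map) {
    override <- codes["CV"] || codes["HG"] || codes["REF"]
    rescue <- codes["HG"] || codes["REF"]
    demoting <- clinvar_class %in% CLINVAR_DEMOTING
    precedence_decisive <- FALSE
    trace <- character()

    ## (1) ClinVar demotion, unless HGMD/literature independently asserts
    ##     pathogenicity (ClinVar pathogenic cannot co-occur with a demoting
    ##     class, so CV itself can never rescue).
    if (demoting) {
        if (!rescue) {
            return(list(branch = "demoted_clinvar", pathogenic = FALSE,
                        trace = sprintf("ClinVar class '%s' demotes the variant",
                                        clinvar_class),
                        precedence_decisive = FALSE))
        }
        precedence_decisive <- TRUE
        trace <- c(trace, sprintf(
            "ClinVar class '%s' would demote but HGMD/published support overrides (precedence rule applied)",
            clinvar_class))
    }

    is_ttn <- identical(gene, "TTN")

    ## (2) TTN missense: never potentially pathogenic, independently of the
    ##     predictors' results.
    if (is_ttn && consequence == "missense") {
        return(list(branch = "ttn_missense_exempt", pathogenic = FALSE,
                    trace = c(trace, "TTN missense exemption"),
                    precedence_decisive = precedence_decisive))
    }

    ## (3) TTN truncating: A-band-in-all-isoforms rule.
    if (is_ttn && consequence %in% TRUNCATING_CLASSES) {
        if (is.null(ttn_map))
            stop("TTN truncating variant but no TTN region map supplied")
        if (is.na(protein_pos))
            stop("TTN truncating variant without a residue position; ",
                 "the band rule cannot be evaluated")
        res <- ttnTruncatingCall(protein_pos, transcript, ttn_map)
        branch <- if (res$pathogenic) "ttn_truncating_a_band" else
            "not_pathogenic"
        return(list(branch = branch, pathogenic = res$pathogenic,
                    trace = c(trace, res$rationale),
                    precedence_decisive = precedence_decisive))
    }

    ## (4) missense: four-predictor consensus ...
    if (consequence == "missense") {
        if (codes["SI"] && codes["PR"] && codes["PP2"] && codes["MT"]) {
            return(list(branch = "missense_consensus", pathogenic = TRUE,
                        trace = c(trace, "SIFT+PROVEAN+PolyPhen-2+MutationTaster consensus"),
                        precedence_decisive = precedence_decisive))
        }
        trace <- c(trace, "predictor consensus not reached")
    } else if (consequence %in% RADICAL_CLASSES) {
        ## (5) radical: MutationTaster alone decides ...
        if (mutation_taster %in% "disease_causing") {
            return(list(branch = "radical_mt", pathogenic = TRUE,
                        trace = c(trace, "radical variant disease-causing by MutationTaster"),
                        precedence_decisive = precedence_decisive))
        }
        trace <- c(trace, "MutationTaster not disease-causing for radical variant")
    } else {
        return(list(branch = "not_pathogenic", pathogenic = FALSE,
                    trace = c(trace, "consequence class outside the rule set"),
                    precedence_decisive = precedence_decisive))
    }

    ## (6) ... a negative predictor outcome flips on database/literature
    ##     evidence (ClinVar pathogenic same phenotype, HGMD, published).
    if (override) {
        return(list(branch = "database_override", pathogenic = TRUE,
                    trace = c(trace, "ClinVar/HGMD/published evidence override"),
                    precedence_decisive = precedence_decisive))
    }
    list(branch = "not_pathogenic", pathogenic = FALSE,
         trace = trace, precedence_decisive = precedence_decisive)
}

#' Classify rare variants as potentially pathogenic
#'
#' Runs the decision tree on each row of a rare-variant table. The rules,
#' in precedence order:
#' \enumerate{
#'   \item A ClinVar class of VUS, likely benign or benign demotes the
#'     variant (negative, branch \code{demoted_clinvar}) unless HGMD or
#'     published data independently assert pathogenicity.
#'   \item TTN missense variants are never potentially pathogenic,
#'     independently of the predictors (branch \code{ttn_missense_exempt}).
#'   \item TTN truncating variants follow the A-band/all-isoforms rule of
#'     [ttnTruncatingCall()] (positive branch \code{ttn_truncating_a_band}).
#'   \item Other missense variants are positive on full predictor consensus
#'     (branch \code{missense_consensus}).
#'   \item Radical variants (nonsense, stop-loss, canonical splice,
#'     frameshift and in-frame indels) are positive when MutationTaster
#'     calls them disease causing (branch \code{radical_mt}).
#'   \item A negative outcome of rules 4--5 flips to positive when ClinVar
#'     (pathogenic, same phenotype), HGMD (same phenotype) or published
#'     data support pathogenicity (branch \code{database_override}).
#' }
#' Exactly one branch fires per variant.
#'
#' @param variants Annotated-variant data.frame with derived columns (from
#'   a [CardioCohort-class] that passed [filterCohort()]).
#' @param ttn_map A [TTNRegionMap-class]; required if any TTN truncating
#'   variant is present, defaults to the bundled map.
#' @return A data.frame (the input plus call columns):
#'   \code{potentially_pathogenic}, \code{branch}, \code{evidence_codes}
#'   (display string), \code{rule_trace} and \code{precedence_decisive}
#'   (whether the demotion-vs-override precedence rule decided the call).
#' @examples
#' fx <- referenceFixtures()
#' calls <- classifyVariant(variants(fx$cohort))
#' table(calls$branch)
#' @export
classifyVariant <- function(variants, ttn_map = ttnDefaultRegionMap()) {
    codes <- evidenceCodes(variants)
    n <- nrow(variants)
    branch <- character(n)
    pathogenic <- logical(n)
    trace <- character(n)
    decisive <- logical(n)
    for (i in seq_len(n)) {
        res <- classify_one(variants$consequence[i], variants$gene[i],
                            variants$protein_pos[i], variants$transcript[i],
                            variants$mutation_taster[i],
                            variants$clinvar_class[i],
                            codes[i, ], ttn_map)
        branch[i] <- res$branch
        pathogenic[i] <- res$pathogenic
        trace[i] <- paste(res$trace, collapse = "; ")
        decisive[i] <- res$precedence_decisive
    }
    out <- variants
    out$potentially_pathogenic <- pathogenic
    out$branch <- branch
    out$evidence_codes <- evidenceCodeString(codes)
    out$rule_trace <- trace
    out$precedence_decisive <- decisive
    out
}

#' Classify a whole rare-variant cohort
#'
#' @param rare A [CardioCohort-class] holding the rare-variant set (the
#'   \code{rare} element of [filterCohort()]).
#' @param ttn_map A [TTNRegionMap-class] (default: bundled map).
#' @return A list with \code{calls} (the [classifyVariant()] table) and
#'   \code{summary}: total and positive counts, positives by consequence
#'   class and calls by rule branch.
#' @examples
#' fx <- referenceFixtures()
#' res <- classifyCohort(filterCohort(fx$cohort)$rare)
#' res$summary$n_positive
#' @export
classifyCohort <- function(rare, ttn_map = ttnDefaultRegionMap()) {
    stopifnot(is(rare, "CardioCohort"))
    v <- variants(rare)
    if (!nrow(v)) {
        return(list(calls = v,
                    summary = list(n = 0L, n_positive = 0L,
                                   positive_by_type = integer(0),
                                   by_branch = integer(0))))
    }
    calls <- classifyVariant(v, ttn_map)
    pos <- calls[calls$potentially_pathogenic, , drop = FALSE]
    list(calls = calls,
         summary = list(
             n = nrow(calls),
             n_positive = nrow(pos),
             positive_by_type = table(factor(pos$consequence,
                                             CONSEQUENCE_CLASSES)),
             by_branch = table(factor(calls$branch, RULE_BRANCHES))))
}
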