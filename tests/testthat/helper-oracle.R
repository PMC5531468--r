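# Shared helpers: a variant-row builder feeding the engine directly, an
# independent nested-conditional re-statement of the classification rules
# (the truth-table oracle), and a linear-scan band-lookup oracle.

engine_row <- function(consequence, gene = "MYH7", protein_pos = 100L,
                       transcript = "NM_000257",
                       sift = "absent", provean = "absent",
                       polyphen2 = "absent", mutation_taster = "absent",
                       phylop = NA_real_, phastcons = NA_real_,
                       grantham = NA_real_,
                       clinvar_class = "absent", clinvar_same_pheno = FALSE,
                       hgmd_same_pheno = FALSE, published_support = FALSE,
                       patient_id = "P1", phenotype = "DCM",
                       chrom = "chr1", pos = 1000L) {
    data.frame(patient_id = patient_id, gene = gene, transcript = transcript,
               chrom = chrom, pos = pos, ref = "A", alt = "G",
               cdna = "c.100A>G", protein = NA_character_,
               depth = 50L, dbsnp = NA_character_, maf_gnomad = NA_real_,
               sift = sift, provean = provean, polyphen2 = polyphen2,
               mutation_taster = mutation_taster,
               phylop = phylop, phastcons = phastcons, grantham = grantham,
               clinvar_class = clinvar_class,
               clinvar_same_pheno = clinvar_same_pheno,
               hgmd_same_pheno = hgmd_same_pheno,
               published_support = published_support,
               genotype = "0/1", protein_kind = NA_character_,
               protein_pos = protein_pos, splice_offset = NA_integer_,
               consequence = consequence, phenotype = phenotype,
               zygosity = "heterozygous", stringsAsFactors = FALSE)
}

# Independent restatement of the decision tree over boolean annotation
# atoms. Kept deliberately flat and literal so it cannot share a defect
# with the vectorised implementation.
oracle_classify <- function(consequence, gene, sift_d, pr_d, pp2_d, mt_d,
                            clinvar_state, hgmd, ref, ttn_rule_pass = FALSE) {
    radical <- consequence %in% c("nonsense", "stoploss", "canonical_splice",
                                  "frameshift_indel", "inframe_indel")
    cv <- clinvar_state == "path_same"
    demote <- clinvar_state == "vus"
    if (demote && !hgmd && !ref)
        return(list(pathogenic = FALSE, branch = "demoted_clinvar"))
    if (gene == "TTN" && consequence == "missense")
        return(list(pathogenic = FALSE, branch = "ttn_missense_exempt"))
    if (gene == "TTN" &&
        consequence %in% c("nonsense", "stoploss", "canonical_splice",
                           "frameshift_indel")) {
        if (ttn_rule_pass)
            return(list(pathogenic = TRUE, branch = "ttn_truncating_a_band"))
        return(list(pathogenic = FALSE, branch = "not_pathogenic"))
    }
    if (consequence == "missense" && sift_d && pr_d && pp2_d && mt_d)
        return(list(pathogenic = TRUE, branch = "missense_consensus"))
    if (radical && mt_d)
        return(list(pathogenic = TRUE, branch = "radical_mt"))
    if (consequence == "other")
        return(list(pathogenic = FALSE, branch = "not_pathogenic"))
    if (cv || hgmd || ref)
        return(list(pathogenic = TRUE, branch = "database_override"))
    list(pathogenic = FALSE, branch = "not_pathogenic")
}

# expand one atom combination into an engine row
atoms_to_row <- function(consequence, gene, sift_d, pr_d, pp2_d, mt_d,
                         clinvar_state, hgmd, ref, protein_pos = 100L) {
    engine_row(consequence, gene = gene,
               transcript = if (gene == "TTN") "NM_003319" else "NM_000257",
               protein_pos = protein_pos,
               sift = if (sift_d) "damaging" else "tolerated",
               provean = if (pr_d) "deleterious" else "neutral",
               polyphen2 = if (pp2_d) "probably_damaging" else "benign",
               mutation_taster = if (mt_d) "disease_causing" else
                   "polymorphism",
               clinvar_class = switch(clinvar_state,
                                      absent = "absent",
                                      path_same = "pathogenic",
                                      path_other = "pathogenic",
                                      vus = "vus"),
               clinvar_same_pheno = clinvar_state == "path_same",
               hgmd_same_pheno = hgmd, published_support = ref)
}

# brute-force band lookup by scanning every interval row
linear_scan_band <- function(position, transcript, map) {
    regions <- methods::slot(map, "regions")
    hit <- NA_character_
    for (j in seq_len(nrow(regions))) {
        if (regions$transcript[j] == transcript &&
            position >= regions$start[j] && position <= regions$end[j])
            hit <- regions$band[j]
    }
    hit
}

# tiny toy band map over a 100-residue protein
toy_band_map <- function() {
    ttnRegionMap(
        regions = data.frame(
            transcript = "TOY",
            band = c("Z", "I", "A", "M"),
            start = c(1L, 11L, 41L, 91L),
            end = c(10L, 40L, 90L, 100L)),
        shared = data.frame(transcript = "TOY", start = 41L, end = 100L),
        isoformSet = "TOY")
}
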