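## Parsing of short-form protein-change and cDNA-change notation into
## consequence classes, plus zygosity assignment.

#' Parse short-form protein-change tokens
#'
#' Parses HGVS-like one-letter tokens as printed in clinical variant tables
#' (\code{"S236F"}, \code{"Q517X"}, \code{"V508fs"}, \code{"V321GfsX11"},
#' \code{"I467del"}, \code{"L140_A146dup"}) into a change kind and the first
#' affected residue. A substitution must replace the residue with a
#' different one: identity tokens such as \code{"A100A"} (synonymous) parse
#' to kind \code{unknown}. A stop written as \code{X}, \code{*} or
#' \code{Ter} in the alternate position is a nonsense change; in the
#' reference position, a stop-loss. Frameshifts carry the \code{fs} suffix
#' with an optional \code{X<n>} extension giving the distance to the new
#' stop. Unparseable tokens yield kind \code{unknown}; parsing never fails.
#'
#' @param raw Character vector of tokens; \code{NA} or \code{""} allowed.
#' @return A data.frame with one row per token and columns \code{raw},
#'   \code{kind} (\code{missense}, \code{nonsense}, \code{stoploss},
#'   \code{frameshift}, \code{inframe_del}, \code{inframe_ins},
#'   \code{inframe_dup}, \code{unknown}), \code{position} (first affected
#'   residue, \code{NA} when unknown), \code{ref_aa}, \code{alt_aa},
#'   \code{end_aa}, \code{end_position} (range operations only) and
#'   \code{fs_ext}.
#' @examples
#' parseProteinChange(c("S236F", "Q517X", "L140_A146dup", "A100A"))
#' @seealso [formatProteinChange()], [classifyConsequence()]
#' @export
parseProteinChange <- function(raw) {
    raw <- as.character(raw)
    n <- length(raw)
    out <- data.frame(raw = raw,
                      kind = rep("unknown", n),
                      position = rep(NA_integer_, n),
                      ref_aa = rep(NA_character_, n),
                      alt_aa = rep(NA_character_, n),
                      end_aa = rep(NA_character_, n),
                      end_position = rep(NA_integer_, n),
                      fs_ext = rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
    tok <- ifelse(is.na(raw), "", trimws(raw))
    tok <- sub("^p\\.", "", tok)

    stop_sym <- function(x) x %in% c("X", "*", "Ter")

    ## frameshift: R2490fs, V508fs, V321GfsX11, V321Gfs*11, V321GfsTer11
    re_fs <- "^([A-Z])(\\d+)([A-Z]?)fs(?:(?:X|\\*|Ter)(\\d+))?$"
    m <- regexec(re_fs, tok)
    for (i in seq_len(n)) {
        g <- regmatches(tok[i], m[i])[[1]]
        if (length(g)) {
            out$kind[i] <- "frameshift"
            out$ref_aa[i] <- g[2]
            out$position[i] <- as.integer(g[3])
            out$alt_aa[i] <- if (nzchar(g[4])) g[4] else NA_character_
            out$fs_ext[i] <- if (nzchar(g[5])) as.integer(g[5]) else NA_integer_
        }
    }

    ## range in-frame ops: L140_A146dup, K100_L102del, A100_V101insGLY
    re_range <- "^([A-Z])(\\d+)_([A-Z])(\\d+)(dup|del|delins[A-Z]*|ins[A-Z]+)$"
    m <- regexec(re_range, tok)
    for (i in which(out$kind == "unknown")) {
        g <- regmatches(tok[i], m[i])[[1]]
        if (length(g)) {
            op <- g[6]
            out$kind[i] <- switch(substr(op, 1, 3),
                                  dup = "inframe_dup",
                                  del = if (startsWith(op, "delins"))
                                            "inframe_ins" else "inframe_del",
                                  ins = "inframe_ins")
            out$ref_aa[i] <- g[2]
            out$position[i] <- as.integer(g[3])
            out$end_aa[i] <- g[4]
            out$end_position[i] <- as.integer(g[5])
            out$alt_aa[i] <- op
        }
    }

    ## single-residue in-frame ops: I467del, S100dup
    re_one <- "^([A-Z])(\\d+)(dup|del)$"
    m <- regexec(re_one, tok)
    for (i in which(out$kind == "unknown")) {
        g <- regmatches(tok[i], m[i])[[1]]
        if (length(g)) {
            out$kind[i] <- if (g[4] == "dup") "inframe_dup" else "inframe_del"
            out$ref_aa[i] <- g[2]
            out$position[i] <- as.integer(g[3])
            out$alt_aa[i] <- g[4]
        }
    }

    ## substitutions: S236F, Q517X, X101Q (stop-loss), A100A (-> unknown)
    re_sub <- "^([A-Z]|\\*)(\\d+)([A-Z]|\\*|Ter)$"
    m <- regexec(re_sub, tok)
    for (i in which(out$kind == "unknown")) {
        g <- regmatches(tok[i], m[i])[[1]]
        if (!length(g)) next
        ref <- g[2]; alt <- g[4]
        kind <- if (ref == alt) "unknown"
                else if (stop_sym(alt)) "nonsense"
                else if (stop_sym(ref)) "stoploss"
                else "missense"
        if (kind == "unknown") next
        out$kind[i] <- kind
        out$ref_aa[i] <- ref
        out$alt_aa[i] <- alt
        out$position[i] <- as.integer(g[3])
    }
    out
}

#' Format a parsed protein change back to its canonical token
#'
#' Inverse of [parseProteinChange()] for all parseable kinds; rows with kind
#' \code{unknown} format back to their raw string.
#'
#' @param pc A data.frame as returned by [parseProteinChange()].
#' @return Character vector of tokens.
#' @export
formatProteinChange <- function(pc) {
    vapply(seq_len(nrow(pc)), function(i) {
        k <- pc$kind[i]
        if (k %in% c("missense", "nonsense", "stoploss"))
            paste0(pc$ref_aa[i], pc$position[i], pc$alt_aa[i])
        else if (k == "frameshift")
            paste0(pc$ref_aa[i], pc$position[i],
                   ifelse(is.na(pc$alt_aa[i]), "", pc$alt_aa[i]), "fs",
                   ifelse(is.na(pc$fs_ext[i]), "",
                          paste0("X", pc$fs_ext[i])))
        else if (k %in% c("inframe_del", "inframe_dup", "inframe_ins")) {
            if (!is.na(pc$end_position[i]))
                paste0(pc$ref_aa[i], pc$position[i], "_",
                       pc$end_aa[i], pc$end_position[i], pc$alt_aa[i])
            else
                paste0(pc$ref_aa[i], pc$position[i], pc$alt_aa[i])
        } else pc$raw[i]
    }, character(1))
}

#' Intronic offset of a cDNA change
#'
#' Extracts the signed offset from the nearest exon boundary out of cDNA
#' tokens such as \code{"c.506-2A>C"} (-2) or \code{"c.821+1G>A"} (+1).
#' Offsets of magnitude 1 or 2 mark canonical donor/acceptor splice-site
#' changes. Exonic or unparseable tokens yield \code{NA}.
#'
#' @param cdna Character vector of cDNA tokens.
#' @return Integer vector of signed offsets (\code{NA} when not intronic).
#' @examples
#' spliceOffset(c("c.506-2A>C", "c.821+1G>A", "c.707C>T"))
#' @export
spliceOffset <- function(cdna) {
    cdna <- as.character(cdna)
    m <- regmatches(cdna, regexec("^c\\.[-*]?\\d+([+-])(\\d+)", cdna))
    vapply(m, function(g) {
        if (!length(g)) return(NA_integer_)
        off <- as.integer(g[3])
        if (g[2] == "-") -off else off
    }, integer(1))
}

#' Map parsed changes to a consequence class
#'
#' The protein-level kind takes precedence when one parsed: substitutions,
#' frameshifts and in-frame indels map directly to their class. Without a
#' usable protein change, a cDNA change with an intronic offset of magnitude
#' 1 or 2 is a canonical splice-site change; everything else (synonymous,
#' deeper intronic, UTR) is \code{other}. The mapping is total: every input
#' receives exactly one class.
#'
#' @param protein_kind Character vector of kinds from [parseProteinChange()].
#' @param splice_offset Integer vector from [spliceOffset()].
#' @return Character vector of consequence classes (\code{missense},
#'   \code{nonsense}, \code{stoploss}, \code{canonical_splice},
#'   \code{frameshift_indel}, \code{inframe_indel}, \code{other}).
#' @examples
#' classifyConsequence("frameshift", NA)          # frameshift_indel
#' classifyConsequence("unknown", -2L)            # canonical_splice
#' classifyConsequence("unknown", -15L)           # other
#' @export
classifyConsequence <- function(protein_kind, splice_offset) {
    n <- max(length(protein_kind), length(splice_offset))
    protein_kind <- rep_len(as.character(protein_kind), n)
    splice_offset <- rep_len(as.integer(splice_offset), n)
    out <- rep("other", n)
    out[protein_kind %in% "missense"] <- "missense"
    out[protein_kind %in% "nonsense"] <- "nonsense"
    out[protein_kind %in% "stoploss"] <- "stoploss"
    out[protein_kind %in% "frameshift"] <- "frameshift_indel"
    out[protein_kind %in% c("inframe_del", "inframe_ins", "inframe_dup")] <-
        "inframe_indel"
    fallthrough <- out == "other"
    out[fallthrough & !is.na(splice_offset) & abs(splice_offset) <= 2] <-
        "canonical_splice"
    out
}

#' Zygosity of a variant call
#'
#' X-chromosome variants in a male carrier are hemizygous; in a carrier of
#' unknown sex the zygosity cannot be typed and is reported \code{unknown}.
#' Elsewhere the genotype string decides: both alleles alternate is
#' homozygous, a single alternate allele heterozygous.
#'
#' @param chrom Chromosome names (\code{"chrX"} and \code{"X"} equivalent).
#' @param sex Carrier sex, \code{M}, \code{F} or \code{unknown}.
#' @param genotype Genotype strings such as \code{"0/1"}, \code{"1/1"} or
#'   \code{"1"}; \code{NA} yields \code{unknown} zygosity off the X.
#' @return Character vector: \code{heterozygous}, \code{homozygous},
#'   \code{hemizygous} or \code{unknown}.
#' @examples
#' assignZygosity("chrX", "M", "1")      # hemizygous
#' assignZygosity("chr1", "F", "0/1")    # heterozygous
#' assignZygosity("chrX", "unknown", "0/1")
#' @export
assignZygosity <- function(chrom, sex, genotype) {
    n <- max(length(chrom), length(sex), length(genotype))
    chrom <- rep_len(as.character(chrom), n)
    sex <- rep_len(as.character(sex), n)
    genotype <- rep_len(as.character(genotype), n)
    chromn <- toupper(sub("^chr", "", chrom, ignore.case = TRUE))
    gt_zyg <- vapply(genotype, function(g) {
        if (is.na(g) || !nzchar(g)) return("unknown")
        alleles <- strsplit(g, "[/|]")[[1]]
        n_alt <- sum(alleles != "0" & alleles != ".")
        if (length(alleles) == 1L) "heterozygous"
        else if (n_alt >= 2L) "homozygous"
        else "heterozygous"
    }, character(1), USE.NAMES = FALSE)
    out <- gt_zyg
    on_x <- chromn == "X"
    out[on_x & sex == "M"] <- "hemizygous"
    out[on_x & sex == "unknown"] <- "unknown"
    out
}

## Derive protein_kind/protein_pos/splice_offset/consequence/phenotype/
## zygosity columns on a raw variant table; used by cardioCohort().
annotateVariants <- function(variants, roster) {
    pc <- parseProteinChange(variants$protein)
    variants$protein_kind <- pc$kind
    variants$protein_pos <- pc$position
    variants$splice_offset <- spliceOffset(variants$cdna)
    variants$consequence <- classifyConsequence(variants$protein_kind,
                                                variants$splice_offset)
    idx <- match(variants$patient_id, roster$patient_id)
    variants$phenotype <- roster$phenotype[idx]
    variants$zygosity <- assignZygosity(variants$chrom, roster$sex[idx],
                                        variants$genotype)
    variants
}
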