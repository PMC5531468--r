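## Readers and writers for every file the pipeline touches. One TSV
## dialect throughout: tab-separated, UTF-8, "." for absent values,
## "#"-prefixed header metadata carrying the schema version. Outputs are
## byte-stable for fixed inputs (sorted keys, fixed float formatting, no
## timestamps).

SCHEMA_VARIANTS <- "cardioTriage annotated-variant TSV v1.0"
SCHEMA_CALLS <- "cardioTriage calls TSV v1.0"
SCHEMA_ROSTER <- "cardioTriage roster TSV v1.0"

PREDICTOR_LEVELS <- list(
    sift = c("damaging", "tolerated", "absent"),
    provean = c("deleterious", "neutral", "absent"),
    polyphen2 = c("probably_damaging", "possibly_damaging", "benign",
                  "absent"),
    mutation_taster = c("disease_causing", "polymorphism", "absent"))

read_tsv_dialect <- function(path) {
    utils::read.delim(path, comment.char = "#", na.strings = ".",
                      stringsAsFactors = FALSE, check.names = FALSE)
}

## normalise decimal-comma frequencies ("0,0004") with a warning
normalize_maf <- function(x, column) {
    if (is.numeric(x)) return(x)
    x <- as.character(x)
    comma <- !is.na(x) & grepl(",", x, fixed = TRUE)
    if (any(comma)) {
        warning(sprintf("column %s: %d value(s) with a decimal comma normalized",
                        column, sum(comma)))
        x[comma] <- gsub(",", ".", x[comma], fixed = TRUE)
    }
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad))
        stop(sprintf("column %s: unparseable frequency value(s): %s",
                     column, paste(utils::head(x[bad], 3), collapse = ", ")))
    as.numeric(x)
}

#' Read an annotated-variant table
#'
#' Reads the canonical tab-separated annotated-variant file: one row per
#' patient x variant, \code{"."} for absent values, \code{#}-prefixed
#' header lines ignored. Required columns: \code{patient_id}, \code{gene},
#' \code{transcript}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#' \code{cdna}, \code{protein}, \code{depth}, \code{dbsnp}, predictor
#' verdicts (\code{sift}, \code{provean}, \code{polyphen2},
#' \code{mutation_taster}), conservation scores (\code{phylop},
#' \code{phastcons}, \code{grantham}), database evidence
#' (\code{clinvar_class}, \code{clinvar_same_pheno}, \code{hgmd_same_pheno},
#' \code{published_support}) and \code{genotype}; any number of
#' \code{maf_<source>} frequency columns. Frequencies written with a
#' decimal comma are normalised with a warning; unknown predictor levels or
#' truncated rows are errors reporting the offending values.
#'
#' @param path Path to the TSV file.
#' @return A data.frame ready for [cardioCohort()].
#' @export
readVariantTable <- function(path) {
    nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                              quote = "")
    keep <- which(!is.na(nf))
    if (length(keep) > 1L) {
        ragged <- keep[nf[keep] != nf[keep[1L]]]
        if (length(ragged))
            stop("truncated or ragged row(s) at line ",
                 paste(utils::head(ragged, 5), collapse = ", "))
    }
    v <- tryCatch(read_tsv_dialect(path), error = function(e)
        stop("failed to parse ", path, ": ", conditionMessage(e)))
    missing_cols <- setdiff(VARIANT_COLUMNS, names(v))
    if (length(missing_cols))
        stop("variant table lacks column(s): ",
             paste(missing_cols, collapse = ", "))
    known <- c(VARIANT_COLUMNS, grep("^maf_", names(v), value = TRUE))
    unknown <- setdiff(names(v), known)
    if (length(unknown))
        stop("unknown column(s) in variant table: ",
             paste(unknown, collapse = ", "))
    for (col in grep("^maf_", names(v), value = TRUE))
        v[[col]] <- normalize_maf(v[[col]], col)
    v$pos <- as.integer(v$pos)
    v$depth <- as.integer(v$depth)
    for (col in c("phylop", "phastcons", "grantham"))
        v[[col]] <- suppressWarnings(as.numeric(v[[col]]))
    for (col in names(PREDICTOR_LEVELS)) {
        v[[col]][is.na(v[[col]])] <- "absent"
        bad <- !v[[col]] %in% PREDICTOR_LEVELS[[col]]
        if (any(bad))
            stop(sprintf("line %s: unknown %s verdict '%s'",
                         paste(which(bad) + 1L, collapse = ","), col,
                         paste(unique(v[[col]][bad]), collapse = "','")))
    }
    v$clinvar_class[is.na(v$clinvar_class)] <- "absent"
    bad <- !v$clinvar_class %in% CLINVAR_CLASSES
    if (any(bad))
        stop("unknown clinvar_class value(s): ",
             paste(unique(v$clinvar_class[bad]), collapse = ", "))
    for (col in c("clinvar_same_pheno", "hgmd_same_pheno",
                  "published_support")) {
        v[[col]] <- as.logical(v[[col]])
        v[[col]][is.na(v[[col]])] <- FALSE
    }
    v
}

#' Read a patient roster
#'
#' Tab-separated file with columns \code{patient_id}, \code{phenotype}
#' (DCM/HCM/ARVC) and optionally \code{sex} (M/F; missing means unknown).
#'
#' @param path Path to the TSV file.
#' @return A data.frame for [cardioCohort()].
#' @export
readRoster <- function(path) {
    r <- read_tsv_dialect(path)
    if (!all(c("patient_id", "phenotype") %in% names(r)))
        stop("roster needs columns patient_id, phenotype")
    if (is.null(r$sex)) r$sex <- "unknown"
    r$sex[is.na(r$sex)] <- "unknown"
    r$patient_id <- as.character(r$patient_id)
    r
}

#' Read a panel association catalog
#'
#' Two-column tab-separated file: gene symbol and comma-separated
#' association tags (\code{DCM}, \code{HCM}, \code{ARVC},
#' \code{channelopathy}).
#'
#' @param path Path to the TSV file.
#' @return An [AssociationCatalog-class].
#' @export
readCatalog <- function(path) {
    raw <- utils::read.delim(path, comment.char = "#", header = FALSE,
                             col.names = c("gene", "tags"),
                             stringsAsFactors = FALSE)
    tags <- strsplit(raw$tags, ",", fixed = TRUE)
    associationCatalog(data.frame(
        gene = rep(raw$gene, lengths(tags)),
        tag = trimws(unlist(tags)), stringsAsFactors = FALSE))
}

#' Read a rarity policy from YAML
#'
#' Layout: \code{thresholds: \{DCM: 0.004, HCM: 0.002, ARVC: 0.0005\}},
#' \code{min_depth: 10}, \code{aggregation: max_across_sources}. Values
#' written as percent strings with a decimal comma (\code{"0,4\%"}) are
#' normalised to fractions.
#'
#' @param path Path to the YAML file.
#' @return A [MAFPolicy-class].
#' @export
readPolicy <- function(path) {
    y <- yaml::read_yaml(path)
    thr <- vapply(y$thresholds, function(v) {
        if (is.character(v)) {
            pct <- grepl("%", v, fixed = TRUE)
            v <- as.numeric(gsub("[%[:space:]]", "",
                                 gsub(",", ".", v, fixed = TRUE)))
            if (pct) v <- v / 100
        }
        as.numeric(v)
    }, numeric(1))
    mafPolicy(thresholds = thr,
              minDepth = if (is.null(y$min_depth)) 10L else y$min_depth,
              aggregation = if (is.null(y$aggregation))
                  "max_across_sources" else y$aggregation)
}

format_tsv_value <- function(x) {
    if (is.numeric(x)) {
        out <- vapply(x, function(v)
            if (is.na(v)) "." else formatC(v, format = "g", digits = 15),
            character(1))
    } else {
        out <- as.character(x)
        out[is.na(out) | out == ""] <- "."
    }
    out
}

write_tsv_dialect <- function(df, path, schema) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# ", schema), con)
    out <- as.data.frame(lapply(df, format_tsv_value),
                         stringsAsFactors = FALSE, check.names = FALSE)
    names(out) <- names(df)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write an annotated-variant table
#'
#' @param variants Variant data.frame (derived columns are dropped so a
#'   written table reloads through [readVariantTable()] unchanged).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeVariantTable <- function(variants, path) {
    keep <- c(VARIANT_COLUMNS, grep("^maf_", names(variants), value = TRUE))
    keep <- names(variants)[names(variants) %in% keep]
    write_tsv_dialect(variants[keep], path, SCHEMA_VARIANTS)
}

#' Write a roster
#' @param roster Roster data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeRoster <- function(roster, path)
    write_tsv_dialect(roster, path, SCHEMA_ROSTER)

#' Write a calls table
#'
#' The annotated-variant columns plus \code{potentially_pathogenic},
#' \code{branch} and the comma-joined \code{evidence_codes}, byte-stable
#' for a fixed input.
#'
#' @param calls Calls data.frame from [classifyCohort()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCalls <- function(calls, path)
    write_tsv_dialect(calls, path, SCHEMA_CALLS)

#' Write the report bundle as JSON
#'
#' Deterministic serialisation (fixed key order, no timestamps); a written
#' bundle reloads to the same structure.
#'
#' @param report A \code{triageReport} from [renderReports()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeReports <- function(report, path) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE,
                         dataframe = "columns")
    invisible(path)
}

## ---------------------------------------------------------------------------
## VCF ingestion (convenience adapter; the TSV model is canonical)
## ---------------------------------------------------------------------------

#' Read variants from a VCF file
#'
#' Converts a VCF 4.x file carrying the annotation bundle in INFO keys into
#' the canonical variant-table model. Multi-allelic records are split, each
#' alternate allele becoming its own row. INFO keys are mapped to model
#' columns through \code{infoKeyMap}; a mapped key absent from a record
#' yields an absent annotation (not an error). Requires the
#' \pkg{VariantAnnotation} package.
#'
#' @param path Path to the VCF.
#' @param patientId Patient identifier assigned to all records (single-
#'   sample VCFs; defaults to the VCF sample name).
#' @param infoKeyMap Named character vector mapping model columns (e.g.
#'   \code{gene}, \code{sift}, \code{maf_gnomad}) to INFO keys. The default
#'   maps upper-cased column names (\code{GENE}, \code{SIFT},
#'   \code{MAF_GNOMAD}, ...).
#' @return A data.frame in the [readVariantTable()] model.
#' @export
readVCF <- function(path, patientId = NULL, infoKeyMap = NULL) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("readVCF() requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    info <- VariantAnnotation::info(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    alts <- VariantAnnotation::alt(vcf)
    n_alt <- lengths(alts)
    idx <- rep(seq_along(n_alt), n_alt)        # record index per output row
    alt_rank <- sequence(n_alt)                # which alt within the record
    n <- length(idx)
    out <- blank_variant(n)

    mapped_cols <- c("gene", "transcript", "cdna", "protein", "depth",
                     "dbsnp", "sift", "provean", "polyphen2",
                     "mutation_taster", "phylop", "phastcons", "grantham",
                     "clinvar_class", "clinvar_same_pheno",
                     "hgmd_same_pheno", "published_support",
                     "maf_gnomad", "maf_1000g", "maf_esp")
    if (is.null(infoKeyMap))
        infoKeyMap <- stats::setNames(toupper(mapped_cols), mapped_cols)

    out$chrom <- as.character(GenomicRanges::seqnames(rr))[idx]
    out$pos <- GenomicRanges::start(rr)[idx]
    out$ref <- as.character(VariantAnnotation::ref(vcf))[idx]
    out$alt <- vapply(seq_len(n), function(i)
        as.character(alts[[idx[i]]][alt_rank[i]]), character(1))

    pick <- function(values, i, rank) {
        v <- values[[i]]
        if (length(v) == 0L || all(is.na(v))) return(NA)
        if (length(v) >= rank) v[[rank]] else v[[1L]]
    }
    for (col in names(infoKeyMap)) {
        key <- infoKeyMap[[col]]
        if (!key %in% names(info)) next
        vals <- info[[key]]
        if (!is.list(vals) && !methods::is(vals, "List"))
            vals <- as.list(vals)
        raw <- vapply(seq_len(n), function(i) {
            v <- pick(vals, idx[i], alt_rank[i])
            if (length(v) == 0L || is.na(v)) NA_character_
            else as.character(v)
        }, character(1))
        out[[col]] <- switch(
            col,
            depth = as.integer(raw),
            phylop = , phastcons = , grantham = ,
            maf_gnomad = , maf_1000g = , maf_esp = as.numeric(raw),
            clinvar_same_pheno = , hgmd_same_pheno = ,
            published_support = !is.na(raw) &
                toupper(raw) %in% c("TRUE", "1", "YES"),
            ifelse(is.na(raw),
                   if (col %in% c(names(PREDICTOR_LEVELS), "clinvar_class"))
                       "absent" else NA_character_,
                   raw))
    }
    gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
    if (!is.null(gt) && ncol(gt) >= 1L)
        out$genotype <- as.character(gt[idx, 1L])
    samp <- colnames(vcf)
    out$patient_id <- if (!is.null(patientId)) patientId
                      else if (length(samp)) samp[1L] else NA_character_
    out
}
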