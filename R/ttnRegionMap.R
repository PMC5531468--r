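## Titin (TTN) sarcomeric band mapping. Truncating TTN variants are only
## flagged potentially pathogenic when they fall in the A-band and in the
## protein region shared by all isoforms under consideration.

#' Per-transcript map of titin sarcomeric bands
#'
#' For each TTN transcript, an ordered partition of the protein into
#' sarcomeric bands (Z-disc, I-band, A-band, M-band), 1-based inclusive
#' residue intervals covering the whole protein with no gaps. A per-
#' transcript set of \emph{shared} intervals marks the protein region
#' encoded by exons common to all isoforms in \code{isoformSet}; the
#' truncating-variant rule requires both the A-band and the shared region.
#' The short novex-3 isoform ends within the I-band and carries no A-band,
#' so its shared set is empty and novex-3-only truncations can never
#' satisfy the rule.
#'
#' @slot regions data.frame with columns \code{transcript}, \code{band}
#'   (\code{Z}, \code{I}, \code{A}, \code{M}), \code{start}, \code{end}.
#' @slot shared data.frame with columns \code{transcript}, \code{start},
#'   \code{end} (may have zero rows for a transcript).
#' @slot isoformSet Character vector of transcript accessions read as
#'   "all TTN isoforms" for the shared-region criterion.
#' @seealso [ttnRegionMap()], [readTTNRegionMap()], [bandOf()],
#'   [ttnTruncatingCall()]
#' @export
setClass("TTNRegionMap",
         representation(regions = "data.frame",
                        shared = "data.frame",
                        isoformSet = "character"))

setValidity("TTNRegionMap", function(object) {
    r <- object@regions
    msg <- character()
    if (!all(c("transcript", "band", "start", "end") %in% names(r)))
        return("regions needs columns transcript, band, start, end")
    if (any(!r$band %in% c("Z", "I", "A", "M")))
        msg <- c(msg, "bands must be Z, I, A or M")
    for (tx in unique(r$transcript)) {
        iv <- r[r$transcript == tx, ]
        iv <- iv[order(iv$start), ]
        if (iv$start[1] != 1L)
            msg <- c(msg, sprintf("%s: intervals must start at residue 1", tx))
        if (any(iv$end < iv$start))
            msg <- c(msg, sprintf("%s: interval end before start", tx))
        if (nrow(iv) > 1 && any(iv$start[-1] != iv$end[-nrow(iv)] + 1L))
            msg <- c(msg, sprintf("%s: intervals must tile 1..length with no gap or overlap", tx))
    }
    if (!all(object@isoformSet %in% r$transcript))
        msg <- c(msg, "isoformSet accession missing from the region map")
    if (length(msg)) msg else TRUE
})

#' Construct a TTN region map
#'
#' @param regions data.frame with columns \code{transcript}, \code{band},
#'   \code{start}, \code{end}; see [TTNRegionMap-class].
#' @param shared data.frame with columns \code{transcript}, \code{start},
#'   \code{end}; defaults to no shared regions.
#' @param isoformSet Transcript accessions treated as "all isoforms".
#' @return A [TTNRegionMap-class].
#' @export
ttnRegionMap <- function(regions,
                         shared = data.frame(transcript = character(),
                                             start = integer(),
                                             end = integer()),
                         isoformSet = character()) {
    new("TTNRegionMap",
        regions = as.data.frame(regions, stringsAsFactors = FALSE),
        shared = as.data.frame(shared, stringsAsFactors = FALSE),
        isoformSet = isoformSet)
}

#' Read a TTN region map from YAML
#'
#' The expected layout is
#' \preformatted{
#' isoform_set: [NM_003319]
#' transcripts:
#'   NM_003319:
#'     bands:
#'       - {band: Z, start: 1, end: 800}
#'       - {band: I, start: 801, end: 13600}
#'       ...
#'     shared:
#'       - {start: 13601, end: 26926}
#' }
#' The map is validated on load (full 1..length tiling per transcript).
#'
#' @param path Path to the YAML file.
#' @return A [TTNRegionMap-class].
#' @export
readTTNRegionMap <- function(path) {
    y <- yaml::read_yaml(path)
    if (is.null(y$transcripts))
        stop("region map YAML lacks a 'transcripts' section")
    reg <- do.call(rbind, lapply(names(y$transcripts), function(tx) {
        b <- y$transcripts[[tx]]$bands
        data.frame(transcript = tx,
                   band = vapply(b, `[[`, character(1), "band"),
                   start = vapply(b, function(x) as.integer(x$start), integer(1)),
                   end = vapply(b, function(x) as.integer(x$end), integer(1)),
                   stringsAsFactors = FALSE)
    }))
    sh <- do.call(rbind, lapply(names(y$transcripts), function(tx) {
        s <- y$transcripts[[tx]]$shared
        if (is.null(s) || !length(s))
            return(NULL)
        data.frame(transcript = tx,
                   start = vapply(s, function(x) as.integer(x$start), integer(1)),
                   end = vapply(s, function(x) as.integer(x$end), integer(1)),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(sh))
        sh <- data.frame(transcript = character(), start = integer(),
                         end = integer())
    iso <- if (is.null(y$isoform_set)) character() else
        as.character(unlist(y$isoform_set))
    ttnRegionMap(reg, sh, iso)
}

#' The region map distributed with the package
#'
#' Loads \code{inst/extdata/ttn_region_map.yaml}: band boundaries for the
#' N2B isoform (NM_003319) and the novex-3 isoform (NM_133379), derived
#' from public titin annotation, with the A/M constitutive region of N2B as
#' the shared region and \code{isoform_set = NM_003319}.
#'
#' @return A [TTNRegionMap-class].
#' @examples
#' ttnDefaultRegionMap()
#' @export
ttnDefaultRegionMap <- function() {
    readTTNRegionMap(system.file("extdata", "ttn_region_map.yaml",
                                 package = "cardioTriage", mustWork = TRUE))
}

#' Sarcomeric band of a residue position
#'
#' @param position Residue index (1-based), vectorised.
#' @param transcript Transcript accession (single value or vector).
#' @param map A [TTNRegionMap-class].
#' @return Character vector of bands (\code{Z}, \code{I}, \code{A},
#'   \code{M}). Unknown transcripts and positions beyond the transcript
#'   length are errors.
#' @examples
#' bandOf(16477, "NM_003319", ttnDefaultRegionMap())
#' @export
bandOf <- function(position, transcript, map) {
    stopifnot(is(map, "TTNRegionMap"))
    n <- max(length(position), length(transcript))
    position <- rep_len(as.integer(position), n)
    transcript <- rep_len(as.character(transcript), n)
    vapply(seq_len(n), function(i) {
        iv <- map@regions[map@regions$transcript == transcript[i], ]
        if (!nrow(iv))
            stop("transcript not in region map: ", transcript[i])
        if (is.na(position[i]) || position[i] < 1L ||
            position[i] > max(iv$end))
            stop("residue position ", position[i],
                 " outside 1..", max(iv$end), " for ", transcript[i])
        iv$band[position[i] >= iv$start & position[i] <= iv$end][1]
    }, character(1))
}

in_shared_region <- function(position, transcript, map) {
    sh <- map@shared[map@shared$transcript == transcript, , drop = FALSE]
    nrow(sh) > 0 && any(position >= sh$start & position <= sh$end)
}

#' TTN truncating-variant rule
#'
#' A truncating TTN variant (nonsense, frameshift, canonical splice or
#' stop-loss) is potentially pathogenic only if its residue position maps to
#' the A-band of its transcript \emph{and} lies in the region shared by all
#' isoforms in the map's \code{isoformSet} -- i.e. the truncation affects
#' all TTN transcripts in their A-band region. Both sub-tests are reported
#' in the rationale.
#'
#' @param position Residue index of the first affected residue.
#' @param transcript Transcript accession the position refers to.
#' @param map A [TTNRegionMap-class]; every accession of its
#'   \code{isoformSet} must be mapped.
#' @return A list with \code{pathogenic} (logical), \code{band},
#'   \code{in_shared} and a human-readable \code{rationale}.
#' @examples
#' m <- ttnDefaultRegionMap()
#' ttnTruncatingCall(16477, "NM_003319", m)$pathogenic   # TRUE  (A-band)
#' ttnTruncatingCall(24944, "NM_003319", m)$pathogenic   # FALSE (M-band)
#' @export
ttnTruncatingCall <- function(position, transcript, map) {
    stopifnot(is(map, "TTNRegionMap"))
    missing_iso <- setdiff(map@isoformSet, unique(map@regions$transcript))
    if (length(missing_iso))
        stop("isoform set accession(s) not mapped: ",
             paste(missing_iso, collapse = ", "))
    band <- bandOf(position, transcript, map)
    shared <- in_shared_region(position, transcript, map)
    ok <- band == "A" && shared
    rationale <- sprintf(
        "residue %d on %s maps to the %s-band [%s]; %s the region shared by all isoforms (%s) [%s]",
        as.integer(position), transcript, band,
        if (band == "A") "pass" else "fail",
        if (shared) "inside" else "outside",
        paste(map@isoformSet, collapse = ","),
        if (shared) "pass" else "fail")
    list(pathogenic = ok, band = band, in_shared = shared,
         rationale = rationale)
}

setMethod("show", "TTNRegionMap", function(object) {
    txs <- unique(object@regions$transcript)
    cat("TTNRegionMap for", length(txs), "transcript(s):",
        paste(txs, collapse = ", "), "\n")
    cat("  isoform set:", paste(object@isoformSet, collapse = ", "), "\n")
})
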