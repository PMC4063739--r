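# Windowed genomic screen for ICEclc-like elements from precomputed homology
# and annotation feature tables. An element is called around a tciR-like
# anchor hit when (i) core-region homology blocks with > identity_min %
# nucleotide identity lie within the core window of the anchor, and (ii) an
# integrase gene lies within the integrase window; a nearby tRNA-Gly is
# scored but never gates the call. Coordinates are 1-based inclusive; BED
# export converts to 0-based half-open.

.FEATURE_KINDS <- c("tciR_hit", "core_block", "integrase", "tRNA_gly")

.FEATURE_COLS <- c("genome_id", "contig_id", "kind", "start", "end", "strand",
                   "evalue", "pct_identity")

#' Validate a feature table
#'
#' A feature table has one row per genomic feature with columns `genome_id`,
#' `contig_id`, `kind` (one of `tciR_hit`, `core_block`, `integrase`,
#' `tRNA_gly`), `start`, `end` (1-based inclusive), `strand`, `evalue`
#' (hits), `pct_identity` (hits/blocks). Missing optional columns are added
#' as `NA`.
#'
#' @param features a `data.frame`.
#' @return The completed, validated `data.frame`.
#' @export
validateFeatureTable <- function(features) {
  if (!is.data.frame(features)) stop("features must be a data.frame")
  need <- c("genome_id", "contig_id", "kind", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (cc in setdiff(.FEATURE_COLS, names(features)))
    features[[cc]] <- if (cc == "strand") rep("*", nrow(features))
                      else rep(NA_real_, nrow(features))
  if (nrow(features) == 0) return(features[, .FEATURE_COLS])
  if (any(!features$kind %in% .FEATURE_KINDS))
    stop("kind must be one of: ", paste(.FEATURE_KINDS, collapse = ", "))
  if (any(features$start > features$end)) stop("start must be <= end")
  if (any(features$start < 1)) stop("coordinates are 1-based: start >= 1")
  pid <- features$pct_identity
  if (any(!is.na(pid) & (pid < 0 | pid > 100)))
    stop("pct_identity must lie in [0, 100]")
  ev <- features$evalue
  if (any(!is.na(ev) & ev < 0)) stop("evalue must be >= 0")
  features[, .FEATURE_COLS]
}

#' Filter anchor hits by E-value
#'
#' Retains `tciR_hit` rows whose BLASTN E-value is strictly below
#' `evalue_max` (published screen threshold: 1e-15); all other feature kinds
#' pass through untouched.
#'
#' @param features a feature table (see [validateFeatureTable()]).
#' @param evalue_max strict E-value cutoff for anchor hits.
#' @return The filtered feature table.
#' @examples
#' ft <- data.frame(genome_id = "g", contig_id = "c", kind = "tciR_hit",
#'                  start = 1, end = 900, evalue = 1e-10)
#' nrow(filterHits(ft))   # 0: 1e-10 is not below 1e-15
#' @export
filterHits <- function(features, evalue_max = 1e-15) {
  features <- validateFeatureTable(features)
  if (nrow(features) == 0) return(features)
  hit <- features$kind == "tciR_hit"
  if (any(hit & is.na(features$evalue)))
    stop("tciR_hit rows must carry an evalue")
  keep <- !hit | features$evalue < evalue_max
  features[keep, , drop = FALSE]
}

## nearest-edge distance between 1-based inclusive intervals; 0 on overlap
.edgeDist <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

.emptyCalls <- function() {
  data.frame(genome_id = character(0), contig_id = character(0),
             start = numeric(0), end = numeric(0),
             anchor_start = numeric(0), anchor_end = numeric(0),
             core_ok = logical(0), integrase_ok = logical(0),
             trna_scored = logical(0), n_core_blocks = integer(0),
             core_len = numeric(0), dist_core = numeric(0),
             dist_integrase = numeric(0), n_anchors = integer(0),
             anchors = character(0))
}

#' Call candidate ICE regions around anchor hits
#'
#' For every surviving `tciR_hit` anchor the screen requires, on the same
#' contig: (i) core homology blocks with `pct_identity > identity_min` whose
#' nearest-edge distance to the anchor lies inside `core_window`
#' (inclusive), with the qualifying blocks summing to at least
#' `core_min_len` bp of aligned core; and (ii) an integrase feature within
#' `int_window` of the anchor. A call is emitted iff both criteria hold. A
#' tRNA-Gly within `trna_window` of a qualifying integrase sets
#' `trna_scored`, without gating the call. Strand never gates calls. The
#' result is independent of input row order.
#'
#' @param features a feature table, already passed through [filterHits()].
#' @param core_window nearest-edge distance window (bp) for core blocks,
#'   default 1-100 kb.
#' @param int_window distance window (bp) for the integrase, default 5-20 kb.
#' @param identity_min strict lower bound on core-block percent identity.
#' @param core_min_len minimum summed length (bp) of qualifying core blocks.
#' @param trna_window distance (bp) from a qualifying integrase within which
#'   a tRNA-Gly is scored.
#' @return A calls `data.frame`: one row per anchor with both criteria met,
#'   with the evidence region, flags and nearest distances.
#' @export
callIce <- function(features, core_window = c(1e3, 1e5),
                    int_window = c(5e3, 2e4), identity_min = 75,
                    core_min_len = 1e4, trna_window = 5e3) {
  features <- validateFeatureTable(features)
  stopifnot(length(core_window) == 2, length(int_window) == 2,
            core_window[1] <= core_window[2], int_window[1] <= int_window[2])
  if (nrow(features) == 0) return(.emptyCalls())
  ## canonical order for determinism
  features <- features[order(features$genome_id, features$contig_id,
                             features$start, features$end, features$kind), ,
                       drop = FALSE]
  anchors <- features[features$kind == "tciR_hit", , drop = FALSE]
  if (nrow(anchors) == 0) return(.emptyCalls())

  rows <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    same <- features[features$genome_id == a$genome_id &
                     features$contig_id == a$contig_id, , drop = FALSE]
    core <- same[same$kind == "core_block", , drop = FALSE]
    ints <- same[same$kind == "integrase", , drop = FALSE]
    trna <- same[same$kind == "tRNA_gly", , drop = FALSE]

    core_d <- .edgeDist(a$start, a$end, core$start, core$end)
    core_q <- !is.na(core$pct_identity) & core$pct_identity > identity_min &
      core_d >= core_window[1] & core_d <= core_window[2]
    core_len <- sum(core$end[core_q] - core$start[core_q] + 1)
    core_ok <- any(core_q) && core_len >= core_min_len

    int_d <- .edgeDist(a$start, a$end, ints$start, ints$end)
    int_q <- int_d >= int_window[1] & int_d <= int_window[2]
    integrase_ok <- any(int_q)

    trna_scored <- FALSE
    if (integrase_ok && nrow(trna) > 0) {
      for (j in which(int_q)) {
        td <- .edgeDist(ints$start[j], ints$end[j], trna$start, trna$end)
        if (any(td <= trna_window)) { trna_scored <- TRUE; break }
      }
    }

    if (!(core_ok && integrase_ok)) next
    ev_start <- min(a$start, core$start[core_q], ints$start[int_q])
    ev_end <- max(a$end, core$end[core_q], ints$end[int_q])
    rows[[i]] <- data.frame(
      genome_id = a$genome_id, contig_id = a$contig_id,
      start = ev_start, end = ev_end,
      anchor_start = a$start, anchor_end = a$end,
      core_ok = core_ok, integrase_ok = integrase_ok,
      trna_scored = trna_scored,
      n_core_blocks = sum(core_q), core_len = core_len,
      dist_core = min(core_d[core_q]), dist_integrase = min(int_d[int_q]),
      n_anchors = 1L,
      anchors = sprintf("%d-%d", a$start, a$end))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptyCalls())
  calls <- do.call(rbind, rows)
  calls[order(calls$genome_id, calls$contig_id, calls$start, calls$end), ,
        drop = FALSE]
}

#' Merge overlapping candidate calls
#'
#' Calls on the same genome and contig whose regions overlap (distinct
#' anchors can share evidence) are merged into one region; evidence flags are
#' unioned, anchors concatenated, distances taken as the minima. Disjoint
#' calls are untouched.
#'
#' @param calls a calls `data.frame` from [callIce()].
#' @return The merged calls `data.frame`.
#' @export
mergeOverlappingCalls <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  out <- list()
  for (key in unique(paste(calls$genome_id, calls$contig_id, sep = "\r"))) {
    part <- strsplit(key, "\r", fixed = TRUE)[[1]]
    cc <- calls[calls$genome_id == part[1] & calls$contig_id == part[2], ,
                drop = FALSE]
    ir <- IRanges::IRanges(start = cc$start, end = cc$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (g in seq_along(red)) {
      idx <- revmap[[g]]
      sub <- cc[idx, , drop = FALSE]
      anchors <- unique(unlist(strsplit(sub$anchors, ",", fixed = TRUE)))
      out[[length(out) + 1]] <- data.frame(
        genome_id = part[1], contig_id = part[2],
        start = min(sub$start), end = max(sub$end),
        anchor_start = min(sub$anchor_start), anchor_end = max(sub$anchor_end),
        core_ok = any(sub$core_ok), integrase_ok = any(sub$integrase_ok),
        trna_scored = any(sub$trna_scored),
        n_core_blocks = max(sub$n_core_blocks),
        core_len = max(sub$core_len),
        dist_core = min(sub$dist_core),
        dist_integrase = min(sub$dist_integrase),
        n_anchors = length(anchors),
        anchors = paste(anchors, collapse = ","))
    }
  }
  merged <- do.call(rbind, out)
  merged[order(merged$genome_id, merged$contig_id, merged$start, merged$end), ,
         drop = FALSE]
}

#' Run the full screen
#'
#' [filterHits()] then [callIce()] then [mergeOverlappingCalls()] with the
#' published defaults.
#'
#' @inheritParams callIce
#' @param evalue_max strict E-value cutoff on anchor hits.
#' @return Merged calls `data.frame`.
#' @export
iceScan <- function(features, evalue_max = 1e-15, core_window = c(1e3, 1e5),
                    int_window = c(5e3, 2e4), identity_min = 75,
                    core_min_len = 1e4, trna_window = 5e3) {
  mergeOverlappingCalls(
    callIce(filterHits(features, evalue_max), core_window = core_window,
            int_window = int_window, identity_min = identity_min,
            core_min_len = core_min_len, trna_window = trna_window))
}

#' Read a feature table from TSV
#'
#' @param path TSV file with a header matching the feature-table columns.
#' @return A validated feature table.
#' @export
readFeatureTable <- function(path) {
  validateFeatureTable(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a feature table to TSV
#'
#' @param features a feature table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.table(validateFeatureTable(features), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BLAST tabular hits as anchor features
#'
#' Maps standard outfmt-6 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore; no header) onto feature
#' rows of kind `kind` on the subject sequence.
#'
#' @param path BLAST tabular output file.
#' @param genome_id genome label to assign.
#' @param kind feature kind for the hits (default `tciR_hit`).
#' @return A feature table.
#' @export
readBlastHits <- function(path, genome_id, kind = "tciR_hit") {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 12) stop("expected 12 BLAST outfmt-6 columns")
  names(b)[1:12] <- cols
  validateFeatureTable(data.frame(
    genome_id = genome_id, contig_id = b$sseqid, kind = kind,
    start = pmin(b$sstart, b$send), end = pmax(b$sstart, b$send),
    strand = ifelse(b$send >= b$sstart, "+", "-"),
    evalue = b$evalue, pct_identity = b$pident))
}

#' Read integrase / tRNA annotations from GFF3
#'
#' Imports a GFF3 file (via \pkg{rtracklayer}) and keeps records whose type
#' or product matches the integrase or tRNA-Gly keyword patterns, mapping
#' them to feature rows.
#'
#' @param path GFF3 file.
#' @param genome_id genome label to assign.
#' @param integrase_pattern regex (case-insensitive) identifying integrase
#'   records in `type` or `product`.
#' @param trna_pattern regex identifying tRNA-Gly records.
#' @return A feature table with kinds `integrase` and `tRNA_gly`.
#' @export
readAnnotationGff <- function(path, genome_id,
                              integrase_pattern = "integrase|intB13",
                              trna_pattern = "tRNA[-_ ]?Gly") {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  txt <- paste(as.character(meta$type),
               if ("product" %in% names(meta)) as.character(meta$product) else "",
               if ("Name" %in% names(meta)) as.character(meta$Name) else "")
  is_int <- grepl(integrase_pattern, txt, ignore.case = TRUE)
  is_trna <- !is_int & grepl(trna_pattern, txt, ignore.case = TRUE)
  keep <- is_int | is_trna
  if (!any(keep)) return(validateFeatureTable(
    data.frame(genome_id = character(0), contig_id = character(0),
               kind = character(0), start = numeric(0), end = numeric(0))))
  gr <- gr[keep]
  validateFeatureTable(data.frame(
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    kind = ifelse(is_int[keep], "integrase", "tRNA_gly"),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))))
}

#' Write calls as TSV
#'
#' @param calls a calls `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCallsTsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export calls as BED
#'
#' Regions are converted from the internal 1-based inclusive convention to
#' BED's 0-based half-open intervals (handled by \pkg{rtracklayer}). The name
#' field carries the genome, anchor count and evidence flags.
#'
#' @param calls a calls `data.frame`.
#' @param path output `.bed` file.
#' @return `path`, invisibly.
#' @export
exportCallsBed <- function(calls, path) {
  if (nrow(calls) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = calls$contig_id,
    ranges = IRanges::IRanges(start = calls$start, end = calls$end),
    name = sprintf("%s|anchors=%s|core=%s|int=%s|tRNA=%s",
                   calls$genome_id, calls$anchors,
                   ifelse(calls$core_ok, "ok", "no"),
                   ifelse(calls$integrase_ok, "ok", "no"),
                   ifelse(calls$trna_scored, "yes", "no")))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
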