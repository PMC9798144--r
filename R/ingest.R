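# Count ingestion: turn read alignments (SAM/BAM against the family
# consensus set) or pre-made TSV tables into the per-position count
# structures each scoring chemistry consumes.
#
# Reads are assumed already aligned to the reduced tRNA reference; only the
# primary alignment of each read is used and soft-clipped bases never move
# an end call (alignment start/end are reference coordinates of the aligned
# span).

.open_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    Rsamtools::indexBam(path)
  }
  path
}

.family_lengths <- function(families) {
  if (inherits(families, "family_reference")) families <- list(families)
  setNames(vapply(families, function(f) nchar(f$consensus), integer(1)),
           vapply(families, `[[`, "", "family_id"))
}

# scan primary alignments; returns tibble(family, pos, end) in 1-based
# reference coordinates, filtered to known families and min mapq
.scan_alignments <- function(path, families, min_mapq = 0) {
  lens <- .family_lengths(families)
  bam <- .open_bam(path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag,
                               what = c("rname", "pos", "cigar", "mapq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(x$pos) == 0) {
    return(tibble(family = character(), pos = integer(), end = integer()))
  }
  fam <- as.character(x$rname)
  mapq <- ifelse(is.na(x$mapq), 0L, x$mapq)
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar)
  keep <- mapq >= min_mapq
  unknown <- !(fam %in% names(lens))
  if (any(unknown & keep)) {
    warning(sum(unknown & keep), " alignment(s) to reference(s) absent from ",
            "the family set were skipped", call. = FALSE)
  }
  keep <- keep & !unknown
  tibble(family = fam[keep], pos = x$pos[keep],
         end = x$pos[keep] + width[keep] - 1L)
}

.per_family_tally <- function(aln, families, f) {
  lens <- .family_lengths(families)
  bind_rows(lapply(names(lens), function(fm) {
    L <- lens[[fm]]
    a <- aln[aln$family == fm, , drop = FALSE]
    f(fm, L, a)
  }))
}

#' Read-end counts from alignments (RiboMethSeq)
#'
#' For every accepted read, the 5'-end counter is incremented at its
#' leftmost aligned position, the 3'-end counter at its rightmost, and
#' coverage across the whole aligned span.
#'
#' @param path SAM or BAM file aligned to the family consensus set.
#' @param families list of [family_reference()] objects (or one).
#' @param sample_id sample identifier stored in the output.
#' @param min_mapq minimum mapping quality (default 0; family-level mapping
#'   is intentionally degenerate).
#' @return tibble with columns `family`, `sample`, `position` (1-based),
#'   `end5`, `end3`, `coverage`.
#' @export
ends_from_alignments <- function(path, families, sample_id = "sample",
                                 min_mapq = 0) {
  aln <- .scan_alignments(path, families, min_mapq)
  .per_family_tally(aln, families, function(fm, L, a) {
    cov <- as.integer(IRanges::coverage(IRanges::IRanges(a$pos, a$end),
                                        width = L))
    tibble(family = fm, sample = sample_id, position = seq_len(L),
           end5 = tabulate(a$pos, L), end3 = tabulate(a$end, L),
           coverage = cov)
  })
}

#' Read-start and read-through counts from alignments (AlkAnilineSeq)
#'
#' The start counter is incremented at the leftmost aligned position of each
#' read; the read-through counter at every covered position strictly after
#' the start. Their sum at a position is the total number of reads passing
#' through it, the denominator of the stop ratio.
#'
#' @inheritParams ends_from_alignments
#' @return tibble with columns `family`, `sample`, `position`, `starts`,
#'   `through`.
#' @export
stops_from_alignments <- function(path, families, sample_id = "sample",
                                  min_mapq = 0) {
  aln <- .scan_alignments(path, families, min_mapq)
  .per_family_tally(aln, families, function(fm, L, a) {
    body <- a[a$end > a$pos, , drop = FALSE]
    thr <- as.integer(IRanges::coverage(
      IRanges::IRanges(body$pos + 1L, body$end), width = L))
    tibble(family = fm, sample = sample_id, position = seq_len(L),
           starts = tabulate(a$pos, L), through = thr)
  })
}

#' Per-position C/T pileup counts from alignments (bisulfite)
#'
#' Counts, at every reference position, the reads presenting a C and a T
#' (bisulfite read space), plus the nucleotide-bearing depth. Reads with a
#' deletion at a position contribute to none of the three.
#'
#' @inheritParams ends_from_alignments
#' @return tibble with columns `family`, `sample`, `position`, `count_c`,
#'   `count_t`, `depth`.
#' @export
pileup_from_alignments <- function(path, families, sample_id = "sample",
                                   min_mapq = 0) {
  lens <- .family_lengths(families)
  bam <- .open_bam(path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  pp <- Rsamtools::PileupParam(max_depth = 10000000L, min_base_quality = 0L,
                               min_mapq = as.integer(min_mapq),
                               min_nucleotide_depth = 0L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  sp <- Rsamtools::ScanBamParam(flag = flag)
  pu <- Rsamtools::pileup(bam, scanBamParam = sp, pileupParam = pp)
  pu$seqnames <- as.character(pu$seqnames)
  pu <- pu[pu$seqnames %in% names(lens), , drop = FALSE]
  bind_rows(lapply(names(lens), function(fm) {
    L <- lens[[fm]]
    p <- pu[pu$seqnames == fm, , drop = FALSE]
    cnt <- function(nuc) {
      z <- p[p$nucleotide == nuc, , drop = FALSE]
      v <- integer(L)
      v[z$pos] <- z$count
      v
    }
    acgt <- cnt("A") + cnt("C") + cnt("G") + cnt("T")
    tibble(family = fm, sample = sample_id, position = seq_len(L),
           count_c = cnt("C"), count_t = cnt("T"), depth = acgt)
  }))
}

# canonical interchange columns per chemistry
.COUNT_COLS <- list(
  rms = c("family", "sample", "position", "end5", "end3", "coverage"),
  aas = c("family", "sample", "position", "starts", "through"),
  bs  = c("family", "sample", "position", "count_c", "count_t", "depth")
)

#' Read / write per-position count tables
#'
#' The canonical interchange format for all downstream modules and the
#' synthetic generator: tab-separated with a header, one row per family x
#' position (x sample). Required columns by chemistry: RiboMethSeq (`rms`)
#' `family, sample, position, end5, end3, coverage`; AlkAnilineSeq (`aas`)
#' `..., starts, through`; bisulfite (`bs`) `..., count_c, count_t, depth`.
#'
#' @param path TSV file path.
#' @param chemistry `"rms"`, `"aas"` or `"bs"`; `read_count_tables()` infers
#'   it from the header when omitted.
#' @return `read_count_tables()` returns the validated count tibble with a
#'   `chemistry` attribute; `write_count_tables()` returns `path` invisibly.
#' @export
read_count_tables <- function(path, chemistry = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) stop("empty count table: ", path, call. = FALSE)
  if (is.null(chemistry)) {
    hit <- vapply(.COUNT_COLS, function(cols) all(cols %in% names(x)),
                  logical(1))
    if (!any(hit)) {
      miss <- vapply(.COUNT_COLS, function(cols)
        paste(setdiff(cols, names(x)), collapse = ","), character(1))
      stop("count table matches no chemistry; missing columns - ",
           paste(names(miss), miss, sep = ": ", collapse = "; "),
           call. = FALSE)
    }
    chemistry <- names(.COUNT_COLS)[which(hit)[1]]
  }
  chemistry <- match.arg(chemistry, names(.COUNT_COLS))
  miss <- setdiff(.COUNT_COLS[[chemistry]], names(x))
  if (length(miss)) {
    stop("count table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cols <- .COUNT_COLS[[chemistry]]
  num <- setdiff(cols, c("family", "sample"))
  if (any(vapply(x[num], function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    stop("negative counts in ", path, call. = FALSE)
  }
  out <- x[cols]
  attr(out, "chemistry") <- chemistry
  out
}

#' @rdname read_count_tables
#' @param counts count tibble as produced by the `*_from_alignments()`
#'   functions or the synthetic generator.
#' @export
write_count_tables <- function(counts, path, chemistry = NULL) {
  if (is.null(chemistry)) {
    hit <- vapply(.COUNT_COLS, function(cols) all(cols %in% names(counts)),
                  logical(1))
    stopifnot(any(hit))
    chemistry <- names(.COUNT_COLS)[which(hit)[1]]
  }
  readr::write_tsv(counts[.COUNT_COLS[[chemistry]]], path, progress = FALSE)
  invisible(path)
}
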