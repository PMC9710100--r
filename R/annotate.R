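#' Transcript annotation container
#'
#' Holds a set of transcript models with their exon structure. Coordinates
#' are stored in the 0-based half-open convention; GTF I/O converts from/to
#' 1-based inclusive and BED12 I/O is natively 0-based half-open.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`+`/`-`), `start`, `end` (0-based half-open span)
#'   and `biotype` (`coding` or `lncRNA`).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open); exons of one transcript must be sorted and
#'   non-overlapping and lie within the transcript span.
#' @return object of class `transcript_set`; `$transcripts` gains a
#'   `length` column (sum of exon widths, nt).
#' @export
transcript_set <- function(transcripts, exons) {
  transcripts <- as.data.frame(transcripts)
  exons <- as.data.frame(exons)
  need_tx <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end", "biotype")
  if (!all(need_tx %in% names(transcripts))) {
    stop("transcripts must have columns: ", paste(need_tx, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicate transcript ids", call. = FALSE)
  }
  if (!all(transcripts$strand %in% c("+", "-"))) {
    stop("parse error: unknown strand character", call. = FALSE)
  }
  if (any(transcripts$start >= transcripts$end)) {
    stop("transcript span must satisfy start < end", call. = FALSE)
  }
  if (!all(exons$transcript_id %in% transcripts$transcript_id)) {
    stop("exon references unknown transcript", call. = FALSE)
  }
  o <- order(match(exons$transcript_id, transcripts$transcript_id), exons$start)
  exons <- exons[o, c("transcript_id", "start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  # per-transcript structural checks
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tid in names(sp)) {
    ex <- exons[sp[[tid]], ]
    tx <- transcripts[transcripts$transcript_id == tid, ]
    if (any(ex$start >= ex$end)) stop("empty exon in ", tid, call. = FALSE)
    if (min(ex$start) < tx$start || max(ex$end) > tx$end) {
      stop("parse error: exon outside declared transcript bounds in ", tid,
           call. = FALSE)
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in ", tid, call. = FALSE)
    }
  }
  lens <- tapply(exons$end - exons$start, exons$transcript_id, sum)
  transcripts$length <- as.integer(lens[transcripts$transcript_id])
  if (any(is.na(transcripts$length) | transcripts$length < 1)) {
    stop("every transcript needs at least one exon", call. = FALSE)
  }
  rownames(transcripts) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  tab <- table(x$transcripts$biotype)
  cat("transcript_set:", nrow(x$transcripts), "transcripts (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ") on",
      length(unique(x$transcripts$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Subset a transcript_set by transcript id
#' @param ts a [transcript_set()].
#' @param ids transcript ids to keep.
#' @export
subset_transcripts <- function(ts, ids) {
  transcript_set(ts$transcripts[ts$transcripts$transcript_id %in% ids, ],
                 ts$exons[ts$exons$transcript_id %in% ids, ])
}

# GRanges of transcript spans (1-based internally for GenomicRanges)
tx_granges <- function(ts) {
  tx <- ts$transcripts
  GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start + 1L, end = tx$end),
    strand = tx$strand,
    transcript_id = tx$transcript_id,
    biotype = tx$biotype
  )
}

# exon IRanges (1-based) for one transcript id
exon_iranges <- function(ts, tid) {
  ex <- ts$exons[ts$exons$transcript_id == tid, ]
  IRanges::IRanges(start = ex$start + 1L, end = ex$end)
}

#' Read transcript models from GTF
#'
#' Exon features must carry `transcript_id`, `gene_id` and a biotype
#' attribute (`biotype`, `transcript_biotype` or `gene_biotype`); the
#' transcript span is the hull of its exons. GTF's 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path GTF file path.
#' @return a [transcript_set()].
#' @export
read_gtf <- function(path) {
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0) {
    return(empty_transcript_set())
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    return(empty_transcript_set())
  }
  meta <- S4Vectors::mcols(gr)
  bt_col <- intersect(c("biotype", "transcript_biotype", "gene_biotype"),
                      names(meta))[1]
  if (is.na(bt_col)) stop("parse error: no biotype attribute in GTF", call. = FALSE)
  ex <- data.frame(
    transcript_id = as.character(meta$transcript_id),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(meta$gene_id),
    biotype = as.character(meta[[bt_col]]),
    stringsAsFactors = FALSE
  )
  if (any(ex$strand == "*")) stop("parse error: unknown strand character", call. = FALSE)
  agg <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(d) {
    data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
               chrom = d$chrom[1], strand = d$strand[1],
               start = min(d$start), end = max(d$end),
               biotype = d$biotype[1], stringsAsFactors = FALSE)
  }))
  transcript_set(agg, ex[, c("transcript_id", "start", "end")])
}

#' Write transcript models to GTF (1-based inclusive)
#' @param ts a [transcript_set()].
#' @param path output path.
#' @export
write_gtf <- function(ts, path) {
  ex <- merge(ts$exons, ts$transcripts[, c("transcript_id", "gene_id", "chrom",
                                           "strand", "biotype")],
              by = "transcript_id", sort = FALSE)
  o <- order(ex$chrom, ex$start)
  ex <- ex[o, ]
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand,
    type = "exon",
    source = "lncarray",
    transcript_id = ex$transcript_id,
    gene_id = ex$gene_id,
    biotype = ex$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from BED12
#'
#' Blocks become exons; the `name` field is used as both transcript and
#' gene id and biotype is inferred from an optional `name` suffix
#' `"|coding"` / `"|lncRNA"` (written by [write_bed12()]).
#' @param path BED12 file path.
#' @return a [transcript_set()].
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) return(empty_transcript_set())
  nm <- as.character(gr$name)
  parts <- strsplit(nm, "|", fixed = TRUE)
  tid <- vapply(parts, `[`, "", 1L)
  gid <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1], "")
  bt <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "coding", "")
  tx <- data.frame(transcript_id = tid, gene_id = gid,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   biotype = bt, stringsAsFactors = FALSE)
  blocks <- gr$blocks
  ex <- do.call(rbind, lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    data.frame(transcript_id = tid[i],
               start = tx$start[i] + IRanges::start(b) - 1L,
               end = tx$start[i] + IRanges::end(b),
               stringsAsFactors = FALSE)
  }))
  transcript_set(tx, ex)
}

#' Write transcript models to BED12 (0-based half-open)
#' @param ts a [transcript_set()].
#' @param path output path.
#' @export
write_bed12 <- function(ts, path) {
  tx <- ts$transcripts
  grl <- GenomicRanges::GRangesList(lapply(seq_len(nrow(tx)), function(i) {
    ex <- ts$exons[ts$exons$transcript_id == tx$transcript_id[i], ]
    GenomicRanges::GRanges(
      seqnames = tx$chrom[i],
      ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
      strand = tx$strand[i]
    )
  }))
  names(grl) <- paste(tx$transcript_id, tx$gene_id, tx$biotype, sep = "|")
  rtracklayer::export(grl, path, format = "bed")
  invisible(path)
}

empty_transcript_set <- function() {
  structure(list(
    transcripts = data.frame(transcript_id = character(), gene_id = character(),
                             chrom = character(), strand = character(),
                             start = integer(), end = integer(),
                             biotype = character(), length = integer(),
                             stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  ), class = "transcript_set")
}
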