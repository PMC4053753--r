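# Readers and writers for the package's plain-text interchange formats.
# All genomic coordinates on disk are 0-based half-open (BED convention);
# conversion to the 1-based closed GRanges convention happens only inside
# the interval-overlap operations.

#' Read or write a probe-level intensity table
#'
#' The probe table is the raw observable of a HELP experiment: one row per
#' probe per channel per array, with columns `probe_id`, `fragment_id`
#' (`"RANDOM"` for background probes), `sample_id`, `group`
#' (`control`/`case`), `channel` (`HpaII`/`MspI`) and `intensity`.
#'
#' @param path Path to a tab-separated file.
#' @return `read_probe_table()`: a `data.table` with the columns above.
#' @export
read_probe_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("probe_id", "fragment_id", "sample_id", "group", "channel", "intensity")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stopf("probe table %s lacks columns: %s", path, paste(missing_cols, collapse = ", "))
  dt
}

#' @rdname read_probe_table
#' @param probes A probe table (`data.frame`/`data.table`).
#' @export
write_probe_table <- function(probes, path) {
  data.table::fwrite(probes, path, sep = "\t")
  invisible(path)
}

#' Read or write BED intervals
#'
#' Minimal BED handling: `chrom`, `start`, `end` are required, `name` and
#' `score` kept when present, any further columns (e.g. narrowPeak extras)
#' are ignored on read. Coordinates are 0-based half-open.
#'
#' @param path File path.
#' @return `read_bed()`: a `data.frame` with columns `chrom`, `start`, `end`
#'   and optionally `name`, `score`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3) stopf("BED file %s has fewer than 3 columns", path)
  cols <- c("chrom", "start", "end", "name", "score")
  data.table::setnames(dt, seq_len(min(ncol(dt), 5)), cols[seq_len(min(ncol(dt), 5))])
  out <- as.data.frame(dt[, seq_len(min(ncol(dt), 5)), with = FALSE])
  if (any(out$end <= out$start)) stopf("BED file %s contains intervals with end <= start", path)
  out
}

#' @rdname read_bed
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score` columns.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(intervals))
  data.table::fwrite(intervals[, cols, drop = FALSE], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read or write refFlat-style gene models
#'
#' Tab-separated with header: `gene`, `chrom`, `strand`, `txStart`, `txEnd`,
#' optional `cdsStart`/`cdsEnd`, and comma-separated `exonStarts`/`exonEnds`.
#' Without coding bounds, UTR categories collapse into `exon` downstream.
#'
#' @param path File path.
#' @return `read_refflat()`: a `data.frame`, exon columns as comma-joined strings.
#' @export
read_refflat <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("exonStarts", "exonEnds")))
  need <- c("gene", "chrom", "strand", "txStart", "txEnd", "exonStarts", "exonEnds")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stopf("gene model table %s lacks columns: %s", path, paste(missing_cols, collapse = ", "))
  as.data.frame(dt)
}

#' @rdname read_refflat
#' @param genes Gene-model data.frame.
#' @export
write_refflat <- function(genes, path) {
  data.table::fwrite(genes, path, sep = "\t")
  invisible(path)
}

#' Read a genome table (chromosome sizes)
#'
#' Two tab-separated columns, `chrom` and `length`, with or without header.
#'
#' @param path File path.
#' @return data.frame with columns `chrom` and `length`.
#' @export
read_genome_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, fixed = TRUE)
  dt <- data.table::fread(path, sep = "\t", header = has_header)
  data.table::setnames(dt, 1:2, c("chrom", "length"))
  as.data.frame(dt[, 1:2])
}

#' Read or write a methylation matrix
#'
#' Fragments x samples of centered log2(HpaII/MspI), serialized with leading
#' annotation columns `fragment_id`, `chrom`, `start`, `end`, `size` followed
#' by one column per sample. Group labels travel in a separate two-column
#' table (`sample_id`, `group`).
#'
#' @param path File path.
#' @param groups Optional named character vector of group labels per sample
#'   (read side: supply to attach labels).
#' @return `read_methylation_matrix()`: a [MethylationMatrix] object.
#' @export
read_methylation_matrix <- function(path, groups = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  ann_cols <- c("fragment_id", "chrom", "start", "end", "size")
  missing_cols <- setdiff(ann_cols, names(dt))
  if (length(missing_cols))
    stopf("matrix file %s lacks columns: %s", path, paste(missing_cols, collapse = ", "))
  samples <- setdiff(names(dt), ann_cols)
  mat <- as.matrix(dt[, samples, with = FALSE])
  rownames(mat) <- dt$fragment_id
  fragments <- as.data.frame(dt[, ann_cols, with = FALSE])
  methylation_matrix(mat, fragments, groups = groups[samples])
}

#' @rdname read_methylation_matrix
#' @param mm A [MethylationMatrix].
#' @export
write_methylation_matrix <- function(mm, path) {
  ann_cols <- c("fragment_id", "chrom", "start", "end", "size")
  out <- data.table::as.data.table(mm$fragments[, ann_cols])
  out <- cbind(out, data.table::as.data.table(mm$values))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a sample group table
#'
#' Two tab-separated columns `sample_id` and `group` (levels `control`, `case`).
#'
#' @param path File path.
#' @return Named character vector of group labels, names = sample ids.
#' @export
read_group_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  data.table::setnames(dt, 1:2, c("sample_id", "group"))
  setNames(as.character(dt$group), dt$sample_id)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

# 0-based half-open data.frame -> GRanges (1-based closed).
as_granges <- function(df, keep = character()) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  gr
}
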