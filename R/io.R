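# Readers/writers for the plain-text formats the pipeline touches.
#
# Internal convention is BED-native: 0-based, half-open intervals everywhere;
# conversion happens only at file boundaries. Chromosome names are matched by
# exact string equality (no "chr" aliasing).

#' Read aligned tags from a 6-column BED file
#'
#' Tags are single-end aligned reads reduced to their 5' coordinate: for a
#' `+` strand entry the 5' end is `start`; for a `-` strand entry it is
#' `end - 1` (0-based). Malformed lines (wrong column count, non-numeric or
#' negative coordinates, bad strand) are skipped and counted.
#'
#' @param path path to a BED6 file.
#' @return a data.frame with columns `chrom`, `pos5`, `strand`, of class
#'   `tag_set`; attributes `total` (number of valid tags) and `n_malformed`.
#' @export
read_tags <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_tags())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf >= 6L
  if (!any(ok)) stop("not a 6-column BED file (no line has >= 6 fields): ", path)
  start <- suppressWarnings(as.numeric(vapply(fields, function(f) f[2], "")))
  end <- suppressWarnings(as.numeric(vapply(fields, function(f) f[3], "")))
  strand <- vapply(fields, function(f) if (length(f) >= 6L) f[6] else NA_character_, "")
  ok <- ok & !is.na(start) & !is.na(end) & start >= 0 & end > start &
    strand %in% c("+", "-")
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    warning(n_bad, " malformed line(s) skipped in ", path)
  }
  chrom <- vapply(fields, `[`, "", 1L)[ok]
  pos5 <- ifelse(strand[ok] == "+", start[ok], end[ok] - 1)
  out <- data.frame(chrom = chrom, pos5 = as.integer(pos5),
                    strand = strand[ok], stringsAsFactors = FALSE)
  as_tag_set(out, n_malformed = n_bad)
}

empty_tags <- function() {
  as_tag_set(data.frame(chrom = character(), pos5 = integer(),
                        strand = character(), stringsAsFactors = FALSE))
}

as_tag_set <- function(df, n_malformed = 0L) {
  stopifnot(all(c("chrom", "pos5", "strand") %in% names(df)))
  if (any(df$pos5 < 0)) stop("negative tag positions are invalid")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  structure(df, class = c("tag_set", "data.frame"),
            total = nrow(df), n_malformed = n_malformed)
}

#' Write tags as BED6
#'
#' Inverse of [read_tags()]: a `+` tag becomes `[pos5, pos5 + read_length)`,
#' a `-` tag `[pos5 - read_length + 1, pos5 + 1)`.
#'
#' @param tags a `tag_set` or data.frame with chrom/pos5/strand.
#' @param path output path.
#' @param read_length nominal read length used to reconstruct the interval.
#' @export
write_tags <- function(tags, path, read_length = 147L) {
  start <- ifelse(tags$strand == "+", tags$pos5, tags$pos5 - read_length + 1L)
  bed <- data.frame(chrom = tags$chrom, start = start,
                    end = start + read_length,
                    name = sprintf("t%d", seq_len(nrow(tags))),
                    score = 0L, strand = tags$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.tag_set <- function(x, ...) {
  cat("Tag set:", nrow(x), "tags on", length(unique(x$chrom)),
      "chromosome(s)\n")
  if (attr(x, "n_malformed") %||% 0L > 0L) {
    cat("  (", attr(x, "n_malformed"), "malformed lines were skipped )\n")
  }
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based) and optionally `tes` (transcript end, 0-based exclusive).
#' @return data.frame sorted by (chrom, tss); duplicate gene ids are an error.
#' @export
read_annotation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df[order(df$chrom, df$tss), , drop = FALSE]
}

#' Read an expression table
#'
#' @param path TSV with header column `gene_id` plus one FPKM column per cell
#'   state; extra columns (e.g. a differential-expression flag) pass through.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("expression table must have gene_id")
  df
}

#' Write a per-bin value track as bedGraph
#'
#' Bins must be sorted and non-overlapping per chromosome; runs of adjacent
#' equal-valued bins are merged into one line. Values are printed with fixed
#' precision so a read/write round trip reproduces them.
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @param digits printed decimal digits.
#' @export
write_bedgraph <- function(track, path, digits = 6L) {
  if (nrow(track)) {
    for (ch in unique(track$chrom)) {
      b <- track[track$chrom == ch, ]
      if (is.unsorted(b$start, strictly = TRUE)) {
        stop("bedGraph bins must be sorted by start within chromosome ", ch)
      }
      if (any(b$start[-1] < b$end[-nrow(b)])) {
        stop("bedGraph bins overlap on chromosome ", ch)
      }
    }
  }
  val <- round(track$value, digits)
  # merge adjacent equal-valued bins
  keep <- logical(nrow(track))
  out <- track[0, ]
  if (nrow(track)) {
    runs <- cumsum(c(TRUE, !(track$chrom[-1] == track$chrom[-nrow(track)] &
                               track$start[-1] == track$end[-nrow(track)] &
                               val[-1] == val[-nrow(track)])))
    out <- data.frame(
      chrom = tapply(track$chrom, runs, `[`, 1L),
      start = as.vector(tapply(track$start, runs, min)),
      end = as.vector(tapply(track$end, runs, max)),
      value = as.vector(tapply(val, runs, `[`, 1L)),
      stringsAsFactors = FALSE
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(out)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", out$chrom, as.integer(out$start),
                       as.integer(out$end),
                       formatC(out$value, digits = digits, format = "f")),
               con)
  }
  invisible(path)
}

#' Read a bedGraph track
#' @param path bedGraph file written by [write_bedgraph()].
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  df
}

#' Write a nucleosome-call table (BED6+3: read_count, occupancy, fuzziness)
#' @param calls a `nuc_calls` data.frame.
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  bed <- data.frame(chrom = calls$chrom, start = calls$dyad - 73L,
                    end = calls$dyad + 74L,
                    name = sprintf("nuc%d", seq_len(nrow(calls))),
                    score = calls$read_count, strand = ".",
                    read_count = calls$read_count,
                    occupancy = calls$occupancy,
                    fuzziness = calls$fuzziness)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
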