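#' Read a per-cytosine methylation count table
#'
#' Reads per-cytosine methylated/unmethylated read counts in either the
#' package's native TSV layout (columns \code{chrom}, \code{pos},
#' \code{strand}, \code{context}, \code{meth}, \code{unmeth}; \code{#}
#' comment lines ignored) or the Bismark cytosine ("CX") report dialect
#' (columns chrom, pos, strand, count_meth, count_unmeth, context,
#' trinucleotide). Positions are 1-based. Zero-coverage cytosines are
#' retained: they are legitimate smoothing neighbours. Duplicate
#' (chrom, pos, strand) rows are rejected.
#'
#' @param path Path to the table.
#' @param dialect \code{"native-tsv"} (default) or \code{"bismark-cx"}.
#' @return data.frame with columns \code{chrom}, \code{pos},
#'   \code{strand}, \code{context}, \code{meth}, \code{unmeth}, sorted by
#'   (chrom, pos).
#' @export
readCytosineTable <- function(path, dialect = c("native-tsv", "bismark-cx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- if (dialect == "native-tsv")
    c("chrom", "pos", "strand", "context", "meth", "unmeth")
  else
    c("chrom", "pos", "strand", "meth", "unmeth", "context", "tri")
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineNo <- which(keep)
  if (!any(keep))
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      meth = integer(0), unmeth = integer(0)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols)))
    stop(sprintf("malformed line %d in %s (expected %d fields, got %d)",
                 lineNo[which(nf != length(cols))[1L]], path,
                 length(cols), nf[which(nf != length(cols))[1L]]),
         call. = FALSE)
  m <- matrix(unlist(fields), ncol = length(cols), byrow = TRUE,
              dimnames = list(NULL, cols))
  df <- data.frame(chrom = m[, "chrom"],
                   pos = suppressWarnings(as.numeric(m[, "pos"])),
                   strand = m[, "strand"], context = m[, "context"],
                   meth = suppressWarnings(as.numeric(m[, "meth"])),
                   unmeth = suppressWarnings(as.numeric(m[, "unmeth"])))
  bad <- which(is.na(df$pos) | is.na(df$meth) | is.na(df$unmeth) |
               df$pos < 1 | df$meth < 0 | df$unmeth < 0 |
               df$pos != floor(df$pos))
  if (length(bad))
    stop(sprintf("malformed line %d in %s", lineNo[bad[1L]], path),
         call. = FALSE)
  checkContext(df$context)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' in ", path, call. = FALSE)
  key <- paste(df$chrom, df$pos, df$strand)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos, strand) position in ", path, call. = FALSE)
  df$pos <- as.integer(df$pos)
  df$meth <- as.integer(df$meth)
  df$unmeth <- as.integer(df$unmeth)
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  df
}

#' Write a per-cytosine table in the native TSV layout
#'
#' @param records data.frame as returned by [readCytosineTable()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCytosineTable <- function(records, path) {
  data.table::fwrite(records[, c("chrom", "pos", "strand", "context",
                                 "meth", "unmeth")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read genomic feature annotations from BED or GFF3
#'
#' Parses feature intervals and normalises coordinates to the package's
#' internal convention (1-based, inclusive): BED input (0-based,
#' half-open) is shifted, GFF3 is kept as is. Features of zero or negative
#' length after conversion are an error. Feature kind (\code{PCG} /
#' \code{TE}) and compartment (\code{pericentromeric_het} /
#' \code{euchromatin}) may be supplied in the BED name field as
#' \code{id|kind|compartment} or in GFF3 attributes \code{ID}, \code{kind},
#' \code{compartment}; missing labels are left \code{NA}.
#'
#' @param path Path to the annotation file.
#' @param format \code{"BED"} or \code{"GFF3"}.
#' @return \code{GRanges} with metadata columns \code{id}, \code{kind},
#'   \code{compartment}.
#' @export
readFeatures <- function(path, format = c("BED", "GFF3")) {
  format <- match.arg(format)
  gr <- if (format == "BED") rtracklayer::import(path, format = "bed")
        else rtracklayer::import(path, format = "gff3")
  if (any(GenomicRanges::width(gr) < 1L))
    stop("feature with start > end after coordinate conversion", call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (format == "BED") {
    nm <- if (!is.null(mc$name)) mc$name else rep(NA_character_, length(gr))
    parts <- strsplit(ifelse(is.na(nm), "", nm), "|", fixed = TRUE)
    id <- vapply(parts, function(p) if (length(p) >= 1 && nzchar(p[1]))
      p[1] else NA_character_, character(1))
    kind <- vapply(parts, function(p) if (length(p) >= 2) p[2]
      else NA_character_, character(1))
    comp <- vapply(parts, function(p) if (length(p) >= 3) p[3]
      else NA_character_, character(1))
  } else {
    id <- if (!is.null(mc$ID)) as.character(mc$ID) else rep(NA_character_, length(gr))
    kind <- if (!is.null(mc$kind)) as.character(mc$kind) else rep(NA_character_, length(gr))
    comp <- if (!is.null(mc$compartment)) as.character(mc$compartment)
            else rep(NA_character_, length(gr))
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(id = id, kind = kind,
                                               compartment = comp)
  gr
}

#' Write DMRs as BED6+ and read them back
#'
#' \code{writeDmrs} writes one row per DMR with BED coordinates (0-based,
#' half-open) in the first three columns, the context as name, a dummy
#' score and the type as strand-agnostic extra columns:
#' \code{chrom, bedStart, bedEnd, context, score, strand, type, nDmcs,
#' pValue, fdr, rateWT, rateMut, diff}. \code{readDmrs} reads such a file
#' back into an identical \code{GRanges} (round-trip identity).
#'
#' @param dmrs \code{GRanges} from [callDmrs()].
#' @param path Output path.
#' @return \code{writeDmrs}: \code{path} invisibly; \code{readDmrs}: a
#'   \code{GRanges}.
#' @export
writeDmrs <- function(dmrs, path) {
  mc <- S4Vectors::mcols(dmrs)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dmrs)),
    bedStart = GenomicRanges::start(dmrs) - 1L,
    bedEnd = GenomicRanges::end(dmrs),
    context = mc$context, score = rep(0L, length(dmrs)),
    strand = rep(".", length(dmrs)),
    type = mc$type, nDmcs = mc$nDmcs, pValue = mc$pValue, fdr = mc$fdr,
    rateWT = mc$rateWT, rateMut = mc$rateMut, diff = mc$diff)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(format(df, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' @rdname writeDmrs
#' @export
readDmrs <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  df <- if (length(lines) > 1L)
    as.data.frame(data.table::fread(text = lines[-1L], header = FALSE,
                                    sep = "\t", col.names = cols))
  else NULL
  if (is.null(df) || nrow(df) == 0L)
    return(dmrFrameToGRanges(
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 context = character(0), type = character(0),
                 nDmcs = integer(0), pValue = numeric(0), fdr = numeric(0),
                 rateWT = numeric(0), rateMut = numeric(0),
                 diff = numeric(0))))
  dmrFrameToGRanges(data.frame(
    chrom = as.character(df$chrom), start = df$bedStart + 1L, end = df$bedEnd,
    context = df$context, type = df$type, nDmcs = as.integer(df$nDmcs),
    pValue = df$pValue, fdr = df$fdr, rateWT = df$rateWT,
    rateMut = df$rateMut, diff = df$diff))
}

#' Read/write a per-locus count table as TSV
#'
#' The TSV has a locus id column, one integer column per library, and two
#' trailing header comment lines carrying locus lengths and library sizes
#' would be fragile; instead lengths are a column and library sizes a
#' \code{#libSizes} header line.
#'
#' @param x A [LocusCounts-class].
#' @param path File path.
#' @return \code{writeLocusCounts}: \code{path} invisibly;
#'   \code{readLocusCounts}: a \code{LocusCounts}.
#' @export
writeLocusCounts <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#libSizes\t",
                    paste(format(libSizes(x), scientific = FALSE, trim = TRUE),
                          collapse = "\t")), con)
  df <- data.frame(locus = rownames(counts(x)), length = locusLengths(x),
                   counts(x), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLocusCounts
#' @export
readLocusCounts <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#libSizes"))
    stop("missing #libSizes header in ", path, call. = FALSE)
  sizes <- as.numeric(strsplit(first, "\t")[[1L]][-1L])
  df <- as.data.frame(data.table::fread(path, skip = 1L, header = TRUE,
                                        sep = "\t"))
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$locus
  LocusCounts(m, lengths = df$length, libSizes = sizes)
}
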