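## Readers and writers: FASTQ-dialect / plain-text reads, gene maps,
## annotation and PAV lists, and TSV tables (headers, 6 significant digits).

#' Read raw tag reads (FASTQ dialect or one read per line)
#'
#' Auto-detects 4-line FASTQ (first character \code{@}) versus plain text;
#' gzip-compressed files are accepted transparently.
#'
#' @param path file path.
#' @return character vector of reads.
#' @export
readTagReads <- function(path) {
  if (!file.exists(path)) stop("read file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) return(character())
  if (startsWith(lines[1], "@")) {
    if (length(lines) %% 4L != 0L) {
      stop("malformed FASTQ (line count not a multiple of 4): ", path,
           call. = FALSE)
    }
    lines[seq(2L, length(lines), by = 4L)]
  } else {
    lines[nzchar(lines)]
  }
}

#' Write raw tag reads
#'
#' @param reads character vector of reads.
#' @param path output path (\code{.gz} compresses).
#' @param format \code{"fastq"} (constant quality \code{I}) or \code{"txt"}.
#' @export
writeTagReads <- function(reads, path, format = c("fastq", "txt")) {
  format <- match.arg(format)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (format == "fastq") {
    n <- length(reads)
    out <- character(4L * n)
    out[seq(1L, by = 4L, length.out = n)] <- paste0("@read_", seq_len(n))
    out[seq(2L, by = 4L, length.out = n)] <- reads
    out[seq(3L, by = 4L, length.out = n)] <- "+"
    out[seq(4L, by = 4L, length.out = n)] <- strrep("I", nchar(reads))
    writeLines(out, con)
  } else {
    writeLines(reads, con)
  }
  invisible(path)
}

#' Read a reference transcriptome FASTA
#'
#' @param path FASTA file; CRLF endings are handled; sequence names are
#'   truncated at the first whitespace.
#' @return named \link[Biostrings]{DNAStringSet}.
#' @export
readReferenceFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path))
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("malformed FASTA (no header line): ", path,
                      call. = FALSE)
  rec <- cumsum(hdr)
  seq_bad <- !hdr & grepl("[^ACGTNacgtn]", lines) & nzchar(lines)
  if (any(seq_bad)) {
    ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
    stop("non-ACGTN characters in record(s): ",
         paste(head(unique(ids[rec[seq_bad]]), 3), collapse = ", "),
         call. = FALSE)
  }
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  dna
}

#' Write a TSV table (header, floats at 6 significant digits)
#'
#' @param x data.frame.
#' @param path output path.
#' @export
writeTsv <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) signif(v, 6))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("TSV not found: ", path, call. = FALSE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "",
             encoding = "UTF-8")
}

#' Read a gene map (gene_id, transcript_id TSV)
#' @param path TSV with columns \code{gene_id} and \code{transcript_id}.
#' @return data.frame.
#' @export
readGeneMap <- function(path) {
  gm <- readTsv(path)
  if (!all(c("gene_id", "transcript_id") %in% names(gm))) {
    stop("gene map needs columns gene_id, transcript_id: ", path,
         call. = FALSE)
  }
  gm
}

#' Read a flat gene-to-term annotation (2-column TSV)
#' @param path TSV with columns \code{gene_id} and \code{term_id}.
#' @return data.frame.
#' @export
readAnnotation <- function(path) {
  an <- readTsv(path)
  if (!all(c("gene_id", "term_id") %in% names(an))) {
    stop("annotation needs columns gene_id, term_id: ", path, call. = FALSE)
  }
  an
}

#' Read a PAV gene list (gene_id, present_in_genome TSV)
#' @param path TSV with columns \code{gene_id} and \code{present_in_genome}
#'   (values "P"/"M").
#' @return data.frame.
#' @export
readPavList <- function(path) {
  pv <- readTsv(path)
  if (!all(c("gene_id", "present_in_genome") %in% names(pv))) {
    stop("PAV list needs columns gene_id, present_in_genome: ", path,
         call. = FALSE)
  }
  pv
}

#' Write / read a trio expression table
#'
#' The TSV holds one gene per row with per-library counts and TPM; the
#' clean-tag totals travel in a leading comment line so the container
#' round-trips exactly.
#'
#' @param x a \linkS4class{DgeExperiment}.
#' @param path TSV path.
#' @export
writeExpressionTable <- function(x, path) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  tpm <- SummarizedExperiment::assay(x, "tpm")
  libs <- colnames(x)
  header <- paste0("#clean_total\t",
                   paste(libs, x$clean_total, sep = "=", collapse = "\t"))
  df <- data.frame(gene_id = rownames(cnt), stringsAsFactors = FALSE)
  for (l in libs) df[[paste0("count_", l)]] <- cnt[, l]
  for (l in libs) df[[paste0("tpm_", l)]] <- tpm[, l]
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname writeExpressionTable
#' @export
readExpressionTable <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#clean_total")) {
    stop("not an expression table (missing #clean_total header): ", path,
         call. = FALSE)
  }
  kv <- strsplit(strsplit(header, "\t")[[1]][-1], "=", fixed = TRUE)
  totals <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                     vapply(kv, `[`, "", 1))
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1L,
                   stringsAsFactors = FALSE)
  libs <- names(totals)
  cnt <- as.matrix(df[paste0("count_", libs)])
  dimnames(cnt) <- list(df$gene_id, libs)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt, tpm = tpmNormalize(cnt, totals)),
    colData = S4Vectors::DataFrame(clean_total = unname(totals),
                                   row.names = libs))
  methods::new("DgeExperiment", se)
}
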