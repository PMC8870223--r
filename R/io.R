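# Readers and writers for the plain-text formats the pipeline touches.
# All interval files on disk are 0-based half-open (BED convention);
# in-memory intervals are 1-based closed GRanges.  The two explicit
# converters below are exact inverses.

#' Coordinate conversions between BED (0-based half-open) and GRanges
#'
#' @param chrom,start0,end0 BED-style fields.
#' @return `bed_to_granges` returns a `GRanges`; `granges_to_bed` a
#'   data.frame with `chrom`, `start0`, `end0`.
#' @export
bed_to_granges <- function(chrom, start0, end0) {
  if (any(start0 >= end0)) stopf("interval with start >= end")
  if (any(start0 < 0)) stopf("negative interval start")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
}

#' @rdname bed_to_granges
#' @param gr a `GRanges`.
#' @export
granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

.read_tsv <- function(path, header = TRUE, col.names = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  args <- list(path, sep = "\t", header = header, stringsAsFactors = FALSE,
               quote = "", comment.char = "")
  if (!is.null(col.names)) args$col.names <- col.names
  do.call(read.table, args)
}

.write_tsv <- function(d, path, col.names = TRUE) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
}

#' Read and write count tables
#'
#' Counts are stored as TSV with a `feature` first column and one column
#' per sample.  Condition labels live in a separate two-column sample
#' sheet (`sample`, `condition`).
#'
#' @param path counts TSV path.
#' @param sample_sheet path of the sample sheet, or a data.frame, or NULL
#'   to return a bare matrix.
#' @param lengths optional named lengths vector attached to the result.
#' @return [count_matrix()] (or plain matrix when no sample sheet).
#' @export
read_counts <- function(path, sample_sheet = NULL, lengths = NULL) {
  d <- .read_tsv(path)
  if (names(d)[1] != "feature")
    stopf("%s: first column must be 'feature' (got '%s')", path, names(d)[1])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m != round(m)))
    stopf("%s: non-integer counts", path)
  rownames(m) <- d$feature
  if (is.null(sample_sheet)) return(m)
  ss <- if (is.character(sample_sheet)) .read_tsv(sample_sheet) else sample_sheet
  cond <- setNames(ss$condition, ss$sample)[colnames(m)]
  if (anyNA(cond)) stopf("sample sheet lacks condition for some samples")
  if (!is.null(lengths)) lengths <- lengths[rownames(m)]
  count_matrix(m, condition = cond, lengths = lengths)
}

#' @rdname read_counts
#' @param cm a [count_matrix()] or matrix.
#' @export
write_counts <- function(cm, path) {
  d <- data.frame(feature = rownames(cm), unclass(as.matrix(cm)),
                  check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(d, path)
  invisible(path)
}

#' @rdname read_counts
#' @export
write_sample_sheet <- function(cm, path) {
  .write_tsv(data.frame(sample = colnames(cm), condition = conditions(cm)),
             path)
  invisible(path)
}

#' Read and write narrowPeak files
#'
#' Ten-column BED dialect: chrom, start, end, name, score, strand,
#' signalValue, pValue, qValue, summit offset from start (-1 = absent).
#' Summits are stored in memory as absolute 1-based positions in a
#' `summit` metadata column; the `score` column carries reference-peak
#' support when writing a compiled reference.
#'
#' @param path file path.
#' @return `GRanges` with `summit`, `score`, `name` metadata.
#' @export
read_narrowpeak <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "summit_offset")
  d <- .read_tsv(path, header = FALSE, col.names = cols)
  bad <- which(d$start >= d$end)
  if (length(bad))
    stopf("%s: start >= end at line %d", path, bad[1])
  bad <- which(d$summit_offset != -1 &
                 (d$summit_offset < 0 | d$summit_offset >= d$end - d$start))
  if (length(bad))
    stopf("%s: summit offset outside peak at line %d", path, bad[1])
  gr <- bed_to_granges(d$chrom, d$start, d$end)
  gr$name <- d$name
  gr$score <- d$score
  gr$summit <- ifelse(d$summit_offset == -1, NA_integer_,
                      d$start + d$summit_offset + 1L)  # absolute, 1-based
  names(gr) <- d$name
  gr
}

#' @rdname read_narrowpeak
#' @param gr `GRanges` with optional `summit` (absolute 1-based), `score`.
#' @export
write_narrowpeak <- function(gr, path) {
  bed <- granges_to_bed(gr)
  summit <- if (!is.null(gr$summit))
    ifelse(is.na(gr$summit), -1L, gr$summit - 1L - bed$start0) else -1L
  d <- data.frame(bed$chrom, bed$start0, bed$end0,
                  name = names(gr) %||% paste0("peak_", seq_along(gr)),
                  score = if (!is.null(gr$score)) gr$score else 0L,
                  strand = ".", signal = 0, pvalue = -1, qvalue = -1,
                  summit = summit)
  .write_tsv(d, path, col.names = FALSE)
  invisible(path)
}

#' Read and write BED6 interval files
#'
#' @param path file path.
#' @return `GRanges` with `name`, `score` metadata.
#' @export
read_bed6 <- function(path) {
  d <- .read_tsv(path, header = FALSE,
                 col.names = c("chrom", "start", "end", "name", "score", "strand"))
  bad <- which(d$start >= d$end)
  if (length(bad)) stopf("%s: start >= end at line %d", path, bad[1])
  gr <- bed_to_granges(d$chrom, d$start, d$end)
  gr$name <- d$name
  gr$score <- d$score
  gr
}

#' @rdname read_bed6
#' @param gr a `GRanges`.
#' @export
write_bed6 <- function(gr, path) {
  bed <- granges_to_bed(gr)
  d <- data.frame(bed$chrom, bed$start0, bed$end0,
                  name = gr$name %||% paste0("iv_", seq_along(gr)),
                  score = gr$score %||% 0L,
                  strand = ".")
  .write_tsv(d, path, col.names = FALSE)
  invisible(path)
}

#' Read and write gene-model tables
#'
#' TSV with header `gene`, `chrom`, `strand`, `tss0`, `length`; the TSS
#' is stored 0-based on disk and converted to the in-memory 1-based
#' `tss`.
#'
#' @param path file path.
#' @return data.frame with `gene`, `chrom`, `strand`, `tss`, `length`.
#' @export
read_gene_models <- function(path) {
  d <- .read_tsv(path)
  need <- c("gene", "chrom", "strand", "tss0", "length")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  out <- data.frame(gene = d$gene, chrom = d$chrom, strand = d$strand,
                    tss = d$tss0 + 1L, length = d$length,
                    stringsAsFactors = FALSE)
  check_gene_models(out)
  out
}

#' @rdname read_gene_models
#' @param gm in-memory gene models (1-based `tss`).
#' @export
write_gene_models <- function(gm, path) {
  .write_tsv(data.frame(gene = gm$gene, chrom = gm$chrom, strand = gm$strand,
                        tss0 = gm$tss - 1L, length = gm$length), path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a line are dropped with a warning.
#'
#' @param path file path.
#' @return Named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3)
  if (length(short)) stopf("%s: line %d has fewer than 3 fields", path, short[1])
  sets <- lapply(seq_along(parts), function(i) {
    members <- parts[[i]][-(1:2)]
    if (anyDuplicated(members)) {
      warnf("%s: line %d has duplicate members; deduplicated", path, i)
      members <- unique(members)
    }
    members
  })
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions (default "na").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write rnk ranking files
#'
#' Two tab-separated columns, gene and score, no header, sorted
#' descending by score.
#'
#' @param path file path.
#' @return data.frame with `gene`, `score`.
#' @export
read_rnk <- function(path) {
  d <- .read_tsv(path, header = FALSE, col.names = c("gene", "score"))
  if (!is.numeric(d$score)) stopf("%s: non-numeric scores", path)
  if (anyDuplicated(d$gene)) stopf("%s: duplicate gene symbols", path)
  d
}

#' @rdname read_rnk
#' @param rnk data.frame with `gene`, `score`.
#' @export
write_rnk <- function(rnk, path) {
  .write_tsv(data.frame(rnk$gene, sprintf("%.6g", rnk$score)), path,
             col.names = FALSE)
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings.
#'
#' @param path file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read and write MEME-minimal motif files
#'
#' Supports the minimal MEME text format: version line, optional ALPHABET
#' and background lines, then per motif a `MOTIF name` line, a
#' `letter-probability matrix:` header and the probability rows.
#'
#' @param path file path.
#' @param pseudo pseudo-count passed to [motif_model()].
#' @return Named list of [motif_model()] objects.
#' @export
read_meme <- function(path, pseudo = 0.1) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    tok <- strsplit(lines[bg_i[1] + 1], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    bg <- vals[!is.na(vals)]
    if (length(bg) != 4) stopf("%s: malformed background line", path)
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stopf("%s: no MOTIF entries", path)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(lines[s], "\\s+")[[1]][2]
    h <- s + grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    if (is.na(w)) stopf("%s: motif %s lacks w= in matrix header", path, name)
    rows <- lines[(h + 1):(h + w)]
    probs <- t(vapply(rows, function(r) {
      v <- as.numeric(strsplit(r, "\\s+")[[1]])
      if (length(v) != 4 || anyNA(v)) stopf("%s: malformed matrix row '%s'", path, r)
      v
    }, numeric(4)))
    pm <- t(probs)
    dimnames(pm) <- NULL
    motifs[[name]] <- motif_model(name, pm, background = bg, pseudo = pseudo)
  }
  motifs
}

#' @rdname read_meme
#' @param motifs named list of [motif_model()] objects.
#' @export
write_meme <- function(motifs, path) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           paste(sprintf("%s %.5f", c("A", "C", "G", "T"),
                         motifs[[1]]$background), collapse = " "), "")
  for (m in motifs) {
    out <- c(out, paste("MOTIF", m$name),
             sprintf("letter-probability matrix: alength= 4 w= %d", m$width),
             apply(m$probs, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read and write patient cohort tables
#'
#' TSV with header `patient`, `time`, `event`, then one expression column
#' per gene (wide form used by the screen).  The four-column long form
#' (`patient`, `expression`, `time`, `event`) for a single gene is also
#' accepted.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  d <- .read_tsv(path)
  if (!all(c("patient", "time", "event") %in% names(d)))
    stopf("%s: cohort table needs patient/time/event columns", path)
  if (any(d$time <= 0)) stopf("%s: non-positive survival time", path)
  if (!all(d$event %in% c(0, 1))) stopf("%s: event must be 0/1", path)
  d
}

#' @rdname read_cohort
#' @param cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  num <- vapply(cohort, is.numeric, TRUE) & !(names(cohort) %in% c("time", "event"))
  cohort[num] <- lapply(cohort[num], function(x) as.numeric(sprintf("%.6g", x)))
  .write_tsv(cohort, path)
  invisible(path)
}
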