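# External formats and the internal coordinate convention.
#
# Everything inside the package is 0-based half-open. GTF (1-based closed)
# and EricScript-style breakpoints (1-based) are converted exactly once, at
# the file boundary. A ChimeraCall stores breakpoint5 as the 0-based genomic
# position of the LAST transcribed base of the 5' segment and breakpoint3 as
# the position of the FIRST transcribed base of the 3' segment.

#' Construct a set of gene models
#'
#' A `gene_models` object holds one record per gene (id, symbol, chromosome,
#' strand) and an exon table in 0-based half-open coordinates, sorted by
#' start and non-overlapping within each gene.
#'
#' @param exons data.frame with columns `gene_id`, `symbol`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), one row per exon.
#' @return an object of class `gene_models` with elements `genes` (one row
#'   per gene) and `exons`.
#' @export
gene_models <- function(exons) {
  need <- c("gene_id", "symbol", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss))
    stop("exon table is missing column(s): ", paste(miss, collapse = ", "))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start)) {
    bad <- which(exons$end <= exons$start)[1]
    stop("invalid exon interval (end <= start) for gene ", exons$gene_id[bad])
  }
  if (!all(exons$strand %in% c("+", "-")))
    stop("exon strand must be '+' or '-'")
  # per-gene consistency
  for (col in c("chrom", "strand", "symbol")) {
    n_per <- tapply(exons[[col]], exons$gene_id, function(v) length(unique(v)))
    if (any(n_per > 1))
      stop("gene ", names(n_per)[which(n_per > 1)[1]],
           " has inconsistent ", col, " across exon records")
  }
  exons <- exons[order(exons$chrom, exons$gene_id, exons$start), , drop = FALSE]
  # merge overlapping or book-ended exons within a gene
  merged <- lapply(split(exons, exons$gene_id), function(df) {
    ir <- IRanges::IRanges(start = df$start + 1L, end = df$end) # to 1-based closed
    red <- IRanges::reduce(ir, min.gapwidth = 1L)               # merges book-ended
    data.frame(gene_id = df$gene_id[1], symbol = df$symbol[1],
               chrom = df$chrom[1], strand = df$strand[1],
               start = IRanges::start(red) - 1L, end = IRanges::end(red),
               stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, merged)
  rownames(exons) <- NULL
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(df) {
    data.frame(gene_id = df$gene_id[1], symbol = df$symbol[1],
               chrom = df$chrom[1], strand = df$strand[1],
               start = min(df$start), end = max(df$end),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read gene models from a GTF/GFF file
#'
#' Reads exon records, converts GTF 1-based closed coordinates to the
#' internal 0-based half-open convention, merges overlapping or book-ended
#' exons per gene, and orders genes deterministically by
#' (chromosome, start, gene_id).
#'
#' @param path GTF file; exon records must carry a `gene_id` attribute
#'   (`gene_name` used as symbol when present).
#' @return a [gene_models()] object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  # light pre-scan so malformed lines are reported with their line number
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("invalid exon interval at GTF line ", i, ": end < start")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0) stop("no exon records in ", path)
  gene_id <- as.character(gr$gene_id)
  if (any(is.na(gene_id) | gene_id == ""))
    stop("exon record without gene_id attribute in ", path)
  symbol <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else gene_id
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]
  chr_per_gene <- tapply(as.character(GenomicRanges::seqnames(gr)), gene_id,
                         function(v) length(unique(v)))
  if (any(chr_per_gene > 1))
    stop("gene ", names(chr_per_gene)[which(chr_per_gene > 1)[1]],
         " spans multiple chromosomes")
  exons <- data.frame(
    gene_id = gene_id, symbol = symbol,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  gene_models(exons)
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_annotation()]: emits one exon feature per exon, 1-based
#' closed coordinates, `gene_id`/`gene_name` attributes.
#'
#' @param models a [gene_models()] object.
#' @param path output file path.
#' @export
write_annotation <- function(models, path) {
  ex <- models$exons
  attrs <- sprintf('gene_id "%s"; gene_name "%s";', ex$gene_id, ex$symbol)
  lines <- paste(ex$chrom, "chimeraScreen", "exon", ex$start + 1L, ex$end,
                 ".", ex$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# EricScript-style chimera call tables

.call_cols <- c("GeneName1", "GeneName2", "chr1", "Breakpoint1", "strand1",
                "chr2", "Breakpoint2", "strand2", "crossingreads",
                "spanningreads", "JunctionSequence")

#' Read an EricScript-style chimera call table
#'
#' Parses a tab-separated caller output with columns `GeneName1`,
#' `GeneName2`, `chr1`, `Breakpoint1`, `strand1`, `chr2`, `Breakpoint2`,
#' `strand2`, `crossingreads`, `spanningreads`, `JunctionSequence`
#' (optionally `call_id`, `SplitIndex`, `EricScore`). File breakpoints are
#' 1-based and converted to the internal 0-based convention; junction
#' sequences are uppercased. The junction split index is taken from the
#' `SplitIndex` column (number of 5' bases) when present, otherwise the
#' midpoint of an even-length junction sequence; odd-length unmarked
#' sequences are rejected. Rejected rows are reported in the `rejected`
#' attribute, not silently dropped.
#'
#' @param path TSV file with a header row.
#' @return a `chimera_calls` data.frame with columns `call_id`, `gene5`,
#'   `gene3`, `chrom5`, `chrom3`, `breakpoint5`, `breakpoint3`, `strand5`,
#'   `strand3`, `junction_seq`, `split_index`, `crossing_reads`,
#'   `spanning_reads`, `caller_score`; attribute `rejected` is a data.frame
#'   of (row, reason).
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("call table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  miss <- setdiff(.call_cols, names(df))
  if (length(miss))
    stop("call table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(empty_calls())

  bp1 <- suppressWarnings(as.integer(df$Breakpoint1))
  bp2 <- suppressWarnings(as.integer(df$Breakpoint2))
  cross <- suppressWarnings(as.integer(df$crossingreads))
  span <- suppressWarnings(as.integer(df$spanningreads))
  jseq <- toupper(df$JunctionSequence)
  split_idx <- if ("SplitIndex" %in% names(df))
    suppressWarnings(as.integer(df$SplitIndex)) else rep(NA_integer_, nrow(df))
  use_mid <- is.na(split_idx)
  split_idx[use_mid] <- ifelse(nchar(jseq[use_mid]) %% 2L == 0L,
                               nchar(jseq[use_mid]) %/% 2L, NA_integer_)

  reasons <- character(nrow(df))
  reasons[is.na(bp1) | is.na(bp2)] <- "unparseable breakpoint"
  reasons[reasons == "" & (is.na(cross) | is.na(span) | cross < 0 | span < 0)] <-
    "invalid read-support count"
  reasons[reasons == "" & is.na(split_idx)] <-
    "odd-length junction sequence without SplitIndex"
  reasons[reasons == "" & !grepl("^[ACGTN]+$", jseq)] <-
    "junction sequence has non-ACGTN characters"
  reasons[reasons == "" & !(split_idx >= 1 & split_idx < nchar(jseq))] <-
    "split index outside junction sequence"
  reasons[reasons == "" &
            !(df$strand1 %in% c("+", "-") & df$strand2 %in% c("+", "-"))] <-
    "invalid strand"

  keep <- reasons == ""
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  df <- df[keep, , drop = FALSE]

  call_id <- if ("call_id" %in% names(df)) df$call_id else
    make.unique(paste0(df$GeneName1, "--", df$GeneName2), sep = "_")
  out <- data.frame(
    call_id = call_id,
    gene5 = df$GeneName1, gene3 = df$GeneName2,
    chrom5 = df$chr1, chrom3 = df$chr2,
    breakpoint5 = bp1[keep] - 1L,  # 1-based file -> 0-based internal
    breakpoint3 = bp2[keep] - 1L,
    strand5 = df$strand1, strand3 = df$strand2,
    junction_seq = jseq[keep], split_index = split_idx[keep],
    crossing_reads = cross[keep], spanning_reads = span[keep],
    caller_score = if ("EricScore" %in% names(df))
      suppressWarnings(as.numeric(df$EricScore)) else NA_real_,
    stringsAsFactors = FALSE)
  same <- out$gene5 == out$gene3 & out$breakpoint5 == out$breakpoint3 &
    out$chrom5 == out$chrom3
  if (any(same))
    stop("call ", out$call_id[which(same)[1]],
         ": identical genes and breakpoints on both sides")
  if (anyDuplicated(out$call_id))
    stop("duplicate call_id in ", path)
  class(out) <- c("chimera_calls", "data.frame")
  attr(out, "rejected") <- rejected
  out
}

empty_calls <- function() {
  out <- data.frame(call_id = character(), gene5 = character(),
                    gene3 = character(), chrom5 = character(),
                    chrom3 = character(), breakpoint5 = integer(),
                    breakpoint3 = integer(), strand5 = character(),
                    strand3 = character(), junction_seq = character(),
                    split_index = integer(), crossing_reads = integer(),
                    spanning_reads = integer(), caller_score = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("chimera_calls", "data.frame")
  attr(out, "rejected") <- data.frame(row = integer(), reason = character())
  out
}

#' Write chimera calls in the EricScript-style layout
#'
#' Inverse of [read_calls()]; breakpoints are written 1-based and the split
#' index is preserved in a `SplitIndex` column.
#'
#' @param calls a `chimera_calls` data.frame.
#' @param path output TSV path.
#' @export
write_calls <- function(calls, path) {
  df <- data.frame(
    call_id = calls$call_id,
    GeneName1 = calls$gene5, GeneName2 = calls$gene3,
    chr1 = calls$chrom5, Breakpoint1 = calls$breakpoint5 + 1L,
    strand1 = calls$strand5,
    chr2 = calls$chrom3, Breakpoint2 = calls$breakpoint3 + 1L,
    strand2 = calls$strand3,
    crossingreads = calls$crossing_reads,
    spanningreads = calls$spanning_reads,
    JunctionSequence = calls$junction_seq,
    SplitIndex = calls$split_index,
    EricScore = ifelse(is.na(calls$caller_score), "",
                       format(calls$caller_score, digits = 6)),
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Background panel (normal-tissue chimera catalog)

#' Read or build a background panel of chimeras
#'
#' The panel keys chimeras by the ordered gene pair (`gene5` before `gene3`;
#' A->B is distinct from B->A), optionally with breakpoint coordinates for
#' breakpoint-level matching.
#'
#' @param path TSV with columns `gene5`, `gene3` and optionally `chrom5`,
#'   `breakpoint5`, `chrom3`, `breakpoint3` (1-based in the file). A leading
#'   `#source=...` comment line, when present, sets the source label.
#' @return a `background_panel` data.frame with attribute `source_label`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  first <- readLines(path, n = 1)
  label <- if (grepl("^#source=", first)) sub("^#source=", "", first) else
    "background panel"
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", colClasses = "character")
  if (!all(c("gene5", "gene3") %in% names(df)))
    stop("panel must have columns gene5 and gene3")
  for (col in c("breakpoint5", "breakpoint3"))
    if (col %in% names(df))
      df[[col]] <- suppressWarnings(as.integer(df[[col]])) - 1L
  key <- paste(df$gene5, df$gene3, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("background_panel", "data.frame"),
            source_label = label)
}

#' @rdname read_panel
#' @param panel a `background_panel` data.frame.
#' @param source_label free-text provenance recorded in the file header.
#' @export
write_panel <- function(panel, path, source_label = NULL) {
  label <- source_label %||% attr(panel, "source_label") %||% "background panel"
  out <- as.data.frame(panel)
  for (col in c("breakpoint5", "breakpoint3"))
    if (col %in% names(out)) out[[col]] <- out[[col]] + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#source=", label), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sample sheets

#' Read a case/control sample sheet
#'
#' @param path TSV with columns `sample_id`, `group` (`case`/`control`) and
#'   `fastq` (one or more paths separated by `;`).
#' @param check_paths verify that every FASTQ path exists.
#' @return a `sample_sheet` data.frame; `fastq` is a list-column of paths.
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "group", "fastq") %in% names(df)))
    stop("sample sheet must have columns sample_id, group, fastq")
  df$fastq <- strsplit(df$fastq, ";", fixed = TRUE)
  # resolve paths relative to the sheet location
  base <- dirname(normalizePath(path))
  df$fastq <- lapply(df$fastq, function(p)
    ifelse(grepl("^/", p), p, file.path(base, p)))
  sample_sheet(df, check_paths = check_paths)
}

#' @rdname read_sample_sheet
#' @param df data.frame with `sample_id`, `group`, `fastq` (list or
#'   `;`-separated character).
#' @export
sample_sheet <- function(df, check_paths = TRUE) {
  if (!is.list(df$fastq)) df$fastq <- strsplit(df$fastq, ";", fixed = TRUE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         df$sample_id[duplicated(df$sample_id)][1])
  if (!all(df$group %in% c("case", "control")))
    stop("sample group must be 'case' or 'control'")
  if (length(unique(df$group)) < 1 || any(table(df$group) < 1))
    stop("every group needs at least one sample")
  if (check_paths) {
    all_paths <- unlist(df$fastq)
    missing <- all_paths[!file.exists(all_paths)]
    if (length(missing))
      stop("FASTQ file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' @rdname read_sample_sheet
#' @param sheet a `sample_sheet`.
#' @param relative_to when set, FASTQ paths are written relative to this
#'   directory.
#' @export
write_sample_sheet <- function(sheet, path, relative_to = NULL) {
  fq <- vapply(sheet$fastq, function(p) {
    if (!is.null(relative_to)) {
      root <- paste0(normalizePath(relative_to), "/")
      p <- sub(root, "", normalizePath(p, mustWork = FALSE), fixed = TRUE)
    }
    paste(p, collapse = ";")
  }, character(1))
  df <- data.frame(sample_id = sheet$sample_id, group = sheet$group,
                   fastq = fq, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Match tables and run metadata

#' Write / read a samples-by-probes match table
#'
#' The first two columns are `sample_id` and `group`; remaining columns are
#' one per probe/call id, holding the number of reads with at least one
#' qualifying junction-probe occurrence.
#'
#' @param mt a `match_table` (see [count_cohort()]).
#' @param path TSV path.
#' @export
write_match_table <- function(mt, path) {
  df <- data.frame(sample_id = rownames(mt$counts), group = mt$group,
                   mt$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_match_table
#' @export
read_match_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("sample_id", "group")),
                         drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$sample_id
  match_table(counts, df$group)
}

#' @rdname write_match_table
#' @param counts integer matrix, samples x probes, with rownames.
#' @param group character vector of `case`/`control` labels per sample.
#' @export
match_table <- function(counts, group) {
  stopifnot(is.matrix(counts), nrow(counts) == length(group),
            all(counts >= 0))
  structure(list(counts = counts, group = as.character(group)),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat("match_table:", nrow(x$counts), "samples x", ncol(x$counts),
      "probes (", sum(x$group == "case"), "case /",
      sum(x$group == "control"), "control )\n")
  invisible(x)
}

#' Write run metadata (parameters, seed, input hashes)
#'
#' Every pipeline command writes this next to its outputs so a run can be
#' reproduced exactly.
#'
#' @param path output JSON path.
#' @param params named list of resolved parameters.
#' @param seed integer seed used for the run (NA when not applicable).
#' @param inputs character vector of input file paths to hash (md5).
#' @export
write_run_metadata <- function(path, params, seed = NA_integer_,
                               inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  md5 <- tools::md5sum(inputs)
  names(md5) <- basename(inputs)
  meta <- list(
    package = "chimeraScreen",
    version = as.character(utils::packageVersion("chimeraScreen")),
    seed = seed,
    parameters = params,
    input_md5 = as.list(md5))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
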