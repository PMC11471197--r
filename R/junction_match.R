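# Junction probes and approximate read matching.
#
# A probe is L/2 transcribed bases ending at the 5' breakpoint joined to
# L/2 transcribed bases starting at the 3' breakpoint (default L = 28, so a
# 14-base anchor on each side of the junction). Reads are scanned with a
# bit-parallel bitap matcher (Hamming by default, Wu-Manber edit-distance
# automata optionally), in both orientations; the counting unit is reads
# with at least one qualifying occurrence.

#' Matching parameters
#'
#' @param k allowed mismatches/errors (default 0, exact matching).
#' @param distance_model `"hamming"` (substitutions only) or `"edit"`
#'   (insert/delete/substitute).
#' @param search_reverse_complement also scan the probe's reverse complement
#'   (default `TRUE`; unstranded libraries).
#' @param min_flank minimum read bases required on each side of the probe's
#'   split point for a hit to count (default 0: any full-probe match counts;
#'   the probe itself already anchors L/2 bases per side).
#' @param probe_length probe length L (even, default 28).
#' @return a `match_params` list.
#' @export
match_params <- function(k = 0L, distance_model = c("hamming", "edit"),
                         search_reverse_complement = TRUE, min_flank = 0L,
                         probe_length = 28L) {
  distance_model <- match.arg(distance_model)
  k <- as.integer(k); probe_length <- as.integer(probe_length)
  if (probe_length %% 2L != 0L)
    cs_stop_config("probe_length must be even (got ", probe_length, ")")
  if (k < 0 || k >= probe_length)
    cs_stop_config("k must satisfy 0 <= k < probe_length")
  structure(list(k = k, distance_model = distance_model,
                 search_reverse_complement = isTRUE(search_reverse_complement),
                 min_flank = as.integer(min_flank),
                 probe_length = probe_length), class = "match_params")
}

#' Build fixed-length junction probes from chimera calls
#'
#' With `source = "from-call"` the probe is cut from the call's junction
#' sequence: L/2 bases on each side of the recorded split. With
#' `source = "from-genome"` it is re-extracted from the genome as the last
#' L/2 transcribed bases of the 5' gene up to `breakpoint5` joined to the
#' first L/2 transcribed bases of the 3' gene from `breakpoint3`
#' (strand-aware; minus-strand segments reverse-complemented). Probes
#' containing `N` and calls with insufficient flanking sequence are skipped
#' and reported; duplicate probe sequences are collapsed with all
#' contributing call ids recorded.
#'
#' @param calls a `chimera_calls` data.frame.
#' @param L probe length (even; default 28).
#' @param source `"from-call"` or `"from-genome"`.
#' @param genome named [Biostrings::DNAStringSet] (required for
#'   `"from-genome"`).
#' @param models a [gene_models()] object (required for `"from-genome"`).
#' @return a `junction_probes` data.frame with columns `probe_id`,
#'   `sequence`, `split_index`, `source`, `call_ids` (`;`-joined);
#'   attribute `skipped` reports (call_id, reason).
#' @export
build_probes <- function(calls, L = 28L, source = c("from-call",
                                                    "from-genome"),
                         genome = NULL, models = NULL) {
  source <- match.arg(source)
  L <- as.integer(L)
  if (L %% 2L != 0L) cs_stop_config("probe length L must be even")
  half <- L %/% 2L
  n <- nrow(calls)
  seqs <- character(n); skip <- character(n)
  if (source == "from-genome" && (is.null(genome) || is.null(models)))
    stop("from-genome probes require genome and models")
  for (i in seq_len(n)) {
    if (source == "from-call") {
      js <- calls$junction_seq[i]; sp <- calls$split_index[i]
      if (sp < half || nchar(js) - sp < half) {
        skip[i] <- "insufficient flank in junction sequence"
        next
      }
      seqs[i] <- substr(js, sp - half + 1L, sp + half)
    } else {
      res <- genome_probe(calls[i, ], half, genome, models)
      if (!is.null(res$reason)) { skip[i] <- res$reason; next }
      seqs[i] <- res$seq
    }
    if (grepl("N", seqs[i], fixed = TRUE)) {
      skip[i] <- "probe contains N"
      seqs[i] <- ""
    }
  }
  keep <- which(skip == "" & nzchar(seqs))
  skipped <- data.frame(call_id = calls$call_id[skip != ""],
                        reason = skip[skip != ""], stringsAsFactors = FALSE)
  # collapse identical probe sequences, keep every contributing call id
  seq_keep <- seqs[keep]
  ids_keep <- calls$call_id[keep]
  first <- !duplicated(seq_keep)
  call_ids <- vapply(seq_keep[first], function(s)
    paste(ids_keep[seq_keep == s], collapse = ";"), character(1))
  out <- data.frame(
    probe_id = ids_keep[first],
    sequence = seq_keep[first],
    split_index = rep(half, sum(first)),
    source = rep(source, sum(first)),
    call_ids = unname(call_ids),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("junction_probes", "data.frame"),
            skipped = skipped, probe_length = L)
}

# Transcribed sequence of a gene (exons spliced, strand-aware) plus the
# transcript coordinate (1-based) of a 0-based genomic position.
gene_transcript <- function(models, symbol, genome) {
  ex <- models$exons[models$exons$symbol == symbol, , drop = FALSE]
  if (nrow(ex) == 0) return(NULL)
  chrom <- ex$chrom[1]; strand <- ex$strand[1]
  chr_seq <- genome[[chrom]]
  if (is.null(chr_seq)) stop("chromosome ", chrom, " absent from genome")
  pieces <- substring(as.character(chr_seq), ex$start + 1L, ex$end)
  if (strand == "+") {
    tx <- paste(pieces, collapse = "")
    ord <- seq_len(nrow(ex))
  } else {
    tx <- paste(rev(revcomp(pieces)), collapse = "")
    ord <- rev(seq_len(nrow(ex)))
  }
  list(seq = toupper(tx), exons = ex, order = ord, strand = strand)
}

# 1-based transcript position of a 0-based genomic position within the gene,
# NA when the position is intronic/outside.
genome_to_tx <- function(txinfo, gpos) {
  ex <- txinfo$exons[txinfo$order, , drop = FALSE]
  cum <- 0L
  for (j in seq_len(nrow(ex))) {
    w <- ex$end[j] - ex$start[j]
    if (gpos >= ex$start[j] && gpos < ex$end[j]) {
      off <- if (txinfo$strand == "+") gpos - ex$start[j]
             else ex$end[j] - 1L - gpos
      return(cum + off + 1L)
    }
    cum <- cum + w
  }
  NA_integer_
}

genome_probe <- function(call, half, genome, models) {
  t5 <- gene_transcript(models, call$gene5, genome)
  t3 <- gene_transcript(models, call$gene3, genome)
  if (is.null(t5) || is.null(t3))
    return(list(reason = "parental gene not in annotation"))
  p5 <- genome_to_tx(t5, call$breakpoint5)
  p3 <- genome_to_tx(t3, call$breakpoint3)
  if (is.na(p5) || is.na(p3))
    return(list(reason = "breakpoint not exonic"))
  if (p5 < half)
    return(list(reason = "insufficient 5' flank"))
  if (nchar(t3$seq) - p3 + 1L < half)
    return(list(reason = "insufficient 3' flank"))
  list(seq = paste0(substr(t5$seq, p5 - half + 1L, p5),
                    substr(t3$seq, p3, p3 + half - 1L)))
}

#' Count qualifying occurrences of a probe in one read
#'
#' Bit-parallel (bitap) approximate matcher. Under the Hamming model it
#' counts alignment offsets where the probe matches a length-L read
#' substring with at most `k` substitutions (`N` never matches); under the
#' edit model it counts end positions with edit distance at most `k`
#' (Wu-Manber insert/delete/substitute automata). When reverse-complement
#' search is on, the reverse-complemented probe is also scanned and the two
#' orientation counts are summed.
#'
#' @param probe probe sequence (ACGT, length <= 64).
#' @param read read sequence (ACGTN).
#' @param params a [match_params()] object.
#' @param split_index probe split position (defaults to `nchar(probe)/2`);
#'   only used when `min_flank > 0`.
#' @return integer occurrence count.
#' @export
bitap_count <- function(probe, read, params = match_params(),
                        split_index = nchar(probe) %/% 2L) {
  cpp_bitap_count(toupper(probe), toupper(read), params$k,
                  params$distance_model == "edit", as.integer(split_index),
                  params$min_flank, params$search_reverse_complement)
}

#' Brute-force occurrence count (verification oracle)
#'
#' Naive sliding-window Hamming scan / semi-global dynamic-programming edit
#' scan with the same counting semantics as [bitap_count()]. Kept as an
#' independent implementation for cross-checking the bitap matcher.
#'
#' @inheritParams bitap_count
#' @return integer occurrence count.
#' @export
naive_count <- function(probe, read, params = match_params(),
                        split_index = nchar(probe) %/% 2L) {
  cpp_naive_count(toupper(probe), toupper(read), params$k,
                  params$distance_model == "edit", as.integer(split_index),
                  params$min_flank, params$search_reverse_complement)
}

#' Count junction-supporting reads for one sample
#'
#' Streams the sample's FASTQ files and counts, per probe, the number of
#' reads containing at least one qualifying occurrence in either
#' orientation. A read contributes at most once per probe (it may support
#' several distinct probes); the result is independent of read order and of
#' how reads are split across files.
#'
#' @param probes a `junction_probes` data.frame (see [build_probes()]).
#' @param fastq_paths character vector of FASTQ(.gz) files for the sample.
#' @param params a [match_params()] object.
#' @param chunk_size reads per streamed chunk.
#' @return named integer vector, one count per probe.
#' @export
count_sample <- function(probes, fastq_paths, params = match_params(),
                         chunk_size = 50000L) {
  if (nrow(probes) == 0) stop("no probes to match")
  counts <- stats::setNames(integer(nrow(probes)), probes$probe_id)
  st <- fastq_stream(fastq_paths, chunk_size = chunk_size)
  repeat {
    ch <- st$next_chunk()
    if (length(ch$seq) == 0) break
    counts <- counts + cpp_reads_with_hit(
      probes$sequence, as.integer(probes$split_index), ch$seq,
      params$k, params$distance_model == "edit", params$min_flank,
      params$search_reverse_complement)
  }
  counts
}

#' Count junction-supporting reads across a cohort
#'
#' One [count_sample()] row per sample-sheet entry; rows are computed
#' independently, so the result is invariant to sample order and to the
#' `threads` chunking (processing is sequential; the argument only controls
#' work partitioning and is accepted for interface stability).
#'
#' @param probes a `junction_probes` data.frame.
#' @param sheet a `sample_sheet` (see [read_sample_sheet()]).
#' @param params a [match_params()] object.
#' @param threads work-partitioning factor; results are identical for every
#'   value.
#' @return a `match_table` (samples x probes counts plus group labels).
#' @export
count_cohort <- function(probes, sheet, params = match_params(),
                         threads = 1L) {
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id")
  n <- nrow(sheet)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / max(1L, ceiling(n / threads))))
  rows <- vector("list", n)
  for (ch in chunks) {
    for (i in ch) {
      rows[[i]] <- tryCatch(
        count_sample(probes, sheet$fastq[[i]], params),
        error = function(e) stop("sample ", sheet$sample_id[i], ": ",
                                 conditionMessage(e)))
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- sheet$sample_id
  match_table(counts, sheet$group)
}
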