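# Shared fixtures, generated in code. The standard dataset mirrors the
# cohort design the package targets (4 case + 4 control, 30 planted
# chimeras over ~40 genes) with error-free reads so recovery is exact; it
# is memoised so several test files can reuse one simulation.

.fixture_env <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    dir <- file.path(tempdir(), "chimeraScreen-shared-ds")
    cfg <- sim_config(seed = 7L, error_rate = 0)
    .fixture_env$ds <- simulate_dataset(cfg, dir)
    .fixture_env$cfg <- cfg
  }
  .fixture_env$ds
}

shared_config <- function() {
  shared_dataset()
  .fixture_env$cfg
}

# a minimal hand-built annotation: two genes on chr1 (one per strand) and
# one on chr2, exact coordinates for edge arithmetic
toy_models <- function() {
  gene_models(data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    symbol = c("A", "A", "B", "B", "C"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "-", "-", "+"),
    start = c(100L, 300L, 1000L, 1400L, 50L),
    end = c(200L, 400L, 1200L, 1600L, 150L),
    stringsAsFactors = FALSE))
}

toy_call <- function(gene5 = "A", gene3 = "B", chrom5 = "chr1",
                     chrom3 = "chr1", bp5 = 199L, bp3 = 1599L,
                     strand5 = "+", strand3 = "-",
                     junction_seq = strrep("ACGT", 7), split_index = 14L,
                     call_id = "c1") {
  out <- data.frame(call_id = call_id, gene5 = gene5, gene3 = gene3,
                    chrom5 = chrom5, chrom3 = chrom3,
                    breakpoint5 = bp5, breakpoint3 = bp3,
                    strand5 = strand5, strand3 = strand3,
                    junction_seq = junction_seq, split_index = split_index,
                    crossing_reads = 5L, spanning_reads = 2L,
                    caller_score = 0.9, stringsAsFactors = FALSE)
  class(out) <- c("chimera_calls", "data.frame")
  out
}

random_probe <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                         replace = TRUE), collapse = "")

write_tmp_fastq <- function(ids, seqs, path, qual = NULL) {
  qual <- qual %||% strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}
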