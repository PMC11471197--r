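# Synthetic test universe: toy genome, multi-exon gene annotation, planted
# chimeric transcripts covering every location and junction-site category,
# case/control read sets with substitution errors, an EricScript-style call
# table, a background panel and a truth ledger.
#
# Determinism contract: simulate_genome() seeds the RNG from the config;
# plant_chimeras() and simulate_reads() consume the stream that follows, so
# running the stages in order (as simulate_dataset() does) is byte-
# reproducible under a fixed seed.

#' Simulation configuration
#'
#' Defaults encode the study design the package targets: a cohort of four
#' case and four control samples, 28-nt junction probes (14-base anchors),
#' a location mix dominated by inter-/intra-chromosomal events with a small
#' read-through fraction, and a junction-site mix placing ~85% of 5'
#' breakpoints on exon edges.
#'
#' @param seed master RNG seed.
#' @param n_chromosomes,n_genes toy genome size.
#' @param exons_per_gene,exon_len,intron_len,intergenic_len integer ranges
#'   (min, max) for gene structure, in bases.
#' @param n_chimeras number of planted chimeras.
#' @param category_mix named proportions over `inter`, `intra`,
#'   `read-through` (must sum to 1).
#' @param junction_site_mix named proportions over `EE`, `EM`, `ME`, `MM`.
#' @param n_background_panel number of planted chimeras also entered into
#'   the background panel.
#' @param panel_extra additional panel entries not corresponding to planted
#'   chimeras.
#' @param n_decoys decoy probes (verified absent from all simulated
#'   sequence) emitted for negative-control matching.
#' @param read_length read length in bases (must be below the minimum
#'   simulated transcript length).
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param junction_coverage expected junction-spanning reads per expressed
#'   chimera per sample (Poisson mean).
#' @param background_reads_per_sample reads drawn uniformly from normal
#'   transcripts per sample.
#' @param n_case,n_control cohort sizes.
#' @param group_exclusive named counts (`case`, `control`) of chimeras
#'   expressed only in that group.
#' @param probe_length junction probe length (even; default 28).
#' @param anchor minimum junction-spanning read overlap on each side of the
#'   breakpoint (default `probe_length / 2`).
#' @param readthrough_gap gap threshold used when planting read-through
#'   pairs (matches the classifier default).
#' @param ensure_min_coverage guarantee at least one junction read per
#'   expressed group per chimera (makes exclusivity recovery exact).
#' @param gzip_fastq write gzip-compressed FASTQ.
#' @param uniqueness_k mismatch allowance at which planted probes are
#'   verified absent from all non-parent sequence.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       n_genes = 40L,
                       exons_per_gene = c(3L, 6L),
                       exon_len = c(80L, 200L),
                       intron_len = c(100L, 400L),
                       intergenic_len = c(300L, 1500L),
                       n_chimeras = 30L,
                       category_mix = c(inter = 0.50, intra = 0.46,
                                        "read-through" = 0.04),
                       junction_site_mix = c(EE = 0.55, EM = 0.30,
                                             ME = 0.075, MM = 0.075),
                       n_background_panel = 5L,
                       panel_extra = 10L,
                       n_decoys = 5L,
                       read_length = 100L,
                       error_rate = 0.002,
                       junction_coverage = 3,
                       background_reads_per_sample = 1000L,
                       n_case = 4L,
                       n_control = 4L,
                       group_exclusive = c(case = 5L, control = 5L),
                       probe_length = 28L,
                       anchor = NULL,
                       readthrough_gap = 50000L,
                       ensure_min_coverage = TRUE,
                       gzip_fastq = FALSE,
                       uniqueness_k = 0L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              intergenic_len = as.integer(intergenic_len),
              n_chimeras = as.integer(n_chimeras),
              category_mix = category_mix,
              junction_site_mix = junction_site_mix,
              n_background_panel = as.integer(n_background_panel),
              panel_extra = as.integer(panel_extra),
              n_decoys = as.integer(n_decoys),
              read_length = as.integer(read_length),
              error_rate = error_rate,
              junction_coverage = junction_coverage,
              background_reads_per_sample = as.integer(background_reads_per_sample),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              group_exclusive = as.integer(group_exclusive),
              probe_length = as.integer(probe_length),
              anchor = as.integer(anchor %||% (probe_length %/% 2L)),
              readthrough_gap = as.integer(readthrough_gap),
              ensure_min_coverage = isTRUE(ensure_min_coverage),
              gzip_fastq = isTRUE(gzip_fastq),
              uniqueness_k = as.integer(uniqueness_k))
  names(cfg$group_exclusive) <- names(group_exclusive)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_mix <- function(mix, want, field) {
    if (!setequal(names(mix), want))
      cs_stop_config(field, " must have names ", paste(want, collapse = ", "))
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
      cs_stop_config(field, " proportions must be non-negative and sum to 1")
  }
  chk_mix(cfg$category_mix, c("inter", "intra", "read-through"),
          "category_mix")
  chk_mix(cfg$junction_site_mix, c("EE", "EM", "ME", "MM"),
          "junction_site_mix")
  counts <- c(cfg$n_chromosomes, cfg$n_genes, cfg$n_chimeras,
              cfg$n_background_panel, cfg$panel_extra, cfg$n_decoys,
              cfg$background_reads_per_sample, cfg$n_case, cfg$n_control,
              cfg$group_exclusive)
  if (any(counts < 0)) cs_stop_config("counts must be >= 0")
  if (cfg$n_case < 1 || cfg$n_control < 1)
    cs_stop_config("n_case and n_control must be >= 1")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    cs_stop_config("error_rate must be in [0, 1)")
  if (cfg$probe_length %% 2L != 0L)
    cs_stop_config("probe_length must be even")
  min_tx <- cfg$exons_per_gene[1] * cfg$exon_len[1]
  if (cfg$read_length >= min_tx)
    cs_stop_config("read_length (", cfg$read_length,
                   ") must be below the minimum transcript length (", min_tx,
                   "); raise exon_len or exons_per_gene")
  if (sum(cfg$group_exclusive) > cfg$n_chimeras)
    cs_stop_config("group_exclusive counts exceed n_chimeras")
  if (cfg$n_background_panel > cfg$n_chimeras)
    cs_stop_config("n_background_panel exceeds n_chimeras")
  invisible(cfg)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rint <- function(range) {
  if (range[1] == range[2]) range[1] else
    sample(seq(range[1], range[2]), 1L)
}

#' Simulate a toy genome and gene annotation
#'
#' Chromosomes are i.i.d. uniform ACGT; genes are non-overlapping,
#' multi-exon, placed sequentially on both strands with the configured
#' exon/intron/intergenic size ranges. Seeds the RNG from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `models` (a [gene_models()] object).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  per_chrom <- largest_remainder(
    config$n_genes, rep(1 / config$n_chromosomes, config$n_chromosomes))
  exon_rows <- list()
  chrom_len <- integer(config$n_chromosomes)
  gi <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("chr%d", ci)
    cursor <- rint(config$intergenic_len)
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      n_ex <- rint(config$exons_per_gene)
      lens <- vapply(seq_len(n_ex), function(i) rint(config$exon_len),
                     integer(1))
      gaps <- if (n_ex > 1)
        vapply(seq_len(n_ex - 1L), function(i) rint(config$intron_len),
               integer(1)) else integer(0)
      starts <- cursor + cumsum(c(0L, lens[-n_ex] + gaps))
      strand <- sample(c("+", "-"), 1L)
      exon_rows[[gi]] <- data.frame(
        gene_id = sprintf("g%03d", gi),
        symbol = sprintf("GENE%03d", gi),
        chrom = chrom, strand = strand,
        start = starts, end = starts + lens,
        stringsAsFactors = FALSE)
      cursor <- starts[n_ex] + lens[n_ex] + rint(config$intergenic_len)
    }
    chrom_len[ci] <- cursor
  }
  seqs <- vapply(chrom_len, rand_dna, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- sprintf("chr%d", seq_len(config$n_chromosomes))
  list(genome = genome, models = gene_models(do.call(rbind, exon_rows)))
}

# 0-based genomic position of the t-th (1-based) transcribed base.
tx_to_genome <- function(txinfo, t) {
  ex <- txinfo$exons[txinfo$order, , drop = FALSE]
  cum <- 0L
  for (j in seq_len(nrow(ex))) {
    w <- ex$end[j] - ex$start[j]
    if (t <= cum + w) {
      off <- t - cum - 1L
      return(if (txinfo$strand == "+") ex$start[j] + off
             else ex$end[j] - 1L - off)
    }
    cum <- cum + w
  }
  stop("transcript position ", t, " beyond transcript length")
}

# Pick a 5'-side breakpoint: returns list(s = prefix length in transcript
# coordinates, gpos = 0-based genomic position) honouring the E/M class.
pick_break5 <- function(txinfo, site, seg_min) {
  ex <- txinfo$exons[txinfo$order, , drop = FALSE]
  lens <- ex$end - ex$start
  cum <- cumsum(lens)
  if (site == "E") {
    ok <- which(cum >= seg_min)
    if (!length(ok)) return(NULL)
    j <- ok[rint(c(1L, length(ok)))]
    s <- cum[j]
  } else {
    cand <- list()
    for (j in seq_along(lens)) {
      lo <- max(seg_min, (if (j > 1) cum[j - 1] else 0L) + 3L)
      hi <- cum[j] - 3L   # >= 2 bases from both exon edges
      if (hi >= lo) cand[[length(cand) + 1L]] <- c(lo, hi)
    }
    if (!length(cand)) return(NULL)
    r <- cand[[rint(c(1L, length(cand)))]]
    s <- rint(r)
  }
  list(s = s, gpos = tx_to_genome(txinfo, s))
}

# 3'-side breakpoint: s = transcript position of the first retained base.
pick_break3 <- function(txinfo, site, seg_min) {
  ex <- txinfo$exons[txinfo$order, , drop = FALSE]
  lens <- ex$end - ex$start
  cum <- cumsum(lens)
  total <- cum[length(cum)]
  if (site == "E") {
    starts <- c(1L, cum[-length(cum)] + 1L)
    ok <- which(total - starts + 1L >= seg_min)
    if (!length(ok)) return(NULL)
    j <- ok[rint(c(1L, length(ok)))]
    s <- starts[j]
  } else {
    cand <- list()
    for (j in seq_along(lens)) {
      start_j <- (if (j > 1) cum[j - 1] else 0L) + 1L
      lo <- start_j + 2L
      hi <- min(cum[j] - 2L, total - seg_min + 1L)
      if (hi >= lo) cand[[length(cand) + 1L]] <- c(lo, hi)
    }
    if (!length(cand)) return(NULL)
    r <- cand[[rint(c(1L, length(cand)))]]
    s <- rint(r)
  }
  list(s = s, gpos = tx_to_genome(txinfo, s))
}

probe_hits <- function(probe, seqs, k) {
  for (s in seqs) {
    if (cpp_bitap_count(probe, s, k, FALSE, nchar(probe) %/% 2L, 0L, TRUE) > 0)
      return(TRUE)
  }
  FALSE
}

#' Plant chimeric transcripts
#'
#' Joins a 5' segment of one gene to a 3' segment of another so that the
#' location-category and junction-site mixes are met exactly (largest-
#' remainder rounding). `E` breakpoints sit exactly on annotated exon
#' edges; `M` breakpoints lie strictly inside an exon, at least 2 bases
#' from both edges. Every junction probe is verified absent (at
#' `uniqueness_k`, both orientations) from the genome, all normal
#' transcripts and all other chimeric transcripts, and is re-drawn
#' otherwise. Consumes the RNG stream (call after [simulate_genome()]).
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome()] (`genome` + `models`).
#' @return list with `calls` (a `chimera_calls` data.frame), `truth`
#'   (truth-ledger data.frame), `chimeric_tx` (named character vector of
#'   chimeric transcript sequences), `split_pos` (named prefix lengths),
#'   `panel` (a `background_panel`), `decoys` (character vector of decoy
#'   probe sequences).
#' @export
plant_chimeras <- function(config, sim) {
  models <- sim$models; genome <- sim$genome
  g <- models$genes
  half <- config$probe_length %/% 2L
  seg_min <- max(config$anchor, ceiling(config$read_length / 2))
  loc_counts <- largest_remainder(config$n_chimeras, config$category_mix)
  junc_counts <- largest_remainder(config$n_chimeras,
                                   config$junction_site_mix)
  loc_vec <- rep(names(loc_counts), loc_counts)
  junc_vec <- sample(rep(names(junc_counts), junc_counts))

  # read-through candidates: same-chromosome, same-strand neighbours in
  # transcription order
  rt_pairs <- list()
  for (chrom in unique(g$chrom)) {
    gc <- g[g$chrom == chrom, , drop = FALSE]
    gc <- gc[order(gc$start), , drop = FALSE]
    for (i in seq_len(nrow(gc) - 1L)) {
      if (gc$strand[i] != gc$strand[i + 1L]) next
      gap <- gc$start[i + 1L] - gc$end[i]
      if (gap < 0 || gap > config$readthrough_gap) next
      if (gc$strand[i] == "+")
        rt_pairs[[length(rt_pairs) + 1L]] <- c(gc$symbol[i], gc$symbol[i + 1L])
      else
        rt_pairs[[length(rt_pairs) + 1L]] <- c(gc$symbol[i + 1L], gc$symbol[i])
    }
  }
  if (sum(loc_vec == "read-through") > length(rt_pairs))
    cs_stop_config("category mix needs ", sum(loc_vec == "read-through"),
                   " read-through pairs but the annotation provides only ",
                   length(rt_pairs),
                   "; increase n_genes or reduce the read-through share")
  rt_order <- if (length(rt_pairs)) sample(length(rt_pairs)) else integer(0)
  rt_next <- 0L

  txcache <- new.env(parent = emptyenv())
  get_tx <- function(sym) {
    if (is.null(txcache[[sym]]))
      txcache[[sym]] <- gene_transcript(models, sym, genome)
    txcache[[sym]]
  }
  chrom_seqs <- as.character(genome)
  normal_tx <- vapply(g$symbol, function(s) get_tx(s)$seq, character(1))
  background_seqs <- c(chrom_seqs, unname(normal_tx))

  used_pairs <- character(0)
  rows <- list(); truth_rows <- list()
  chimeric_tx <- character(0); split_pos <- integer(0)
  probes_seen <- character(0)

  pick_pair <- function(loc) {
    if (loc == "read-through") {
      rt_next <<- rt_next + 1L
      if (rt_next > length(rt_order)) return(NULL)
      return(rt_pairs[[rt_order[rt_next]]])
    }
    for (a in seq_len(200L)) {
      s5 <- g$symbol[rint(c(1L, nrow(g)))]
      s3 <- g$symbol[rint(c(1L, nrow(g)))]
      if (s5 == s3) next
      key <- panel_key(s5, s3)
      if (key %in% used_pairs) next
      c5 <- g$chrom[g$symbol == s5]; c3 <- g$chrom[g$symbol == s3]
      st5 <- g$strand[g$symbol == s5]; st3 <- g$strand[g$symbol == s3]
      if (loc == "inter" && c5 != c3) return(c(s5, s3))
      if (loc == "intra" && c5 == c3 && st5 != st3) return(c(s5, s3))
    }
    NULL
  }

  for (i in seq_len(config$n_chimeras)) {
    loc <- loc_vec[i]; junc <- junc_vec[i]
    side5 <- substr(junc, 1, 1); side3 <- substr(junc, 2, 2)
    planted <- FALSE
    for (attempt in seq_len(200L)) {
      pair <- pick_pair(loc)
      if (is.null(pair))
        cs_stop_config("cannot satisfy location mix: no eligible gene pair ",
                       "for category '", loc, "'")
      t5 <- get_tx(pair[1]); t3 <- get_tx(pair[2])
      b5 <- pick_break5(t5, side5, seg_min)
      b3 <- pick_break3(t3, side3, seg_min)
      if (is.null(b5) || is.null(b3)) next
      probe <- paste0(substr(t5$seq, b5$s - half + 1L, b5$s),
                      substr(t3$seq, b3$s, b3$s + half - 1L))
      # uniqueness: probe absent from genome, normal transcripts and other
      # chimeric transcripts; other probes absent from this new transcript
      ctx <- paste0(substr(t5$seq, 1L, b5$s),
                    substr(t3$seq, b3$s, nchar(t3$seq)))
      if (probe_hits(probe, c(background_seqs, chimeric_tx),
                     config$uniqueness_k)) next
      if (length(probes_seen) &&
          any(vapply(probes_seen, function(p)
            probe_hits(p, ctx, config$uniqueness_k), logical(1)))) next

      id <- sprintf("chim%03d", i)
      used_pairs <- c(used_pairs, panel_key(pair[1], pair[2]))
      jseq <- paste0(substr(t5$seq, b5$s - half + 1L, b5$s),
                     substr(t3$seq, b3$s, b3$s + half - 1L))
      rows[[i]] <- data.frame(
        call_id = id, gene5 = pair[1], gene3 = pair[2],
        chrom5 = g$chrom[g$symbol == pair[1]],
        chrom3 = g$chrom[g$symbol == pair[2]],
        breakpoint5 = b5$gpos, breakpoint3 = b3$gpos,
        strand5 = g$strand[g$symbol == pair[1]],
        strand3 = g$strand[g$symbol == pair[2]],
        junction_seq = jseq, split_index = half,
        crossing_reads = rpois(1, 20) + 1L,
        spanning_reads = rpois(1, 10) + 1L,
        caller_score = round(runif(1, 0.5, 1), 4),
        stringsAsFactors = FALSE)
      loc_label <- c(inter = "inter-chromosomal", intra = "intra-chromosomal",
                     "read-through" = "read-through")[loc]
      truth_rows[[i]] <- data.frame(
        call_id = id, gene5 = pair[1], gene3 = pair[2],
        location_category = unname(loc_label),
        junction_site_category = junc,
        stringsAsFactors = FALSE)
      chimeric_tx[id] <- ctx
      split_pos[id] <- b5$s
      probes_seen <- c(probes_seen, probe)
      planted <- TRUE
      break
    }
    if (!planted)
      cs_stop_config("failed to plant chimera ", i, " (category ", loc, "/",
                     junc, ") after 200 attempts; the requested mix appears ",
                     "unsatisfiable with this annotation")
  }

  calls <- do.call(rbind, rows)
  class(calls) <- c("chimera_calls", "data.frame")
  truth <- do.call(rbind, truth_rows)

  # group exclusivity labels
  grp <- rep("both", config$n_chimeras)
  ord <- sample(config$n_chimeras)
  ne <- config$group_exclusive
  if (ne[["case"]] > 0) grp[ord[seq_len(ne[["case"]])]] <- "case"
  if (ne[["control"]] > 0)
    grp[ord[ne[["case"]] + seq_len(ne[["control"]])]] <- "control"
  truth$group <- grp

  # background panel: a subset of planted chimeras plus unrelated pairs
  in_panel <- rep(FALSE, config$n_chimeras)
  if (config$n_background_panel > 0)
    in_panel[sample(config$n_chimeras, config$n_background_panel)] <- TRUE
  truth$in_panel <- in_panel
  panel_rows <- data.frame(gene5 = calls$gene5[in_panel],
                           gene3 = calls$gene3[in_panel],
                           breakpoint5 = calls$breakpoint5[in_panel],
                           breakpoint3 = calls$breakpoint3[in_panel],
                           stringsAsFactors = FALSE)
  extra <- 0L
  while (extra < config$panel_extra) {
    s5 <- g$symbol[rint(c(1L, nrow(g)))]
    s3 <- g$symbol[rint(c(1L, nrow(g)))]
    if (s5 == s3) next
    key <- panel_key(s5, s3)
    if (key %in% c(used_pairs, panel_key(panel_rows$gene5, panel_rows$gene3)))
      next
    panel_rows <- rbind(panel_rows,
                        data.frame(gene5 = s5, gene3 = s3,
                                   breakpoint5 = NA_integer_,
                                   breakpoint3 = NA_integer_,
                                   stringsAsFactors = FALSE))
    extra <- extra + 1L
  }
  panel <- structure(panel_rows, class = c("background_panel", "data.frame"),
                     source_label = "synthetic normal-tissue panel")

  # decoy probes: random sequences absent from every simulated sequence
  decoys <- character(0)
  avoid <- c(background_seqs, unname(chimeric_tx))
  while (length(decoys) < config$n_decoys) {
    cand <- rand_dna(config$probe_length)
    if (!probe_hits(cand, avoid, config$uniqueness_k))
      decoys <- c(decoys, cand)
  }

  truth$junction_seq <- calls$junction_seq
  truth$tx_length <- nchar(chimeric_tx[truth$call_id])
  list(calls = calls, truth = truth, chimeric_tx = chimeric_tx,
       split_pos = split_pos, panel = panel, decoys = decoys)
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate case/control FASTQ read sets
#'
#' Background reads are drawn uniformly from normal transcripts; junction-
#' spanning reads overlap each chimera's breakpoint by at least
#' `config$anchor` bases on each side, with per-sample counts
#' Poisson(`junction_coverage`) (zero for chimeras exclusive to the other
#' group; when `ensure_min_coverage` is set, at least one junction read per
#' expressed group is guaranteed). Substitution errors are applied i.i.d.
#' at `error_rate` and ~50% of reads are emitted reverse-complemented.
#' Consumes the RNG stream (call after [plant_chimeras()]).
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @param planted output of [plant_chimeras()].
#' @param out_dir directory for the per-sample FASTQ files (created).
#' @return list with `sheet` (a `sample_sheet`), `realized` (chimeras x
#'   samples integer matrix of emitted junction-read counts) and `truth`
#'   (the planted truth with realized counts attached as columns
#'   `reads_<sample_id>`).
#' @export
simulate_reads <- function(config, sim, planted, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- sim$models$genes
  normal_tx <- vapply(g$symbol, function(s)
    gene_transcript(sim$models, s, sim$genome)$seq, character(1))
  RL <- config$read_length
  anchor <- config$anchor
  samples <- c(sprintf("case_%d", seq_len(config$n_case)),
               sprintf("control_%d", seq_len(config$n_control)))
  groups <- c(rep("case", config$n_case), rep("control", config$n_control))
  truth <- planted$truth
  nC <- nrow(truth)

  expressed <- outer(truth$group, groups,
                     function(tg, sg) tg == "both" | tg == sg)
  realized <- matrix(0L, nC, length(samples),
                     dimnames = list(truth$call_id, samples))
  realized[expressed] <- rpois(sum(expressed), config$junction_coverage)
  if (config$ensure_min_coverage) {
    for (grp in c("case", "control")) {
      cols <- which(groups == grp)
      for (i in seq_len(nC)) {
        if (!expressed[i, cols[1]]) next
        if (sum(realized[i, cols]) == 0L)
          realized[i, cols[1]] <- 1L
      }
    }
  }

  ext <- if (config$gzip_fastq) ".fastq.gz" else ".fastq"
  paths <- character(length(samples))
  for (si in seq_along(samples)) {
    sm <- samples[si]
    ids <- character(0); seqs <- character(0)
    # background reads
    nb <- config$background_reads_per_sample
    if (nb > 0) {
      tx_i <- sample(length(normal_tx), nb, replace = TRUE)
      for (b in seq_len(nb)) {
        tx <- normal_tx[[tx_i[b]]]
        start <- rint(c(0L, nchar(tx) - RL))
        seqs <- c(seqs, substr(tx, start + 1L, start + RL))
        ids <- c(ids, sprintf("%s:bg:%05d", sm, b))
      }
    }
    # junction-spanning reads
    for (i in seq_len(nC)) {
      n <- realized[i, si]
      if (n == 0L) next
      id <- truth$call_id[i]
      tx <- planted$chimeric_tx[[id]]
      s <- planted$split_pos[[id]]  # prefix length; breakpoint after base s
      lo <- max(0L, s + anchor - RL)
      hi <- min(s - anchor, nchar(tx) - RL)
      for (r in seq_len(n)) {
        start <- rint(c(lo, hi))
        seqs <- c(seqs, substr(tx, start + 1L, start + RL))
        ids <- c(ids, sprintf("%s:junc:%s:%03d", sm, id, r))
      }
    }
    seqs <- apply_errors(seqs, config$error_rate)
    flip <- runif(length(seqs)) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    paths[si] <- file.path(out_dir, paste0(sm, ext))
    write_fastq(ids, seqs, paths[si])
  }

  sheet <- sample_sheet(data.frame(sample_id = samples, group = groups,
                                   fastq = I(as.list(paths)),
                                   stringsAsFactors = FALSE))
  for (si in seq_along(samples))
    truth[[paste0("reads_", samples[si])]] <- realized[, si]
  list(sheet = sheet, realized = realized, truth = truth)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [simulate_genome()], [plant_chimeras()] and [simulate_reads()] and
#' writes every artefact the pipeline consumes: `genome.fa`,
#' `annotation.gtf`, `transcripts.fa`, `chimeric_transcripts.fa`,
#' `calls.tsv`, `panel.tsv`, `samples.tsv`, `truth.tsv`,
#' `decoy_probes.tsv`, per-sample FASTQ under `fastq/`, and the resolved
#' configuration as `config.json`. Fully deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) a list with all in-memory objects: `genome`,
#'   `models`, `calls`, `truth`, `panel`, `decoys`, `sheet`, `realized`,
#'   `chimeric_tx`, `split_pos`, `paths`.
#' @export
simulate_dataset <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  planted <- plant_chimeras(config, sim)
  reads <- simulate_reads(config, sim, planted, file.path(out_dir, "fastq"))

  p <- list(genome = file.path(out_dir, "genome.fa"),
            annotation = file.path(out_dir, "annotation.gtf"),
            transcripts = file.path(out_dir, "transcripts.fa"),
            chimeric_tx = file.path(out_dir, "chimeric_transcripts.fa"),
            calls = file.path(out_dir, "calls.tsv"),
            panel = file.path(out_dir, "panel.tsv"),
            samples = file.path(out_dir, "samples.tsv"),
            truth = file.path(out_dir, "truth.tsv"),
            decoys = file.path(out_dir, "decoy_probes.tsv"),
            config = file.path(out_dir, "config.json"))
  Biostrings::writeXStringSet(sim$genome, p$genome)
  write_annotation(sim$models, p$annotation)
  g <- sim$models$genes
  normal_tx <- Biostrings::DNAStringSet(vapply(g$symbol, function(s)
    gene_transcript(sim$models, s, sim$genome)$seq, character(1)))
  names(normal_tx) <- g$symbol
  Biostrings::writeXStringSet(normal_tx, p$transcripts)
  ctx <- Biostrings::DNAStringSet(planted$chimeric_tx)
  Biostrings::writeXStringSet(ctx, p$chimeric_tx)
  write_calls(planted$calls, p$calls)
  write_panel(planted$panel, p$panel)
  write_sample_sheet(reads$sheet, p$samples, relative_to = out_dir)
  utils::write.table(reads$truth, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(decoy_id = sprintf("decoy%02d", seq_along(planted$decoys)),
               sequence = planted$decoys, stringsAsFactors = FALSE),
    p$decoys, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_out <- unclass(config)
  jsonlite::write_json(cfg_out, p$config, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(genome = sim$genome, models = sim$models,
                 calls = planted$calls, truth = reads$truth,
                 panel = planted$panel, decoys = planted$decoys,
                 sheet = reads$sheet, realized = reads$realized,
                 chimeric_tx = planted$chimeric_tx,
                 split_pos = planted$split_pos, paths = p))
}
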