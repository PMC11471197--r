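# Cohort-level outputs: presence/absence, group-exclusive chimera sets,
# cross-cohort frequency comparison, marker sensitivity/specificity and
# parental-gene chromosome enrichment.

#' Presence/absence matrix from a match table
#'
#' @param mt a `match_table`.
#' @param threshold minimum supporting reads for a chimera to count as
#'   present in a sample (default 1: any detection is presence).
#' @return a `presence_matrix`: logical samples x chimeras matrix with a
#'   `group` attribute.
#' @export
presence <- function(mt, threshold = 1L) {
  if (threshold < 1) stop("presence threshold must be >= 1")
  m <- mt$counts >= threshold
  structure(m, group = mt$group, class = c("presence_matrix", class(m)))
}

#' Partition chimeras by group exclusivity
#'
#' A chimera is case-exclusive when present in at least one case sample and
#' in zero control samples (and symmetrically); shared when present in at
#' least one sample of each group; absent otherwise. The four sets
#' partition the chimera universe.
#'
#' @param pm a [presence()] matrix.
#' @return list with character vectors `case_exclusive`,
#'   `control_exclusive`, `shared`, `absent`.
#' @export
exclusivity <- function(pm) {
  group <- attr(pm, "group")
  if (length(unique(group)) < 2)
    stop("exclusivity requires both case and control samples")
  in_case <- colSums(pm[group == "case", , drop = FALSE]) > 0
  in_ctrl <- colSums(pm[group == "control", , drop = FALSE]) > 0
  ids <- colnames(pm)
  list(case_exclusive = ids[in_case & !in_ctrl],
       control_exclusive = ids[!in_case & in_ctrl],
       shared = ids[in_case & in_ctrl],
       absent = ids[!in_case & !in_ctrl])
}

#' Compare chimera frequencies across cohorts/databases
#'
#' Produces a long-format table with, per (database, chimera, group), the
#' summed match counts and the number of positive samples, plus a per-
#' chimera consistency flag: `"consistent"` when the case-vs-control
#' direction (sign of case total minus control total) is identical in every
#' database, `"inconsistent"` otherwise. A chimera missing from a table is
#' recorded as zero and flagged in the `missing_from` column.
#'
#' @param tables named list of `match_table`s (names are database labels).
#' @param threshold presence threshold for the positive-sample tally.
#' @return list with `table` (long data.frame) and `consistency`
#'   (data.frame: chimera, direction per database, flag).
#' @export
frequency_comparison <- function(tables, threshold = 1L) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list (database labels)")
  all_ids <- unique(unlist(lapply(tables, function(t) colnames(t$counts))))
  rows <- list()
  dir_mat <- matrix(NA_integer_, nrow = length(all_ids),
                    ncol = length(tables),
                    dimnames = list(all_ids, names(tables)))
  missing_from <- stats::setNames(rep("", length(all_ids)), all_ids)
  for (db in names(tables)) {
    mt <- tables[[db]]
    for (id in all_ids) {
      present_col <- id %in% colnames(mt$counts)
      v <- if (present_col) mt$counts[, id] else
        stats::setNames(rep(0L, length(mt$group)), rownames(mt$counts))
      if (!present_col)
        missing_from[id] <- paste(c(missing_from[id], db)[
          nzchar(c(missing_from[id], db))], collapse = ";")
      for (g in c("case", "control")) {
        sel <- mt$group == g
        rows[[length(rows) + 1L]] <- data.frame(
          database = db, chimera = id, group = g,
          total_count = sum(v[sel]),
          n_positive = sum(v[sel] >= threshold),
          stringsAsFactors = FALSE)
      }
      dir_mat[id, db] <- sign(sum(v[mt$group == "case"]) -
                                sum(v[mt$group == "control"]))
    }
  }
  long <- do.call(rbind, rows)
  flag <- apply(dir_mat, 1, function(d) {
    if (length(unique(d)) == 1L) "consistent" else "inconsistent"
  })
  consistency <- data.frame(chimera = all_ids,
                            flag = unname(flag[all_ids]),
                            missing_from = unname(missing_from[all_ids]),
                            stringsAsFactors = FALSE)
  consistency <- cbind(consistency,
                       as.data.frame(dir_mat[all_ids, , drop = FALSE]))
  rownames(consistency) <- NULL
  list(table = long, consistency = consistency)
}

#' Diagnostic performance of a single chimera marker
#'
#' Treats presence of the chimera as a positive test and the sample group as
#' ground truth: sensitivity = TP / cases, specificity = TN / controls.
#' Percentages are reported at one decimal, rounding half away from zero
#' (so 11 of 12 positive cases gives 91.7).
#'
#' @param pm a [presence()] matrix.
#' @param chimera_id column to evaluate.
#' @return a `marker_performance` list: counts (`n_cases`, `n_controls`,
#'   `true_positives`, `false_negatives`, `false_positives`,
#'   `true_negatives`), proportions (`sensitivity`, `specificity`) and
#'   percentages (`sensitivity_pct`, `specificity_pct`).
#' @export
marker_performance <- function(pm, chimera_id) {
  if (!chimera_id %in% colnames(pm))
    stop("unknown chimera id: ", chimera_id)
  group <- attr(pm, "group")
  pos <- pm[, chimera_id]
  tp <- sum(pos & group == "case")
  fn <- sum(!pos & group == "case")
  fp <- sum(pos & group == "control")
  tn <- sum(!pos & group == "control")
  n_cases <- tp + fn; n_controls <- fp + tn
  sens <- if (n_cases > 0) tp / n_cases else NA_real_
  spec <- if (n_controls > 0) tn / n_controls else NA_real_
  structure(list(chimera_id = chimera_id,
                 n_cases = n_cases, n_controls = n_controls,
                 true_positives = tp, false_negatives = fn,
                 false_positives = fp, true_negatives = tn,
                 sensitivity = sens, specificity = spec,
                 sensitivity_pct = pct_1dp(sens),
                 specificity_pct = pct_1dp(spec)),
            class = "marker_performance")
}

#' @export
print.marker_performance <- function(x, ...) {
  cat(sprintf("marker %s: sensitivity %.1f%% (%d/%d), specificity %.1f%% (%d/%d)\n",
              x$chimera_id, x$sensitivity_pct, x$true_positives, x$n_cases,
              x$specificity_pct, x$true_negatives, x$n_controls))
  invisible(x)
}

#' Chromosome enrichment of parental genes
#'
#' For each chromosome, a one-sided binomial test of the observed number of
#' parental genes against the background proportion of annotated genes on
#' that chromosome, with Benjamini-Hochberg correction across chromosomes.
#' Parental genes are deduplicated by gene id once per side; with
#' `side = "both"` a gene contributes once per side in which it appears.
#'
#' @param calls a `chimera_calls` data.frame.
#' @param models a [gene_models()] object providing per-chromosome gene
#'   totals.
#' @param side `"5prime"`, `"3prime"` or `"both"`.
#' @return data.frame: `chrom`, `observed`, `background_genes`,
#'   `background_proportion`, `p_value` (one-sided, greater), `q_value`
#'   (BH).
#' @export
chromosome_enrichment <- function(calls, models,
                                  side = c("both", "5prime", "3prime")) {
  side <- match.arg(side)
  g <- models$genes
  sym2chr <- stats::setNames(g$chrom, g$symbol)
  pick <- function(genes) {
    genes <- unique(genes)
    chr <- sym2chr[genes]
    if (anyNA(chr))
      stop("parental gene(s) missing from annotation: ",
           paste(genes[is.na(chr)], collapse = ", "))
    chr
  }
  chroms <- switch(side,
    "5prime" = pick(calls$gene5),
    "3prime" = pick(calls$gene3),
    "both" = c(pick(calls$gene5), pick(calls$gene3)))
  bad <- setdiff(unique(chroms), unique(g$chrom))
  if (length(bad))
    stop("chromosome absent from annotation: ", paste(bad, collapse = ", "))
  bg <- table(g$chrom)
  n_total <- length(chroms)
  obs <- table(factor(chroms, levels = names(bg)))
  p0 <- as.numeric(bg) / sum(bg)
  # one-sided upper tail: P(X >= observed), X ~ Binomial(n_total, p0)
  pv <- stats::pbinom(as.integer(obs) - 1L, n_total, p0, lower.tail = FALSE)
  out <- data.frame(chrom = names(bg),
                    observed = as.integer(obs),
                    background_genes = as.integer(bg),
                    background_proportion = p0,
                    p_value = pv,
                    q_value = bh_adjust(pv),
                    stringsAsFactors = FALSE)
  out[order(out$chrom), , drop = FALSE]
}
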