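# Classification of chimera calls and the specificity filters.
#
# Location: parents on different chromosomes -> inter-chromosomal; same
# chromosome -> read-through iff strands agree, the 3' partner lies
# downstream of the 5' partner in the shared transcription direction, and
# the intergenic gap is at most `readthrough_gap`; otherwise
# intra-chromosomal. Junction site: each side is E when the breakpoint
# coincides (within `edge_tolerance`) with the strand-aware splice edge of
# an annotated exon — the donor (transcription-3') edge on the 5' side, the
# acceptor (transcription-5') edge on the 3' side — and M otherwise.

.loc_levels <- c("inter-chromosomal", "intra-chromosomal", "read-through")
.junc_levels <- c("EE", "EM", "ME", "MM")

gene_lookup <- function(models) {
  g <- models$genes
  stats::setNames(seq_len(nrow(g)), g$symbol)
}

#' Classify chimera calls by parental-gene location
#'
#' @param calls a `chimera_calls` data.frame.
#' @param models a [gene_models()] object; calls whose parents are missing
#'   from the annotation are classified from the call coordinates alone and
#'   flagged.
#' @param readthrough_gap maximum intergenic gap (bases) between the 5'
#'   partner's transcription end and the 3' partner's transcription start
#'   for a same-strand pair to count as read-through. Default 50 kb.
#' @return `calls` with added columns `location_category` (factor) and
#'   `location_flag` (`""` or `"parents-unannotated"`).
#' @export
classify_location <- function(calls, models, readthrough_gap = 50000L) {
  idx <- gene_lookup(models)
  g <- models$genes
  n <- nrow(calls)
  cat_out <- character(n)
  flag <- character(n)
  for (i in seq_len(n)) {
    i5 <- idx[calls$gene5[i]]; i3 <- idx[calls$gene3[i]]
    annotated <- !is.na(i5) && !is.na(i3)
    if (annotated) {
      if (g$chrom[i5] != calls$chrom5[i] || g$chrom[i3] != calls$chrom3[i])
        stop("call ", calls$call_id[i],
             ": chromosomes contradict the annotation")
      chrom5 <- g$chrom[i5]; chrom3 <- g$chrom[i3]
      strand5 <- g$strand[i5]; strand3 <- g$strand[i3]
    } else {
      flag[i] <- "parents-unannotated"
      chrom5 <- calls$chrom5[i]; chrom3 <- calls$chrom3[i]
      strand5 <- calls$strand5[i]; strand3 <- calls$strand3[i]
    }
    if (chrom5 != chrom3) {
      cat_out[i] <- "inter-chromosomal"
      next
    }
    rt <- FALSE
    if (strand5 == strand3) {
      if (annotated) {
        gap <- if (strand5 == "+") g$start[i3] - g$end[i5]
               else g$start[i5] - g$end[i3]
      } else {
        # fall back to breakpoints when the genes are unannotated
        gap <- if (strand5 == "+") calls$breakpoint3[i] - calls$breakpoint5[i]
               else calls$breakpoint5[i] - calls$breakpoint3[i]
      }
      rt <- gap >= 0 && gap <= readthrough_gap
    }
    cat_out[i] <- if (rt) "read-through" else "intra-chromosomal"
  }
  calls$location_category <- factor(cat_out, levels = .loc_levels)
  calls$location_flag <- flag
  calls
}

# Strand-aware exon edges, 0-based positions of transcribed bases:
# donor edge = last transcribed base of an exon (end-1 on '+', start on '-');
# acceptor edge = first transcribed base (start on '+', end-1 on '-').
exon_edges <- function(models, symbol, which = c("donor", "acceptor")) {
  which <- match.arg(which)
  ex <- models$exons[models$exons$symbol == symbol, , drop = FALSE]
  if (nrow(ex) == 0) return(NULL)
  plus <- ex$strand[1] == "+"
  if (which == "donor") {
    if (plus) ex$end - 1L else ex$start
  } else {
    if (plus) ex$start else ex$end - 1L
  }
}

#' Classify chimera calls by junction-site position
#'
#' Each junction side is labelled `E` (edge) when the breakpoint coincides
#' with the strand-aware splice edge of an annotated exon of the parental
#' gene, and `M` (middle) otherwise; the pair is combined as
#' `EE`/`EM`/`ME`/`MM`. A breakpoint falling outside all exons and introns
#' of its gene is flagged `outside-gene` and labelled `M`.
#'
#' @inheritParams classify_location
#' @param edge_tolerance maximum distance (bases) from an exon edge still
#'   counted as `E`. Default 0 (exact splice-site coincidence).
#' @return `calls` with added columns `junction_site_category` (factor),
#'   `junction_side5`, `junction_side3`, `junction_flag`.
#' @export
classify_junction_site <- function(calls, models, edge_tolerance = 0L) {
  n <- nrow(calls)
  side5 <- character(n); side3 <- character(n); flag <- character(n)
  g <- models$genes
  idx <- gene_lookup(models)
  side_of <- function(symbol, bp, which) {
    edges <- exon_edges(models, symbol, which)
    if (is.null(edges)) return(list(side = "M", flag = "gene-unannotated"))
    i <- idx[symbol]
    fl <- ""
    if (bp < g$start[i] || bp >= g$end[i]) fl <- "outside-gene"
    side <- if (any(abs(edges - bp) <= edge_tolerance)) "E" else "M"
    if (fl == "outside-gene") side <- "M"
    list(side = side, flag = fl)
  }
  for (i in seq_len(n)) {
    s5 <- side_of(calls$gene5[i], calls$breakpoint5[i], "donor")
    s3 <- side_of(calls$gene3[i], calls$breakpoint3[i], "acceptor")
    side5[i] <- s5$side; side3[i] <- s3$side
    fl <- c(if (nzchar(s5$flag)) paste0("5:", s5$flag),
            if (nzchar(s3$flag)) paste0("3:", s3$flag))
    flag[i] <- paste(fl, collapse = ";")
  }
  calls$junction_side5 <- side5
  calls$junction_side3 <- side3
  calls$junction_site_category <- factor(paste0(side5, side3),
                                         levels = .junc_levels)
  calls$junction_flag <- flag
  calls
}

panel_key <- function(g5, g3) paste(g5, g3, sep = "\r")

#' Filter calls against a normal-tissue background panel
#'
#' Removes every call whose key matches a panel entry. The default
#' `"gene-pair"` mode keys on the ordered pair (gene5 -> gene3); the
#' `"breakpoint"` mode additionally requires both breakpoints to lie within
#' `breakpoint_tol` bases of a panel entry's breakpoints.
#'
#' @param calls a `chimera_calls` data.frame.
#' @param panel a `background_panel` (see [read_panel()]).
#' @param match_mode `"gene-pair"` (default) or `"breakpoint"`.
#' @param breakpoint_tol tolerance in bases for breakpoint mode.
#' @return list with `retained` (calls) and `report` (a `filter_report`).
#' @export
filter_background <- function(calls, panel, match_mode = c("gene-pair",
                                                           "breakpoint"),
                              breakpoint_tol = 10L) {
  match_mode <- match.arg(match_mode)
  if (nrow(calls) == 0 || nrow(panel) == 0) {
    removed <- rep(FALSE, nrow(calls))
  } else if (match_mode == "gene-pair") {
    removed <- panel_key(calls$gene5, calls$gene3) %in%
      panel_key(panel$gene5, panel$gene3)
  } else {
    if (!all(c("breakpoint5", "breakpoint3") %in% names(panel)))
      stop("breakpoint match mode requires panel breakpoint columns")
    removed <- vapply(seq_len(nrow(calls)), function(i) {
      hit <- panel$gene5 == calls$gene5[i] & panel$gene3 == calls$gene3[i] &
        abs(panel$breakpoint5 - calls$breakpoint5[i]) <= breakpoint_tol &
        abs(panel$breakpoint3 - calls$breakpoint3[i]) <= breakpoint_tol
      any(hit, na.rm = TRUE)
    }, logical(1))
  }
  report <- filter_report(
    n_input = nrow(calls),
    removed = data.frame(call_id = calls$call_id[removed],
                         reason = rep("background-panel", sum(removed)),
                         stringsAsFactors = FALSE))
  list(retained = calls[!removed, , drop = FALSE], report = report)
}

#' Remove M/M junction-site calls
#'
#' Drops every call classified `MM` (both breakpoints in exon middles);
#' `EE`/`EM`/`ME` calls are retained. Calls must have been classified with
#' [classify_junction_site()] first.
#'
#' @param calls a classified `chimera_calls` data.frame.
#' @return list with `retained` and `report` (a `filter_report`).
#' @export
filter_mm <- function(calls) {
  if (nrow(calls) > 0 &&
      (is.null(calls$junction_site_category) ||
       anyNA(calls$junction_site_category)))
    stop("calls must be classified with classify_junction_site() before ",
         "the MM filter")
  removed <- if (nrow(calls)) calls$junction_site_category == "MM" else logical(0)
  report <- filter_report(
    n_input = nrow(calls),
    removed = data.frame(call_id = calls$call_id[removed],
                         reason = rep("MM-junction", sum(removed)),
                         stringsAsFactors = FALSE))
  list(retained = calls[!removed, , drop = FALSE], report = report)
}

filter_report <- function(n_input, removed) {
  structure(list(
    n_input = n_input,
    n_removed_panel = sum(removed$reason == "background-panel"),
    n_removed_mm = sum(removed$reason == "MM-junction"),
    n_retained = n_input - nrow(removed),
    removed = removed), class = "filter_report")
}

combine_reports <- function(panel_rep, mm_rep) {
  removed <- rbind(panel_rep$removed, mm_rep$removed)
  structure(list(
    n_input = panel_rep$n_input,
    n_removed_panel = panel_rep$n_removed_panel,
    n_removed_mm = mm_rep$n_removed_mm,
    n_retained = panel_rep$n_input - nrow(removed),
    removed = removed), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "calls in;",
      x$n_removed_panel, "removed (background panel),",
      x$n_removed_mm, "removed (MM junction);",
      x$n_retained, "retained\n")
  invisible(x)
}

#' Tabulate location and junction-site categories
#'
#' @param calls classified `chimera_calls`.
#' @return data.frame with columns `axis` (`location`/`junction_site`),
#'   `category`, `n`, `proportion`; proportions sum to 1 within each axis.
#' @export
category_summary <- function(calls) {
  if (nrow(calls) == 0) {
    warning("no calls to summarise")
    return(data.frame(axis = character(), category = character(),
                      n = integer(), proportion = numeric()))
  }
  one_axis <- function(axis, values, levels) {
    tab <- table(factor(values, levels = levels))
    data.frame(axis = axis, category = names(tab), n = as.integer(tab),
               proportion = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    if (!is.null(calls$location_category))
      one_axis("location", calls$location_category, .loc_levels),
    if (!is.null(calls$junction_site_category))
      one_axis("junction_site", calls$junction_site_category, .junc_levels))
  rownames(out) <- NULL
  out
}

#' Run the full screening stage
#'
#' Applies, in order: background-panel filter, location classification,
#' junction-site classification, MM filter, category summary — the
#' specificity-screening stage of the pipeline.
#'
#' @inheritParams classify_location
#' @inheritParams classify_junction_site
#' @inheritParams filter_background
#' @return list with `retained` (classified, filtered calls), `report`
#'   (combined `filter_report`), `summary` (category table of retained
#'   calls).
#' @export
screen_calls <- function(calls, models, panel,
                         readthrough_gap = 50000L, edge_tolerance = 0L,
                         match_mode = "gene-pair", breakpoint_tol = 10L) {
  fb <- filter_background(calls, panel, match_mode = match_mode,
                          breakpoint_tol = breakpoint_tol)
  kept <- classify_location(fb$retained, models,
                            readthrough_gap = readthrough_gap)
  kept <- classify_junction_site(kept, models,
                                 edge_tolerance = edge_tolerance)
  fm <- filter_mm(kept)
  smry <- if (nrow(fm$retained)) category_summary(fm$retained) else
    suppressWarnings(category_summary(fm$retained))
  list(retained = fm$retained,
       report = combine_reports(fb$report, fm$report),
       summary = smry)
}
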