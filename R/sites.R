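#' Aggregate hybrids into target sites
#'
#' Hybrids sharing the same small RNA and the same (extended) mRNA target
#' window represent a common target site.  Weights are summed; the weight of
#' hybrids carrying at least one deletion (and, separately, at least one
#' substitution) is tallied per site.  Sites are sorted by transcript,
#' window start, then small RNA id.
#'
#' @param hybrids hybrid table carrying `window_start`, `window_end` and
#'   `score` columns (added by [run_pipeline()] via [extend_site()]).
#' @param cims filtered mutation table (used to flag carrier hybrids).
#' @return data.frame of sites: ids, window, `total_weight`, `n_hybrids`,
#'   `cim_del_weight`, `cim_sub_weight`, `score`, plus a `site_id` key.
#' @export
aggregate_sites <- function(hybrids, cims = NULL) {
  if (nrow(hybrids) == 0) {
    return(empty_df(list(site_id = character(), srna_id = character(),
                         transcript_id = character(), window_start = integer(),
                         window_end = integer(), total_weight = numeric(),
                         n_hybrids = integer(), cim_del_weight = numeric(),
                         cim_sub_weight = numeric(), score = numeric())))
  }
  key <- paste(hybrids$srna_id, hybrids$transcript_id, hybrids$window_start,
               hybrids$window_end, sep = "|")
  del_reads <- sub_reads <- character(0)
  if (!is.null(cims) && nrow(cims)) {
    del_reads <- unique(cims$read_id[cims$kind == "deletion"])
    sub_reads <- unique(cims$read_id[cims$kind == "substitution"])
  }
  grp <- split(seq_len(nrow(hybrids)), key)
  out <- lapply(names(grp), function(k) {
    idx <- grp[[k]]
    h <- hybrids[idx, , drop = FALSE]
    data.frame(site_id = k, srna_id = h$srna_id[1],
               transcript_id = h$transcript_id[1],
               window_start = h$window_start[1],
               window_end = h$window_end[1],
               total_weight = sum(h$weight), n_hybrids = nrow(h),
               cim_del_weight = sum(h$weight[h$read_id %in% del_reads]),
               cim_sub_weight = sum(h$weight[h$read_id %in% sub_reads]),
               score = h$score[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$transcript_id, out$window_start, out$srna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Abundance tier of a target site
#'
#' High for (normalized) read counts >= 5, medium for counts in `[2, 5)`,
#' low for counts below 2 (a single read, or fractional weights from
#' ambiguity splitting).
#'
#' @param total_weight site read count(s).
#' @return character vector of tiers.
#' @export
classify_abundance <- function(total_weight) {
  stopifnot(all(total_weight > 0))
  ifelse(total_weight >= 5, "high", ifelse(total_weight >= 2, "medium", "low"))
}

#' Score tertiles of target sites
#'
#' Sites are ranked by score (descending, ties by small RNA then transcript
#' id) and split into thirds: the top tier takes `ceiling(n/3)` sites, the
#' middle tier `ceiling((n - top)/2)`, the rest are low.  Fewer than 3
#' scored sites are all `"unclassified"`.
#'
#' @param sites site table with a `score` column.
#' @return the site table with a `score_tier` column added.
#' @export
classify_score_tertiles <- function(sites) {
  n <- nrow(sites)
  sites$score_tier <- rep("unclassified", n)
  scored <- which(!is.na(sites$score))
  if (length(scored) < 3) return(sites)
  ord <- scored[order(-sites$score[scored], sites$srna_id[scored],
                      sites$transcript_id[scored])]
  m <- length(ord)
  n_high <- ceiling(m / 3)
  n_med <- ceiling((m - n_high) / 2)
  tier <- c(rep("high", n_high), rep("medium", n_med),
            rep("low", m - n_high - n_med))
  sites$score_tier[ord] <- tier
  sites
}

#' Correlation between CIM-carrying and total hybrid abundance
#'
#' Pearson correlation across sites between the weight of mutation-carrying
#' hybrids (deletions and substitutions separately) and the total hybrid
#' weight.  Zero variance in either variable yields `NA`.
#'
#' @param sites site table ([aggregate_sites()]).
#' @return list with elements `deletion` and `substitution`.
#' @export
cim_abundance_correlation <- function(sites) {
  if (nrow(sites) < 3) stop_ctx("need at least 3 sites")
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  list(deletion = safe_cor(sites$cim_del_weight, sites$total_weight),
       substitution = safe_cor(sites$cim_sub_weight, sites$total_weight))
}

#' Flag sites with poor targeting scores
#'
#' @param score numeric site score(s).
#' @param tool scoring tool the scores came from: `"pirscan"` (poor below
#'   -15), `"miranda"` (poor below 140) or `"builtin"`.
#' @param builtin_threshold poor-score cutoff for the built-in scorer.
#' @return logical vector: `TRUE` when the score is strictly below the
#'   tool's threshold.
#' @export
flag_poor_score <- function(score, tool, builtin_threshold = 12) {
  thr <- switch(tool,
                pirscan = -15,
                miranda = 140,
                builtin = builtin_threshold,
                stop_ctx("unknown scoring tool: ", tool))
  score < thr
}
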