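# Scoring predictions against references: Spearman rank correlation at the
# alpha-carbon level, best-of-replicates aggregation, descriptive summaries.

#' Spearman correlation at alpha carbons
#'
#' Rank correlation (average ranks for ties) between predicted and reference
#' values restricted to the masked positions. Rank-based, so invariant under
#' any strictly increasing transform of either argument.
#'
#' @param pred,ref numeric vectors of equal length.
#' @param ca_mask logical vector marking the alpha-carbon positions
#'   (default: all positions).
#' @return Spearman rho, or NaN with a warning if either masked vector has
#'   zero variance.
#' @export
spearman_ca <- function(pred, ref, ca_mask = NULL) {
  pred <- as.numeric(pred)
  ref <- as.numeric(ref)
  if (length(pred) != length(ref))
    stop("prediction and reference lengths differ")
  if (is.null(ca_mask)) ca_mask <- rep(TRUE, length(pred))
  p <- pred[ca_mask]
  r <- ref[ca_mask]
  if (length(p) < 3) stop("need at least 3 masked atoms for a correlation")
  if (sd(p) == 0 || sd(r) == 0) {
    warning("zero variance in masked values; correlation undefined")
    return(NaN)
  }
  cor(p, r, method = "spearman")
}

#' Best-of-replicates aggregation
#'
#' For each protein scored against several replicate references, keeps the
#' maximum correlation, then summarizes the maxima.
#'
#' @param scores data.frame with columns `id`, `replicate`, `rho`.
#' @return List with `per_protein` (data.frame: id, best_rho, best_replicate),
#'   `mean` and `median` of the per-protein maxima (NaN/NA excluded, with a
#'   count in `n_excluded`).
#' @export
best_of_replicates <- function(scores) {
  if (!all(c("id", "replicate", "rho") %in% names(scores)) ||
      nrow(scores) < 1)
    stop("scores must be a non-empty data.frame with id, replicate, rho")
  per <- do.call(rbind, lapply(split(scores, scores$id), function(d) {
    ok <- is.finite(d$rho)
    if (!any(ok))
      return(data.frame(id = d$id[1], best_rho = NA_real_,
                        best_replicate = NA))
    b <- which(d$rho == max(d$rho[ok]) & ok)[1]
    data.frame(id = d$id[1], best_rho = d$rho[b],
               best_replicate = d$replicate[b])
  }))
  rownames(per) <- NULL
  ok <- is.finite(per$best_rho)
  list(per_protein = per,
       mean = mean(per$best_rho[ok]),
       median = median(per$best_rho[ok]),
       n_excluded = sum(!ok))
}

#' Descriptive summary of per-protein correlations
#'
#' Mean, median and quartiles of the scores, with undefined (NaN/NA) scores
#' excluded and tallied, and negative-correlation outliers flagged.
#'
#' @param rho numeric vector of per-protein correlations.
#' @param ids optional protein identifiers for the outlier report.
#' @return List with `n`, `n_excluded`, `mean`, `median`, `q1`, `q3` and
#'   `outliers` (ids or indices with rho < 0).
#' @export
summarize_scores <- function(rho, ids = NULL) {
  if (length(rho) < 1) stop("no scores to summarize")
  if (is.null(ids)) ids <- seq_along(rho)
  ok <- is.finite(rho)
  r <- rho[ok]
  list(n = length(r), n_excluded = sum(!ok),
       mean = mean(r), median = median(r),
       q1 = unname(quantile(r, 0.25)), q3 = unname(quantile(r, 0.75)),
       outliers = ids[ok][r < 0])
}
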