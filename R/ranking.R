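# Candidate-ligand re-ranking: nonparametric combination of the density-fit
# term (RSCC) with the normalized interaction energy.

#' Combine density fit and normalized energy into a candidate ranking
#'
#' Each metric is converted to a within-list rank (RSCC: higher is better;
#' normalized energy: lower is better; ties share the mean rank) and the
#' combined score is the mean of the two ranks -- a nonparametric average
#' that is invariant under any order-preserving transformation of either
#' metric.  Candidates are ordered by ascending combined score; ties are
#' broken by the better normalized energy, then lexicographically by id.
#'
#' @param candidates A data frame with columns \code{ligand_id}, \code{rscc},
#'   \code{e_normalized}, or a list of \code{c(id, rscc, e_normalized)}
#'   triples.
#' @param method \code{"rank"} (the nonparametric average, default) or
#'   \code{"minmax"} (mean of min-max-rescaled metrics, provided for
#'   comparison).
#' @return The candidate data frame with columns \code{combined} and
#'   \code{rank} (1 = best), ordered by rank.
#' @export
combined_rank <- function(candidates, method = c("rank", "minmax")) {
  method <- match.arg(method)
  cand <- .as_candidates(candidates)
  n <- nrow(cand)
  if (n < 1L) stop("at least one candidate required")
  if (any(is.na(cand$rscc))) stop("missing RSCC for candidate(s): ",
                                  paste(cand$ligand_id[is.na(cand$rscc)],
                                        collapse = ", "))
  if (method == "rank") {
    r_rscc <- rank(-cand$rscc, ties.method = "average")
    r_e <- rank(cand$e_normalized, ties.method = "average")
    cand$combined <- (r_rscc + r_e) / 2
  } else {
    mm <- function(x, higher_better) {
      if (max(x) == min(x)) return(rep(0.5, length(x)))
      z <- (x - min(x)) / (max(x) - min(x))
      if (higher_better) z else 1 - z
    }
    # rescaled goodness in [0, 1]; invert to ascending-is-better score
    cand$combined <- 1 - (mm(cand$rscc, TRUE) +
                            mm(cand$e_normalized, FALSE)) / 2
  }
  ord <- order(cand$combined, cand$e_normalized, cand$ligand_id)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(n)
  rownames(cand) <- NULL
  cand
}

.as_candidates <- function(x) {
  if (is.data.frame(x)) {
    need <- c("ligand_id", "rscc", "e_normalized")
    if (!all(need %in% names(x)))
      stop("candidate table needs columns: ", paste(need, collapse = ", "))
    out <- x[, need, drop = FALSE]
  } else if (is.list(x)) {
    out <- do.call(rbind, lapply(x, function(t) {
      data.frame(ligand_id = as.character(t[[1]]),
                 rscc = as.numeric(t[[2]]),
                 e_normalized = as.numeric(t[[3]]),
                 stringsAsFactors = FALSE)
    }))
  } else stop("cannot interpret candidates")
  out$ligand_id <- as.character(out$ligand_id)
  out
}

#' Tabular ranking report
#'
#' @param candidates Output of \code{\link{combined_rank}} (or raw candidates,
#'   which are ranked first).
#' @param path Optional path; when given, the table is written as TSV.
#' @return Data frame with columns \code{ligand_id}, \code{rscc},
#'   \code{e_normalized}, \code{combined}, \code{rank}, \code{category}.
#' @export
rank_report <- function(candidates, path = NULL) {
  cand <- if (is.data.frame(candidates) && "rank" %in% names(candidates))
    candidates else combined_rank(candidates)
  cand$category <- vapply(cand$e_normalized, classify_complex, character(1))
  cand <- cand[, c("ligand_id", "rscc", "e_normalized", "combined", "rank",
                   "category")]
  if (!is.null(path))
    utils::write.table(cand, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  cand
}
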