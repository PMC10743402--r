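#' Local rank scores from raw method scores
#'
#' Converts a column of raw method scores into rank scores in `(0, 1]`:
#' scores are oriented so that higher means more damaging, then mapped to
#' `rank / N` over the non-missing values, with ties receiving their mean
#' rank. This mirrors the dbNSFP rank-score convention but is computed
#' locally over the supplied column only, so it is an approximation used
#' when genome-wide rank scores are not available as input.
#'
#' @param scores numeric vector (may contain `NA`)
#' @param direction `"higher_is_pathogenic"` or `"lower_is_pathogenic"`
#' @return numeric vector aligned with `scores`; `NA` preserved
#' @examples
#' rank_scores_from_raw(c(0.1, 0.5, 0.9))   # 1/3, 2/3, 1
#' @export
rank_scores_from_raw <- function(scores,
                                 direction = c("higher_is_pathogenic",
                                               "lower_is_pathogenic")) {
  direction <- match.arg(direction)
  ok <- !is.na(scores)
  if (!any(ok)) stop("all scores are missing")
  s <- scores[ok]
  if (direction == "lower_is_pathogenic") s <- -s
  out <- rep(NA_real_, length(scores))
  out[ok] <- rank(s, ties.method = "average") / length(s)
  out
}

#' Mean rank score over a method panel
#'
#' Row-wise arithmetic mean of rank scores across methods, ignoring
#' missing values; the number of contributing methods is returned alongside.
#' A row with no non-missing rank score is an error.
#'
#' @param rank_scores data frame or matrix, one column per method
#' @return data frame with `mean_rank_score` and `n_methods`
#' @export
mean_rank_score <- function(rank_scores) {
  m <- as.matrix(as.data.frame(rank_scores))
  n_ok <- rowSums(!is.na(m))
  if (any(n_ok == 0L))
    stop("row(s) with no non-missing rank score: ",
         paste(which(n_ok == 0L), collapse = ", "))
  data.frame(mean_rank_score = rowMeans(m, na.rm = TRUE), n_methods = n_ok)
}

#' Consensus criteria for VUS prioritization
#'
#' @param construct_threshold ConStruct probability a VUS must strictly
#'   exceed (default 0.85)
#' @param required_methods method names that must all call the variant
#'   pathogenic
#' @param require_all if `TRUE` (default) every required method must call
#'   `P`; a missing call blocks selection
#' @return list of class `consensus_criteria`
#' @export
consensus_criteria <- function(construct_threshold = 0.85,
                               required_methods,
                               require_all = TRUE) {
  if (construct_threshold < 0 || construct_threshold > 1)
    stop("construct_threshold must be in [0, 1]")
  if (missing(required_methods) || length(required_methods) == 0L)
    stop("required_methods must be non-empty")
  structure(list(construct_threshold = construct_threshold,
                 required_methods = as.character(required_methods),
                 require_all = isTRUE(require_all)),
            class = "consensus_criteria")
}

#' Consensus prioritization of VUS
#'
#' Nominates probable pathogenic variants among VUS by consensus: a
#' variant is selected when (1) its ConStruct probability strictly exceeds
#' the criteria threshold and (2) every required method calls it
#' pathogenic (under `require_all`; a missing call blocks selection).
#' Variants are returned sorted by mean rank score over the rank-score
#' panel, descending, with ties broken by (`position`, `ref_aa`,
#' `alt_aa`) ascending, so the most strongly supported candidates head the
#' table.
#'
#' @param vus variant data frame (columns `position`, `ref_aa`, `alt_aa`,
#'   optionally `rs_id`, `allele_frequency`)
#' @param construct_probs numeric vector of ConStruct probabilities
#'   aligned with `vus` rows; missing values are an error
#' @param method_calls data frame/matrix of `P`/`B`/`NA` calls, columns
#'   named by method, rows aligned with `vus`
#' @param rank_scores data frame/matrix of rank scores for the mean
#'   rank-score panel, rows aligned with `vus`
#' @param criteria a [consensus_criteria()] object
#' @return data frame of class `prioritization`: the variant key columns
#'   plus `construct_probability`, `mean_rank_score`, `n_rank_methods`,
#'   `selected`, sorted as described
#' @export
consensus_select <- function(vus, construct_probs, method_calls,
                             rank_scores, criteria) {
  vus <- as.data.frame(vus)
  stopifnot(inherits(criteria, "consensus_criteria"))
  n <- nrow(vus)
  if (length(construct_probs) != n)
    stop("construct_probs not aligned with vus")
  if (anyNA(construct_probs))
    stop("missing ConStruct probability for ",
         sum(is.na(construct_probs)), " VUS")
  calls <- as.data.frame(method_calls)
  if (nrow(calls) != n) stop("method_calls not aligned with vus")
  miss <- setdiff(criteria$required_methods, names(calls))
  if (length(miss))
    stop("required method(s) missing from calls: ",
         paste(miss, collapse = ", "))
  req <- as.matrix(calls[criteria$required_methods])
  all_p <- if (criteria$require_all) {
    apply(req, 1L, function(r) all(!is.na(r) & r == "P"))
  } else {
    apply(req, 1L, function(r) any(!is.na(r) & r == "P"))
  }
  mrs <- mean_rank_score(rank_scores)
  out <- cbind(vus[intersect(c("position", "ref_aa", "alt_aa", "rs_id",
                               "allele_frequency"), names(vus))],
               construct_probability = construct_probs,
               mean_rank_score = mrs$mean_rank_score,
               n_rank_methods = mrs$n_methods,
               selected = construct_probs > criteria$construct_threshold &
                 all_p)
  o <- order(-out$mean_rank_score, out$position, out$ref_aa, out$alt_aa)
  structure(out[o, , drop = FALSE],
            class = c("prioritization", "data.frame"))
}

#' @export
print.prioritization <- function(x, ...) {
  cat(sprintf("VUS prioritization: %d variant(s), %d selected\n",
              nrow(x), sum(x$selected)))
  df <- as.data.frame(x)
  df$variant <- format_protein_variant(df$position, df$ref_aa, df$alt_aa)
  show <- utils::head(df[c("variant", "construct_probability",
                           "mean_rank_score", "selected")], 10L)
  print(show, row.names = FALSE)
  if (nrow(df) > 10L) cat("  ... and", nrow(df) - 10L, "more\n")
  invisible(x)
}
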