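# Rank-based (1D) annotation enrichment of dephosphorylation scores over
# flat term sets (GO-BP style), Mann-Whitney per term with BH correction.

#' Aggregate site scores to protein scores
#'
#' Terms annotate proteins while the pipeline scores sites, so site scores
#' are rolled up per protein before enrichment. Default aggregator is `max`:
#' a protein is a substrate if any of its sites is.
#'
#' @param scored Output of [score_table()] (needs `protein_id`, `score`).
#' @param agg `"max"` or `"mean"`.
#' @return Named numeric vector, protein id to aggregated score. Proteins
#'   with no scored site are absent.
#' @export
protein_scores <- function(scored, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  stopifnot(nrow(scored) > 0L)
  ok <- scored[!is.na(scored$score), , drop = FALSE]
  if (nrow(ok) == 0L) return(setNames(numeric(0), character(0)))
  f <- if (agg == "max") max else mean
  vapply(split(ok$score, ok$protein_id), f, numeric(1))
}

#' Rank-based enrichment score and Mann-Whitney p for one term
#'
#' `U` counts (member, other) pairs with member > other, ties as 1/2; the
#' enrichment score is `s = 2 * U / (n1 * n2) - 1`, in `[-1, 1]`, positive
#' when members tend to score higher. The two-sided p-value uses the exact
#' Mann-Whitney distribution when `n1 * n2 <= 400` and the values are
#' tie-free, and the normal approximation with tie and continuity correction
#' otherwise.
#'
#' @param member_values Scores of proteins annotated with the term.
#' @param other_values Scores of all other proteins.
#' @return List with `s`, `p`, `U`, `n1`, `n2`.
#' @export
enrichment_score <- function(member_values, other_values) {
  n1 <- length(member_values)
  n2 <- length(other_values)
  if (n1 == 0L || n2 == 0L) stop("both value lists must be nonempty")
  r <- rank(c(member_values, other_values))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  s <- 2 * U / (n1 * n2) - 1
  has_ties <- anyDuplicated(c(member_values, other_values)) > 0L
  if (n1 * n2 <= 400 && !has_ties) {
    p <- stats::wilcox.test(member_values, other_values, exact = TRUE)$p.value
  } else {
    p <- stats::wilcox.test(member_values, other_values, exact = FALSE,
                            correct = TRUE)$p.value
  }
  list(s = s, p = min(p, 1), U = U, n1 = n1, n2 = n2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values aligned with `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run annotation enrichment over a term map
#'
#' Tests each term with at least `min_size` members among the scored
#' proteins, using the rank-based enrichment score against all other scored
#' proteins, and applies BH correction across all tested terms.
#'
#' @param scores Named numeric vector from [protein_scores()].
#' @param annotations Named list: term id to character vector of protein ids.
#' @param min_size Minimum term size after intersection with scored proteins
#'   (default 5; smaller terms give degenerate rank tests).
#' @param term_names Optional named character vector of display names.
#' @return `data.frame` with one row per tested term: `term_id`, `term_name`,
#'   `n_members`, `mean_score`, `s`, `p`, `q`, sorted by increasing `q` then
#'   `p`.
#' @export
run_enrichment <- function(scores, annotations, min_size = 5L,
                           term_names = NULL) {
  stopifnot(length(scores) > 0L)
  universe <- names(scores)
  members <- lapply(annotations, function(ids) intersect(ids, universe))
  sizes <- vapply(members, length, integer(1))
  testable <- names(annotations)[sizes >= min_size &
                                   sizes < length(universe)]
  if (length(testable) == 0L) {
    stop("no term has >= ", min_size, " scored members")
  }
  rows <- lapply(testable, function(tid) {
    m <- members[[tid]]
    es <- enrichment_score(scores[m], scores[setdiff(universe, m)])
    data.frame(term_id = tid,
               term_name = if (!is.null(term_names) && tid %in%
                               names(term_names)) term_names[[tid]] else tid,
               n_members = length(m),
               mean_score = mean(scores[m]),
               s = es$s, p = es$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$q, out$p, out$term_id), , drop = FALSE]
}

#' Filter an enrichment table the way the headline analysis reports it
#'
#' Keeps terms with `mean_score > score_min` and `q < q_max`, both strict.
#'
#' @param enrichment Output of [run_enrichment()].
#' @param score_min Minimum mean dephosphorylation score (default 1).
#' @param q_max FDR cut-off (default 0.02).
#' @return Filtered rows.
#' @export
filter_enrichment <- function(enrichment, score_min = 1, q_max = 0.02) {
  enrichment[enrichment$mean_score > score_min & enrichment$q < q_max, ,
             drop = FALSE]
}

#' Read a term-to-protein annotation map (TSV)
#'
#' Two required columns `term_id`, `protein_id` (one pair per line), optional
#' third column `term_name`.
#'
#' @param path Path to the TSV.
#' @return List with `annotations` (named list of protein id vectors) and
#'   `term_names` (named character vector, possibly empty).
#' @export
read_annotation_map <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("term_id", "protein_id") %in% names(tab)))
  annotations <- lapply(split(tab$protein_id, tab$term_id), unique)
  term_names <- character(0)
  if ("term_name" %in% names(tab)) {
    first <- !duplicated(tab$term_id)
    term_names <- setNames(tab$term_name[first], tab$term_id[first])
  }
  list(annotations = annotations, term_names = term_names)
}
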