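# Forward/reverse SILAC dephosphorylation scoring.
#
# Conditions: 1 = constitutively active holoenzyme cofactor (Phactr1-XXX),
# 2 = PP1-binding-deficient control (Phactr1-XXX-dC), 3 = empty vector.
# H/L = heavy (R10K8) / light (R0K0) labelling. All four ratios are stored as
# control over active-complex signal, so a high score means the site is
# dephosphorylated in a holoenzyme-dependent manner.

RATIO_SLOTS <- c("r2H1L", "r3H1L", "r2L1H", "r3L1H")

#' Compute the dephosphorylation score for one site
#'
#' The complete-case score is the geometric mean of the four control/active
#' SILAC ratios: `log2(score) = 0.25 * (log2 r2H1L + log2 r3H1L +
#' log2 r2L1H + log2 r3L1H)`. Under the `"balanced"` missing-data policy the
#' score is the mean of the available log2 ratios, requiring at least
#' `min_ratios` present and at least one ratio from each labelling
#' orientation (forward `*H1L`, reverse `*L1H`).
#'
#' @param ratios Named list or vector with elements `r2H1L`, `r3H1L`,
#'   `r2L1H`, `r3L1H`; missing ratios as `NA`.
#' @param policy `"strict"` (all four ratios required) or `"balanced"`.
#' @param min_ratios Minimum ratios required under `"balanced"` (default 2).
#' @return List with `log2_score`, `score`, `n_ratios_used`, `scored`
#'   (logical). Sites failing the policy are returned unscored
#'   (`scored = FALSE`, scores `NA`), not dropped.
#' @export
compute_dephos_score <- function(ratios, policy = c("strict", "balanced"),
                                 min_ratios = 2L) {
  policy <- match.arg(policy)
  r <- unlist(ratios)[RATIO_SLOTS]
  names(r) <- RATIO_SLOTS
  present <- !is.na(r)
  if (any(r[present] <= 0)) {
    stop("nonpositive SILAC ratio: ",
         paste(names(r)[present & r <= 0], collapse = ", "))
  }
  ok <- if (policy == "strict") {
    all(present)
  } else {
    sum(present) >= min_ratios &&
      any(present[c("r2H1L", "r3H1L")]) &&
      any(present[c("r2L1H", "r3L1H")])
  }
  if (!ok) {
    return(list(log2_score = NA_real_, score = NA_real_,
                n_ratios_used = 0L, scored = FALSE))
  }
  log2_score <- mean(log2(r[present]))
  list(log2_score = log2_score, score = 2^log2_score,
       n_ratios_used = sum(present), scored = TRUE)
}

#' Score a site table
#'
#' Applies [compute_dephos_score()] row-wise. The design maps each ratio slot
#' to one quantification column and states the orientation in which that
#' column is stored; columns stored as active/control are inverted at mapping
#' time.
#'
#' @param table Site table with quantification columns.
#' @param design Named list mapping each of `r2H1L`, `r3H1L`, `r2L1H`,
#'   `r3L1H` either to a column name (string, assumed stored as
#'   control/active) or to `list(column =, invert = TRUE/FALSE)`.
#' @param policy,min_ratios Passed to [compute_dephos_score()].
#' @return `data.frame` with `site_id`, `protein_id`, `log2_score`, `score`,
#'   `n_ratios_used`, `scored` (plus `window` when present in the input).
#' @export
score_table <- function(table, design, policy = c("strict", "balanced"),
                        min_ratios = 2L) {
  policy <- match.arg(policy)
  missing_slots <- setdiff(RATIO_SLOTS, names(design))
  if (length(missing_slots) > 0L) {
    stop("design missing slot(s): ", paste(missing_slots, collapse = ", "))
  }
  out <- data.frame(site_id = character(0), protein_id = character(0),
                    log2_score = numeric(0), score = numeric(0),
                    n_ratios_used = integer(0), scored = logical(0),
                    stringsAsFactors = FALSE)
  ratio_mat <- matrix(NA_real_, nrow = nrow(table), ncol = 4L,
                      dimnames = list(NULL, RATIO_SLOTS))
  for (slot in RATIO_SLOTS) {
    d <- design[[slot]]
    if (is.character(d)) d <- list(column = d, invert = FALSE)
    if (!d$column %in% names(table)) {
      stop("design slot ", slot, " refers to absent column '", d$column, "'")
    }
    v <- as.numeric(table[[d$column]])
    if (isTRUE(d$invert)) v <- 1 / v
    ratio_mat[, slot] <- v
  }
  if (nrow(table) == 0L) return(out)
  scored <- lapply(seq_len(nrow(table)), function(i) {
    compute_dephos_score(ratio_mat[i, ], policy = policy,
                         min_ratios = min_ratios)
  })
  out <- data.frame(
    site_id = table$site_id,
    protein_id = table$protein_id,
    log2_score = vapply(scored, `[[`, numeric(1), "log2_score"),
    score = vapply(scored, `[[`, numeric(1), "score"),
    n_ratios_used = vapply(scored, `[[`, integer(1), "n_ratios_used"),
    scored = vapply(scored, `[[`, logical(1), "scored"),
    stringsAsFactors = FALSE
  )
  if (!is.null(table$window)) out$window <- table$window
  out
}

#' Select substrate candidates above a score threshold
#'
#' @param scored Output of [score_table()].
#' @param threshold Score cut-off; rows with `score > threshold` (strict) are
#'   kept. Default 2.5, the cut-off at which the acidic/hydrophobic sequence
#'   bias of holoenzyme substrates becomes apparent.
#' @return The selected rows sorted by descending score, ties broken by
#'   `site_id` for determinism.
#' @export
select_candidates <- function(scored, threshold = 2.5) {
  stopifnot(nrow(scored) > 0L)
  keep <- scored[!is.na(scored$score) & scored$score > threshold, ,
                 drop = FALSE]
  keep[order(-keep$score, keep$site_id), , drop = FALSE]
}
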