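# TMT differential phosphoproteomics: per-sample Z-score normalisation,
# within-block (DMSO - CD) treatment deltas, Welch two-sample testing of
# wild-type versus knockout deltas, and overlap with SILAC candidates.

#' Build a TMT sample design table
#'
#' One row per sample; each (genotype, treatment, replicate, region, ms_mode)
#' combination must be unique. Sample names are synthesised as
#' `<genotype>_<treatment>_rep<replicate>_<region>_<ms_mode>`.
#'
#' @param genotypes,treatments,replicates,regions,ms_modes Factors crossed to
#'   form the design (defaults: WT/KO, DMSO/CD, 2 replicates,
#'   cortical/hippocampal, MS2/MS3).
#' @return `data.frame` of class `tmt_design` with columns `sample`,
#'   `genotype`, `treatment`, `replicate`, `region`, `ms_mode`.
#' @export
tmt_design <- function(genotypes = c("WT", "KO"),
                       treatments = c("DMSO", "CD"),
                       replicates = 1:2,
                       regions = c("cortical", "hippocampal"),
                       ms_modes = c("MS2", "MS3")) {
  d <- expand.grid(genotype = genotypes, treatment = treatments,
                   replicate = replicates, region = regions,
                   ms_mode = ms_modes, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  d$sample <- paste(d$genotype, d$treatment, paste0("rep", d$replicate),
                    d$region, d$ms_mode, sep = "_")
  if (anyDuplicated(d$sample)) stop("design rows are not unique")
  structure(d[, c("sample", "genotype", "treatment", "replicate", "region",
                  "ms_mode")], class = c("tmt_design", "data.frame"))
}

#' Z-score normalise a TMT intensity matrix per sample column
#'
#' Each column is transformed to mean 0 and sample SD 1 over its present
#' (non-missing) values; missing entries are preserved.
#'
#' @param matrix Numeric sites x samples matrix (log intensities).
#' @return Normalised matrix of the same shape.
#' @export
zscore_normalize <- function(matrix) {
  stopifnot(is.matrix(matrix))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    v <- matrix[, j]
    ok <- is.finite(v)
    if (sum(ok) < 2L || stats::sd(v[ok]) == 0) {
      stop("sample column ", if (!is.null(colnames(matrix)))
        colnames(matrix)[j] else j, " is constant or nearly empty")
    }
    out[ok, j] <- (v[ok] - mean(v[ok])) / stats::sd(v[ok])
  }
  out
}

#' Per-site, per-genotype treatment deltas
#'
#' Computes `delta = value_<trt_a> - value_<trt_b>` (default DMSO - CD)
#' within each (replicate, region, ms_mode) block, then pools blocks across
#' region and MS mode, yielding one delta vector per genotype per site.
#' Blocks missing either treatment are skipped with a warning.
#'
#' @param matrix Normalised sites x samples matrix with column names matching
#'   `design$sample`.
#' @param design A [tmt_design()].
#' @param pair Character pair `c(trt_a, trt_b)`, default `c("DMSO", "CD")`.
#' @return List with `delta` (list: genotype -> sites x blocks matrix) and
#'   `n_skipped_blocks`.
#' @export
treatment_deltas <- function(matrix, design, pair = c("DMSO", "CD")) {
  stopifnot(all(colnames(matrix) %in% design$sample))
  design <- design[match(colnames(matrix), design$sample), , drop = FALSE]
  genotypes <- unique(design$genotype)
  n_skipped <- 0L
  delta <- list()
  for (g in genotypes) {
    blocks <- unique(design[design$genotype == g,
                            c("replicate", "region", "ms_mode")])
    cols <- list()
    for (b in seq_len(nrow(blocks))) {
      sel <- design$genotype == g &
        design$replicate == blocks$replicate[b] &
        design$region == blocks$region[b] &
        design$ms_mode == blocks$ms_mode[b]
      a_col <- which(sel & design$treatment == pair[1L])
      b_col <- which(sel & design$treatment == pair[2L])
      if (length(a_col) != 1L || length(b_col) != 1L) {
        n_skipped <- n_skipped + 1L
        next
      }
      cols[[length(cols) + 1L]] <- matrix[, a_col] - matrix[, b_col]
    }
    delta[[g]] <- do.call(cbind, cols)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " unpaired block(s) skipped")
  }
  list(delta = delta, n_skipped_blocks = n_skipped)
}

#' Welch test of wild-type versus knockout treatment deltas for one site
#'
#' The differential Z-score is `mean(delta_wt) - mean(delta_ko)`; p is the
#' two-sided Welch (unequal-variance) two-sample t-test with
#' Welch-Satterthwaite degrees of freedom. `pooled = TRUE` switches to the
#' equal-variance Student test.
#'
#' @param delta_wt,delta_ko Numeric delta vectors (length >= 2 each after
#'   removing missing values); shorter input marks the site untestable.
#' @param pooled Use pooled-variance t-test instead of Welch.
#' @return List with `diff_z`, `t_stat`, `df`, `p`, `testable`.
#' @export
differential_test <- function(delta_wt, delta_ko, pooled = FALSE) {
  delta_wt <- delta_wt[is.finite(delta_wt)]
  delta_ko <- delta_ko[is.finite(delta_ko)]
  if (length(delta_wt) < 2L || length(delta_ko) < 2L) {
    return(list(diff_z = NA_real_, t_stat = NA_real_, df = NA_real_,
                p = NA_real_, testable = FALSE))
  }
  diff_z <- mean(delta_wt) - mean(delta_ko)
  if (stats::sd(delta_wt) == 0 && stats::sd(delta_ko) == 0) {
    # degenerate: identical constant groups
    return(list(diff_z = diff_z, t_stat = if (diff_z == 0) 0 else Inf,
                df = length(delta_wt) + length(delta_ko) - 2,
                p = if (diff_z == 0) 1 else 0, testable = TRUE))
  }
  tt <- stats::t.test(delta_wt, delta_ko, var.equal = pooled)
  list(diff_z = diff_z, t_stat = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, testable = TRUE)
}

#' Run the differential test across all sites
#'
#' @param deltas Output of [treatment_deltas()] with genotypes `WT` and `KO`.
#' @param pooled Passed to [differential_test()].
#' @return `data.frame` with one row per site: `site_id`, `diff_z`, `t_stat`,
#'   `df`, `p`, `testable`.
#' @export
differential_table <- function(deltas, pooled = FALSE) {
  wt <- deltas$delta[["WT"]]
  ko <- deltas$delta[["KO"]]
  stopifnot(!is.null(wt), !is.null(ko), nrow(wt) == nrow(ko))
  ids <- rownames(wt)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(wt)))
  rows <- lapply(seq_len(nrow(wt)), function(i) {
    differential_test(wt[i, ], ko[i, ], pooled = pooled)
  })
  data.frame(
    site_id = ids,
    diff_z = vapply(rows, `[[`, numeric(1), "diff_z"),
    t_stat = vapply(rows, `[[`, numeric(1), "t_stat"),
    df = vapply(rows, `[[`, numeric(1), "df"),
    p = vapply(rows, `[[`, numeric(1), "p"),
    testable = vapply(rows, `[[`, logical(1), "testable"),
    stringsAsFactors = FALSE
  )
}

#' Call differential hits and overlap them with SILAC candidates
#'
#' Hits are testable sites with `p < alpha` and `diff_z > 0` (CD-induced
#' dephosphorylation requiring the wild-type holoenzyme); set
#' `signless = TRUE` to drop the sign constraint. Ids are mapped into the
#' SILAC id space before intersecting; unmappable ids are counted, not fatal.
#'
#' @param rows Output of [differential_table()].
#' @param alpha Significance threshold (default 0.05).
#' @param silac_hits Character vector of SILAC candidate site ids.
#' @param id_map Optional named character vector mapping TMT site ids to
#'   SILAC site ids; identity when `NULL`.
#' @param signless Ignore the sign of `diff_z`.
#' @return List with `hits` (TMT ids), `overlap` (SILAC-space ids),
#'   `n_unmapped`.
#' @export
call_and_overlap <- function(rows, alpha = 0.05, silac_hits = character(0),
                             id_map = NULL, signless = FALSE) {
  ok <- rows$testable & !is.na(rows$p) & rows$p < alpha
  if (!signless) ok <- ok & rows$diff_z > 0
  hits <- rows$site_id[ok]
  if (is.null(id_map)) {
    mapped <- hits
    n_unmapped <- 0L
  } else {
    mapped <- unname(id_map[hits])
    n_unmapped <- sum(is.na(mapped))
    mapped <- mapped[!is.na(mapped)]
  }
  list(hits = hits, overlap = intersect(mapped, silac_hits),
       n_unmapped = n_unmapped)
}
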