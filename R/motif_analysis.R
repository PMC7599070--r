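# Positional amino-acid frequency contrast and the flexible-spacing scanner
# for the S/T-x(2-3)-phi-L dephosphorylation motif.

#' Construct a dephosphorylation motif pattern
#'
#' The core recognition element is a target serine/threonine, a spacer of 2-3
#' arbitrary residues, a hydrophobic residue (phi), then leucine. The spacer-3
#' register (phi at +4, L at +5) is the canonical one; spacer 2 (phi at +3,
#' L at +4) describes "stretched" substrates. The hydrophobic set is
#' {L, I, V, M, F}: the positional frequency data show L/I/V enrichment at
#' +4/+5, and tryptophan is excluded because array substitutions to W
#' nonspecifically increase binding. Set `relax_terminal = TRUE` to allow any
#' phi residue (not just L) at the distal position.
#'
#' @param target_set Residues accepted at the phosphosite (default S, T).
#' @param spacer_range Integer vector of allowed spacer lengths (default 2:3).
#' @param phi_set Hydrophobic residues accepted at the phi position.
#' @param relax_terminal Allow any `phi_set` residue at the terminal position.
#' @return An object of class `motif_pattern`.
#' @export
motif_pattern <- function(target_set = c("S", "T"), spacer_range = 2:3,
                          phi_set = c("L", "I", "V", "M", "F"),
                          relax_terminal = FALSE) {
  stopifnot(length(target_set) > 0L, length(spacer_range) > 0L,
            length(phi_set) > 0L, all(spacer_range >= 0L))
  structure(list(target_set = target_set,
                 spacer_range = sort(unique(as.integer(spacer_range))),
                 phi_set = phi_set,
                 terminal_set = if (relax_terminal) phi_set else "L"),
            class = "motif_pattern")
}

#' Scan a sequence for dephosphorylation motif matches
#'
#' Reports every position whose residue is in the pattern's target set and
#' for which some spacer length `s` places a phi residue at `pos + s + 1` and
#' a terminal residue at `pos + s + 2`. When both spacers match, the longer
#' (canonical, phi at +4 / L at +5) register is reported as primary and the
#' alternative recorded.
#'
#' @param sequence Protein or peptide sequence.
#' @param pattern A [motif_pattern()].
#' @return `data.frame` with `target_position` (1-based), `residue`,
#'   `spacer_len`, `phi_residue`, `class` (`"canonical"` for the longest
#'   spacer in the pattern, `"stretched"` otherwise) and `also_spacer`
#'   (alternative matching spacer length or `NA`). Empty for no match.
#' @export
scan_motif <- function(sequence, pattern = motif_pattern()) {
  stopifnot(nchar(sequence) >= 1L)
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  canonical_spacer <- max(pattern$spacer_range)
  rows <- list()
  for (pos in which(chars %in% pattern$target_set)) {
    hits <- integer(0)
    for (s in pattern$spacer_range) {
      phi_at <- pos + s + 1L
      term_at <- pos + s + 2L
      if (term_at <= n &&
          chars[phi_at] %in% pattern$phi_set &&
          chars[term_at] %in% pattern$terminal_set) {
        hits <- c(hits, s)
      }
    }
    if (length(hits) > 0L) {
      primary <- max(hits)
      rows[[length(rows) + 1L]] <- data.frame(
        target_position = pos,
        residue = chars[pos],
        spacer_len = primary,
        phi_residue = chars[pos + primary + 1L],
        class = if (primary == canonical_spacer) "canonical" else "stretched",
        also_spacer = if (length(hits) > 1L) min(hits) else NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(target_position = integer(0), residue = character(0),
                      spacer_len = integer(0), phi_residue = character(0),
                      class = character(0), also_spacer = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Positional amino-acid frequency matrix from site windows
#'
#' Positions run -h..+h around the centred site. Pad characters (`'_'`) are
#' excluded from counts; each position is normalised by its own non-pad
#' count.
#'
#' @param windows Character vector of equal odd-length window strings.
#' @return List of class `frequency_matrix` with `freq` (positions x 20
#'   residues), `counts` (non-pad count per position) and `positions`.
#' @export
positional_frequency <- function(windows) {
  stopifnot(length(windows) > 0L)
  lens <- unique(nchar(windows))
  if (length(lens) != 1L) stop("windows have mixed lengths")
  if (lens %% 2L == 0L) stop("window length must be odd")
  h <- (lens - 1L) %/% 2L
  positions <- (-h):h
  mat <- do.call(rbind, strsplit(windows, ""))
  counts <- integer(lens)
  freq <- matrix(0, nrow = lens, ncol = length(AA20),
                 dimnames = list(positions, AA20))
  for (j in seq_len(lens)) {
    col <- mat[, j]
    col <- col[col != PAD_CHAR]
    counts[j] <- length(col)
    if (length(col) > 0L) {
      tab <- table(factor(col, levels = AA20))
      freq[j, ] <- as.numeric(tab) / length(col)
    }
  }
  structure(list(freq = freq, counts = counts, positions = positions),
            class = "frequency_matrix")
}

#' Log2 enrichment contrast between two frequency matrices
#'
#' Computes `log2((c_fore + pseudo) / (n_fore + 20 * pseudo)) -
#' log2((c_back + pseudo) / (n_back + 20 * pseudo))` per position and
#' residue, i.e. pseudocounts are applied on the count scale before
#' renormalisation.
#'
#' @param foreground,background `frequency_matrix` objects of equal
#'   dimensions.
#' @param pseudocount Count-scale pseudocount (default 0.5).
#' @return Matrix of log2 enrichments (positions x residues).
#' @export
frequency_contrast <- function(foreground, background, pseudocount = 0.5) {
  if (!identical(dim(foreground$freq), dim(background$freq))) {
    stop("frequency matrices have mismatched dimensions")
  }
  k <- ncol(foreground$freq)
  f_counts <- foreground$freq * foreground$counts
  b_counts <- background$freq * background$counts
  f_adj <- (f_counts + pseudocount) /
    (foreground$counts + k * pseudocount)
  b_adj <- (b_counts + pseudocount) /
    (background$counts + k * pseudocount)
  log2(f_adj / b_adj)
}

#' Classify scored candidates by motif register
#'
#' Scans each candidate's window centred on its site and labels it
#' `"canonical"`, `"stretched"` or `"none"` according to the register of the
#' match at the central position.
#'
#' @param candidates `data.frame` with `site_id` and `window` columns (as
#'   from [select_candidates()] on a windowed table).
#' @param pattern A [motif_pattern()].
#' @return `candidates` with an added `motif_class` column; an attribute
#'   `n_center_mismatch` counts windows whose centre residue is outside the
#'   pattern's target set (labelled `"none"`).
#' @export
classify_candidates <- function(candidates, pattern = motif_pattern()) {
  if (nrow(candidates) == 0L) {
    candidates$motif_class <- character(0)
    return(candidates)
  }
  stopifnot(!is.null(candidates$window))
  n_mismatch <- 0L
  cls <- vapply(candidates$window, function(w) {
    h <- (nchar(w) - 1L) %/% 2L
    centre <- h + 1L
    if (!substr(w, centre, centre) %in% pattern$target_set) {
      n_mismatch <<- n_mismatch + 1L
      return("none")
    }
    m <- scan_motif(w, pattern)
    m <- m[m$target_position == centre, , drop = FALSE]
    if (nrow(m) == 0L) "none" else m$class[1L]
  }, character(1), USE.NAMES = FALSE)
  if (n_mismatch > 0L) {
    warning(n_mismatch, " candidate window(s) not centred on a target residue")
  }
  candidates$motif_class <- cls
  attr(candidates, "n_center_mismatch") <- n_mismatch
  candidates
}
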