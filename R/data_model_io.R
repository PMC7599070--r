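# Core site-table types and I/O shared by all pipeline stages.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD_CHAR <- "_"

#' Read a FASTA file into a named character vector
#'
#' Protein identifiers are taken as the first whitespace-delimited token of
#' each header line; sequences are uppercased and concatenated across wrapped
#' lines.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping protein id to sequence, in file
#'   order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  ids <- names(recs)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  setNames(toupper(unlist(recs, use.names = FALSE)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, as.string = TRUE, nbchar = width)
  invisible(path)
}

#' Extract a phosphosite sequence window
#'
#' Returns the subsequence centred on `position` with `halfwidth` residues on
#' each side, padded with `'_'` beyond the protein termini, so the result
#' always has length `2 * halfwidth + 1` and its centre character equals the
#' residue at `position`.
#'
#' @param sequence Protein sequence (single string).
#' @param position 1-based residue index of the site.
#' @param halfwidth Number of flanking residues on each side (default 7,
#'   covering the -7..+7 context used for logo-style frequency analysis).
#' @return Window string of length `2 * halfwidth + 1`.
#' @export
extract_window <- function(sequence, position, halfwidth = 7L) {
  n <- nchar(sequence)
  if (length(position) != 1L || is.na(position) || position < 1L ||
      position > n) {
    stop("position ", position, " out of range 1..", n)
  }
  idx <- (position - halfwidth):(position + halfwidth)
  chars <- rep(PAD_CHAR, length(idx))
  ok <- idx >= 1L & idx <= n
  chars[ok] <- strsplit(substr(sequence, min(idx[ok]), max(idx[ok])), "")[[1L]]
  paste(chars, collapse = "")
}

site_table_required <- c("protein_id", "position", "residue")

#' Read a phosphosite table (TSV)
#'
#' Minimal MaxQuant-like dialect: tab-separated with a header row; required
#' columns `protein_id`, `position` (1-based), `residue` (S/T/Y); optional
#' columns `site_id`, `localization_prob`, `window`, plus arbitrary
#' quantification columns. Missing numeric values are encoded as `NA`.
#'
#' @param path Path to a TSV file.
#' @param fasta Optional named character vector of protein sequences (as from
#'   [read_fasta()]); when supplied, windows are recomputed from the
#'   sequences, overriding any `window` column.
#' @param halfwidth Window halfwidth used when recomputing windows.
#' @return A `data.frame` with one row per site; `site_id` is synthesised as
#'   `<protein_id>_<residue><position>` when absent.
#' @export
read_site_table <- function(path, fasta = NULL, halfwidth = 7L) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = "NA")
  missing_cols <- setdiff(site_table_required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("site table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(tab$residue %in% c("S", "T", "Y")))
  if (length(bad) > 0L) {
    stop("invalid residue '", tab$residue[bad[1L]], "' at row ", bad[1L],
         " (must be S, T or Y)")
  }
  tab$position <- as.integer(tab$position)
  if (is.null(tab$site_id)) {
    tab$site_id <- paste0(tab$protein_id, "_", tab$residue, tab$position)
  }
  if (anyDuplicated(tab$site_id)) {
    stop("duplicate site_id: ", tab$site_id[duplicated(tab$site_id)][1L])
  }
  if (!is.null(fasta)) {
    tab$window <- vapply(seq_len(nrow(tab)), function(i) {
      pid <- tab$protein_id[i]
      if (!pid %in% names(fasta)) {
        stop("protein ", pid, " (row ", i, ") not found in FASTA")
      }
      extract_window(fasta[[pid]], tab$position[i], halfwidth)
    }, character(1))
  }
  validate_site_table(tab, fasta)
  tab
}

#' Write a phosphosite table (TSV)
#'
#' @param table Site table as returned by [read_site_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate a site table against its invariants
#'
#' Checks that residues are S/T/Y, site ids are unique, windows (when
#' present) are centred on the stated residue with pads only at the ends, and
#' positions fall within the protein when sequences are supplied.
#'
#' @param table Site table.
#' @param fasta Optional named sequence vector for positional checks.
#' @return `table`, invisibly; stops with a descriptive error on violation.
#' @export
validate_site_table <- function(table, fasta = NULL) {
  stopifnot(all(site_table_required %in% names(table)))
  if (anyDuplicated(table$site_id)) {
    stop("duplicate site_id: ", table$site_id[duplicated(table$site_id)][1L])
  }
  if (!all(table$residue %in% c("S", "T", "Y"))) {
    stop("residue column contains values outside S/T/Y")
  }
  if (!is.null(table$window)) {
    w <- table$window[!is.na(table$window)]
    len <- unique(nchar(w))
    if (length(len) > 1L) stop("windows have mixed lengths")
    if (length(len) == 1L) {
      if (len %% 2L == 0L) stop("window length must be odd")
      h <- (len - 1L) %/% 2L
      centre <- substr(w, h + 1L, h + 1L)
      rows <- which(!is.na(table$window))
      off <- which(centre != table$residue[rows])
      if (length(off) > 0L) {
        stop("window centre does not match residue for site ",
             table$site_id[rows[off[1L]]])
      }
      # pads must be contiguous runs at the window ends only
      internal_pad <- grepl("[^_]_+[^_]", w)
      if (any(internal_pad)) {
        stop("internal pad character in window for site ",
             table$site_id[rows[which(internal_pad)[1L]]])
      }
    }
  }
  if (!is.null(fasta)) {
    for (i in seq_len(nrow(table))) {
      pid <- table$protein_id[i]
      if (pid %in% names(fasta)) {
        n <- nchar(fasta[[pid]])
        if (table$position[i] < 1L || table$position[i] > n) {
          stop("position ", table$position[i], " of site ",
               table$site_id[i], " outside protein ", pid, " (length ", n, ")")
        }
        res <- substr(fasta[[pid]], table$position[i], table$position[i])
        if (res != table$residue[i]) {
          stop("residue mismatch for site ", table$site_id[i], ": table says ",
               table$residue[i], ", sequence has ", res)
        }
      }
    }
  }
  invisible(table)
}

#' Filter sites by localization probability
#'
#' Optional class-I style filter: keeps sites whose localization probability
#' meets the threshold. Off by default in the pipeline (no cutoff is assumed
#' upstream); sites without a `localization_prob` value are dropped when the
#' filter is applied.
#'
#' @param table Site table.
#' @param min_prob Minimum localization probability (default 0.75).
#' @return Filtered table.
#' @export
filter_localization <- function(table, min_prob = 0.75) {
  if (is.null(table$localization_prob)) {
    stop("table has no localization_prob column")
  }
  table[!is.na(table$localization_prob) &
          table$localization_prob >= min_prob, , drop = FALSE]
}
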