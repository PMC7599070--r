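# Shared fixtures built in code at test time.

default_design <- function() {
  list(r2H1L = "r2H1L", r3H1L = "r3H1L", r2L1H = "r2L1H", r3L1H = "r3L1H")
}

make_scored_toy <- function(scores, proteins = NULL) {
  n <- length(scores)
  data.frame(
    site_id = names(scores),
    protein_id = if (is.null(proteins)) names(scores) else proteins,
    log2_score = log2(scores),
    score = scores,
    n_ratios_used = rep(4L, n),
    scored = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

# independent brute-force pair-count oracle for the rank enrichment score
brute_force_s <- function(members, others) {
  u <- 0
  for (m in members) for (o in others) {
    u <- u + (m > o) + 0.5 * (m == o)
  }
  list(U = u, s = 2 * u / (length(members) * length(others)) - 1)
}

# independent step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# independent textbook Welch t-test
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# exhaustive (pos, spacer) motif-scan oracle, independent of scan_motif
scan_oracle <- function(sequence, target = c("S", "T"), spacers = 2:3,
                        phi = c("L", "I", "V", "M", "F"), terminal = "L") {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (pos in seq_len(n)) {
    if (!chars[pos] %in% target) next
    for (s in spacers) {
      if (pos + s + 2 <= n && chars[pos + s + 1] %in% phi &&
          chars[pos + s + 2] %in% terminal) {
        hits[[length(hits) + 1]] <- c(pos = pos, spacer = s)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(pos = integer(0), spacer = integer(0)))
  }
  as.data.frame(do.call(rbind, hits))
}

random_sequence <- function(n) {
  paste(sample(c(LETTERS[LETTERS %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]]),
               n, replace = TRUE), collapse = "")
}
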