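# Seeded generators for every input the pipeline consumes, with ground-truth
# labels, plus the mutant binding-fixture table. All generators are pure
# functions of (parameters, seed).

#' Binding fixtures for the cofactor peptide and its mutants
#'
#' Dissociation constants for the wild-type PP1-binding peptide
#' (Phactr1 517-580 against PP1a 7-300) and a panel of interface mutants,
#' expressed as fold reductions relative to wild type (Kd 10.4 nM).
#' `bound_flag` marks constructs whose affinity loss is only bounded from
#' below (e.g. ">300 fold"); those rows are stored at the bound and are not
#' suitable for equality checks. The on-rate is a synthetic convention
#' (1e5 M^-1 s^-1, a typical peptide-protein on-rate); only Kd values are
#' measured quantities.
#'
#' @return `data.frame` with `name`, `fold_vs_wt`, `kd_M`, `bound_flag`.
#' @export
binding_fixtures <- function() {
  kd_wt <- 10.4e-9
  fx <- data.frame(
    name = c("WT", "I520A", "F522A", "R536P", "Y534A", "W542A", "R544A",
             "LFL-3A", "L574D", "F577A", "H578A", "HHH-A"),
    fold_vs_wt = c(1, 4, 650, 300, 10, 40, 3, 900, 17, 16, 7, 50),
    bound_flag = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  fx$kd_M <- fx$fold_vs_wt * kd_wt
  fx[, c("name", "fold_vs_wt", "kd_M", "bound_flag")]
}

FIXTURE_KON <- 1e5 # M^-1 s^-1, synthetic convention

#' Generate a synthetic proteome with planted substrate motifs
#'
#' Background residues are uniform over the 20 amino acids. Each substrate
#' protein receives one planted serine-centred motif window: basic residues
#' (K/R) immediately N-terminal, a leucine doublet at +4/+5 and acidic
#' residues (D/E) at +6..+8, mimicking the sequence bias of holoenzyme
#' substrates. Every planted site matches the default [motif_pattern()] by
#' construction.
#'
#' @param n_proteins Number of proteins.
#' @param length Protein length (>= 20).
#' @param n_substrates Number of substrate proteins (<= `n_proteins`).
#' @param seed Integer seed.
#' @return List with `fasta` (named sequences) and `truth` (`data.frame`:
#'   `site_id`, `protein_id`, `position`, `residue`).
#' @export
gen_proteome <- function(n_proteins = 100L, length = 60L,
                         n_substrates = 20L, seed = 1L) {
  if (length < 20L) stop("protein length must be >= 20")
  stopifnot(n_substrates <= n_proteins)
  with_seed(child_seed(seed, "proteome"), {
    ids <- sprintf("prot%03d", seq_len(n_proteins))
    seqs <- vapply(seq_len(n_proteins), function(i) {
      paste(sample(AA20, length, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- ids
    truth <- data.frame(site_id = character(0), protein_id = character(0),
                        position = integer(0), residue = character(0),
                        stringsAsFactors = FALSE)
    if (n_substrates > 0L) {
      subs <- ids[seq_len(n_substrates)]
      pos <- integer(n_substrates)
      for (k in seq_len(n_substrates)) {
        # keep the full -3..+8 planted context inside the protein
        p <- sample(12:(length - 8L), 1L)
        s <- strsplit(seqs[[subs[k]]], "")[[1L]]
        s[(p - 3L):(p - 1L)] <- sample(c("K", "R"), 3L, replace = TRUE)
        s[p] <- "S"
        s[p + 4L] <- "L"
        s[p + 5L] <- "L"
        s[(p + 6L):(p + 8L)] <- sample(c("D", "E"), 3L, replace = TRUE)
        seqs[subs[k]] <- paste(s, collapse = "")
        pos[k] <- p
      }
      truth <- data.frame(site_id = paste0(subs, "_S", pos),
                          protein_id = subs, position = pos,
                          residue = "S", stringsAsFactors = FALSE)
    }
    list(fasta = seqs, truth = truth)
  })
}

#' Generate a SILAC phosphosite table with planted dephosphorylated sites
#'
#' Builds a site table of `n_sites` phosphosites over the synthetic proteome
#' (the planted substrate sites plus decoy S/T sites on other proteins) with
#' four control/active ratio columns. Substrate sites have all four ratios
#' centred at `2^effect_log2`; decoys at 1. Noise is lognormal (ratios are
#' multiplicative): each ratio is multiplied by `2^N(0, noise_sd_log2)`.
#'
#' @param proteome Output of [gen_proteome()].
#' @param n_sites Total number of sites in the table.
#' @param effect_log2 Planted log2 dephosphorylation effect (default 3).
#' @param noise_sd_log2 Per-ratio log2 noise SD (default 0.3).
#' @param seed Integer seed.
#' @param halfwidth Window halfwidth.
#' @return Site table `data.frame` with ratio columns `r2H1L`, `r3H1L`,
#'   `r2L1H`, `r3L1H` and an `is_substrate` truth column.
#' @export
gen_silac <- function(proteome, n_sites = 500L, effect_log2 = 3.0,
                      noise_sd_log2 = 0.3, seed = 1L, halfwidth = 7L) {
  if (noise_sd_log2 < 0) stop("noise SD cannot be negative")
  truth <- proteome$truth
  stopifnot(nrow(truth) > 0L || n_sites > 0L)
  with_seed(child_seed(seed, "silac"), {
    fasta <- proteome$fasta
    rows <- truth[, c("site_id", "protein_id", "position", "residue")]
    rows$is_substrate <- rep(TRUE, nrow(rows))
    n_decoys <- n_sites - nrow(rows)
    if (n_decoys < 0L) stop("n_sites smaller than number of planted sites")
    # decoy sites: random S/T positions on any protein, excluding planted ones
    got <- 0L
    decoy <- list()
    pids <- names(fasta)
    while (got < n_decoys) {
      pid <- sample(pids, 1L)
      chars <- strsplit(fasta[[pid]], "")[[1L]]
      st <- which(chars %in% c("S", "T"))
      st <- setdiff(st, truth$position[truth$protein_id == pid])
      if (length(st) == 0L) next
      p <- if (length(st) == 1L) st else sample(st, 1L)
      sid <- paste0(pid, "_", chars[p], p)
      if (sid %in% rows$site_id ||
          sid %in% vapply(decoy, `[[`, character(1), "site_id")) next
      decoy[[length(decoy) + 1L]] <- data.frame(
        site_id = sid, protein_id = pid, position = p,
        residue = chars[p], is_substrate = FALSE, stringsAsFactors = FALSE)
      got <- got + 1L
    }
    tab <- rbind(rows, do.call(rbind, decoy))
    tab$window <- vapply(seq_len(nrow(tab)), function(i) {
      extract_window(fasta[[tab$protein_id[i]]], tab$position[i], halfwidth)
    }, character(1))
    mu <- ifelse(tab$is_substrate, effect_log2, 0)
    for (col in RATIO_SLOTS) {
      tab[[col]] <- 2^(mu + stats::rnorm(nrow(tab), 0, noise_sd_log2))
    }
    rownames(tab) <- NULL
    tab
  })
}

#' Generate a TMT log-intensity matrix with planted holoenzyme-dependent sites
#'
#' Each site gets a baseline level shared across samples plus Gaussian sample
#' noise. Planted sites additionally lose `effect` Z-units in the CD-treated
#' wild-type samples only, so their (DMSO - CD) delta is `effect` in WT and 0
#' in KO.
#'
#' @param n_sites Number of sites.
#' @param n_planted Number of planted holoenzyme-dependent sites.
#' @param design A [tmt_design()]; must contain both genotypes and both
#'   treatments of the DMSO/CD pair with >= 2 replicates.
#' @param effect Planted (DMSO - CD) effect in WT, Z-units (default 1.5).
#' @param noise_sd Per-sample Gaussian noise SD (default 0.5).
#' @param seed Integer seed.
#' @return List with `matrix` (sites x samples, rownames = site ids) and
#'   `truth` (planted site ids).
#' @export
gen_tmt <- function(n_sites = 2000L, n_planted = 20L, design = tmt_design(),
                    effect = 1.5, noise_sd = 0.5, seed = 1L) {
  if (noise_sd < 0) stop("noise SD cannot be negative")
  need <- c("WT", "KO")
  if (!all(need %in% design$genotype) ||
      !all(c("DMSO", "CD") %in% design$treatment) ||
      max(design$replicate) < 2L) {
    stop("design must contain WT and KO genotypes, DMSO and CD treatments, ",
         "and >= 2 replicates")
  }
  stopifnot(n_planted <= n_sites)
  with_seed(child_seed(seed, "tmt"), {
    ids <- sprintf("tmtsite%05d", seq_len(n_sites))
    planted <- ids[seq_len(n_planted)]
    base <- stats::rnorm(n_sites, 0, 1)
    m <- matrix(base, nrow = n_sites, ncol = nrow(design))
    if (noise_sd > 0) {
      m <- m + matrix(stats::rnorm(n_sites * nrow(design), 0, noise_sd),
                      nrow = n_sites)
    }
    cd_wt <- which(design$genotype == "WT" & design$treatment == "CD")
    m[seq_len(n_planted), cd_wt] <- m[seq_len(n_planted), cd_wt] - effect
    dimnames(m) <- list(ids, design$sample)
    list(matrix = m, truth = planted)
  })
}

#' Generate a single-timepoint phosphatase assay plate
#'
#' Product concentrations follow the single-timepoint Michaelis-Menten model,
#' converted to A620 readings through the standard curve, with optional
#' Gaussian absorbance noise.
#'
#' @param kcat_over_km,km Generator kinetic parameters (efficiency per min
#'   per U; K_M in uM).
#' @param series A [dilution_series()].
#' @param curve A [standard_curve()].
#' @param t Incubation time (min).
#' @param enzyme Enzyme amount in units U.
#' @param noise_sd_abs Absorbance noise SD.
#' @param seed Integer seed.
#' @return `data.frame` with `well`, `dilution_step`, `substrate_conc_uM`,
#'   `a620`.
#' @export
gen_assay_plate <- function(kcat_over_km, km, series = dilution_series(),
                            curve = standard_curve(0.01), t = 15, enzyme = 1,
                            noise_sd_abs = 0, seed = 1L) {
  conc <- final_concentrations(series)
  p <- predict_mm_product(conc, kcat_over_km, km, t = t, enzyme = enzyme)
  a620 <- curve$intercept + curve$slope * p
  if (noise_sd_abs > 0) {
    a620 <- a620 + with_seed(child_seed(seed, "plate"),
                             stats::rnorm(length(a620), 0, noise_sd_abs))
  }
  data.frame(well = sprintf("A%02d", seq_along(conc)),
             dilution_step = seq_along(conc),
             substrate_conc_uM = conc, a620 = a620,
             stringsAsFactors = FALSE)
}

#' Generate 1:1 binding sensorgrams for a fixture or explicit parameters
#'
#' Fixture on-rates use the synthetic convention `kon = 1e5 M^-1 s^-1` with
#' `koff = kon * kd`. Default concentrations are 8 log-spaced points
#' bracketing the fixture's Kd (Kd/30 to 30 Kd), which is needed for the
#' weak-binding mutants.
#'
#' @param fixture Fixture name from [binding_fixtures()], or a
#'   [binding_params()] object.
#' @param conc Analyte concentrations (M); default brackets the Kd.
#' @param t_assoc,t_dissoc,dt Phase timings (s).
#' @param noise_sd Response noise SD.
#' @param seed Integer seed.
#' @return List of sensorgram `data.frame`s with attribute `params`.
#' @export
gen_sensorgrams <- function(fixture = "WT", conc = NULL, t_assoc = 600,
                            t_dissoc = 600, dt = 1, noise_sd = 0,
                            seed = 1L) {
  if (inherits(fixture, "binding_params")) {
    params <- fixture
  } else {
    fx <- binding_fixtures()
    if (!fixture %in% fx$name) {
      stop("unknown fixture '", fixture, "'; known: ",
           paste(fx$name, collapse = ", "))
    }
    kd <- fx$kd_M[fx$name == fixture]
    params <- binding_params(kon = FIXTURE_KON, koff = FIXTURE_KON * kd,
                             rmax = 1)
  }
  if (is.null(conc)) {
    conc <- params$kd * 10^seq(-1.5, 1.5, length.out = 8L)
  }
  out <- lapply(seq_along(conc), function(i) {
    simulate_sensorgram(params, conc[i], t_assoc = t_assoc,
                        t_dissoc = t_dissoc, dt = dt, noise_sd = noise_sd,
                        seed = child_seed(seed, paste0("sensorgram", i)))
  })
  attr(out, "params") <- params
  out
}

#' Noise-free equilibrium binding responses for a fixture
#'
#' Exact `Req = rmax * C / (C + kd)` values at concentrations bracketing the
#' fixture's Kd, for steady-state fitting.
#'
#' @param fixture Fixture name or [binding_params()].
#' @param n_conc Number of log-spaced concentrations (default 8).
#' @param span_decades Half-width of the concentration bracket in decades
#'   (default 1.5).
#' @return `data.frame` with `analyte_conc_M`, `req`, plus attribute `kd`.
#' @export
gen_equilibrium_responses <- function(fixture = "WT", n_conc = 8L,
                                      span_decades = 1.5) {
  if (inherits(fixture, "binding_params")) {
    kd <- fixture$kd
    rmax <- fixture$rmax
  } else {
    fx <- binding_fixtures()
    if (!fixture %in% fx$name) {
      stop("unknown fixture '", fixture, "'; known: ",
           paste(fx$name, collapse = ", "))
    }
    kd <- fx$kd_M[fx$name == fixture]
    rmax <- 1
  }
  conc <- kd * 10^seq(-span_decades, span_decades, length.out = n_conc)
  out <- data.frame(analyte_conc_M = conc, req = rmax * conc / (conc + kd))
  attr(out, "kd") <- kd
  out
}

#' Calibrate a synthetic enzyme so that 1 U matches the unit definition
#'
#' Given a K_M, returns the catalytic efficiency (per U) for which one unit
#' of enzyme releases exactly 15 uM phosphate in 15 min from 125 uM standard
#' substrate, i.e. the efficiency solving
#' `15 = 15 * 1 * eff * 125 / (125 / km + 1)`.
#'
#' @param km Michaelis constant of the standard substrate (uM).
#' @return Catalytic efficiency `kcat/KM` per unit.
#' @export
unit_calibrated_efficiency <- function(km) {
  stopifnot(km > 0)
  15 / (15 * 125 / (125 / km + 1))
}
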