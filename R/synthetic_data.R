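# Seeded generators for every input the rest of the package consumes:
# random phosphopeptides, a smooth deterministic fragmentation rule,
# an additive residue-coefficient retention model, identification
# tables, two-proteome dilution quant matrices, and toy proteomes with
# phosphosite tables. These emulate the *structure* of real data (not
# instrument physics) so models and estimators are testable end to end.

#' Synthetic-data generator configuration
#'
#' Defaults mirror common phosphoproteome data regimes: peptides of
#' length 7-30, a mono-phosphosite majority (1/2/3 sites with
#' probability 0.70/0.25/0.05), precursor charges mostly 2-3, and
#' multiplicative lognormal intensity noise with sdlog 0.1 (about 10%
#' CV, the replicate-reproducibility regime of typical DIA data).
#'
#' @param seed Seed fixing all downstream randomness.
#' @param n_peptides Number of unique modified peptides.
#' @param length_range Peptide length window.
#' @param phospho_site_probs Probabilities of 1, 2, 3 phosphosites.
#' @param charge_probs Named probabilities over precursor charges.
#' @param prob_oxidation Per-methionine oxidation probability.
#' @param prob_acetyl N-terminal acetylation probability.
#' @param spectrum_noise_sd Lognormal sdlog of fragment intensities.
#' @param rt_noise_sd Gaussian SD of RT noise (RT units).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_peptides = 100L,
                         length_range = c(7L, 30L),
                         phospho_site_probs = c(0.70, 0.25, 0.05),
                         charge_probs = c("2" = 0.45, "3" = 0.45, "4" = 0.10),
                         prob_oxidation = 0.1, prob_acetyl = 0.1,
                         spectrum_noise_sd = 0.1, rt_noise_sd = 1) {
  stopifnot(abs(sum(phospho_site_probs) - 1) < 1e-8,
            abs(sum(charge_probs) - 1) < 1e-8,
            length_range[1] >= 4L, length_range[1] <= length_range[2])
  structure(list(seed = as.integer(seed), n_peptides = as.integer(n_peptides),
                 length_range = as.integer(length_range),
                 phospho_site_probs = phospho_site_probs,
                 charge_probs = charge_probs,
                 prob_oxidation = prob_oxidation, prob_acetyl = prob_acetyl,
                 spectrum_noise_sd = spectrum_noise_sd,
                 rt_noise_sd = rt_noise_sd),
            class = "synth_config")
}

#' Generate random phosphopeptide precursors
#'
#' Unique modified sequences with phosphosites only on S/T/Y (the
#' required number of S/T/Y residues is forced into each peptide),
#' optional methionine oxidation and N-terminal acetylation, and a
#' charge drawn from the configured distribution.
#'
#' @param cfg A [synth_config()].
#' @return Data frame with `modified_peptide` (compact) and `charge`.
#' @export
gen_peptides <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  seen <- character(0)
  out <- vector("list", cfg$n_peptides)
  guard <- 0L
  while (length(seen) < cfg$n_peptides) {
    guard <- guard + 1L
    if (guard > 100L * cfg$n_peptides)
      stop("could not generate enough unique peptides; constraints infeasible")
    lens <- cfg$length_range[1]:cfg$length_range[2]
    n <- lens[sample.int(length(lens), 1L)]
    nsites <- sample(seq_along(cfg$phospho_site_probs), 1L,
                     prob = cfg$phospho_site_probs)
    res <- sample(AA_LETTERS, n, replace = TRUE)
    sty <- which(res %in% c("S", "T", "Y"))
    if (length(sty) < nsites) {
      nonsty <- setdiff(seq_len(n), sty)
      fill <- nonsty[sample.int(length(nonsty), nsites - length(sty))]
      res[fill] <- sample(c("S", "T", "Y"), length(fill), replace = TRUE)
      sty <- which(res %in% c("S", "T", "Y"))
    }
    ppos <- sort(sty[sample.int(length(sty), nsites)])
    mods <- stats::setNames(rep("phospho", nsites), as.character(ppos))
    mpos <- which(res == "M")
    if (length(mpos)) {
      ox <- mpos[stats::runif(length(mpos)) < cfg$prob_oxidation]
      if (length(ox))
        mods <- c(mods, stats::setNames(rep("oxidation", length(ox)),
                                        as.character(ox)))
    }
    p <- modified_peptide(res, mods, stats::runif(1) < cfg$prob_acetyl,
                          min_len = cfg$length_range[1],
                          max_len = cfg$length_range[2])
    key <- format_peptide(p, "compact")
    if (key %in% seen) next
    seen <- c(seen, key)
    charge <- as.integer(sample(names(cfg$charge_probs), 1L,
                                prob = cfg$charge_probs))
    out[[length(seen)]] <- data.frame(modified_peptide = key, charge = charge,
                                      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# smooth deterministic intensity rule: a Gaussian bump over relative
# fragment position, series- and charge-dependent, with loss channels a
# fixed fraction of their no-loss partner
ground_truth_intensity <- function(series, frag_charge, loss, i, n,
                                   precursor_charge, loss_fraction = 0.4) {
  pos <- if (n > 2L) (i - 1) / (n - 2) else 0.5
  center <- if (series == "b") 0.35 else 0.60
  base <- exp(-(pos - center)^2 / (2 * 0.25^2))
  base <- base * if (series == "b") 0.7 else 1.0
  base <- base * if (frag_charge == 2L) {
    if (precursor_charge >= 3L) 0.45 else 0.15
  } else 1.0
  if (loss == "H3PO4") base <- base * loss_fraction
  base
}

#' Generate ground-truth fragment matrices
#'
#' A deterministic, smooth fragmentation rule (series- and
#' charge-dependent Gaussian bump over relative fragment position;
#' H3PO4-loss channels a fixed fraction of their no-loss partner),
#' optionally perturbed by multiplicative lognormal noise, then
#' max-normalized. Masks match [validity_mask()] exactly. This is a
#' learning-test harness, not a fragmentation theory.
#'
#' @param precursors Data frame with `modified_peptide`, `charge`.
#' @param cfg A [synth_config()]; `spectrum_noise_sd = 0` gives the
#'   noiseless rule.
#' @param L Matrix rows (default: max peptide length in `precursors`).
#' @return List of `L x 8` fragment matrices.
#' @export
gen_ground_truth_spectra <- function(precursors, cfg = synth_config(),
                                     L = NULL) {
  peps <- lapply(precursors$modified_peptide, as_peptide)
  if (is.null(L)) L <- max(vapply(peps, function(p) length(p$residues), 1L))
  set.seed(cfg$seed + 1L)
  ch <- ion_channels()
  lapply(seq_along(peps), function(b) {
    p <- peps[[b]]
    n <- length(p$residues)
    msk <- validity_mask(p, L)
    m <- matrix(0, L, 8, dimnames = dimnames(msk))
    for (i in seq_len(max(n - 1L, 0L))) for (cidx in seq_len(8L)) {
      if (!msk[i, cidx]) next
      v <- ground_truth_intensity(ch$series[cidx], ch$frag_charge[cidx],
                                  ch$loss[cidx], i, n, precursors$charge[b])
      if (cfg$spectrum_noise_sd > 0)
        v <- v * exp(stats::rnorm(1L, 0, cfg$spectrum_noise_sd))
      m[i, cidx] <- v
    }
    mx <- max(m[msk])
    if (mx > 0) m[msk] <- m[msk] / mx
    m[!msk] <- -1
    m
  })
}

#' Per-residue retention coefficients of the additive RT model
#'
#' The generator's ground truth: RT is the sum of fixed per-residue
#' coefficients plus a per-phosphosite offset, a methionine-oxidation
#' offset and an N-terminal-acetyl offset. Published here so tests know
#' the truth the RT model must recover.
#'
#' @return List with `residues` (named numeric), `phospho`, `oxidation`,
#'   `acetyl`, `intercept`.
#' @export
rt_coefficients <- function() {
  list(residues = c(
    A = 1.10, C = 0.45, D = 0.15, E = 0.95, F = 10.90, G = -0.35,
    H = -1.45, I = 8.00, K = -2.05, L = 9.30, M = 6.20, N = -0.85,
    P = 2.10, Q = -0.40, R = -1.40, S = -0.15, T = 0.65, V = 5.00,
    W = 12.25, Y = 4.85),
    phospho = -2.0, oxidation = -4.0, acetyl = 2.0, intercept = 0)
}

#' Generate ground-truth retention times
#'
#' @param peptides List of peptides or compact strings.
#' @param cfg A [synth_config()]; `rt_noise_sd = 0` gives exact sums.
#' @return Numeric RT vector (generator units).
#' @export
gen_ground_truth_rt <- function(peptides, cfg = synth_config()) {
  co <- rt_coefficients()
  set.seed(cfg$seed + 2L)
  vapply(peptides, function(p) {
    p <- as_peptide(p)
    v <- sum(co$residues[p$residues]) + co$intercept
    v <- v + sum(p$mods == "phospho") * co$phospho
    v <- v + sum(p$mods == "oxidation") * co$oxidation
    if (p$nterm_acetyl) v <- v + co$acetyl
    v + stats::rnorm(1L, 0, cfg$rt_noise_sd)
  }, numeric(1))
}

#' Generate a normalized-dialect identification table
#'
#' Serializes ground-truth spectra and RTs as an identification table
#' with localization probabilities drawn so a configurable fraction
#' falls below the 0.75 class-I threshold, exercising the reader's
#' filter.
#'
#' @param precursors Data frame with `modified_peptide`, `charge`.
#' @param spectra List of fragment matrices, aligned with `precursors`.
#' @param rts Numeric RT vector, aligned.
#' @param path Output TSV path.
#' @param cfg A [synth_config()].
#' @param fraction_below Fraction of entries below the threshold.
#' @return The path, invisibly; attribute `n_below` on the return value
#'   gives the count drawn below 0.75.
#' @export
gen_identification_tables <- function(precursors, spectra, rts, path,
                                      cfg = synth_config(),
                                      fraction_below = 0.2) {
  set.seed(cfg$seed + 3L)
  nb <- stats::rbinom(1L, nrow(precursors), fraction_below)
  below <- sample(seq_len(nrow(precursors)), nb)
  loc <- stats::runif(nrow(precursors), 0.76, 1.0)
  loc[below] <- stats::runif(nb, 0.30, 0.74)
  elist <- list(); plist <- list()
  for (i in seq_len(nrow(precursors))) {
    p <- as_peptide(precursors$modified_peptide[i])
    pk <- peaks_from_matrix(p, spectra[[i]], floor = 0, top_n = Inf)
    key <- entry_key(precursors$modified_peptide[i], precursors$charge[i])
    pk$key <- key
    elist[[i]] <- data.frame(
      key = key, modified_peptide = precursors$modified_peptide[i],
      charge = as.integer(precursors$charge[i]),
      precursor_mz = precursor_mz(p, precursors$charge[i]),
      irt = rts[i], protein_ids = "", source = "experimental_DDA",
      localization = loc[i], species = NA_character_,
      stringsAsFactors = FALSE)
    plist[[i]] <- pk[, c("key", "series", "frag_charge", "loss",
                         "fragment_number", "mz", "intensity")]
  }
  lib <- spectral_library(do.call(rbind, elist), do.call(rbind, plist),
                          provenance = "synthetic-ids")
  write_library_tsv(lib, path)
  tsv <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- match(entry_key(
    vapply(tsv$ModifiedPeptide, function(s)
      format_peptide(parse_bracket(s), "compact"), ""),
    tsv$PrecursorCharge), lib$entries$key)
  tsv$LocalizationProb <- sprintf("%.4f", lib$entries$localization[m])
  utils::write.table(tsv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- path
  attr(out, "n_below") <- nb
  invisible(out)
}

#' Generate a two-proteome dilution quant matrix
#'
#' Emulates the spike-in design used to benchmark quantification: a
#' fixed background species and a spiked species whose abundance is
#' scaled by 0.25/0.5/1.5/2 across four conditions relative to the
#' control, six replicates per condition, multiplicative lognormal
#' noise.
#'
#' @param cfg A [synth_config()]; `spectrum_noise_sd` is reused as the
#'   lognormal sdlog of the intensities.
#' @param n_background,n_spike Precursors per species.
#' @param n_replicates Replicates per condition.
#' @param expected_ratios Named spike ratios per non-control condition.
#' @param missing_rate Fraction of measurements dropped at random.
#' @return Long data frame (`precursor`, `species`, `condition`,
#'   `replicate`, `intensity`, `norm_factor`); attribute
#'   `expected_ratios` carries the design.
#' @export
gen_two_proteome_quant <- function(cfg = synth_config(), n_background = 80L,
                                   n_spike = 40L, n_replicates = 6L,
                                   expected_ratios = c(C025 = 0.25, C05 = 0.5,
                                                       C15 = 1.5, C2 = 2),
                                   missing_rate = 0) {
  set.seed(cfg$seed + 4L)
  conds <- c("control", names(expected_ratios))
  ratio_of <- c(control = 1, expected_ratios)
  prec <- data.frame(
    precursor = c(sprintf("BG_%03d", seq_len(n_background)),
                  sprintf("SP_%03d", seq_len(n_spike))),
    species = rep(c("background", "spike"), c(n_background, n_spike)),
    base = exp(stats::rnorm(n_background + n_spike, log(1e5), 1)),
    stringsAsFactors = FALSE)
  grid <- expand.grid(i = seq_len(nrow(prec)), condition = conds,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ratio <- ifelse(prec$species[grid$i] == "spike",
                  ratio_of[grid$condition], 1)
  noise <- if (cfg$spectrum_noise_sd > 0)
    exp(stats::rnorm(nrow(grid), 0, cfg$spectrum_noise_sd)) else 1
  q <- data.frame(
    precursor = prec$precursor[grid$i], species = prec$species[grid$i],
    condition = grid$condition, replicate = grid$replicate,
    intensity = prec$base[grid$i] * ratio * noise,
    norm_factor = 1, stringsAsFactors = FALSE)
  if (missing_rate > 0)
    q <- q[stats::runif(nrow(q)) >= missing_rate, , drop = FALSE]
  attr(q, "expected_ratios") <- expected_ratios
  q
}

#' Generate a toy proteome with registered phosphosites
#'
#' Random protein sequences (with K/R cleavage sites scattered through)
#' plus a site table registering a subset of their S/T/Y positions, for
#' exercising the digestion stack without external databases.
#'
#' @param cfg A [synth_config()].
#' @param n_proteins Number of proteins.
#' @param protein_length Mean protein length.
#' @param sites_per_protein Mean registered phosphosites per protein.
#' @return List with `proteome` (named character) and `sites` (data
#'   frame: `protein_id`, `position`, `residue`).
#' @export
gen_proteome_with_sites <- function(cfg = synth_config(), n_proteins = 5L,
                                    protein_length = 200L,
                                    sites_per_protein = 5L) {
  set.seed(cfg$seed + 5L)
  proteome <- character(n_proteins)
  names(proteome) <- sprintf("PROT%02d", seq_len(n_proteins))
  sites <- list()
  for (i in seq_len(n_proteins)) {
    n <- max(30L, stats::rpois(1L, protein_length))
    res <- sample(AA_LETTERS, n, replace = TRUE)
    proteome[i] <- paste(res, collapse = "")
    sty <- which(res %in% c("S", "T", "Y"))
    if (length(sty)) {
      k <- min(length(sty), max(1L, stats::rpois(1L, sites_per_protein)))
      pos <- sort(sty[sample.int(length(sty), k)])
      sites[[i]] <- data.frame(protein_id = names(proteome)[i],
                               position = pos, residue = res[pos],
                               stringsAsFactors = FALSE)
    }
  }
  list(proteome = proteome, sites = do.call(rbind, sites))
}
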