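# The L x 8 fragment-ion channel space: channel order, validity masks,
# b/y fragment and precursor m/z with H3PO4 neutral loss, and conversion
# between peak lists and intensity matrices.

#' Monoisotopic mass table
#'
#' Residue monoisotopic masses (Da), modification deltas and physical
#' constants used throughout. Cysteine is treated as carbamidomethylated
#' (fixed +57.02146) by default, mirroring standard search settings.
#'
#' @param carbamidomethyl Apply the fixed Cys carbamidomethyl delta.
#' @return List with `residues` (named numeric), `deltas`, `proton`,
#'   `water`, `h3po4`.
#' @export
mass_table <- function(carbamidomethyl = TRUE) {
  residues <- c(
    G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
    V = 99.06841391, T = 101.04767847, C = 103.00918496, L = 113.08406398,
    I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
    K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
    F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295)
  deltas <- c(phospho = 79.96633089, oxidation = 15.99491462,
              nterm_acetyl = 42.01056468, carbamidomethyl = 57.02146372)
  if (carbamidomethyl) residues[["C"]] <- residues[["C"]] + deltas[["carbamidomethyl"]]
  list(residues = residues, deltas = deltas,
       proton = 1.00727646688, water = 18.0105646863, h3po4 = 97.9768957)
}

#' The eight fragment-ion channels
#'
#' Column order of the fragment matrix is fixed: for every fragment
#' number i the channels are b+1/b+2 without loss, b+1/b+2 with H3PO4
#' loss, then the same four for y ions.
#'
#' @return Data frame with columns `series`, `frag_charge`, `loss` and
#'   `column` (0-based index), one row per channel in matrix order.
#' @export
ion_channels <- function() {
  df <- data.frame(
    series = rep(c("b", "y"), each = 4),
    frag_charge = rep(c(1L, 2L, 1L, 2L), 2),
    loss = rep(c("noloss", "noloss", "H3PO4", "H3PO4"), 2),
    stringsAsFactors = FALSE)
  df$column <- 0:7
  df$label <- paste0(df$series, "+", df$frag_charge, "-", df$loss)
  df
}

#' Channel column index
#'
#' @param series `"b"` or `"y"`.
#' @param frag_charge Fragment charge, 1 or 2.
#' @param loss `"noloss"` or `"H3PO4"`.
#' @return 0-based column index in the fragment matrix (0..7).
#' @export
channel_index <- function(series, frag_charge, loss) {
  ch <- ion_channels()
  hit <- ch$series == series & ch$frag_charge == as.integer(frag_charge) &
    ch$loss == loss
  if (sum(hit) != 1L)
    stop("invalid channel: ", series, "+", frag_charge, "-", loss)
  ch$column[hit]
}

# positions covered by fragment i of a peptide of length n
fragment_span <- function(series, i, n) {
  if (series == "b") seq_len(i) else (n - i + 1L):n
}

#' Validity mask of the fragment matrix
#'
#' Row i of the matrix describes fragments b_i / y_i. A cell is valid
#' when the fragment exists (i <= n-1) and, for the H3PO4 neutral-loss
#' channels, when the fragment actually contains at least one
#' phosphorylated residue; a phosphate that is not there cannot be lost,
#' and predictions on such channels are filtered out.
#'
#' @param p `ModifiedPeptide` or compact string.
#' @param L Number of rows (maximum peptide length of the dataset).
#' @return `L x 8` logical matrix.
#' @export
validity_mask <- function(p, L) {
  p <- as_peptide(p)
  n <- length(p$residues)
  if (n > L) stop("peptide length ", n, " exceeds matrix rows L = ", L)
  ch <- ion_channels()
  m <- matrix(FALSE, L, 8, dimnames = list(NULL, ch$label))
  if (n < 2L) return(m)
  ppos <- as.integer(names(p$mods))[p$mods == "phospho"]
  for (i in seq_len(n - 1L)) {
    b_has_p <- length(ppos) > 0 && any(ppos <= i)
    y_has_p <- length(ppos) > 0 && any(ppos >= n - i + 1L)
    m[i, ] <- c(TRUE, TRUE, b_has_p, b_has_p, TRUE, TRUE, y_has_p, y_has_p)
  }
  m
}

peptide_residue_masses <- function(p, mt = mass_table()) {
  p <- as_peptide(p)
  masses <- unname(mt$residues[p$residues])
  pos <- as.integer(names(p$mods))
  for (k in seq_along(pos))
    masses[pos[k]] <- masses[pos[k]] + mt$deltas[[p$mods[[k]]]]
  masses
}

#' Fragment ion m/z
#'
#' Standard b/y ion chemistry: `b_i` sums residues 1..i, `y_i` sums the
#' C-terminal i residues plus water; protons added per fragment charge;
#' H3PO4-loss channels subtract 97.97690 Da from the neutral fragment.
#' N-terminal acetylation contributes to b ions (and to y_n only).
#'
#' @inheritParams validity_mask
#' @param series,frag_charge,loss Channel, see [ion_channels()].
#' @param i Fragment number (1..n-1).
#' @param mt Mass table.
#' @return m/z in Da per charge.
#' @export
fragment_mz <- function(p, series, frag_charge, loss, i, mt = mass_table()) {
  p <- as_peptide(p)
  n <- length(p$residues)
  i <- as.integer(i)
  if (i < 1L || i > n - 1L) stop("fragment number ", i, " out of range 1..", n - 1L)
  msk <- validity_mask(p, n)
  if (!msk[i, channel_index(series, frag_charge, loss) + 1L])
    stop("channel ", series, "+", frag_charge, "-", loss,
         " invalid for fragment ", i, " of ", format_peptide(p))
  rm <- peptide_residue_masses(p, mt)
  z <- as.integer(frag_charge)
  neutral <- if (series == "b") {
    sum(rm[seq_len(i)]) + if (p$nterm_acetyl) mt$deltas[["nterm_acetyl"]] else 0
  } else {
    sum(rm[(n - i + 1L):n]) + mt$water
  }
  if (loss == "H3PO4") neutral <- neutral - mt$h3po4
  (neutral + z * mt$proton) / z
}

#' Precursor m/z
#'
#' @inheritParams validity_mask
#' @param charge Precursor charge.
#' @param mt Mass table.
#' @return (monoisotopic peptide mass + water + charge protons) / charge.
#' @export
precursor_mz <- function(p, charge, mt = mass_table()) {
  p <- as_peptide(p)
  z <- as.integer(charge)
  neutral <- sum(peptide_residue_masses(p, mt)) + mt$water +
    if (p$nterm_acetyl) mt$deltas[["nterm_acetyl"]] else 0
  (neutral + z * mt$proton) / z
}

#' Build a fragment matrix from a peak list
#'
#' Invalid cells are set to the -1 sentinel; valid cells without a peak
#' are 0; the rest are normalized to the maximum peak intensity (base
#' peak = 1).
#'
#' @inheritParams validity_mask
#' @param peaks Data frame with columns `series`, `frag_charge`, `loss`,
#'   `fragment_number`, `intensity`.
#' @param on_invalid `"error"` rejects peaks on invalid channels,
#'   `"drop"` discards them silently.
#' @return `L x 8` numeric matrix with values in `{-1} U [0, 1]`.
#' @export
matrix_from_peaks <- function(p, peaks, L, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  p <- as_peptide(p)
  msk <- validity_mask(p, L)
  m <- matrix(0, L, 8, dimnames = dimnames(msk))
  if (nrow(peaks)) {
    for (r in seq_len(nrow(peaks))) {
      col <- channel_index(peaks$series[r], peaks$frag_charge[r], peaks$loss[r]) + 1L
      row <- as.integer(peaks$fragment_number[r])
      if (row < 1L || row > L || !msk[row, col]) {
        if (on_invalid == "error")
          stop("peak on invalid channel: ", peaks$series[r], peaks$frag_charge[r],
               "-", peaks$loss[r], " fragment ", row, " of ", format_peptide(p))
        next
      }
      m[row, col] <- m[row, col] + peaks$intensity[r]
    }
    mx <- max(m[msk])
    if (mx > 0) m[msk] <- m[msk] / mx
  }
  m[!msk] <- -1
  m
}

#' Extract a peak list from a fragment matrix
#'
#' Emits valid cells above an intensity floor, at most `top_n` peaks by
#' descending intensity (ties broken deterministically by channel order
#' then fragment number), each with its computed m/z.
#'
#' @inheritParams validity_mask
#' @param m Fragment matrix conforming to the mask of `p`.
#' @param floor Minimum relative intensity (exclusive).
#' @param top_n Maximum number of peaks.
#' @param mt Mass table.
#' @return Data frame of peaks with `mz` and `intensity`.
#' @export
peaks_from_matrix <- function(p, m, floor = 0, top_n = Inf, mt = mass_table()) {
  p <- as_peptide(p)
  msk <- validity_mask(p, nrow(m))
  ch <- ion_channels()
  idx <- which(msk & m > floor, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(series = character(), frag_charge = integer(),
                      loss = character(), fragment_number = integer(),
                      mz = numeric(), intensity = numeric(),
                      stringsAsFactors = FALSE))
  }
  pk <- data.frame(
    series = ch$series[idx[, 2]],
    frag_charge = ch$frag_charge[idx[, 2]],
    loss = ch$loss[idx[, 2]],
    fragment_number = as.integer(idx[, 1]),
    intensity = m[idx],
    stringsAsFactors = FALSE)
  ord <- order(-pk$intensity, match(pk$series, c("b", "y")),
               pk$fragment_number, pk$frag_charge, match(pk$loss, c("noloss", "H3PO4")))
  pk <- pk[ord, , drop = FALSE]
  if (is.finite(top_n) && nrow(pk) > top_n) pk <- pk[seq_len(top_n), , drop = FALSE]
  pk$mz <- vapply(seq_len(nrow(pk)), function(r)
    fragment_mz(p, pk$series[r], pk$frag_charge[r], pk$loss[r],
                pk$fragment_number[r], mt), numeric(1))
  rownames(pk) <- NULL
  pk[, c("series", "frag_charge", "loss", "fragment_number", "mz", "intensity")]
}
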