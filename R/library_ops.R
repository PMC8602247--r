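# Spectral-library construction, transformation and TSV serialization:
# predicted libraries from model output, iRT calibration, hybrid merge,
# focused libraries for iterative search, reverse-decoy and two-species
# entrapment libraries, parameter-grid screening.

LIB_TSV_COLS <- c("PrecursorMz", "PrecursorCharge", "ModifiedPeptide",
                  "StrippedPeptide", "iRT", "FragmentMz", "RelativeIntensity",
                  "FragmentType", "FragmentNumber", "FragmentCharge",
                  "FragmentLossType", "ProteinId", "Source")

entry_key <- function(modified_peptide, charge)
  paste0(modified_peptide, "|", charge)

empty_entries <- function() data.frame(
  key = character(), modified_peptide = character(), charge = integer(),
  precursor_mz = numeric(), irt = numeric(), protein_ids = character(),
  source = character(), localization = numeric(), species = character(),
  stringsAsFactors = FALSE)

empty_peaks <- function() data.frame(
  key = character(), series = character(), frag_charge = integer(),
  loss = character(), fragment_number = integer(), mz = numeric(),
  intensity = numeric(), stringsAsFactors = FALSE)

#' Construct a spectral library
#'
#' A spectral library is a set of precursor entries (modified peptide +
#' charge) each carrying an iRT value and a list of annotated fragment
#' peaks. Entries are keyed by `modified_peptide|charge`; keys must be
#' unique and every entry must own at least one peak.
#'
#' @param entries Data frame with columns `modified_peptide` (compact
#'   dialect), `charge`, `precursor_mz`, `irt`, `protein_ids`, `source`,
#'   optionally `localization` and `species`.
#' @param peaks Data frame with columns `key`, `series`, `frag_charge`,
#'   `loss`, `fragment_number`, `mz`, `intensity`.
#' @param provenance Free-text tag describing how the library was built.
#' @return An object of class `SpectralLibrary`.
#' @export
spectral_library <- function(entries, peaks, provenance = "manual") {
  if (!nrow(entries)) {
    entries <- empty_entries()
    peaks <- empty_peaks()
  } else {
    if (!"key" %in% names(entries))
      entries$key <- entry_key(entries$modified_peptide, entries$charge)
    if (!"localization" %in% names(entries)) entries$localization <- NA_real_
    if (!"species" %in% names(entries)) entries$species <- NA_character_
    if (anyDuplicated(entries$key))
      stop("duplicate library keys: ",
           paste(utils::head(entries$key[duplicated(entries$key)], 3), collapse = ", "))
    orphan <- setdiff(entries$key, unique(peaks$key))
    if (length(orphan))
      stop("entries without peaks: ", paste(utils::head(orphan, 3), collapse = ", "))
    peaks <- peaks[peaks$key %in% entries$key, , drop = FALSE]
  }
  rownames(entries) <- NULL
  rownames(peaks) <- NULL
  structure(list(entries = entries, peaks = peaks, provenance = provenance),
            class = "SpectralLibrary")
}

#' @export
print.SpectralLibrary <- function(x, ...) {
  cat("<SpectralLibrary> ", nrow(x$entries), " precursors, ",
      nrow(x$peaks), " fragments (", x$provenance, ")\n", sep = "")
  if (nrow(x$entries))
    print(table(x$entries$source))
  invisible(x)
}

#' Number of precursor entries in a library
#' @param lib A `SpectralLibrary`.
#' @return Integer count.
#' @export
library_size <- function(lib) nrow(lib$entries)

#' Library construction filters
#'
#' @param precursor_mz_range,fragment_mz_range Numeric `c(lo, hi)`
#'   windows (defaults: unbounded precursors, fragments 200-2000).
#' @param length_range Peptide length window.
#' @param max_phospho Maximum phosphosites per peptide.
#' @param charges Retained precursor charges.
#' @param top_n Best-N fragments kept per precursor (default 25).
#' @param intensity_floor Minimum relative fragment intensity (default
#'   0.05).
#' @return A `library_filters` list.
#' @export
library_filters <- function(precursor_mz_range = c(0, Inf),
                            fragment_mz_range = c(200, 2000),
                            length_range = c(7, 50), max_phospho = 3L,
                            charges = 1:6, top_n = 25L,
                            intensity_floor = 0.05) {
  stopifnot(precursor_mz_range[1] < precursor_mz_range[2],
            fragment_mz_range[1] < fragment_mz_range[2],
            length_range[1] <= length_range[2], length(charges) >= 1L)
  structure(list(precursor_mz_range = precursor_mz_range,
                 fragment_mz_range = fragment_mz_range,
                 length_range = as.integer(length_range),
                 max_phospho = max_phospho, charges = as.integer(charges),
                 top_n = top_n, intensity_floor = intensity_floor),
            class = "library_filters")
}

precursor_passes <- function(p, charge, filters) {
  n <- length(p$residues)
  nph <- sum(p$mods == "phospho")
  mz <- precursor_mz(p, charge)
  charge %in% filters$charges &&
    n >= filters$length_range[1] && n <= filters$length_range[2] &&
    nph <= filters$max_phospho &&
    mz >= filters$precursor_mz_range[1] && mz <= filters$precursor_mz_range[2]
}

#' Generate a predicted spectral library
#'
#' Runs the trained ion and RT models over a precursor list, converts
#' predicted fragment matrices to peak lists (intensity floor, best-N
#' cap, fragment m/z window) and attaches predicted iRT. Precursors
#' violating the precursor-level filters are dropped and counted.
#'
#' @param precursors Data frame with `modified_peptide` (compact) and
#'   `charge`; an optional `protein_ids` column is carried through.
#' @param ion_model Trained `phospho_ion_model`.
#' @param rt_model Trained `phospho_rt_ensemble`.
#' @param filters A [library_filters()].
#' @param source Source tag for the entries (default `"predicted"`).
#' @return A `SpectralLibrary`; attribute `dropped` counts precursors
#'   removed by each filter stage.
#' @export
generate_predicted_library <- function(precursors, ion_model, rt_model,
                                       filters = library_filters(),
                                       source = "predicted") {
  peps <- lapply(precursors$modified_peptide, as_peptide)
  keep <- vapply(seq_along(peps), function(i)
    precursor_passes(peps[[i]], precursors$charge[i], filters), logical(1))
  dropped <- c(precursor_filters = sum(!keep))
  idx <- which(keep)
  entries <- empty_entries()
  peaks <- empty_peaks()
  if (length(idx)) {
    mats <- predict_ion(ion_model, peps[idx], precursors$charge[idx])
    irts <- predict_rt(rt_model, peps[idx])
    elist <- list(); plist <- list()
    no_peaks <- 0L
    for (j in seq_along(idx)) {
      i <- idx[j]
      pk <- peaks_from_matrix(peps[[i]], mats[[j]],
                              floor = filters$intensity_floor,
                              top_n = filters$top_n)
      pk <- pk[pk$mz >= filters$fragment_mz_range[1] &
                 pk$mz <= filters$fragment_mz_range[2], , drop = FALSE]
      if (!nrow(pk)) { no_peaks <- no_peaks + 1L; next }
      key <- entry_key(precursors$modified_peptide[i], precursors$charge[i])
      pk$key <- key
      elist[[length(elist) + 1L]] <- data.frame(
        key = key, modified_peptide = precursors$modified_peptide[i],
        charge = as.integer(precursors$charge[i]),
        precursor_mz = precursor_mz(peps[[i]], precursors$charge[i]),
        irt = irts[j],
        protein_ids = if ("protein_ids" %in% names(precursors))
          precursors$protein_ids[i] else "",
        source = source, localization = NA_real_, species = NA_character_,
        stringsAsFactors = FALSE)
      plist[[length(plist) + 1L]] <-
        pk[, c("key", "series", "frag_charge", "loss", "fragment_number",
               "mz", "intensity")]
    }
    dropped <- c(dropped, no_surviving_peaks = no_peaks)
    if (length(elist)) {
      entries <- do.call(rbind, elist)
      peaks <- do.call(rbind, plist)
    }
  }
  if (!nrow(entries)) warning("predicted library is empty")
  lib <- spectral_library(entries, peaks, provenance = "predicted")
  attr(lib, "dropped") <- dropped
  lib
}

#' Calibrate predicted iRT onto an experimental RT scale
#'
#' Ordinary least squares of observed RT on predicted iRT over shared
#' peptides; the fitted line is applied to every entry of the library.
#'
#' @param lib A `SpectralLibrary` with predicted iRT.
#' @param observed Data frame with `modified_peptide` (compact) and `rt`.
#' @return List with `fit` (slope, intercept, r2, median absolute
#'   residual, n) and `library` (transformed).
#' @export
calibrate_irt <- function(lib, observed) {
  shared <- merge(lib$entries[, c("modified_peptide", "irt")],
                  observed, by = "modified_peptide")
  shared <- shared[!duplicated(shared$modified_peptide), , drop = FALSE]
  if (nrow(shared) < 3L) stop("need at least 3 shared peptides to calibrate")
  if (stats::sd(shared$irt) == 0) stop("degenerate predicted iRT variance")
  fit <- stats::lm(rt ~ irt, data = shared)
  co <- stats::coef(fit)
  out <- lib
  out$entries$irt <- co[[2]] * lib$entries$irt + co[[1]]
  list(fit = list(slope = co[[2]], intercept = co[[1]],
                  r2 = summary(fit)$r.squared,
                  median_abs_residual = stats::median(abs(stats::resid(fit))),
                  n = nrow(shared)),
       library = out)
}

#' Merge a direct-DIA library with a predicted library
#'
#' Union by precursor key; when a precursor is present in both, the
#' experimental entry (spectrum and iRT) wins entirely. Sources are
#' preserved, so shared entries keep their experimental source tag.
#'
#' @param dia_lib Experimental (direct DIA) `SpectralLibrary`.
#' @param predicted_lib Predicted `SpectralLibrary`.
#' @return Hybrid `SpectralLibrary`.
#' @export
merge_hybrid <- function(dia_lib, predicted_lib) {
  add <- !(predicted_lib$entries$key %in% dia_lib$entries$key)
  entries <- rbind(dia_lib$entries, predicted_lib$entries[add, , drop = FALSE])
  peaks <- rbind(dia_lib$peaks,
                 predicted_lib$peaks[predicted_lib$peaks$key %in%
                                       predicted_lib$entries$key[add], , drop = FALSE])
  spectral_library(entries, peaks, provenance = "hybrid")
}

#' Build a focused library for an iterative search
#'
#' Restricts predicted-source entries to the keys identified in the
#' initial search; experimental-source entries are kept whole when
#' `keep_experimental_whole` (the hybrid-library rule), else filtered
#' identically.
#'
#' @param initial_lib The library used in the initial search.
#' @param identified_keys Character vector of identified precursor keys.
#' @param keep_experimental_whole Keep all experimental entries.
#' @return Focused `SpectralLibrary`.
#' @export
build_focused <- function(initial_lib, identified_keys,
                          keep_experimental_whole = TRUE) {
  unknown <- setdiff(identified_keys, initial_lib$entries$key)
  if (length(unknown))
    warning(length(unknown), " identified key(s) not in the initial library; dropped")
  identified_keys <- intersect(identified_keys, initial_lib$entries$key)
  experimental <- initial_lib$entries$source %in%
    c("experimental_DDA", "direct_DIA")
  keep <- initial_lib$entries$key %in% identified_keys
  if (keep_experimental_whole) keep <- keep | experimental
  entries <- initial_lib$entries[keep, , drop = FALSE]
  if (!nrow(entries)) stop("focused library is empty")
  peaks <- initial_lib$peaks[initial_lib$peaks$key %in% entries$key, , drop = FALSE]
  spectral_library(entries, peaks, provenance = "focused")
}

#' Reverse a peptide for decoy generation
#'
#' Reverses residues 1..n-1, keeping the C-terminal residue fixed;
#' modifications travel with their residues and the N-terminal acetyl
#' flag is retained.
#'
#' @param p `ModifiedPeptide` or compact string.
#' @return Reversed `ModifiedPeptide`.
#' @export
reverse_peptide <- function(p) {
  p <- as_peptide(p)
  n <- length(p$residues)
  if (n < 2L) stop("cannot reverse a peptide of length < 2")
  perm <- c(rev(seq_len(n - 1L)), n)   # new order of old positions
  res <- p$residues[perm]
  newpos <- order(perm)                # old position -> new position
  mods <- p$mods
  if (length(mods))
    names(mods) <- as.character(newpos[as.integer(names(p$mods))])
  modified_peptide(res, mods, p$nterm_acetyl, min_len = 2L, max_len = 100L)
}

#' Append a predicted reverse-decoy library
#'
#' For each target entry, predicts the spectrum and iRT of the reversed
#' sequence at the original charge and appends it with source `decoy`.
#' Decoys colliding with any target key (palindromic reversals) are
#' dropped and counted.
#'
#' @param lib Target `SpectralLibrary`.
#' @param ion_model,rt_model Trained models.
#' @param filters A [library_filters()] applied to decoy peak emission.
#' @return Combined target+decoy `SpectralLibrary`; attribute
#'   `decoy_collisions` counts dropped palindromes.
#' @export
build_decoy_appended_library <- function(lib, ion_model, rt_model,
                                         filters = library_filters()) {
  ent <- lib$entries
  rev_peps <- vapply(ent$modified_peptide,
                     function(s) format_peptide(reverse_peptide(s), "compact"), "")
  dec <- data.frame(modified_peptide = unname(rev_peps), charge = ent$charge,
                    protein_ids = paste0("DECOY_", ent$protein_ids),
                    stringsAsFactors = FALSE)
  collide <- entry_key(dec$modified_peptide, dec$charge) %in% ent$key
  dec <- dec[!collide, , drop = FALSE]
  dec <- dec[!duplicated(entry_key(dec$modified_peptide, dec$charge)), , drop = FALSE]
  dlib <- generate_predicted_library(dec, ion_model, rt_model, filters,
                                     source = "decoy")
  entries <- rbind(ent, dlib$entries)
  peaks <- rbind(lib$peaks, dlib$peaks)
  out <- spectral_library(entries, peaks, provenance = "target+decoy")
  attr(out, "decoy_collisions") <- sum(collide)
  out
}

#' Combine a main and an entrapment (foreign-species) library
#'
#' Concatenates the two libraries with species labels and records the
#' per-species unique-phosphopeptide counts needed by the entrapment
#' FDR estimator. Modified sequences present in both species are
#' dropped from the entrapment side and counted.
#'
#' @param main_lib,entrapment_lib `SpectralLibrary` objects.
#' @param main_species,entrapment_species Species labels.
#' @return Combined `SpectralLibrary` with attribute `libsizes`
#'   (named: main, entrapment) and `entrapment_overlap` (dropped count).
#' @export
build_entrapment_library <- function(main_lib, entrapment_lib,
                                     main_species = "main",
                                     entrapment_species = "entrapment") {
  if (identical(main_species, entrapment_species))
    stop("species tags must be distinct")
  me <- main_lib$entries
  ee <- entrapment_lib$entries
  overlap <- ee$modified_peptide %in% me$modified_peptide
  ee <- ee[!overlap, , drop = FALSE]
  me$species <- main_species
  ee$species <- entrapment_species
  entries <- rbind(me, ee)
  peaks <- rbind(main_lib$peaks,
                 entrapment_lib$peaks[entrapment_lib$peaks$key %in% ee$key, ,
                                      drop = FALSE])
  out <- spectral_library(entries, peaks, provenance = "two-species")
  attr(out, "libsizes") <- c(
    main = length(unique(me$modified_peptide)),
    entrapment = length(unique(ee$modified_peptide)))
  attr(out, "entrapment_overlap") <- sum(overlap)
  out
}

#' Screen a grid of library filters
#'
#' Builds one predicted library per filter combination and summarizes
#' entry and peak counts, emulating parameter screening for
#' database-derived libraries.
#'
#' @param precursors Precursor data frame (see
#'   [generate_predicted_library()]).
#' @param grid List of [library_filters()] objects.
#' @param ion_model,rt_model Trained models.
#' @return Data frame with one row per combination: `combo`, `entries`,
#'   `peaks`.
#' @export
screen_parameter_grid <- function(precursors, grid, ion_model, rt_model) {
  if (!length(grid)) stop("empty filter grid")
  res <- lapply(seq_along(grid), function(i) {
    lib <- suppressWarnings(
      generate_predicted_library(precursors, ion_model, rt_model, grid[[i]]))
    data.frame(combo = i, entries = library_size(lib), peaks = nrow(lib$peaks))
  })
  do.call(rbind, res)
}

# ---- TSV I/O -------------------------------------------------------------

#' Write a spectral library as TSV
#'
#' One row per fragment with the fixed column set (`PrecursorMz`,
#' `PrecursorCharge`, `ModifiedPeptide` in bracket dialect,
#' `StrippedPeptide`, `iRT`, `FragmentMz`, `RelativeIntensity`,
#' `FragmentType`, `FragmentNumber`, `FragmentCharge`,
#' `FragmentLossType`, `ProteinId`, `Source`). m/z, iRT and intensity
#' are written to 4 decimal places.
#'
#' @param lib A `SpectralLibrary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(lib, path) {
  ent <- lib$entries
  pk <- lib$peaks
  m <- match(pk$key, ent$key)
  df <- data.frame(
    PrecursorMz = sprintf("%.4f", ent$precursor_mz[m]),
    PrecursorCharge = ent$charge[m],
    ModifiedPeptide = vapply(ent$modified_peptide[m],
                             function(s) format_peptide(as_peptide(s), "bracket"), ""),
    StrippedPeptide = vapply(ent$modified_peptide[m], stripped_sequence, ""),
    iRT = sprintf("%.4f", ent$irt[m]),
    FragmentMz = sprintf("%.4f", pk$mz),
    RelativeIntensity = sprintf("%.4f", pk$intensity),
    FragmentType = pk$series,
    FragmentNumber = pk$fragment_number,
    FragmentCharge = pk$frag_charge,
    FragmentLossType = pk$loss,
    ProteinId = ent$protein_ids[m],
    Source = ent$source[m],
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectral library TSV
#'
#' Inverse of [write_library_tsv()]. Validates the mandatory columns and
#' the neutral-loss annotation: a `H3PO4` loss on a fragment containing
#' no phosphosite is a format error.
#'
#' @param path TSV file.
#' @return A `SpectralLibrary`.
#' @export
read_library_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$ProteinId[is.na(df$ProteinId)] <- ""
  missing_cols <- setdiff(LIB_TSV_COLS, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  compact <- vapply(df$ModifiedPeptide,
                    function(s) format_peptide(parse_bracket(s), "compact"), "")
  key <- entry_key(compact, df$PrecursorCharge)
  # per-fragment loss validation against the peptide's phosphosites
  for (r in which(df$FragmentLossType == "H3PO4")) {
    p <- parse_bracket(df$ModifiedPeptide[r])
    msk <- validity_mask(p, length(p$residues))
    col <- channel_index(df$FragmentType[r], df$FragmentCharge[r], "H3PO4") + 1L
    if (!msk[df$FragmentNumber[r], col])
      stop("row ", r, ": H3PO4 loss on a fragment without phosphosite (",
           df$ModifiedPeptide[r], " ", df$FragmentType[r],
           df$FragmentNumber[r], ")")
  }
  first <- !duplicated(key)
  entries <- data.frame(
    key = key[first], modified_peptide = compact[first],
    charge = as.integer(df$PrecursorCharge[first]),
    precursor_mz = as.numeric(df$PrecursorMz[first]),
    irt = as.numeric(df$iRT[first]),
    protein_ids = as.character(df$ProteinId[first]),
    source = df$Source[first], localization = NA_real_,
    species = NA_character_, stringsAsFactors = FALSE)
  peaks <- data.frame(
    key = key, series = df$FragmentType,
    frag_charge = as.integer(df$FragmentCharge), loss = df$FragmentLossType,
    fragment_number = as.integer(df$FragmentNumber),
    mz = as.numeric(df$FragmentMz),
    intensity = as.numeric(df$RelativeIntensity), stringsAsFactors = FALSE)
  spectral_library(entries, peaks, provenance = paste0("read:", basename(path)))
}

#' Read an identification table
#'
#' Adapters for simplified identification outputs. The `normalized`
#' dialect is this package's library TSV plus a `LocalizationProb`
#' column; `spectronaut_report` and `maxquant_msms` are best-effort
#' column-subset adapters, not full parsers. Entries with localization
#' probability not strictly above the threshold are excluded (class I
#' sites); fragment annotations outside the 8-channel space are dropped
#' while the entry is kept.
#'
#' @param path TSV file.
#' @param dialect Input dialect.
#' @param min_localization Strict lower bound on localization
#'   probability (default 0.75).
#' @return A `SpectralLibrary` (source `experimental_DDA`) with the
#'   `localization` column filled; attribute `excluded_localization`
#'   counts filtered entries.
#' @export
read_id_table <- function(path, dialect = c("normalized", "spectronaut_report",
                                            "maxquant_msms"),
                          min_localization = 0.75) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "normalized") {
    need <- c(LIB_TSV_COLS, "LocalizationProb")
    if (length(setdiff(need, names(df))))
      stop("normalized dialect needs columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    mod <- df$ModifiedPeptide
    charge <- as.integer(df$PrecursorCharge)
    rt <- as.numeric(df$iRT)
    loc <- as.numeric(df$LocalizationProb)
    ftype <- df$FragmentType; fnum <- as.integer(df$FragmentNumber)
    fch <- as.integer(df$FragmentCharge); floss <- df$FragmentLossType
    fint <- as.numeric(df$RelativeIntensity)
    protein <- as.character(df$ProteinId)
  } else if (dialect == "spectronaut_report") {
    need <- c("ModifiedPeptide", "PrecursorCharge", "iRT", "FragmentType",
              "FragmentNumber", "FragmentCharge", "FragmentLossType",
              "RelativeIntensity", "PTMLocalizationProbability")
    if (length(setdiff(need, names(df))))
      stop("spectronaut_report dialect needs columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    mod <- df$ModifiedPeptide
    charge <- as.integer(df$PrecursorCharge)
    rt <- as.numeric(df$iRT)
    loc <- as.numeric(df$PTMLocalizationProbability)
    ftype <- df$FragmentType; fnum <- as.integer(df$FragmentNumber)
    fch <- as.integer(df$FragmentCharge); floss <- df$FragmentLossType
    fint <- as.numeric(df$RelativeIntensity)
    protein <- if ("ProteinId" %in% names(df)) as.character(df$ProteinId) else ""
  } else {
    # maxquant-like: one row per PSM; Matches/Intensities are ;-separated
    need <- c("ModifiedSequence", "Charge", "RetentionTime",
              "LocalizationProb", "Matches", "Intensities")
    if (length(setdiff(need, names(df))))
      stop("maxquant_msms dialect needs columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    rows <- list()
    for (r in seq_len(nrow(df))) {
      ann <- strsplit(df$Matches[r], ";", fixed = TRUE)[[1]]
      ints <- as.numeric(strsplit(df$Intensities[r], ";", fixed = TRUE)[[1]])
      for (k in seq_along(ann)) {
        m <- regmatches(ann[k],
                        regexec("^([by])(\\d+)(\\((\\d)\\+\\))?(-H3PO4)?$", ann[k]))[[1]]
        if (!length(m)) next   # annotation outside the channel space
        rows[[length(rows) + 1L]] <- data.frame(
          mod = mq_to_compact(df$ModifiedSequence[r]),
          charge = as.integer(df$Charge[r]), rt = as.numeric(df$RetentionTime[r]),
          loc = as.numeric(df$LocalizationProb[r]), ftype = m[2],
          fnum = as.integer(m[3]),
          fch = if (nzchar(m[5])) as.integer(m[5]) else 1L,
          floss = if (nzchar(m[6])) "H3PO4" else "noloss",
          fint = ints[k], protein = "", stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) stop("no parseable rows in ", path)
    long <- do.call(rbind, rows)
    mod <- long$mod; charge <- long$charge; rt <- long$rt; loc <- long$loc
    ftype <- long$ftype; fnum <- long$fnum; fch <- long$fch
    floss <- long$floss; fint <- long$fint; protein <- long$protein
  }
  compact <- vapply(mod, function(s)
    tryCatch(format_peptide(as_peptide(s), "compact"),
             error = function(e) NA_character_), "")
  ok_row <- !is.na(compact)
  skipped <- sum(!ok_row)
  key <- entry_key(compact, charge)
  keep_entry <- !is.na(loc) & loc > min_localization
  excluded <- length(unique(key[ok_row & !keep_entry]))
  use <- ok_row & keep_entry
  if (!any(use)) stop("no identification rows survive the filters")
  # drop peaks whose channel is invalid for the peptide; keep the entry
  chan_ok <- logical(sum(use))
  ui <- which(use)
  for (j in seq_along(ui)) {
    r <- ui[j]
    p <- as_peptide(compact[r])
    chan_ok[j] <- tryCatch({
      msk <- validity_mask(p, length(p$residues))
      col <- channel_index(ftype[r], fch[r], floss[r]) + 1L
      fnum[r] >= 1L && fnum[r] <= nrow(msk) && msk[fnum[r], col]
    }, error = function(e) FALSE)
  }
  ui <- ui[chan_ok]
  if (!length(ui)) stop("no valid fragment annotations survive")
  first <- ui[!duplicated(key[ui])]
  entries <- data.frame(
    key = key[first], modified_peptide = compact[first],
    charge = charge[first],
    precursor_mz = vapply(first, function(r)
      precursor_mz(as_peptide(compact[r]), charge[r]), numeric(1)),
    irt = rt[first], protein_ids = as.character(protein[first]),
    source = "experimental_DDA", localization = loc[first],
    species = NA_character_, stringsAsFactors = FALSE)
  peaks <- data.frame(
    key = key[ui], series = ftype[ui], frag_charge = fch[ui],
    loss = floss[ui], fragment_number = fnum[ui],
    mz = vapply(ui, function(r)
      fragment_mz(as_peptide(compact[r]), ftype[r], fch[r], floss[r], fnum[r]),
      numeric(1)),
    intensity = fint[ui], stringsAsFactors = FALSE)
  # renormalize intensities per entry
  for (k in unique(peaks$key)) {
    sel <- peaks$key == k
    mx <- max(peaks$intensity[sel])
    if (mx > 0) peaks$intensity[sel] <- peaks$intensity[sel] / mx
  }
  lib <- spectral_library(entries, peaks, provenance = paste0("ids:", dialect))
  attr(lib, "excluded_localization") <- excluded
  attr(lib, "skipped_rows") <- skipped
  lib
}

# MaxQuant-style "_ (ac)AS(ph)DK _" notation to the compact dialect
mq_to_compact <- function(s) {
  s <- gsub("^_|_$", "", s)
  nterm <- FALSE
  if (startsWith(s, "(ac)")) { nterm <- TRUE; s <- substring(s, 5L) }
  s <- gsub("S\\(ph\\)", "2", s)
  s <- gsub("T\\(ph\\)", "3", s)
  s <- gsub("Y\\(ph\\)", "4", s)
  s <- gsub("M\\(ox\\)", "1", s)
  paste0(if (nterm) "*" else "@", s)
}
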