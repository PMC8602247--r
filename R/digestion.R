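# In silico tryptic digestion and phosphosite-driven enumeration of
# phosphopeptide precursors from a proteome plus a site table.

#' Digestion configuration
#'
#' @param enzyme `"trypsin"` (cleaves C-terminal to K/R, suppressed
#'   before P) or `"trypsin/P"` (no proline suppression).
#' @param min_len,max_len Retained peptide length range.
#' @param missed_cleavages Number of allowed missed cleavages.
#' @param max_phospho_per_peptide Maximum phosphosites per enumerated form.
#' @param precursor_charges Charges assigned to each phosphopeptide.
#' @return A `digest_config` list.
#' @export
digest_config <- function(enzyme = c("trypsin", "trypsin/P"), min_len = 7L,
                          max_len = 30L, missed_cleavages = 0L,
                          max_phospho_per_peptide = 1L,
                          precursor_charges = c(2L, 3L, 4L)) {
  enzyme <- match.arg(enzyme)
  stopifnot(min_len <= max_len, missed_cleavages >= 0L,
            max_phospho_per_peptide >= 1L)
  structure(list(enzyme = enzyme, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 missed_cleavages = as.integer(missed_cleavages),
                 max_phospho_per_peptide = as.integer(max_phospho_per_peptide),
                 precursor_charges = as.integer(precursor_charges)),
            class = "digest_config")
}

# cleavage positions: indices i such that the bond after residue i is cut
cleavage_sites <- function(res, enzyme) {
  n <- length(res)
  if (n < 2L) return(integer())
  i <- which(res[-n] %in% c("K", "R"))
  if (enzyme == "trypsin") i <- i[res[i + 1L] != "P"]
  i
}

#' Tryptic in silico digestion
#'
#' Cleaves C-terminal to K/R (under rule `"trypsin"` cleavage before
#' proline is suppressed), supports missed cleavages, and drops peptides
#' outside the configured length range.
#'
#' @param sequence Protein sequence (string over the 20-letter alphabet).
#' @param cfg A [digest_config()].
#' @return Data frame with `peptide`, `start`, `end` (1-based inclusive
#'   protein coordinates).
#' @export
tryptic_digest <- function(sequence, cfg = digest_config()) {
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, AA_LETTERS)
  if (length(bad))
    stop("non-standard residue(s) in protein: ", paste(unique(bad), collapse = ","))
  n <- length(res)
  cuts <- c(0L, cleavage_sites(res, cfg$enzyme), n)
  out <- list()
  nseg <- length(cuts) - 1L
  for (i in seq_len(nseg)) {
    for (m in 0:cfg$missed_cleavages) {
      j <- i + m
      if (j > nseg) break
      s <- cuts[i] + 1L
      e <- cuts[j + 1L]
      len <- e - s + 1L
      if (len >= cfg$min_len && len <= cfg$max_len)
        out[[length(out) + 1L]] <- data.frame(
          peptide = paste(res[s:e], collapse = ""), start = s, end = e,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Enumerate phosphoforms of a digested peptide
#'
#' Generates one modified form per combination of registered
#' phosphosites falling inside the peptide, up to
#' `max_phospho_per_peptide` sites per form. Unmodified forms are not
#' emitted.
#'
#' @param peptide Peptide sequence (string).
#' @param start,end Protein coordinates of the peptide (1-based).
#' @param sites Integer vector of phosphosite positions on the protein.
#' @param site_residues Residue letters at those positions (checked
#'   against the peptide sequence).
#' @param cfg A [digest_config()].
#' @return List of `ModifiedPeptide` (possibly empty).
#' @export
enumerate_phosphoforms <- function(peptide, start, end, sites, site_residues,
                                   cfg = digest_config()) {
  res <- strsplit(peptide, "")[[1]]
  inside <- which(sites >= start & sites <= end)
  forms <- list()
  if (!length(inside)) return(forms)
  local <- sites[inside] - start + 1L
  for (k in seq_along(local)) {
    r <- res[local[k]]
    if (r != site_residues[inside[k]])
      stop("site residue mismatch at protein position ", sites[inside[k]],
           ": table says ", site_residues[inside[k]], ", sequence has ", r)
    if (!r %in% c("S", "T", "Y"))
      stop("registered phosphosite on non-S/T/Y residue ", r)
  }
  maxk <- min(cfg$max_phospho_per_peptide, length(local))
  ls <- sort(local)
  for (k in seq_len(maxk)) {
    combos <- lapply(utils::combn(seq_along(ls), k, simplify = FALSE),
                     function(ix) ls[ix])
    for (cmb in combos) {
      mods <- stats::setNames(rep("phospho", length(cmb)), as.character(cmb))
      forms[[length(forms) + 1L]] <- modified_peptide(
        res, mods, FALSE, min_len = cfg$min_len, max_len = cfg$max_len)
    }
  }
  forms
}

#' Read a UniProt-style FASTA proteome
#'
#' Accession is the second pipe-delimited field of the header when
#' present, else the first word.
#'
#' @param path FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  ids <- vapply(names(aa), function(h) {
    h <- strsplit(h, "\\s+")[[1]][1]
    parts <- strsplit(h, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) parts[2] else parts[1]
  }, "")
  stats::setNames(unname(seqs), unname(ids))
}

#' Read a phosphosite table
#'
#' TSV with columns `protein_id`, `position` (1-based on the protein)
#' and `residue` (S/T/Y).
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_site_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  df$position <- as.integer(df$position)
  df
}

#' Build phosphopeptide precursors from a proteome and a site table
#'
#' Digests every protein, enumerates phosphoforms at the registered
#' sites, deduplicates by modified sequence (protein ids of paralogous
#' origins concatenated) and emits each unique phosphopeptide at every
#' configured charge state.
#'
#' @param proteome Named character vector of protein sequences, or a
#'   FASTA path.
#' @param sites Site table data frame (see [read_site_table()]) or path.
#' @param cfg A [digest_config()].
#' @return Data frame with `modified_peptide` (compact), `charge`,
#'   `protein_ids`.
#' @export
build_sitedb_precursors <- function(proteome, sites, cfg = digest_config()) {
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome))
    proteome <- read_proteome_fasta(proteome)
  if (is.character(sites) && length(sites) == 1L && file.exists(sites))
    sites <- read_site_table(sites)
  shared <- intersect(names(proteome), unique(sites$protein_id))
  if (!length(shared))
    stop("no overlap between FASTA protein ids and site table")
  acc <- new.env(parent = emptyenv())  # compact -> protein id set
  for (pid in shared) {
    seqp <- proteome[[pid]]
    stab <- sites[sites$protein_id == pid, , drop = FALSE]
    peps <- tryCatch(tryptic_digest(seqp, cfg), error = function(e) {
      warning("skipping protein ", pid, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(peps) || !nrow(peps)) next
    for (r in seq_len(nrow(peps))) {
      forms <- enumerate_phosphoforms(peps$peptide[r], peps$start[r],
                                      peps$end[r], stab$position,
                                      stab$residue, cfg)
      for (f in forms) {
        key <- format_peptide(f, "compact")
        acc[[key]] <- union(if (is.null(acc[[key]])) character() else acc[[key]],
                            pid)
      }
    }
  }
  keys <- sort(ls(acc))
  if (!length(keys))
    return(data.frame(modified_peptide = character(), charge = integer(),
                      protein_ids = character(), stringsAsFactors = FALSE))
  out <- expand.grid(modified_peptide = keys, charge = cfg$precursor_charges,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$protein_ids <- vapply(out$modified_peptide,
                            function(k) paste(sort(acc[[k]]), collapse = ";"), "")
  out <- out[order(out$modified_peptide, out$charge), , drop = FALSE]
  rownames(out) <- NULL
  out
}
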