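# Parsing, validation and tokenization of modified phosphopeptides.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Digit tokens: compact modification encoding. Each digit stands for a
# modified residue and replaces the base letter at that position.
MOD_DIGITS <- c("1" = "M", "2" = "S", "3" = "T", "4" = "Y")
MOD_KINDS  <- c("1" = "oxidation", "2" = "phospho", "3" = "phospho", "4" = "phospho")
# Inverse map: residue + kind -> digit
mod_digit_for <- function(residue, kind) {
  if (kind == "oxidation") {
    if (residue != "M") stop("oxidation only allowed on M, got ", residue)
    return("1")
  }
  if (kind == "phospho") {
    d <- c(S = "2", T = "3", Y = "4")[residue]
    if (is.na(d)) stop("phospho only allowed on S/T/Y, got ", residue)
    return(unname(d))
  }
  stop("unknown modification kind: ", kind)
}

#' Construct a modified phosphopeptide
#'
#' The unit of prediction: a residue sequence over the 20 standard amino
#' acids with per-residue modification state (phospho on S/T/Y, oxidation
#' on M) and an N-terminal acetylation flag.
#'
#' @param residues Character vector of single amino-acid letters.
#' @param mods Named character vector: names are 1-based residue
#'   positions, values are `"phospho"` or `"oxidation"`.
#' @param nterm_acetyl Logical, N-terminal acetylation.
#' @param min_len,max_len Accepted length bounds (validation).
#' @param validate Check chemistry and length bounds (default `TRUE`).
#' @return An object of class `ModifiedPeptide`.
#' @export
modified_peptide <- function(residues, mods = character(), nterm_acetyl = FALSE,
                             min_len = 7L, max_len = 50L, validate = TRUE) {
  residues <- as.character(residues)
  if (length(residues) == 1L && nchar(residues[1]) > 1L)
    residues <- strsplit(residues, "")[[1]]
  mods <- as.character(mods) |> stats::setNames(names(mods))
  p <- structure(list(residues = residues, mods = mods,
                      nterm_acetyl = isTRUE(nterm_acetyl)),
                 class = "ModifiedPeptide")
  if (validate) validate_peptide(p, min_len = min_len, max_len = max_len)
  p
}

#' @export
print.ModifiedPeptide <- function(x, ...) {
  cat("<ModifiedPeptide> ", format_peptide(x), "  (n=", length(x$residues), ")\n",
      sep = "")
  invisible(x)
}

#' Validate a modified peptide
#'
#' Checks the residue alphabet, modification chemistry (phospho only on
#' S/T/Y, oxidation only on M), position uniqueness and length bounds.
#'
#' @inheritParams modified_peptide
#' @param p A `ModifiedPeptide`.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_peptide <- function(p, min_len = 7L, max_len = 50L) {
  stopifnot(inherits(p, "ModifiedPeptide"))
  n <- length(p$residues)
  bad <- setdiff(p$residues, AA_LETTERS)
  if (length(bad))
    stop("unknown residue token(s): ", paste(unique(bad), collapse = ", "))
  if (n < min_len || n > max_len)
    stop("peptide length ", n, " outside configured bounds [",
         min_len, ", ", max_len, "]")
  if (length(p$mods)) {
    pos <- as.integer(names(p$mods))
    if (anyNA(pos) || any(pos < 1L) || any(pos > n))
      stop("modification positions must be within 1..n")
    if (anyDuplicated(pos))
      stop("duplicate modification positions")
    for (k in seq_along(pos)) {
      r <- p$residues[pos[k]]
      kind <- p$mods[[k]]
      if (kind == "phospho" && !r %in% c("S", "T", "Y"))
        stop("phospho at position ", pos[k], " on residue ", r,
             " (only S/T/Y allowed)")
      if (kind == "oxidation" && r != "M")
        stop("oxidation at position ", pos[k], " on residue ", r,
             " (only M allowed)")
      if (!kind %in% c("phospho", "oxidation"))
        stop("unknown modification kind: ", kind)
    }
  }
  invisible(p)
}

#' Parse a compact modified-sequence string
#'
#' The compact dialect starts with `*` (N-terminally acetylated) or `@`
#' (free N-terminus) followed by one token per residue: an amino-acid
#' letter, or a digit for a modified residue (`1` = oxidized M, `2`/`3`/`4`
#' = phosphorylated S/T/Y).
#'
#' @param text Compact string, e.g. `"@A2DK"` for ASDK with phospho-S2.
#' @inheritParams modified_peptide
#' @return A `ModifiedPeptide`.
#' @export
#' @examples
#' parse_peptide("@LKSD2EFHK")
parse_peptide <- function(text, min_len = 7L, max_len = 50L, validate = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "")[[1]]
  if (length(ch) < 2L || !ch[1] %in% c("*", "@"))
    stop("compact string must begin with '*' or '@': ", text)
  nterm <- ch[1] == "*"
  body <- ch[-1]
  residues <- character(length(body))
  mods <- character(0)
  for (i in seq_along(body)) {
    tok <- body[i]
    if (tok %in% AA_LETTERS) {
      residues[i] <- tok
    } else if (tok %in% names(MOD_DIGITS)) {
      residues[i] <- MOD_DIGITS[[tok]]
      mods[as.character(i)] <- MOD_KINDS[[tok]]
    } else {
      stop("unknown token '", tok, "' in compact string: ", text)
    }
  }
  modified_peptide(residues, mods, nterm, min_len = min_len,
                   max_len = max_len, validate = validate)
}

#' Parse several compact strings
#' @param texts Character vector of compact strings.
#' @inheritParams parse_peptide
#' @return List of `ModifiedPeptide`.
#' @export
parse_peptides <- function(texts, min_len = 7L, max_len = 50L) {
  lapply(texts, parse_peptide, min_len = min_len, max_len = max_len)
}

#' Render a peptide in a library text dialect
#'
#' @param p A `ModifiedPeptide` (or compact string).
#' @param dialect `"compact"` (inverse of [parse_peptide()]) or
#'   `"bracket"` (underscore-delimited modified sequence with
#'   `[Phospho (STY)]`-style annotations, the form spectral-library TSVs
#'   carry).
#' @return A single string.
#' @export
#' @examples
#' format_peptide(parse_peptide("@A2DKLMNR"), "bracket")
format_peptide <- function(p, dialect = c("compact", "bracket")) {
  dialect <- match.arg(dialect)
  p <- as_peptide(p)
  pos <- as.integer(names(p$mods))
  if (dialect == "compact") {
    toks <- p$residues
    for (k in seq_along(pos))
      toks[pos[k]] <- mod_digit_for(p$residues[pos[k]], p$mods[[k]])
    return(paste0(if (p$nterm_acetyl) "*" else "@", paste(toks, collapse = "")))
  }
  ann <- c(phospho = "[Phospho (STY)]", oxidation = "[Oxidation (M)]")
  toks <- p$residues
  for (k in seq_along(pos))
    toks[pos[k]] <- paste0(p$residues[pos[k]], ann[[p$mods[[k]]]])
  paste0("_", if (p$nterm_acetyl) "[Acetyl (Protein N-term)]" else "",
         paste(toks, collapse = ""), "_")
}

#' Parse a bracket-dialect modified sequence
#'
#' Inverse of `format_peptide(p, "bracket")`. Accepts
#' `[Phospho (STY)]`, `[Oxidation (M)]` and a leading
#' `[Acetyl (Protein N-term)]`; surrounding underscores optional.
#'
#' @param text Bracket-dialect string.
#' @inheritParams parse_peptide
#' @return A `ModifiedPeptide`.
#' @export
parse_bracket <- function(text, min_len = 7L, max_len = 50L) {
  s <- gsub("^_|_$", "", text)
  nterm <- FALSE
  if (startsWith(s, "[Acetyl (Protein N-term)]")) {
    nterm <- TRUE
    s <- substring(s, nchar("[Acetyl (Protein N-term)]") + 1L)
  }
  residues <- character(0)
  mods <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substring(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substring(s, i), fixed = TRUE)
      if (j < 0) stop("unbalanced bracket in: ", text)
      ann <- substring(s, i, i + j - 1L)
      kind <- switch(ann,
                     "[Phospho (STY)]" = "phospho",
                     "[Oxidation (M)]" = "oxidation",
                     stop("unsupported modification annotation: ", ann))
      if (!length(residues)) stop("modification before any residue in: ", text)
      mods[as.character(length(residues))] <- kind
      i <- i + j
    } else {
      residues <- c(residues, ch)
      i <- i + 1L
    }
  }
  modified_peptide(residues, mods, nterm, min_len = min_len, max_len = max_len)
}

# Internal coercion: lenient length bounds (chemistry still checked),
# so worked examples and decoys shorter than the parse default pass.
as_peptide <- function(p) {
  if (inherits(p, "ModifiedPeptide")) return(p)
  if (is.character(p) && length(p) == 1L) {
    if (startsWith(p, "_") || grepl("[", p, fixed = TRUE))
      return(parse_bracket(p, min_len = 2L, max_len = 100L))
    return(parse_peptide(p, min_len = 2L, max_len = 100L))
  }
  stop("cannot interpret object of class ", paste(class(p), collapse = "/"),
       " as a ModifiedPeptide")
}

#' Stripped (unmodified) sequence of a peptide
#' @param p A `ModifiedPeptide` or compact string.
#' @return Plain amino-acid string.
#' @export
stripped_sequence <- function(p) paste(as_peptide(p)$residues, collapse = "")

# ---- token vocabulary ----------------------------------------------------

#' Model token vocabulary
#'
#' Fixed token-id assignment so trained checkpoints are portable:
#' the 20 amino acids in alphabetical order, the modified-residue digits
#' `1`-`4`, the N-terminal markers `*` and `@`, precursor-charge tokens
#' `+1`..`+6`, then the padding token.
#'
#' @return Named integer vector mapping token to id.
#' @export
token_vocab <- function() {
  toks <- c(AA_LETTERS, "1", "2", "3", "4", "*", "@",
            paste0("+", 1:6), "<pad>")
  stats::setNames(seq_along(toks), toks)
}

peptide_tokens <- function(p) {
  p <- as_peptide(p)
  toks <- p$residues
  pos <- as.integer(names(p$mods))
  for (k in seq_along(pos))
    toks[pos[k]] <- mod_digit_for(p$residues[pos[k]], p$mods[[k]])
  c(if (p$nterm_acetyl) "*" else "@", toks)
}

#' Encode a precursor for the fragment-intensity model
#'
#' Token-id sequence `[x0, x1..xn, +q]`: leading `*`/`@` marker, one token
#' per residue (digits for modified residues) and a trailing
#' precursor-charge token.
#'
#' @param p `ModifiedPeptide` or compact string.
#' @param charge Precursor charge.
#' @param allowed_charges Accepted charge states (default 1..6).
#' @return Integer vector of token ids, length `n + 2`.
#' @export
encode_ion_input <- function(p, charge, allowed_charges = 1:6) {
  charge <- as.integer(charge)
  if (!charge %in% allowed_charges)
    stop("charge ", charge, " outside allowed set {",
         paste(allowed_charges, collapse = ","), "}")
  v <- token_vocab()
  unname(v[c(peptide_tokens(p), paste0("+", charge))])
}

#' Encode a peptide for the retention-time model
#'
#' Same as [encode_ion_input()] without the charge token
#' (length `n + 1`).
#'
#' @inheritParams encode_ion_input
#' @return Integer vector of token ids.
#' @export
encode_rt_input <- function(p) {
  v <- token_vocab()
  unname(v[peptide_tokens(p)])
}

#' Read a peptide list
#'
#' Accepts either plain text (one compact string per line, optional
#' tab-separated charge) or a TSV with columns `ModifiedPeptide` and
#' `PrecursorCharge` (compact or bracket dialect).
#'
#' @param path File path.
#' @param default_charge Used when no charge column/field is present.
#' @return Data frame with columns `modified_peptide` (compact) and `charge`.
#' @export
read_peptide_list <- function(path, default_charge = 2L) {
  first <- readLines(path, n = 1L)
  if (grepl("ModifiedPeptide", first, fixed = TRUE)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    pep <- vapply(df$ModifiedPeptide,
                  function(s) format_peptide(as_peptide(s), "compact"), "")
    ch <- if ("PrecursorCharge" %in% names(df)) as.integer(df$PrecursorCharge)
          else rep(default_charge, nrow(df))
    return(data.frame(modified_peptide = unname(pep), charge = ch,
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  data.frame(
    modified_peptide = vapply(parts, `[[`, "", 1L),
    charge = vapply(parts, function(x)
      if (length(x) >= 2L) as.integer(x[2]) else as.integer(default_charge),
      integer(1)),
    stringsAsFactors = FALSE)
}
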