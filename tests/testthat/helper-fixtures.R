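# Shared fixture builders (everything generated in code at test time).

# random modified peptide via the generator, as a compact string
random_peptides <- function(n, seed, len = c(7, 14), noise = 0) {
  gen_peptides(synth_config(seed = seed, n_peptides = n, length_range = len,
                            spectrum_noise_sd = noise))
}

# brute-force mask oracle: enumerate each fragment's residue set and
# test phospho membership directly
oracle_mask <- function(p, L) {
  p <- phosphoDIA:::as_peptide(p)
  n <- length(p$residues)
  ppos <- as.integer(names(p$mods))[p$mods == "phospho"]
  ch <- ion_channels()
  m <- matrix(FALSE, L, 8)
  for (i in seq_len(L)) {
    if (i > n - 1) next
    for (c8 in 1:8) {
      span <- if (ch$series[c8] == "b") 1:i else (n - i + 1):n
      has_p <- any(ppos %in% span)
      m[i, c8] <- if (ch$loss[c8] == "H3PO4") has_p else TRUE
    }
  }
  m
}

# independent monoisotopic mass oracle (recomputed from scratch, not
# via fragment_mz): cumulative sums over an explicit mass list
oracle_fragment_mz <- function(p, series, z, loss, i) {
  p <- phosphoDIA:::as_peptide(p)
  mt <- mass_table()
  rm <- mt$residues[p$residues]
  pos <- as.integer(names(p$mods))
  for (k in seq_along(pos)) rm[pos[k]] <- rm[pos[k]] + mt$deltas[[p$mods[[k]]]]
  n <- length(rm)
  neutral <- if (series == "b") {
    sum(rm[1:i]) + (if (p$nterm_acetyl) mt$deltas[["nterm_acetyl"]] else 0)
  } else sum(rm[(n - i + 1):n]) + mt$water
  if (loss == "H3PO4") neutral <- neutral - mt$h3po4
  (neutral + z * mt$proton) / z
}

# brute-force digestion oracle: test every substring against the rule
oracle_digest <- function(seqc, enzyme, min_len, max_len) {
  res <- strsplit(seqc, "")[[1]]
  n <- length(res)
  is_cut <- function(i) {           # bond after residue i is cleaved
    if (i < 1 || i >= n) return(FALSE)
    if (!res[i] %in% c("K", "R")) return(FALSE)
    if (enzyme == "trypsin" && res[i + 1] == "P") return(FALSE)
    TRUE
  }
  out <- character(0)
  for (s in 1:n) for (e in s:n) {
    len <- e - s + 1
    if (len < min_len || len > max_len) next
    if (s > 1 && !is_cut(s - 1)) next
    if (e < n && !is_cut(e)) next
    if (e > s && any(vapply((s):(e - 1), is_cut, logical(1)))) next
    out <- c(out, paste(res[s:e], collapse = ""))
  }
  out
}

# a tiny trained ion model + rt ensemble shared by library tests; an
# untrained model is enough for structural library algebra (predictions
# only need to be deterministic, not accurate)
tiny_models <- function(max_len = 14, seed = 11) {
  list(ion = build_ion_model(reduced_ion_config(max_len = max_len), seed),
       rt = build_rt_ensemble(reduced_rt_config(max_len = max_len), seed))
}

# small predicted library fixture
tiny_library <- function(n = 8, seed = 21, max_len = 14) {
  prec <- random_peptides(n, seed, len = c(7, 12))
  m <- tiny_models(max_len)
  suppressWarnings(generate_predicted_library(
    prec, m$ion, m$rt, library_filters(intensity_floor = 0.01)))
}
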