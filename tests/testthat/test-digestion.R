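test_that("worked digestion examples match the rule", {
  d1 <- tryptic_digest("MAGKPLEDVIRSTK", digest_config(enzyme = "trypsin"))
  expect_equal(d1$peptide, "MAGKPLEDVIR")     # KP bond suppressed; STK too short
  expect_equal(c(d1$start, d1$end), c(1L, 11L))
  d2 <- tryptic_digest("MAGKPLEDVIRSTK", digest_config(enzyme = "trypsin/P"))
  expect_equal(d2$peptide, "PLEDVIR")         # MAGK and STK dropped by length
  # no K/R: one peptide iff length in range
  expect_equal(tryptic_digest("MAGHLEDVI", digest_config())$peptide, "MAGHLEDVI")
  expect_equal(nrow(tryptic_digest("MAGHLE", digest_config())), 0)
  expect_error(tryptic_digest("MAGXLEDVI", digest_config()), "non-standard")
})

test_that("digestion equals the brute-force oracle on random proteins", {
  set.seed(501)
  for (rep in 1:100) {
    n <- sample(40:120, 1)
    seqc <- paste(sample(phosphoDIA:::AA_LETTERS, n, replace = TRUE),
                  collapse = "")
    for (enz in c("trypsin", "trypsin/P")) {
      got <- tryptic_digest(seqc, digest_config(enzyme = enz))$peptide
      want <- oracle_digest(seqc, enz, 7, 30)
      expect_identical(sort(got), sort(want))
    }
  }
})

test_that("missed cleavages extend peptides across one boundary", {
  d <- tryptic_digest("AAAKGGGKCCCC", digest_config(enzyme = "trypsin/P",
                                                    min_len = 3, max_len = 30,
                                                    missed_cleavages = 1))
  expect_setequal(d$peptide, c("AAAK", "GGGK", "CCCC", "AAAKGGGK", "GGGKCCCC"))
})

test_that("trypsin/P digest partitions the protein", {
  set.seed(502)
  for (rep in 1:20) {
    n <- sample(50:150, 1)
    seqc <- paste(sample(phosphoDIA:::AA_LETTERS, n, replace = TRUE),
                  collapse = "")
    d <- tryptic_digest(seqc, digest_config(enzyme = "trypsin/P", min_len = 1,
                                            max_len = 1000))
    expect_identical(paste(d$peptide, collapse = ""), seqc)
    expect_identical(d$start, c(1L, utils::head(d$end, -1) + 1L))
  }
})

test_that("phosphoform enumeration follows the site table and the cap", {
  # peptide GSADTLKEF at protein positions 11..19, sites at 12 (S), 15 (T)
  cfg1 <- digest_config(max_phospho_per_peptide = 1)
  f1 <- enumerate_phosphoforms("GSADTLKEF", 11, 19, c(12L, 15L), c("S", "T"), cfg1)
  expect_length(f1, 2)
  expect_setequal(vapply(f1, format_peptide, ""), c("@G2ADTLKEF", "@GSAD3LKEF"))
  # no registered sites inside -> empty
  expect_length(enumerate_phosphoforms("GSADTLKEF", 11, 19, 99L, "S", cfg1), 0)
  # max 2 with 3 sites: C(3,1) + C(3,2) = 6 forms
  cfg2 <- digest_config(max_phospho_per_peptide = 2)
  f2 <- enumerate_phosphoforms("GSADTLYKE", 1, 9, c(2L, 5L, 7L),
                               c("S", "T", "Y"), cfg2)
  expect_length(f2, 6)
  expect_error(enumerate_phosphoforms("GSADTLKEF", 11, 19, 12L, "T", cfg1),
               "mismatch")
})

test_that("every emitted phosphoform is phosphorylated at a registered S/T/Y", {
  pw <- gen_proteome_with_sites(synth_config(seed = 503), n_proteins = 4)
  cfg <- digest_config(max_phospho_per_peptide = 2)
  prec <- build_sitedb_precursors(pw$proteome, pw$sites, cfg)
  expect_gt(nrow(prec), 0)
  expect_setequal(unique(prec$charge), c(2L, 3L, 4L))
  for (s in unique(prec$modified_peptide)) {
    p <- phosphoDIA:::as_peptide(s)
    pos <- as.integer(names(p$mods))[p$mods == "phospho"]
    expect_true(all(p$residues[pos] %in% c("S", "T", "Y")))
  }
  # each unique phosphopeptide appears at all three charges
  tab <- table(prec$modified_peptide)
  expect_true(all(tab == 3))
})

test_that("sitedb output is invariant to protein order and deduplicates", {
  pw <- gen_proteome_with_sites(synth_config(seed = 504), n_proteins = 5)
  a <- build_sitedb_precursors(pw$proteome, pw$sites)
  b <- build_sitedb_precursors(rev(pw$proteome), pw$sites)
  expect_identical(a[c("modified_peptide", "charge")],
                   b[c("modified_peptide", "charge")])
  # paralogous duplicate: same protein twice under two ids
  dup <- c(pw$proteome[1], pw$proteome[1])
  names(dup) <- c("P1", "P2")
  sites <- pw$sites[pw$sites$protein_id == names(pw$proteome)[1], ]
  if (nrow(sites)) {
    s2 <- rbind(transform(sites, protein_id = "P1"),
                transform(sites, protein_id = "P2"))
    d <- build_sitedb_precursors(dup, s2)
    expect_true(all(table(d$modified_peptide) == 3))   # dedup by sequence
    expect_true(all(grepl("P1;P2", d$protein_ids)))
  }
  expect_error(build_sitedb_precursors(pw$proteome,
                                       transform(pw$sites, protein_id = "NOPE")),
               "no overlap")
})

test_that("end-to-end precursor count equals a brute-force enumeration", {
  pw <- gen_proteome_with_sites(synth_config(seed = 505), n_proteins = 3)
  cfg <- digest_config()
  got <- nrow(build_sitedb_precursors(pw$proteome, pw$sites, cfg))
  forms <- character(0)
  for (pid in names(pw$proteome)) {
    stab <- pw$sites[pw$sites$protein_id == pid, ]
    peps <- oracle_digest(pw$proteome[[pid]], "trypsin", 7, 30)
    res <- strsplit(pw$proteome[[pid]], "")[[1]]
    # locate each oracle peptide in the protein (may repeat)
    for (pep in peps) {
      hits <- gregexpr(pep, pw$proteome[[pid]], fixed = TRUE)[[1]]
      for (s in hits) {
        e <- s + nchar(pep) - 1
        for (k in seq_len(nrow(stab))) {
          if (stab$position[k] >= s && stab$position[k] <= e) {
            loc <- stab$position[k] - s + 1
            toks <- strsplit(pep, "")[[1]]
            toks[loc] <- c(S = "2", T = "3", Y = "4")[toks[loc]]
            forms <- c(forms, paste0("@", paste(toks, collapse = "")))
          }
        }
      }
    }
  }
  expect_equal(got, length(unique(forms)) * 3)
})

test_that("FASTA and site tables read back correctly", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P12345|TEST_HUMAN Some protein", "MAGKPLEDVIRSTK",
               ">Q99999", "GSADTLKEFR"), fa)
  prot <- read_proteome_fasta(fa)
  expect_identical(names(prot), c("P12345", "Q99999"))
  expect_identical(unname(prot[1]), "MAGKPLEDVIRSTK")
  st <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition\tresidue", "P12345\t12\tS"), st)
  tab <- read_site_table(st)
  expect_identical(tab$position, 12L)
  expect_error(read_site_table(fa), "columns")
})
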