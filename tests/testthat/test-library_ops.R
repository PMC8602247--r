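test_that("predicted library generation applies the filter stages", {
  prec <- random_peptides(10, seed = 601, len = c(7, 12))
  m <- tiny_models()
  lib <- suppressWarnings(generate_predicted_library(
    prec, m$ion, m$rt, library_filters(intensity_floor = 0.01)))
  expect_s3_class(lib, "SpectralLibrary")
  expect_lte(library_size(lib), nrow(prec))
  expect_true(all(lib$peaks$mz >= 200 & lib$peaks$mz <= 2000))
  expect_true(all(lib$entries$source == "predicted"))
  # a precursor m/z window that excludes everything empties the library
  lib0 <- suppressWarnings(generate_predicted_library(
    prec, m$ion, m$rt, library_filters(precursor_mz_range = c(1, 2))))
  expect_equal(library_size(lib0), 0)
  # top-n cap limits per-entry peaks
  lib3 <- suppressWarnings(generate_predicted_library(
    prec, m$ion, m$rt, library_filters(top_n = 3, intensity_floor = 0.01)))
  expect_true(all(table(lib3$peaks$key) <= 3))
})

test_that("iRT calibration recovers a known line", {
  lib <- tiny_library()
  # observed RT on an exact line rt = 2*irt + 10
  obs <- data.frame(modified_peptide = lib$entries$modified_peptide,
                    rt = 2 * lib$entries$irt + 10)
  cal <- calibrate_irt(lib, obs)
  expect_equal(cal$fit$slope, 2, tolerance = 1e-9)
  expect_equal(cal$fit$intercept, 10, tolerance = 1e-9)
  expect_equal(cal$fit$r2, 1, tolerance = 1e-9)
  expect_equal(cal$library$entries$irt, 2 * lib$entries$irt + 10)
  # identity pairs
  cal2 <- calibrate_irt(lib, transform(obs, rt = lib$entries$irt))
  expect_equal(cal2$fit$slope, 1, tolerance = 1e-9)
  expect_equal(cal2$fit$intercept, 0, tolerance = 1e-6)
  # noisy line recovered within standard-error bounds
  set.seed(6)
  x <- runif(100, 0, 100)
  libN <- lib
  libN$entries <- do.call(rbind, replicate(13, lib$entries, simplify = FALSE))
  libN$entries$modified_peptide <- sprintf("@PEPT%03dIDEK", 1:104)
  libN$entries$irt <- c(x, runif(4))
  libN$entries$key <- phosphoDIA:::entry_key(libN$entries$modified_peptide,
                                             libN$entries$charge)
  obsN <- data.frame(modified_peptide = libN$entries$modified_peptide[1:100],
                     rt = 1.5 * x + 20 + rnorm(100, 0, 2))
  fitN <- stats::lm(rt ~ irt,
                    data = merge(libN$entries[, c("modified_peptide", "irt")],
                                 obsN, by = "modified_peptide"))
  se <- summary(fitN)$coefficients[, "Std. Error"]
  calN <- calibrate_irt(libN, obsN)
  expect_lt(abs(calN$fit$slope - 1.5), 4 * se["irt"])
  expect_lt(abs(calN$fit$intercept - 20), 4 * se["(Intercept)"])
  expect_error(calibrate_irt(lib, obs[1:2, ]), "at least 3")
})

test_that("hybrid merge keeps experimental entries on collision", {
  lib <- tiny_library(n = 8, seed = 602)
  # a 'direct DIA' library: 2 precursors of its own plus 3 shared keys
  dia <- tiny_library(n = 5, seed = 999)
  dia$entries$source <- "direct_DIA"
  keep <- lib$entries$key[1:3]
  for (i in 1:3) {
    old <- dia$entries$key[i]
    dia$entries$modified_peptide[i] <- lib$entries$modified_peptide[i]
    dia$entries$charge[i] <- lib$entries$charge[i]
    dia$entries$key[i] <- keep[i]
    dia$peaks$key[dia$peaks$key == old] <- keep[i]
  }
  dia_e <- dia$entries[1:3, ]
  dia <- spectral_library(dia$entries, dia$peaks, "direct-dia")
  hyb <- merge_hybrid(dia, lib)
  expect_equal(library_size(hyb), 2 + 8)        # union of keys
  shared <- hyb$entries[hyb$entries$key %in% keep, ]
  expect_true(all(shared$source == "direct_DIA"))     # experimental wins
  expect_equal(shared$irt, dia_e$irt)
  # idempotence
  hyb2 <- merge_hybrid(hyb, lib)
  expect_equal(hyb2$entries[order(hyb2$entries$key), ],
               hyb$entries[order(hyb$entries$key), ], ignore_attr = TRUE)
})

test_that("focused libraries subset predictions and keep experimental whole", {
  lib <- tiny_library(n = 8, seed = 603)
  ids <- lib$entries$key[1:3]
  foc <- build_focused(lib, ids, keep_experimental_whole = TRUE)
  expect_equal(sort(foc$entries$key), sort(ids))
  expect_lte(library_size(foc), library_size(lib))
  # hybrid: experimental stays whole
  exp_lib <- lib
  exp_lib$entries$source[4:8] <- "direct_DIA"
  foc2 <- build_focused(exp_lib, ids, keep_experimental_whole = TRUE)
  expect_equal(library_size(foc2), 3 + 5)
  foc3 <- build_focused(exp_lib, ids, keep_experimental_whole = FALSE)
  expect_equal(sort(foc3$entries$key), sort(ids))
  expect_warning(build_focused(lib, c(ids, "@NOTINLIB|2")), "not in the initial")
  expect_error(suppressWarnings(build_focused(lib, "@NOTINLIB|2")), "empty")
})

test_that("reverse-decoy rule fixes the C-terminus and moves mods", {
  expect_identical(format_peptide(reverse_peptide("@ASDEFK")), "@FEDSAK")
  expect_identical(format_peptide(reverse_peptide("@A2DK")), "@D2AK")
  prec <- random_peptides(100, seed = 604)
  for (s in prec$modified_peptide) {
    p <- phosphoDIA:::as_peptide(s)
    r <- reverse_peptide(p)
    n <- length(p$residues)
    expect_identical(r$residues[n], p$residues[n])              # C-term fixed
    expect_identical(sort(r$residues), sort(p$residues))        # composition
    expect_identical(r$nterm_acetyl, p$nterm_acetyl)
    expect_identical(sort(unname(r$mods)), sort(unname(p$mods)))
    for (k in seq_along(r$mods)) {                              # mods travel
      pos <- as.integer(names(r$mods)[k])
      expect_true((r$mods[k] == "phospho" &&
                     r$residues[pos] %in% c("S", "T", "Y")) ||
                    (r$mods[k] == "oxidation" && r$residues[pos] == "M"))
    }
    expect_identical(format_peptide(reverse_peptide(r)), s)     # involution
  }
  expect_error(reverse_peptide(modified_peptide("A", min_len = 1,
                                                validate = FALSE)), "length")
})

test_that("decoy-appended libraries double the size and keep charges", {
  lib <- tiny_library(n = 8, seed = 605)
  m <- tiny_models()
  dl <- build_decoy_appended_library(lib, m$ion, m$rt,
                                     library_filters(intensity_floor = 0.01))
  dec <- dl$entries[dl$entries$source == "decoy", ]
  tar <- dl$entries[dl$entries$source != "decoy", ]
  expect_equal(nrow(tar), library_size(lib))
  expect_lte(nrow(dec), nrow(tar))
  expect_equal(library_size(dl), nrow(tar) + nrow(dec))
  # every decoy charge equals its target's charge
  rev_of <- vapply(tar$modified_peptide,
                   function(s) format_peptide(reverse_peptide(s)), "")
  m2 <- match(dec$modified_peptide, rev_of)
  expect_false(anyNA(m2))
  expect_equal(dec$charge, tar$charge[m2])
})

test_that("entrapment combination records sizes and drops overlaps", {
  main <- tiny_library(n = 8, seed = 606)
  ent <- tiny_library(n = 5, seed = 607)
  # force one overlap
  ent$entries$modified_peptide[1] <- main$entries$modified_peptide[1]
  ent$entries$key[1] <- phosphoDIA:::entry_key(ent$entries$modified_peptide[1],
                                               ent$entries$charge[1])
  ent$peaks$key[ent$peaks$key == ent$peaks$key[1]] <- ent$entries$key[1]
  two <- build_entrapment_library(main, ent, "human", "arabidopsis")
  sizes <- attr(two, "libsizes")
  expect_equal(unname(sizes["main"]), 8)
  expect_equal(unname(sizes["entrapment"]), 4)
  expect_equal(attr(two, "entrapment_overlap"), 1)
  expect_equal(library_size(two), 12)
  # size metadata equals recount from the merged library
  expect_equal(unname(sizes["main"]),
               length(unique(two$entries$modified_peptide[
                 two$entries$species == "human"])))
  expect_error(build_entrapment_library(main, ent, "x", "x"), "distinct")
})

test_that("filter tightening is monotone over a screening grid", {
  prec <- random_peptides(12, seed = 608, len = c(7, 12))
  m <- tiny_models()
  grid <- list(
    library_filters(intensity_floor = 0.01),
    library_filters(intensity_floor = 0.01, length_range = c(7, 10)),
    library_filters(intensity_floor = 0.01, length_range = c(7, 10),
                    charges = 2L),
    library_filters(intensity_floor = 0.2, length_range = c(7, 10),
                    charges = 2L),
    library_filters(intensity_floor = 0.2, length_range = c(7, 10),
                    charges = 2L, fragment_mz_range = c(300, 900)))
  res <- screen_parameter_grid(prec, grid, m$ion, m$rt)
  expect_equal(nrow(res), 5)
  expect_true(all(diff(res$entries) <= 0))
  expect_true(all(diff(res$peaks) <= 0))
  expect_error(screen_parameter_grid(prec, list(), m$ion, m$rt), "empty")
})

test_that("library TSV round-trips all fields to 4 decimals", {
  lib <- tiny_library(n = 6, seed = 609)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_library_tsv(lib, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr, phosphoDIA:::LIB_TSV_COLS)
  expect_equal(length(readLines(f)) - 1, nrow(lib$peaks))
  back <- read_library_tsv(f)
  expect_equal(library_size(back), library_size(lib))
  ord <- function(x) x[order(x$key, x$series, x$fragment_number,
                             x$frag_charge, x$loss), ]
  a <- ord(lib$peaks); b <- ord(back$peaks)
  expect_equal(a$mz, b$mz, tolerance = 1e-4)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-4)
  expect_identical(a$series, b$series)
  expect_identical(a$loss, b$loss)
  e1 <- lib$entries[order(lib$entries$key), ]
  e2 <- back$entries[order(back$entries$key), ]
  expect_equal(e1$precursor_mz, e2$precursor_mz, tolerance = 1e-4)
  expect_equal(e1$irt, e2$irt, tolerance = 1e-4)
  expect_identical(e1$source, e2$source)
  # a second round-trip is exact (fixed-point of the 4-decimal rendering)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_library_tsv(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed TSVs are rejected with diagnostics", {
  lib <- tiny_library(n = 4, seed = 610)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_library_tsv(lib, f)
  df <- utils::read.delim(f, check.names = FALSE)
  # missing mandatory column
  f1 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[, -1], f1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_library_tsv(f1), "PrecursorMz")
  # H3PO4 loss on a phospho-free fragment
  df2 <- df
  df2$ModifiedPeptide <- gsub("\\[Phospho \\(STY\\)\\]", "", df2$ModifiedPeptide)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  if (any(df2$FragmentLossType == "H3PO4")) {
    expect_error(read_library_tsv(f2), "H3PO4")
  }
})

test_that("identification tables filter strictly above 0.75 localization", {
  cfgs <- synth_config(seed = 611, n_peptides = 10, length_range = c(7, 10))
  prec <- gen_peptides(cfgs)
  sp <- gen_ground_truth_spectra(prec, cfgs)
  rts <- gen_ground_truth_rt(prec$modified_peptide, cfgs)
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- gen_identification_tables(prec, sp, rts, f, cfgs, fraction_below = 0.3)
  lib <- read_id_table(f, "normalized")
  expect_equal(library_size(lib), nrow(prec) - attr(out, "n_below"))
  expect_true(all(lib$entries$localization > 0.75))
  # the 0.75 boundary itself is excluded (strict >)
  df <- utils::read.delim(f, check.names = FALSE)
  df$LocalizationProb <- 0.75
  f3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_id_table(f3, "normalized"), "survive")
  # fraction_below = 0 keeps everything
  f4 <- withr::local_tempfile(fileext = ".tsv")
  gen_identification_tables(prec, sp, rts, f4, cfgs, fraction_below = 0)
  expect_equal(library_size(read_id_table(f4, "normalized")), nrow(prec))
})

test_that("maxquant-style adapter parses its documented column subset", {
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(
    ModifiedSequence = c("_AS(ph)DKLMNR_", "_(ac)M(ox)AGKLSTR_"),
    Charge = c(2L, 3L), RetentionTime = c(30.5, 55.1),
    LocalizationProb = c(0.99, 0.60),
    Matches = c("y2;b3;b4-H3PO4;w9", "y3;b2(2+)"),
    Intensities = c("100;50;30;10", "200;80"),
    stringsAsFactors = FALSE), f, sep = "\t", quote = FALSE, row.names = FALSE)
  lib <- read_id_table(f, "maxquant_msms")
  # second entry fails the localization filter; 'w9' is outside the space
  expect_equal(library_size(lib), 1)
  expect_identical(lib$entries$modified_peptide, "@A2DKLMNR")
  expect_equal(nrow(lib$peaks), 3)
  expect_equal(max(lib$peaks$intensity), 1)   # per-entry renormalization
})

test_that("library transforms never mutate their inputs", {
  lib <- tiny_library(n = 6, seed = 612)
  snap <- list(entries = lib$entries, peaks = lib$peaks)
  ids <- lib$entries$key[1:2]
  invisible(build_focused(lib, ids))
  m <- tiny_models()
  invisible(build_decoy_appended_library(lib, m$ion, m$rt,
                                         library_filters(intensity_floor = 0.01)))
  invisible(merge_hybrid(lib, tiny_library(n = 3, seed = 613)))
  expect_identical(lib$entries, snap$entries)
  expect_identical(lib$peaks, snap$peaks)
})
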